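test_that("forward map is the literal affine chain", {
  cfg <- model_config(2L, 2L, n_hidden = 0L, dropout_rate = 0, seed = 1)
  m <- init_model(cfg)
  m$layers[[1]]$W <- diag(2)
  m$layers[[1]]$b <- c(0, 0)
  expect_equal(nnod_forward(m, c(1, -1)), c(1, -1))

  # rectifier with all-negative pre-activations passes only the output bias
  cfg1 <- model_config(2L, 3L, n_hidden = 1L, hidden_width = 4L,
                       activation = "rectifier", dropout_rate = 0, seed = 2)
  m1 <- init_model(cfg1)
  m1$layers[[1]]$W <- matrix(-1, 4, 2)
  m1$layers[[1]]$b <- rep(-5, 4)
  m1$layers[[2]]$b <- c(7, -2, 0.5)
  expect_equal(nnod_forward(m1, c(1, 2)), c(7, -2, 0.5))

  # random small models against an independent affine-chain oracle
  withr::with_seed(5, {
    for (nh in 0:3) {
      cfg_r <- model_config(4L, 3L, n_hidden = nh, hidden_width = 5L,
                            activation = "rectifier", dropout_rate = 0,
                            seed = nh + 10L)
      mr <- init_model(cfg_r)
      x <- stats::rnorm(4)
      expect_equal(nnod_forward(mr, x), oracle_forward(mr, x),
                   tolerance = 1e-6)
    }
  })
  expect_error(nnod_forward(m, c(1, 2, 3)), "dimension")
})

test_that("output links give calibrated probabilities", {
  cfg <- model_config(2L, 3L, n_hidden = 0L, output_mode = "binary",
                      dropout_rate = 0, seed = 1)
  m <- init_model(cfg)
  m$layers[[1]]$W <- matrix(0, 3, 2)
  m$layers[[1]]$b <- c(0, 1, 10)
  p <- predict_binary(m, c(0, 0))
  expect_equal(p[1], 0.5)
  expect_equal(p[2], 0.7310586, tolerance = 1e-6)
  expect_true(all(p > 0 & p < 1))
  expect_true(p[3] > p[2] && p[2] > p[1])   # sigmoid monotone in the logit
  expect_error(predict_multinomial(m, c(0, 0)), "multinomial")

  cfgm <- model_config(2L, 3L, n_hidden = 0L, output_mode = "multinomial",
                       dropout_rate = 0, seed = 1)
  mm <- init_model(cfgm)
  mm$layers[[1]]$W <- matrix(0, 3, 2)
  mm$layers[[1]]$b <- c(0, 0, 0)
  expect_equal(predict_multinomial(mm, c(0, 0)), rep(1 / 3, 3))
  mm$layers[[1]]$b <- c(1, 2, 3)
  expect_equal(predict_multinomial(mm, c(0, 0)),
               c(0.0900306, 0.2447285, 0.6652410), tolerance = 1e-6)
  mm$layers[[1]]$b <- c(1, 2, 3) + 100     # softmax shift invariance
  expect_equal(predict_multinomial(mm, c(0, 0)),
               c(0.0900306, 0.2447285, 0.6652410), tolerance = 1e-6)
  expect_error(predict_binary(mm, c(0, 0)), "binary")
})

test_that("losses reproduce hand-computed values and invariances", {
  expect_equal(loss_binary(c(1, 0), c(0.5, 0.5)), 2 * log(2),
               tolerance = 1e-12)
  expect_lt(loss_binary(c(1, 0), c(1 - 1e-7, 1e-7)), 1e-5)
  # coordinate-wise improvement lowers the loss
  expect_gt(loss_binary(c(1, 0), c(0.5, 0.5)),
            loss_binary(c(1, 0), c(0.7, 0.5)))
  expect_gt(loss_binary(c(1, 0), c(0.7, 0.5)),
            loss_binary(c(1, 0), c(0.7, 0.3)))
  expect_error(loss_binary(c(1, 0), c(0.5, 0.5, 0.5)), "mismatch")

  expect_equal(loss_multinomial(c(1, 1, 0), c(0.5, 0.5, 0)), log(2),
               tolerance = 1e-6)
  expect_lt(loss_multinomial(c(1, 0, 0), c(1 - 2e-7, 1e-7, 1e-7)), 1e-5)
  # scaling the label vector changes nothing (normalization)
  expect_equal(loss_multinomial(c(3, 3, 0), c(0.5, 0.5, 0)),
               loss_multinomial(c(1, 1, 0), c(0.5, 0.5, 0)))
  expect_error(loss_multinomial(c(0, 0, 0), c(0.3, 0.3, 0.4)), "all-zero")

  # multinomial with one positive equals categorical cross-entropy
  p <- c(0.2, 0.5, 0.3)
  expect_equal(loss_multinomial(c(0, 1, 0), p), -log(0.5), tolerance = 1e-9)

  # elastic-net penalty: hand value, null case, sign invariance
  expect_identical(regularization(list(matrix(0, 2, 2)), 0.5, 0.5), 0)
  expect_equal(regularization(list(matrix(2, 1, 1)), 0.001, 0.001), 0.006)
  W <- matrix(c(1, -2, 3, -4), 2)
  expect_equal(regularization(list(W), 0.01, 0.02),
               regularization(list(-W), 0.01, 0.02))
})

test_that("binary loss equals the sum of independent one-label cross-entropies", {
  withr::with_seed(7, {
    y <- stats::rbinom(6, 1, 0.5)
    p <- stats::runif(6, 0.05, 0.95)
  })
  one_label <- vapply(seq_along(y), function(l) {
    -(y[l] * log(p[l]) + (1 - y[l]) * log(1 - p[l]))
  }, 0)
  expect_equal(loss_binary(y, p), sum(one_label), tolerance = 1e-12)
})

test_that("analytic gradients match central finite differences everywhere", {
  withr::with_seed(42, {
    for (mode in c("binary", "multinomial")) {
      for (act in c("identity", "rectifier")) {
        for (nh in 0:3) {
          cfg <- model_config(5L, 4L, n_hidden = nh, hidden_width = 6L,
                              activation = act, output_mode = mode,
                              l1_weight = 0.01, l2_weight = 0.02,
                              dropout_rate = 0, seed = nh + 3L)
          m <- init_model(cfg)
          X <- matrix(stats::rnorm(8 * 5), 8)
          Y <- matrix(stats::rbinom(8 * 4, 1L, 0.4), 8)
          Y[rowSums(Y) == 0, 1] <- 1L
          expect_lt(fd_gradient_check(m, X, Y), 1e-4)
        }
      }
    }
  })
})

test_that("training solves a separable problem and is reproducible", {
  withr::with_seed(30, {
    n <- 120
    cls <- stats::rbinom(n, 1, 0.5)
    X <- cbind(cls * 2 - 1 + stats::rnorm(n, 0, 0.1),
               stats::rnorm(n, 0, 0.5))
    Y <- cbind(a = cls, b = 1L - cls)
  })
  cfg <- model_config(2L, 2L, n_hidden = 0L, l1_weight = 0, l2_weight = 0,
                      dropout_rate = 0, seed = 4)
  fit <- train_nnod(cfg, X, Y, epochs = 60L, learning_rate = 1e-2)
  hist <- attr(fit, "loss_history")
  expect_true(all(diff(hist[1:10]) < 0))    # early epochs strictly improve
  expect_equal(per_label_auc(Y, predict_scores(fit, X))$macro_auc, 1.0)

  fit2 <- train_nnod(cfg, X, Y, epochs = 60L, learning_rate = 1e-2)
  expect_identical(fit$layers, fit2$layers)  # bit-identical, seeded
})

test_that("unregularized 0-hidden training matches an off-the-shelf logistic fit", {
  withr::with_seed(31, {
    n <- 200
    X <- matrix(stats::rnorm(n * 4), n)
    z <- X %*% c(1.5, -1, 0.5, 0)
    Y <- cbind(l1 = as.integer(z + stats::rnorm(n, 0, 0.8) > 0),
               l2 = as.integer(-z + stats::rnorm(n, 0, 0.8) > 0))
  })
  cfg <- model_config(4L, 2L, n_hidden = 0L, l1_weight = 0, l2_weight = 0,
                      dropout_rate = 0, seed = 6)
  fit <- train_nnod(cfg, X, Y, epochs = 200L, learning_rate = 1e-2)
  ours <- per_label_auc(Y, predict_scores(fit, X))$macro_auc
  ref <- mean(vapply(1:2, function(l) {
    gm <- glmnet::glmnet(X, Y[, l], family = "binomial", lambda = 0)
    auc_ref <- per_label_auc(Y[, l, drop = FALSE],
                             stats::predict(gm, X))$macro_auc
    auc_ref
  }, 0))
  expect_lt(abs(ours - ref), 0.02)
})

test_that("stronger l1 shrinks the converged weight mass in the convex case", {
  withr::with_seed(32, {
    n <- 150
    X <- matrix(stats::rnorm(n * 5), n)
    Y <- cbind(y = as.integer(X[, 1] - X[, 2] + stats::rnorm(n, 0, 0.5) > 0))
  })
  norms <- vapply(c(0, 0.01, 0.1, 1), function(l1) {
    cfg <- model_config(5L, 1L, n_hidden = 0L, l1_weight = l1, l2_weight = 0,
                        dropout_rate = 0, seed = 8)
    fit <- train_nnod(cfg, X, Y, epochs = 150L, learning_rate = 1e-2)
    sum(abs(fit$layers[[1]]$W))
  }, 0)
  expect_true(all(diff(norms) <= 1e-6))
})

test_that("grid search selects by validation macro AUC with stable ties", {
  fx <- xor_fixture(300, 3)
  val <- xor_fixture(150, 4)
  base <- model_config(8L, 2L, n_hidden = 0L, l1_weight = 0, l2_weight = 0,
                       dropout_rate = 0, seed = 2)
  single <- grid_search_nnod(list(base), fx$X, fx$Y, val$X, val$Y,
                             epochs = 30L, learning_rate = 1e-2)
  expect_identical(single$best_config, base)
  expect_identical(nrow(single$scores), 1L)

  crushed <- base
  crushed$l1_weight <- 1e3
  gs <- grid_search_nnod(list(base, crushed), fx$X, fx$Y, val$X, val$Y,
                         epochs = 30L, learning_rate = 1e-2)
  expect_identical(nrow(gs$scores), 2L)
  expect_identical(gs$best_config$l1_weight, 0)   # over-penalized never wins
})

test_that("model checkpoints round-trip through JSON", {
  cfg <- model_config(3L, 2L, n_hidden = 1L, hidden_width = 4L, seed = 9)
  m <- init_model(cfg)
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m, path)
  back <- read_model(path)
  expect_equal(back$layers, m$layers, tolerance = 1e-12)
  x <- c(0.3, -1, 2)
  expect_equal(nnod_forward(back, x), nnod_forward(m, x), tolerance = 1e-12)
})
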