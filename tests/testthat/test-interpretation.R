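test_that("linear-model sensitivity is the back-projected weight row", {
  grid <- small_grid()
  d <- generate_dictionary(6L, grid, seed = 3)
  cfg <- model_config(6L, 2L, n_hidden = 0L, dropout_rate = 0, seed = 3)
  m <- init_model(cfg)
  m$vocabulary <- c("cA", "cB")
  withr::with_seed(9, X <- matrix(stats::rnorm(30), 5, 6))
  sm <- sensitivity_map(m, X, d, "cB")
  expect_identical(sm$kind, "decoding")
  expect_equal(mask_values(sm$volume),
               mask_values(back_project(m$layers[[1]]$W[2, ], d)),
               tolerance = 1e-10)
  # gradient of an affine map cannot depend on the inputs
  withr::with_seed(10, X2 <- matrix(stats::rnorm(60), 10, 6))
  expect_equal(mask_values(sensitivity_map(m, X2, d, "cB")$volume),
               mask_values(sm$volume), tolerance = 1e-10)
  expect_error(sensitivity_map(m, X, d, "missing"), "vocabulary")
})

test_that("back-projection is linear and one-hot gradients recover components", {
  grid <- small_grid()
  d <- generate_dictionary(5L, grid, seed = 4)
  g1 <- c(1, 0, 0, 0, 0)
  g2 <- c(0, 0, 2, 0, 0)
  expect_equal(mask_values(back_project(g1 + g2, d)),
               mask_values(back_project(g1, d)) +
                 mask_values(back_project(g2, d)))
  # one-hot on component 3 gives component 3's map up to the scale 2
  expect_equal(mask_values(back_project(g2, d)),
               2 * d$components[3, ])
})

test_that("sensitivity concentrates on the generating signature", {
  # each concept recruits 3 components with loadings in [0.5, 1.5]; the
  # top-5 average gradient should recover most of that support (the
  # faintest component of a network can legitimately fall outside)
  fm <- fitted_standard_model()
  sig <- fm$fx$signatures
  top5_hits <- function(cid, positives_of = NULL) {
    sm <- sensitivity_map(fm$fit, fm$Xp[fm$ids, ], fm$fx$dicts, cid,
                          positives_of = positives_of)
    g <- attr(sm, "gradient")
    sum(order(-abs(g))[1:5] %in% which(sig[, cid] > 0))
  }
  hits_all <- vapply(colnames(fm$fx$Y), top5_hits, 0)
  # averaged over all maps, discriminative down-weighting of networks
  # shared through the hierarchy can hide part of a support
  expect_true(all(hits_all >= 1))
  expect_gte(mean(hits_all), 2)
  # averaged over the concept's positives, the network is recovered
  hits_pos <- vapply(colnames(fm$fx$Y), top5_hits, 0,
                     positives_of = fm$fx$Y)
  expect_true(all(hits_pos >= 2))
  expect_gte(mean(hits_pos), 2.5)
})

test_that("encoding regression recovers per-component effects", {
  # single concept, loadings = a + b*y + noise: coefficient ~ b
  withr::with_seed(12, {
    n <- 120
    y <- stats::rbinom(n, 1L, 0.5)
    b <- c(2, -1, 0.5, 0, 3)
    X <- outer(rep(1, n), c(1, 1, 1, 1, 1)) + outer(y, b) +
      matrix(stats::rnorm(n * 5, 0, 0.1), n)
  })
  grid <- small_grid()
  d <- generate_dictionary(5L, grid, seed = 5)
  Y <- matrix(y, ncol = 1, dimnames = list(paste0("m", 1:120), "c1"))
  rownames(X) <- rownames(Y)
  em <- encoding_map(X, Y, d, "c1")
  expect_identical(em$kind, "encoding")
  expect_equal(mask_values(em$volume), mask_values(back_project(b, d)),
               tolerance = 0.2)

  # concept uncorrelated with the loadings: coefficients near zero
  withr::with_seed(13, {
    Y2 <- cbind(Y, c2 = stats::rbinom(120, 1L, 0.5))
    Xn <- matrix(stats::rnorm(120 * 5, 0, 0.1), 120,
                 dimnames = list(rownames(Y), NULL))
  })
  em0 <- encoding_map(Xn, Y2, d, "c2")
  expect_lt(max(abs(mask_values(em0$volume))), 0.2)

  expect_error(encoding_map(X, Y * 0L, d, "c1"), "no positive")
})

test_that("noiseless encoding recovers effect-size-scaled signatures", {
  grid <- small_grid()
  d <- generate_dictionary(10L, grid, seed = 7)
  ont <- generate_ontology(6L, 0L, max_depth = 1L, seed = 7)
  cfg <- synth_config(n_collections = 1L, maps_per_collection = 60L,
                      noise_sd = 0, baseline_shift_sd = 0,
                      annotation_noise = list(synonym = 0, abbrev = 0,
                                              typo = 0, omit = 0),
                      contaminant_rates = list(thresholded = 0,
                                               low_coverage = 0,
                                               wrong_modality = 0),
                      map_type_probs = c(z = 1, t = 0, beta = 0), seed = 7)
  maps <- generate_repository(ont, d, cfg)
  sig <- attr(maps, "signatures")
  X <- embed_repository(maps, d, positive = FALSE)
  Y <- hypernym_close(extract_exact_labels(maps, ont, ont$concepts$id), ont)
  em <- encoding_map(X[rownames(Y), ], Y, d, "c002")
  expect_equal(mask_values(em$volume),
               mask_values(back_project(cfg$concept_effect_size * sig[, "c002"],
                                        d)),
               tolerance = 1e-6)
})

test_that("display thresholding keeps exactly the top quantile and is idempotent", {
  grid <- make_grid(c(5L, 5L, 4L), mask = array(TRUE, c(5, 5, 4)))
  withr::with_seed(14, v <- sample(seq_len(100)) / 10)   # 100 distinct values
  cm <- nnod:::new_concept_map("c", set_mask_values(grid, v), "decoding")
  th <- threshold_for_display(cm, 0.95)
  expect_identical(sum(mask_values(th$volume) != 0), 5L)
  expect_identical(th$threshold_percentile, 0.95)
  expect_equal(mask_values(threshold_for_display(th, 0.95)$volume),
               mask_values(th$volume))
  # q near zero leaves the map unchanged
  lo <- threshold_for_display(cm, 1e-6)
  expect_equal(mask_values(lo$volume), v)
})

test_that("decoding down-weights hypernym-shared networks relative to encoding", {
  fm <- fitted_standard_model(baseline_shift_sd = 3)
  fx <- fm$fx
  children <- fx$ont$hypernyms$child
  dec <- enc <- c()
  for (cid in children) {
    par <- fx$ont$hypernyms$parent[fx$ont$hypernyms$child == cid][1]
    pv <- mask_values(back_project(fx$signatures[, par], fx$dicts))
    pvox <- abs(pv) > stats::quantile(abs(pv), 0.9)
    dm <- mask_values(sensitivity_map(fm$fit, fm$Xp[fm$ids, ], fx$dicts,
                                      cid)$volume)
    em <- mask_values(encoding_map(fm$Xa[fm$ids, ], fx$Y[fm$ids, ], fx$dicts,
                                   cid)$volume)
    dec <- c(dec, mean(abs(dm)[pvox]) / max(abs(dm)))
    enc <- c(enc, mean(abs(em)[pvox]) / max(abs(em)))
  }
  expect_lt(mean(dec), mean(enc))
})

test_that("concept maps serialize as NIfTI with an index", {
  grid <- small_grid()
  d <- generate_dictionary(4L, grid, seed = 8)
  cm <- nnod:::new_concept_map(
    "auditory perception", back_project(c(1, 0, 0.5, 0), d), "encoding")
  dir <- withr::local_tempdir()
  write_concept_maps(list(cm), dir)
  idx <- jsonlite::read_json(file.path(dir, "index.json"),
                             simplifyVector = TRUE)
  expect_identical(idx$concept, "auditory perception")
  vol <- read_nifti(file.path(dir, idx$file))
  expect_equal(as.numeric(vol$data[grid$mask]), mask_values(cm$volume),
               tolerance = 1e-5)
})
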