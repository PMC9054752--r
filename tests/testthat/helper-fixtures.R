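# Shared fixtures and independent oracles. Fixtures are generated in code
# (seeded) and cached per session; oracles are deliberately naive
# enumerations, independent of the package's implementations.

.fixture_cache <- new.env(parent = emptyenv())

`%||%` <- function(a, b) if (is.null(a)) b else a

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

small_grid <- function(shape = c(8L, 8L, 8L)) make_grid(shape)

# The standard synthetic fixture: 3 collections x 170 maps, 20 concepts,
# high SNR, dictionaries 64/32/16 on an 11x13x11 grid. baseline_shift_sd = 1
# is the clean regime, 3 the corrupted one.
standard_fixture <- function(seed = 11L, baseline_shift_sd = 1) {
  cached(sprintf("std_%d_%g", seed, baseline_shift_sd), {
    grid <- make_grid(c(11L, 13L, 11L))
    dicts <- lapply(seq_along(c(64L, 32L, 16L)), function(i) {
      generate_dictionary(c(64L, 32L, 16L)[i], grid, seed = seed + i)
    })
    ont <- generate_ontology(20L, 4L, 3L, seed = seed)
    cfg <- synth_config(baseline_shift_sd = baseline_shift_sd, seed = seed)
    maps <- generate_repository(ont, dicts, cfg)
    kept <- deduplicate(qc_filter(maps)$kept)
    Y <- hypernym_close(extract_exact_labels(kept, ont, ont$concepts$id), ont)
    list(grid = grid, dicts = dicts, ont = ont, cfg = cfg, maps = maps,
         kept = kept, Y = Y, manifest = repository_manifest(kept),
         signatures = attr(maps, "signatures"),
         baselines = attr(maps, "baselines"))
  })
}

# reference model (stacked positive input, 1 hidden x 300 rectifier,
# dropout 0.2, l1 = l2 = 0.001) trained on the standard fixture
fitted_standard_model <- function(seed = 11L, baseline_shift_sd = 1) {
  cached(sprintf("fit_%d_%g", seed, baseline_shift_sd), {
    fx <- standard_fixture(seed, baseline_shift_sd)
    Xp <- embed_repository(fx$kept, fx$dicts, positive = TRUE)
    Xa <- embed_repository(fx$kept, fx$dicts, positive = FALSE)
    ids <- intersect(rownames(fx$Y), rownames(Xp))
    cfg <- model_config(ncol(Xp), ncol(fx$Y), seed = seed)
    fit <- train_nnod(cfg, Xp[ids, ], fx$Y[ids, ])
    list(fit = fit, Xp = Xp, Xa = Xa, ids = ids, fx = fx)
  })
}

# exclusive-or fixture in embedding space: the first label is active iff
# exactly one of two components is high; only a nonlinear model can decode
xor_fixture <- function(n, seed) {
  withr::with_seed(seed, {
    a <- stats::rbinom(n, 1, 0.5)
    b <- stats::rbinom(n, 1, 0.5)
    X <- cbind(a + stats::rnorm(n, 0, 0.2), b + stats::rnorm(n, 0, 0.2),
               matrix(stats::rnorm(n * 6, 0, 0.5), n))
    colnames(X) <- paste0("f", 1:8)
    Y <- cbind(xor_lab = as.integer(xor(a == 1, b == 1)),
               lin_lab = as.integer(a == 1))
    rownames(X) <- rownames(Y) <- paste0("m", seq_len(n))
    list(X = X, Y = Y)
  })
}

# ontology reproducing the published hypernymy chain around auditory
# sentence comprehension
closure_example_ontology <- function() {
  concepts <- data.frame(
    id = c("asc", "asp", "ap", "p", "lc", "l"),
    name = c("auditory sentence comprehension", "auditory sentence perception",
             "auditory perception", "perception", "language comprehension",
             "language"),
    stringsAsFactors = FALSE
  )
  hyp <- data.frame(
    child = c("asc", "asc", "asp", "ap", "lc"),
    parent = c("asp", "lc", "ap", "p", "l"),
    stringsAsFactors = FALSE
  )
  ontology(concepts, hypernyms = hyp)
}

# ---- independent oracles -------------------------------------------------

# pairwise-enumeration AUC with ties counted one half
oracle_auc <- function(y, s) {
  pos <- s[y == 1]
  neg <- s[y == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# explicit top-k enumeration WR@k (score desc, label index asc on ties)
oracle_wr_at_k <- function(Y, S, k) {
  recalls <- c()
  for (l in seq_len(ncol(Y))) {
    pos <- which(Y[, l] == 1)
    if (!length(pos)) next
    hits <- 0
    for (i in pos) {
      topk <- order(-S[i, ], seq_len(ncol(S)))[seq_len(k)]
      if (l %in% topk) hits <- hits + 1
    }
    recalls <- c(recalls, hits / length(pos))
  }
  mean(recalls)
}

# brute-force vocabulary pruning: same stated rule, naive implementation
oracle_prune <- function(Y, min_count, max_abs_corr) {
  repeat {
    changed <- FALSE
    keep <- colSums(Y) >= min_count
    if (!all(keep)) {
      Y <- Y[, keep, drop = FALSE]
      changed <- TRUE
    }
    if (ncol(Y) >= 2L) {
      found <- FALSE
      for (i in seq_len(ncol(Y) - 1L)) {
        if (found) break
        for (j in (i + 1L):ncol(Y)) {
          r <- suppressWarnings(stats::cor(Y[, i], Y[, j]))
          if (is.finite(r) && abs(r) > max_abs_corr) {
            drop <- if (sum(Y[, j]) <= sum(Y[, i])) j else i
            Y <- Y[, -drop, drop = FALSE]
            found <- TRUE
            changed <- TRUE
            break
          }
        }
      }
    }
    if (!changed) break
  }
  colnames(Y)
}

# normal-equations least squares (full-rank case)
oracle_normal_equations <- function(dictionary, v) {
  A <- t(dictionary$components)
  solve(crossprod(A), crossprod(A, v))
}

# plain matrix-arithmetic forward pass, written independently of the
# package's layer loop
oracle_forward <- function(model, x) {
  a <- matrix(x, nrow = 1L)
  nl <- length(model$layers)
  for (l in seq_len(nl)) {
    z <- a %*% t(model$layers[[l]]$W) + model$layers[[l]]$b[col(matrix(0, 1, length(model$layers[[l]]$b)))]
    a <- if (l < nl && model$config$activation == "rectifier") pmax(z, 0) else z
  }
  as.numeric(a)
}

# central finite-difference gradient of the training objective
fd_gradient_check <- function(model, X, Y, h = 1e-5, n_entries = 4L) {
  g <- nnod:::nnod_gradient(model, X, Y)
  worst <- 0
  for (l in seq_along(model$layers)) {
    idx <- seq_len(min(n_entries, length(model$layers[[l]]$W)))
    for (i in idx) {
      mp <- model; mp$layers[[l]]$W[i] <- mp$layers[[l]]$W[i] + h
      mm <- model; mm$layers[[l]]$W[i] <- mm$layers[[l]]$W[i] - h
      fd <- (nnod_objective(mp, X, Y) - nnod_objective(mm, X, Y)) / (2 * h)
      an <- g$grads[[l]]$W[i]
      worst <- max(worst, abs(fd - an) / max(1e-6, abs(fd), abs(an)))
    }
    for (i in seq_len(min(n_entries, length(model$layers[[l]]$b)))) {
      mp <- model; mp$layers[[l]]$b[i] <- mp$layers[[l]]$b[i] + h
      mm <- model; mm$layers[[l]]$b[i] <- mm$layers[[l]]$b[i] - h
      fd <- (nnod_objective(mp, X, Y) - nnod_objective(mm, X, Y)) / (2 * h)
      an <- g$grads[[l]]$b[i]
      worst <- max(worst, abs(fd - an) / max(1e-6, abs(fd), abs(an)))
    }
  }
  worst
}
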