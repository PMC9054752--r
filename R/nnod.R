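#' Configuration of a decoding model
#'
#' Describes one member of the model family: shallow fully connected
#' networks over dictionary loadings, from plain logistic regression
#' (\code{n_hidden = 0}) to three hidden layers, with elastic-net weight
#' penalties and dropout. The defaults mirror the selected reference model:
#' one rectifier hidden layer of width 300, dropout 0.2, and an l1 = l2 =
#' 0.001 penalty, over the stacked 1664-dimensional representation.
#'
#' @param input_dim input dimension p (length of the embedding).
#' @param n_labels number of concepts scored jointly.
#' @param n_hidden number of hidden layers, 0 to 3.
#' @param hidden_width width of each hidden layer (>= 1 when
#'   \code{n_hidden >= 1}).
#' @param activation hidden-unit activation: \code{"rectifier"}
#'   (\code{max(z, 0)}) or \code{"identity"} (a linear model).
#' @param output_mode \code{"binary"} (independent Bernoulli per label,
#'   sigmoid outputs) or \code{"multinomial"} (one categorical distribution
#'   over labels, softmax outputs).
#' @param l1_weight,l2_weight elastic-net coefficients, applied to every
#'   layer's weight matrix (biases exempt).
#' @param dropout_rate dropout probability in [0, 1), applied to the input
#'   and to every hidden activation during training (inverted scaling, so
#'   expected activations match evaluation mode).
#' @param seed integer seed for initialization and batching.
#' @return A \code{model_config} list.
#' @export
model_config <- function(input_dim, n_labels, n_hidden = 1L,
                         hidden_width = 300L, activation = "rectifier",
                         output_mode = "binary", l1_weight = 0.001,
                         l2_weight = 0.001, dropout_rate = 0.2, seed = 1L) {
  activation <- match.arg(activation, c("rectifier", "identity"))
  output_mode <- match.arg(output_mode, c("binary", "multinomial"))
  n_hidden <- as.integer(n_hidden)
  if (n_hidden < 0L || n_hidden > 3L) {
    stop("`n_hidden` must be in 0..3", call. = FALSE)
  }
  if (n_hidden >= 1L && hidden_width < 1L) {
    stop("`hidden_width` must be >= 1 when hidden layers exist", call. = FALSE)
  }
  stopifnot(l1_weight >= 0, l2_weight >= 0,
            dropout_rate >= 0, dropout_rate < 1)
  structure(list(input_dim = as.integer(input_dim),
                 n_labels = as.integer(n_labels),
                 n_hidden = n_hidden,
                 hidden_width = as.integer(hidden_width),
                 activation = activation, output_mode = output_mode,
                 l1_weight = l1_weight, l2_weight = l2_weight,
                 dropout_rate = dropout_rate, seed = as.integer(seed)),
            class = "model_config")
}

layer_dims <- function(config) {
  c(config$input_dim, rep(config$hidden_width, config$n_hidden),
    config$n_labels)
}

#' Initialize model parameters
#'
#' Symmetric uniform weights scaled by fan-in
#' (\code{U(-1/sqrt(fan_in), 1/sqrt(fan_in))}), zero biases; seeded from
#' the config.
#'
#' @param config a \code{\link{model_config}}.
#' @return A \code{trained_model} (untrained parameters).
#' @export
init_model <- function(config) {
  dims <- layer_dims(config)
  withr::with_seed(config$seed, {
    layers <- lapply(seq_len(length(dims) - 1L), function(l) {
      fan_in <- dims[l]
      lim <- 1 / sqrt(fan_in)
      list(W = matrix(stats::runif(dims[l + 1L] * fan_in, -lim, lim),
                      nrow = dims[l + 1L]),
           b = numeric(dims[l + 1L]))
    })
    structure(list(layers = layers, config = config), class = "trained_model")
  })
}

#' @export
print.trained_model <- function(x, ...) {
  dims <- layer_dims(x$config)
  cat(sprintf("<trained_model> %s, %s mode, layers %s\n",
              x$config$activation, x$config$output_mode,
              paste(dims, collapse = " -> ")))
  invisible(x)
}

apply_activation <- function(z, activation) {
  if (activation == "rectifier") pmax(z, 0) else z
}

# Forward pass keeping per-layer post-activation caches.
# X: n x p matrix. masks: optional list of dropout masks (input + hidden),
# already inverted-scaled. Returns list(logits, acts).
forward_pass <- function(model, X, masks = NULL) {
  cfg <- model$config
  A <- X
  if (!is.null(masks)) A <- A * masks[[1L]]
  acts <- list(A)
  nl <- length(model$layers)
  for (l in seq_len(nl)) {
    Z <- A %*% t(model$layers[[l]]$W) +
      rep(model$layers[[l]]$b, each = nrow(A))
    if (l < nl) {
      A <- apply_activation(Z, cfg$activation)
      if (!is.null(masks)) A <- A * masks[[l + 1L]]
      acts[[l + 1L]] <- A
    } else {
      A <- Z
    }
  }
  list(logits = A, acts = acts)
}

#' Model forward map (logits)
#'
#' Applies each hidden affine map followed by the configured activation,
#' then the output affine map; no output activation. With no hidden layers
#' this is exactly \code{W x + b} — logistic regression up to the output
#' link.
#'
#' @param model a \code{trained_model}.
#' @param x numeric vector of length \code{input_dim}, or an n x p matrix.
#' @return Logit vector of length \code{n_labels} (or n x |L| matrix).
#' @export
nnod_forward <- function(model, x) {
  vec <- is.null(dim(x))
  X <- if (vec) matrix(x, nrow = 1L) else as.matrix(x)
  if (ncol(X) != model$config$input_dim) {
    stop("input dimension mismatch", call. = FALSE)
  }
  out <- forward_pass(model, X)$logits
  if (vec) as.numeric(out) else out
}

sigmoid <- function(z) 1 / (1 + exp(-z))

softmax <- function(z) {
  if (is.null(dim(z))) z <- matrix(z, nrow = 1L)
  z <- z - apply(z, 1L, max)           # max-subtraction for stability
  e <- exp(z)
  e / rowSums(e)
}

#' Per-label Bernoulli probabilities
#'
#' Elementwise sigmoid of the forward logits; requires
#' \code{output_mode = "binary"}.
#'
#' @param model a \code{trained_model}.
#' @param x input vector or matrix.
#' @return Probabilities in (0, 1), same shape as the logits.
#' @export
predict_binary <- function(model, x) {
  if (model$config$output_mode != "binary") {
    stop("model is not in binary output mode", call. = FALSE)
  }
  sigmoid(nnod_forward(model, x))
}

#' Categorical label distribution
#'
#' Softmax of the forward logits (rows sum to 1); requires
#' \code{output_mode = "multinomial"}.
#'
#' @param model a \code{trained_model}.
#' @param x input vector or matrix.
#' @return Probability vector(s) on the simplex.
#' @export
predict_multinomial <- function(model, x) {
  if (model$config$output_mode != "multinomial") {
    stop("model is not in multinomial output mode", call. = FALSE)
  }
  out <- softmax(nnod_forward(model, x))
  if (is.null(dim(x))) as.numeric(out) else out
}

#' Label scores for ranking and AUC
#'
#' Output probabilities under the configured output mode (sigmoid per label
#' in binary mode, softmax across labels in multinomial mode).
#'
#' @param model a \code{trained_model}.
#' @param X n x p input matrix.
#' @return n x |L| score matrix.
#' @export
predict_scores <- function(model, X) {
  X <- as.matrix(X)
  if (model$config$output_mode == "binary") {
    predict_binary(model, X)
  } else {
    predict_multinomial(model, X)
  }
}

#' Elastic-net penalty on model weights
#'
#' \code{l1 * sum|W| + l2 * sum(W^2)} over all layer weight matrices;
#' biases are excluded.
#'
#' @param theta a \code{trained_model}, or a list of weight matrices.
#' @param l1_weight,l2_weight penalty coefficients.
#' @return The penalty value.
#' @export
regularization <- function(theta, l1_weight, l2_weight) {
  Ws <- if (inherits(theta, "trained_model")) {
    lapply(theta$layers, `[[`, "W")
  } else {
    theta
  }
  if (l1_weight == 0 && l2_weight == 0) return(0)
  sum(vapply(Ws, function(W) {
    l1_weight * sum(abs(W)) + l2_weight * sum(W^2)
  }, 0))
}

clamp_prob <- function(p, eps = 1e-7) pmin(pmax(p, eps), 1 - eps)

#' Multi-label binary cross-entropy loss
#'
#' \code{-sum_l [y^l log(yhat^l) + (1 - y^l) log(1 - yhat^l)] + R(theta)},
#' treating each label as an independent Bernoulli task. Probabilities are
#' clamped to [1e-7, 1 - 1e-7].
#'
#' @param y binary label vector (or n x |L| matrix; matrices return the
#'   mean per-sample loss).
#' @param yhat predicted probabilities, same shape.
#' @param theta optional \code{trained_model} or weight list for the
#'   penalty term.
#' @param l1_weight,l2_weight penalty coefficients (taken from the model
#'   config when \code{theta} is a \code{trained_model} and they are left
#'   \code{NULL}).
#' @return The loss value.
#' @export
loss_binary <- function(y, yhat, theta = NULL, l1_weight = NULL,
                        l2_weight = NULL) {
  if (length(y) != length(yhat)) stop("length mismatch", call. = FALSE)
  pen <- loss_penalty(theta, l1_weight, l2_weight)
  yhat <- clamp_prob(yhat)
  ce <- -(y * log(yhat) + (1 - y) * log(1 - yhat))
  data_loss <- if (is.matrix(y)) mean(rowSums(ce)) else sum(ce)
  data_loss + pen
}

#' Multinomial (categorical) cross-entropy loss
#'
#' \code{-sum_l (y^l / sum_k y^k) log(yhat^l) + R(theta)}: the label vector
#' is normalized to a distribution, so multi-label targets spread their
#' mass uniformly over the positive labels and scaling y leaves the loss
#' unchanged.
#'
#' @inheritParams loss_binary
#' @param yhat probabilities on the simplex (rows, for matrices).
#' @return The loss value.
#' @export
loss_multinomial <- function(y, yhat, theta = NULL, l1_weight = NULL,
                             l2_weight = NULL) {
  if (length(y) != length(yhat)) stop("length mismatch", call. = FALSE)
  pen <- loss_penalty(theta, l1_weight, l2_weight)
  if (!is.matrix(y)) {
    y <- matrix(y, nrow = 1L)
    yhat <- matrix(yhat, nrow = 1L)
  }
  sums <- rowSums(y)
  if (any(sums <= 0)) {
    stop("a label vector is all-zero: normalization undefined", call. = FALSE)
  }
  ytil <- y / sums
  mean(-rowSums(ytil * log(clamp_prob(yhat)))) + pen
}

loss_penalty <- function(theta, l1_weight, l2_weight) {
  if (is.null(theta)) return(0)
  if (inherits(theta, "trained_model")) {
    if (is.null(l1_weight)) l1_weight <- theta$config$l1_weight
    if (is.null(l2_weight)) l2_weight <- theta$config$l2_weight
  } else {
    if (is.null(l1_weight)) l1_weight <- 0
    if (is.null(l2_weight)) l2_weight <- 0
  }
  regularization(theta, l1_weight, l2_weight)
}

#' Full training objective of a model on a batch
#'
#' Mean per-sample data loss under the configured output mode plus the
#' elastic-net penalty — the quantity mini-batch training minimizes
#' (without dropout). Useful for finite-difference gradient checks.
#'
#' @param model a \code{trained_model}.
#' @param X n x p inputs.
#' @param Y n x |L| binary labels.
#' @return The objective value.
#' @export
nnod_objective <- function(model, X, Y) {
  logits <- forward_pass(model, as.matrix(X))$logits
  if (model$config$output_mode == "binary") {
    loss_binary(Y, sigmoid(logits), model)
  } else {
    loss_multinomial(Y, softmax(logits), model)
  }
}

# Analytic gradient of the training objective. masks: optional dropout
# masks (inverted-scaled) as in forward_pass. Returns list(grads, loss):
# grads mirrors model$layers.
nnod_gradient <- function(model, X, Y, masks = NULL) {
  cfg <- model$config
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  n <- nrow(X)
  fp <- forward_pass(model, X, masks)
  logits <- fp$logits
  if (cfg$output_mode == "binary") {
    P <- sigmoid(logits)
    data_loss <- loss_binary(Y, P)
    delta <- (P - Y) / n
  } else {
    sums <- rowSums(Y)
    if (any(sums <= 0)) {
      stop("a label vector is all-zero: normalization undefined",
           call. = FALSE)
    }
    P <- softmax(logits)
    data_loss <- loss_multinomial(Y, P)
    delta <- (P - Y / sums) / n
  }
  nl <- length(model$layers)
  grads <- vector("list", nl)
  for (l in rev(seq_len(nl))) {
    W <- model$layers[[l]]$W
    gW <- crossprod(delta, fp$acts[[l]]) +
      cfg$l1_weight * sign(W) + 2 * cfg$l2_weight * W
    grads[[l]] <- list(W = gW, b = colSums(delta))
    if (l > 1L) {
      back <- delta %*% W
      if (!is.null(masks)) back <- back * masks[[l]]
      if (cfg$activation == "rectifier") {
        back <- back * (fp$acts[[l]] > 0)
      }
      delta <- back
    }
  }
  list(grads = grads,
       loss = data_loss + regularization(model, cfg$l1_weight, cfg$l2_weight))
}

#' Train a decoding model
#'
#' Mini-batch gradient descent with adaptive moments (Adam) on the
#' configured loss. Dropout is applied to the input and hidden activations
#' during training only, with inverted scaling so expected activations
#' match evaluation mode. Bit-reproducible given \code{config$seed}.
#'
#' @param config a \code{\link{model_config}}.
#' @param X n x p embedding matrix.
#' @param Y n x |L| binary label matrix, rows aligned with \code{X}.
#' @param epochs passes over the data.
#' @param batch_size mini-batch size.
#' @param learning_rate Adam step size.
#' @return A \code{trained_model} with attribute \code{loss_history}
#'   (mean objective per epoch).
#' @export
train_nnod <- function(config, X, Y, epochs = 100L, batch_size = 256L,
                       learning_rate = 1e-3) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  if (!nrow(X) || !nrow(Y)) stop("empty training data", call. = FALSE)
  if (nrow(X) != nrow(Y)) stop("X and Y row counts differ", call. = FALSE)
  model <- init_model(config)
  p_drop <- config$dropout_rate
  nl <- length(model$layers)
  mom <- lapply(model$layers, function(l) {
    list(mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0)
  })
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  t_step <- 0L
  history <- numeric(epochs)
  withr::with_seed(config$seed + 1L, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(nrow(X))
      starts <- seq(1L, nrow(X), by = batch_size)
      ep_loss <- 0
      for (s in starts) {
        rows <- ord[s:min(s + batch_size - 1L, nrow(X))]
        Xb <- X[rows, , drop = FALSE]
        Yb <- Y[rows, , drop = FALSE]
        masks <- NULL
        if (p_drop > 0) {
          widths <- c(config$input_dim,
                      rep(config$hidden_width, config$n_hidden))
          masks <- lapply(widths, function(w) {
            matrix(stats::rbinom(length(rows) * w, 1L, 1 - p_drop),
                   nrow = length(rows)) / (1 - p_drop)
          })
        }
        g <- nnod_gradient(model, Xb, Yb, masks)
        ep_loss <- ep_loss + g$loss * length(rows)
        t_step <- t_step + 1L
        corr1 <- 1 - b1^t_step
        corr2 <- 1 - b2^t_step
        for (l in seq_len(nl)) {
          mom[[l]]$mW <- b1 * mom[[l]]$mW + (1 - b1) * g$grads[[l]]$W
          mom[[l]]$vW <- b2 * mom[[l]]$vW + (1 - b2) * g$grads[[l]]$W^2
          mom[[l]]$mb <- b1 * mom[[l]]$mb + (1 - b1) * g$grads[[l]]$b
          mom[[l]]$vb <- b2 * mom[[l]]$vb + (1 - b2) * g$grads[[l]]$b^2
          model$layers[[l]]$W <- model$layers[[l]]$W - learning_rate *
            (mom[[l]]$mW / corr1) / (sqrt(mom[[l]]$vW / corr2) + eps)
          model$layers[[l]]$b <- model$layers[[l]]$b - learning_rate *
            (mom[[l]]$mb / corr1) / (sqrt(mom[[l]]$vb / corr2) + eps)
        }
      }
      history[ep] <- ep_loss / nrow(X)
    }
  })
  attr(model, "loss_history") <- history
  if (!is.null(colnames(Y))) model$vocabulary <- colnames(Y)
  model
}

#' Grid search over model configurations
#'
#' Trains every configuration on the training split and scores it on the
#' validation split by label-macro AUC (the model-selection metric); the
#' best configuration is the argmax, ties broken by earlier position.
#'
#' @param configs list of \code{\link{model_config}}.
#' @param X_train,Y_train training split.
#' @param X_val,Y_val validation split.
#' @param epochs,batch_size,learning_rate training parameters shared by all
#'   runs.
#' @return List with \code{best_config}, \code{model} (retained fit of the
#'   best config) and \code{scores} (data.frame, one row per config).
#' @export
grid_search_nnod <- function(configs, X_train, Y_train, X_val, Y_val,
                             epochs = 100L, batch_size = 256L,
                             learning_rate = 1e-3) {
  stopifnot(length(configs) >= 1L)
  fits <- vector("list", length(configs))
  rows <- vector("list", length(configs))
  for (i in seq_along(configs)) {
    cfg <- configs[[i]]
    fits[[i]] <- train_nnod(cfg, X_train, Y_train, epochs = epochs,
                            batch_size = batch_size,
                            learning_rate = learning_rate)
    auc <- per_label_auc(Y_val, predict_scores(fits[[i]], X_val))$macro_auc
    rows[[i]] <- data.frame(config = i, n_hidden = cfg$n_hidden,
                            hidden_width = cfg$hidden_width,
                            activation = cfg$activation,
                            output_mode = cfg$output_mode,
                            l1_weight = cfg$l1_weight,
                            l2_weight = cfg$l2_weight,
                            dropout_rate = cfg$dropout_rate,
                            val_macro_auc = auc, stringsAsFactors = FALSE)
  }
  scores <- do.call(rbind, rows)
  best <- which.max(scores$val_macro_auc)   # first maximum: earlier wins ties
  list(best_config = configs[[best]], model = fits[[best]], scores = scores)
}

#' Write / read a model checkpoint
#'
#' Portable JSON archive: the configuration plus per-layer weight and bias
#' arrays.
#' @param model a \code{trained_model}.
#' @param path file path.
#' @return \code{path} (write) or the model (read).
#' @export
write_model <- function(model, path) {
  payload <- list(
    config = unclass(model$config),
    layers = lapply(model$layers, function(l) {
      list(W = as.numeric(l$W), dim = dim(l$W), b = l$b)
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(model_config, x$config[c("input_dim", "n_labels", "n_hidden",
                                          "hidden_width", "activation",
                                          "output_mode", "l1_weight",
                                          "l2_weight", "dropout_rate",
                                          "seed")])
  layers <- lapply(seq_len(nrow_or_len(x$layers)), function(i) {
    li <- if (is.data.frame(x$layers)) lapply(x$layers, `[[`, i) else x$layers[[i]]
    list(W = matrix(unlist(li$W), nrow = unlist(li$dim)[1L]),
         b = as.numeric(unlist(li$b)))
  })
  structure(list(layers = layers, config = cfg), class = "trained_model")
}

nrow_or_len <- function(x) if (is.data.frame(x)) nrow(x) else length(x)
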