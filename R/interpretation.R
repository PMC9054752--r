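new_concept_map <- function(concept, vol, kind, threshold_percentile = NULL,
                            flags = character()) {
  structure(list(concept = concept, volume = vol, kind = kind,
                 threshold_percentile = threshold_percentile,
                 flags = flags),
            class = "concept_map")
}

#' @export
print.concept_map <- function(x, ...) {
  cat(sprintf("<concept_map> %s (%s)%s\n", x$concept, x$kind,
              if (!is.null(x$threshold_percentile)) {
                sprintf(", thresholded at q=%.2f", x$threshold_percentile)
              } else ""))
  invisible(x)
}

# gradient of one output logit w.r.t. the input, one row per sample of X
input_gradient <- function(model, X, label_index) {
  X <- as.matrix(X)
  fp <- forward_pass(model, X)
  nl <- length(model$layers)
  delta <- matrix(0, nrow(X), model$config$n_labels)
  delta[, label_index] <- 1
  for (l in rev(seq_len(nl))) {
    delta <- delta %*% model$layers[[l]]$W
    if (l > 1L && model$config$activation == "rectifier") {
      delta <- delta * (fp$acts[[l]] > 0)
    }
  }
  delta
}

model_label_index <- function(model, concept) {
  vocab <- model$vocabulary
  if (is.numeric(concept)) {
    if (concept < 1 || concept > model$config$n_labels) {
      stop("concept index out of range", call. = FALSE)
    }
    return(as.integer(concept))
  }
  if (is.null(vocab) || !concept %in% vocab) {
    stop("concept is not in the model vocabulary", call. = FALSE)
  }
  match(concept, vocab)
}

#' Decoding sensitivity map of a concept
#'
#' Differentiates the concept's output score (the pre-activation logit, to
#' avoid sigmoid/softmax saturation) with respect to the input loadings,
#' averages the gradient over the given maps, and back-projects it to voxel
#' space through the dictionaries: each component is weighted by its
#' gradient entry and the weighted components are summed (stacked inputs
#' back-project through their respective dictionaries). For a linear model
#' the gradient is the concept's weight row, independent of \code{X}.
#'
#' @param model a \code{trained_model} (vocabulary attached by
#'   \code{\link{train_nnod}}).
#' @param X n x p embedding matrix to average the gradient over.
#' @param dictionaries \code{component_dictionary} or list of them, in
#'   stacking order.
#' @param concept concept id (or label index).
#' @param positives_of optional binary label matrix aligned with the rows
#'   of \code{X}: when given, the gradient is averaged only over the
#'   concept's positive maps instead of all maps.
#' @return A \code{concept_map} with \code{kind = "decoding"}.
#' @export
sensitivity_map <- function(model, X, dictionaries, concept,
                            positives_of = NULL) {
  j <- model_label_index(model, concept)
  X <- as.matrix(X)
  if (!is.null(positives_of)) {
    keep <- positives_of[rownames(X), model$vocabulary[j] %||% j] == 1
    if (!any(keep)) stop("concept has no positive map in X", call. = FALSE)
    X <- X[keep, , drop = FALSE]
  }
  g <- colMeans(input_gradient(model, X, j))
  vol <- back_project(g, dictionaries)
  out <- new_concept_map(if (is.numeric(concept)) model$vocabulary[j] %||%
                           as.character(j) else concept,
                         vol, "decoding")
  attr(out, "gradient") <- g       # loading-space sensitivities
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Encoding map of a concept
#'
#' Fits, for every component loading, an ordinary least-squares regression
#' of that loading on the full binary concept matrix (intercept included),
#' takes the concept's coefficient across components, and back-projects it
#' to voxels — the encoding-direction complement of the decoding
#' sensitivity map. A rank-deficient concept matrix is resolved by the
#' minimum-norm fit and flagged.
#'
#' @param X n x p embedding matrix.
#' @param Y binary label matrix, rows aligned with \code{X}.
#' @param dictionaries \code{component_dictionary} or list of them.
#' @param concept concept id (a column name of \code{Y}).
#' @return A \code{concept_map} with \code{kind = "encoding"}.
#' @export
encoding_map <- function(X, Y, dictionaries, concept) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (!concept %in% colnames(Y)) {
    stop("concept has no column in Y", call. = FALSE)
  }
  if (sum(Y[, concept]) < 1) {
    stop("concept has no positive map", call. = FALSE)
  }
  D <- cbind(intercept = 1, Y)
  qd <- qr(D)
  flags <- character()
  if (qd$rank == ncol(D)) {
    B <- qr.coef(qd, X)
  } else {
    sv <- svd(D)
    pos <- sv$d > max(sv$d) * max(dim(D)) * .Machine$double.eps
    B <- sv$v[, pos, drop = FALSE] %*%
      (crossprod(sv$u[, pos, drop = FALSE], X) / sv$d[pos])
    rownames(B) <- colnames(D)
    flags <- "rank_deficient_minimum_norm"
  }
  beta <- B[match(concept, colnames(D)), ]
  new_concept_map(concept, back_project(as.numeric(beta), dictionaries),
                  "encoding", flags = flags)
}

#' Threshold a concept map for display
#'
#' Zeroes the \code{floor(q * n)} in-mask voxels of smallest absolute value
#' (e.g. q = 0.95 keeps the top 5% of voxels), recording the percentile.
#' Rank-based, so exactly the top 1 - q fraction survives, the map is
#' unchanged in the q -> 0 limit, and re-thresholding at the same q is a
#' no-op.
#'
#' @param map a \code{concept_map}.
#' @param q quantile in (0, 1).
#' @return The thresholded \code{concept_map}.
#' @export
threshold_for_display <- function(map, q = 0.95) {
  stopifnot(q > 0, q < 1)
  v <- mask_values(map$volume)
  k <- floor(q * length(v))
  if (k > 0) v[order(abs(v))[seq_len(k)]] <- 0
  map$volume <- set_mask_values(map$volume, v)
  map$threshold_percentile <- q
  map
}

#' Write concept maps as NIfTI with an index
#'
#' One image per concept and kind plus \code{index.json} listing files and
#' parameters.
#'
#' @param maps list of \code{concept_map}.
#' @param dir output directory.
#' @return \code{dir}, invisibly.
#' @export
write_concept_maps <- function(maps, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  index <- lapply(maps, function(m) {
    fn <- paste0(gsub("[^a-z0-9]+", "_", tolower(m$concept)), "_", m$kind,
                 ".nii.gz")
    write_nifti(m$volume, file.path(dir, fn))
    list(concept = m$concept, kind = m$kind, file = fn,
         threshold_percentile = m$threshold_percentile,
         flags = as.list(m$flags))
  })
  jsonlite::write_json(index, file.path(dir, "index.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
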