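#' Project a statistical map onto a component dictionary
#'
#' Ordinary-least-squares loadings of the in-mask voxel vector on the
#' dictionary components: \code{argmin_w || v - t(C) w ||^2}. Rank-deficient
#' dictionaries get the minimum-norm solution (SVD pseudoinverse).
#'
#' @param map a \code{stat_map} standardized to the dictionary grid.
#' @param dictionary a \code{component_dictionary}.
#' @return An embedding: list with \code{loadings}, \code{resolution_tag},
#'   \code{positive_only}, \code{map_id}, class \code{nnod_embedding}.
#' @export
project <- function(map, dictionary) {
  if (!same_geometry(map$volume, dictionary$grid)) {
    stop("map is not on the dictionary grid; resample first", call. = FALSE)
  }
  w <- ols_loadings(matrix(mask_values(map$volume), ncol = 1L), dictionary)
  new_embedding(as.numeric(w), as.character(dictionary$K), FALSE, map$map_id)
}

new_embedding <- function(loadings, tag, positive_only, map_id) {
  structure(list(loadings = loadings, resolution_tag = tag,
                 positive_only = positive_only, map_id = map_id),
            class = "nnod_embedding")
}

#' @export
print.nnod_embedding <- function(x, ...) {
  cat(sprintf("<nnod_embedding> %s, p=%d%s, map %s\n", x$resolution_tag,
              length(x$loadings), if (x$positive_only) " (positive part)" else "",
              x$map_id))
  invisible(x)
}

# V x n matrix of voxel vectors -> K x n loading matrix (min-norm OLS)
ols_loadings <- function(vmat, dictionary) {
  A <- t(dictionary$components)          # V x K design
  qa <- qr(A)
  if (qa$rank == ncol(A)) {
    qr.coef(qa, vmat)
  } else {
    sv <- svd(A)
    pos <- sv$d > max(sv$d) * max(dim(A)) * .Machine$double.eps
    sv$v[, pos, drop = FALSE] %*%
      ((crossprod(sv$u[, pos, drop = FALSE], vmat)) / sv$d[pos])
  }
}

#' Positive part of an embedding
#'
#' Clips negative loadings at zero. Because the components are non-negative,
#' this amounts to keeping only the positive part of the map, suppressing
#' control-condition (baseline) artifacts. Idempotent.
#'
#' @param e a \code{nnod_embedding}.
#' @return The clipped embedding with \code{positive_only = TRUE}.
#' @export
positive_part <- function(e) {
  e$loadings <- pmax(e$loadings, 0)
  e$positive_only <- TRUE
  e
}

#' Stack embeddings into a multi-resolution representation
#'
#' Concatenates the loading vectors in the given order (convention:
#' highest resolution first, e.g. 1024 then 512 then 128, giving the
#' 1664-dimensional stacked representation for the standard dictionary
#' trio). All parts must share map_id and positive_only status.
#'
#' @param parts ordered list of \code{nnod_embedding}.
#' @return A single \code{nnod_embedding} with
#'   \code{resolution_tag = "stacked"}.
#' @export
stack_embeddings <- function(parts) {
  stopifnot(length(parts) >= 1L)
  ids <- unique(vapply(parts, `[[`, "", "map_id"))
  if (length(ids) != 1L) stop("mixed map_ids in stack", call. = FALSE)
  pos <- unique(vapply(parts, `[[`, NA, "positive_only"))
  if (length(pos) != 1L) stop("mixed positive_only flags in stack", call. = FALSE)
  new_embedding(unlist(lapply(parts, `[[`, "loadings"), use.names = FALSE),
                "stacked", pos, ids)
}

#' Project a whole repository onto one or more dictionaries
#'
#' Computes the OLS loadings of every map on every dictionary with one
#' matrix decomposition per dictionary, optionally clips to the positive
#' part, and concatenates dictionaries in the given order.
#'
#' @param maps list of \code{stat_map} on the common grid.
#' @param dictionaries a \code{component_dictionary} or list of them
#'   (stacking order = list order; pass highest resolution first).
#' @param positive clip loadings at zero.
#' @return n_maps x p numeric matrix, rows named by map_id, with
#'   attribute \code{sizes} giving the per-dictionary widths.
#' @export
embed_repository <- function(maps, dictionaries, positive = TRUE) {
  if (inherits(dictionaries, "component_dictionary")) {
    dictionaries <- list(dictionaries)
  }
  vmat <- vapply(maps, function(m) mask_values(m$volume),
                 numeric(sum(maps[[1L]]$volume$mask)))
  blocks <- lapply(dictionaries, function(d) t(ols_loadings(vmat, d)))
  X <- do.call(cbind, blocks)
  if (positive) X <- pmax(X, 0)
  rownames(X) <- vapply(maps, `[[`, "", "map_id")
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  attr(X, "sizes") <- vapply(dictionaries, `[[`, 0L, "K")
  X
}

#' Write / read an embedding matrix as CSV
#'
#' One row per map_id, p feature columns.
#' @param X matrix from \code{\link{embed_repository}}.
#' @param path output path.
#' @return \code{path} (write) or the matrix (read).
#' @export
write_embeddings <- function(X, path) {
  df <- data.frame(map_id = rownames(X), X, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_embeddings
#' @export
read_embeddings <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  X <- as.matrix(df[, -1, drop = FALSE])
  rownames(X) <- df$map_id
  X
}

#' Compare decoding performance across signal representations
#'
#' Trains a baseline logistic model (0 hidden layers, binary losses) for
#' every combination of representation (each dictionary alone plus the
#' stacked trio) and sign handling (all loadings vs positive part), and
#' evaluates label-macro AUC and WR@k on a held-out collection. This is the
#' representation-selection experiment: with heterogeneous per-collection
#' baselines, the positive-part stacked representation is expected to lead.
#'
#' @param maps list of \code{stat_map} (QC'd, on the common grid).
#' @param dictionaries list of >= 2 \code{component_dictionary}, highest
#'   resolution first.
#' @param labels binary label matrix (rows = map_ids).
#' @param test_collections collection ids held out for evaluation.
#' @param k rank cutoff for WR@k.
#' @param epochs,learning_rate training parameters of the baseline model.
#' @param seed seed for model initialization.
#' @return data.frame with columns representation, positive, auc, wr_at_k;
#'   one row per (representation, sign) cell.
#' @export
compare_representations <- function(maps, dictionaries, labels,
                                    test_collections, k = 10L,
                                    epochs = 60L, learning_rate = 1e-2,
                                    seed = 1L) {
  if (length(dictionaries) < 2L) {
    stop("need >= 2 dictionaries to compare", call. = FALSE)
  }
  manifest <- repository_manifest(maps)
  split <- leave_collections_out_split(labels, manifest, test_collections)
  reps <- c(as.list(seq_along(dictionaries)), list(seq_along(dictionaries)))
  rep_names <- c(vapply(dictionaries, function(d) as.character(d$K), ""),
                 "stacked")
  X_all <- embed_repository(maps, dictionaries, positive = FALSE)
  sizes <- attr(X_all, "sizes")
  offsets <- cumsum(c(0L, sizes))
  out <- list()
  for (ri in seq_along(reps)) {
    cols <- unlist(lapply(reps[[ri]], function(d) {
      (offsets[d] + 1L):offsets[d + 1L]
    }))
    for (positive in c(FALSE, TRUE)) {
      X <- X_all[, cols, drop = FALSE]
      if (positive) X <- pmax(X, 0)
      Xtr <- X[split$train_ids, , drop = FALSE]
      Xte <- X[split$test_ids, , drop = FALSE]
      Ytr <- labels[split$train_ids, split$evaluable, drop = FALSE]
      Yte <- labels[split$test_ids, split$evaluable, drop = FALSE]
      cfg <- model_config(n_hidden = 0L, output_mode = "binary",
                          input_dim = ncol(X), n_labels = ncol(Ytr),
                          seed = seed)
      fit <- train_nnod(cfg, Xtr, Ytr, epochs = epochs,
                        learning_rate = learning_rate)
      scores <- predict_scores(fit, Xte)
      auc <- per_label_auc(Yte, scores)$macro_auc
      wr <- wr_at_k(Yte, scores, k = min(k, ncol(Yte)))
      out[[length(out) + 1L]] <- data.frame(
        representation = rep_names[ri], positive = positive,
        auc = auc, wr_at_k = wr, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
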