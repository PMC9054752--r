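#' Weighted recall at k
#'
#' For each label, the fraction of its positive maps whose score ranking
#' places the label among that map's top-k labels, averaged with uniform
#' weights over labels — so rare labels count as much as common ones.
#' Labels with no positive map are excluded from the average. Top-k ties at
#' the boundary are broken by ascending label index after the score sort.
#'
#' @param Y binary label matrix (maps x labels).
#' @param scores real score matrix, same shape.
#' @param k rank cutoff, 1 <= k <= number of labels.
#' @return WR@k in [0, 1].
#' @export
wr_at_k <- function(Y, scores, k = 10L) {
  Y <- as.matrix(Y); scores <- as.matrix(scores)
  if (!all(dim(Y) == dim(scores))) stop("shape mismatch", call. = FALSE)
  k <- as.integer(k)
  if (k < 1L || k > ncol(Y)) stop("`k` out of range", call. = FALSE)
  # top-k membership per map: stable order (score desc, label index asc)
  in_top <- t(apply(scores, 1L, function(s) {
    top <- order(-s, seq_along(s))[seq_len(k)]
    seq_along(s) %in% top
  }))
  if (ncol(Y) == 1L) in_top <- matrix(in_top, ncol = 1L)
  npos <- colSums(Y == 1L)
  eval_lab <- npos > 0L
  if (!any(eval_lab)) stop("no label has a positive map", call. = FALSE)
  recall <- colSums((Y == 1L) & in_top)[eval_lab] / npos[eval_lab]
  mean(recall)
}

# midrank AUC for one label: P(score_pos > score_neg), ties 1/2
auc_one <- function(y, s) {
  r <- rank(s)                         # midranks
  n_pos <- sum(y == 1L)
  n_neg <- sum(y == 0L)
  (sum(r[y == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Per-label ROC AUC and macro average
#'
#' For every label with at least one positive and one negative map, the
#' probability that a random positive map scores the label higher than a
#' random negative one (ties counted one half; computed by midrank
#' statistics). Labels with a single class are excluded, with a reason,
#' rather than scored 0.5. The macro AUC is the unweighted mean over
#' evaluated labels.
#'
#' @param Y binary label matrix (maps x labels).
#' @param scores real score matrix, same shape.
#' @return List: \code{per_label_auc} (named numeric), \code{macro_auc},
#'   \code{evaluated_labels}, \code{excluded_labels} (named character of
#'   reasons).
#' @export
per_label_auc <- function(Y, scores) {
  Y <- as.matrix(Y); scores <- as.matrix(scores)
  if (!all(dim(Y) == dim(scores))) stop("shape mismatch", call. = FALSE)
  labs <- colnames(Y)
  if (is.null(labs)) labs <- paste0("label", seq_len(ncol(Y)))
  npos <- colSums(Y == 1L)
  nneg <- colSums(Y == 0L)
  evaluable <- npos > 0L & nneg > 0L
  if (!any(evaluable)) stop("no evaluable label", call. = FALSE)
  aucs <- vapply(which(evaluable), function(j) auc_one(Y[, j], scores[, j]), 0)
  names(aucs) <- labs[evaluable]
  excluded <- ifelse(npos == 0L, "no_positives", "no_negatives")[!evaluable]
  names(excluded) <- labs[!evaluable]
  list(per_label_auc = aucs,
       macro_auc = mean(aucs),
       evaluated_labels = labs[evaluable],
       excluded_labels = excluded)
}

#' Leave-collections-out validation split
#'
#' All maps of the named collections form the test set, everything else the
#' training set — generalization is measured on whole unseen studies, never
#' on held-out maps of a seen study. The evaluable vocabulary is the set of
#' concepts positive in both splits (what can be tested depends on the
#' left-out collections).
#'
#' @param labels binary label matrix, rows named by map_id.
#' @param manifest data.frame with columns map_id, collection_id (see
#'   \code{\link{repository_manifest}}).
#' @param test_collections nonempty character vector of collection ids.
#' @return List: \code{train_ids}, \code{test_ids} (map ids with labels),
#'   \code{evaluable} (concept ids positive in both splits).
#' @export
leave_collections_out_split <- function(labels, manifest, test_collections) {
  if (!length(test_collections)) {
    stop("`test_collections` is empty", call. = FALSE)
  }
  unknown <- setdiff(test_collections, manifest$collection_id)
  if (length(unknown)) {
    stop("unknown collection(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  coll <- stats::setNames(manifest$collection_id, manifest$map_id)
  ids <- intersect(rownames(labels), manifest$map_id)
  test_ids <- ids[coll[ids] %in% test_collections]
  train_ids <- setdiff(ids, test_ids)
  pos_train <- colSums(labels[train_ids, , drop = FALSE]) > 0L
  pos_test <- colSums(labels[test_ids, , drop = FALSE]) > 0L
  list(train_ids = train_ids, test_ids = test_ids,
       evaluable = colnames(labels)[pos_train & pos_test])
}

#' Full evaluation report
#'
#' Bundles per-label AUC, macro AUC and WR@k for one (labels, scores) pair.
#'
#' @param Y binary label matrix.
#' @param scores score matrix.
#' @param k WR@k cutoff (clipped to the label count).
#' @return List of class \code{eval_report}.
#' @export
eval_report <- function(Y, scores, k = 10L) {
  auc <- per_label_auc(Y, scores)
  wr <- wr_at_k(Y, scores, k = min(as.integer(k), ncol(Y)))
  structure(c(auc, list(wr_at_k = wr, k = min(as.integer(k), ncol(Y)),
                        n_maps = nrow(Y))),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d maps, %d labels evaluated\n",
              x$n_maps, length(x$evaluated_labels)))
  cat(sprintf("  macro AUC = %.3f   WR@%d = %.3f\n", x$macro_auc, x$k,
              x$wr_at_k))
  if (length(x$excluded_labels)) {
    cat(sprintf("  excluded: %s\n",
                paste(names(x$excluded_labels), x$excluded_labels,
                      sep = " (", collapse = "), ")))
  }
  invisible(x)
}

#' Serialize an evaluation report
#'
#' JSON for the summary plus a per-label CSV next to it.
#' @param report an \code{eval_report}.
#' @param path JSON output path; the CSV replaces the extension with
#'   \code{.csv}.
#' @return \code{path}, invisibly.
#' @export
write_eval_report <- function(report, path) {
  jsonlite::write_json(
    list(macro_auc = report$macro_auc, wr_at_k = report$wr_at_k,
         k = report$k, n_maps = report$n_maps,
         evaluated_labels = report$evaluated_labels,
         excluded_labels = as.list(report$excluded_labels)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(
    data.frame(concept = names(report$per_label_auc),
               auc = as.numeric(report$per_label_auc)),
    sub("\\.json$", ".csv", path), row.names = FALSE)
  invisible(path)
}
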