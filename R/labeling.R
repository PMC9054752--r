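normalize_text <- function(x) {
  x <- tolower(x)
  gsub("\\s+", " ", trimws(x))
}

annotation_text <- function(map) {
  fields <- map$annotations
  fields$image_type <- NULL            # modality flag is not free text
  normalize_text(paste(unlist(fields), collapse = " ; "))
}

# word-boundary, case-insensitive occurrence of `needle` in normalized text
name_pattern <- function(needle) {
  paste0("\\b", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", normalize_text(needle)),
         "\\b")
}

#' Extract exactly-matched concept labels from annotations
#'
#' A concept is assigned to a map when its canonical name or a registered
#' synonym occurs as a word-boundary-delimited, case-insensitive substring
#' in any free-text annotation field. Maps with no matched concept are
#' dropped from the matrix (they carry no supervision).
#'
#' @param maps list of \code{stat_map}.
#' @param ont a \code{nnod_ontology}.
#' @param vocabulary character vector of concept ids (ordered; defines label
#'   indexing). Must be a subset of the ontology's concepts.
#' @return Binary matrix, rows = labeled map_ids, columns = vocabulary.
#' @export
extract_exact_labels <- function(maps, ont, vocabulary) {
  if (!all(vocabulary %in% ont$concepts$id)) {
    stop("vocabulary contains ids outside the ontology", call. = FALSE)
  }
  texts <- vapply(maps, annotation_text, "")
  pats <- lapply(vocabulary, function(cid) {
    nm <- ont$concepts$name[ont$concepts$id == cid]
    syn <- ont$synonyms$name[ont$synonyms$concept_id == cid]
    vapply(c(nm, syn), name_pattern, "")
  })
  Y <- vapply(pats, function(p) {
    hit <- rep(FALSE, length(texts))
    for (pp in p) hit <- hit | grepl(pp, texts, perl = TRUE)
    as.integer(hit)
  }, integer(length(texts)))
  Y <- matrix(Y, nrow = length(texts),
              dimnames = list(vapply(maps, `[[`, "", "map_id"), vocabulary))
  Y[rowSums(Y) > 0L, , drop = FALSE]
}

#' Close a label matrix under hypernymy
#'
#' For every positive concept, all of its ontology ancestors that are
#' present in the vocabulary are also set positive: a task involving
#' "auditory sentence comprehension" involves "auditory sentence
#' perception", "auditory perception", "perception", "language
#' comprehension" and "language" as well. Idempotent; never removes a
#' positive.
#'
#' @param labels binary matrix (columns = concept ids).
#' @param ont a \code{nnod_ontology}.
#' @return The closed binary matrix, same shape.
#' @export
hypernym_close <- function(labels, ont) {
  vocab <- colnames(labels)
  anc <- lapply(vocab, function(cid) {
    intersect(concept_ancestors(ont, cid), vocab)
  })
  out <- labels
  for (j in seq_along(vocab)) {
    if (length(anc[[j]])) {
      pos <- labels[, j] == 1L
      if (any(pos)) out[pos, anc[[j]]] <- 1L
    }
  }
  out
}

#' Construct a labeling rule set
#'
#' Collection-tailored enrichment rules: token corrections for common
#' errors and abbreviations, per-collection annotation patterns that fire
#' additional concepts, and synonym merges that collapse two concept
#' columns into one.
#'
#' @param synonym_merges data.frame with columns \code{survivor},
#'   \code{merged} (concept ids); no concept may be merged into two
#'   distinct survivors.
#' @param collection_rules named list: collection id -> list of rules, each
#'   a list with \code{pattern} (regex on normalized annotation text) and
#'   \code{concepts} (ids to set positive).
#' @param correction_map named character vector: token -> replacement.
#' @return A \code{label_ruleset}.
#' @export
ruleset <- function(synonym_merges = NULL, collection_rules = list(),
                    correction_map = character()) {
  if (is.null(synonym_merges)) {
    synonym_merges <- data.frame(survivor = character(), merged = character(),
                                 stringsAsFactors = FALSE)
  }
  synonym_merges <- as.data.frame(synonym_merges, stringsAsFactors = FALSE)
  if (nrow(synonym_merges)) {
    tab <- tapply(synonym_merges$survivor, synonym_merges$merged,
                  function(s) length(unique(s)))
    if (any(tab > 1L)) {
      stop("a concept is merged into two distinct survivors", call. = FALSE)
    }
    if (any(synonym_merges$merged %in% synonym_merges$survivor)) {
      stop("a merge survivor is itself merged away", call. = FALSE)
    }
  }
  structure(list(synonym_merges = synonym_merges,
                 collection_rules = collection_rules,
                 correction_map = correction_map),
            class = "label_ruleset")
}

#' Extract labels with an enrichment rule set
#'
#' Annotation text is first passed through the token \code{correction_map},
#' labels are exact-matched, per-collection rules fire additional concepts
#' for matching maps, and synonym-merge pairs collapse the merged column
#' into the survivor by logical OR. With an empty rule set this reduces to
#' \code{\link{extract_exact_labels}}.
#'
#' @param maps list of \code{stat_map}.
#' @param ont a \code{nnod_ontology}.
#' @param vocabulary ordered concept ids.
#' @param rules a \code{\link{ruleset}}.
#' @return Binary label matrix (merged columns removed).
#' @export
apply_ruleset <- function(maps, ont, vocabulary, rules = ruleset()) {
  stopifnot(inherits(rules, "label_ruleset"))
  corrected <- lapply(maps, function(m) {
    for (f in names(m$annotations)) {
      if (identical(f, "image_type")) next
      txt <- m$annotations[[f]]
      for (tok in names(rules$correction_map)) {
        txt <- gsub(name_pattern(tok), rules$correction_map[[tok]], txt,
                    perl = TRUE, ignore.case = TRUE)
      }
      m$annotations[[f]] <- txt
    }
    m
  })
  Y <- extract_exact_labels(corrected, ont, vocabulary)
  if (length(rules$collection_rules)) {
    texts <- vapply(corrected, annotation_text, "")
    ids <- vapply(corrected, `[[`, "", "map_id")
    colls <- vapply(corrected, `[[`, "", "collection_id")
    extra <- matrix(0L, length(corrected), length(vocabulary),
                    dimnames = list(ids, vocabulary))
    for (coll in names(rules$collection_rules)) {
      sel <- colls == coll
      if (!any(sel)) next
      for (rule in rules$collection_rules[[coll]]) {
        hit <- sel & grepl(rule$pattern, texts, perl = TRUE)
        extra[hit, intersect(rule$concepts, vocabulary)] <- 1L
      }
    }
    keep <- rownames(extra)[rowSums(extra) > 0L | rownames(extra) %in% rownames(Y)]
    full <- matrix(0L, length(keep), length(vocabulary),
                   dimnames = list(keep, vocabulary))
    full[rownames(Y)[rownames(Y) %in% keep], ] <-
      Y[rownames(Y) %in% keep, , drop = FALSE]
    full <- pmax(full, extra[keep, , drop = FALSE])
    Y <- full
  }
  if (nrow(rules$synonym_merges)) {
    for (i in seq_len(nrow(rules$synonym_merges))) {
      sv <- rules$synonym_merges$survivor[i]
      mg <- rules$synonym_merges$merged[i]
      if (mg %in% colnames(Y) && sv %in% colnames(Y)) {
        Y[, sv] <- pmax(Y[, sv], Y[, mg])
        Y <- Y[, colnames(Y) != mg, drop = FALSE]
      }
    }
  }
  Y[rowSums(Y) > 0L, , drop = FALSE]
}

phi_correlation <- function(Y) {
  suppressWarnings(cc <- stats::cor(Y))
  cc[!is.finite(cc)] <- 0
  cc
}

#' Prune rare and redundant concepts from a vocabulary
#'
#' Drops concepts with fewer than \code{min_count} positive maps; among
#' pairs whose absolute phi correlation exceeds \code{max_abs_corr}, drops
#' the rarer member (ties: the later concept in vocabulary order), and
#' iterates to a fixed point.
#'
#' @param labels binary label matrix.
#' @param min_count minimum positive count per surviving concept (>= 1).
#' @param max_abs_corr maximum tolerated |phi| between survivors, in (0,1].
#' @return List with \code{vocabulary} (surviving ids, original order) and
#'   \code{labels} (matrix restricted to survivors, zero rows dropped).
#' @export
prune_vocabulary <- function(labels, min_count = 10L, max_abs_corr = 0.95) {
  stopifnot(min_count >= 1L, max_abs_corr > 0, max_abs_corr <= 1)
  Y <- labels
  repeat {
    changed <- FALSE
    counts <- colSums(Y)
    rare <- counts < min_count
    if (any(rare)) {
      Y <- Y[, !rare, drop = FALSE]
      changed <- TRUE
    }
    if (ncol(Y) == 0L) stop("all concepts pruned", call. = FALSE)
    if (ncol(Y) >= 2L) {
      cc <- abs(phi_correlation(Y))
      counts <- colSums(Y)
      offending <- which(upper.tri(cc) & cc > max_abs_corr, arr.ind = TRUE)
      if (nrow(offending)) {
        offending <- offending[order(offending[, 1L], offending[, 2L]), ,
                               drop = FALSE]
        i <- offending[1L, 1L]; j <- offending[1L, 2L]
        drop_j <- counts[j] <= counts[i]   # rarer, tie -> later in order
        Y <- Y[, -(if (drop_j) j else i), drop = FALSE]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  Y <- Y[rowSums(Y) > 0L, , drop = FALSE]
  list(vocabulary = colnames(Y), labels = Y)
}

#' Write / read a label matrix as CSV
#'
#' Long-to-wide CSV with a map_id column followed by one 0/1 column per
#' concept id.
#' @param labels binary matrix.
#' @param path file path.
#' @return \code{path} (write) or the matrix (read).
#' @export
write_labels <- function(labels, path) {
  df <- data.frame(map_id = rownames(labels), labels, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  Y <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(Y) <- "integer"
  rownames(Y) <- df$map_id
  Y
}
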