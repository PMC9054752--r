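#' Construct a concept ontology
#'
#' Concepts with canonical names, a synonym table and hypernymy ("is-a")
#' edges, the structure a cognitive ontology such as Cognitive Atlas
#' provides. The hypernym relation must be acyclic and every synonym must
#' resolve to exactly one concept.
#'
#' @param concepts data.frame with columns \code{id} and \code{name}.
#' @param synonyms optional data.frame with columns \code{name},
#'   \code{concept_id}.
#' @param hypernyms optional data.frame with columns \code{child},
#'   \code{parent} (both concept ids; child is-a parent).
#' @return An object of class \code{nnod_ontology}.
#' @export
ontology <- function(concepts, synonyms = NULL, hypernyms = NULL) {
  concepts <- as.data.frame(concepts, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "name") %in% names(concepts)))
  if (anyDuplicated(concepts$id)) stop("duplicate concept ids", call. = FALSE)
  if (anyDuplicated(tolower(concepts$name))) {
    stop("duplicate concept names", call. = FALSE)
  }
  if (is.null(synonyms)) {
    synonyms <- data.frame(name = character(), concept_id = character(),
                           stringsAsFactors = FALSE)
  }
  if (is.null(hypernyms)) {
    hypernyms <- data.frame(child = character(), parent = character(),
                            stringsAsFactors = FALSE)
  }
  synonyms <- as.data.frame(synonyms, stringsAsFactors = FALSE)
  hypernyms <- as.data.frame(hypernyms, stringsAsFactors = FALSE)
  if (anyDuplicated(tolower(synonyms$name))) {
    stop("a synonym resolves to more than one concept", call. = FALSE)
  }
  if (!all(synonyms$concept_id %in% concepts$id)) {
    stop("synonym points at an unknown concept", call. = FALSE)
  }
  if (nrow(hypernyms) &&
      !all(c(hypernyms$child, hypernyms$parent) %in% concepts$id)) {
    stop("hypernym edge references an unknown concept", call. = FALSE)
  }
  ont <- structure(list(concepts = concepts, synonyms = synonyms,
                        hypernyms = hypernyms),
                   class = "nnod_ontology")
  if (has_cycle(ont)) stop("hypernym relation contains a cycle", call. = FALSE)
  ont
}

has_cycle <- function(ont) {
  edges <- ont$hypernyms
  if (!nrow(edges)) return(FALSE)
  nodes <- unique(c(edges$child, edges$parent))
  repeat {
    # peel nodes with no outgoing child->parent edge left
    sinks <- setdiff(nodes, edges$child)
    if (!length(sinks)) return(length(nodes) > 0L)
    nodes <- setdiff(nodes, sinks)
    edges <- edges[edges$parent %in% nodes & edges$child %in% nodes, ,
                   drop = FALSE]
    if (!length(nodes)) return(FALSE)
  }
}

#' @export
print.nnod_ontology <- function(x, ...) {
  cat(sprintf("<nnod_ontology> %d concepts, %d synonyms, %d hypernym edges\n",
              nrow(x$concepts), nrow(x$synonyms), nrow(x$hypernyms)))
  invisible(x)
}

#' All hypernym ancestors of a set of concepts
#'
#' @param ont a \code{nnod_ontology}.
#' @param ids character vector of concept ids.
#' @return Character vector of ancestor concept ids (excluding \code{ids}
#'   themselves unless a concept is an ancestor of another).
#' @export
concept_ancestors <- function(ont, ids) {
  out <- character()
  frontier <- ids
  while (length(frontier)) {
    parents <- ont$hypernyms$parent[ont$hypernyms$child %in% frontier]
    parents <- setdiff(unique(parents), c(out, ids))
    out <- c(out, parents)
    frontier <- parents
  }
  out
}

concept_depth <- function(ont) {
  ids <- ont$concepts$id
  depth <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  frontier <- setdiff(ids, ont$hypernyms$child)   # roots
  depth[frontier] <- 1L
  while (anyNA(depth)) {
    kids <- ont$hypernyms$child[ont$hypernyms$parent %in% frontier]
    kids <- unique(kids[is.na(depth[kids])])
    if (!length(kids)) break
    for (k in kids) {
      depth[k] <- max(depth[ont$hypernyms$parent[ont$hypernyms$child == k]],
                      na.rm = TRUE) + 1L
    }
    frontier <- kids
  }
  depth
}

ontology_heads <- function() {
  c("perception", "memory", "attention", "comprehension", "recognition",
    "decision making", "response inhibition", "mental imagery", "reasoning",
    "retrieval", "judgment", "conflict monitoring", "response execution",
    "learning", "language", "emotion processing")
}
ontology_mods <- function() {
  c("auditory", "visual", "spatial", "verbal", "motor", "semantic",
    "episodic", "social", "numerical", "tactile", "sentence", "face",
    "object", "reward", "phonological", "working")
}
ontology_mods2 <- function() {
  c("cued", "delayed", "rapid", "covert", "passive", "incidental",
    "forced", "sustained")
}

#' Generate a synthetic concept ontology
#'
#' Builds an acyclic hypernym forest over realistic-sounding cognitive
#' concept names. Names are compositional — bare heads ("perception"),
#' modifier compounds ("auditory perception"), and doubly modified
#' compounds ("cued auditory perception") — and hypernym edges follow the
#' linguistic structure: a compound's parent is the compound obtained by
#' stripping its leading modifier. A concept's name therefore contains the
#' names of exactly its ancestors, mirroring how ontology terms nest in
#' real annotations. Abbreviation-style synonyms (initials or
#' vowel-stripped forms) are attached to \code{n_synonym_pairs} concepts.
#' Deterministic given the seed.
#'
#' @param n_concepts number of concepts (>= 1).
#' @param n_synonym_pairs number of synonyms to attach (at most
#'   \code{n_concepts}).
#' @param max_depth maximum ancestor-chain length (root counts as depth 1).
#' @param seed integer seed.
#' @return A \code{nnod_ontology}.
#' @export
generate_ontology <- function(n_concepts, n_synonym_pairs = 0L,
                              max_depth = 3L, seed = 1L) {
  if (n_concepts < 1L) stop("`n_concepts` must be >= 1", call. = FALSE)
  if (n_synonym_pairs > n_concepts) {
    stop("`n_synonym_pairs` exceeds the number of concepts", call. = FALSE)
  }
  if (max_depth < 1L) stop("`max_depth` must be >= 1", call. = FALSE)
  heads <- ontology_heads()
  withr::with_seed(as.integer(seed), {
    lvl2 <- as.vector(outer(sample(ontology_mods()), sample(heads), paste))
    pool_names <- c(heads, if (max_depth >= 2L) lvl2)
    if (max_depth >= 3L) {
      pool_names <- c(pool_names,
                      as.vector(outer(sample(ontology_mods2()), lvl2, paste)))
    }
    if (n_concepts > length(pool_names)) {
      pool_names <- c(pool_names,
                      paste("process",
                            seq_len(n_concepts - length(pool_names))))
    }
    names_ <- pool_names[seq_len(n_concepts)]  # heads first: parents precede
    ids <- sprintf("c%03d", seq_len(n_concepts))
    id_by_name <- stats::setNames(ids, names_)
    parent_name <- vapply(names_, function(nm) {
      words <- strsplit(nm, " ", fixed = TRUE)[[1L]]
      while (length(words) > 1L) {
        words <- words[-1L]                    # strip leading modifier
        cand <- paste(words, collapse = " ")
        if (cand %in% names_) return(cand)
      }
      NA_character_
    }, "")
    has_parent <- !is.na(parent_name)
    edges_child <- ids[has_parent]
    edges_parent <- unname(id_by_name[parent_name[has_parent]])
    syn_name <- character(); syn_id <- character()
    if (n_synonym_pairs > 0L) {
      chosen <- sample.int(n_concepts, n_synonym_pairs)
      taken <- tolower(names_)
      for (ci in chosen) {
        words <- strsplit(names_[ci], " ", fixed = TRUE)[[1L]]
        cand <- paste(substr(words, 1L, 1L), collapse = "")       # initials
        if (tolower(cand) %in% c(taken, tolower(syn_name))) {
          cand <- gsub("[aeiou]", "", names_[ci])                 # drop vowels
        }
        if (tolower(cand) %in% c(taken, tolower(syn_name))) {
          cand <- paste0(cand, ci)
        }
        syn_name <- c(syn_name, cand)
        syn_id <- c(syn_id, ids[ci])
      }
    }
    ontology(
      data.frame(id = ids, name = names_, stringsAsFactors = FALSE),
      data.frame(name = syn_name, concept_id = syn_id,
                 stringsAsFactors = FALSE),
      data.frame(child = edges_child, parent = edges_parent,
                 stringsAsFactors = FALSE)
    )
  })
}

#' Write an ontology as JSON
#' @param ont a \code{nnod_ontology}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_ontology <- function(ont, path) {
  jsonlite::write_json(
    list(concepts = ont$concepts, synonyms = ont$synonyms,
         hypernym_edges = ont$hypernyms),
    path, dataframe = "rows", auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read an ontology from JSON
#' @param path path written by \code{\link{write_ontology}}.
#' @return A \code{nnod_ontology}.
#' @export
read_ontology <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  syn <- if (length(x$synonyms)) x$synonyms else NULL
  hyp <- if (length(x$hypernym_edges)) x$hypernym_edges else NULL
  ontology(x$concepts, syn, hyp)
}
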