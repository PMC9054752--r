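#' Configuration of the synthetic repository generator
#'
#' The defaults describe the package's standard test world: 3 collections of
#' 170 maps on a small grid, a high signal-to-noise regime (effect size 4
#' vs unit-scale voxel noise), a per-collection baseline confound of
#' comparable scale to one concept's signal, mild annotation noise and a 10%
#' overall contaminant load — a desk-scale caricature of a public
#' statistical-map repository.
#'
#' @param n_collections number of collections.
#' @param maps_per_collection maps in each collection.
#' @param concept_effect_size mean loading added per active concept.
#' @param noise_sd voxelwise Gaussian noise scale.
#' @param baseline_shift_sd scale of the per-collection control-condition
#'   loading pattern, subtracted from every map of the collection with a
#'   map-specific magnitude (the baseline artifact the positive-part
#'   representation mitigates).
#' @param annotation_noise named list of independent Bernoulli probabilities:
#'   \code{synonym} (substitute a registered synonym), \code{abbrev}
#'   (vowel-dropping abbreviation), \code{typo} (single-character typo),
#'   \code{omit} (drop a whole annotation field).
#' @param contaminant_rates named list of probabilities for mutually
#'   exclusive contaminant classes: \code{thresholded}, \code{low_coverage},
#'   \code{wrong_modality}.
#' @param map_type_probs probabilities for drawing each map's type
#'   (named: z, t, beta).
#' @param seed integer seed; generation is bit-identical given the seed.
#' @return A \code{synth_config} list.
#' @export
synth_config <- function(n_collections = 3L,
                         maps_per_collection = 170L,
                         concept_effect_size = 4,
                         noise_sd = 0.5,
                         baseline_shift_sd = 1,
                         annotation_noise = list(synonym = 0.10, abbrev = 0.05,
                                                 typo = 0.05, omit = 0.05),
                         contaminant_rates = list(thresholded = 0.05,
                                                  low_coverage = 0.03,
                                                  wrong_modality = 0.02),
                         map_type_probs = c(z = 0.7, t = 0.2, beta = 0.1),
                         seed = 1L) {
  probs <- c(unlist(annotation_noise), unlist(contaminant_rates))
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0,1]", call. = FALSE)
  }
  if (sum(unlist(contaminant_rates)) > 1) {
    stop("contaminant rates must sum to at most 1", call. = FALSE)
  }
  if (noise_sd < 0 || baseline_shift_sd < 0 || concept_effect_size < 0) {
    stop("scales must be >= 0", call. = FALSE)
  }
  structure(list(n_collections = as.integer(n_collections),
                 maps_per_collection = as.integer(maps_per_collection),
                 concept_effect_size = concept_effect_size,
                 noise_sd = noise_sd,
                 baseline_shift_sd = baseline_shift_sd,
                 annotation_noise = annotation_noise,
                 contaminant_rates = contaminant_rates,
                 map_type_probs = map_type_probs,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Fixed component-loading signature of each concept
#'
#' Each concept is deterministically assigned a sparse non-negative loading
#' vector over the dictionary components — the "brain system" the concept
#' recruits. When a list of dictionaries is given, the signature spans
#' their concatenation, so a concept's network mixes spatial scales and no
#' single resolution captures it completely (the motivation for the
#' stacked representation). A concept inherits its hypernym ancestors'
#' signatures on top of its own components: tasks probing "auditory
#' reasoning" engage the reasoning network plus auditory areas, so the
#' shared ancestor components are the "common responses" that encoding
#' maps display and discriminative decoding down-weights. Signatures
#' depend only on (ontology, dictionary sizes, seed), so they are a
#' stable, learnable decoding target.
#'
#' @param ont a \code{nnod_ontology}.
#' @param dictionary a \code{component_dictionary} or list of them.
#' @param seed integer seed.
#' @param n_active_components components recruited per concept (default 3).
#' @return K x n_concepts matrix (K = total component count), columns
#'   named by concept id.
#' @export
concept_signatures <- function(ont, dictionary, seed,
                               n_active_components = 3L) {
  K <- if (inherits(dictionary, "component_dictionary")) {
    dictionary$K
  } else {
    sum(vapply(dictionary, `[[`, 0L, "K"))
  }
  n_active <- min(as.integer(n_active_components), K)
  ids <- ont$concepts$id
  withr::with_seed(as.integer(seed), {
    own <- matrix(0, nrow = K, ncol = length(ids),
                  dimnames = list(NULL, ids))
    for (j in seq_along(ids)) {
      sup <- sample.int(K, n_active)
      own[sup, j] <- stats::runif(n_active, 0.5, 1.5)
    }
    # inherit ancestor networks, parents before children
    sig <- own
    depth <- concept_depth(ont)[ids]
    for (j in order(depth)) {
      parents <- ont$hypernyms$parent[ont$hypernyms$child == ids[j]]
      parents <- parents[parents %in% ids]
      if (length(parents)) {
        sig[, j] <- own[, j] +
          rowSums(sig[, parents, drop = FALSE])
      }
    }
    sig
  })
}

strip_vowels <- function(s) {
  first <- substr(s, 1L, 1L)
  paste0(first, gsub("[aeiou ]", "", substr(s, 2L, nchar(s))))
}

corrupt_mention <- function(name, concept_id, ont, noise) {
  syns <- ont$synonyms$name[ont$synonyms$concept_id == concept_id]
  if (length(syns) && stats::runif(1) < noise$synonym) {
    name <- syns[[1L]]
  }
  if (stats::runif(1) < noise$abbrev) {
    name <- strip_vowels(name)
  }
  if (stats::runif(1) < noise$typo && nchar(name) > 1L) {
    pos <- sample.int(nchar(name), 1L)
    substr(name, pos, pos) <- sample(letters, 1L)
  }
  name
}

#' Generate a repository of synthetic statistical maps
#'
#' Forward model per map: a uniform 1--3 concepts are active; their fixed
#' component signatures (see \code{\link{concept_signatures}}) are summed
#' and scaled by \code{concept_effect_size}; the collection's
#' control-condition pattern (a non-negative loading vector of scale
#' \code{baseline_shift_sd}) is subtracted with a per-map magnitude drawn
#' uniformly in [0.5, 1.5] — each study uses its own baseline and each
#' contrast removes more or less of it, which is exactly the negative-going
#' artifact the positive-part representation clips away; the result is
#' back-projected to voxels and perturbed by voxelwise Gaussian noise. t-maps are z-maps rescaled by a factor in
#' [0.8, 1.25]; beta-maps add heavier-tailed (Student t, 3 df) noise.
#' Ground truth labels are the hypernym closure of the active set.
#' Annotations carry the active concepts' canonical names, corrupted per
#' \code{annotation_noise}; contaminant maps are injected per
#' \code{contaminant_rates} and flagged in the \code{contaminant} field.
#'
#' @param ont a nonempty \code{nnod_ontology}.
#' @param dictionary the generating \code{component_dictionary}, or a list
#'   of them: signals are then drawn over their concatenation, mixing
#'   spatial scales.
#' @param config a \code{\link{synth_config}}.
#' @return List of \code{stat_map} with attributes \code{signatures}
#'   (K x n_concepts) and \code{baselines} (K x n_collections).
#' @export
generate_repository <- function(ont, dictionary, config = synth_config()) {
  if (!nrow(ont$concepts)) stop("ontology is empty", call. = FALSE)
  dicts <- if (inherits(dictionary, "component_dictionary")) {
    list(dictionary)
  } else {
    dictionary
  }
  C <- do.call(rbind, lapply(dicts, `[[`, "components"))
  K <- nrow(C)
  V <- ncol(C)
  grid <- dicts[[1L]]$grid
  sig <- concept_signatures(ont, dictionary, config$seed)
  ids <- ont$concepts$id
  names_by_id <- stats::setNames(ont$concepts$name, ids)
  cr <- config$contaminant_rates
  an <- config$annotation_noise
  p_cont <- c(thresholded = cr$thresholded, low_coverage = cr$low_coverage,
              wrong_modality = cr$wrong_modality)
  type_p <- config$map_type_probs[c("z", "t", "beta")]

  withr::with_seed(config$seed + 1L, {
    # control conditions recruit a sparse set of regions (~20% of
    # components), strongly: their pattern is zero elsewhere
    baselines <- matrix(0, nrow = K, ncol = config$n_collections,
                        dimnames = list(NULL,
                                        paste0("coll", seq_len(config$n_collections))))
    # control conditions recruit a sparse set of localized (finest-scale)
    # regions: the pattern lives on ~20% of the first dictionary's
    # components and is zero elsewhere
    K1 <- dicts[[1L]]$K
    n_base <- max(1L, round(0.2 * K1))
    for (ci in seq_len(config$n_collections)) {
      sup <- sample.int(K1, n_base)
      baselines[sup, ci] <- abs(stats::rnorm(n_base,
                                             sd = config$baseline_shift_sd))
    }
    maps <- vector("list", config$n_collections * config$maps_per_collection)
    m <- 0L
    for (ci in seq_len(config$n_collections)) {
      coll <- colnames(baselines)[ci]
      for (mi in seq_len(config$maps_per_collection)) {
        m <- m + 1L
        n_act <- sample(1:3, 1L)
        active <- sample(ids, min(n_act, length(ids)))
        loadings <- config$concept_effect_size *
          rowSums(sig[, active, drop = FALSE]) -
          abs(stats::rnorm(1, 0, 1.5)) * baselines[, ci]
        vox <- as.numeric(crossprod(C, loadings))
        if (config$noise_sd > 0) {
          vox <- vox + stats::rnorm(V, sd = config$noise_sd)
        }
        map_type <- sample(c("z", "t", "beta"), 1L, prob = type_p)
        if (map_type == "t") {
          vox <- vox * stats::runif(1, 0.8, 1.25)
        } else if (map_type == "beta") {
          vox <- vox + config$noise_sd * stats::rt(V, df = 3)
        }
        u <- stats::runif(1)
        contaminant <- NULL
        if (u < p_cont[["thresholded"]]) {
          contaminant <- "thresholded"
          vox[abs(vox) < stats::quantile(abs(vox), 0.8)] <- 0
        } else if (u < sum(p_cont[1:2])) {
          contaminant <- "low_coverage"
          vox[seq_along(vox) > 0.3 * V] <- 0     # partial field of view
        } else if (u < sum(p_cont)) {
          contaminant <- "wrong_modality"
          vox <- abs(stats::rnorm(V, mean = 3))  # anatomical-like intensities
        }
        truth <- sort(c(active, concept_ancestors(ont, active)))
        mention <- vapply(active, function(a) {
          corrupt_mention(names_by_id[[a]], a, ont, an)
        }, "")
        ann <- list(
          image_type = if (identical(contaminant, "wrong_modality"))
            "anatomical" else "statistical",
          name = paste(paste(mention, collapse = ", "), "run 1"),
          contrast_definition = paste(paste(mention, collapse = " and "),
                                      "vs baseline"),
          description = "subject-level contrast map"
        )
        if (identical(contaminant, "wrong_modality")) {
          ann$name <- "T1 structural scan"
          ann$contrast_definition <- ""
          truth <- character()
        }
        # field omission: each free-text field independently dropped
        for (f in c("name", "contrast_definition", "description")) {
          if (stats::runif(1) < an$omit) ann[[f]] <- NULL
        }
        maps[[m]] <- stat_map(set_mask_values(grid, vox), map_type, coll,
                              sprintf("m%05d", m), ann,
                              truth_labels = truth, contaminant = contaminant)
      }
    }
    attr(maps, "signatures") <- sig
    attr(maps, "baselines") <- baselines
    maps
  })
}

#' Write a repository to disk
#'
#' One NIfTI-1 image per map, a shared brain-mask image, a JSON manifest per
#' collection (map_id, file, map_type, annotations, collection_id) and a
#' ground-truth CSV (map_id x concept id, 0/1) when truth labels are present.
#'
#' @param maps list of \code{stat_map}.
#' @param dir output directory (created if missing).
#' @param ont optional \code{nnod_ontology}, written as \code{ontology.json}.
#' @return \code{dir}, invisibly.
#' @export
write_repository <- function(maps, dir, ont = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  grid <- maps[[1L]]$volume
  write_nifti(set_mask_values(grid, rep(1, sum(grid$mask))),
              file.path(dir, "mask.nii.gz"))
  colls <- split(maps, vapply(maps, `[[`, "", "collection_id"))
  for (coll in names(colls)) {
    cdir <- file.path(dir, coll)
    dir.create(cdir, showWarnings = FALSE)
    entries <- lapply(colls[[coll]], function(m) {
      fn <- file.path(coll, paste0(m$map_id, ".nii.gz"))
      write_nifti(m$volume, file.path(dir, fn))
      list(map_id = m$map_id, file = fn, map_type = m$map_type,
           collection_id = m$collection_id, annotations = m$annotations)
    })
    jsonlite::write_json(entries, file.path(cdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  if (!is.null(ont)) write_ontology(ont, file.path(dir, "ontology.json"))
  truths <- lapply(maps, `[[`, "truth_labels")
  if (any(lengths(truths) > 0)) {
    concepts <- sort(unique(unlist(truths)))
    tm <- t(vapply(truths, function(tl) as.integer(concepts %in% tl),
                   integer(length(concepts))))
    df <- data.frame(map_id = vapply(maps, `[[`, "", "map_id"), tm)
    names(df) <- c("map_id", concepts)
    utils::write.csv(df, file.path(dir, "ground_truth.csv"), row.names = FALSE)
  }
  invisible(dir)
}

#' Read a repository written by \code{\link{write_repository}}
#'
#' @param dir repository directory.
#' @return List of \code{stat_map} (truth labels reattached when
#'   \code{ground_truth.csv} is present) with attribute \code{ontology}
#'   when \code{ontology.json} is present.
#' @export
read_repository <- function(dir) {
  mask_vol <- read_nifti(file.path(dir, "mask.nii.gz"))
  mask <- array(mask_vol$data != 0, dim = dim(mask_vol$data))
  truth <- NULL
  tf <- file.path(dir, "ground_truth.csv")
  if (file.exists(tf)) {
    truth <- utils::read.csv(tf, check.names = FALSE)
    rownames(truth) <- truth$map_id
  }
  manifests <- sort(list.files(dir, pattern = "^manifest\\.json$",
                               recursive = TRUE, full.names = TRUE))
  maps <- list()
  for (mf in manifests) {
    entries <- jsonlite::read_json(mf)
    for (e in entries) {
      vol <- read_nifti(file.path(dir, e$file))
      vol <- volume(vol$data, vol$affine, mask)
      tl <- NULL
      if (!is.null(truth) && e$map_id %in% rownames(truth)) {
        row <- truth[e$map_id, -1, drop = FALSE]
        tl <- names(row)[as.numeric(row) == 1]
      }
      maps[[length(maps) + 1L]] <- stat_map(
        vol, e$map_type, e$collection_id, e$map_id,
        lapply(e$annotations, as.character), truth_labels = tl)
    }
  }
  of <- file.path(dir, "ontology.json")
  if (file.exists(of)) attr(maps, "ontology") <- read_ontology(of)
  maps
}
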