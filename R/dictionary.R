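#' Construct a component dictionary
#'
#' A dictionary of K non-negative sparse spatial components defined over the
#' in-mask voxels of a shared grid, the representation basis the decoder
#' projects statistical maps onto (DiFuMo-style probabilistic atlases at
#' resolutions such as 128/512/1024 components).
#'
#' @param components K x V numeric matrix of non-negative loadings over the
#'   V in-mask voxels of \code{grid} (V = \code{sum(grid$mask)}).
#' @param grid a \code{nnod_volume} giving the shared geometry and mask.
#' @return An object of class \code{component_dictionary}.
#' @export
component_dictionary <- function(components, grid) {
  components <- as.matrix(components)
  if (ncol(components) != sum(grid$mask)) {
    stop("component columns must equal the in-mask voxel count", call. = FALSE)
  }
  if (any(components < 0)) stop("components must be non-negative", call. = FALSE)
  nz <- rowSums(components != 0)
  if (any(nz == 0)) stop("every component needs >= 1 nonzero voxel", call. = FALSE)
  structure(list(components = components, K = nrow(components), grid = grid),
            class = "component_dictionary")
}

#' @export
print.component_dictionary <- function(x, ...) {
  cat(sprintf("<component_dictionary> K=%d over %d voxels, sparsity %.2f\n",
              x$K, ncol(x$components), mean(x$components == 0)))
  invisible(x)
}

#' Generate a sparse non-negative component dictionary
#'
#' Components are built on a seeded random partition of the in-mask voxels:
#' each component owns a disjoint block of support voxels (so
#' \code{overlap = 0} gives exactly disjoint supports), and a fraction
#' \code{overlap} of each component's support is exchanged for voxels of the
#' preceding component, reproducing the "sparse but overlapping" structure of
#' real functional-mode dictionaries. Loadings are positive uniform draws.
#'
#' @param K number of components (>= 1, at most the in-mask voxel count).
#' @param grid a \code{nnod_volume} with a nonempty mask.
#' @param sparsity target fraction of zero entries per component, in (0,1).
#' @param overlap fraction in [0,1) of each support shared with the previous
#'   component.
#' @param seed integer seed; the result is bit-identical for equal seeds.
#' @return A \code{component_dictionary}.
#' @export
generate_dictionary <- function(K, grid, sparsity = 0.9, overlap = 0.1,
                                seed = 1L) {
  V <- sum(grid$mask)
  if (V == 0L) stop("grid mask is empty", call. = FALSE)
  if (K < 1L || K > V) {
    stop("`K` must be between 1 and the in-mask voxel count (", V, ")",
         call. = FALSE)
  }
  stopifnot(sparsity > 0, sparsity < 1, overlap >= 0, overlap < 1)
  m <- max(1L, round((1 - sparsity) * V))
  withr::with_seed(as.integer(seed), {
    perm <- sample.int(V)
    comps <- matrix(0, nrow = K, ncol = V)
    supports <- vector("list", K)
    for (i in seq_len(K)) {
      # disjoint blocks while they fit; wrap (forced overlap) beyond that
      pos <- ((i - 1L) * m + seq_len(m) - 1L) %% V + 1L
      supports[[i]] <- perm[pos]
    }
    for (i in seq_len(K)) {
      sup <- supports[[i]]
      if (overlap > 0 && i > 1L) {
        n_shared <- round(overlap * m)
        if (n_shared > 0L) {
          shared <- sample(supports[[i - 1L]], min(n_shared, m))
          keep <- sample(sup, m - length(shared))
          sup <- unique(c(keep, shared))
        }
      }
      comps[i, sup] <- stats::runif(length(sup), 0.5, 1.5)
    }
    component_dictionary(comps, grid)
  })
}

#' Generate a multi-resolution dictionary pyramid
#'
#' Builds a trio (or any ladder) of dictionaries the way real
#' multi-resolution functional parcellations relate: the finest level is a
#' random sparse non-negative dictionary; each coarser level aggregates
#' groups of the previous level's components (supports union, loadings
#' add) and then annexes a fraction \code{jitter} of fresh voxels of its
#' own. Coarse components therefore overlap their fine ancestors — so
#' every resolution sees most of a signal spanning the pyramid — without
#' any level's span containing another's, which is what makes stacking the
#' resolutions informative.
#'
#' @param sizes integer component counts, finest first (e.g.
#'   \code{c(1024, 512, 128)} or a scaled-down \code{c(64, 32, 16)}).
#' @param grid a \code{nnod_volume} with a nonempty mask.
#' @param sparsity target zero fraction of the finest level.
#' @param overlap support sharing rate of the finest level.
#' @param jitter fraction of extra own-territory voxels per coarse
#'   component, in [0, 1).
#' @param seed integer seed.
#' @return List of \code{component_dictionary}, in \code{sizes} order.
#' @export
generate_dictionary_pyramid <- function(sizes, grid, sparsity = 0.9,
                                        overlap = 0.1, jitter = 0.3,
                                        seed = 1L) {
  stopifnot(length(sizes) >= 1L, all(diff(sizes) < 0), jitter >= 0,
            jitter < 1)
  dicts <- vector("list", length(sizes))
  dicts[[1L]] <- generate_dictionary(sizes[1L], grid, sparsity, overlap,
                                     seed = seed)
  V <- sum(grid$mask)
  for (j in seq_along(sizes)[-1L]) {
    prev <- dicts[[j - 1L]]$components
    withr::with_seed(as.integer(seed) + j, {
      groups <- split(sample.int(nrow(prev)),
                      cut(seq_len(nrow(prev)), sizes[j], labels = FALSE))
      comps <- t(vapply(groups, function(g) {
        comp <- colSums(prev[g, , drop = FALSE])
        extra <- sample.int(V, round(jitter * sum(comp != 0)))
        comp[extra] <- comp[extra] + stats::runif(length(extra), 0.5, 1.5)
        comp
      }, numeric(V)))
    })
    dicts[[j]] <- component_dictionary(comps, grid)
  }
  dicts
}

#' Back-project component loadings to voxel space
#'
#' Weights each spatial component by its loading and sums, returning a
#' volume on the dictionary grid. For a list of dictionaries (stacked
#' features) the loading vector is split by dictionary size in order and
#' the per-dictionary back-projections are summed.
#'
#' @param loadings numeric vector (length K, or sum of K's for a list).
#' @param dictionary a \code{component_dictionary} or a list of them.
#' @return A \code{nnod_volume}.
#' @export
back_project <- function(loadings, dictionary) {
  if (inherits(dictionary, "component_dictionary")) dictionary <- list(dictionary)
  ks <- vapply(dictionary, `[[`, 0L, "K")
  if (length(loadings) != sum(ks)) {
    stop("loading length must equal the total component count", call. = FALSE)
  }
  grid <- dictionary[[1L]]$grid
  vox <- numeric(sum(grid$mask))
  off <- 0L
  for (d in dictionary) {
    w <- loadings[(off + 1L):(off + d$K)]
    vox <- vox + as.numeric(crossprod(d$components, w))
    off <- off + d$K
  }
  set_mask_values(grid, vox)
}
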