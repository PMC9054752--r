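#' Construct a brain volume
#'
#' A volume couples a 3-D data array with a voxel-to-world affine and a
#' boolean brain mask of the same shape. Values outside the mask carry no
#' signal meaning and are ignored by every downstream computation.
#'
#' @param data 3-D numeric array.
#' @param affine 4x4 invertible voxel-to-world transform (0-based voxel
#'   indices map through \code{affine \%*\% c(i, j, k, 1)}).
#' @param mask logical 3-D array, same shape as \code{data}.
#' @return An object of class \code{nnod_volume}.
#' @export
volume <- function(data, affine, mask) {
  if (length(dim(data)) != 3L) stop("`data` must be a 3-D array", call. = FALSE)
  if (!all(dim(mask) == dim(data))) {
    stop("`mask` and `data` shapes differ", call. = FALSE)
  }
  if (!is.logical(mask)) mask <- array(as.logical(mask), dim(mask))
  if (!all(dim(affine) == c(4L, 4L))) stop("`affine` must be 4x4", call. = FALSE)
  det_a <- det(affine)
  if (!is.finite(det_a) || abs(det_a) < .Machine$double.eps) {
    stop("`affine` must be invertible", call. = FALSE)
  }
  structure(list(data = data, affine = affine, mask = mask),
            class = "nnod_volume")
}

#' Build an empty volume geometry
#'
#' Creates a grid with an isotropic affine and an ellipsoidal "brain" mask
#' inscribed in the array, the shape real standardized templates have after
#' masking. Used as the common target geometry of a study.
#'
#' @param shape integer length-3 array dimensions.
#' @param voxel_size voxel edge length in mm (default 3, typical of
#'   group-level statistical maps).
#' @param mask optional logical array; default is an inscribed ellipsoid.
#' @return A \code{nnod_volume} with zero data.
#' @export
make_grid <- function(shape, voxel_size = 3, mask = NULL) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 1L))
  if (is.null(mask)) {
    cx <- (shape - 1) / 2
    rad <- pmax(shape / 2 - 0.5, 0.5)
    idx <- expand.grid(i = seq_len(shape[1]) - 1,
                       j = seq_len(shape[2]) - 1,
                       k = seq_len(shape[3]) - 1)
    d2 <- ((idx$i - cx[1]) / rad[1])^2 + ((idx$j - cx[2]) / rad[2])^2 +
      ((idx$k - cx[3]) / rad[3])^2
    mask <- array(d2 <= 1, dim = shape)
  }
  affine <- diag(c(rep(voxel_size, 3), 1))
  # centre the world origin like template spaces do
  affine[1:3, 4] <- -voxel_size * (shape - 1) / 2
  volume(array(0, dim = shape), affine, mask)
}

#' @export
print.nnod_volume <- function(x, ...) {
  cat(sprintf("<nnod_volume> %s, %d in-mask voxels\n",
              paste(dim(x$data), collapse = "x"), sum(x$mask)))
  invisible(x)
}

#' In-mask values of a volume
#'
#' @param vol a \code{nnod_volume}.
#' @return Numeric vector of the values inside the mask, in array order.
#' @export
mask_values <- function(vol) {
  as.numeric(vol$data[vol$mask])
}

#' Replace the in-mask values of a volume
#'
#' Out-of-mask voxels are set to zero.
#'
#' @param vol a \code{nnod_volume}.
#' @param values numeric vector, length \code{sum(vol$mask)}.
#' @return The updated volume.
#' @export
set_mask_values <- function(vol, values) {
  stopifnot(length(values) == sum(vol$mask))
  vol$data[] <- 0
  vol$data[vol$mask] <- values
  vol
}

same_geometry <- function(a, b, tol = 1e-6) {
  all(dim(a$data) == dim(b$data)) &&
    max(abs(a$affine - b$affine)) < tol &&
    identical(a$mask, b$mask)
}

#' Construct a statistical map
#'
#' One statistical brain volume together with its repository metadata:
#' the map type (z, t or regression beta), the collection it belongs to
#' and free-text annotation fields.
#'
#' @param vol a \code{nnod_volume}.
#' @param map_type one of \code{"z"}, \code{"t"}, \code{"beta"}.
#' @param collection_id collection identifier.
#' @param map_id map identifier, unique within a repository.
#' @param annotations named list of free-text character fields.
#' @param truth_labels optional character vector of ground-truth concept ids
#'   (synthetic data only).
#' @param contaminant internal contaminant flag (synthetic data only): one of
#'   \code{"thresholded"}, \code{"low_coverage"}, \code{"wrong_modality"} or
#'   \code{NULL}.
#' @return An object of class \code{stat_map}.
#' @export
stat_map <- function(vol, map_type, collection_id, map_id,
                     annotations = list(), truth_labels = NULL,
                     contaminant = NULL) {
  map_type <- match.arg(map_type, c("z", "t", "beta"))
  structure(list(volume = vol, map_type = map_type,
                 collection_id = as.character(collection_id),
                 map_id = as.character(map_id),
                 annotations = annotations,
                 truth_labels = truth_labels,
                 contaminant = contaminant),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("<stat_map> %s [%s-map] collection %s\n",
              x$map_id, x$map_type, x$collection_id))
  invisible(x)
}

#' Manifest table of a repository
#'
#' @param maps list of \code{stat_map}.
#' @return data.frame with one row per map: map_id, collection_id, map_type.
#' @export
repository_manifest <- function(maps) {
  data.frame(
    map_id = vapply(maps, `[[`, "", "map_id"),
    collection_id = vapply(maps, `[[`, "", "collection_id"),
    map_type = vapply(maps, `[[`, "", "map_type"),
    stringsAsFactors = FALSE
  )
}
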