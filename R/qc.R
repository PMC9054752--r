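#' Quality-control filter for statistical maps
#'
#' Applies the map-selection rules of the preparation stage: rejects maps
#' flagged as non-statistical in their metadata (\code{image_type} other
#' than "statistical"), maps whose in-mask nonzero coverage is below
#' \code{coverage_min}, maps whose exact-zero fraction exceeds
#' \code{zero_fraction_max} (a thresholding proxy), and z/t maps whose
#' maximum absolute value exceeds \code{value_cap} (unreasonable for
#' contrast-effect statistics). Beta maps are exempt from the absolute cap
#' but are screened for extreme values by a per-map spike rule: rejected
#' when the in-mask maximum absolute value exceeds \code{beta_spike_factor}
#' times the map's own 99th percentile of absolute values.
#'
#' @param maps list of \code{stat_map}.
#' @param coverage_min minimum fraction of in-mask voxels that are nonzero.
#' @param zero_fraction_max maximum fraction of exact zeros in-mask.
#' @param value_cap maximum |value| for z- and t-maps.
#' @param beta_spike_factor spike ratio bound for beta maps.
#' @return List with \code{kept} (list of \code{stat_map}) and
#'   \code{report} (data.frame: map_id, decision, reasons — semicolon
#'   separated, empty iff kept).
#' @export
qc_filter <- function(maps, coverage_min = 0.5, zero_fraction_max = 0.5,
                      value_cap = 50, beta_spike_factor = 50) {
  stopifnot(coverage_min >= 0, coverage_min <= 1,
            zero_fraction_max >= 0, zero_fraction_max <= 1,
            value_cap > 0, beta_spike_factor > 1)
  if (!length(maps)) {
    return(list(kept = list(),
                report = data.frame(map_id = character(),
                                    decision = character(),
                                    reasons = character(),
                                    stringsAsFactors = FALSE)))
  }
  reasons <- lapply(maps, function(m) {
    r <- character()
    itype <- m$annotations$image_type
    if (!is.null(itype) && !identical(itype, "statistical")) {
      r <- c(r, "wrong_modality")
    }
    v <- mask_values(m$volume)
    zero_frac <- mean(v == 0)
    if (1 - zero_frac < coverage_min) r <- c(r, "low_coverage")
    if (zero_frac > zero_fraction_max) r <- c(r, "thresholded")
    if (m$map_type %in% c("z", "t")) {
      if (max(abs(v)) > value_cap) r <- c(r, "extreme_values")
    } else {
      p99 <- stats::quantile(abs(v), 0.99, names = FALSE)
      if (p99 > 0 && max(abs(v)) > beta_spike_factor * p99) {
        r <- c(r, "extreme_values")
      }
    }
    r
  })
  rejected <- lengths(reasons) > 0L
  report <- data.frame(
    map_id = vapply(maps, `[[`, "", "map_id"),
    decision = ifelse(rejected, "rejected", "kept"),
    reasons = vapply(reasons, paste, "", collapse = ";"),
    stringsAsFactors = FALSE
  )
  list(kept = maps[!rejected], report = report)
}

#' Resample a map to a common grid
#'
#' Standardizes a map to the target geometry: every target in-mask voxel is
#' mapped through the target affine to world coordinates, then through the
#' inverse source affine to source voxel coordinates, and the value is
#' interpolated trilinearly (points outside the source array get 0). The
#' target mask is adopted as-is; out-of-mask voxels are set to zero.
#'
#' @param map a \code{stat_map}.
#' @param target a \code{nnod_volume} giving the target geometry.
#' @return The resampled \code{stat_map} on the target grid.
#' @export
resample_to_common <- function(map, target) {
  src <- map$volume
  det_a <- det(src$affine)
  if (!is.finite(det_a) || abs(det_a) < .Machine$double.eps) {
    stop("source affine is not invertible", call. = FALSE)
  }
  if (same_geometry(src, target)) {
    out <- target
    out$data[] <- 0
    out$data[target$mask] <- src$data[target$mask]
    map$volume <- out
    return(map)
  }
  tdim <- dim(target$data)
  idx <- which(target$mask, arr.ind = TRUE) - 1   # 0-based voxel indices
  world <- target$affine %*% rbind(t(idx), 1)
  svox <- solve(src$affine, world)[1:3, , drop = FALSE]
  vals <- trilinear_sample(src$data, svox)
  map$volume <- set_mask_values(volume(array(0, tdim), target$affine,
                                       target$mask), vals)
  map
}

# vectorized trilinear interpolation; pts is 3 x n of 0-based coordinates.
# Out-of-bounds coordinates are clamped to the boundary (nearest-edge
# extension), which keeps interpolation exact on constant images.
trilinear_sample <- function(arr, pts) {
  d <- dim(arr)
  for (m in 1:3) pts[m, ] <- pmin(pmax(pts[m, ], 0), d[m] - 1)
  f <- floor(pts)
  w <- pts - f
  out <- numeric(ncol(pts))
  for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
    i <- pmin(f[1, ] + di, d[1] - 1)
    j <- pmin(f[2, ] + dj, d[2] - 1)
    k <- pmin(f[3, ] + dk, d[3] - 1)
    wt <- (if (di) w[1, ] else 1 - w[1, ]) *
          (if (dj) w[2, ] else 1 - w[2, ]) *
          (if (dk) w[3, ] else 1 - w[3, ])
    out <- out + wt * arr[1 + i + d[1] * (j + d[2] * k)]
  }
  out
}

#' Remove exact-duplicate maps
#'
#' Maps whose standardized in-mask values are bit-identical are collapsed
#' to the first occurrence, the uniqueness step of map preparation.
#'
#' @param maps list of \code{stat_map} on a common grid.
#' @return The deduplicated list, original order preserved.
#' @export
deduplicate <- function(maps) {
  if (length(maps) <= 1L) return(maps)
  keys <- vapply(maps, function(m) {
    paste(format(mask_values(m$volume), digits = 17), collapse = ",")
  }, "")
  maps[!duplicated(keys)]
}

#' Write a QC report as CSV
#' @param report data.frame from \code{\link{qc_filter}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_qc_report <- function(report, path) {
  utils::write.csv(report, path, row.names = FALSE)
  invisible(path)
}
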