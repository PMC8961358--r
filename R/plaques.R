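## Amyloid plaque segmentation and dendrite-to-plaque edge distances.

#' Segment plaques from a ThioS-like channel
#'
#' Bright connected components above a hysteresis threshold (Otsu seed,
#' relative weak level), kept when their volume reaches the floor given
#' as an equivalent diameter (default 2 um). Gain-invariant by
#' construction.
#'
#' @param stack an [image_stack()].
#' @param channel plaque channel name.
#' @param min_equiv_diameter_um smallest plaque kept, as the diameter of
#'   the equivalent sphere.
#' @return list of `plaque` objects: `voxels` (linear indices),
#'   `centroid_um`, `volume_um3`, `equivalent_radius_um`.
#' @export
segment_plaques <- function(stack, channel = "thios",
                            min_equiv_diameter_um = 2) {
  mask <- suppressWarnings(
    segment_neurites(stack, channel, smooth_sigma_um = 0.4,
                     weak_factor = 0.45, min_volume_um3 = 0))
  d <- dim(mask); vs <- stack$voxel_size_um
  if (!any(mask)) return(list())
  lab <- cpp_label3d(as.logical(mask), as.integer(d))
  vol_vox <- prod(vs)
  min_vol <- 4 / 3 * pi * (min_equiv_diameter_um / 2)^3
  out <- list()
  for (li in seq_len(max(lab))) {
    vox <- which(lab == li)
    vol <- length(vox) * vol_vox
    if (vol < min_vol) next
    ctr <- colMeans(voxel_centres(stack, vox))
    out[[length(out) + 1L]] <- structure(
      list(voxels = vox, centroid_um = ctr, volume_um3 = vol,
           equivalent_radius_um = (3 * vol / (4 * pi))^(1 / 3)),
      class = "plaque")
  }
  out
}

#' @export
print.plaque <- function(x, ...) {
  cat("plaque: centroid (", paste(round(x$centroid_um, 2), collapse = ", "),
      ") um, equivalent radius ", round(x$equivalent_radius_um, 2), " um\n",
      sep = "")
  invisible(x)
}

#' Distance from a dendrite segment to the nearest plaque edge
#'
#' The segment-level scalar: the minimum over plaques of the minimum
#' Euclidean (3-D, physical) distance from any path point to the
#' plaque's voxel surface. A path point inside a plaque gives 0. With
#' no plaques present the distinguished no-plaque value `NA` is
#' returned -- never 0.
#'
#' @param segment a `dendrite_segment` (or n x 3 path matrix).
#' @param plaques list of `plaque` from [segment_plaques()].
#' @param stack the stack the plaques were segmented from.
#' @return distance in um, or `NA_real_` when `plaques` is empty.
#' @export
distance_to_nearest_plaque <- function(segment, plaques, stack) {
  if (!length(plaques)) return(NA_real_)
  path <- if (inherits(segment, "dendrite_segment")) segment$path
          else as.matrix(segment)
  d <- stack_dim(stack)
  best <- Inf
  pvx <- linear_index(d, phys_to_voxel(stack, path))
  for (pl in plaques) {
    if (any(pvx %in% pl$voxels)) return(0)
    m <- array(FALSE, d); m[pl$voxels] <- TRUE
    dd <- min(cpp_dist_points_to_mask(path, as.logical(m), as.integer(d),
                                      stack$voxel_size_um, stack$origin))
    best <- min(best, dd)
  }
  best
}

#' Bin a plaque distance into near / far / no-plaque
#'
#' Near is the closed interval 0-30 um from the plaque edge; far is
#' strictly greater than 30 um; the no-plaque value (`NA`) maps to
#' `"no_plaque"`.
#'
#' @param distance_um distance(s) from [distance_to_nearest_plaque()].
#' @param near_max_um the near/far boundary (default 30 um, inclusive
#'   on the near side).
#' @return factor with levels near, far, no_plaque.
#' @export
proximity_bin <- function(distance_um, near_max_um = 30) {
  out <- character(length(distance_um))
  na <- is.na(distance_um)
  if (any(distance_um[!na] < 0)) stop("negative plaque distance")
  out[na] <- "no_plaque"
  out[!na & distance_um <= near_max_um] <- "near"
  out[!na & distance_um > near_max_um] <- "far"
  factor(out, levels = c("near", "far", "no_plaque"))
}
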