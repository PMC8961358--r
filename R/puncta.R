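## Synaptic puncta detection, density along processes, object-level
## colocalisation, and background-normalised intensity measures.

#' Detect punctate objects in a channel
#'
#' Band-pass (difference-of-Gaussians) filtering followed by
#' thresholding at a robust multiple of the filtered background spread;
#' connected components within the volume bounds become puncta.
#' Components holding two or more well-separated local intensity peaks
#' are split by nearest-peak assignment (a seeded watershed on peak
#' geometry), so touching blobs resolve into separate puncta.
#'
#' @param stack an [image_stack()].
#' @param channel channel to detect in.
#' @param size_bounds_um3 (min, max) accepted component volume.
#' @param dog_sigma_um inner Gaussian sigma of the band-pass (um);
#'   the outer sigma is twice this.
#' @param k threshold in robust SDs of the filtered image.
#' @param split_min_sep_um minimal peak separation that splits a
#'   component.
#' @return list of `punctum`: `centroid_um`, `volume_um3`,
#'   `peak_intensity`, `mean_intensity`, `channel`.
#' @export
detect_puncta <- function(stack, channel, size_bounds_um3 = c(0.02, 3),
                          dog_sigma_um = 0.15, k = 6,
                          split_min_sep_um = 0.8) {
  img <- get_channel(stack, channel)
  d <- dim(img); vs <- stack$voxel_size_um
  s1 <- pmax(dog_sigma_um / vs, 0.3)
  g1 <- cpp_gauss3d(as.numeric(img), as.integer(d), s1)
  g2 <- cpp_gauss3d(as.numeric(img), as.integer(d), 2 * s1)
  dog <- g1 - g2
  thr <- stats::median(dog) + k * stats::mad(dog)
  mask <- array(dog > thr, d)
  if (!any(mask)) return(list())
  lab <- cpp_label3d(as.logical(mask), as.integer(d))
  vol_vox <- prod(vs)
  out <- list()
  for (li in seq_len(max(lab))) {
    vox <- which(lab == li)
    vol <- length(vox) * vol_vox
    if (vol < size_bounds_um3[1L] || vol > size_bounds_um3[2L] * 4) next
    cc <- voxel_centres(stack, vox)
    iv <- dog[vox]
    # split touching blobs on distinct peaks
    pk <- vox[iv >= 0.6 * max(iv)]
    pkc <- voxel_centres(stack, pk)
    ncl <- if (nrow(pkc) >= 2L)
      count_point_clusters(pkc, link_um = split_min_sep_um, min_size = 1L)
      else 1L
    if (ncl >= 2L) {
      km <- suppressWarnings(stats::kmeans(cc, centers = min(ncl, 4L),
                                           nstart = 3L))
      groups <- km$cluster
    } else groups <- rep(1L, length(vox))
    for (g in unique(groups)) {
      gi <- groups == g
      vol_g <- sum(gi) * vol_vox
      if (vol_g < size_bounds_um3[1L] || vol_g > size_bounds_um3[2L]) next
      wts <- pmax(iv[gi], 0)
      ctr <- colSums(cc[gi, , drop = FALSE] * wts) / sum(wts)
      out[[length(out) + 1L]] <- structure(
        list(centroid_um = ctr, volume_um3 = vol_g,
             peak_intensity = max(img[vox[gi]]),
             mean_intensity = mean(img[vox[gi]]),
             channel = channel),
        class = "punctum")
    }
  }
  out
}

puncta_centroids <- function(puncta) {
  if (!length(puncta)) return(matrix(numeric(), ncol = 3L))
  do.call(rbind, lapply(puncta, `[[`, "centroid_um"))
}

#' Density of puncta along traced processes
#'
#' Counts puncta whose centroid lies within `max_offset_um` of any of
#' the given process paths and divides by the total path length.
#'
#' @param puncta list of `punctum` (or an n x 3 centroid matrix).
#' @param paths a single n x 3 path, a list of paths, or a
#'   `skeleton_graph` whose edges are used.
#' @param max_offset_um maximal centroid-to-path distance counted as
#'   on-process (default 1 um).
#' @return puncta per um of process length.
#' @export
synapse_density_along <- function(puncta, paths, max_offset_um = 1) {
  if (inherits(paths, "skeleton_graph"))
    paths <- lapply(paths$edges, `[[`, "path")
  if (is.matrix(paths)) paths <- list(paths)
  total_len <- sum(vapply(paths, polyline_length, 1))
  if (total_len <= 0) stop("zero-length skeleton")
  ctr <- if (is.matrix(puncta)) puncta else puncta_centroids(puncta)
  if (!nrow(ctr)) return(0)
  dmin <- rep(Inf, nrow(ctr))
  for (p in paths)
    dmin <- pmin(dmin, cpp_dist_points_to_polyline(ctr, p))
  sum(dmin <= max_offset_um) / total_len
}

#' Object-level colocalisation of two puncta sets
#'
#' Greedy nearest-neighbour matching under a criterion radius, each
#' punctum used at most once. The reported fraction is directional:
#' matched query puncta over total query puncta (e.g. Kv3.4 puncta with
#' a Homer partner / all Kv3.4 puncta). With no query puncta the
#' fraction is undefined (`NA`) rather than 0.
#'
#' @param query,reference lists of `punctum` or n x 3 centroid matrices.
#' @param criterion_radius_um maximal centroid distance for a match.
#' @return list: `fraction`, `n_matched`, `n_query`, `pairs`
#'   (query index, reference index, distance), `undefined` flag.
#' @export
colocalise <- function(query, reference, criterion_radius_um = 0.5) {
  q <- if (is.matrix(query)) query else puncta_centroids(query)
  r <- if (is.matrix(reference)) reference else puncta_centroids(reference)
  nq <- nrow(q); nr <- nrow(r)
  if (nq == 0L)
    return(list(fraction = NA_real_, n_matched = 0L, n_query = 0L,
                pairs = data.frame(), undefined = TRUE))
  pairs <- data.frame(qi = integer(), ri = integer(), dist = numeric())
  if (nr > 0L) {
    dm <- matrix(Inf, nq, nr)
    for (j in seq_len(nr))
      dm[, j] <- sqrt(colSums((t(q) - r[j, ])^2))
    cand <- which(dm <= criterion_radius_um, arr.ind = TRUE)
    if (nrow(cand)) {
      ord <- order(dm[cand])
      used_q <- logical(nq); used_r <- logical(nr)
      for (i in ord) {
        qi <- cand[i, 1L]; ri <- cand[i, 2L]
        if (used_q[qi] || used_r[ri]) next
        used_q[qi] <- TRUE; used_r[ri] <- TRUE
        pairs <- rbind(pairs, data.frame(qi = qi, ri = ri,
                                         dist = dm[qi, ri]))
      }
    }
  }
  list(fraction = nrow(pairs) / nq, n_matched = nrow(pairs), n_query = nq,
       pairs = pairs, undefined = FALSE)
}

# Background region: voxels of the ROI's z-sections well clear of all
# objects (distance > clearance from the object mask).
background_region <- function(stack, roi_mask, objects_mask = NULL,
                              clearance_um = 2.5) {
  d <- stack_dim(stack); vs <- stack$voxel_size_um
  if (is.null(objects_mask)) objects_mask <- roi_mask
  z_used <- which(apply(roi_mask, 3L, any))
  bg <- array(FALSE, d)
  if (any(objects_mask)) {
    dist_to_obj <- array(cpp_edt3d(as.logical(!objects_mask), as.integer(d),
                                   vs), d)
    far <- dist_to_obj > clearance_um
  } else far <- array(TRUE, d)
  bg[, , z_used] <- far[, , z_used]
  bg
}

#' Background-normalised intensity of a region of interest
#'
#' The ratio of the mean intensity within the ROI to the mean background
#' intensity sampled from the same z-sections the ROI occupies.
#' Background voxels are, by default, all voxels well clear of the
#' object mask in those sections (`policy = "outside_objects"`, which
#' keeps the estimate unbiased under Poisson + read noise); the
#' alternative `"lowest_decile"` uses the dimmest decile of those voxels
#' for cluttered fields.
#'
#' @param stack an [image_stack()].
#' @param channel intensity channel.
#' @param roi_mask logical array selecting the ROI.
#' @param objects_mask logical array of all structures to exclude from
#'   background (defaults to the ROI itself).
#' @param policy `"outside_objects"` or `"lowest_decile"`.
#' @param clearance_um exclusion margin around objects.
#' @return list: `roi_mean`, `background_mean`, `ratio`, `n_roi`,
#'   `n_background`.
#' @export
normalised_intensity <- function(stack, channel, roi_mask,
                                 objects_mask = NULL,
                                 policy = c("outside_objects",
                                            "lowest_decile"),
                                 clearance_um = 2.5) {
  policy <- match.arg(policy)
  img <- get_channel(stack, channel)
  if (!any(roi_mask)) stop("empty ROI")
  bg_mask <- background_region(stack, roi_mask, objects_mask, clearance_um)
  if (!any(bg_mask)) stop("no background voxels available")
  bg_vals <- img[bg_mask]
  if (policy == "lowest_decile")
    bg_vals <- bg_vals[bg_vals <= stats::quantile(bg_vals, 0.1)]
  roi_mean <- mean(img[roi_mask])
  bg_mean <- mean(bg_vals)
  if (bg_mean <= 0) stop("background mean is zero")
  list(roi_mean = roi_mean, background_mean = bg_mean,
       ratio = roi_mean / bg_mean,
       n_roi = sum(roi_mask), n_background = length(bg_vals))
}

#' Mean (optionally normalised) channel intensity within a process mask
#'
#' Mean intensity of `channel` over the MAP2-positive voxels, with the
#' same background-normalisation policy as [normalised_intensity()]
#' available.
#'
#' @param stack an [image_stack()].
#' @param channel intensity channel (e.g. Kv3.4 stain).
#' @param process_mask logical array of the dendrite (MAP2) voxels.
#' @param normalise divide by the background mean from the same
#'   z-sections.
#' @inheritParams normalised_intensity
#' @return list: `mean_intensity`, and when normalising also
#'   `background_mean` and `ratio`.
#' @export
dendritic_intensity <- function(stack, channel, process_mask,
                                normalise = TRUE, clearance_um = 2.5) {
  if (!any(process_mask)) stop("empty process mask")
  img <- get_channel(stack, channel)
  m <- mean(img[process_mask])
  if (!normalise) return(list(mean_intensity = m))
  res <- normalised_intensity(stack, channel, process_mask,
                              clearance_um = clearance_um)
  list(mean_intensity = m, background_mean = res$background_mean,
       ratio = m / res$background_mean)
}
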