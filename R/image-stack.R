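#' Calibrated multi-channel 3-D image stack
#'
#' `image_stack()` bundles one or more 3-D intensity arrays with their
#' physical calibration. All channels share a single voxel grid; voxel
#' sizes are in micrometres and the physical coordinate of the centre of
#' voxel `(i, j, k)` (1-based) is `origin + (c(i, j, k) - 0.5) * voxel_size_um`.
#'
#' @param channels named list of numeric 3-D arrays (identical dims), or a
#'   single array. Intensities must be non-negative.
#' @param voxel_size_um numeric length-3, voxel pitch in um along (x, y, z).
#' @param origin physical coordinate (um) of the corner of voxel (1,1,1).
#' @return an object of class `image_stack`.
#' @export
image_stack <- function(channels, voxel_size_um, origin = c(0, 0, 0)) {
  if (is.array(channels)) channels <- list(ch1 = channels)
  if (is.null(names(channels)) || any(!nzchar(names(channels))))
    stop("channels must be a named list")
  dims <- lapply(channels, dim)
  if (any(vapply(dims, length, 1L) != 3L))
    stop("each channel must be a 3-D array")
  if (length(unique(lapply(dims, as.integer))) != 1L)
    stop("all channels must share one grid shape")
  voxel_size_um <- as.numeric(voxel_size_um)
  if (length(voxel_size_um) != 3L || any(!is.finite(voxel_size_um)) ||
      any(voxel_size_um <= 0))
    stop("voxel_size_um must be three strictly positive numbers")
  if (any(vapply(channels, function(ch) any(ch < 0), TRUE)))
    stop("intensities must be non-negative")
  structure(
    list(channels = channels, voxel_size_um = voxel_size_um,
         origin = as.numeric(origin)),
    class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- stack_dim(x)
  cat("image_stack:", paste(d, collapse = " x "), "voxels,",
      length(x$channels), "channel(s)\n")
  cat("  channels  :", paste(names(x$channels), collapse = ", "), "\n")
  cat("  voxel size:", paste(signif(x$voxel_size_um, 4), collapse = " x "),
      "um\n")
  cat("  extent    :",
      paste(signif(d * x$voxel_size_um, 4), collapse = " x "), "um\n")
  invisible(x)
}

#' @rdname image_stack
#' @param x an `image_stack`.
#' @export
stack_dim <- function(x) dim(x$channels[[1L]])

#' @rdname image_stack
#' @param channel channel name or index.
#' @export
get_channel <- function(x, channel) {
  if (is.character(channel) && !channel %in% names(x$channels))
    stop("no channel named '", channel, "'")
  x$channels[[channel]]
}

# Physical centre coordinates of all voxels of a logical/index subset,
# as an n x 3 matrix.
voxel_centres <- function(stack, which_idx) {
  d <- stack_dim(stack)
  ijk <- arrayInd(which_idx, d)
  sweep(sweep(ijk - 0.5, 2, stack$voxel_size_um, "*"), 2, stack$origin, "+")
}

# Convert physical points (n x 3) to nearest 1-based voxel indices,
# clamped to the grid.
phys_to_voxel <- function(stack, points) {
  d <- stack_dim(stack)
  ijk <- sweep(points, 2, stack$origin, "-")
  ijk <- sweep(ijk, 2, stack$voxel_size_um, "/") + 0.5
  ijk <- round(ijk)
  for (a in 1:3) ijk[, a] <- pmin(pmax(ijk[, a], 1L), d[a])
  storage.mode(ijk) <- "integer"
  ijk
}

linear_index <- function(dims, ijk) {
  ijk[, 1L] + dims[1L] * (ijk[, 2L] - 1L) + dims[1L] * dims[2L] * (ijk[, 3L] - 1L)
}
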