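#' Write a calibrated stack to multi-page TIFF
#'
#' Pages are ordered channel-major (all z-slices of channel 1, then
#' channel 2, ...), written as 32-bit float after scaling to `[0, 1]`.
#' Calibration (voxel size, origin, channel names, intensity scale) is
#' embedded in an ImageJ-style description tag and duplicated in a JSON
#' sidecar `<path>.json`, which is the authoritative record on re-read.
#'
#' @param stack an [image_stack()].
#' @param path output TIFF filename.
#' @param sidecar write the JSON sidecar (default TRUE).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, sidecar = TRUE) {
  d <- stack_dim(stack)
  scale <- max(1e-12, max(vapply(stack$channels, max, 1)))
  pages <- list()
  for (ch in names(stack$channels)) {
    arr <- stack$channels[[ch]] / scale
    for (k in seq_len(d[3L]))
      # TIFF pages are row-major images: rows = y, cols = x
      pages[[length(pages) + 1L]] <- t(arr[, , k])
  }
  desc <- paste0(
    "ImageJ=1.53\nimages=", length(pages),
    "\nchannels=", length(stack$channels),
    "\nslices=", d[3L],
    "\nunit=micron\nspacing=", format(stack$voxel_size_um[3L], digits = 12),
    "\n")
  attr(pages[[1L]], "description") <- desc
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE,
                  compression = "none")
  if (sidecar) {
    meta <- list(channel_names = names(stack$channels),
                 voxel_size_um = stack$voxel_size_um,
                 origin = stack$origin,
                 dim = d,
                 intensity_scale = scale)
    jsonlite::write_json(meta, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a calibrated stack from multi-page TIFF
#'
#' Calibration is resolved from the JSON sidecar `<path>.json` when
#' present, otherwise from ImageJ-style metadata in the TIFF description
#' tag plus the x-resolution tag. A file with neither is rejected:
#' voxel sizes are never silently assumed.
#'
#' @param path TIFF filename written by [write_stack()] or an
#'   ImageJ-convention multi-page TIFF.
#' @return an [image_stack()].
#' @export
read_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    vs <- as.numeric(meta$voxel_size_um)
    ch_names <- meta$channel_names
    n_ch <- length(ch_names)
    origin <- as.numeric(meta$origin %||% c(0, 0, 0))
    scale <- meta$intensity_scale %||% 1
  } else {
    info <- attributes(pages[[1L]])
    desc <- info$description %||% ""
    if (!grepl("unit=micron", desc, fixed = TRUE) ||
        is.null(info$x.resolution))
      stop("no voxel-size calibration: missing sidecar '", sidecar,
           "' and no ImageJ metadata in the TIFF; refusing to assume 1 um voxels")
    spacing <- as.numeric(sub(".*spacing=([0-9.eE+-]+).*", "\\1", desc))
    xy <- 1 / info$x.resolution
    vs <- c(xy, xy, spacing)
    n_ch <- if (grepl("channels=", desc))
      as.integer(sub(".*channels=([0-9]+).*", "\\1", desc)) else 1L
    ch_names <- paste0("ch", seq_len(n_ch))
    origin <- c(0, 0, 0)
    scale <- 1
  }
  n_pages <- length(pages)
  if (n_pages %% n_ch != 0L) stop("page count not divisible by channel count")
  nz <- n_pages %/% n_ch
  nx <- ncol(pages[[1L]]); ny <- nrow(pages[[1L]])
  channels <- vector("list", n_ch)
  for (c_i in seq_len(n_ch)) {
    arr <- array(0, dim = c(nx, ny, nz))
    for (k in seq_len(nz)) {
      pg <- pages[[(c_i - 1L) * nz + k]]
      if (length(dim(pg)) == 3L) pg <- pg[, , 1L]   # tolerate grey-as-RGB
      arr[, , k] <- t(pg)
    }
    channels[[c_i]] <- arr * scale
  }
  names(channels) <- ch_names
  image_stack(channels, voxel_size_um = vs, origin = origin)
}

#' Code-blind a set of image files before measurement
#'
#' Copies each file (and its sidecar, if any) under an opaque code drawn
#' as a random permutation, so the measuring observer cannot infer the
#' experimental condition from the filename. Optionally exports a
#' single-channel greyscale copy of the measurement channel, mirroring
#' blinded greyscale quantification. The key mapping codes back to the
#' original names is written separately and only consulted at unblinding.
#'
#' @param paths character vector of distinct stack filenames.
#' @param seed integer; fixes the permutation.
#' @param out_dir directory receiving the blinded copies.
#' @param greyscale_channel optional channel name; when given, a
#'   greyscale single-channel TIFF `<code>_grey.tif` is also written.
#' @return a `blinding_key`: data.frame with columns `original`, `code`,
#'   plus attributes `seed` and `out_dir`.
#' @export
blind_dataset <- function(paths, seed, out_dir = tempfile("blinded"),
                          greyscale_channel = NULL) {
  if (anyDuplicated(paths)) stop("paths must be distinct")
  if (!all(file.exists(paths))) stop("missing input file(s)")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  n <- length(paths)
  codes <- with_seed(seed, sprintf("IMG%04d", sample.int(max(n, 1L) * 10L, n)))
  stopifnot(!anyDuplicated(codes))   # sample.int without replacement
  key <- data.frame(original = paths,
                    code = paste0(codes, ".tif"),
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    dest <- file.path(out_dir, key$code[i])
    file.copy(paths[i], dest, overwrite = TRUE)
    sc <- paste0(paths[i], ".json")
    if (file.exists(sc)) file.copy(sc, paste0(dest, ".json"), overwrite = TRUE)
    if (!is.null(greyscale_channel)) {
      st <- read_stack(paths[i])
      grey <- image_stack(
        stats::setNames(list(get_channel(st, greyscale_channel)), "grey"),
        st$voxel_size_um, st$origin)
      write_stack(grey, file.path(out_dir, sub("\\.tif$", "_grey.tif",
                                               key$code[i])))
    }
  }
  structure(key, seed = seed, out_dir = out_dir, class = c("blinding_key",
                                                           "data.frame"))
}

#' Reverse a blinding key
#'
#' @param key a `blinding_key` from [blind_dataset()].
#' @param codes optional subset of codes; default all.
#' @return named character vector code -> original filename.
#' @export
unblind <- function(key, codes = key$code) {
  m <- match(codes, key$code)
  if (anyNA(m)) stop("unknown code(s): ", paste(codes[is.na(m)], collapse = ", "))
  stats::setNames(key$original[m], codes)
}
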