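#' Quantify one dendrite field end to end
#'
#' The full per-stack measurement chain: segment the fill channel,
#' skeletonise, extract segments passing the length filter, detect /
#' measure / classify spines, compute linear density and shaft
#' diameters, and (when a plaque channel is present) the distance to
#' the nearest plaque edge with its near/far bin. Returns one dendrite
#' record per admitted segment, ready for the stats layer.
#'
#' @param stack an [image_stack()].
#' @param fill_channel neuron-fill channel name.
#' @param thios_channel optional plaque channel name.
#' @param labels named list of condition labels copied onto each record
#'   (e.g. mouse_id, genotype, treatment).
#' @param min_length_um segment inclusion filter (um).
#' @param source image identifier recorded on each row.
#' @return data.frame of dendrite records (possibly 0 rows): labels,
#'   `length_um`, `density_per_um`, per-class counts, `mean_diameter_um`,
#'   `tortuosity`, `distance_um`, `proximity`.
#' @export
quantify_dendrite_field <- function(stack, fill_channel = "fill",
                                    thios_channel = NULL, labels = list(),
                                    min_length_um = 20,
                                    source = NA_character_) {
  mask <- suppressWarnings(segment_neurites(stack, fill_channel))
  empty <- data.frame()
  if (!any(mask)) return(empty)
  skel <- skeletonize(mask, stack$voxel_size_um)
  segs <- extract_segments(skel, min_length_um, source = source,
                           labels = labels)
  if (!length(segs)) return(empty)
  plaques <- if (!is.null(thios_channel))
    segment_plaques(stack, thios_channel) else list()
  rows <- lapply(segs, function(seg) {
    seg <- tryCatch(shaft_diameter(seg, mask, stack$voxel_size_um,
                                   stack = stack, channel = fill_channel),
                    error = function(e) seg)
    sp <- quantify_spines(stack, mask, seg)
    dist_um <- if (!is.null(thios_channel))
      distance_to_nearest_plaque(seg, plaques, stack) else NA_real_
    rec <- data.frame(
      length_um = seg$length_um,
      density_per_um = spine_density(seg, sp),
      n_mushroom = sum(sp$spine_class == "mushroom"),
      n_thin = sum(sp$spine_class == "thin"),
      n_stubby = sum(sp$spine_class == "stubby"),
      n_branched = sum(sp$spine_class == "branched"),
      mean_diameter_um = seg$mean_diameter_um,
      tortuosity = tortuosity(seg),
      distance_um = dist_um,
      proximity = proximity_bin(dist_um),
      stringsAsFactors = FALSE)
    for (nm in rev(names(labels))) rec <- cbind(stats::setNames(
      data.frame(labels[[nm]], stringsAsFactors = FALSE), nm), rec)
    rec
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
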