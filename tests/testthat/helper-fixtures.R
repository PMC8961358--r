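# Shared desk-scale fixtures. All stacks are generated in code; sizes
# are chosen so each test runs in seconds while structures stay
# resolvable (lateral pixel 0.15 um, z-step 0.3 um).

test_recipe <- function(seed = 1L, field = c(34, 16), z = 8,
                        xy = 0.15, noise = list(photon_scale = 1,
                                                read_sd = 2)) {
  stack_recipe(field_size_um = field, z_depth_um = z, z_step_um = 0.3,
               xy_pixel_um = xy, noise = noise, seed = seed)
}

noiseless_recipe <- function(seed = 1L, ...) {
  test_recipe(seed = seed, noise = list(photon_scale = 0, read_sd = 0), ...)
}

# Render a bare tube (optionally with extra capsules) into a stack,
# bypassing the spine-planting front end, for geometry-only tests.
tube_stack <- function(recipe, capsules, channel = "fill") {
  d <- spinemorph:::recipe_dims(recipe)
  vs <- spinemorph:::recipe_voxel_size(recipe)
  clean <- spinemorph:::cpp_render_capsules(as.integer(d), vs, c(0, 0, 0),
                                            capsules)
  img <- spinemorph:::finish_channel(recipe, array(clean, d))
  image_stack(stats::setNames(list(img), channel), vs)
}

# Greedy 1-D matching of detected anchors to true anchor positions.
match_anchors <- function(true_x, det_x, radius = 0.5) {
  used <- logical(length(det_x))
  match_idx <- rep(NA_integer_, length(true_x))
  for (i in order(true_x)) {
    dd <- abs(det_x - true_x[i])
    dd[used] <- Inf
    j <- if (length(dd)) which.min(dd) else integer()
    if (length(j) && dd[j] <= radius) {
      used[j] <- TRUE
      match_idx[i] <- j
    }
  }
  match_idx
}

# Full spine quantification of one generated dendrite stack; returns
# truth, detections and the traced segment.
quantify_generated <- function(ds) {
  st <- ds$stack
  mask <- suppressWarnings(segment_neurites(st, "fill"))
  sk <- skeletonize(mask, st$voxel_size_um)
  segs <- extract_segments(sk, 20)
  if (!length(segs)) return(NULL)
  seg <- segs[[which.max(vapply(segs, `[[`, 1, "length_um"))]]
  sp <- quantify_spines(st, mask, seg)
  det_x <- if (nrow(sp))
    spinemorph:::points_at_arclength(seg$path, sp$anchor_um)[, 1L]
    else numeric()
  list(segment = seg, spines = sp, det_x = det_x,
       true_x = ds$truth$dendrite_path[1L, 1L] + ds$truth$spines$anchor_um,
       truth = ds$truth, mask = mask, stack = st)
}

# Independently coded classification oracle (different construction
# from the production rule: explicit per-case if/else walk).
classify_oracle <- function(head, neck, visible, heads) {
  mapply(function(h, k, v, m) {
    if (m > 1L) return("branched")
    if (!v) return("stubby")
    if (h < k) return("stubby")
    if (h / k >= 2) return("mushroom")
    "thin"
  }, head, neck, visible, heads)
}
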