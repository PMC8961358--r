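ipsc_fixture <- function(seed = 11, coloc = 0.6, tort = 1.2) {
  rec <- test_recipe(seed = seed, field = c(40, 30), z = 6, xy = 0.2)
  make_ipsc_field(rec, n_neurites = 2, tortuosity_target = tort,
                  puncta_rates = c(homer = 0.35, kv34 = 0.35),
                  coloc_fraction = coloc)
}

greedy_match_frac <- function(det, truth, radius = 0.5) {
  if (!nrow(truth)) return(c(match = 0, n_true = 0, n_det = nrow(det)))
  used <- logical(nrow(det))
  hits <- 0L
  for (i in seq_len(nrow(truth))) {
    dd <- sqrt(colSums((t(det) - truth[i, ])^2))
    dd[used] <- Inf
    j <- which.min(dd)
    if (length(j) && dd[j] <= radius) { used[j] <- TRUE; hits <- hits + 1L }
  }
  c(match = hits, n_true = nrow(truth), n_det = nrow(det))
}

test_that("planted puncta are detected with high recall and precision", {
  tot <- c(match = 0, n_true = 0, n_det = 0)
  for (sd in c(11, 12, 13)) {
    ip <- ipsc_fixture(seed = sd)
    hp <- detect_puncta(ip$stack, "homer")
    ctr <- do.call(rbind, lapply(hp, `[[`, "centroid_um"))
    tot <- tot + greedy_match_frac(ctr, ip$truth$homer_centres)
  }
  expect_gte(tot["match"] / tot["n_true"], 0.9)
  expect_gte(tot["match"] / tot["n_det"], 0.9)
})

test_that("an empty channel has no puncta; close pairs are resolved", {
  rec <- test_recipe(seed = 2, field = c(15, 10), z = 4, xy = 0.2)
  d <- spinemorph:::recipe_dims(rec)
  empty <- image_stack(list(kv34 = spinemorph:::finish_channel(
    rec, array(0, d))), spinemorph:::recipe_voxel_size(rec))
  expect_length(detect_puncta(empty, "kv34"), 0L)

  two <- array(spinemorph:::cpp_render_blobs(
    as.integer(d), spinemorph:::recipe_voxel_size(rec), c(0, 0, 0),
    rbind(c(6, 5, 2), c(8, 5, 2)), c(0.15, 0.15, 0.25), c(900, 900)), d)
  st <- image_stack(list(homer = spinemorph:::finish_channel(rec, two,
                                                             blur = FALSE)),
                    spinemorph:::recipe_voxel_size(rec))
  expect_length(detect_puncta(st, "homer"), 2L)
})

test_that("synapse density counts only on-process puncta per um", {
  path <- cbind(seq(0, 20, by = 0.5), 5, 2)
  on <- cbind(seq(1, 19, length.out = 10), 5.3, 2)
  expect_equal(synapse_density_along(on, path), 0.5)
  off <- cbind(seq(1, 19, length.out = 10), 9, 2)
  expect_equal(synapse_density_along(off, path), 0)
  expect_error(synapse_density_along(on, path[1, , drop = FALSE]),
               "zero-length")
  ratio <- vapply(c(14, 15, 16), function(sd) {
    ip <- ipsc_fixture(seed = sd)
    hp <- detect_puncta(ip$stack, "homer")
    den <- synapse_density_along(hp, ip$truth$paths)
    den / (nrow(ip$truth$homer_centres) /
             sum(vapply(ip$truth$paths, spinemorph:::polyline_length, 1)))
  }, 1)
  expect_equal(mean(ratio), 1, tolerance = 0.1)
})

test_that("colocalisation matches greedily with a defined empty case", {
  pts <- matrix(runif(30, 0, 20), ncol = 3)
  expect_equal(colocalise(pts, pts)$fraction, 1)
  far <- pts + 5
  expect_equal(colocalise(pts, far)$fraction, 0)
  und <- colocalise(matrix(numeric(), ncol = 3), pts)
  expect_true(und$undefined)
  expect_true(is.na(und$fraction))
  # each punctum used at most once
  q <- rbind(c(0, 0, 0), c(0.3, 0, 0))
  r <- rbind(c(0.1, 0, 0))
  expect_equal(colocalise(q, r)$n_matched, 1L)
})

test_that("planted colocalisation fraction is recovered within 0.05", {
  errs <- vapply(c(21, 22, 23), function(sd) {
    ip <- ipsc_fixture(seed = sd, coloc = 0.6)
    kv <- detect_puncta(ip$stack, "kv34")
    hp <- detect_puncta(ip$stack, "homer")
    colocalise(kv, hp)$fraction - ip$truth$coloc_fraction_planted
  }, 1)
  expect_lte(mean(abs(errs)), 0.05)
})

test_that("normalised intensity is scale-invariant with sane errors", {
  rec <- noiseless_recipe(seed = 2, field = c(24, 24), z = 14, xy = 0.3)
  ms <- make_soma_stack(rec, soma_mean = 300, background_mean = 100)
  roi <- get_channel(ms$stack, "fill") > 0.5
  obj <- suppressWarnings(segment_neurites(ms$stack, "stain",
                                           smooth_sigma_um = 0.4,
                                           weak_factor = 0.25))
  ni <- normalised_intensity(ms$stack, "stain", roi, objects_mask = obj)
  expect_equal(ni$ratio, 3, tolerance = 2e-3)
  st2 <- image_stack(list(stain = ms$stack$channels$stain * 2,
                          fill = ms$stack$channels$fill),
                     ms$stack$voxel_size_um)
  ni2 <- normalised_intensity(st2, "stain", roi, objects_mask = obj)
  expect_equal(ni2$ratio, ni$ratio, tolerance = 1e-9)
  # uniform image -> ratio 1
  uni <- image_stack(list(stain = array(50, dim(roi))),
                     ms$stack$voxel_size_um)
  expect_equal(normalised_intensity(uni, "stain", roi)$ratio, 1)
  expect_error(normalised_intensity(ms$stack, "stain",
                                    array(FALSE, dim(roi))), "empty ROI")
  zero <- image_stack(list(stain = array(0, dim(roi))),
                      ms$stack$voxel_size_um)
  expect_error(normalised_intensity(zero, "stain", roi), "zero")
})

test_that("dendritic intensity recovers a planted level over background", {
  rec <- stack_recipe(field_size_um = c(36, 20), z_depth_um = 5,
                      z_step_um = 0.3, xy_pixel_um = 0.2,
                      psf_sigma_um = c(0.1, 0.2),
                      noise = list(photon_scale = 2, read_sd = 1),
                      background_level = 50, seed = 5)
  ip <- make_ipsc_field(rec, n_neurites = 2, tortuosity_target = 1.05,
                        puncta_rates = c(homer = 0, kv34 = 0),
                        coloc_fraction = 0, kv_dendrite_amplitude = 150)
  m2 <- segment_neurites(ip$stack, "map2")
  di <- dendritic_intensity(ip$stack, "kv34", m2)
  expect_equal(di$ratio, 4, tolerance = 0.4)    # (150 + 50) / 50
  bg_mask <- array(FALSE, dim(m2)); bg_mask[1:8, 1:8, ] <- TRUE
  di_bg <- dendritic_intensity(ip$stack, "kv34", bg_mask)
  expect_equal(di_bg$ratio, 1, tolerance = 0.1)
  # doubling only the stain channel doubles the unnormalised mean
  st2 <- image_stack(list(map2 = ip$stack$channels$map2,
                          kv34 = ip$stack$channels$kv34 * 2),
                     ip$stack$voxel_size_um)
  expect_equal(dendritic_intensity(st2, "kv34", m2,
                                   normalise = FALSE)$mean_intensity,
               2 * di$mean_intensity)
  expect_error(dendritic_intensity(ip$stack, "kv34",
                                   array(FALSE, dim(m2))), "empty")
})

test_that("measured tortuosity tracks the generator's target", {
  ip <- ipsc_fixture(seed = 31, tort = 1.3)
  mask <- segment_neurites(ip$stack, "map2")
  segs <- extract_segments(skeletonize(mask, ip$stack$voxel_size_um), 30)
  expect_gte(length(segs), 1L)
  t_meas <- vapply(segs, tortuosity, 1)
  expect_true(all(abs(t_meas - 1.3) <= 0.03))
})
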