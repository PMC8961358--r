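test_that("zero spine rates give a bare shaft and empty ground truth", {
  ds <- make_dendrite_stack(test_recipe(seed = 2), segment_length_um = 22,
                            spine_spec = c())
  expect_equal(nrow(ds$truth$spines), 0L)
  expect_s3_class(ds$stack, "image_stack")
})

test_that("identical recipe + seed reproduce the stack bit for bit", {
  rec <- test_recipe(seed = 5, field = c(26, 12), z = 6)
  a <- make_dendrite_stack(rec, segment_length_um = 21,
                           spine_spec = c(mushroom = 0.3))
  b <- make_dendrite_stack(rec, segment_length_um = 21,
                           spine_spec = c(mushroom = 0.3))
  expect_identical(a$stack$channels$fill, b$stack$channels$fill)
  expect_identical(a$truth$spines, b$truth$spines)
  expect_true(all(a$truth$spines$true_class == "mushroom"))
})

test_that("per-class spine counts honour the Poisson rates", {
  rates <- c(mushroom = 0.5, thin = 0.5, stubby = 0.5, branched = 0.1)
  L <- 22
  counts <- t(vapply(1:60, function(sd) {
    ds <- make_dendrite_stack(test_recipe(seed = sd, field = c(26, 12),
                                          z = 5),
                              segment_length_um = L, spine_spec = rates)
    tb <- table(factor(ds$truth$spines$true_class, names(rates)))
    as.numeric(tb)
  }, numeric(4)))
  mu <- rates * L
  se <- sqrt(mu / 60)
  expect_true(all(abs(colMeans(counts) - mu) < 3 * se + 1e-9))
})

test_that("generator geometry always agrees with the classifier", {
  for (sd in 1:5) {
    ds <- make_dendrite_stack(test_recipe(seed = sd, field = c(26, 12),
                                          z = 5),
                              segment_length_um = 21,
                              spine_spec = c(mushroom = 0.3, thin = 0.3,
                                             stubby = 0.2, branched = 0.1))
    tr <- ds$truth$spines
    if (!nrow(tr)) next
    expect_identical(
      classify_spine(tr$head_diameter_um, tr$neck_diameter_um,
                     tr$neck_visible, tr$n_heads),
      tr$true_class)
  }
})

test_that("unresolvable spine geometry is rejected with a calibration error", {
  coarse <- stack_recipe(field_size_um = c(26, 12), z_depth_um = 5,
                         xy_pixel_um = 0.3, seed = 1)
  expect_error(make_dendrite_stack(coarse, segment_length_um = 21,
                                   spine_spec = c(thin = 0.3)),
               "calibration error")
  expect_error(make_dendrite_stack(test_recipe(), segment_length_um = 15),
               ">= 20")
})

test_that("plaques respect bounds and record exact geometry", {
  rec <- test_recipe(seed = 3, field = c(30, 30), z = 10, xy = 0.3)
  expect_error(make_plaque_field(rec, rbind(c(80, 80, 5)), 3),
               "outside the stack bounds")
  pf0 <- make_plaque_field(rec, NULL)
  th0 <- get_channel(pf0$stack, "thios")
  expect_equal(mean(th0), rec$background_level, tolerance = 0.05)
  expect_lt(stats::quantile(th0, 0.999), 2.5 * rec$background_level)
  pf <- make_plaque_field(rec, rbind(c(10, 20, 5)), 5)
  expect_equal(pf$truth$plaque_radii, 5)
  # analytic edge distance from a point 20 um away from the centre
  pt <- rbind(c(10, 20, 5) + c(20, 0, 0), c(10, 20, 5) + c(21, 0, 0))
  expect_equal(min(sqrt(rowSums(sweep(pt, 2, c(10, 20, 5))^2))) - 5, 15)
})

test_that("soma stack encodes the planted normalised intensity", {
  rec <- noiseless_recipe(seed = 2, field = c(24, 24), z = 14, xy = 0.3)
  expect_error(make_soma_stack(rec, soma_mean = 50, background_mean = 100),
               "soma_mean")
  ms <- make_soma_stack(rec, soma_mean = 300, background_mean = 100)
  expect_equal(ms$truth$expected_ratio, 3)
  roi <- get_channel(ms$stack, "fill") > 0.5
  obj <- suppressWarnings(segment_neurites(ms$stack, "stain",
                                           smooth_sigma_um = 0.4,
                                           weak_factor = 0.25))
  ni <- normalised_intensity(ms$stack, "stain", roi, objects_mask = obj)
  expect_equal(ni$ratio, 3, tolerance = 2e-3)     # pre-noise
  ms2 <- make_soma_stack(rec, soma_mean = 100, background_mean = 100)
  roi2 <- get_channel(ms2$stack, "fill") > 0.5
  ni2 <- normalised_intensity(ms2$stack, "stain", roi2)
  expect_equal(ni2$ratio, 1, tolerance = 2e-3)
})

test_that("ipsc fields meet tortuosity and colocalisation contracts", {
  rec <- test_recipe(seed = 6, field = c(36, 24), z = 6, xy = 0.2)
  straight <- make_ipsc_field(rec, n_neurites = 2, tortuosity_target = 1,
                              puncta_rates = c(homer = 0.3, kv34 = 0.3),
                              coloc_fraction = 0.5)
  expect_equal(straight$truth$true_tortuosity, c(1, 1), tolerance = 1e-9)
  all_on <- make_ipsc_field(rec, n_neurites = 2, tortuosity_target = 1.1,
                            puncta_rates = c(homer = 0.4, kv34 = 0.3),
                            coloc_fraction = 1)
  tr <- all_on$truth
  if (tr$n_kv > 0) {
    dmin <- apply(tr$kv_centres, 1, function(p)
      min(sqrt(rowSums(sweep(tr$homer_centres, 2, p)^2))))
    expect_true(all(dmin < 1e-9))   # every Kv punctum sits on a Homer punctum
  }
  # binomial split reproducible under the seed
  again <- make_ipsc_field(rec, n_neurites = 2, tortuosity_target = 1.1,
                           puncta_rates = c(homer = 0.4, kv34 = 0.3),
                           coloc_fraction = 1)
  expect_identical(again$truth$n_coloc_planted, tr$n_coloc_planted)
  expect_error(make_ipsc_field(rec, tortuosity_target = 5),
               "unreachable tortuosity")
})

test_that("spine table reproduces cohort means exactly at zero dispersion", {
  tab <- make_spine_table(seed = 3)
  coh <- mouse_cohort()
  for (i in seq_len(nrow(coh))) {
    sel <- tab$mouse_id == coh$mouse_id[i] &
      tab$treatment == coh$treatment[i] & tab$proximity == coh$proximity[i]
    expect_equal(sum(sel), coh$n_dendrites[i])
    expect_true(all(tab$density_per_um[sel] == coh$mean_density[i]))
  }
  # spot values: TS23 control (20 records at 1.82), TS533 knockdown far 2.26
  expect_true(all(tab$density_per_um[tab$mouse_id == "TS23" &
                                     tab$treatment == "control"] == 1.82))
  expect_true(all(tab$density_per_um[tab$mouse_id == "TS533" &
                                     tab$treatment == "knockdown" &
                                     tab$proximity == "far"] == 2.26))
  # distance bins
  near <- tab$distance_um[tab$proximity == "near"]
  far <- tab$distance_um[tab$proximity == "far"]
  expect_true(all(near >= 0 & near <= 30))
  expect_true(all(far > 30 & far <= 90))
  expect_true(all(is.na(tab$distance_um[tab$proximity == "no_plaque"])))
})

test_that("negative generated densities are truncated and flagged", {
  coh <- mouse_cohort()[1:2, ]
  coh$mean_density <- 0.05
  tab <- make_spine_table(coh, dendrite_sd = 1, seed = 8)
  expect_true(any(tab$truncated))
  expect_true(all(tab$density_per_um >= 0))
})

test_that("qPCR plates encode fold changes in reference-normalised Cq", {
  q <- make_qpcr_plate(c(KCNC4 = 0.5), cq_noise_sd = 0, seed = 4)
  dcq <- function(cond) {
    r <- q[q$condition == cond, ]
    mean(vapply(unique(r$sample_id), function(s) {
      rr <- r[r$sample_id == s, ]
      rr$cq[rr$gene == "KCNC4"] -
        mean(rr$cq[rr$gene %in% c("GAPDH", "RPLP1")])
    }, 1))
  }
  expect_equal(dcq("treated") - dcq("control"), 1)     # exactly one cycle
  q1 <- make_qpcr_plate(c(KCNC4 = 1), cq_noise_sd = 0, seed = 4)
  d1 <- ddcq(q1, "KCNC4")
  expect_equal(d1$fold[d1$condition == "treated"], 1)
  expect_error(make_qpcr_plate(c(KCNC4 = -1)), "positive")
})
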