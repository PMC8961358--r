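test_that("power-ladder transform behaves on analytic cases", {
  x <- runif(50, 1, 5)
  out <- tukey_ladder_transform(x, lambda_grid = 1)
  expect_identical(out$values, x)
  expect_equal(out$lambda, 1)
  expect_warning(res <- tukey_ladder_transform(rep(2, 20)), "constant")
  expect_equal(res$lambda, 1)
  expect_error(tukey_ladder_transform(c(1, NA)), "finite")
})

test_that("the ladder picks identity for normal and log for lognormal data", {
  lam_norm <- vapply(1:100, function(s) {
    set.seed(1000 + s)
    tukey_ladder_transform(rnorm(250, 10, 3.5))$lambda
  }, 1)
  expect_gte(mean(lam_norm == 1), 0.9)
  lam_ln <- vapply(1:100, function(s) {
    set.seed(2000 + s)
    tukey_ladder_transform(rlnorm(250, 1, 0.8))$lambda
  }, 1)
  expect_gte(mean(lam_ln == 0), 0.8)
})

test_that("the tortuosity transform is (t - 1)^(1/7)", {
  expect_equal(tortuosity_transform(1), 0)
  expect_equal(tortuosity_transform(2), 1)
  expect_equal(tortuosity_transform(1.5), 0.5^(1 / 7))
  expect_error(tortuosity_transform(0.9), ">= 1")
})

test_that("rmcorr equals the within-subject ANCOVA decomposition", {
  set.seed(7)
  for (rep_i in 1:5) {
    k <- 5; n <- 8
    subj <- rep(seq_len(k), each = n)
    x <- rnorm(k * n)
    y <- 0.4 * x + rnorm(k * n) + rep(rnorm(k, sd = 2), each = n)
    r <- rmcorr(subj, x, y)
    # independent oracle: Pearson correlation of within-subject-centred data
    xc <- x - stats::ave(x, subj)
    yc <- y - stats::ave(y, subj)
    expect_equal(r$r, stats::cor(xc, yc), tolerance = 1e-10)
    expect_equal(r$df, k * n - k - 1L)
    expect_true(r$conf_int[1] <= r$r && r$r <= r$conf_int[2])
    expect_true(r$p >= 0 && r$p <= 1)
  }
  # y = x within every subject -> r exactly 1
  subj <- rep(1:4, each = 5); x <- rnorm(20)
  y <- x + rep(c(5, 9, -3, 0), each = 5)
  expect_equal(suppressWarnings(rmcorr(subj, x, y)$r), 1)
  # one subject: pooled Pearson with adjusted df
  x1 <- rnorm(15); y1 <- 0.5 * x1 + rnorm(15)
  r1 <- rmcorr(rep(1, 15), x1, y1)
  expect_equal(abs(r1$r), abs(stats::cor(x1, y1)), tolerance = 1e-10)
  expect_equal(r1$df, 15 - 1 - 1)
  expect_error(rmcorr(rep(1:3, each = 4), rep(1, 12), rnorm(12)),
               "constant")
})

test_that("rmcorr is centred on zero under the null", {
  rs <- vapply(1:400, function(s) {
    set.seed(s)
    subj <- rep(1:10, each = 20)
    rmcorr(subj, rnorm(200), rnorm(200))$r
  }, 1)
  expect_lt(abs(mean(rs)), 2 * stats::sd(rs) / sqrt(length(rs)))
})

test_that("chi-square matches the hand formula with Bonferroni post hocs", {
  tab <- matrix(c(10, 20, 20, 10), 2, 2, byrow = TRUE)
  res <- chisq_shape_test(tab)
  # brute-force Pearson statistic
  exp_cells <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  chi_bf <- sum((tab - exp_cells)^2 / exp_cells)
  expect_equal(res$chi2, chi_bf, tolerance = 1e-10)
  expect_equal(res$chi2, 20 / 3, tolerance = 1e-10)
  expect_equal(res$df, 1)

  same <- matrix(c(12, 8, 5, 12, 8, 5), 2, 3, byrow = TRUE)
  res0 <- chisq_shape_test(same)
  expect_equal(res0$chi2, 0)
  expect_equal(res0$p, 1)
  expect_equal(res0$df, (2 - 1) * (3 - 1))
  expect_true(all(res0$post_hoc$p_adj >= res0$post_hoc$p_raw))
  expect_error(chisq_shape_test(matrix(c(0, 0, 3, 4), 2, 2)),
               "pool")

  set.seed(3)
  big <- matrix(rpois(8, 40) + 5, 2, 4,
                dimnames = list(NULL, c("mushroom", "thin", "stubby",
                                        "branched")))
  res2 <- chisq_shape_test(big)
  exp2 <- outer(rowSums(big), colSums(big)) / sum(big)
  expect_equal(res2$chi2, sum((big - exp2)^2 / exp2), tolerance = 1e-10)
  expect_equal(nrow(res2$post_hoc), 4L)
  res3 <- chisq_shape_test(big, include_classes = c("mushroom", "thin",
                                                    "stubby"))
  expect_equal(nrow(res3$post_hoc), 3L)
})

test_that("delta-delta-Cq recovers planted fold changes", {
  q <- make_qpcr_plate(c(KCNC4 = 0.5), cq_noise_sd = 0, seed = 2)
  res <- ddcq(q, "KCNC4")
  expect_equal(res$fold[res$condition == "control"], 1)
  expect_equal(res$fold[res$condition == "treated"], 0.5)

  folds <- vapply(1:100, function(s) {
    qq <- make_qpcr_plate(c(KCNC4 = 0.5), cq_noise_sd = 0.2, seed = s)
    d <- ddcq(qq, "KCNC4")
    d$fold[d$condition == "treated"]
  }, 1)
  expect_gte(mean(folds), 0.45)
  expect_lte(mean(folds), 0.55)

  qbad <- q[!(q$sample_id == "treated_1" & q$gene == "GAPDH"), ]
  expect_warning(res2 <- ddcq(qbad, "KCNC4"), "excluded")
  expect_equal(res2$n[res2$condition == "treated"], 3)
})

test_that("percent change follows the stated sign convention", {
  expect_equal(percent_change(2, 2), 0)
  expect_equal(percent_change(2, 1), 50)
  expect_equal(percent_change(2, 3), -50)
  expect_error(percent_change(0, 1), "non-zero")
  # cell-weighted knockdown decrease from the intensity reference cohort
  ic <- mouse_intensity_cohort()
  wm <- vapply(c("control", "knockdown"), function(tr) {
    r <- ic[ic$treatment == tr, ]
    sum(r$mean_intensity * r$n_cells) / sum(r$n_cells)
  }, 1)
  dec <- percent_change(wm["control"], wm["knockdown"])
  expect_gte(unname(dec), 20)
  expect_lte(unname(dec), 25)
})

test_that("the mixed model reproduces cell means on dispersion-free data", {
  coh <- data.frame(mouse_id = rep(paste0("m", 1:6), each = 2),
                    genotype = rep(c("WT", "TG"), each = 6),
                    sex = "F",
                    treatment = rep(c("control", "knockdown"), 6),
                    proximity = "no_plaque",
                    mean_density = rep(c(1.5, 2.0, 0.6, 1.1), each = 3),
                    n_dendrites = 10)
  # constant within mouse-condition, but mouse means differ by genotype
  coh$mean_density <- c(1.5, 2.0, 1.5, 2.0, 1.5, 2.0,
                        0.6, 1.1, 0.6, 1.1, 0.6, 1.1)
  tab <- make_spine_table(coh, seed = 2)
  # convergence warnings are expected on dispersion-free (degenerate) data
  gm <- suppressWarnings(fit_group_model(tab,
                                         fixed = c("genotype", "treatment")))
  em <- emmeans::emmeans(gm$fit, c("genotype", "treatment"))
  emdf <- as.data.frame(em)
  cellmeans <- aggregate(.y ~ genotype + treatment,
                         data = cbind(gm$fit@frame), FUN = mean)
  m <- merge(emdf, cellmeans)
  expect_equal(m$emmean, m$.y, tolerance = 1e-6)
})

test_that("marginal-mean contrasts difference balanced group means", {
  set.seed(5)
  tab <- make_spine_table(dendrite_sd = 0.3, seed = 6)
  gm <- fit_group_model(tab, fixed = c("genotype", "treatment"))
  expect_true(all(c("genotype", "treatment") %in% rownames(gm$anova)))
  ct <- emm_contrasts(gm, "treatment")
  expect_equal(nrow(ct), 1L)
  # adjusted p never smaller than unadjusted across a 4-level grid
  tab$cell <- interaction(tab$genotype, tab$treatment)
  gm2 <- fit_group_model(tab, fixed = "cell")
  tuk <- emm_contrasts(gm2, "cell", adjust = "tukey")
  raw <- emm_contrasts(gm2, "cell", adjust = "none")
  expect_true(all(tuk$p.value >= raw$p.value - 1e-12))
})

test_that("the treatment F test is calibrated and powered", {
  # null: flat cohort, within-mouse treatment, 200 replicates
  pv <- vapply(1:200, function(s) {
    coh <- mouse_cohort()
    coh$mean_density <- 1.2
    tb <- make_spine_table(coh, dendrite_sd = 0.35, mouse_sd = 0.3,
                           seed = s)
    fit_group_model(tb, fixed = c("genotype", "treatment"))$anova[
      "treatment", "Pr(>F)"]
  }, 1)
  expect_gte(mean(pv < 0.05), 0.02)
  expect_lte(mean(pv < 0.05), 0.08)

  # a planted 40% knockdown increase is detected nearly always
  pw <- vapply(1:60, function(s) {
    coh <- mouse_cohort()
    coh$mean_density <- ifelse(coh$treatment == "knockdown", 1.4, 1.0)
    tb <- make_spine_table(coh, dendrite_sd = 0.35, mouse_sd = 0.3,
                           seed = 5000 + s)
    fit_group_model(tb, fixed = c("genotype", "treatment"))$anova[
      "treatment", "Pr(>F)"]
  }, 1)
  expect_gte(mean(pw < 0.05), 0.8)
})

test_that("a planted within-mouse distance slope is found by rmcorr", {
  hits <- vapply(1:40, function(s) {
    tab <- make_spine_table(dendrite_sd = 0.25, distance_slope = 0.01,
                            seed = 3000 + s)
    tg <- tab[tab$genotype == "APP/PS1" & tab$treatment == "control" &
              !is.na(tab$distance_um), ]
    r <- rmcorr(tg$mouse_id, tg$distance_um, tg$density_per_um)
    r$r > 0 && r$p < 0.05
  }, TRUE)
  expect_gte(mean(hits), 0.8)
})
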