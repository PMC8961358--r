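#' Reference mouse cohort: per-mouse mean spine densities
#'
#' The built-in calibration cohort: 6 wild-type and 10 APP/PS1 mice, one
#' hemisphere per treatment (tdTomato control fill vs eYFP fill with
#' Kv3.4 knockdown), with per-mouse mean linear spine densities
#' (spines/um) and dendritic-segment counts per condition. APP/PS1
#' dendrites are split by plaque proximity (near = 0-30 um from the
#' nearest plaque edge, far > 30 um); wild-type mice carry no plaques,
#' so their dendrites are a single `no_plaque` condition.
#'
#' @return data.frame with columns `mouse_id`, `genotype`, `sex`,
#'   `treatment` (control/knockdown), `proximity` (near/far/no_plaque),
#'   `mean_density`, `n_dendrites`.
#' @export
mouse_cohort <- function() {
  w <- function(id, sex, td, n_td, ey, n_ey) data.frame(
    mouse_id = id, genotype = "WT", sex = sex,
    treatment = c("control", "knockdown"),
    proximity = "no_plaque",
    mean_density = c(td, ey), n_dendrites = c(n_td, n_ey),
    stringsAsFactors = FALSE)
  a <- function(id, sex, td_f, n1, td_n, n2, ey_f, n3, ey_n, n4) data.frame(
    mouse_id = id, genotype = "APP/PS1", sex = sex,
    treatment = rep(c("control", "knockdown"), each = 2L),
    proximity = rep(c("far", "near"), 2L),
    mean_density = c(td_f, td_n, ey_f, ey_n),
    n_dendrites = c(n1, n2, n3, n4),
    stringsAsFactors = FALSE)
  rbind(
    w("TS23",  "F", 1.82, 20, 2.38, 20),
    w("TS25",  "F", 2.11, 20, 2.52, 20),
    w("TS511", "M", 1.59, 20, 2.37, 20),
    w("TS517", "F", 1.77, 20, 2.42, 20),
    w("TS531", "M", 2.07, 20, 2.12, 20),
    w("TS532", "M", 0.80, 20, 1.17, 20),
    a("TS476", "F", 0.66, 20, 0.58, 24, 0.64, 20, 0.48, 32),
    a("TS478", "F", 0.72, 10, 0.53, 37, 0.66, 19, 0.52, 30),
    a("TS481", "M", 0.80, 12, 0.61, 26, 1.33, 23, 0.79, 24),
    a("TS499", "F", 0.48, 26, 0.46, 37, 0.49, 12, 0.46, 29),
    a("TS518", "F", 0.44, 13, 0.48, 10, 0.68, 39, 0.85, 38),
    a("TS520", "M", 1.43, 20, 0.73, 20, 1.20, 20, 0.88, 20),
    a("TS526", "F", 0.83, 20, 0.50, 20, 1.59, 20, 1.17, 20),
    a("TS533", "F", 2.04, 20, 1.33, 20, 2.26, 18, 1.92, 23),
    a("TS538", "M", 1.39, 20, 0.57, 20, 1.78, 20, 1.37, 20),
    a("TS546", "M", 1.45, 20, 0.75, 18, 1.72, 20, 1.06, 20))
}

#' Reference cohort: per-mouse mean normalised Kv3.4 soma intensities
#'
#' Mean Kv3.4 immunostain intensity of cell bodies, normalised to
#' background in the same stack, with the number of cell bodies per
#' condition, for the subset of mice assessed for knockdown efficiency.
#'
#' @return data.frame with `mouse_id`, `genotype`, `treatment`,
#'   `mean_intensity`, `n_cells`.
#' @export
mouse_intensity_cohort <- function() {
  r <- function(id, gt, td, n_td, ey, n_ey) data.frame(
    mouse_id = id, genotype = gt,
    treatment = c("control", "knockdown"),
    mean_intensity = c(td, ey), n_cells = c(n_td, n_ey),
    stringsAsFactors = FALSE)
  rbind(
    r("TS23",  "WT", 3.10, 14, 2.34, 10),
    r("TS25",  "WT", 2.65, 10, 2.32, 10),
    r("TS511", "WT", 2.79, 13, 2.34, 16),
    r("TS517", "WT", 2.30,  9, 2.30, 11),
    r("TS531", "WT", 2.46, 10, 2.00, 14),
    r("TS532", "WT", 1.85, 11, 1.48, 10),
    r("TS520", "APP/PS1", 2.40, 10, 1.98, 14),
    r("TS526", "APP/PS1", 3.20, 10, 2.43, 11),
    r("TS533", "APP/PS1", 3.22, 10, 2.36, 11),
    r("TS538", "APP/PS1", 2.36, 11, 2.17, 11),
    r("TS546", "APP/PS1", 4.81, 12, 2.04, 12))
}

#' Generate a per-dendrite spine-density table from a cohort
#'
#' Draws one record per dendritic segment from a hierarchical model:
#' the cohort supplies each mouse-condition mean; an optional extra
#' mouse-level intercept (`mouse_sd`) and dendrite-level Gaussian noise
#' (`dendrite_sd`) are added on top. Plaque distances are drawn uniform
#' within the condition's bin (near 0-30 um, far 30-90 um) and an
#' optional within-mouse distance-density slope can be planted; the
#' slope is applied around the bin's mean distance so that the
#' mouse-condition mean density is preserved. Negative densities are
#' truncated at zero and flagged.
#'
#' @param cohort a data.frame like [mouse_cohort()].
#' @param dendrite_sd sd of dendrite-level noise (spines/um).
#' @param mouse_sd sd of an extra mouse-level random intercept.
#' @param distance_slope planted within-mouse density change per um of
#'   plaque distance (applies to near/far records only).
#' @param class_mix named proportions for `mushroom`, `thin`, `stubby`,
#'   `branched`, used to split each record's spine count.
#' @param length_range segment lengths drawn uniform in this range (um).
#' @param seed integer seed.
#' @return data.frame of dendrite records: `mouse_id`, `genotype`, `sex`,
#'   `treatment`, `proximity`, `distance_um`, `density_per_um`,
#'   `length_um`, `n_mushroom`, `n_thin`, `n_stubby`, `n_branched`,
#'   `truncated`.
#' @export
make_spine_table <- function(cohort = mouse_cohort(),
                             dendrite_sd = 0, mouse_sd = 0,
                             distance_slope = 0,
                             class_mix = c(mushroom = 0.45, thin = 0.35,
                                           stubby = 0.15, branched = 0.05),
                             length_range = c(20, 40),
                             seed = 1L) {
  stopifnot(all(c("mouse_id", "genotype", "treatment", "proximity",
                  "mean_density", "n_dendrites") %in% names(cohort)))
  class_mix <- class_mix / sum(class_mix)
  mice <- unique(cohort$mouse_id)
  out <- NULL
  for (mi in seq_along(mice)) {
    m_off <- if (mouse_sd > 0)
      with_seed(sub_seed(seed, 700L, mi), rnorm(1L, 0, mouse_sd)) else 0
    rows <- cohort[cohort$mouse_id == mice[mi], , drop = FALSE]
    for (ri in seq_len(nrow(rows))) {
      r <- rows[ri, ]
      n <- r$n_dendrites
      rec <- with_seed(sub_seed(seed, 800L + ri, mi), {
        dist_um <- switch(r$proximity,
                          near = runif(n, 0, 30),
                          far  = runif(n, 30, 90),
                          rep(NA_real_, n))
        mid <- switch(r$proximity, near = 15, far = 60, NA_real_)
        dens <- r$mean_density + m_off +
          (if (dendrite_sd > 0) rnorm(n, 0, dendrite_sd) else 0) +
          (if (!is.na(mid)) distance_slope * (dist_um - mid) else 0)
        len <- if (diff(length_range) > 0)
          runif(n, length_range[1L], length_range[2L])
          else rep(length_range[1L], n)
        truncated <- dens < 0
        dens[truncated] <- 0
        n_sp <- round(dens * len)
        counts <- t(vapply(n_sp, function(k)
          as.numeric(stats::rmultinom(1L, k, class_mix)), numeric(4L)))
        data.frame(mouse_id = r$mouse_id, genotype = r$genotype,
                   sex = r$sex %||% NA_character_,
                   treatment = r$treatment, proximity = r$proximity,
                   distance_um = dist_um, density_per_um = dens,
                   length_um = len,
                   n_mushroom = counts[, 1L], n_thin = counts[, 2L],
                   n_stubby = counts[, 3L], n_branched = counts[, 4L],
                   truncated = truncated, stringsAsFactors = FALSE)
      })
      out <- rbind(out, rec)
    }
  }
  rownames(out) <- NULL
  out
}

#' Generate a synthetic qPCR Cq plate
#'
#' Produces Cq values for one target gene and two reference genes in a
#' treated and a control condition, consistent with the planted fold
#' changes under the given amplification efficiency (2.0 = perfect
#' doubling). Sample-to-sample loading offsets are shared by all genes
#' of a sample, so reference normalisation removes them exactly.
#'
#' @param true_fold_changes named fold changes (treated relative to
#'   control) per target gene; must be positive.
#' @param efficiency amplification efficiency (fold per cycle).
#' @param cq_noise_sd Gaussian well noise on each Cq.
#' @param n_replicates biological replicates per condition.
#' @param reference_genes names of the two reference genes.
#' @param seed integer seed.
#' @return data.frame with `sample_id`, `condition`, `gene`, `cq`,
#'   `replicate`.
#' @export
make_qpcr_plate <- function(true_fold_changes = c(KCNC4 = 0.5),
                            efficiency = 2.0, cq_noise_sd = 0,
                            n_replicates = 4L,
                            reference_genes = c("GAPDH", "RPLP1"),
                            seed = 1L) {
  if (any(true_fold_changes <= 0)) stop("fold changes must be positive")
  base_cq <- c(stats::setNames(rep(24, length(true_fold_changes)),
                               names(true_fold_changes)),
               stats::setNames(c(18, 19), reference_genes))
  genes <- names(base_cq)
  out <- NULL
  with_seed(seed, {
    for (cond in c("control", "treated")) {
      for (rep_i in seq_len(n_replicates)) {
        loading <- runif(1L, -0.5, 0.5)
        for (g in genes) {
          cq <- base_cq[[g]] + loading
          if (cond == "treated" && g %in% names(true_fold_changes))
            cq <- cq - log(true_fold_changes[[g]]) / log(efficiency)
          if (cq_noise_sd > 0) cq <- cq + rnorm(1L, 0, cq_noise_sd)
          out <- rbind(out, data.frame(
            sample_id = paste0(cond, "_", rep_i), condition = cond,
            gene = g, cq = cq, replicate = rep_i,
            stringsAsFactors = FALSE))
        }
      }
    }
  })
  rownames(out) <- NULL
  out
}
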