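## Inference layer: transforms, mixed-effects group contrasts,
## spine-shape chi-square, repeated-measures correlation and ddCq.

#' Tukey power-ladder transform chosen by residual normality
#'
#' Picks a power from the fixed ladder (-2, -1, -1/2, log, 1/2, 1, 2)
#' that maximises the Shapiro-Wilk normality statistic of the
#' transformed, centred values (centring within the cells of an
#' optional grouping keeps group shifts from masquerading as
#' non-normality). Negative and zero powers require positive data;
#' x^lambda is negated for lambda < 0 to preserve order.
#'
#' @param values numeric vector.
#' @param groups optional factor; normality is scored on within-group
#'   centred values.
#' @param lambda_grid powers to consider; 0 means log.
#' @return list: `values` (transformed), `lambda`.
#' @export
tukey_ladder_transform <- function(values, groups = NULL,
                                   lambda_grid = c(-2, -1, -0.5, 0,
                                                   0.5, 1, 2)) {
  if (any(!is.finite(values))) stop("values must be finite")
  apply_lambda <- function(x, l) {
    if (l == 0) log(x) else if (l > 0) x^l else -(x^l)
  }
  if (stats::sd(values) == 0) {
    warning("constant input; identity transform")
    return(list(values = values, lambda = 1))
  }
  if (min(values) <= 0)
    lambda_grid <- lambda_grid[lambda_grid >= 1]
  score <- function(x) {
    if (!is.null(groups)) x <- x - stats::ave(x, groups)
    xs <- if (length(x) > 4500) sample(x, 4500) else x
    if (stats::sd(xs) == 0) return(-Inf)
    stats::shapiro.test(xs)$statistic
  }
  sc <- vapply(lambda_grid, function(l) score(apply_lambda(values, l)), 1)
  lam <- lambda_grid[which.max(sc)]
  list(values = apply_lambda(values, lam), lambda = lam)
}

#' Tortuosity normalising transform
#'
#' `(t - 1)^(1/7)` for tortuosity ratios `t >= 1`; maps a straight
#' segment (t = 1) to 0 and t = 2 to 1 exactly.
#'
#' @param t tortuosity ratio(s), >= 1.
#' @return transformed value(s).
#' @export
tortuosity_transform <- function(t) {
  if (any(!is.finite(t)) || any(t < 1)) stop("tortuosity must be >= 1")
  (t - 1)^(1 / 7)
}

#' Fit the hierarchical group-contrast model
#'
#' Linear mixed-effects model of a per-dendrite response with a random
#' intercept per mouse (multiple dendrites per mouse are not
#' independent), fixed factors fully crossed, fitted by REML via
#' `lmer`, followed by a Type III ANOVA with Satterthwaite denominator
#' degrees of freedom. Singular fits (a variance component at zero) are
#' reported in the result, not dropped.
#'
#' @param records data.frame of dendrite records.
#' @param response response column name (default `density_per_um`).
#' @param fixed character vector of fixed-factor column names.
#' @param random grouping column for the random intercept
#'   (default `mouse_id`).
#' @param transform `NULL`, `"tukey"` (ladder chosen on the cell-centred
#'   response), or a function applied to the response.
#' @return a `group_model` list: `fit` (lmerModLmerTest), `anova`
#'   (data.frame), `transform`, `lambda`, `singular`, `residuals`,
#'   `fitted`.
#' @export
fit_group_model <- function(records, response = "density_per_um",
                            fixed = c("genotype", "treatment"),
                            random = "mouse_id", transform = NULL) {
  stopifnot(all(c(response, fixed, random) %in% names(records)))
  if (length(unique(records[[random]])) < 2L)
    stop("need at least 2 grouping units for a random intercept")
  dat <- records
  for (f in fixed) dat[[f]] <- factor(dat[[f]])
  dat[[random]] <- factor(dat[[random]])
  lambda <- NA_real_
  y <- dat[[response]]
  if (is.character(transform) && identical(transform, "tukey")) {
    cells <- interaction(dat[fixed], drop = TRUE)
    tl <- tukey_ladder_transform(y, groups = cells)
    y <- tl$values; lambda <- tl$lambda
  } else if (is.function(transform)) {
    y <- transform(y)
  }
  dat$.y <- y
  fml <- stats::as.formula(paste0(".y ~ ", paste(fixed, collapse = " * "),
                                  " + (1 | ", random, ")"))
  fit <- lmerTest::lmer(fml, data = dat,
                        control = lme4::lmerControl(
                          check.conv.singular = lme4::.makeCC(
                            action = "ignore", tol = 1e-4)))
  an <- as.data.frame(stats::anova(fit, type = 3, ddf = "Satterthwaite"))
  structure(list(fit = fit, anova = an,
                 transform = if (is.character(transform)) transform
                             else if (is.function(transform)) "function"
                             else "none",
                 lambda = lambda,
                 singular = lme4::isSingular(fit),
                 residuals = stats::residuals(fit),
                 fitted = stats::fitted(fit),
                 fixed = fixed, random = random, response = response),
            class = "group_model")
}

#' @export
print.group_model <- function(x, ...) {
  cat("Mixed-effects group model:", x$response, "~",
      paste(x$fixed, collapse = " * "), "+ (1 |", x$random, ")\n")
  if (x$transform != "none")
    cat("  transform:", x$transform,
        if (!is.na(x$lambda)) paste0("(lambda = ", x$lambda, ")"), "\n")
  if (x$singular) cat("  note: singular fit (a variance component is 0)\n")
  cat("\nType III ANOVA (Satterthwaite df):\n")
  print(round(x$anova, 4))
  invisible(x)
}

#' Estimated-marginal-means contrasts with Tukey adjustment
#'
#' Pairwise contrasts over the grid of one or more fixed factors of a
#' [fit_group_model()] fit, with family-wise Tukey correction.
#' Inestimable contrasts (empty cells) are kept as NA rows.
#'
#' @param model a `group_model`.
#' @param factors factor name(s) to compare; defaults to all fixed
#'   factors crossed.
#' @param adjust multiplicity adjustment (default `"tukey"`).
#' @param by optional conditioning factor(s).
#' @return data.frame of contrasts: estimate, SE, df, t, adjusted p.
#' @export
emm_contrasts <- function(model, factors = NULL, adjust = "tukey",
                          by = NULL) {
  fit <- if (inherits(model, "group_model")) model$fit else model
  factors <- factors %||% model$fixed
  emm <- emmeans::emmeans(fit, specs = factors, by = by,
                          lmer.df = "satterthwaite")
  as.data.frame(emmeans::contrast(emm, method = "pairwise", adjust = adjust))
}

#' Repeated-measures correlation
#'
#' The common within-subject correlation between `x` and `y`, from the
#' ANCOVA with subject as a factor and `x` as covariate:
#' `r_rm = sign(slope) * sqrt(SS_x / (SS_x + SS_error))` with
#' `df = N - k - 1` for N observations on k subjects. The confidence
#' interval uses the Fisher z transform with that df; the p-value is the
#' two-sided t test of the common slope on df degrees of freedom.
#'
#' @param subject subject identifiers (the repeated-measures grouping).
#' @param x,y numeric covariate and response.
#' @param conf_level CI level (default 0.95).
#' @return list: `r`, `df`, `conf_int`, `p`, `slope`, `n`, `k`.
#' @export
rmcorr <- function(subject, x, y, conf_level = 0.95) {
  ok <- stats::complete.cases(subject, x, y)
  subject <- factor(subject[ok]); x <- x[ok]; y <- y[ok]
  N <- length(x); k <- nlevels(subject)
  if (N < 4L) stop("too few observations")
  xc <- x - stats::ave(x, subject)
  if (all(abs(xc) < 1e-12))
    stop("x is constant within every subject; no within-subject information")
  fit <- if (k > 1L) stats::lm(y ~ subject + x) else stats::lm(y ~ x)
  an <- stats::anova(fit)
  ss_x <- an["x", "Sum Sq"]
  ss_err <- an["Residuals", "Sum Sq"]
  slope <- stats::coef(fit)[["x"]]
  r <- sign(slope) * sqrt(ss_x / (ss_x + ss_err))
  df <- N - k - 1L
  tstat <- r * sqrt(df / max(1 - r^2, 1e-12))
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  se_z <- 1 / sqrt(max(df - 1L, 1L))
  zc <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- tanh(atanh(r) + c(-1, 1) * zc * se_z)
  list(r = r, df = df, conf_int = ci, p = p, slope = slope, n = N, k = k)
}

#' Pearson chi-square on a condition x spine-class table
#'
#' Uncorrected Pearson chi-square on the pooled contingency table, with
#' per-class post hocs: each class is collapsed against all others and
#' tested, p-values Bonferroni-adjusted over the number of classes
#' tested. Zero expected cells are an error (pool categories first).
#'
#' @param counts matrix of pooled spine counts, rows = conditions,
#'   columns = classes.
#' @param include_classes optional subset of class columns to test
#'   (e.g. excluding branched spines).
#' @return list: `chi2`, `df`, `p`, `expected`, `post_hoc` (per-class
#'   chi2 and Bonferroni-adjusted p).
#' @export
chisq_shape_test <- function(counts, include_classes = NULL) {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("class", seq_len(ncol(counts)))
  counts <- counts[, include_classes %||% colnames(counts), drop = FALSE]
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero expected counts: pool or drop empty categories first")
  main <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  if (any(main$expected <= 0))
    stop("zero expected counts: pool or drop empty categories first")
  classes <- colnames(counts)
  ph <- lapply(seq_along(classes), function(j) {
    tab <- cbind(counts[, j], rowSums(counts[, -j, drop = FALSE]))
    sub <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    data.frame(class = classes[j],
               chi2 = unname(sub$statistic), df = unname(sub$parameter),
               p_raw = sub$p.value, stringsAsFactors = FALSE)
  })
  ph <- do.call(rbind, ph)
  ph$p_adj <- pmin(1, ph$p_raw * length(classes))   # Bonferroni family = classes
  list(chi2 = unname(main$statistic), df = unname(main$parameter),
       p = main$p.value, expected = main$expected, post_hoc = ph)
}

#' Relative expression by the delta-delta-Cq method
#'
#' Per sample, `dCq = Cq_target - mean(Cq of the reference genes)`;
#' per condition, `ddCq = mean dCq(condition) - mean dCq(calibrator)`;
#' fold change `= 2^(-ddCq)`. Samples missing a reference well are
#' excluded with a warning.
#'
#' @param records data.frame with `sample_id`, `condition`, `gene`, `cq`.
#' @param target target gene name.
#' @param reference_genes the reference genes (both required per sample).
#' @param calibrator calibrator condition (fold change 1 by definition).
#' @return data.frame: condition, n samples, mean dCq, ddCq, fold.
#' @export
ddcq <- function(records, target, reference_genes = c("GAPDH", "RPLP1"),
                 calibrator = "control") {
  stopifnot(all(c("sample_id", "condition", "gene", "cq") %in% names(records)))
  samples <- unique(records$sample_id)
  dcq <- lapply(samples, function(s) {
    r <- records[records$sample_id == s, ]
    refs <- vapply(reference_genes,
                   function(g) mean(r$cq[r$gene == g]), 1)
    tgt <- mean(r$cq[r$gene == target])
    if (any(!is.finite(refs)) || !is.finite(tgt)) return(NULL)
    data.frame(sample_id = s, condition = r$condition[1L],
               dcq = tgt - mean(refs), stringsAsFactors = FALSE)
  })
  dropped <- samples[vapply(dcq, is.null, TRUE)]
  if (length(dropped))
    warning("samples missing a reference well excluded: ",
            paste(dropped, collapse = ", "))
  dcq <- do.call(rbind, dcq)
  if (!calibrator %in% dcq$condition) stop("calibrator condition not found")
  cal <- mean(dcq$dcq[dcq$condition == calibrator])
  agg <- stats::aggregate(dcq ~ condition, dcq, mean)
  agg$n <- as.vector(table(dcq$condition)[agg$condition])
  agg$ddcq <- agg$dcq - cal
  agg$fold <- 2^(-agg$ddcq)
  names(agg)[names(agg) == "dcq"] <- "mean_dcq"
  agg[, c("condition", "n", "mean_dcq", "ddcq", "fold")]
}

#' Percent change of a comparison mean relative to a reference mean
#'
#' `100 * (reference - comparison) / reference`: positive values are
#' decreases relative to the reference, negative values increases.
#'
#' @param reference_mean non-zero reference (e.g. control) mean.
#' @param comparison_mean comparison (e.g. knockdown) mean.
#' @return percent change (positive = decrease).
#' @export
percent_change <- function(reference_mean, comparison_mean) {
  if (any(reference_mean == 0)) stop("reference mean must be non-zero")
  100 * (reference_mean - comparison_mean) / reference_mean
}
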