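#' @useDynLib spinemorph, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rpois rnorm runif rbinom sd quantile lm anova aov
#'   coef pt qnorm pchisq chisq.test shapiro.test median setNames
#'   as.formula p.adjust complete.cases
#' @importFrom utils read.csv write.csv head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a temporary RNG state seeded with `seed`, then
# restore the caller's stream. All generator randomness flows through
# this so that identical recipe + seed gives identical output.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a per-object sub-seed so adding objects never perturbs the
# streams of existing ones.
sub_seed <- function(seed, stream, i = 0L) {
  (as.integer(seed) * 1103L + stream * 9973L + as.integer(i) * 7919L) %% 2147483629L
}

stopifnot_scalar_pos <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(what, " must be a single positive number", call. = FALSE)
  invisible(x)
}

polyline_length <- function(path) {
  if (nrow(path) < 2L) return(0)
  d <- diff(path)
  sum(sqrt(rowSums(d^2)))
}

cumulative_arclength <- function(path) {
  if (nrow(path) < 2L) return(0)
  c(0, cumsum(sqrt(rowSums(diff(path)^2))))
}
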