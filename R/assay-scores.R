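#' SING climbing score
#'
#' Startle-induced negative geotaxis: flies are tapped down and counted
#' per tube after climbing; tube 1 (bottom) scores 0, tube 5 scores 4, and
#' the score is the count-weighted mean normalized to `[0, 1]`:
#' `(N1*0 + N2*1 + N3*2 + N4*3 + N5*4) / (4 * sum(N))`.
#'
#' @param counts Numeric vector of 5 non-negative tube counts
#'   (tube 1 = bottom).
#' @return Score in `[0, 1]`.
#' @export
sing_score <- function(counts) {
  if (length(counts) != 5 || any(counts < 0)) {
    stop("counts must be 5 non-negative values (tubes 1-5)")
  }
  total <- sum(counts)
  if (total == 0) stop("total fly count must be > 0")
  sum(counts * 0:4) / (4 * total)
}

#' Normalize a score to the control mean
#'
#' @param score Score(s) to normalize.
#' @param control_scores Control scores whose mean is the reference.
#' @return `score / mean(control_scores)`.
#' @export
normalize_score <- function(score, control_scores) {
  m <- mean(control_scores)
  if (!is.finite(m) || m <= 0) stop("control mean must be > 0")
  score / m
}

#' Percentage of seizure-free flies
#'
#' @param n_without Number of flies without seizure-like behavior.
#' @param n_total Total flies tested (> 0).
#' @return Percentage in `[0, 100]`.
#' @export
seizure_free_pct <- function(n_without, n_total) {
  if (any(n_total <= 0)) stop("n_total must be > 0")
  if (any(n_without < 0) || any(n_without > n_total)) {
    stop("n_without must lie in [0, n_total]")
  }
  100 * n_without / n_total
}

#' Correlation of two genotype-level phenotype means
#'
#' Ordinary least squares of `y` on `x` across genotypes, with R-squared,
#' the slope-test p-value and a 95% confidence band for the fitted line.
#'
#' @param x,y Named numeric vectors of per-genotype means (same genotype
#'   set, n >= 3).
#' @return List with `r_squared`, `p_value`, `slope`, `intercept`, `fit`
#'   (the `lm` object) and `band` (`data.frame(x, fit, lwr, upr)`).
#' @export
genotype_correlation <- function(x, y) {
  if (!is.null(names(x)) && !is.null(names(y))) {
    if (!setequal(names(x), names(y))) stop("genotype sets differ")
    y <- y[names(x)]
  }
  if (length(x) != length(y) || length(x) < 3) {
    stop("need the same genotypes on both axes, n >= 3")
  }
  fit <- lm(y ~ x)
  sm <- summary(fit)
  grid <- data.frame(x = seq(min(x), max(x), length.out = 50))
  band <- cbind(grid, predict(fit, grid, interval = "confidence", level = 0.95))
  list(
    r_squared = sm$r.squared,
    p_value = sm$coefficients["x", "Pr(>|t|)"],
    slope = coef(fit)[["x"]],
    intercept = coef(fit)[["(Intercept)"]],
    fit = fit,
    band = band
  )
}
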