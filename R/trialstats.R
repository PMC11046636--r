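# Subject-level correlations between conceptual change and gaze
# displacement, with Fisher-z group inference (frequentist t tests plus
# default JZS Bayes factors).

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties.  Errors on constant input,
#' where the correlation is undefined.
#'
#' @param x,y numeric vectors of equal length (at least 3).
#' @param method `"spearman"` (default) or `"pearson"`, the latter provided
#'   for sensitivity checks.
#' @return the correlation coefficient.
#' @export
spearman_rho <- function(x, y, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop_config("x and y must have equal length")
  if (length(x) < 3) stop_config("need at least 3 pairs")
  if (anyNA(x) || anyNA(y)) stop_config("missing values in input")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    stop_config("undefined correlation: constant vector")
  cor(x, y, method = method)
}

#' Fisher z-transform of a correlation
#'
#' @param rho correlation in `(-1, 1)`; with `clip = TRUE` values at
#'   `|rho| = 1` are clipped to `1 - 1e-7` in magnitude instead of erroring.
#' @param clip clip instead of erroring at the boundary.
#' @return `atanh(rho)`.
#' @export
fisher_z <- function(rho, clip = FALSE) {
  if (any(abs(rho) > 1)) stop_config("|rho| > 1")
  if (any(abs(rho) == 1)) {
    if (!clip) stop_config("infinite Fisher transform at |rho| = 1")
    rho <- sign(rho) * pmin(abs(rho), 1 - 1e-7)
  }
  atanh(rho)
}

#' Correlate a displacement series with a conceptual change series
#'
#' Aligns the two series on their transition index (`from_trial`) and
#' correlates the gaze quantity selected by `axis` with the conceptual
#' quantity selected by `mode`:
#' * `combined`: signed gaze change vs signed conceptual change (for
#'   `euclid_2d`, the unsigned 2D displacement vs the unsigned conceptual
#'   distance, since a signed quantity cannot pair with a non-negative
#'   one);
#' * `magnitude_only`: `|gaze|` vs `|change|`;
#' * `sign_only`: `sign(gaze)` vs `sign(change)` (1D axes only);
#' * `control_transition`: unsigned gaze change vs the transition-frequency
#'   control values.
#'
#' @param disp displacement series from [displacement_series()].
#' @param change concept-change series (same session).
#' @param axis `"x_signed"`, `"y_signed"` or `"euclid_2d"`.
#' @param mode `"combined"`, `"sign_only"`, `"magnitude_only"` or
#'   `"control_transition"`.
#' @param subject,condition identifiers copied into the result.
#' @param method correlation method, see [spearman_rho()].
#' @return one-row data frame: `subject`, `condition`, `axis`, `mode`,
#'   `rho`, `z` (Fisher transform, clipped at `|rho| = 1`), `n_pairs`.
#' @export
condition_correlation <- function(disp, change,
                                  axis = c("x_signed", "y_signed",
                                           "euclid_2d"),
                                  mode = c("combined", "sign_only",
                                           "magnitude_only",
                                           "control_transition"),
                                  subject = NA_character_,
                                  condition = NA_character_,
                                  method = "spearman") {
  axis <- match.arg(axis)
  mode <- match.arg(mode)
  m <- match(change$from_trial, disp$from_trial)
  keep <- !is.na(m)
  if (sum(keep) < 3)
    stop_config("fewer than 3 aligned transition pairs")
  gaze <- switch(axis,
                 x_signed = disp$dx, y_signed = disp$dy,
                 euclid_2d = disp$d2)[m[keep]]
  conc <- change$value[keep]

  if (mode == "sign_only" && axis == "euclid_2d")
    stop_config("sign_only is undefined for the unsigned 2D displacement")
  v <- switch(mode,
    combined = {
      if (axis == "euclid_2d") list(gaze, abs(conc)) else list(gaze, conc)
    },
    magnitude_only = list(abs(gaze), abs(conc)),
    sign_only = list(sign(gaze), sign(conc)),
    control_transition = {
      if (axis == "euclid_2d") list(gaze, conc) else list(abs(gaze), conc)
    })
  rho <- spearman_rho(v[[1]], v[[2]], method = method)
  data.frame(subject = subject, condition = condition, axis = axis,
             mode = mode, rho = rho, z = fisher_z(rho, clip = TRUE),
             n_pairs = sum(keep), stringsAsFactors = FALSE)
}

#' First-order partial Spearman correlation
#'
#' Rank-transforms all three vectors and partials `control` out of the
#' `x`-`y` rank correlation with the standard first-order formula
#' `(r_xy - r_xc r_yc) / sqrt((1 - r_xc^2)(1 - r_yc^2))`.  The p-value uses
#' the t approximation with `n - 3` degrees of freedom.
#'
#' @param x,y,control numeric vectors of equal length (at least 4).
#' @return list with `rho_partial` and `p` (two-sided).
#' @export
partial_spearman <- function(x, y, control) {
  n <- length(x)
  if (length(y) != n || length(control) != n)
    stop_config("x, y and control must have equal length")
  if (n < 4) stop_config("need at least 4 observations")
  rx <- rank(x); ry <- rank(y); rc <- rank(control)
  rxy <- cor(rx, ry); rxc <- cor(rx, rc); ryc <- cor(ry, rc)
  if (1 - rxc^2 < 1e-12 || 1 - ryc^2 < 1e-12)
    stop_config("control is collinear with x or y")
  rp <- (rxy - rxc * ryc) / sqrt((1 - rxc^2) * (1 - ryc^2))
  tt <- rp * sqrt((n - 3) / max(1 - rp^2, 1e-12))
  list(rho_partial = rp, p = 2 * pt(-abs(tt), df = n - 3))
}

#' Group-level t test on Fisher-z values, with Bayes factor
#'
#' One-sample t test of per-subject Fisher-z correlations against zero, or a
#' paired t test between two conditions, plus the default two-sided JZS
#' Bayes factor computed from the resulting t statistic.
#'
#' @param values numeric vector of per-subject values (typically Fisher-z).
#' @param mode `"one_sample_vs_zero"` or `"paired"`.
#' @param values2 second condition for the paired mode (same length).
#' @param bf_scale Cauchy prior scale for the Bayes factor (default
#'   `sqrt(2) / 2`).
#' @return object of class `group_stats`: list with `mean_z`, `sd_z`, `t`,
#'   `df`, `p`, `bf10`, `n`.
#' @export
group_t <- function(values, mode = c("one_sample_vs_zero", "paired"),
                    values2 = NULL, bf_scale = sqrt(2) / 2) {
  mode <- match.arg(mode)
  if (mode == "paired") {
    if (is.null(values2) || length(values2) != length(values))
      stop_config("paired mode needs values2 of equal length")
    values <- values - values2
  }
  n <- length(values)
  if (n < 2) stop_config("need at least 2 subjects")
  if (sd(values) == 0)
    stop_config("degenerate variance: all values equal")
  ht <- t.test(values, mu = 0)
  structure(list(mean_z = mean(values), sd_z = sd(values),
                 t = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value,
                 bf10 = jzs_bf10(unname(ht$statistic), n, scale = bf_scale),
                 n = n),
            class = "group_stats")
}

#' @export
print.group_stats <- function(x, ...) {
  cat(sprintf("group t-test: mean = %.4f (SD %.4f), t(%d) = %.3f, p = %.4g, BF10 = %.4g\n",
              x$mean_z, x$sd_z, x$df, x$t, x$p, x$bf10))
  invisible(x)
}

#' Two-sided JZS one-sample Bayes factor
#'
#' Default Bayes factor for a one-sample (or paired) t test: a Cauchy prior
#' with the given scale on the standardized effect size under H1, a point
#' null under H0.  The marginal likelihood under H1 is obtained by
#' integrating the t likelihood over the variance-mixture representation of
#' the Cauchy (an inverse-gamma(1/2, scale^2/2) mixing density), using
#' adaptive quadrature.
#'
#' @param t observed t statistic.
#' @param n number of observations (pairs); degrees of freedom `n - 1`.
#' @param scale Cauchy prior scale (default `sqrt(2) / 2`).
#' @return the Bayes factor BF10 in favor of H1 over H0.
#' @export
jzs_bf10 <- function(t, n, scale = sqrt(2) / 2) {
  if (!is_count(n) || n < 2) stop_config("n must be an integer >= 2")
  if (scale <= 0) stop_config("scale must be positive")
  nu <- n - 1
  log_null <- -(nu + 1) / 2 * log1p(t^2 / nu)
  integrand <- function(g) {
    out <- numeric(length(g))
    ok <- g > 0
    g <- g[ok]
    out[ok] <- exp(-0.5 * log1p(n * g) -
          (nu + 1) / 2 * log1p(t^2 / ((1 + n * g) * nu)) -
          log_null +                       # fold the ratio in for stability
          log(scale) - 0.5 * log(2 * pi) - 1.5 * log(g) -
          scale^2 / (2 * g))
    out
  }
  int <- tryCatch(
    integrate(integrand, 0, Inf, rel.tol = 1e-9, abs.tol = 0,
              subdivisions = 500L),
    error = function(e) stop_config("Bayes factor integration failed: %s",
                                    conditionMessage(e)))
  if (int$message != "OK")
    stop_config("Bayes factor integration did not converge: %s", int$message)
  int$value
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise error rate in `(0, 1)`.
#' @param m number of comparisons.
#' @return `alpha / m`.
#' @export
bonferroni_alpha <- function(alpha = 0.05, m = 1L) {
  if (!is_count(m)) stop_config("m must be a positive integer")
  if (alpha <= 0 || alpha >= 1) stop_config("alpha must lie in (0, 1)")
  alpha / m
}
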