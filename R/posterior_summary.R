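# Posterior summaries on the reporting scale: mean coefficients, equal-tailed
# credible intervals, percent change per unit exposure, geometric-mean
# relative risks, and the population-average exposure-response density.

#' Equal-tailed credible interval
#'
#' Sample quantiles at \eqn{(1-level)/2} and \eqn{1-(1-level)/2} (linear
#' interpolation, quantile type 7).
#'
#' @param draws Numeric vector of posterior draws (at least 100 for a 95%
#'   interval to be meaningful).
#' @param level Credibility level, default 0.95.
#' @return Named numeric vector `c(lower, upper)`.
#' @export
credible_interval <- function(draws, level = 0.95) {
  if (!length(draws)) stop("empty draws")
  if (level <= 0 || level >= 1) stop("`level` must be in (0, 1)")
  a <- (1 - level) / 2
  q <- quantile(draws, probs = c(a, 1 - a), type = 7, names = FALSE)
  c(lower = q[1], upper = q[2])
}

#' Percent change in rates per unit exposure
#'
#' \eqn{(1 - e^\beta) \times 100}: positive values are percent decreases in
#' the expected rate for a one-unit exposure increase (e.g. one physician per
#' 10,000 people).
#'
#' @param beta Log-scale coefficient(s).
#' @param digits Display rounding (half away from zero); `NULL` for no
#'   rounding.
#' @return Percent change (decrease when positive).
#' @examples
#' percent_change(-0.037)  # 3.6 (% decrease)
#' @export
percent_change <- function(beta, digits = 1L) {
  stopifnot(all(is.finite(beta)))
  pc <- (1 - exp(beta)) * 100
  if (is.null(digits)) pc else round_half_away(pc, digits)
}

#' Geometric-mean relative risk
#'
#' \eqn{\exp(\bar\beta)} — equivalently the geometric mean of the
#' exponentiated draws: the centre of the population-average
#' exposure-response distribution.
#'
#' @param draws Posterior draws of a log-scale coefficient.
#' @return Scalar relative risk.
#' @examples
#' geometric_mean_rr(-0.028)  # 0.972...
#' @export
geometric_mean_rr <- function(draws) {
  if (!length(draws)) stop("empty draws")
  exp(mean(draws))
}

#' Population-average exposure-response density
#'
#' Kernel density estimate of the exponentiated coefficient draws
#' \eqn{e^\beta} — the posterior of the multiplicative change in expected
#' risk per unit exposure increase. Degenerate (constant) draws return a
#' point-mass representation instead of crashing.
#'
#' @param draws Posterior draws of the log-scale coefficient (>= 500
#'   recommended).
#' @param n_grid Grid size of the density estimate.
#' @return List with `type` (`"density"` or `"point_mass"`); for densities,
#'   `grid`, `value` and `bandwidth` (trapezoid-normalized to integrate to 1);
#'   for a point mass, `at`.
#' @export
exposure_response_density <- function(draws, n_grid = 512L) {
  if (!length(draws)) stop("empty draws")
  rr <- exp(draws)
  if (max(rr) - min(rr) < 1e-12) {
    return(list(type = "point_mass", at = rr[1]))
  }
  d <- density(rr, n = n_grid)
  dx <- diff(d$x)
  mass <- sum((d$y[-1] + d$y[-length(d$y)]) / 2 * dx)
  list(type = "density", grid = d$x, value = d$y / mass, bandwidth = d$bw)
}

#' Bundle the reported summaries of one coefficient
#'
#' Computes the quantities such analyses report for each exposure model: the
#' posterior mean coefficient, the 95% equal-tailed credible interval, the
#' percent change per unit exposure, the geometric-mean relative risk, and a
#' significance flag (interval excludes zero).
#'
#' @param draws A `posterior_draws` object, draw matrix, or numeric vector.
#' @param parameter Parameter name when `draws` is an object/matrix.
#' @param level Credibility level.
#' @return An object of class `effect_summary` (a list with fields `parameter`,
#'   `mean`, `ci_lower`, `ci_upper`, `percent_change`, `rr`, `significant`,
#'   `n_draws`).
#' @export
summarize_effect <- function(draws, parameter = "beta_x", level = 0.95) {
  ch <- param_chain(draws, parameter)
  ci <- credible_interval(ch, level)
  m <- mean(ch)
  structure(list(parameter = parameter,
                 mean = m,
                 ci_lower = unname(ci[1]), ci_upper = unname(ci[2]),
                 percent_change = percent_change(m, digits = NULL),
                 rr = geometric_mean_rr(ch),
                 significant = unname(ci[1] > 0 || ci[2] < 0),
                 n_draws = length(ch), level = level),
            class = "effect_summary")
}

#' @export
print.effect_summary <- function(x, ...) {
  cat(sprintf(
    "%s: mean %.3f, %d%% CI (%.3f, %.3f)%s\n  RR %.2f, %s of %.1f%% per unit exposure\n",
    x$parameter, x$mean, round(100 * x$level), x$ci_lower, x$ci_upper,
    if (x$significant) " *" else "", x$rr,
    if (x$percent_change >= 0) "decrease" else "increase",
    abs(round_half_away(x$percent_change, 1))))
  invisible(x)
}

#' Tabulate effect summaries across fitted models
#'
#' @param fits Named list of `posterior_draws` objects.
#' @param parameter Coefficient to summarize.
#' @return Data frame with one row per model: mean coefficient (3 decimals in
#'   `mean_3dp`), credible interval, RR (2 decimals in `rr_2dp`), percent
#'   change and significance.
#' @export
effect_table <- function(fits, parameter = "beta_x") {
  rows <- lapply(names(fits), function(nm) {
    s <- summarize_effect(fits[[nm]], parameter)
    data.frame(model = nm, mean = s$mean,
               mean_3dp = round_half_away(s$mean, 3),
               ci_lower = s$ci_lower, ci_upper = s$ci_upper,
               rr = s$rr, rr_2dp = round_half_away(s$rr, 2),
               percent_change = round_half_away(s$percent_change, 1),
               significant = s$significant)
  })
  do.call(rbind, rows)
}
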