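# Closed-form starting-point sample sizes: the calibration-slope (uniform
# shrinkage) criterion and the overall-risk precision criterion, with a
# simulation-based conversion from an anticipated c-statistic to the
# Cox-Snell R-squared the slope criterion needs.

#' Convert an anticipated c-statistic to a Cox--Snell R-squared
#'
#' Simulation-based conversion: outcomes are drawn at the anticipated
#' prevalence and a latent linear predictor is drawn normal within outcome
#' groups with separation `sqrt(2) * qnorm(C)` (the binormal model attaining
#' c-statistic `C`); each individual's risk follows from Bayes' rule, and
#' the Cox--Snell R-squared is computed from the Bernoulli log-likelihoods
#' of those risks against the prevalence-only null.
#'
#' @param C Anticipated c-statistic in (0.5, 1).
#' @param prev Anticipated outcome prevalence in (0, 1).
#' @param sim_size Simulation size (default 1e6; stable to about 0.001).
#' @param seed Integer seed.
#' @return The Cox--Snell R-squared (scalar).
#' @export
cstat_to_r2cs <- function(C, prev, sim_size = 1e6, seed = 2025L) {
  if (C <= 0.5 || C >= 1) stop("C must be in (0.5, 1)")
  if (prev <= 0 || prev >= 1) stop("prev must be in (0, 1)")
  if (!is_count(sim_size)) stop("sim_size must be a positive integer")
  set.seed(seed)
  mu <- sqrt(2) * qnorm(C)
  y <- rbinom(sim_size, 1L, prev)
  lp <- rnorm(sim_size, mu * y, 1)
  num <- prev * dnorm(lp, mu)
  p <- num / (num + (1 - prev) * dnorm(lp, 0))
  ll1 <- sum(y * log(p) + (1 - y) * log(1 - p))
  ll0 <- sum(y * log(prev) + (1 - y) * log(1 - prev))
  1 - exp(2 * (ll0 - ll1) / sim_size)
}

#' Minimum sample size targeting a calibration slope (uniform shrinkage)
#'
#' Closed-form criterion `n = P / ((S - 1) * ln(1 - R2_CS / S))` for the
#' expected uniform shrinkage `S` of an unpenalised logistic regression
#' with `P` predictor parameters.
#'
#' @param P Number of candidate predictor parameters.
#' @param r2_cs Anticipated Cox--Snell R-squared (see [cstat_to_r2cs()]).
#' @param S Target expected shrinkage / calibration slope (default 0.9).
#' @param cap Error when the required `n` exceeds this cap (guards the
#'   `r2_cs -> 0` divergence; default 1e7).
#' @return Minimum sample size (integer, ceiling of the real solution).
#' @export
n_slope_criterion <- function(P, r2_cs, S = 0.9, cap = 1e7) {
  stopifnot(is_count(P))
  if (S <= 0 || S >= 1) stop("S must be in (0, 1)")
  if (r2_cs <= 0) stop("r2_cs must be positive")
  if (r2_cs >= S) stop("r2_cs must be below the target shrinkage S")
  n <- P / ((S - 1) * log(1 - r2_cs / S))
  if (!is.finite(n) || n > cap) {
    stop("required sample size exceeds cap (", format(cap), "); r2_cs is ",
         "too close to 0")
  }
  as.integer(ceiling(n))
}

#' Minimum sample size for precise overall-risk estimation
#'
#' `n = ceil(1.96^2 * prev * (1 - prev) / (ci_width / 2)^2)`: the smallest
#' sample whose 95% confidence interval for the overall outcome risk has at
#' most the target width.
#'
#' @param prev Anticipated outcome prevalence in (0, 1).
#' @param ci_width Target 95% confidence-interval width (default 0.1).
#' @return Minimum sample size (integer).
#' @export
n_risk_precision <- function(prev, ci_width = 0.1) {
  if (prev <= 0 || prev >= 1) stop("prev must be strictly inside (0, 1)")
  if (ci_width <= 0 || ci_width >= 1) stop("ci_width must be in (0, 1)")
  as.integer(ceiling(1.96^2 * prev * (1 - prev) / (ci_width / 2)^2))
}

#' Starter sample-size criteria
#'
#' Runs the two closed-form starting-point criteria and reports the larger:
#' the calibration-slope (uniform shrinkage) criterion, via the
#' c-statistic to Cox--Snell R-squared conversion, and the overall-risk
#' precision criterion. Expected events (`round(n * prev)`) are reported
#' alongside each size.
#'
#' @param C Anticipated c-statistic.
#' @param prev Anticipated outcome prevalence.
#' @param P Number of candidate predictor parameters.
#' @param S Target shrinkage (default 0.9).
#' @param ci_width Target 95% CI width for the overall risk (default 0.1).
#' @param sim_size Conversion simulation size (default 1e6).
#' @param seed Conversion seed.
#' @return An object of class `starter_result` with `r2_cs`, `max_r2_cs`,
#'   `n_slope`, `n_risk`, `n_min`, expected events, and the echoed inputs.
#' @export
starter_sizes <- function(C, prev, P, S = 0.9, ci_width = 0.1,
                          sim_size = 1e6, seed = 2025L) {
  r2 <- cstat_to_r2cs(C, prev, sim_size, seed)
  max_r2 <- 1 - exp(2 * (prev * log(prev) + (1 - prev) * log(1 - prev)))
  n_slope <- n_slope_criterion(P, r2, S)
  n_risk <- n_risk_precision(prev, ci_width)
  structure(list(
    r2_cs = r2, max_r2_cs = max_r2,
    n_slope = n_slope, n_risk = n_risk,
    n_min = max(n_slope, n_risk),
    events_slope = round(n_slope * prev), events_risk = round(n_risk * prev),
    inputs = list(C = C, prev = prev, P = P, S = S, ci_width = ci_width,
                  sim_size = sim_size, seed = seed)
  ), class = "starter_result")
}

#' @export
print.starter_result <- function(x, ...) {
  cat("Starter sample-size criteria\n")
  cat(sprintf("  anticipated C = %.3f, prevalence = %.3f, P = %d\n",
              x$inputs$C, x$inputs$prev, x$inputs$P))
  cat(sprintf("  Cox-Snell R2 = %.4f (max attainable %.4f)\n",
              x$r2_cs, x$max_r2_cs))
  cat(sprintf("  calibration-slope criterion (S = %.2f): n = %d (~%d events)\n",
              x$inputs$S, x$n_slope, x$events_slope))
  cat(sprintf("  overall-risk precision (CI width %.2f): n = %d (~%d events)\n",
              x$inputs$ci_width, x$n_risk, x$events_risk))
  cat(sprintf("  recommended minimum: n = %d\n", x$n_min))
  invisible(x)
}
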