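# Performance, degradation, classification and value-of-information measures,
# evaluated in the (large) target population.

#' Concordance statistic (c-statistic / AUROC)
#'
#' Rank-based concordance between estimated risks and binary outcomes, with
#' ties counted one half.
#'
#' @param phat Estimated risks.
#' @param y Binary outcomes (0/1); both classes must be present.
#' @return The c-statistic in \[0, 1\].
#' @export
c_statistic <- function(phat, y) {
  stopifnot(length(phat) == length(y))
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) {
    stop("c-statistic undefined: only one outcome class present")
  }
  r <- rank(phat)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (as.numeric(n1) * as.numeric(n0))
}

#' Calibration slope, calibration-in-the-large, and calibration curve
#'
#' Fits `logit(P(y=1)) = alpha_cal + beta_cal * logit(phat)`. The slope
#' `beta_cal` comes from logistic regression of the outcomes on the logit of
#' the estimated risks; the calibration-in-the-large `alpha_cal` from the
#' same regression with the slope fixed at 1 (logit risks as offset). Risks
#' are clipped to `[eps, 1 - eps]` before the logit (tree-based models can
#' emit exact 0/1). If the predictions are (numerically) constant, the slope
#' is recorded as 0 with a flag.
#'
#' @param phat Estimated risks.
#' @param y Binary outcomes (0/1).
#' @param eps Clipping bound before the logit (default 1e-8).
#' @param curve If `TRUE`, also return a flexible calibration curve
#'   (natural cubic spline of observed on logit predicted risk) evaluated on
#'   a grid of predicted risks.
#' @return List with `slope`, `intercept`, `flags`, and (optionally) `curve`
#'   (a data frame of `predicted` and `observed`).
#' @export
calibration <- function(phat, y, eps = 1e-8, curve = FALSE) {
  stopifnot(length(phat) == length(y))
  if (length(unique(y)) < 2L) {
    stop("calibration undefined: only one outcome class present")
  }
  lp <- qlogis(clip_prob(phat, eps))
  y <- as.integer(y)
  flags <- character()
  if (var(lp) < 1e-12) {
    slope <- 0
    flags <- "constant_predictions"
    a <- logistic_newton(matrix(1, length(y), 1), y, lp)[1L]
  } else {
    cf <- logistic_newton(cbind(1, lp), y, numeric(0))
    slope <- cf[2L]
    a <- logistic_newton(matrix(1, length(y), 1), y, lp)[1L]
  }
  out <- list(slope = slope, intercept = a, flags = flags)
  if (curve) {
    basis <- splines::ns(lp, df = 3)
    f <- suppressWarnings(glm.fit(cbind(1, basis), y, family = binomial()))
    grid_lp <- seq(quantile(lp, 0.01), quantile(lp, 0.99), length.out = 100)
    gb <- predict(basis, grid_lp)
    obs <- plogis(cbind(1, gb) %*% f$coefficients)
    out$curve <- data.frame(predicted = plogis(grid_lp),
                            observed = as.numeric(obs))
  }
  out
}

#' Prediction error against the true risks
#'
#' @param phat Estimated risks.
#' @param p_true True (reference-model) risks, same length.
#' @return List with `mape` (mean absolute prediction error) and `rmspe`
#'   (root mean squared prediction error).
#' @export
prediction_error <- function(phat, p_true) {
  if (length(phat) != length(p_true)) {
    stop("phat and p_true must have equal length")
  }
  d <- phat - p_true
  list(mape = mean(abs(d)), rmspe = sqrt(mean(d^2)))
}

#' Net benefit of a risk model at a threshold
#'
#' `NB = TP/n - FP/n * t/(1-t)` with individuals classified positive when
#' their estimated risk is at or above the threshold.
#'
#' @param phat Estimated risks (or a logical classification vector).
#' @param y Binary outcomes (0/1).
#' @param threshold Risk threshold in (0, 1).
#' @return Net benefit (scalar).
#' @export
net_benefit <- function(phat, y, threshold) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  pos <- if (is.logical(phat)) phat else phat >= threshold
  n <- length(y)
  tp <- sum(pos & y == 1)
  fp <- sum(pos & y == 0)
  (tp - fp * threshold / (1 - threshold)) / n
}

#' Net benefit of the treat-all strategy
#'
#' @param y Binary outcomes (0/1), or a single prevalence in (0, 1).
#' @param threshold Risk threshold in (0, 1).
#' @return `phi - (1 - phi) * t / (1 - t)` where `phi` is the prevalence.
#' @export
nb_treat_all <- function(y, threshold) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  phi <- if (length(y) == 1L && y > 0 && y < 1) y else mean(y)
  phi - (1 - phi) * threshold / (1 - threshold)
}

#' Degradation and relative value of sample information for net benefit
#'
#' @param nb_model Net benefit of the developed model.
#' @param nb_max Net benefit of the true (reference) model.
#' @return List with `degradation = nb_model - nb_max` (the per-model value
#'   underlying the expected value of sample information), `rvsi = 100 *
#'   nb_model / nb_max`, and `flags` (RVSI undefined when `nb_max <= 0`).
#' @export
value_of_information <- function(nb_model, nb_max) {
  flags <- character()
  rvsi <- if (nb_max <= 0) {
    flags <- "nb_max_nonpositive"
    NA_real_
  } else {
    100 * nb_model / nb_max
  }
  list(degradation = nb_model - nb_max, rvsi = rvsi, flags = flags)
}

#' Net benefit of the winner strategy
#'
#' Among the developed model, treat-all and treat-none, selects the strategy
#' with the highest observed net benefit in the development sample (ties
#' broken with precedence model > treat-all > treat-none) and returns that
#' strategy's net benefit evaluated in the target population.
#'
#' @param fit A `fitted_cpm`.
#' @param dev The development data the model was fitted on.
#' @param pop_phat Model risks in the target population.
#' @param pop_y Target-population outcomes.
#' @param threshold Risk threshold.
#' @return List with `winner` (label) and `nb` (population net benefit).
#' @export
winner_net_benefit <- function(fit, dev, pop_phat, pop_y, threshold) {
  dev_phat <- predict_risk(fit, dev$X)
  nb_dev <- c(model = net_benefit(dev_phat, dev$y, threshold),
              treat_all = nb_treat_all(dev$y, threshold),
              treat_none = 0)
  winner <- names(nb_dev)[which.max(nb_dev)]  # first max = precedence order
  nb_pop <- switch(winner,
    model = net_benefit(pop_phat, pop_y, threshold),
    treat_all = nb_treat_all(pop_y, threshold),
    treat_none = 0
  )
  list(winner = winner, nb = nb_pop)
}

#' Per-individual misclassification probability
#'
#' For each individual, the fraction of simulated models whose estimated
#' risk falls on the opposite side of the threshold from the individual's
#' true risk (values at the threshold count as "at or above").
#'
#' @param values Matrix of risk draws, individuals in rows, simulated models
#'   in columns.
#' @param truth True risks, one per row.
#' @param threshold Risk threshold.
#' @return Vector of misclassification probabilities, one per individual.
#' @export
misclassification_probability <- function(values, truth, threshold) {
  stopifnot(is.matrix(values), nrow(values) == length(truth))
  side_true <- truth >= threshold
  rowMeans((values >= threshold) != side_true)
}

#' Per-individual prediction instability summaries
#'
#' @param values Matrix of risk draws, individuals in rows, simulated models
#'   in columns.
#' @param ess_cap Cap for the effective sample size when the draw variance
#'   is numerically zero (flagged).
#' @return Data frame with per-individual `mean`, 95% interval `width`
#'   (2.5th to 97.5th percentile), effective sample size `ess`
#'   (`pbar (1 - pbar) / var`), and `ess_capped`.
#' @export
instability_summaries <- function(values, ess_cap = 1e6) {
  stopifnot(is.matrix(values))
  qs <- apply(values, 1, quantile, probs = c(0.025, 0.975), names = FALSE)
  pbar <- rowMeans(values)
  v <- apply(values, 1, var)
  capped <- v < 1e-12
  ess <- ifelse(capped, ess_cap, pbar * (1 - pbar) / pmax(v, 1e-12))
  ess <- pmin(ess, ess_cap)
  data.frame(mean = pbar, width = qs[2, ] - qs[1, ], ess = ess,
             ess_capped = capped)
}

#' Cox--Snell and Nagelkerke R-squared
#'
#' Computed from the Bernoulli log-likelihood of the estimated risks against
#' the outcome-prevalence null model; Nagelkerke rescales Cox--Snell by its
#' attainable maximum.
#'
#' @param phat Estimated risks.
#' @param y Binary outcomes (0/1).
#' @return List with `r2_cs` and `r2_nagelkerke`.
#' @export
r2_measures <- function(phat, y) {
  stopifnot(length(phat) == length(y))
  n <- length(y)
  p <- clip_prob(phat)
  ll1 <- sum(y * log(p) + (1 - y) * log(1 - p))
  phi <- mean(y)
  ll0 <- sum(y * log(phi) + (1 - y) * log(1 - phi))
  r2_cs <- 1 - exp(2 * (ll0 - ll1) / n)
  max_cs <- 1 - exp(2 * ll0 / n)
  list(r2_cs = r2_cs, r2_nagelkerke = r2_cs / max_cs)
}

# truth baselines of the reference model in the target population
truth_metrics <- function(p_true, y, thresholds) {
  list(
    c = c_statistic(p_true, y),
    nb_max = vapply(thresholds, function(t) net_benefit(p_true, y, t),
                    numeric(1)),
    prevalence = mean(y)
  )
}

#' All replicate-level performance and degradation metrics
#'
#' Evaluates one developed model in the target population against the
#' reference-model truth: discrimination, calibration, prediction error,
#' overall fit, and net benefit / value of sample information at each
#' threshold, plus the degradation of each (developed minus true; the true
#' model's calibration slope is 1 by construction).
#'
#' @param phat Developed model's risks in the target population.
#' @param p_true Reference-model risks.
#' @param y Target-population outcomes.
#' @param truth Baselines from the reference model (internal; computed once
#'   per population).
#' @param thresholds Risk threshold(s).
#' @param fit,dev Optionally, the fitted model and development data, to also
#'   compute the winner-strategy net benefit.
#' @return One-row data frame of metrics (first threshold; additional
#'   thresholds add suffixed `nb`/`rvsi` columns).
#' @export
replicate_metrics <- function(phat, p_true, y, truth = NULL,
                              thresholds = 0.5, fit = NULL, dev = NULL) {
  if (is.null(truth)) truth <- truth_metrics(p_true, y, thresholds)
  cal <- calibration(phat, y)
  pe <- prediction_error(phat, p_true)
  r2 <- r2_measures(phat, y)
  cs <- c_statistic(phat, y)
  row <- data.frame(
    c = cs, cal_slope = cal$slope, cal_intercept = cal$intercept,
    mape = pe$mape, rmspe = pe$rmspe,
    r2_cs = r2$r2_cs, r2_nagelkerke = r2$r2_nagelkerke,
    c_deg = cs - truth$c, slope_deg = cal$slope - 1
  )
  flags <- cal$flags
  for (i in seq_along(thresholds)) {
    t <- thresholds[i]
    nb <- net_benefit(phat, y, t)
    voi <- value_of_information(nb, truth$nb_max[i])
    suff <- if (i == 1L) "" else paste0("_t", t)
    row[[paste0("nb", suff)]] <- nb
    row[[paste0("nb_deg", suff)]] <- voi$degradation
    row[[paste0("rvsi", suff)]] <- voi$rvsi
    flags <- c(flags, voi$flags)
    if (!is.null(fit) && !is.null(dev)) {
      w <- winner_net_benefit(fit, dev, phat, y, t)
      row[[paste0("nb_winner", suff)]] <- w$nb
      row[[paste0("rvsi_winner", suff)]] <-
        value_of_information(w$nb, truth$nb_max[i])$rvsi
    }
  }
  row$flags <- paste(flags, collapse = ";")
  row
}

#' Metrics within fairness subgroups
#'
#' Recomputes the replicate metrics within each subgroup label. Groups where
#' a metric is undefined (e.g. one outcome class) yield flagged partial
#' results rather than an error.
#'
#' @param phat,p_true,y As in [replicate_metrics()].
#' @param groups Vector of subgroup labels, one per individual.
#' @param thresholds Risk threshold(s).
#' @return Data frame with one row per subgroup (column `group` first).
#' @export
subgroup_metrics <- function(phat, p_true, y, groups, thresholds = 0.5) {
  stopifnot(length(groups) == length(y))
  out <- lapply(split(seq_along(y), groups), function(idx) {
    if (length(idx) == 0L) stop("empty subgroup")
    tryCatch(
      replicate_metrics(phat[idx], p_true[idx], y[idx],
                        thresholds = thresholds),
      error = function(e) {
        pe <- prediction_error(phat[idx], p_true[idx])
        data.frame(c = NA_real_, cal_slope = NA_real_,
                   cal_intercept = NA_real_, mape = pe$mape,
                   rmspe = pe$rmspe, r2_cs = NA_real_,
                   r2_nagelkerke = NA_real_, c_deg = NA_real_,
                   slope_deg = NA_real_, nb = NA_real_, nb_deg = NA_real_,
                   rvsi = NA_real_, flags = paste0("partial:", e$message))
      }
    )
  })
  res <- do.call(rbind, out)
  res <- cbind(data.frame(group = names(out), stringsAsFactors = FALSE,
                          row.names = NULL),
               res[, setdiff(colnames(res), "group"), drop = FALSE])
  rownames(res) <- NULL
  res
}
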