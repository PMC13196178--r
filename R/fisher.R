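# Fast approximation for (penalised) logistic regression: decompose the
# posterior covariance into sample size and Fisher's unit information, so the
# anticipated posterior at any sample size n is MVN(beta_ref, (n I)^{-1})
# (flat priors) or a shrinkage-prior posterior sampled by MH against that
# MVN pseudo-likelihood -- avoiding per-replicate development draws and fits.

#' Fisher unit-information matrix for logistic regression
#'
#' The per-observation expected information `I = E[w_i x_i x_i']` with
#' `w_i = p_i (1 - p_i)`, averaged across the rows of the case-mix matrix
#' (intercept column included), so that an n-observation maximum-likelihood
#' fit has approximate covariance `(n I)^{-1}`. Independent of sample size.
#'
#' @param beta Coefficient vector including the intercept first (e.g.
#'   `c(alpha, delta * beta)` of a calibrated reference model).
#' @param X Case-mix matrix (no intercept column); should be large so the
#'   average is stable.
#' @return An object of class `unit_information`: the `(P+1) x (P+1)`
#'   matrix with a `basis` attribute naming the columns (intercept first).
#' @export
unit_information <- function(beta, X) {
  X <- as.matrix(X)
  if (length(beta) != ncol(X) + 1L) {
    stop("beta must have length ncol(X) + 1 (intercept first)")
  }
  Xi <- cbind("(Intercept)" = 1, X)
  if (qr(Xi)$rank < ncol(Xi)) {
    warning("case-mix design matrix is rank deficient; the unit ",
            "information matrix will be singular")
  }
  p <- plogis(as.numeric(Xi %*% beta))
  w <- p * (1 - p)
  I <- crossprod(Xi * sqrt(w)) / nrow(Xi)
  dimnames(I) <- list(colnames(Xi), colnames(Xi))
  structure(I, basis = colnames(Xi), class = c("unit_information", "matrix"))
}

# (n I)^{-1} with conditioning diagnostics on failure
ui_covariance <- function(I, n) {
  ch <- tryCatch(chol(unclass(I)), error = function(e) e)
  if (inherits(ch, "error")) {
    stop("unit information matrix is not invertible (reciprocal condition ",
         "number ", format(rcond(unclass(I)), digits = 3), "); remove ",
         "collinear predictors or supply a larger case-mix sample")
  }
  chol2inv(ch) / n
}

#' Sample the anticipated unpenalised-logistic posterior
#'
#' Draws coefficient vectors from `MVN(beta_ref, (n I)^{-1})`: the
#' anticipated posterior for an unpenalised logistic regression of size `n`
#' under flat priors, with the covariance decomposed into sample size and
#' unit information.
#'
#' @param beta_ref Reference coefficient vector (intercept first).
#' @param I A [unit_information()] matrix.
#' @param n Development sample size of interest.
#' @param n_draws Number of posterior draws (default 1000).
#' @param seed Integer seed.
#' @return Matrix of draws (`n_draws` rows), columns named as the basis.
#' @export
sample_unpenalized_posterior <- function(beta_ref, I, n, n_draws = 1000L,
                                         seed = NULL) {
  stopifnot(length(beta_ref) == nrow(I), is_count(n))
  Sigma <- ui_covariance(I, n)
  R <- chol(Sigma)
  if (!is.null(seed)) set.seed(seed)
  Z <- matrix(rnorm(n_draws * length(beta_ref)), n_draws)
  draws <- Z %*% R
  draws <- sweep(draws, 2, beta_ref, "+")
  colnames(draws) <- attr(I, "basis") %||% names(beta_ref)
  draws
}

#' Sample the shrinkage-prior posterior via the unit-information likelihood
#'
#' One-sample Bayesian approximation for penalised logistic regression: the
#' exact likelihood is replaced by `MVN(beta, (n I)^{-1})` evaluated at the
#' reference coefficients (the "data" is the reference coefficient vector),
#' combined with the ridge or lasso shrinkage priors of [prior_spec()] and
#' sampled by adaptive random-walk Metropolis--Hastings with the penalty on
#' the log scale.
#'
#' @param beta_ref Reference coefficient vector (intercept first).
#' @param I A [unit_information()] matrix.
#' @param n Development sample size of interest.
#' @param prior A [prior_spec()].
#' @param mcmc An [mcmc_config()]; defaults here to burn-in 10000,
#'   thinning 10, 1000 retained draws.
#' @param seed Integer seed.
#' @return Matrix of retained coefficient draws with attributes
#'   `accept_rate` and `lag1_autocorrelation` (a warning is issued when the
#'   latter exceeds 0.3).
#' @export
mh_shrinkage_posterior <- function(beta_ref, I, n, prior = prior_spec("ridge"),
                                   mcmc = mcmc_config(burn_in = 10000L),
                                   seed = NULL) {
  stopifnot(length(beta_ref) == nrow(I), is_count(n),
            inherits(prior, "prior_spec"), inherits(mcmc, "mcmc_config"))
  Sigma <- ui_covariance(I, n)
  k <- length(beta_ref)
  pscale <- sqrt(diag(Sigma)) / sqrt(k)
  init <- as.numeric(beta_ref)
  fixed <- !is.null(prior$fixed_lambda)
  if (!fixed) {
    init <- c(init, 0)
    pscale <- c(pscale, 0.3)
  }
  if (!is.null(seed)) set.seed(seed)
  res <- mh_shrinkage(matrix(0, 0, 0), integer(0),
                      as.numeric(beta_ref), unclass(I), as.double(n),
                      mode = 1L,
                      prior_family = if (prior$family == "ridge") 0L else 1L,
                      intercept_var = prior$intercept_var,
                      hyp_a = prior$hyper[1L], hyp_b = prior$hyper[2L],
                      fixed_lambda = fixed,
                      lambda_value = prior$fixed_lambda %||% 1,
                      burn_in = mcmc$burn_in, thin = mcmc$thin,
                      n_keep = mcmc$draws, init = init, prop_scale = pscale,
                      target_acc = mcmc$target_acceptance)
  draws <- res$draws
  colnames(draws) <- attr(I, "basis") %||% names(beta_ref)
  ac1 <- mean(vapply(seq_len(ncol(draws)), function(j) {
    x <- draws[, j]
    if (sd(x) < 1e-12) return(0)
    stats::cor(x[-1L], x[-length(x)])
  }, numeric(1)))
  if (is.finite(ac1) && ac1 > 0.3) {
    warning("retained-draw lag-1 autocorrelation ", round(ac1, 2),
            " exceeds 0.3; consider more thinning")
  }
  attr(draws, "accept_rate") <- res$accept_rate
  attr(draws, "lag1_autocorrelation") <- ac1
  draws
}

#' Run the unit-information approximation end to end
#'
#' The fast counterpart of [run_simulation()] for (penalised) logistic
#' regression: computes the unit information once from the case-mix, draws
#' coefficient vectors from the anticipated posterior at sample size `n`
#' (multivariate normal for unpenalised; Metropolis--Hastings with
#' shrinkage priors for Bayesian ridge/lasso), converts each draw to risk
#' predictions for the target population, and summarises the same
#' performance and degradation metrics as the full simulation. Output
#' matches the shape of [run_simulation()] so the same reporting applies.
#'
#' @param casemix A `casemix_sample` serving as both the averaging set for
#'   the unit information and the evaluation population.
#' @param ref A calibrated `reference_model`.
#' @param n Development sample size of interest.
#' @param prior `NULL` for the unpenalised (flat-prior) approximation, or a
#'   [prior_spec()] for Bayesian ridge/lasso.
#' @param n_draws Number of posterior draws (unpenalised mode).
#' @param mcmc An [mcmc_config()] (shrinkage mode; default burn-in 10000).
#' @param thresholds Risk threshold(s).
#' @param targets List of [assurance_target()]s.
#' @param seed Master seed.
#' @param n_instability Instability subsample size (as in the engine).
#' @return A `cpm_size_sim`-like object (class `cpm_size_approx`).
#' @export
run_approximation <- function(casemix, ref, n, prior = NULL,
                              n_draws = 1000L,
                              mcmc = mcmc_config(burn_in = 10000L),
                              thresholds = 0.5, targets = list(),
                              seed = 1L, n_instability = 1000L) {
  stopifnot(inherits(casemix, "casemix_sample"),
            inherits(ref, "reference_model"))
  X <- casemix$X[, ref$predictor_names, drop = FALSE]
  beta_ref <- ref_coefficients(ref)
  I <- unit_information(beta_ref, X)
  draws <- if (is.null(prior)) {
    sample_unpenalized_posterior(beta_ref, I, n, n_draws,
                                 seed = substream_seed(seed, "mvn"))
  } else {
    mh_shrinkage_posterior(beta_ref, I, n, prior, mcmc,
                           seed = substream_seed(seed, "mh"))
  }
  n_T <- nrow(X)
  p_pop <- true_risks(ref, X)
  y_pop <- simulate_outcomes(p_pop, substream_seed(seed, "outcomes"))
  truth <- truth_metrics(p_pop, y_pop, thresholds)

  n_inst <- min(n_instability, n_T)
  inst_idx <- with_seed(substream_seed(seed, "instability"),
                        sample.int(n_T, n_inst))
  S <- nrow(draws)
  pm <- matrix(NA_real_, n_inst, S)
  Xi <- cbind(1, X)
  rows <- vector("list", S)
  for (s in seq_len(S)) {
    phat <- as.numeric(plogis(Xi %*% draws[s, ]))
    rows[[s]] <- cbind(data.frame(replicate = s),
                       replicate_metrics(phat, p_pop, y_pop, truth,
                                         thresholds))
    pm[, s] <- phat[inst_idx]
  }
  replicates <- do.call(rbind, rows)
  replicates$strategy <- if (is.null(prior)) "approx_unpenalized" else
    paste0("approx_bayes_", prior$family)
  replicates$n <- n
  summ <- summarise_draws(replicates, targets)
  inst <- instability_summaries(pm)
  inst$p_true <- p_pop[inst_idx]
  inst$misclassification <- misclassification_probability(
    pm, p_pop[inst_idx], thresholds[1L])
  structure(list(replicates = replicates, summary = summ$metrics,
                 assurance = summ$assurance, prediction_matrix = pm,
                 instability_index = inst_idx, instability = inst,
                 truth = truth, reference = ref, draws = draws,
                 unit_information = I, failures = 0L,
                 config = list(n = n, n_draws = S, prior = prior,
                               thresholds = thresholds, seed = seed)),
            class = c("cpm_size_approx", "cpm_size_sim"))
}
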