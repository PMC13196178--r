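# Model-development strategies: each consumes a development dataset and
# returns a fitted CPM exposing risk predictions for new predictor rows.
# All regression strategies standardise predictors on the development sample
# (the scaling is stored, and folded into original-scale coefficients so that
# prediction is a single linear-predictor evaluation).

fit_scaling <- function(X) {
  center <- colMeans(X)
  scale <- apply(X, 2, sd)
  scale[scale < 1e-12] <- 1
  list(center = center, scale = scale)
}

# coefficients (a, b) on the standardised scale -> original scale
unscale_coef <- function(a, b, scaling) {
  b0 <- b / scaling$scale
  c(a - sum(scaling$center * b0), b0)
}

new_fitted_cpm <- function(subclass, strategy_name, details = list(),
                           scaling = NULL, flags = character()) {
  structure(list(strategy_name = strategy_name, details = details,
                 scaling = scaling, flags = flags),
            class = c(subclass, "fitted_cpm"))
}

#' Predict risks from a fitted CPM
#'
#' @param fit A `fitted_cpm` from one of the `fit_*` strategies.
#' @param X Predictor matrix with columns matching the development data.
#' @return Vector of risks in \[0, 1\].
#' @export
predict_risk <- function(fit, X) UseMethod("predict_risk")

#' @export
predict_risk.cpm_glm <- function(fit, X) {
  X <- as.matrix(X)
  cf <- fit$details$coef_original
  if (!is.null(colnames(X)) && !is.null(names(cf))) {
    nm <- names(cf)[-1L]
    if (all(nm %in% colnames(X))) X <- X[, nm, drop = FALSE]
  }
  as.numeric(plogis(cf[1L] + X %*% cf[-1L]))
}

#' @export
predict_risk.cpm_ranger <- function(fit, X) {
  df <- as.data.frame(X)
  colnames(df) <- fit$details$feature_names
  pr <- predict(fit$details$forest, data = df, num.threads = 1)$predictions
  as.numeric(pr[, "1"])
}

#' @export
predict_risk.cpm_xgb <- function(fit, X) {
  X <- as.matrix(X)
  colnames(X) <- fit$details$feature_names
  as.numeric(predict(fit$details$booster,
                     xgboost::xgb.DMatrix(X, nthread = 1)))
}

#' @export
predict_risk.cpm_oracle <- function(fit, X) {
  true_risks(fit$details$reference, X)
}

#' @export
print.fitted_cpm <- function(x, ...) {
  cat("<fitted_cpm>", x$strategy_name)
  if (length(x$flags)) cat("  [", paste(x$flags, collapse = ", "), "]")
  cat("\n")
  invisible(x)
}

check_dev <- function(dev) {
  stopifnot(is.list(dev), is.matrix(dev$X), length(dev$y) == nrow(dev$X))
  if (length(unique(dev$y)) < 2L) {
    stop("development outcome is constant; both classes must be present")
  }
}

# log-likelihood pieces for the likelihood-ratio chi-square
bernoulli_ll <- function(p, y) sum(y * log(p) + (1 - y) * log(1 - p))

#' Unpenalised maximum-likelihood logistic regression
#'
#' Fits a standard logistic model on standardised predictors. Fits with
#' detected separation (huge coefficients or non-convergence) are retained
#' and flagged rather than dropped, so that downstream instability summaries
#' reflect them.
#'
#' @param dev A `development_data` from [draw_development()].
#' @return A `fitted_cpm`.
#' @export
fit_logistic_mle <- function(dev) {
  check_dev(dev)
  scaling <- fit_scaling(dev$X)
  Z <- sweep(sweep(dev$X, 2, scaling$center), 2, scaling$scale, "/")
  f <- suppressWarnings(
    glm.fit(cbind(1, Z), dev$y, family = binomial())
  )
  cf <- f$coefficients
  flags <- character()
  if (anyNA(cf)) {  # rank-deficient design (e.g. constant predictor)
    cf[is.na(cf)] <- 0
    flags <- c(flags, "rank_deficient")
  }
  if (!f$converged) flags <- c(flags, "nonconverged")
  if (any(abs(cf[-1L]) > 10)) flags <- c(flags, "separation")
  P <- ncol(Z)
  null_dev <- -2 * bernoulli_ll(mean(dev$y), dev$y)
  lr_chisq <- null_dev - f$deviance
  coef_std <- stats::setNames(cf, c("(Intercept)", colnames(dev$X)))
  coef_orig <- stats::setNames(unscale_coef(cf[1L], cf[-1L], scaling),
                               c("(Intercept)", colnames(dev$X)))
  new_fitted_cpm("cpm_glm", "logistic_mle",
                 details = list(coef_std = coef_std,
                                coef_original = coef_orig,
                                lr_chisq = lr_chisq, P = P,
                                deviance = f$deviance),
                 scaling = scaling, flags = flags)
}

#' Logistic regression with heuristic uniform shrinkage
#'
#' Fits the unpenalised model, multiplies its slopes by the heuristic
#' shrinkage factor `S = (chi2_LR - P) / chi2_LR`, and re-estimates the
#' intercept by refitting an intercept-only logistic model with the shrunken
#' linear predictor as a fixed offset. When `S <= 0` (weak fits at small n)
#' the sign-flipped model is retained and flagged.
#'
#' @param dev A `development_data`.
#' @return A `fitted_cpm`; `details$S` holds the shrinkage factor.
#' @export
fit_logistic_uniform_shrinkage <- function(dev) {
  base <- fit_logistic_mle(dev)
  P <- base$details$P
  chi2 <- base$details$lr_chisq
  flags <- base$flags
  if (chi2 <= 0) {
    S <- 0
    flags <- c(flags, "zero_lr_chisq")
  } else {
    S <- (chi2 - P) / chi2
  }
  if (S <= 0 && chi2 > 0) flags <- c(flags, "nonpositive_shrinkage")
  scaling <- base$scaling
  Z <- sweep(sweep(dev$X, 2, scaling$center), 2, scaling$scale, "/")
  b_shrunk <- S * base$details$coef_std[-1L]
  off <- as.numeric(Z %*% b_shrunk)
  a <- logistic_newton(matrix(1, nrow(Z), 1), as.integer(dev$y), off)[1L]
  coef_std <- c("(Intercept)" = a, b_shrunk)
  coef_orig <- stats::setNames(unscale_coef(a, b_shrunk, scaling),
                               names(coef_std))
  new_fitted_cpm("cpm_glm", "logistic_uniform_shrinkage",
                 details = list(coef_std = coef_std,
                                coef_original = coef_orig,
                                S = S, lr_chisq = chi2, P = P,
                                reestimated_intercept = a),
                 scaling = scaling, flags = flags)
}

#' Penalised logistic regression tuned by cross-validation
#'
#' Ridge or lasso logistic regression with the penalty weight chosen by
#' minimising the cross-validated binomial deviance over a 100-value
#' log-spaced grid, then refitting on the full development data at the
#' chosen penalty. Folds are stratified by outcome; if a class has fewer
#' members than the requested folds, the fold count is reduced with a
#' warning.
#'
#' @param dev A `development_data`.
#' @param penalty `"ridge"` or `"lasso"`.
#' @param folds Number of cross-validation folds (default 10).
#' @param seed Integer seed for the fold assignment.
#' @param lambda Optional fixed penalty value, bypassing cross-validation.
#' @return A `fitted_cpm`; `details$lambda` records the chosen penalty.
#' @export
fit_penalized_cv <- function(dev, penalty = c("ridge", "lasso"), folds = 10L,
                             seed = NULL, lambda = NULL) {
  penalty <- match.arg(penalty)
  check_dev(dev)
  alpha <- if (penalty == "ridge") 0 else 1
  scaling <- fit_scaling(dev$X)
  Z <- sweep(sweep(dev$X, 2, scaling$center), 2, scaling$scale, "/")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(lambda)) {
    cls_min <- min(table(dev$y))
    if (cls_min < folds) {
      folds <- max(2L, as.integer(cls_min))
      warning("reduced cross-validation folds to ", folds,
              " (minority class too small for stratified folds)")
    }
    foldid <- integer(length(dev$y))
    for (cls in c(0L, 1L)) {
      idx <- which(dev$y == cls)
      foldid[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
    cv <- glmnet::cv.glmnet(Z, dev$y, family = "binomial", alpha = alpha,
                            foldid = foldid, type.measure = "deviance",
                            standardize = FALSE, nlambda = 100,
                            lambda.min.ratio = 1e-6)
    lambda_hat <- cv$lambda.min
    fit <- cv$glmnet.fit
  } else {
    lambda_hat <- lambda
    fit <- glmnet::glmnet(Z, dev$y, family = "binomial", alpha = alpha,
                          lambda = lambda, standardize = FALSE)
  }
  cf <- as.numeric(coef(fit, s = lambda_hat, exact = FALSE))
  flags <- character()
  if (all(abs(cf[-1L]) < 1e-10)) flags <- "all_slopes_zero"
  coef_std <- stats::setNames(cf, c("(Intercept)", colnames(dev$X)))
  coef_orig <- stats::setNames(unscale_coef(cf[1L], cf[-1L], scaling),
                               names(coef_std))
  new_fitted_cpm("cpm_glm", paste0(penalty, "_cv"),
                 details = list(coef_std = coef_std,
                                coef_original = coef_orig,
                                lambda = lambda_hat, penalty = penalty),
                 scaling = scaling, flags = flags)
}

#' Prior specification for Bayesian shrinkage
#'
#' Priors mirroring ridge and lasso penalties: a vague normal prior on the
#' intercept, and for the slopes either `N(0, lambda^2)` (ridge, with an
#' inverse-gamma hyperprior on `lambda^2`) or `Laplace(0, 1/lambda)` (lasso,
#' with a gamma hyperprior on `lambda^2`, shape--scale convention so
#' `gamma(1, 1/1.78)` has rate 1.78). Larger lasso `lambda` means stronger
#' shrinkage; for ridge, `lambda^2` is the prior slope variance.
#'
#' @param family `"ridge"` or `"lasso"`.
#' @param intercept_var Intercept prior variance (default 1e6).
#' @param hyper Hyperprior parameters: ridge `c(shape, rate)` of the
#'   inverse-gamma (default `c(0.01, 0.01)`; shape--rate convention);
#'   lasso `c(shape, rate)` of the gamma (default `c(1, 1.78)`).
#' @param fixed_lambda Optional fixed `lambda`, disabling the hyperprior.
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(family = c("ridge", "lasso"), intercept_var = 1e6,
                       hyper = NULL, fixed_lambda = NULL) {
  family <- match.arg(family)
  if (is.null(hyper)) {
    hyper <- if (family == "ridge") c(0.01, 0.01) else c(1, 1.78)
  }
  stopifnot(length(hyper) == 2L, all(hyper > 0), intercept_var > 0)
  if (!is.null(fixed_lambda)) stopifnot(fixed_lambda > 0)
  structure(list(family = family, intercept_var = intercept_var,
                 hyper = hyper, fixed_lambda = fixed_lambda),
            class = "prior_spec")
}

#' MCMC configuration
#'
#' @param burn_in Burn-in iterations (default 5000, the full-simulation
#'   setting; the unit-information approximation defaults to 10000).
#' @param thin Thinning interval (default 10: every 10th draw retained).
#' @param draws Number of retained draws (default 1000).
#' @param target_acceptance Target acceptance rate for proposal adaptation.
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(burn_in = 5000L, thin = 10L, draws = 1000L,
                        target_acceptance = 0.25) {
  stopifnot(burn_in >= 0, thin >= 1, draws >= 1,
            target_acceptance > 0, target_acceptance < 1)
  structure(list(burn_in = as.integer(burn_in), thin = as.integer(thin),
                 draws = as.integer(draws),
                 target_acceptance = target_acceptance),
            class = "mcmc_config")
}

#' Bayesian penalised logistic regression via Metropolis--Hastings
#'
#' Samples the posterior of the logistic coefficients under the exact
#' Bernoulli likelihood and the shrinkage priors of [prior_spec()], using an
#' adaptive random-walk Metropolis--Hastings sampler (penalty sampled on the
#' log scale; proposal scale adapted during burn-in only). The fitted CPM's
#' point predictions use the posterior-mean coefficients by default.
#'
#' @param dev A `development_data`.
#' @param prior A `prior_spec` (default Bayesian ridge).
#' @param mcmc An `mcmc_config`.
#' @param seed Integer seed; same seed gives identical retained draws.
#' @param point `"beta_mean"` (default) or `"risk_mean"`: whether point
#'   predictions come from the posterior-mean coefficients or from averaging
#'   per-draw risks.
#' @return A `fitted_cpm`; `details$draws` holds the retained coefficient
#'   draws on the standardised scale.
#' @export
fit_bayes_penalized <- function(dev, prior = prior_spec("ridge"),
                                mcmc = mcmc_config(), seed = NULL,
                                point = c("beta_mean", "risk_mean")) {
  point <- match.arg(point)
  check_dev(dev)
  stopifnot(inherits(prior, "prior_spec"), inherits(mcmc, "mcmc_config"))
  scaling <- fit_scaling(dev$X)
  Z <- sweep(sweep(dev$X, 2, scaling$center), 2, scaling$scale, "/")
  Xd <- cbind(1, Z)
  k <- ncol(Xd)
  init_fit <- suppressWarnings(glm.fit(Xd, dev$y, family = binomial()))
  init <- init_fit$coefficients
  init[!is.finite(init)] <- 0
  init <- pmin(pmax(init, -5), 5)
  # rough per-coordinate proposal scales from the inverse information
  w <- init_fit$weights
  info <- crossprod(Xd * sqrt(pmax(w, 1e-8)))
  pscale <- sqrt(diag(tryCatch(chol2inv(chol(info)),
                               error = function(e) diag(k))))
  pscale <- pscale / sqrt(k)  # joint updates: shrink per-coordinate steps
  fixed <- !is.null(prior$fixed_lambda)
  if (!fixed) {
    init <- c(init, 0)       # log lambda^2 starts at 0
    pscale <- c(pscale, 0.3)
  }
  if (!is.null(seed)) set.seed(seed)
  res <- mh_shrinkage(Xd, as.integer(dev$y),
                      numeric(0), matrix(0, 0, 0), 0,
                      mode = 0L,
                      prior_family = if (prior$family == "ridge") 0L else 1L,
                      intercept_var = prior$intercept_var,
                      hyp_a = prior$hyper[1L], hyp_b = prior$hyper[2L],
                      fixed_lambda = fixed,
                      lambda_value = prior$fixed_lambda %||% 1,
                      burn_in = mcmc$burn_in, thin = mcmc$thin,
                      n_keep = mcmc$draws, init = init, prop_scale = pscale,
                      target_acc = mcmc$target_acceptance)
  draws <- res$draws
  colnames(draws) <- c("(Intercept)", colnames(dev$X))
  flags <- character()
  if (is.finite(res$accept_rate) &&
      (res$accept_rate < 0.05 || res$accept_rate > 0.8)) {
    flags <- "acceptance_rate_out_of_range"
    warning("MH acceptance rate ", round(res$accept_rate, 3),
            " outside (0.05, 0.8) after adaptation")
  }
  cf <- colMeans(draws)
  coef_orig <- stats::setNames(unscale_coef(cf[1L], cf[-1L], scaling),
                               names(cf))
  fit <- new_fitted_cpm("cpm_glm", paste0("bayes_", prior$family),
                        details = list(coef_std = cf,
                                       coef_original = coef_orig,
                                       draws = draws,
                                       accept_rate = res$accept_rate,
                                       prior = prior, point = point),
                        scaling = scaling, flags = flags)
  if (point == "risk_mean") class(fit) <- c("cpm_bayes_risk", class(fit))
  fit
}

#' @export
predict_risk.cpm_bayes_risk <- function(fit, X) {
  X <- as.matrix(X)
  Z <- sweep(sweep(X, 2, fit$scaling$center), 2, fit$scaling$scale, "/")
  lp <- cbind(1, Z) %*% t(fit$details$draws)
  as.numeric(rowMeans(plogis(lp)))
}

#' Random forest strategy
#'
#' Probability forest: predictions are the mean of per-tree leaf class
#' proportions.
#'
#' @param dev A `development_data`.
#' @param n_trees Number of trees (default 100).
#' @param max_depth Maximum tree depth (default 3; the contrasting
#'   high-variance setting uses 15).
#' @param seed Integer seed.
#' @return A `fitted_cpm`.
#' @export
fit_random_forest <- function(dev, n_trees = 100L, max_depth = 3L,
                              seed = NULL) {
  check_dev(dev)
  df <- as.data.frame(dev$X)
  feat <- colnames(df)
  df$.y <- factor(dev$y, levels = c("0", "1"))
  rf <- ranger::ranger(
    dependent.variable.name = ".y", data = df, probability = TRUE,
    num.trees = n_trees, max.depth = max_depth,
    seed = seed %||% sample.int(1e6, 1), num.threads = 1
  )
  new_fitted_cpm("cpm_ranger", sprintf("random_forest_d%d", max_depth),
                 details = list(forest = rf, feature_names = feat,
                                n_trees = n_trees, max_depth = max_depth))
}

#' Gradient boosting strategy
#'
#' Gradient-boosted decision trees with logistic loss.
#'
#' @param dev A `development_data`.
#' @param n_trees Number of boosting rounds (default 100).
#' @param max_depth Maximum tree depth (default 15).
#' @param learning_rate Shrinkage per round (default 0.1; recorded in the
#'   fit metadata).
#' @param seed Integer seed.
#' @return A `fitted_cpm`.
#' @export
fit_gradient_boosting <- function(dev, n_trees = 100L, max_depth = 15L,
                                  learning_rate = 0.1, seed = NULL) {
  check_dev(dev)
  X <- as.matrix(dev$X)
  if (!is.null(seed)) set.seed(seed)
  dtrain <- xgboost::xgb.DMatrix(X, label = dev$y, nthread = 1)
  bst <- xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = max_depth,
                  eta = learning_rate, nthread = 1,
                  seed = seed %||% sample.int(1e6, 1)),
    data = dtrain, nrounds = n_trees, verbose = 0
  )
  new_fitted_cpm("cpm_xgb", "gradient_boosting",
                 details = list(booster = bst, feature_names = colnames(X),
                                n_trees = n_trees, max_depth = max_depth,
                                learning_rate = learning_rate))
}

#' Oracle strategy (test harness)
#'
#' A strategy that returns the reference model itself, so every degradation
#' metric should be zero up to evaluation noise. Useful for validating the
#' engine and metrics.
#'
#' @param ref A `reference_model`.
#' @return A `fitted_cpm` whose predictions reproduce the true risks.
#' @export
oracle_strategy <- function(ref) {
  stopifnot(inherits(ref, "reference_model"))
  new_fitted_cpm("cpm_oracle", "oracle", details = list(reference = ref))
}

#' Describe a model-development strategy for the simulation engine
#'
#' @param name One of `"logistic_mle"`, `"logistic_uniform_shrinkage"`,
#'   `"ridge_cv"`, `"lasso_cv"`, `"bayes_ridge"`, `"bayes_lasso"`,
#'   `"random_forest"`, `"gradient_boosting"`, `"oracle"`.
#' @param ... Strategy-specific arguments (e.g. `folds`, `n_trees`,
#'   `max_depth`, `prior`, `mcmc`, `learning_rate`).
#' @return An object of class `strategy_spec`.
#' @export
strategy_spec <- function(name, ...) {
  known <- c("logistic_mle", "logistic_uniform_shrinkage", "ridge_cv",
             "lasso_cv", "bayes_ridge", "bayes_lasso", "random_forest",
             "gradient_boosting", "oracle")
  if (!name %in% known) {
    stop("unknown strategy '", name, "'; available: ",
         paste(known, collapse = ", "))
  }
  structure(list(name = name, args = list(...)), class = "strategy_spec")
}

# fit a strategy_spec on a development dataset; `ref` is only consulted by
# the oracle strategy, `seed` by strategies with internal randomness
fit_strategy <- function(spec, dev, seed = NULL, ref = NULL) {
  stopifnot(inherits(spec, "strategy_spec"))
  a <- spec$args
  switch(spec$name,
    logistic_mle = fit_logistic_mle(dev),
    logistic_uniform_shrinkage = fit_logistic_uniform_shrinkage(dev),
    ridge_cv = do.call(fit_penalized_cv,
                       c(list(dev = dev, penalty = "ridge", seed = seed), a)),
    lasso_cv = do.call(fit_penalized_cv,
                       c(list(dev = dev, penalty = "lasso", seed = seed), a)),
    bayes_ridge = do.call(fit_bayes_penalized,
                          c(list(dev = dev,
                                 prior = a$prior %||% prior_spec("ridge"),
                                 mcmc = a$mcmc %||% mcmc_config(),
                                 seed = seed),
                            a[setdiff(names(a), c("prior", "mcmc"))])),
    bayes_lasso = do.call(fit_bayes_penalized,
                          c(list(dev = dev,
                                 prior = a$prior %||% prior_spec("lasso"),
                                 mcmc = a$mcmc %||% mcmc_config(),
                                 seed = seed),
                            a[setdiff(names(a), c("prior", "mcmc"))])),
    random_forest = do.call(fit_random_forest,
                            c(list(dev = dev, seed = seed), a)),
    gradient_boosting = do.call(fit_gradient_boosting,
                                c(list(dev = dev, seed = seed), a)),
    oracle = {
      if (is.null(ref)) stop("oracle strategy needs the reference model")
      oracle_strategy(ref)
    }
  )
}
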