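test_that("maximum-likelihood logistic recovers known coefficients", {
  fx <- small_dev(n = 50000, seed = 31)
  fit <- fit_logistic_mle(fx$dev)
  # compare on the original scale against the generating model, within
  # 3 standard errors (from a direct glm refit as the oracle)
  g <- glm(fx$dev$y ~ fx$dev$X, family = binomial())
  se <- summary(g)$coefficients[, 2]
  truth <- c(fx$ref$alpha, fx$ref$beta)
  expect_true(all(abs(fit$details$coef_original - truth) < 3 * se))
  # identical predictions to the oracle refit
  expect_equal(predict_risk(fit, fx$dev$X),
               unname(fitted(g)), tolerance = 1e-6)
})

test_that("degenerate development data is handled explicitly", {
  fx <- small_dev(n = 200, seed = 32)
  dev0 <- fx$dev
  dev0$X[] <- 0  # no usable predictors -> intercept-only fit, flagged
  fit <- fit_logistic_mle(dev0)
  expect_true("rank_deficient" %in% fit$flags)
  expect_equal(unname(fit$details$coef_original[1]), qlogis(mean(dev0$y)),
               tolerance = 1e-6)
  expect_equal(predict_risk(fit, dev0$X), rep(mean(dev0$y), 200),
               tolerance = 1e-6)

  dev1 <- fx$dev
  dev1$y <- rep(1L, dev1$n)
  expect_error(fit_logistic_mle(dev1), "constant")
})

test_that("uniform shrinkage applies the heuristic factor", {
  fx <- small_dev(n = 5000, seed = 33)
  mle <- fit_logistic_mle(fx$dev)
  fit <- fit_logistic_uniform_shrinkage(fx$dev)
  S <- fit$details$S
  expect_equal(S, (mle$details$lr_chisq - 3) / mle$details$lr_chisq)
  expect_equal(unname(fit$details$coef_std[-1]),
               unname(S * mle$details$coef_std[-1]))
  # large n: S close to 1 and coefficients close to the MLE
  expect_gt(S, 0.98)
  expect_lt(max(abs(fit$details$coef_original - mle$details$coef_original)),
            0.05)
})

test_that("weak fits can yield nonpositive shrinkage, retained and flagged", {
  # pure-noise predictors at small n keep the LR chi-square below P
  spec <- casemix_spec_normal(10)
  ref <- reference_model(0.3, rep(0, 10),
                         predictor_names = paste0("x", 1:10))
  found <- FALSE
  for (s in 1:10) {
    dev <- draw_development(spec, ref, 60, seed = 300 + s)
    mle <- try(fit_logistic_mle(dev), silent = TRUE)
    if (inherits(mle, "try-error")) next
    if (mle$details$lr_chisq < 10 && mle$details$lr_chisq > 0) {
      fit <- fit_logistic_uniform_shrinkage(dev)
      expect_lte(fit$details$S, 0)
      expect_true("nonpositive_shrinkage" %in% fit$flags)
      found <- TRUE
      break
    }
  }
  expect_true(found)
})

test_that("penalised regression shrinks fully and recovers the MLE limit", {
  fx <- small_dev(n = 800, seed = 34)
  # huge fixed lasso penalty: intercept-only model
  full <- fit_penalized_cv(fx$dev, "lasso", lambda = 100)
  expect_true(all(abs(full$details$coef_std[-1]) < 1e-10))
  expect_equal(unname(full$details$coef_std[1]), qlogis(mean(fx$dev$y)),
               tolerance = 1e-4)
  expect_equal(var(predict_risk(full, fx$dev$X)), 0, tolerance = 1e-12)
  expect_true("all_slopes_zero" %in% full$flags)

  # vanishing penalty: matches the unpenalised fit
  mle <- fit_logistic_mle(fx$dev)
  none <- fit_penalized_cv(fx$dev, "ridge", lambda = 1e-8)
  expect_lt(max(abs(none$details$coef_std - mle$details$coef_std)), 1e-4)

  # fold assignment and tuned lambda are seed-reproducible
  f1 <- fit_penalized_cv(fx$dev, "lasso", seed = 35)
  f2 <- fit_penalized_cv(fx$dev, "lasso", seed = 35)
  expect_identical(f1$details$lambda, f2$details$lambda)
  expect_identical(f1$details$coef_std, f2$details$coef_std)
})

test_that("Bayesian shrinkage matches the MLE under flat priors", {
  fx <- small_dev(n = 4000, seed = 36)
  mle <- fit_logistic_mle(fx$dev)
  flat <- fit_bayes_penalized(fx$dev, prior_spec("ridge", fixed_lambda = 1e6),
                              mcmc_config(burn_in = 4000, thin = 5,
                                          draws = 800), seed = 37)
  # posterior-mean coefficients within 3 Monte Carlo standard errors
  # (inflated for autocorrelation) of the MLE
  mcse <- apply(flat$details$draws, 2, sd) / sqrt(800 / 5)
  expect_true(all(abs(flat$details$coef_std - mle$details$coef_std)
                  < 3 * mcse + 0.02))

  strong <- fit_bayes_penalized(fx$dev,
                                prior_spec("ridge", fixed_lambda = 0.01),
                                mcmc_config(burn_in = 3000, thin = 5,
                                            draws = 500), seed = 38)
  expect_true(all(abs(strong$details$coef_std[-1])
                  < abs(mle$details$coef_std[-1])))

  r1 <- fit_bayes_penalized(fx$dev, prior_spec("lasso"),
                            mcmc_config(burn_in = 500, thin = 2,
                                        draws = 100), seed = 39)
  r2 <- fit_bayes_penalized(fx$dev, prior_spec("lasso"),
                            mcmc_config(burn_in = 500, thin = 2,
                                        draws = 100), seed = 39)
  expect_identical(r1$details$draws, r2$details$draws)
})

test_that("tree ensembles emit valid, seeded probability predictions", {
  fx <- small_dev(n = 1000, seed = 40)
  eval_X <- generate_casemix(fx$spec, 3000, seed = 41)$X

  rf <- fit_random_forest(fx$dev, max_depth = 3, seed = 42)
  pr <- predict_risk(rf, eval_X)
  expect_true(all(pr >= 0 & pr <= 1))
  rf2 <- fit_random_forest(fx$dev, max_depth = 3, seed = 42)
  expect_identical(pr, predict_risk(rf2, eval_X))

  gb <- fit_gradient_boosting(fx$dev, seed = 43)
  pg <- predict_risk(gb, eval_X)
  expect_true(all(pg >= 0 & pg <= 1))

  # null-signal oracle: with pure-noise predictors an independent
  # evaluation set shows no discrimination and boosting predictions
  # concentrate around the outcome rate
  spec <- casemix_spec_normal(4)
  ref0 <- reference_model(qlogis(0.4), rep(0, 4),
                          predictor_names = paste0("x", 1:4))
  dev0 <- draw_development(spec, ref0, 1500, seed = 44)
  ev <- draw_development(spec, ref0, 4000, seed = 45)
  rf0 <- fit_random_forest(dev0, max_depth = 3, seed = 46)
  expect_lt(abs(c_statistic(predict_risk(rf0, ev$X), ev$y) - 0.5), 0.06)
  gb0 <- fit_gradient_boosting(dev0, seed = 47)
  expect_lt(abs(mean(predict_risk(gb0, ev$X)) - mean(dev0$y)), 0.1)
})

test_that("the oracle strategy reproduces the reference model exactly", {
  fx <- small_dev(n = 500, seed = 48)
  fit <- oracle_strategy(fx$ref)
  X <- generate_casemix(fx$spec, 1000, seed = 49)$X
  expect_identical(predict_risk(fit, X), true_risks(fx$ref, X))
})

test_that("predictions are invariant to pre-standardising the inputs", {
  fx <- small_dev(n = 1500, seed = 50)
  fit_raw <- fit_logistic_mle(fx$dev)
  devz <- fx$dev
  devz$X <- scale(fx$dev$X)
  attr(devz$X, "scaled:center") <- NULL
  attr(devz$X, "scaled:scale") <- NULL
  fit_std <- fit_logistic_mle(devz)
  expect_equal(predict_risk(fit_raw, fx$dev$X),
               predict_risk(fit_std, devz$X), tolerance = 1e-8)
})

test_that("the strategy registry dispatches by name and validates it", {
  fx <- small_dev(n = 800, seed = 51)
  fit <- fit_strategy(strategy_spec("logistic_mle"), fx$dev)
  expect_s3_class(fit, "fitted_cpm")
  fit2 <- fit_strategy(strategy_spec("random_forest", max_depth = 3,
                                     n_trees = 20), fx$dev, seed = 52)
  expect_equal(fit2$details$n_trees, 20)
  expect_error(strategy_spec("neural_net"), "unknown strategy")
  expect_error(fit_strategy(strategy_spec("oracle"), fx$dev),
               "reference model")
})
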