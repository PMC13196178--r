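test_that("c-statistic matches the brute-force pair count", {
  expect_equal(c_statistic(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0)), 1)
  expect_equal(c_statistic(rep(0.4, 10), rep(c(0, 1), 5)), 0.5)
  expect_error(c_statistic(runif(5), rep(1, 5)), "one outcome class")
  for (s in 1:5) {
    set.seed(s)
    phat <- round(runif(20), 2)  # rounding forces some ties
    y <- rbinom(20, 1, 0.5)
    if (length(unique(y)) < 2) next
    expect_equal(c_statistic(phat, y), cstat_bruteforce(phat, y),
                 tolerance = 1e-12)
  }
})

test_that("calibration slope and intercept behave as constructed", {
  set.seed(61)
  q <- plogis(rnorm(3e4, -0.5, 1.5))
  y <- rbinom(3e4, 1, q)

  self <- calibration(q, y)
  expect_lt(abs(self$slope - 1), 0.05)
  expect_lt(abs(self$intercept), 0.05)

  # predictions built from half the true logit have slope ~ 2, and the
  # fast fit agrees with a direct glm refit
  half <- plogis(0.5 * qlogis(q))
  cal <- calibration(half, y)
  g <- glm(y ~ qlogis(half), family = binomial())
  expect_equal(cal$slope, unname(coef(g)[2]), tolerance = 1e-6)
  expect_lt(abs(cal$slope - 2), 0.15)

  const <- calibration(rep(0.3, 1000), rbinom(1000, 1, 0.3))
  expect_equal(const$slope, 0)
  expect_true("constant_predictions" %in% const$flags)

  crv <- calibration(q, y, curve = TRUE)$curve
  expect_equal(nrow(crv), 100)
  expect_true(all(crv$observed >= 0 & crv$observed <= 1))
})

test_that("prediction error matches hand arithmetic and its inequality", {
  expect_equal(prediction_error(c(0.5, 0.5), c(0.5, 0.5)),
               list(mape = 0, rmspe = 0))
  pe <- prediction_error(c(0.2, 0.6), c(0.1, 0.8))
  expect_equal(pe$mape, 0.15)
  expect_equal(pe$rmspe, sqrt(0.025))
  for (s in 1:10) {
    set.seed(s)
    pe <- prediction_error(runif(50), runif(50))
    expect_gte(pe$rmspe, pe$mape)
  }
  expect_error(prediction_error(runif(3), runif(4)), "equal length")
})

test_that("net benefit matches its defining 2x2 arithmetic", {
  # treat-all at prevalence 0.68 and threshold 0.5
  expect_equal(nb_treat_all(0.68, 0.5), 0.36)
  y <- rep(c(1, 0), c(68, 32))
  expect_equal(net_benefit(rep(1, 100), y, 0.5), 0.36)
  expect_equal(net_benefit(rep(0, 100), y, 0.5), 0)
  # TP = 30, FP = 10, n = 100 at t = 0.2
  phat <- c(rep(0.9, 40), rep(0.05, 60))
  y2 <- c(rep(1, 30), rep(0, 10), rep(1, 20), rep(0, 40))
  expect_equal(net_benefit(phat, y2, 0.2), 30 / 100 - 10 / 100 * 0.25)
  expect_error(net_benefit(phat, y2, 1.2), "threshold")
})

test_that("value of sample information follows its identities", {
  expect_equal(value_of_information(0.41, 0.41)$rvsi, 100)
  expect_equal(value_of_information(0.41, 0.41)$degradation, 0)
  expect_equal(value_of_information(0.36, 0.41)$rvsi, 100 * 36 / 41)
  expect_equal(value_of_information(0, 0.41)$rvsi, 0)
  voi <- value_of_information(0.1, -0.01)
  expect_true(is.na(voi$rvsi))
  expect_true("nb_max_nonpositive" %in% voi$flags)
})

test_that("the winner strategy is selected in the development sample", {
  fx <- small_dev(n = 400, seed = 62)
  pop <- draw_development(fx$spec, fx$ref, 5000, seed = 63)

  # a degenerate model predicting 0 for everyone loses to treat-all when
  # the development prevalence exceeds the threshold odds
  zero_fit <- structure(
    list(strategy_name = "zero",
         details = list(coef_original = c(-50, rep(0, 3))),
         scaling = NULL, flags = character()),
    class = c("cpm_glm", "fitted_cpm")
  )
  w <- winner_net_benefit(zero_fit, fx$dev,
                          predict_risk(zero_fit, pop$X), pop$y, 0.3)
  expect_equal(w$winner, "treat_all")
  expect_equal(w$nb, nb_treat_all(pop$y, 0.3))

  oracle <- oracle_strategy(fx$ref)
  w2 <- winner_net_benefit(oracle, fx$dev,
                           predict_risk(oracle, pop$X), pop$y, 0.3)
  expect_equal(w2$winner, "model")
})

test_that("misclassification probabilities count opposite-side draws", {
  truth <- c(0.7, 0.2)
  vals <- rbind(c(rep(0.9, 13), rep(0.1, 7)),   # 7 of 20 opposite
                rep(0.1, 20))                    # all on the true side
  out <- misclassification_probability(vals, truth, 0.5)
  expect_equal(out, c(7 / 20, 0))
  # a draw exactly at the threshold counts as "at or above"
  expect_equal(misclassification_probability(matrix(0.5), 0.5, 0.5), 0)
})

test_that("instability summaries match order-statistics expectations", {
  z <- matrix(0.4, 3, 50)
  s <- instability_summaries(z)
  expect_equal(s$width, rep(0, 3))
  expect_true(all(s$ess_capped))

  set.seed(64)
  u <- matrix(runif(2e4, 0.25, 0.75), 1)
  su <- instability_summaries(u)
  expect_lt(abs(su$width - 0.95 * 0.5), 0.01)
  expect_false(su$ess_capped)

  m <- matrix(runif(200), 10, 20)
  expect_true(all(instability_summaries(m)$width >= 0))
})

test_that("R-squared measures derive from the Bernoulli likelihoods", {
  y <- c(1, 1, 0, 1, 0, 0, 1, 1)
  expect_equal(r2_measures(rep(mean(y), 8), y)$r2_cs, 0, tolerance = 1e-12)

  phat <- c(0.9, 0.8, 0.3, 0.6, 0.2, 0.4, 0.7, 0.5)
  ll1 <- sum(y * log(phat) + (1 - y) * log(1 - phat))
  ll0 <- sum(y * log(mean(y)) + (1 - y) * log(1 - mean(y)))
  r2 <- r2_measures(phat, y)
  expect_equal(r2$r2_cs, 1 - exp(2 * (ll0 - ll1) / 8))
  expect_equal(r2$r2_nagelkerke, r2$r2_cs / (1 - exp(2 * ll0 / 8)))
  expect_gte(r2$r2_nagelkerke, 0)
  expect_lte(r2$r2_nagelkerke, 1)
})

test_that("subgroup metrics partition and flag degenerate groups", {
  set.seed(65)
  n <- 2000
  p <- plogis(rnorm(n))
  phat <- plogis(qlogis(p) + rnorm(n, 0, 0.2))
  y <- rbinom(n, 1, p)

  one <- subgroup_metrics(phat, p, y, rep("all", n))
  overall <- replicate_metrics(phat, p, y)
  expect_equal(one$c, overall$c)
  expect_equal(one$mape, overall$mape)

  # two identical half-populations give equal per-group metrics
  idx <- rep(1:2, each = n / 2)
  two <- subgroup_metrics(rep(phat, 2), rep(p, 2), rep(y, 2),
                          rep(c("a", "b"), each = n))
  expect_equal(two$c[1], two$c[2])
  expect_equal(two$cal_slope[1], two$cal_slope[2])

  # a one-class group yields a flagged partial row, not an error
  g <- c(rep("main", n - 5), rep("tiny", 5))
  y2 <- y
  y2[(n - 4):n] <- 1
  res <- subgroup_metrics(phat, p, y2, g)
  expect_true(grepl("partial", res$flags[res$group == "tiny"]))
  expect_false(is.na(res$mape[res$group == "tiny"]))

  # an empty group label is an error
  gf <- factor(g, levels = c("main", "tiny", "absent"))
  expect_error(subgroup_metrics(phat, p, y, gf), "empty subgroup")
})
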