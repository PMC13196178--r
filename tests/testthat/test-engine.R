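engine_cfg <- function(strategy = strategy_spec("logistic_mle"), n = 200,
                       n_sims = 4, pop = 5000, seed = 71, ...) {
  fx <- small_calibrated()
  simulation_config(fx$spec, fx$ref, strategy, n = n, n_sims = n_sims,
                    population_size = pop, seed = seed, ...)
}

test_that("a smoke run produces aligned replicate tables and draws", {
  cfg <- engine_cfg(n_sims = 2)
  res <- run_simulation(cfg)
  expect_equal(nrow(res$replicates), 2)
  expect_equal(ncol(res$prediction_matrix), 2)
  expect_equal(nrow(res$prediction_matrix), cfg$n_instability)
  expect_true(all(c("c", "cal_slope", "mape", "rmspe", "nb", "rvsi",
                    "c_deg", "slope_deg", "nb_deg", "nb_winner")
                  %in% colnames(res$replicates)))
})

test_that("the oracle strategy shows no degradation and full assurance", {
  cfg <- engine_cfg(strategy_spec("oracle"), n_sims = 3, pop = 20000,
                    targets = list(assurance_target("cal_slope", 0.9, 1.1)))
  res <- run_simulation(cfg)
  expect_lt(max(abs(res$replicates$c_deg)), 0.01)
  expect_lt(max(abs(res$replicates$slope_deg)), 0.1)
  expect_lt(max(res$replicates$mape), 1e-12)
  expect_equal(res$assurance$probability, 1)
  expect_equal(max(res$instability$misclassification), 0)
})

test_that("runs are bit-identical under the same master seed", {
  r1 <- run_simulation(engine_cfg(n_sims = 3))
  r2 <- run_simulation(engine_cfg(n_sims = 3))
  expect_identical(r1$replicates, r2$replicates)
  expect_identical(r1$prediction_matrix, r2$prediction_matrix)
})

test_that("degradation and instability decrease with sample size", {
  fx <- small_calibrated()
  means <- lapply(c(75, 456), function(n) {
    cfg <- simulation_config(fx$spec, fx$ref, strategy_spec("logistic_mle"),
                             n = n, n_sims = 40, population_size = 2e4,
                             seed = 72)
    r <- run_simulation(cfg)$replicates
    list(mape = mean(r$mape), mcse_mape = sd(r$mape) / sqrt(40),
         absdev = mean(abs(r$cal_slope - 1)),
         width = mean(r$rmspe))
  })
  expect_lt(means[[2]]$mape,
            means[[1]]$mape + 2 * means[[1]]$mcse_mape)
  expect_lt(means[[2]]$absdev, means[[1]]$absdev)
})

test_that("failed replicates are flagged and excessive failure aborts", {
  fx <- small_calibrated()
  # two-individual development samples are usually one-class, so the
  # strategy fails in well over 20% of replicates
  cfg <- simulation_config(fx$spec, fx$ref, strategy_spec("logistic_mle"),
                           n = 2, n_sims = 5, population_size = 2000,
                           seed = 73)
  expect_error(run_simulation(cfg), "20%")
})

test_that("a one-component mixture reproduces the single-model run", {
  fx <- small_calibrated()
  single <- simulation_config(fx$spec, fx$ref, strategy_spec("logistic_mle"),
                              n = 150, n_sims = 3, population_size = 5000,
                              seed = 74)
  mix <- simulation_config(fx$spec, reference_mixture(list(fx$ref), 1),
                           strategy_spec("logistic_mle"),
                           n = 150, n_sims = 3, population_size = 5000,
                           seed = 74)
  expect_identical(run_simulation(single)$replicates,
                   run_simulation(mix)$replicates)
})

test_that("mixture runs draw truth per replicate", {
  fx <- small_calibrated()
  m2 <- fx$ref
  m2$delta <- fx$ref$delta * 1.5
  mix <- reference_mixture(list(fx$ref, m2), c(0.5, 0.5))
  cfg <- simulation_config(fx$spec, mix, strategy_spec("oracle"),
                           n = 100, n_sims = 10, population_size = 3000,
                           seed = 75)
  res <- run_simulation(cfg)
  expect_true(all(res$replicates$reference_index %in% 1:2))
  expect_gt(length(unique(res$replicates$reference_index)), 1)
  # the oracle tracks whichever model was drawn, so degradation stays ~ 0
  expect_lt(max(res$replicates$mape), 1e-12)
})

test_that("posterior summaries follow order-statistics expectations", {
  const <- summarise_draws(rep(3.2, 100))
  expect_equal(const$metrics$mean, 3.2)
  expect_equal(const$metrics$q97.5 - const$metrics$q2.5, 0)

  set.seed(76)
  u <- summarise_draws(runif(2e4))
  expect_lt(abs(u$metrics$q2.5 - 0.025), 0.01)
  expect_lt(abs(u$metrics$q97.5 - 0.975), 0.01)

  one <- summarise_draws(5)
  expect_true(is.na(one$metrics$mcse))

  tg <- summarise_draws(data.frame(cal_slope = c(0.95, 1.0, 1.3)),
                        list(assurance_target("cal_slope", 0.9, 1.1)))
  expect_equal(tg$assurance$probability, 2 / 3)
  expect_error(
    summarise_draws(data.frame(x = 1:3),
                    list(assurance_target("missing_metric", 0, 1))),
    "unknown metric"
  )
})

test_that("sample-size sweeps report the smallest qualifying grid value", {
  fx <- small_calibrated()
  cfg <- simulation_config(fx$spec, fx$ref, strategy_spec("oracle"),
                           n = 100, n_sims = 3, population_size = 3000,
                           seed = 77)
  always <- sweep_criterion("mape", "mean", lower = -Inf, upper = Inf)
  sw <- sweep_sample_sizes(cfg, c(75, 150), list(always))
  expect_equal(sw$n_min, 75L)
  expect_equal(nrow(sw$table), 2)

  never <- sweep_criterion("mape", "assurance", lower = -1, upper = 2,
                           prob = 1.1)
  sw2 <- sweep_sample_sizes(cfg, c(75, 150), list(never))
  expect_true(is.na(sw2$n_min))

  expect_error(sweep_sample_sizes(cfg, integer(0), list(always)),
               "empty")
})

test_that("configuration files round-trip and reject unknown keys", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c(
    "casemix:",
    "  variables:",
    "    - {name: x1, type: continuous}",
    "    - {name: x2, type: continuous}",
    "    - {name: sex, type: binary, prevalence: 0.5}",
    "reference:",
    "  alpha: -0.4",
    "  delta: 1.0",
    "  beta: {x1: 0.5, x2: -0.3, sex: 0.2}",
    "strategy:",
    "  name: logistic_mle",
    "run:",
    "  sample_size: 120",
    "  n_sims: 2",
    "  population_size: 2000",
    "  seed: 5",
    "targets:",
    "  - {metric: cal_slope, lower: 0.9, upper: 1.1}",
    "grid: [75, 120]"
  ), f)
  cfg <- parse_config(f)
  expect_s3_class(cfg, "simulation_config")
  expect_equal(cfg$n, 120L)
  expect_equal(attr(cfg, "grid"), c(75, 120))
  expect_equal(length(cfg$targets), 1)
  res <- run_simulation(cfg)
  expect_equal(nrow(res$replicates), 2)

  writeLines(c("casemics:", "  variables: []"), f)
  expect_error(parse_config(f), "casemics")
})

test_that("reports round-trip through the long-format replicate export", {
  res <- run_simulation(engine_cfg(n_sims = 3))
  dir <- tempfile()
  paths <- write_report(res, dir)
  expect_true(all(file.exists(paths)))
  manifest <- jsonlite::read_json(paths[["manifest"]])
  expect_equal(manifest$seed, 71)
  expect_equal(manifest$strategy, "logistic_mle")

  # the summary regenerated from the saved replicate table matches
  back <- read.csv(paths[["replicates"]])
  s2 <- summarise_draws(back)$metrics
  s1 <- res$summary
  expect_equal(s2$mean[s2$metric == "cal_slope"],
               s1$mean[s1$metric == "cal_slope"], tolerance = 1e-10)
  long <- read.csv(paths[["replicates_long"]])
  expect_setequal(unique(long$metric),
                  s1$metric[s1$metric != "flags"])
})
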