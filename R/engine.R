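# Orchestration: the replicate loop (development draw -> fit -> evaluate in
# the target population), posterior summaries with assurance probabilities,
# and sample-size sweeps.

#' Assurance target
#'
#' An event about a replicate-level metric whose probability (the assurance)
#' is reported by [run_simulation()], e.g. calibration slope in \[0.9, 1.1\]
#' or RVSI at least 90%.
#'
#' @param metric Name of a replicate metric column (e.g. `"cal_slope"`,
#'   `"rvsi"`, `"mape"`, `"c_deg"`).
#' @param lower,upper Event bounds (inclusive; one may be infinite).
#' @param label Optional display label.
#' @return An object of class `assurance_target`.
#' @export
assurance_target <- function(metric, lower = -Inf, upper = Inf,
                             label = NULL) {
  stopifnot(is.character(metric), length(metric) == 1L, lower <= upper,
            is.finite(lower) || is.finite(upper))
  label <- label %||% paste0("P(", if (is.finite(lower)) paste0(lower, " <= ")
                             else "", metric,
                             if (is.finite(upper)) paste0(" <= ", upper)
                             else "", ")")
  structure(list(metric = metric, lower = lower, upper = upper,
                 label = label),
            class = "assurance_target")
}

#' Simulation configuration
#'
#' Bundles everything one run of the simulation-based sample size
#' calculation needs.
#'
#' @param casemix A `casemix_spec` (fresh development draws each replicate)
#'   or a finite `casemix_sample` (population and development samples carved
#'   from the pool, disjoint, without replacement).
#' @param reference A `reference_model`, a `reference_mixture`, or a list
#'   `list(relative_beta =, target_c =, target_prev =)` to be calibrated on
#'   the generated target population (tolerance 0.002).
#' @param strategy A [strategy_spec()].
#' @param n Development sample size.
#' @param n_sims Number of replicates (default 1000).
#' @param population_size Target-population size (default 100000).
#' @param thresholds Risk threshold(s) for net benefit (default 0.5).
#' @param targets List of [assurance_target()]s.
#' @param seed Master seed; all randomness is derived from it via named
#'   substreams.
#' @param n_instability Number of target-population individuals on which
#'   per-individual prediction draws are retained for instability and
#'   misclassification summaries (default 1000; a fixed random subsample,
#'   keeping memory bounded).
#' @param winner If `TRUE` (default), also compute the winner-strategy net
#'   benefit per replicate.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(casemix, reference, strategy, n,
                              n_sims = 1000L, population_size = 100000L,
                              thresholds = 0.5, targets = list(),
                              seed = 1L, n_instability = 1000L,
                              winner = TRUE) {
  stopifnot(inherits(casemix, c("casemix_spec", "casemix_sample")),
            inherits(strategy, "strategy_spec"),
            is_count(n), is_count(n_sims), is_count(population_size),
            all(thresholds > 0 & thresholds < 1),
            is.numeric(seed), length(seed) == 1L)
  ok_ref <- inherits(reference, c("reference_model", "reference_mixture")) ||
    (is.list(reference) && !is.null(reference$target_c))
  if (!ok_ref) {
    stop("reference must be a reference_model, reference_mixture, or a ",
         "list(relative_beta, target_c, target_prev) to calibrate")
  }
  if (length(targets)) {
    stopifnot(all(vapply(targets, inherits, logical(1), "assurance_target")))
  }
  structure(list(casemix = casemix, reference = reference,
                 strategy = strategy, n = as.integer(n),
                 n_sims = as.integer(n_sims),
                 population_size = as.integer(population_size),
                 thresholds = thresholds, targets = targets,
                 seed = as.integer(seed),
                 n_instability = as.integer(n_instability),
                 winner = isTRUE(winner)),
            class = "simulation_config")
}

# resolve the configured reference into a calibrated model or mixture,
# using the population case-mix when calibration is requested
resolve_reference <- function(reference, pop_casemix) {
  if (inherits(reference, "reference_mixture") &&
      length(reference$models) == 1L) {
    # a one-component mixture is the single model: collapse so the run is
    # bit-identical to a single-model run under the same seed
    return(reference$models[[1L]])
  }
  if (inherits(reference, c("reference_model", "reference_mixture"))) {
    return(reference)
  }
  beta <- reference$relative_beta
  if (is.null(names(beta))) names(beta) <- colnames(pop_casemix$X)
  skel <- reference_model(0, beta)
  calibrate_reference(skel, pop_casemix, reference$target_c,
                      reference$target_prev,
                      tol = reference$tol %||% 0.002)
}

#' Run the simulation-based sample size calculation
#'
#' Generates the target population once, then repeatedly draws a development
#' dataset of size `n`, fits the configured strategy, predicts every
#' individual in the target population, and computes performance and
#' degradation metrics; finally summarises the posterior distributions of
#' all metrics with means, 95% ranges, Monte Carlo standard errors and
#' assurance probabilities. Under a reference-model mixture, each replicate
#' first draws a reference model, which defines both the population truth
#' (risks and outcomes regenerated for that replicate) and the
#' development-data generator; under a single reference model, the
#' population truth is fixed across replicates. A replicate whose strategy
#' fit fails is flagged and recorded; the run aborts if more than 20% fail.
#'
#' @param cfg A [simulation_config()].
#' @param verbose Print progress every 100 replicates.
#' @return An object of class `cpm_size_sim`: list with `replicates` (one
#'   row per replicate), `summary`, `assurance`, `prediction_matrix`
#'   (instability subsample x replicates), `instability`, `truth`, `flags`,
#'   and the `config`.
#' @export
run_simulation <- function(cfg, verbose = FALSE) {
  stopifnot(inherits(cfg, "simulation_config"))
  seed <- cfg$seed
  n_T <- cfg$population_size

  # target population (fixed design matrix)
  if (inherits(cfg$casemix, "casemix_spec")) {
    pop <- generate_casemix(cfg$casemix, n_T,
                            substream_seed(seed, "population"))
    dev_source <- cfg$casemix
  } else {
    pool <- cfg$casemix
    if (nrow(pool$X) < n_T + cfg$n) {
      stop("finite case-mix pool (", nrow(pool$X), " rows) cannot supply a ",
           "population of ", n_T, " plus development samples of ", cfg$n)
    }
    idx <- with_seed(substream_seed(seed, "population"),
                     sample.int(nrow(pool$X), n_T))
    pop <- new_casemix_sample(pool$X[idx, , drop = FALSE], pool$meta,
                              if (!is.null(pool$groups))
                                pool$groups[idx, , drop = FALSE] else NULL)
    dev_source <- new_casemix_sample(pool$X[-idx, , drop = FALSE],
                                     pool$meta,
                                     if (!is.null(pool$groups))
                                       pool$groups[-idx, , drop = FALSE]
                                     else NULL)
  }
  Xpop <- pop$X

  reference <- resolve_reference(cfg$reference, pop)
  mixture <- inherits(reference, "reference_mixture")
  if (!mixture) {
    p_pop <- true_risks(reference, Xpop)
    y_pop <- simulate_outcomes(p_pop, substream_seed(seed, "outcomes"))
    truth <- truth_metrics(p_pop, y_pop, cfg$thresholds)
  }

  n_inst <- min(cfg$n_instability, n_T)
  inst_idx <- with_seed(substream_seed(seed, "instability"),
                        sample.int(n_T, n_inst))
  pm <- matrix(NA_real_, n_inst, cfg$n_sims)
  pm_truth <- if (!mixture) p_pop[inst_idx] else NULL

  rows <- vector("list", cfg$n_sims)
  failures <- 0L
  max_fail <- ceiling(0.2 * cfg$n_sims)

  for (k in seq_len(cfg$n_sims)) {
    ref_k <- if (mixture) {
      draw_reference(reference, substream_seed(seed, "mixture", k))
    } else reference
    if (mixture) {
      p_pop <- true_risks(ref_k, Xpop)
      y_pop <- simulate_outcomes(p_pop,
                                 substream_seed(seed, "outcomes", k))
      truth <- truth_metrics(p_pop, y_pop, cfg$thresholds)
    }
    dev <- draw_development(dev_source, ref_k, cfg$n,
                            substream_seed(seed, "development", k))
    fit <- tryCatch(
      fit_strategy(cfg$strategy, dev, substream_seed(seed, "strategy", k),
                   ref = ref_k),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      failures <- failures + 1L
      if (failures > max_fail) {
        stop("more than 20% of replicates failed (", failures, " of ", k,
             "); last error: ", conditionMessage(fit))
      }
      rows[[k]] <- data.frame(replicate = k,
                              flags = paste0("fit_failed:",
                                             conditionMessage(fit)))
      next
    }
    phat <- predict_risk(fit, Xpop)
    row <- replicate_metrics(phat, p_pop, y_pop, truth, cfg$thresholds,
                             fit = if (cfg$winner) fit else NULL,
                             dev = if (cfg$winner) dev else NULL)
    extra_flags <- fit$flags
    if (length(extra_flags)) {
      row$flags <- paste(c(extra_flags,
                           if (nzchar(row$flags)) row$flags),
                         collapse = ";")
    }
    row <- cbind(data.frame(replicate = k), row)
    if (mixture) row$reference_index <- attr(ref_k, "index")
    rows[[k]] <- row
    pm[, k] <- phat[inst_idx]
    if (verbose && k %% 100 == 0) {
      message("replicate ", k, "/", cfg$n_sims)
    }
  }
  if (failures > max_fail) {
    stop("more than 20% of replicates failed (", failures, " of ",
         cfg$n_sims, ")")
  }

  # align columns across flagged-failure and successful rows
  ncols <- vapply(rows, ncol, 0L)
  template_cols <- colnames(rows[[which.max(ncols)]])
  replicates <- do.call(rbind, lapply(rows, function(r) {
    miss <- setdiff(template_cols, colnames(r))
    for (m in miss) r[[m]] <- if (m == "flags") "" else NA_real_
    r[template_cols]
  }))
  replicates$strategy <- cfg$strategy$name
  replicates$n <- cfg$n

  ok <- !is.na(replicates$c)
  summ <- summarise_draws(replicates, cfg$targets)
  inst <- if (any(ok)) {
    instability_summaries(pm[, ok, drop = FALSE])
  } else NULL
  if (!is.null(inst) && !is.null(pm_truth)) {
    inst$p_true <- pm_truth
    inst$misclassification <- misclassification_probability(
      pm[, ok, drop = FALSE], pm_truth, cfg$thresholds[1L])
  }

  structure(list(replicates = replicates, summary = summ$metrics,
                 assurance = summ$assurance, prediction_matrix = pm,
                 instability_index = inst_idx, instability = inst,
                 truth = if (!mixture) truth else NULL,
                 reference = reference, failures = failures,
                 config = cfg),
            class = "cpm_size_sim")
}

#' Summarise posterior draws of replicate metrics
#'
#' @param replicates Data frame of replicate metrics (or a named list /
#'   single numeric vector).
#' @param targets List of [assurance_target()]s.
#' @return List with `metrics` (mean, 2.5%/97.5% percentiles, Monte Carlo
#'   standard error of the mean, flag count per metric) and `assurance`
#'   (one row per target with the satisfied fraction).
#' @export
summarise_draws <- function(replicates, targets = list()) {
  if (is.numeric(replicates)) {
    replicates <- data.frame(value = replicates)
  }
  num_cols <- setdiff(
    names(replicates)[vapply(replicates, is.numeric, logical(1))],
    c("replicate", "n", "reference_index")
  )
  metrics <- do.call(rbind, lapply(num_cols, function(m) {
    x <- replicates[[m]]
    x <- x[!is.na(x)]
    n <- length(x)
    data.frame(metric = m, mean = mean(x),
               q2.5 = if (n) quantile(x, 0.025, names = FALSE) else NA_real_,
               q97.5 = if (n) quantile(x, 0.975, names = FALSE) else NA_real_,
               mcse = if (n > 1) sd(x) / sqrt(n) else NA_real_,
               n_draws = n)
  }))
  assurance <- if (length(targets)) {
    do.call(rbind, lapply(targets, function(tg) {
      x <- replicates[[tg$metric]]
      if (is.null(x)) {
        stop("assurance target refers to unknown metric '", tg$metric, "'")
      }
      data.frame(label = tg$label, metric = tg$metric, lower = tg$lower,
                 upper = tg$upper,
                 probability = mean(x >= tg$lower & x <= tg$upper,
                                    na.rm = TRUE))
    }))
  } else NULL
  list(metrics = metrics, assurance = assurance)
}

#' @export
print.cpm_size_sim <- function(x, ...) {
  cfg <- x$config
  cat("<cpm_size_sim> strategy =", cfg$strategy$name,
      " n =", cfg$n, " replicates =", cfg$n_sims,
      " population =", cfg$population_size, "\n")
  if (x$failures) cat("  flagged fit failures:", x$failures, "\n")
  core <- x$summary[x$summary$metric %in%
                      c("c", "cal_slope", "mape", "nb", "rvsi"), ]
  print(core, row.names = FALSE, digits = 3)
  if (!is.null(x$assurance)) {
    cat("assurance:\n")
    print(x$assurance[, c("label", "probability")], row.names = FALSE,
          digits = 3)
  }
  invisible(x)
}

#' Criterion for a sample-size sweep
#'
#' Either a bound on a metric's posterior mean, or a minimum assurance
#' probability for an event about the metric.
#'
#' @param metric Replicate metric name.
#' @param type `"mean"` or `"assurance"`.
#' @param lower,upper For `"assurance"`: the event bounds; for `"mean"`:
#'   the acceptable range of the posterior mean.
#' @param prob Minimum assurance probability (assurance criteria only).
#' @return An object of class `sweep_criterion`.
#' @export
sweep_criterion <- function(metric, type = c("assurance", "mean"),
                            lower = -Inf, upper = Inf, prob = 0.9) {
  type <- match.arg(type)
  structure(list(metric = metric, type = type, lower = lower,
                 upper = upper, prob = prob),
            class = "sweep_criterion")
}

#' Sweep candidate development sample sizes
#'
#' Runs [run_simulation()] at each sample size in the grid and reports the
#' smallest grid value meeting every criterion. No interpolation between
#' grid points is attempted (metric--sample-size curves are noisy, and
#' candidate sizes are usually a small discrete set).
#'
#' @param cfg A [simulation_config()] (its `n` is overridden per grid
#'   point).
#' @param n_grid Candidate sample sizes.
#' @param criteria List of [sweep_criterion()]s.
#' @param verbose Print progress.
#' @return List with `table` (one row per grid size: per-criterion values
#'   and whether each is met) and `n_min` (smallest size meeting all
#'   criteria, or `NA` when none does).
#' @export
sweep_sample_sizes <- function(cfg, n_grid, criteria, verbose = FALSE) {
  if (length(n_grid) == 0L) stop("n_grid must not be empty")
  stopifnot(all(vapply(criteria, inherits, logical(1), "sweep_criterion")))
  n_grid <- sort(unique(as.integer(n_grid)))
  rows <- lapply(n_grid, function(n) {
    cfg$n <- n
    if (verbose) message("running n = ", n)
    res <- run_simulation(cfg)
    row <- data.frame(n = n)
    met_all <- TRUE
    for (i in seq_along(criteria)) {
      cr <- criteria[[i]]
      x <- res$replicates[[cr$metric]]
      if (is.null(x)) stop("criterion metric '", cr$metric, "' not found")
      if (cr$type == "assurance") {
        val <- mean(x >= cr$lower & x <= cr$upper, na.rm = TRUE)
        met <- val >= cr$prob
      } else {
        val <- mean(x, na.rm = TRUE)
        met <- val >= cr$lower && val <= cr$upper
      }
      row[[paste0("criterion", i, "_value")]] <- val
      row[[paste0("criterion", i, "_met")]] <- met
      met_all <- met_all && met
    }
    row$all_met <- met_all
    row
  })
  table <- do.call(rbind, rows)
  met_ns <- table$n[table$all_met]
  list(table = table,
       n_min = if (length(met_ns)) min(met_ns) else NA_integer_)
}
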