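# YAML/JSON run configuration and report output.

#' Parse a run configuration file
#'
#' Reads a YAML (or JSON) configuration with blocks `casemix`, `reference`,
#' `strategy`, `run`, and optional `targets` and `grid`, validates it, and
#' builds a [simulation_config()]. Unknown keys are an error naming the key.
#'
#' @param path Path to the configuration file.
#' @return A `simulation_config`; an optional sweep grid is attached as
#'   attribute `grid`.
#' @export
parse_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("casemix", "reference", "strategy", "run", "targets", "grid")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  for (req in c("casemix", "reference", "strategy", "run")) {
    if (is.null(cfg[[req]])) stop("missing configuration block '", req, "'")
  }

  cm <- cfg$casemix
  casemix <- if (!is.null(cm$file)) {
    load_casemix(cm$file, cm$groups %||% character())
  } else {
    vars <- lapply(cm$variables, function(v) {
      do.call(cm_variable, v)
    })
    corr <- if (!is.null(cm$correlation)) {
      do.call(rbind, cm$correlation)
    } else NULL
    casemix_spec(vars, correlation = corr,
                 fairness_groups = cm$groups %||% character())
  }

  build_ref <- function(rf) {
    if (!is.null(rf$alpha)) {
      reference_model(rf$alpha, unlist(rf$beta), rf$delta %||% 1,
                      predictor_names = rf$predictor_names %||%
                        names(rf$beta))
    } else if (!is.null(rf$target_c)) {
      list(relative_beta = unlist(rf$relative_beta),
           target_c = rf$target_c, target_prev = rf$target_prev,
           tol = rf$tol %||% 0.002)
    } else {
      stop("reference block needs either alpha/beta or ",
           "relative_beta/target_c/target_prev")
    }
  }
  rf <- cfg$reference
  reference <- if (!is.null(rf$mixture)) {
    models <- lapply(rf$mixture, build_ref)
    if (any(vapply(models, is.list, logical(1)) &
            !vapply(models, inherits, logical(1), "reference_model"))) {
      stop("mixture components must be explicit alpha/delta/beta models")
    }
    reference_mixture(models,
                      vapply(rf$mixture, function(m) m$prob, numeric(1)))
  } else {
    build_ref(rf)
  }

  st <- cfg$strategy
  if (is.null(st$name)) stop("strategy block needs a 'name'")
  strategy <- do.call(strategy_spec,
                      c(list(name = st$name),
                        st[setdiff(names(st), "name")]))

  run <- cfg$run
  targets <- lapply(cfg$targets %||% list(), function(tg) {
    assurance_target(tg$metric, tg$lower %||% -Inf, tg$upper %||% Inf,
                     tg$label %||% NULL)
  })
  n_dev <- run$sample_size %||% run$n  # YAML 1.1 reads a bare `n` key as
  if (is.logical(n_dev)) {             # boolean; require `sample_size`
    stop("use the key 'sample_size' (not 'n') for the development sample ",
         "size in the run block")
  }
  out <- simulation_config(
    casemix = casemix, reference = reference, strategy = strategy,
    n = n_dev, n_sims = run$n_sims %||% 1000L,
    population_size = run$population_size %||% 100000L,
    thresholds = unlist(run$thresholds %||% 0.5),
    targets = targets, seed = run$seed %||% 1L,
    n_instability = run$n_instability %||% 1000L
  )
  attr(out, "grid") <- unlist(cfg$grid)
  out
}

#' Write a simulation report to disk
#'
#' Writes the replicate-level metrics (wide and long format), the posterior
#' summary, assurance probabilities, per-individual instability summaries,
#' and a JSON run manifest (seed, sizes, package version).
#'
#' @param res A `cpm_size_sim` from [run_simulation()] or
#'   [run_approximation()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(res, dir) {
  stopifnot(inherits(res, "cpm_size_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    summary = file.path(dir, "summary.csv"),
    replicates = file.path(dir, "replicates.csv"),
    replicates_long = file.path(dir, "replicates_long.csv"),
    instability = file.path(dir, "instability.csv"),
    manifest = file.path(dir, "manifest.json")
  )
  write.csv(res$summary, paths["summary"], row.names = FALSE)
  write.csv(res$replicates, paths["replicates"], row.names = FALSE)
  write.csv(replicates_long(res$replicates), paths["replicates_long"],
            row.names = FALSE)
  if (!is.null(res$instability)) {
    write.csv(cbind(individual = res$instability_index, res$instability),
              paths["instability"], row.names = FALSE)
  }
  if (!is.null(res$assurance)) {
    paths["assurance"] <- file.path(dir, "assurance.csv")
    write.csv(res$assurance, paths["assurance"], row.names = FALSE)
  }
  cfg <- res$config
  manifest <- list(
    package = "predsize",
    version = as.character(utils::packageVersion("predsize")),
    created = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = cfg$seed,
    n = cfg$n,
    n_sims = cfg$n_sims %||% cfg$n_draws,
    population_size = cfg$population_size,
    thresholds = cfg$thresholds,
    strategy = if (inherits(cfg, "simulation_config"))
      cfg$strategy$name else res$replicates$strategy[1L],
    failures = res$failures
  )
  jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(paths)
}

#' Long-format replicate metrics
#'
#' @param replicates Replicate-metric data frame from a `cpm_size_sim`.
#' @return Data frame with columns `replicate`, `strategy`, `n`, `metric`,
#'   `value` -- the raw material for cross-strategy summary tables and
#'   posterior-distribution plots.
#' @export
replicates_long <- function(replicates) {
  num_cols <- setdiff(
    names(replicates)[vapply(replicates, is.numeric, logical(1))],
    c("replicate", "n", "reference_index")
  )
  out <- do.call(rbind, lapply(num_cols, function(m) {
    data.frame(replicate = replicates$replicate,
               strategy = replicates$strategy %||% NA_character_,
               n = replicates$n %||% NA_integer_,
               metric = m, value = replicates[[m]])
  }))
  rownames(out) <- NULL
  out
}
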