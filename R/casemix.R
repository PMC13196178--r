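# Case-mix of the target population: specify, generate and load the joint
# predictor distribution, and draw development datasets from it.

#' Declare one case-mix variable
#'
#' Helper constructor for the entries of [casemix_spec()]. Continuous
#' variables have a normal marginal (standardised by default), binary
#' variables a prevalence, categorical variables a vector of level
#' probabilities (entering the design matrix as `k - 1` dummy columns).
#'
#' @param name Variable name (unique within a spec).
#' @param type One of `"continuous"`, `"binary"`, `"categorical"`.
#' @param mean,sd Marginal mean and standard deviation (continuous only).
#' @param prevalence Event probability in (0, 1) (binary only).
#' @param probs Level probabilities summing to 1 (categorical only).
#' @param levels Optional level labels (categorical only).
#' @return A list describing the variable, for use in [casemix_spec()].
#' @export
cm_variable <- function(name, type = c("continuous", "binary", "categorical"),
                        mean = 0, sd = 1, prevalence = NULL, probs = NULL,
                        levels = NULL) {
  type <- match.arg(type)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  v <- list(name = name, type = type)
  if (type == "continuous") {
    stopifnot(is.finite(mean), is.finite(sd), sd > 0)
    v$mean <- mean
    v$sd <- sd
  } else if (type == "binary") {
    if (is.null(prevalence) || !is.numeric(prevalence) ||
        prevalence <= 0 || prevalence >= 1) {
      stop("binary variable '", name, "' needs a prevalence in (0, 1)")
    }
    v$prevalence <- prevalence
  } else {
    if (is.null(probs) || any(probs <= 0) || abs(sum(probs) - 1) > 1e-8) {
      stop("categorical variable '", name,
           "' needs positive level probabilities summing to 1")
    }
    if (length(probs) < 2L) stop("categorical variable needs >= 2 levels")
    v$probs <- probs
    v$levels <- levels %||% paste0("l", seq_along(probs))
    stopifnot(length(v$levels) == length(probs))
  }
  v
}

#' Specify the case-mix (joint predictor distribution) of a target population
#'
#' The default is conditional independence of the predictors; an optional
#' correlation matrix on the latent Gaussian scale induces dependence via a
#' Gaussian copula (latent multivariate normal draws transformed to the
#' requested marginals).
#'
#' @param variables List of variables from [cm_variable()].
#' @param correlation Optional latent-scale correlation matrix (one row/column
#'   per variable, in order): symmetric, unit diagonal, positive semi-definite.
#' @param fairness_groups Character vector of variable names used only for
#'   subgroup (fairness) reporting; they are generated alongside the
#'   predictors but kept out of the design matrix.
#' @return An object of class `casemix_spec`.
#' @export
casemix_spec <- function(variables, correlation = NULL,
                         fairness_groups = character()) {
  stopifnot(is.list(variables), length(variables) >= 1L)
  nms <- vapply(variables, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("variable names must be unique")
  if (!all(fairness_groups %in% nms)) {
    stop("fairness_groups must name declared variables")
  }
  k <- length(variables)
  if (!is.null(correlation)) {
    correlation <- as.matrix(correlation)
    if (!isTRUE(all.equal(dim(correlation), c(k, k)))) {
      stop("correlation must be ", k, "x", k)
    }
    if (max(abs(correlation - t(correlation))) > 1e-10) {
      stop("correlation matrix must be symmetric")
    }
    if (max(abs(diag(correlation) - 1)) > 1e-10) {
      stop("correlation matrix must have unit diagonal")
    }
    ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8) {
      stop("correlation matrix is not positive semi-definite ",
           "(smallest eigenvalue ", format(min(ev)), ")")
    }
  }
  structure(list(variables = variables, correlation = correlation,
                 fairness_groups = fairness_groups),
            class = "casemix_spec")
}

#' Independent standard-normal case-mix
#'
#' Convenience constructor for the common working assumption of `P`
#' standardised, conditionally independent continuous predictors.
#'
#' @param P Number of predictors.
#' @param prefix Name prefix for the generated variables.
#' @return A `casemix_spec`.
#' @export
casemix_spec_normal <- function(P, prefix = "x") {
  casemix_spec(lapply(seq_len(P), function(j) {
    cm_variable(paste0(prefix, j), "continuous")
  }))
}

# one latent-normal column -> marginal values + design columns
cm_transform_one <- function(v, z) {
  switch(v$type,
    continuous = {
      x <- v$mean + v$sd * z
      list(values = x, X = matrix(x, ncol = 1,
                                  dimnames = list(NULL, v$name)))
    },
    binary = {
      x <- as.numeric(z > qnorm(1 - v$prevalence))
      list(values = x, X = matrix(x, ncol = 1,
                                  dimnames = list(NULL, v$name)))
    },
    categorical = {
      cuts <- qnorm(cumsum(v$probs))
      idx <- findInterval(z, cuts[-length(cuts)]) + 1L
      lab <- v$levels[idx]
      # reference level = first; k - 1 dummy columns
      X <- vapply(v$levels[-1L], function(l) as.numeric(lab == l),
                  numeric(length(z)))
      colnames(X) <- paste(v$name, v$levels[-1L], sep = ".")
      list(values = lab, X = X)
    }
  )
}

#' Generate a case-mix sample
#'
#' Draws `n` i.i.d. rows from the joint predictor distribution of a
#' [casemix_spec()]. Without a correlation matrix, variables are independent;
#' with one, a latent multivariate-normal draw is transformed to the requested
#' marginals (Gaussian copula). Fairness-group variables are returned as
#' labels in `$groups`, not as design-matrix columns.
#'
#' @param spec A `casemix_spec`.
#' @param n Number of rows (>= 1).
#' @param seed Integer seed; fixed seed gives identical samples.
#' @return An object of class `casemix_sample` with elements `X` (numeric
#'   matrix, no intercept column), `meta` (per-column descriptors) and
#'   `groups` (data frame of subgroup labels, or `NULL`).
#' @export
generate_casemix <- function(spec, n, seed = NULL) {
  stopifnot(inherits(spec, "casemix_spec"))
  if (!is_count(n)) stop("n must be a positive integer")
  if (!is.null(seed)) set.seed(seed)
  k <- length(spec$variables)
  Z <- matrix(rnorm(n * k), nrow = n, ncol = k)
  if (!is.null(spec$correlation)) {
    # PSD (possibly singular) -> eigen factor rather than chol
    e <- eigen(spec$correlation, symmetric = TRUE)
    L <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), k)
    Z <- Z %*% t(L)
  }
  cols <- list()
  groups <- list()
  meta <- list()
  for (j in seq_len(k)) {
    v <- spec$variables[[j]]
    tr <- cm_transform_one(v, Z[, j])
    if (v$name %in% spec$fairness_groups) {
      groups[[v$name]] <- tr$values
    } else {
      cols[[v$name]] <- tr$X
      meta[[v$name]] <- v
    }
  }
  X <- do.call(cbind, unname(cols))
  groups <- if (length(groups)) as.data.frame(groups,
                                              stringsAsFactors = FALSE)
            else NULL
  new_casemix_sample(X, meta, groups)
}

new_casemix_sample <- function(X, meta, groups = NULL) {
  stopifnot(is.matrix(X), nrow(X) >= 1L, !anyNA(X))
  structure(list(X = X, meta = meta, groups = groups),
            class = "casemix_sample")
}

#' @export
print.casemix_sample <- function(x, ...) {
  cat("<casemix_sample> ", nrow(x$X), " individuals x ", ncol(x$X),
      " predictor columns\n", sep = "")
  if (!is.null(x$groups)) {
    cat("  fairness groups:", paste(names(x$groups), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Load a case-mix sample from a delimited file
#'
#' Reads a CSV (comma separated, header row) of individuals by candidate
#' predictors. Missing cells are an error, never imputed. Columns named in
#' `declared_groups` are removed from the design matrix and stored as
#' subgroup labels.
#'
#' @param path Path to the CSV file.
#' @param declared_groups Character vector of fairness-group column names.
#' @return A `casemix_sample`.
#' @export
load_casemix <- function(path, declared_groups = character()) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) < 1L) stop("case-mix file has no rows")
  na_idx <- which(is.na(df) | df == "", arr.ind = TRUE)
  if (nrow(na_idx)) {
    stop("missing value in case-mix file at row ", na_idx[1, 1],
         ", column '", names(df)[na_idx[1, 2]], "' (missing input is an ",
         "error; impute or drop before loading)")
  }
  missing_grp <- setdiff(declared_groups, names(df))
  if (length(missing_grp)) {
    stop("declared group column(s) not in file: ",
         paste(missing_grp, collapse = ", "))
  }
  groups <- if (length(declared_groups)) df[declared_groups] else NULL
  pred <- df[setdiff(names(df), declared_groups)]
  nonnum <- names(pred)[!vapply(pred, is.numeric, logical(1))]
  if (length(nonnum)) {
    stop("non-numeric predictor column(s) not declared as groups: ",
         paste(nonnum, collapse = ", "))
  }
  X <- as.matrix(pred)
  meta <- lapply(colnames(X), function(nm) list(name = nm, type = "loaded"))
  names(meta) <- colnames(X)
  new_casemix_sample(X, meta, groups)
}

#' Draw a development dataset
#'
#' Draws `n` individuals from a case-mix source (fresh generation from a
#' `casemix_spec`, or row sampling from a finite `casemix_sample`) and
#' simulates their binary outcomes from the reference model's true risks.
#'
#' @param source A `casemix_spec` or `casemix_sample`.
#' @param ref A [reference_model()] generating the outcomes.
#' @param n Development sample size.
#' @param seed Integer seed.
#' @param replace For a finite source, sample rows with replacement
#'   (default `FALSE`: without replacement, `n` must not exceed the pool).
#' @return A `development_data` list with `X`, `y` and `n`.
#' @export
draw_development <- function(source, ref, n, seed = NULL, replace = FALSE) {
  if (!is_count(n)) stop("n must be a positive integer")
  if (!is.null(seed)) set.seed(seed)
  if (inherits(source, "casemix_spec")) {
    X <- generate_casemix(source, n)$X
  } else if (inherits(source, "casemix_sample")) {
    pool <- nrow(source$X)
    if (!replace && n > pool) {
      stop("n = ", n, " exceeds the finite case-mix pool (", pool,
           " rows); set replace = TRUE to sample with replacement")
    }
    X <- source$X[sample.int(pool, n, replace = replace), , drop = FALSE]
  } else {
    stop("source must be a casemix_spec or casemix_sample")
  }
  p <- true_risks(ref, X)
  y <- rbinom(n, 1L, p)
  structure(list(X = X, y = y, n = n), class = "development_data")
}
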