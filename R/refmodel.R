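# The reference ("true") model: a logistic equation
#   logit(p_i) = alpha + delta * (beta_1 x_1i + ... + beta_P x_Pi)
# against which the degradation of developed models is measured.

#' Construct a reference model
#'
#' @param alpha Intercept on the logit scale.
#' @param beta Predictor weights (log-odds per unit); relative weights when
#'   the model is later calibrated via [calibrate_reference()].
#' @param delta Scaling factor applied to the linear combination of weights
#'   (default 1).
#' @param predictor_names Names matching the case-mix design-matrix columns;
#'   defaults to `names(beta)`.
#' @return An object of class `reference_model`.
#' @export
reference_model <- function(alpha, beta, delta = 1,
                            predictor_names = names(beta)) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, is.finite(alpha),
            is.numeric(delta), length(delta) == 1L, is.finite(delta),
            is.numeric(beta), all(is.finite(beta)))
  if (is.null(predictor_names)) {
    predictor_names <- paste0("x", seq_along(beta))
  }
  stopifnot(length(predictor_names) == length(beta))
  structure(list(alpha = alpha, delta = delta,
                 beta = stats::setNames(as.numeric(beta), predictor_names),
                 predictor_names = predictor_names),
            class = "reference_model")
}

#' @export
print.reference_model <- function(x, ...) {
  cat("<reference_model> alpha =", format(x$alpha, digits = 4),
      " delta =", format(x$delta, digits = 4),
      " P =", length(x$beta), "\n")
  invisible(x)
}

# full coefficient vector (intercept first) on the design scale
ref_coefficients <- function(model) {
  c("(Intercept)" = model$alpha, model$delta * model$beta)
}

#' True risks under a reference model
#'
#' @param model A `reference_model`.
#' @param X Design matrix whose columns match `model$predictor_names`
#'   (matched by name when column names are present).
#' @return Vector of risks `plogis(alpha + delta * X beta)`.
#' @export
true_risks <- function(model, X) {
  stopifnot(inherits(model, "reference_model"))
  X <- as.matrix(X)
  if (ncol(X) != length(model$beta)) {
    stop("X has ", ncol(X), " columns but the reference model expects ",
         length(model$beta))
  }
  if (!is.null(colnames(X))) {
    if (!all(model$predictor_names %in% colnames(X))) {
      stop("X columns do not match reference-model predictors: missing ",
           paste(setdiff(model$predictor_names, colnames(X)), collapse = ", "))
    }
    X <- X[, model$predictor_names, drop = FALSE]
  }
  as.numeric(plogis(model$alpha + model$delta * (X %*% model$beta)))
}

#' Expected concordance (c-statistic) of a risk vector
#'
#' The c-statistic the risks would attain, in expectation, against outcomes
#' drawn as `Bernoulli(p_i)`: the probability that a randomly chosen event
#' individual has a higher risk than a randomly chosen non-event individual,
#' counting ties one half. Computed exactly in O(n log n) by sorting, so it
#' carries no Monte Carlo noise (used by the calibration bisection).
#'
#' @param p Vector of risks in \[0, 1\].
#' @return Expected c-statistic.
#' @export
expected_cstat <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  ps <- sort(p)
  grp <- cumsum(c(TRUE, diff(ps) > 0))
  sp <- rowsum(ps, grp)          # sum of p within each tied value
  sq <- rowsum(1 - ps, grp)      # sum of (1 - p) within each tied value
  spq <- rowsum(ps * (1 - ps), grp)
  above <- rev(cumsum(rev(sp))) - sp  # sum of p over strictly larger values
  num <- sum(sq * above) + 0.5 * sum(sp * sq - spq)
  den <- sum(ps) * sum(1 - ps) - sum(ps * (1 - ps))
  if (den <= 0) return(0.5)  # degenerate: all risks 0 or 1
  as.numeric(num / den)
}

#' Calibrate a reference model to a target c-statistic and prevalence
#'
#' Iteratively identifies the intercept `alpha` and scaling factor `delta`
#' so that, on the supplied case-mix, the model's mean risk matches
#' `target_prev` and its expected c-statistic matches `target_c`: an outer
#' bisection on `delta` (expected concordance is nondecreasing in `delta`)
#' with, at each `delta`, an inner root-find on `alpha` for the prevalence.
#'
#' @param skeleton A `reference_model` holding the relative predictor
#'   weights (its `alpha`/`delta` are ignored).
#' @param casemix A `casemix_sample` (recommended >= 1e5 rows) defining the
#'   population on which the targets must hold.
#' @param target_c Target c-statistic in \[0.5, 1).
#' @param target_prev Target outcome prevalence in (0, 1).
#' @param tol Tolerance on both achieved targets (default 0.002).
#' @param max_iter Maximum outer bisection iterations (default 50).
#' @return A calibrated `reference_model`; attributes `achieved_c` and
#'   `achieved_prev` record the attained values.
#' @export
calibrate_reference <- function(skeleton, casemix, target_c, target_prev,
                                tol = 0.002, max_iter = 50L) {
  stopifnot(inherits(skeleton, "reference_model"),
            inherits(casemix, "casemix_sample"))
  if (target_c < 0.5 || target_c >= 1) stop("target_c must be in [0.5, 1)")
  if (target_prev <= 0 || target_prev >= 1) {
    stop("target_prev must be in (0, 1)")
  }
  X <- casemix$X
  if (!is.null(colnames(X))) X <- X[, skeleton$predictor_names, drop = FALSE]
  lp0 <- as.numeric(X %*% skeleton$beta)

  solve_alpha <- function(delta) {
    f <- function(a) mean(plogis(a + delta * lp0)) - target_prev
    uniroot(f, lower = -50, upper = 50, tol = 1e-10)$root
  }
  c_of <- function(delta) {
    a <- solve_alpha(delta)
    list(alpha = a, c = expected_cstat(plogis(a + delta * lp0)))
  }

  done <- function(alpha, delta, achieved_c) {
    out <- reference_model(alpha, skeleton$beta, delta,
                           skeleton$predictor_names)
    attr(out, "achieved_c") <- achieved_c
    attr(out, "achieved_prev") <- mean(plogis(alpha + delta * lp0))
    out
  }

  if (abs(target_c - 0.5) <= tol) {
    return(done(solve_alpha(0), 0, 0.5))
  }

  # bracket delta: expected concordance is 0.5 at delta = 0 and
  # nondecreasing in delta
  lo <- 0; hi <- 1
  r_hi <- c_of(hi)
  while (r_hi$c < target_c) {
    prev_c <- r_hi$c
    hi <- hi * 2
    r_hi <- c_of(hi)
    if (hi > 1e6 || r_hi$c - prev_c < 1e-9) {
      stop("calibration failed: target c-statistic ", target_c,
           " unattainable on this case-mix (best C = ",
           format(r_hi$c, digits = 4), " at delta = ", format(hi),
           ", alpha = ", format(r_hi$alpha, digits = 4), ")")
    }
  }
  best <- NULL
  for (it in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    r <- c_of(mid)
    best <- list(alpha = r$alpha, delta = mid, c = r$c)
    if (abs(r$c - target_c) <= tol) {
      return(done(r$alpha, mid, r$c))
    }
    if (r$c < target_c) lo <- mid else hi <- mid
  }
  stop("calibration did not converge in ", max_iter, " iterations: best ",
       "(alpha = ", format(best$alpha, digits = 5), ", delta = ",
       format(best$delta, digits = 5), ") achieved C = ",
       format(best$c, digits = 5), " vs target ", target_c,
       " (prevalence matched to ", target_prev, ")")
}

#' Simulate binary outcomes from risks
#'
#' @param p Vector of risks in \[0, 1\].
#' @param seed Optional integer seed.
#' @return Integer 0/1 vector of independent `Bernoulli(p_i)` draws.
#' @export
simulate_outcomes <- function(p, seed = NULL) {
  if (anyNA(p) || any(p < 0 | p > 1)) stop("risks must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  rbinom(length(p), 1L, p)
}

#' Mixture of reference models
#'
#' Represents uncertainty in the reference model: each simulation replicate
#' selects one model at random with the stated probabilities, and that model
#' defines both the population truth and the development-data generator for
#' the replicate.
#'
#' @param models List of `reference_model` objects.
#' @param probs Selection probabilities (nonnegative, summing to 1).
#' @return An object of class `reference_mixture`.
#' @export
reference_mixture <- function(models, probs) {
  stopifnot(is.list(models), length(models) >= 1L,
            all(vapply(models, inherits, logical(1), "reference_model")))
  probs <- as.numeric(probs)
  if (length(probs) != length(models) || any(probs < 0)) {
    stop("probs must be nonnegative, one per model")
  }
  if (abs(sum(probs) - 1) > 1e-12) {
    stop("selection probabilities must sum to 1 (got ", format(sum(probs),
         digits = 15), ")")
  }
  structure(list(models = models, probs = probs),
            class = "reference_mixture")
}

#' Draw one reference model from a mixture
#'
#' @param mix A `reference_mixture`.
#' @param seed Optional integer seed.
#' @return The selected `reference_model`, with attribute `index`.
#' @export
draw_reference <- function(mix, seed = NULL) {
  stopifnot(inherits(mix, "reference_mixture"))
  if (!is.null(seed)) set.seed(seed)
  i <- sample.int(length(mix$models), 1L, prob = mix$probs)
  out <- mix$models[[i]]
  attr(out, "index") <- i
  out
}
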