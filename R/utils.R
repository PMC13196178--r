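#' @useDynLib predsize, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm rbinom qnorm pnorm dnorm plogis qlogis uniroot
#'   glm.fit binomial quantile sd var rgamma coef predict
#' @importFrom utils read.csv write.csv
"_PACKAGE"

# Deterministic substream seeds: one master seed fans out into named streams
# (population draw, per-replicate development draw, strategy internals, ...)
# so that swapping one component does not perturb the draws of another.
# Kept below 2^31 - 1 so set.seed() accepts the result.
substream_seed <- function(master, label, index = 0L) {
  m <- 2147483647
  h <- as.double(master) %% m
  for (ch in utf8ToInt(as.character(label))) {
    h <- (h * 31 + ch) %% m
  }
  h <- (h * 69069 + 12345 + 1000003 * (as.double(index) %% m)) %% m
  as.integer(h)
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

clip_prob <- function(p, eps = 1e-8) pmin(pmax(p, eps), 1 - eps)

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 1 && x == floor(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
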