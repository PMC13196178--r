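# Shared fixtures, built lazily and cached for the test run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

# a 20,000-row case-mix of 10 iid standard normals with a reference model
# calibrated to C = 0.76, prevalence 0.68 (the applied-example conditions,
# at a size suitable for unit tests)
small_calibrated <- function() {
  fixture("small_calibrated", function() {
    spec <- casemix_spec_normal(10)
    cm <- generate_casemix(spec, 2e4, seed = 424242)
    skel <- reference_model(0, rep(1, 10), predictor_names = colnames(cm$X))
    ref <- calibrate_reference(skel, cm, 0.76, 0.68)
    list(spec = spec, cm = cm, ref = ref)
  })
}

# small development dataset generated from a known 3-predictor model
small_dev <- function(n = 2000, seed = 77) {
  spec <- casemix_spec_normal(3)
  ref <- reference_model(-0.3, c(0.8, -0.5, 0.2),
                         predictor_names = paste0("x", 1:3))
  dev <- draw_development(spec, ref, n, seed = seed)
  list(spec = spec, ref = ref, dev = dev)
}

# brute-force O(n^2) all-pairs concordance with ties counted one half
cstat_bruteforce <- function(phat, y) {
  ev <- phat[y == 1]
  ne <- phat[y == 0]
  conc <- 0
  for (a in ev) for (b in ne) {
    conc <- conc + (a > b) + 0.5 * (a == b)
  }
  conc / (length(ev) * length(ne))
}
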