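# Shared fixtures: deterministic reference subjects and small cached
# simulations so expensive objects are built once per test run.

.test_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.test_cache[[key]])) .test_cache[[key]] <- force(expr)
  .test_cache[[key]]
}

ref_subject <- function(weight = 62.3, class = "lean", female = TRUE) {
  spec <- population_spec(class, n_subjects = 1,
                          proportion_female = as.numeric(female),
                          target_mean_weight = weight,
                          variability = FALSE, seed = 1)
  build_baseline(spec)[[1]]
}

ref_profile <- function(compound = "cefazolin", dose = 500,
                        infusion_min = 2, ...) {
  key <- paste("profile", compound, dose, infusion_min, sep = "_")
  cached(key, {
    cmp <- load_compound(compound)
    suppressWarnings(simulate_subject(ref_subject(), cmp,
                                      dosing_regimen(dose, infusion_min),
                                      ...))
  })
}

lean_spec <- function(n = 4, seed = 1, variability = TRUE, weight = 62.3) {
  population_spec("lean", n_subjects = n, proportion_female = 1,
                  target_mean_weight = weight, variability = variability,
                  seed = seed)
}
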