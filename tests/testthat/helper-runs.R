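# full simulation runs shared between test files, executed at most once per
# session; sizes keep the whole suite within a desk-scale time budget while
# leaving the stochastic comparisons at 2-3 sigma resolution
run_cache <- new.env(parent = emptyenv())

cached_run <- function(name, maker) {
  if (is.null(run_cache[[name]])) run_cache[[name]] <- maker()
  run_cache[[name]]
}

water_run <- function() {
  cached_run("water", function() {
    run_simulation(run_config("water", n_histories = 4e6, seed = 20101))
  })
}

pmma_run <- function() {
  cached_run("pmma", function() {
    run_simulation(run_config("pmma", n_histories = 2.5e6, seed = 20102))
  })
}

air_run <- function() {
  cached_run("air", function() {
    run_simulation(run_config(phantom_air_sphere(), n_histories = 1e6,
                              seed = 20103, cells = NULL,
                              detectors = c(25, 50, 75, 100)))
  })
}

air_sk_fit <- function() {
  cached_run("air_sk", function() fit_air_kerma_strength(air_run()$detectors))
}
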