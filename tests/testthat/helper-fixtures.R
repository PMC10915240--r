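# Shared fixtures. Everything is generated in code; the heavier two-state
# cohort run is memoised so several test files can reuse it.

.fixture_cache <- new.env(parent = emptyenv())

# A deterministic 100x100 test image: one rendered pulse window.
fixture_waveform_image <- function(seed = 1) {
  key <- paste0("img", seed)
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  tr <- generate_rf_trace(pulsation_params(seed = seed),
                          equivalent_circuit(), duration = 15)
  img <- resize_bicubic(render_waveform(tr$values[1:300]))
  .fixture_cache[[key]] <- img
  img
}

# Full two-state cohort pipeline at the study scale (13 subjects, 1 min per
# state, reduced hyperparameter grids), used by the end-to-end tests.
fixture_cohort_run <- function() {
  if (!is.null(.fixture_cache$run)) return(.fixture_cache$run)
  cfg <- default_config()
  cfg$classify$grid <- "reduced"
  run <- run_pipeline(cfg, out_dir = file.path(tempdir(), "ecscbf-accept"),
                      seed = 42, write_images = FALSE, verbose = FALSE)
  .fixture_cache$run <- run
  run
}

# Amplitude-decay cohort (13 subjects, six post-caffeine minute marks).
fixture_decay_cohort <- function() {
  if (!is.null(.fixture_cache$decay)) return(.fixture_cache$decay)
  traces <- generate_cohort(13, minutes = c(5, 10, 15, 20, 25, 30),
                            circuit = equivalent_circuit(),
                            params_base = pulsation_params(), seed = 7)
  .fixture_cache$decay <- traces
  traces
}
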