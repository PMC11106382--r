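# A small cohort shared across test files (computed once per test run).
# Reduced problem size relative to the study conditions: unit tests check
# mechanics, the acceptance suite checks behaviour at full scale.
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_cohort(
        default_config(), n_patients = 4, n_controls = 4,
        n_timepoints = 100, n_rois = 24,
        coupled_rois = c(2, 7, 12, 17), deficit_nodes = c(4, 20),
        enhanced_nodes = 9, k_true = 2, dwell_mean_tr = 40, seed = 42)
    }
    cache
  }
})
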