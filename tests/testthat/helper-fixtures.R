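# Shared fixtures, built once per test session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, .fixture_cache)) assign(key, builder(), .fixture_cache)
  get(key, .fixture_cache)
}

# deterministic multi-channel test signal (not white: distinct per channel)
toy_signal <- function(n_samples, rate = 250, seed = 42) {
  set.seed(seed)
  t <- (seq_len(n_samples) - 1) / rate
  sapply(seq_along(montage_electrodes()), function(i) {
    5 * sin(2 * pi * (4 + i %% 7) * t + i) + rnorm(n_samples, 0, 2)
  }) |> t()
}

toy_recording <- function(duration_s = 60, rate = 250, seed = 42,
                          annotations = NULL) {
  n <- duration_s * rate
  if (is.null(annotations)) {
    annotations <- data.frame(
      onset_s = c(0, 40, 50), duration_s = c(40, 10, 10),
      label = c("rest", "slow_soft", "fast_hard"))
  }
  eeg_recording(toy_signal(n, rate, seed), montage_electrodes(), rate,
                annotations, subject_id = "T01", group = "control")
}

# small cohort reused by io / pipeline tests
small_cohort <- function() {
  cached("small_cohort", function() {
    simulate_cohort(cohort_spec(n_patients = 5, n_controls = 5,
                                n_trials = 2, n_rest = 6, seed = 71))
  })
}

# reduced-size spec used by the resampling-heavy acceptance checks:
# 3 trials per stimulus type and 12 rest fragments keep the per-cohort
# cost low while preserving the trial structure
reduced_spec <- function(...) {
  cohort_spec(n_trials = 3, n_rest = 12, ...)
}

# straight-line contrast fixture for cluster tests
flat_contrast <- function(values, subjects = sprintf("P%02d", seq_along(values))) {
  m <- matrix(values, length(values), 19,
              dimnames = list(subjects, montage_electrodes()))
  m
}

# per-subject theta contrast computed the cheap way (all-stimulation merge)
theta_contrast_of <- function(cohort, normalize = "relative") {
  tab <- condition_table(cohort$epoch_sets, band_scheme("contrast"),
                         merge_rule = "all_stimulation",
                         normalize = normalize)
  band_contrast(tab, "theta")
}
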