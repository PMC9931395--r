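# Shared small fixtures: a reduced-grid cohort spec (same stated world as
# the defaults, lower resolution so the suite stays fast) and a cached
# noiseless patient phantom reused by several test files.

small_spec <- function(noise_sigma = 0, seed = 7, ...) {
  cohort_spec(grid_shape = c(32, 32, 16), lesion_radius_range = c(2, 3),
              noise_sigma = noise_sigma, seed = seed, ...)
}

.test_cache <- new.env(parent = emptyenv())

cached_patient_phantom <- function() {
  if (is.null(.test_cache$patient)) {
    .test_cache$patient <- build_phantom(small_spec(), "patient", seed = 11)
  }
  .test_cache$patient
}

cached_noiseless_series <- function() {
  if (is.null(.test_cache$series)) {
    ph <- cached_patient_phantom()
    .test_cache$series <- simulate_echo_series(ph$truth, n_echoes = 48,
                                               echo_spacing = 8,
                                               refocusing_flip = 165,
                                               noise_sigma = 0, seed = 1)
  }
  .test_cache$series
}
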