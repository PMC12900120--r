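# Noise-free generator settings: every nuisance term disabled so detection
# and feature recovery can be compared against the analytic template truth.
quiet_params <- function(...) {
  generator_params(noise_sd = 0, drift_amp = 0, pp_jitter_sd = 0,
                   zeta_jitter_sd = 0, hr_jitter_sd = 0, ...)
}

# Foot/peak truth times tiled over a record's duration.
truth_times <- function(rec, landmark) {
  lmk <- rec$truth$landmarks
  T <- rec$truth$period
  tt <- lmk[[landmark]] + T * (0:ceiling(40))
  tt[tt >= 0 & tt < max(rec$time) + 1 / rec$fs]
}

valid_fiducials <- function(x, fs, hr) {
  Filter(function(f) isTRUE(f$valid), detect_all_fiducials(x, fs, hr))
}

# Worst-case localization error (in samples) of detected landmarks against
# the template truth.
localization_error <- function(rec, channel = "p1", landmark = "foot",
                               field = "foot") {
  v <- valid_fiducials(rec$conditioned[[channel]], rec$fs, rec$config$hr_bpm)
  tt <- truth_times(rec, landmark)
  max(vapply(v, function(f) {
    min(abs((f[[field]] - 1) / rec$fs - tt))
  }, numeric(1))) * rec$fs
}
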