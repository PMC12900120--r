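#' Per-beat features from fiducial points
#'
#' Crest time is the foot-to-systolic-peak interval (the first zero-crossing
#' of the pulse derivative after onset is the peak), systole time the
#' foot-to-falling-steep interval, and pulse pressure the foot-to-peak
#' amplitude measured on the pre-normalization signal.
#'
#' @param fiducials A valid `fiducial_set`.
#' @param raw_beat The conditioned, pre-normalization signal the indices
#'   refer to.
#' @param fs Sampling rate in samples/s.
#' @param next_foot Optional foot index of the following beat, to compute the
#'   pulse-to-pulse interval.
#' @return A list of class `beat_features`: `crest_time`, `systole_time`
#'   (seconds), `pulse_pressure` (raw units), `pp_interval` (seconds or NA).
#' @examples
#' f <- structure(list(foot = 10L, rising_steep = 25L, systolic_peak = 40L,
#'                     falling_steep = 70L, dicrotic_notch = NA, valid = TRUE),
#'                class = "fiducial_set")
#' beat_features(f, raw_beat = seq(0, 1, length.out = 200), fs = 200)
#' @export
beat_features <- function(fiducials, raw_beat, fs, next_foot = NA) {
  if (!isTRUE(fiducials$valid)) stop("fiducial set flagged invalid")
  crest <- (fiducials$systolic_peak - fiducials$foot) / fs
  systole <- (fiducials$falling_steep - fiducials$foot) / fs
  pp <- raw_beat[fiducials$systolic_peak] - raw_beat[fiducials$foot]
  ppi <- if (is.na(next_foot)) NA_real_ else (next_foot - fiducials$foot) / fs
  if (crest <= 0 || systole <= crest || pp <= 0) {
    stop("beat features violate ordering invariants")
  }
  structure(list(crest_time = crest, systole_time = systole,
                 pulse_pressure = pp, pp_interval = ppi),
            class = "beat_features")
}

#' Express a time feature as a percentage of the cardiac cycle
#'
#' Heart-rate compensation: durations are compared across pump settings as a
#' percentage of the measured cycle length.
#'
#' @param value_s Duration in seconds, strictly inside `(0, cycle_s)`.
#' @param cycle_s Cycle length in seconds.
#' @return Percentage of the cycle.
#' @examples
#' normalize_time(0.30, 1.0)   # 30
#' normalize_time(0.30, 0.75)  # 40
#' @export
normalize_time <- function(value_s, cycle_s) {
  if (any(value_s <= 0) || any(cycle_s <= 0)) stop("durations must be positive")
  if (any(value_s >= cycle_s)) {
    stop("feature duration must be shorter than the cycle")
  }
  100 * value_s / cycle_s
}

#' Aggregate per-beat features into one trial-level vector
#'
#' The median across beats is used for every feature (robust to the
#' occasional mis-detected beat), and time features are normalized by the
#' median pulse-to-pulse interval.
#'
#' @param beat_features_list List of `beat_features` from the valid beats of
#'   one trial.
#' @param config The trial's [setup_config()].
#' @return A one-row data.frame of class `feature_vector`: `sv`, `hr`, `w`,
#'   `sha`, `crest_pct`, `systole_pct`, `pp`, `pp_interval`, `n_beats`.
#' @export
aggregate_trial <- function(beat_features_list, config) {
  if (length(beat_features_list) == 0) stop("no valid beats in trial")
  if (length(beat_features_list) < 5) {
    warning("fewer than 5 valid beats: low-confidence aggregate")
  }
  med <- function(field) {
    stats::median(vapply(beat_features_list, function(b) b[[field]],
                         numeric(1)), na.rm = TRUE)
  }
  cycle <- med("pp_interval")
  if (!is.finite(cycle)) cycle <- 60 / config$hr_bpm
  out <- data.frame(
    sv = config$sv_ml, hr = config$hr_bpm, w = config$wall_mm,
    sha = config$shore_a,
    crest_pct = normalize_time(med("crest_time"), cycle),
    systole_pct = normalize_time(med("systole_time"), cycle),
    pp = med("pulse_pressure"),
    pp_interval = cycle,
    n_beats = length(beat_features_list)
  )
  class(out) <- c("feature_vector", "data.frame")
  out
}

#' Engineered feature set
#'
#' Adds the nine engineered features to a trial-level feature vector:
#' `rr` (60/HR), `systole_over_rr`, `crest_over_rr`, the compliance and
#' stiffness proxies `sv_over_pp` and `pp_over_sv`, the wall-thickness
#' interactions `pp_over_w` and `w_times_pp`, and the variance-stabilizing
#' transforms `log1p_pp` and `log1p_sv`.
#'
#' @param fv A `feature_vector` from [aggregate_trial()].
#' @return The feature vector with the nine engineered columns appended.
#' @export
engineer_features <- function(fv) {
  if (fv$pp < 0 || fv$sv <= 0) stop("need pp >= 0 and sv > 0")
  if (fv$pp == 0) stop("division by zero: sv_over_pp undefined at pp = 0")
  rr <- 60 / fv$hr
  fv$rr <- rr
  fv$systole_over_rr <- (fv$systole_pct / 100 * fv$pp_interval) / rr
  fv$crest_over_rr <- (fv$crest_pct / 100 * fv$pp_interval) / rr
  fv$sv_over_pp <- fv$sv / fv$pp
  fv$pp_over_sv <- fv$pp / fv$sv
  fv$pp_over_w <- fv$pp / fv$w
  fv$w_times_pp <- fv$w * fv$pp
  fv$log1p_pp <- log1p(fv$pp)
  fv$log1p_sv <- log1p(fv$sv)
  fv
}

#' Engineered feature column names
#' @return Character vector of the nine engineered feature names.
#' @export
engineered_feature_names <- function() {
  c("rr", "systole_over_rr", "crest_over_rr", "sv_over_pp", "pp_over_sv",
    "pp_over_w", "w_times_pp", "log1p_pp", "log1p_sv")
}

#' Extract the trial-level feature vector from one record
#'
#' Runs the conditioning chain, fiducial detection on the upstream pressure
#' channel, per-beat feature computation and median aggregation, then appends
#' the engineered features.
#'
#' @param record A `waveform_record`.
#' @param spec A [filter_spec()].
#' @param channel Channel to analyse (default `"p1"`).
#' @return A one-row `feature_vector` data.frame with engineered columns.
#' @export
extract_features <- function(record, spec = filter_spec(), channel = "p1") {
  rec <- preprocess_record(record, spec)
  x <- rec$conditioned[[channel]]
  fsets <- detect_all_fiducials(x, rec$fs, rec$config$hr_bpm)
  valid <- Filter(function(f) isTRUE(f$valid), fsets)
  if (length(valid) == 0) stop("no valid beats detected in record")
  feats <- vector("list", length(valid))
  for (i in seq_along(valid)) {
    nf <- if (i < length(valid)) valid[[i + 1]]$foot else NA
    feats[[i]] <- beat_features(valid[[i]], x, rec$fs, next_foot = nf)
  }
  engineer_features(aggregate_trial(feats, rec$config))
}

#' Build the trial-by-feature table for a generated dataset
#'
#' @param dataset Output of [generate_dataset()].
#' @param spec A [filter_spec()].
#' @return A data.frame with one row per trial: setup labels, base features
#'   and the engineered feature set.
#' @export
feature_table <- function(dataset, spec = filter_spec()) {
  rows <- lapply(dataset$records, extract_features, spec = spec)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
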