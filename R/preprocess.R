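#' Filter specification for the signal-conditioning chain
#'
#' The chain is a high-pass zero-phase filter at 0.2 Hz (baseline removal:
#' the maintained 30 mmHg line pressure and sub-0.2 Hz drift), followed by a
#' heart-rate-adaptive low-pass zero-phase filter whose cutoff (3, 6 or 8 Hz)
#' keeps at least four harmonics of the pump fundamental.
#'
#' @param hp_cutoff High-pass cutoff in Hz (default 0.2).
#' @param lp_cutoff Low-pass cutoff in Hz (3, 6 or 8 in the study design).
#' @param filter_order Butterworth order of each single pass (default 4).
#' @return A list of class `filter_spec`.
#' @export
filter_spec <- function(hp_cutoff = 0.2, lp_cutoff = 6, filter_order = 4) {
  if (hp_cutoff <= 0 || lp_cutoff <= hp_cutoff) {
    stop("need 0 < hp_cutoff < lp_cutoff")
  }
  structure(list(hp_cutoff = hp_cutoff, lp_cutoff = lp_cutoff,
                 filter_order = filter_order, zero_phase = TRUE),
            class = "filter_spec")
}

.check_filter_len <- function(signal, fs, cutoff) {
  # forward-backward filtering needs a few time constants of the slowest pole
  if (length(signal) < max(24, ceiling(fs / cutoff))) {
    stop("signal too short for filtering at this cutoff")
  }
}

# filtfilt with odd-reflection end padding sized to the filter time constant,
# so edge transients decay inside the pad instead of the signal
.filtfilt_padded <- function(bf, x, fs, cutoff) {
  n <- length(x)
  pad <- min(n - 1L, as.integer(ceiling(3 * fs / cutoff)))
  pre <- 2 * x[1] - x[(pad + 1L):2L]
  post <- 2 * x[n] - x[(n - 1L):(n - pad)]
  y <- signal::filtfilt(bf, c(pre, x, post))
  y[(pad + 1L):(pad + n)]
}

#' Remove the baseline with a zero-phase high-pass filter
#'
#' 4th-order Butterworth applied forward-backward ([signal::filtfilt]), so
#' there is no group delay: landmark positions are preserved. Removes the
#' constant offset (maintained line pressure) and drift below the cutoff.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate in samples/s.
#' @param hp_cutoff High-pass cutoff in Hz (default 0.2).
#' @param order Butterworth order (default 4).
#' @return Filtered signal, same length.
#' @export
remove_baseline <- function(x, fs, hp_cutoff = 0.2, order = 4) {
  if (fs <= 2 * hp_cutoff) stop("sampling rate too low for this cutoff")
  .check_filter_len(x, fs, hp_cutoff)
  bf <- signal::butter(order, hp_cutoff / (fs / 2), type = "high")
  # demean first: the near-unit-circle high-pass poles amplify roundoff in
  # proportion to the absolute signal level
  .filtfilt_padded(bf, x - mean(x), fs, hp_cutoff)
}

#' Zero-phase low-pass filter
#'
#' @inheritParams remove_baseline
#' @param lp_cutoff Low-pass cutoff in Hz; must be below the Nyquist rate.
#' @return Filtered signal, same length.
#' @export
lowpass_zero_phase <- function(x, fs, lp_cutoff, order = 4) {
  if (lp_cutoff >= fs / 2) stop("cutoff must be below the Nyquist frequency")
  .check_filter_len(x, fs, lp_cutoff)
  bf <- signal::butter(order, lp_cutoff / (fs / 2), type = "low")
  .filtfilt_padded(bf, x, fs, lp_cutoff)
}

#' Select the adaptive low-pass cutoff for a nominal heart rate
#'
#' Maps the nearest nominal pump rate to its cutoff: 30 bpm -> 3 Hz,
#' 60 bpm -> 6 Hz, 80 bpm -> 8 Hz. Each choice retains at least the first
#' four harmonics of the fundamental (4 * HR/60 <= cutoff). Rates whose
#' fourth harmonic would exceed the largest cutoff (above 120 bpm) are
#' rejected.
#'
#' @param heart_rate_nominal Heart rate in bpm.
#' @return Cutoff frequency in Hz (3, 6 or 8).
#' @examples
#' select_cutoff(80)   # 8
#' select_cutoff(59.4) # 6
#' @export
select_cutoff <- function(heart_rate_nominal) {
  if (heart_rate_nominal <= 0) stop("heart rate must be positive")
  if (4 * heart_rate_nominal / 60 > 8) {
    stop("unsupported rate: fourth harmonic exceeds 8 Hz above 120 bpm")
  }
  nominal <- c(30, 60, 80)
  cutoffs <- c(3, 6, 8)
  cutoffs[which.min(abs(nominal - heart_rate_nominal))]
}

# Welch power spectral density: averaged Hann-windowed periodograms over
# 50%-overlapping segments.
.welch_psd <- function(x, fs, seg_len = NULL, overlap = 0.5) {
  n <- length(x)
  if (is.null(seg_len)) seg_len <- min(8 * fs, n)
  seg_len <- as.integer(seg_len)
  step <- max(1L, as.integer(seg_len * (1 - overlap)))
  starts <- seq(1L, n - seg_len + 1L, by = step)
  if (length(starts) < 2) stop("signal shorter than two Welch segments")
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg_len) / (seg_len + 1))  # Hann
  U <- sum(w^2)
  acc <- 0
  for (s in starts) {
    seg <- x[s:(s + seg_len - 1L)]
    seg <- (seg - mean(seg)) * w
    acc <- acc + Mod(stats::fft(seg))^2 / (U * fs)
  }
  p <- acc / length(starts)
  half <- seq_len(floor(seg_len / 2) + 1L)
  list(frequencies = (half - 1) * fs / seg_len, power = p[half])
}

#' Estimate the fundamental frequency by Welch's method
#'
#' Welch power spectral density (8 s Hann segments, 50% overlap) with the
#' fundamental taken as the maximum-power bin in the 0.2-3 Hz pump band.
#' Flagged low-confidence when that peak is below three times the median
#' in-band power (no clear periodicity).
#'
#' @param x Numeric signal, at least ~12 s so two Welch segments fit.
#' @param fs Sampling rate in samples/s.
#' @param band Search band in Hz (default `c(0.2, 3)`).
#' @return A list of class `spectrum_estimate`: `frequencies`, `power`, `f0`,
#'   `low_confidence`.
#' @export
estimate_fundamental <- function(x, fs, band = c(0.2, 3)) {
  ps <- .welch_psd(x, fs)
  sel <- ps$frequencies >= band[1] & ps$frequencies <= band[2]
  if (!any(sel)) stop("search band not resolvable at this segment length")
  pk <- which.max(ps$power[sel])
  f0 <- ps$frequencies[sel][pk]
  low_conf <- ps$power[sel][pk] < 3 * stats::median(ps$power[sel])
  structure(list(frequencies = ps$frequencies, power = ps$power,
                 f0 = f0, low_confidence = low_conf),
            class = "spectrum_estimate")
}

#' Normalize a signal to the amplitude range [0, 1]
#'
#' Affine map sending the minimum to 0 and the maximum to 1. The scale and
#' offset are attached as attributes so amplitude features (pulse pressure)
#' can still be computed from pre-normalization units.
#'
#' @param x Numeric signal with `max(x) > min(x)`.
#' @return Normalized signal with attributes `scale` and `offset` such that
#'   `x == normalized * scale + offset`.
#' @examples
#' normalize_amplitude(c(2, 4, 6))  # 0, 0.5, 1
#' @export
normalize_amplitude <- function(x) {
  r <- range(x)
  if (r[1] >= r[2]) stop("degenerate range: constant signal cannot be normalized")
  y <- (x - r[1]) / (r[2] - r[1])
  attr(y, "scale") <- r[2] - r[1]
  attr(y, "offset") <- r[1]
  y
}

#' Apply the full conditioning chain to a waveform record
#'
#' Baseline removal, adaptive low-pass selection from the nominal heart rate,
#' low-pass filtering, and per-record amplitude normalization, per channel.
#' Both the conditioned (pre-normalization) and normalized signals are kept:
#' time features use the normalized shape, pulse pressure uses
#' pre-normalization amplitudes.
#'
#' @param record A `waveform_record`.
#' @param spec A [filter_spec()]; its `lp_cutoff` is overridden by the
#'   adaptive choice unless `adaptive = FALSE`.
#' @param adaptive Select the low-pass cutoff from the record's nominal heart
#'   rate (default TRUE).
#' @return The record with an added `conditioned` element (data.frame, same
#'   channels, baseline removed and low-passed), `normalized` (each channel
#'   mapped to `[0,1]`) and `lp_cutoff_used`.
#' @export
preprocess_record <- function(record, spec = filter_spec(), adaptive = TRUE) {
  lp <- if (adaptive) select_cutoff(record$config$hr_bpm) else spec$lp_cutoff
  cond <- record$channels
  norm <- record$channels
  for (j in seq_along(cond)) {
    y <- remove_baseline(record$channels[[j]], record$fs,
                         spec$hp_cutoff, spec$filter_order)
    y <- lowpass_zero_phase(y, record$fs, lp, spec$filter_order)
    cond[[j]] <- y
    norm[[j]] <- normalize_amplitude(y)
  }
  record$conditioned <- cond
  record$normalized <- norm
  record$lp_cutoff_used <- lp
  record
}
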