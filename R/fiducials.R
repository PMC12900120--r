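#' Central-difference derivatives of a conditioned signal
#'
#' First, second and third derivatives by repeated central differences scaled
#' by the sampling rate, with edge replication so all outputs keep the input
#' length. Meaningful only on band-limited (low-passed) signals.
#'
#' @param x Numeric signal, length >= 5.
#' @param fs Sampling rate in samples/s.
#' @return A list with `d1`, `d2`, `d3`.
#' @export
derivatives <- function(x, fs) {
  if (length(x) < 5) stop("signal too short for third derivatives")
  cdiff <- function(v) {
    n <- length(v)
    d <- c(v[2] - v[1], (v[3:n] - v[1:(n - 2)]) / 2, v[n] - v[n - 1]) * fs
    d
  }
  d1 <- cdiff(x)
  d2 <- cdiff(d1)
  d3 <- cdiff(d2)
  list(d1 = d1, d2 = d2, d3 = d3)
}

#' Segment a conditioned signal into beats around systolic peaks
#'
#' Finds systolic peaks as local maxima separated by a refractory period of
#' 0.6 nominal cycles and at least a quarter of the signal range above its
#' median, then forms beat windows spanning midpoint-to-midpoint between
#' adjacent peaks.
#'
#' @param x Conditioned (baseline-removed, low-passed) signal.
#' @param fs Sampling rate in samples/s.
#' @param hr_hint Nominal heart rate in bpm (sets the refractory period).
#' @return A list of beats, each a list with `start`, `end`, `peak` (sample
#'   indices into `x`, 1-based). Empty (with a warning) when no peaks exist.
#' @export
segment_beats <- function(x, fs, hr_hint) {
  if (hr_hint <= 0) stop("hr_hint must be positive")
  refractory <- max(1L, floor(0.6 * (60 / hr_hint) * fs))
  thresh <- stats::median(x) + 0.25 * (max(x) - stats::median(x))
  if (max(x) - min(x) < .Machine$double.eps^0.5 * max(abs(x), 1)) {
    warning("no peaks found: flat signal")
    return(list())
  }
  pk <- pracma::findpeaks(x, minpeakdistance = refractory,
                          minpeakheight = thresh, sortstr = FALSE)
  if (is.null(pk)) {
    warning("no peaks found")
    return(list())
  }
  peaks <- sort(pk[, 2])
  n <- length(x)
  mids <- if (length(peaks) > 1) {
    floor((peaks[-length(peaks)] + peaks[-1]) / 2)
  } else integer(0)
  starts <- as.integer(c(1L, mids + 1L))
  ends <- as.integer(c(mids, n))
  peaks <- as.integer(peaks)
  mapply(function(s, e, p) list(start = s, end = e, peak = p),
         starts, ends, peaks, SIMPLIFY = FALSE)
}

# sign-change positions of v: returns indices i where v[i] and v[i+1] differ
# in sign in the requested direction
.crossings <- function(v, dir = c("up", "down", "any")) {
  dir <- match.arg(dir)
  s <- sign(v)
  i <- seq_len(length(v) - 1)
  cross <- switch(dir,
    up = which(s[i] < 0 & s[i + 1] >= 0),
    down = which(s[i] > 0 & s[i + 1] <= 0),
    any = which(s[i] * s[i + 1] < 0 | (s[i] != 0 & s[i + 1] == 0))
  )
  cross
}

#' Detect fiducial points within one beat window
#'
#' Zero-crossing analysis of the first three derivatives:
#' * foot — last negative-to-positive crossing of the first derivative before
#'   the systolic peak ("the last minimum before the systolic peak"); falls
#'   back to the pre-peak minimum when filtering leaves no sign change;
#' * rising steep — maximum upslope (argmax of d1) between foot and peak;
#' * falling steep — first local minimum of d1 after the rising steep;
#' * dicrotic notch — first zero-crossing of the third derivative after the
#'   systolic peak, absent when none occurs before the window end.
#'
#' Beats whose landmarks violate the ordering
#' foot < rising < peak < falling are flagged invalid.
#'
#' @param beat A beat window from [segment_beats()].
#' @param x The conditioned signal the beat indexes into (for the argmin
#'   fallback of the foot).
#' @param d Derivative list from [derivatives()] (full-signal indices).
#' @param fs Sampling rate in samples/s.
#' @return A list of class `fiducial_set` with 1-based full-signal sample
#'   indices `foot`, `rising_steep`, `systolic_peak`, `falling_steep`,
#'   `dicrotic_notch` (NA when absent) and `valid`.
#' @export
detect_fiducials <- function(beat, x, d, fs) {
  s <- beat$start; e <- beat$end; p <- beat$peak
  out <- list(foot = NA_integer_, rising_steep = NA_integer_,
              systolic_peak = p, falling_steep = NA_integer_,
              dicrotic_notch = NA_integer_, valid = FALSE)
  class(out) <- "fiducial_set"
  if (p <= s + 2 || p >= e - 2) return(out)

  d1 <- d$d1[s:e]
  rel_p <- p - s + 1L

  up <- .crossings(d1[seq_len(rel_p)], "up")
  foot_rel <- if (length(up)) {
    i <- max(up)  # crossing between i and i+1: take the sample nearer zero
    if (abs(d1[i]) <= abs(d1[i + 1])) i else i + 1L
  } else which.min(x[s:p])
  out$foot <- s + foot_rel - 1L

  if (out$foot >= p) return(out)
  rise_rel <- which.max(d$d1[out$foot:p])
  out$rising_steep <- out$foot + rise_rel - 1L

  # first local minimum of d1 after the rising steep
  seg <- d$d1[out$rising_steep:e]
  loc_min <- which(diff(sign(diff(seg))) > 0) + 1L
  if (length(loc_min)) out$falling_steep <- out$rising_steep + loc_min[1] - 1L

  # dicrotic notch: first d3 sign change strictly after the systolic peak
  if (p + 2 <= e) {
    d3seg <- d$d3[(p + 1):e]
    cr <- .crossings(d3seg, "any")
    if (length(cr)) out$dicrotic_notch <- p + cr[1]
  }

  ok <- !is.na(out$falling_steep) &&
    out$foot < out$rising_steep && out$rising_steep < out$systolic_peak &&
    out$systolic_peak < out$falling_steep &&
    (is.na(out$dicrotic_notch) || out$dicrotic_notch > out$systolic_peak)
  out$valid <- ok
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Detect fiducials for every beat of a conditioned signal
#'
#' @param x Conditioned signal.
#' @param fs Sampling rate in samples/s.
#' @param hr_hint Nominal heart rate in bpm.
#' @return List of `fiducial_set`, one per detected beat (invalid beats
#'   retained but flagged).
#' @export
detect_all_fiducials <- function(x, fs, hr_hint) {
  beats <- segment_beats(x, fs, hr_hint)
  d <- derivatives(x, fs)
  n <- length(x)
  lapply(seq_along(beats), function(i) {
    fset <- detect_fiducials(beats[[i]], x, d, fs)
    fset$beat_index <- i
    # windows clipped at the record ends are not midpoint-to-midpoint beats
    # and sit in the filter-transient region: excluded from aggregation
    if (beats[[i]]$start == 1L || beats[[i]]$end == n) fset$valid <- FALSE
    fset
  })
}

#' Per-landmark detection rates
#'
#' @param fiducial_sets List of `fiducial_set`.
#' @param expected_beats Number of beats expected in the record (> 0).
#' @return A list of class `detection_report`: `expected_beats`, `detected`
#'   and `success_rate` (percent) per landmark.
#' @export
detection_rate <- function(fiducial_sets, expected_beats) {
  if (expected_beats <= 0) stop("expected_beats must be positive")
  landmarks <- c("foot", "rising_steep", "systolic_peak",
                 "falling_steep", "dicrotic_notch")
  detected <- vapply(landmarks, function(lm) {
    sum(vapply(fiducial_sets,
               function(f) isTRUE(f$valid) && !is.na(f[[lm]]), logical(1)))
  }, numeric(1))
  structure(list(expected_beats = expected_beats, detected = detected,
                 success_rate = 100 * detected / expected_beats),
            class = "detection_report")
}

#' @export
print.detection_report <- function(x, ...) {
  cat("Detection report (", x$expected_beats, "beats expected )\n")
  for (lm in names(x$detected)) {
    cat(sprintf("  %-14s %3d detected (%.2f%%)\n",
                lm, x$detected[[lm]], x$success_rate[[lm]]))
  }
  invisible(x)
}
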