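#' Experimental setup configuration
#'
#' A setup configuration describes one trial of the phantom experiment: the
#' pump settings (stroke volume, heart rate) and the silicone vessel segment
#' (wall thickness, Shore A hardness). These four quantities are both the
#' tunable experimental conditions and the covariates of the hardness models.
#'
#' @param sv_ml Stroke volume in mL (grid values: 10, 20).
#' @param hr_bpm Nominal pump heart rate in beats per minute (grid: 30, 60, 80).
#' @param wall_mm Vessel wall thickness in mm (grid: 1, 1.5, 2).
#' @param shore_a Shore A hardness of the vessel material (grid: 10..50).
#' @return A one-row `data.frame` of class `setup_config`.
#' @examples
#' setup_config(10, 60, 1.5, 30)
#' @export
setup_config <- function(sv_ml, hr_bpm, wall_mm, shore_a) {
  stopifnot(length(sv_ml) == 1, length(hr_bpm) == 1,
            length(wall_mm) == 1, length(shore_a) == 1)
  if (any(c(sv_ml, hr_bpm, wall_mm, shore_a) <= 0) ||
      !all(is.finite(c(sv_ml, hr_bpm, wall_mm, shore_a)))) {
    stop("all setup parameters must be finite and positive")
  }
  out <- data.frame(sv_ml = sv_ml, hr_bpm = hr_bpm,
                    wall_mm = wall_mm, shore_a = shore_a)
  class(out) <- c("setup_config", "data.frame")
  out
}

#' Build the factorial grid of setup configurations
#'
#' Forms the Cartesian product of the supplied stroke volumes, heart rates,
#' wall thicknesses and hardness levels, in deterministic order: stroke volume
#' varies slowest, Shore A hardness fastest. The study grid
#' (2 SV x 3 HR x 3 W x 5 ShA) yields 90 configurations; the reduced
#' three-class hardness grid yields 54.
#'
#' @param sv_list,hr_list,w_list,sha_list Positive numeric vectors of grid
#'   levels. Defaults reproduce the full experimental grid.
#' @return A `data.frame` with columns `sv_ml`, `hr_bpm`, `wall_mm`, `shore_a`,
#'   one row per configuration.
#' @examples
#' nrow(make_config_grid())                                  # 90
#' nrow(make_config_grid(sha_list = c(10, 20, 30)))          # 54
#' @export
make_config_grid <- function(sv_list = c(10, 20),
                             hr_list = c(30, 60, 80),
                             w_list = c(1, 1.5, 2),
                             sha_list = c(10, 20, 30, 40, 50)) {
  for (v in list(sv_list, hr_list, w_list, sha_list)) {
    if (length(v) == 0) stop("grid level lists must be non-empty")
    if (any(!is.finite(v)) || any(v <= 0)) stop("grid levels must be positive")
  }
  # expand.grid varies the first factor fastest -> shore_a minor, sv major
  g <- expand.grid(shore_a = sha_list, wall_mm = w_list,
                   hr_bpm = hr_list, sv_ml = sv_list,
                   KEEP.OUT.ATTRS = FALSE)
  g <- g[, c("sv_ml", "hr_bpm", "wall_mm", "shore_a")]
  rownames(g) <- NULL
  g
}

#' Generator parameters for synthetic waveform records
#'
#' Controls the morphology, nuisance terms and ground-truth physics of the
#' synthetic two-site records. The defaults emulate the phantom study
#' conditions: a maintained 30 mmHg baseline, 200 samples/s acquisition
#' (2000 samples/s for the reference transit-time mode), a 30 cm sensor
#' separation, pulse pressure and systole fraction increasing with hardness,
#' and a dicrotic lobe shrinking with hardness. Ground-truth PWV is derived
#' from the selected Shore-A-to-elasticity conversion through the
#' Moens-Korteweg relation, and the downstream channels are the upstream
#' signal delayed by `distance / pwv_true`.
#'
#' @param fs Sampling rate in samples/s (200 or 2000 in the study design).
#' @param duration Record length in seconds.
#' @param noise_sd Additive white-noise standard deviation, as a fraction of
#'   the trial's pulse pressure.
#' @param drift_amp,drift_freq Baseline drift sinusoid amplitude (signal
#'   units) and frequency (Hz; must stay below the 0.2 Hz baseline-removal
#'   cutoff so conditioning can cancel it).
#' @param mean_offset Constant baseline in signal units (the maintained
#'   30 mmHg line pressure).
#' @param pp_base,pp_sv,pp_sha Affine map from (SV, ShA) to pulse pressure:
#'   `pp = pp_base + pp_sv*SV + pp_sha*ShA`.
#' @param zeta_base,zeta_sha Affine map from ShA to the systole fraction
#'   `zeta` of the cycle: `zeta = zeta_base + zeta_sha*ShA`.
#' @param dicrotic_base,dicrotic_sha Affine map from ShA to the dicrotic lobe
#'   amplitude as a fraction of the systolic lobe.
#' @param pp_jitter_sd Relative log-normal jitter on pulse pressure per trial
#'   (material/assembly variability).
#' @param zeta_jitter_sd Absolute Gaussian jitter on the systole fraction.
#' @param hr_jitter_sd Relative jitter of the realized pump rate around the
#'   nominal heart rate.
#' @param conversion_model Conversion defining ground-truth elasticity/PWV
#'   (default `"Ruess"`).
#' @param distance Pressure-sensor separation in metres (default 0.30).
#' @param attenuation Amplitude scale factor applied to the downstream
#'   pressure channel.
#' @param constants [pwv_constants()] giving fluid density and inner diameter.
#' @param seed Integer seed; every stochastic draw in the generator descends
#'   from it.
#' @return A list of class `generator_params`.
#' @export
generator_params <- function(fs = 200, duration = 20, noise_sd = 0.02,
                             drift_amp = 1, drift_freq = 0.05,
                             mean_offset = 30,
                             pp_base = 8, pp_sv = 0.6, pp_sha = 0.25,
                             zeta_base = 0.22, zeta_sha = 0.003,
                             dicrotic_base = 0.18, dicrotic_sha = -0.002,
                             pp_jitter_sd = 0.03, zeta_jitter_sd = 0.005,
                             hr_jitter_sd = 0.005,
                             conversion_model = "Ruess",
                             distance = 0.30, attenuation = 0.95,
                             constants = pwv_constants(),
                             seed = 1L) {
  if (drift_freq >= 0.2) stop("drift_freq must be below the 0.2 Hz baseline cutoff")
  if (fs <= 0 || duration <= 0) stop("fs and duration must be positive")
  structure(list(fs = fs, duration = duration, noise_sd = noise_sd,
                 drift_amp = drift_amp, drift_freq = drift_freq,
                 mean_offset = mean_offset,
                 pp_base = pp_base, pp_sv = pp_sv, pp_sha = pp_sha,
                 zeta_base = zeta_base, zeta_sha = zeta_sha,
                 dicrotic_base = dicrotic_base, dicrotic_sha = dicrotic_sha,
                 pp_jitter_sd = pp_jitter_sd, zeta_jitter_sd = zeta_jitter_sd,
                 hr_jitter_sd = hr_jitter_sd,
                 conversion_model = conversion_model,
                 distance = distance, attenuation = attenuation,
                 constants = constants, seed = as.integer(seed)),
            class = "generator_params")
}

# Morphology maps (deterministic part, before per-trial jitter)
.morph_targets <- function(config, params) {
  pp <- params$pp_base + params$pp_sv * config$sv_ml +
    params$pp_sha * config$shore_a
  zeta <- params$zeta_base + params$zeta_sha * config$shore_a
  dic <- params$dicrotic_base + params$dicrotic_sha * config$shore_a
  if (zeta <= 0.15 || zeta >= 0.6) {
    stop("systole fraction outside (0.15, 0.6); adjust zeta map")
  }
  list(pp = pp, zeta = max(zeta, 0.16), dic = max(dic, 0))
}

# Continuous beat model: systolic and dicrotic Gaussian lobes plus a sharp
# onset dip that pins the pulse foot (real feet are sharp: near-flat
# diastole broken by a rapid upstroke). Closed-form value and derivative of
# the T-periodic template (neighbouring periods included so the inter-beat
# region is well defined).
.template_fun <- function(T, pp, zeta, dic, offset) {
  sigma_s <- zeta * T / 3.5
  mu_s <- 0.04 * T + 2.5 * sigma_s
  mu_d <- mu_s + 3.2 * sigma_s
  sigma_d <- 0.8 * sigma_s
  mu_f <- mu_s - 2.2 * sigma_s   # onset dip location (the foot)
  sigma_f <- 0.8 * sigma_s
  dip <- 0.15
  lobe <- function(t, mu, sigma) exp(-(t - mu)^2 / (2 * sigma^2))
  dlobe <- function(t, mu, sigma) -(t - mu) / sigma^2 * lobe(t, mu, sigma)
  unit <- function(t) {
    v <- 0
    for (k in -2:2) {
      tk <- t - k * T
      v <- v + lobe(tk, mu_s, sigma_s) + dic * lobe(tk, mu_d, sigma_d) -
        dip * lobe(tk, mu_f, sigma_f)
    }
    v
  }
  dunit <- function(t) {
    v <- 0
    for (k in -2:2) {
      tk <- t - k * T
      v <- v + dlobe(tk, mu_s, sigma_s) + dic * dlobe(tk, mu_d, sigma_d) -
        dip * dlobe(tk, mu_f, sigma_f)
    }
    v
  }
  # scale so max - min over one period equals pp
  tt <- seq(0, T, length.out = 4096)
  u <- unit(tt)
  A <- pp / (max(u) - min(u))
  list(f = function(t) offset + A * unit(t),
       df = function(t) A * dunit(t),
       mu_s = mu_s, sigma_s = sigma_s, mu_d = mu_d, sigma_d = sigma_d,
       A = A, T = T)
}

# Landmark truth of the continuous template, by sign-change bracketing on the
# closed-form derivative followed by uniroot refinement.
.template_landmarks <- function(tpl, fs) {
  T <- tpl$T
  grid <- seq(-0.5 * T, T, length.out = 8192)
  d <- tpl$df(grid)
  sgn <- sign(d)
  idx <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  roots <- vapply(idx, function(i) {
    stats::uniroot(tpl$df, lower = grid[i], upper = grid[i + 1],
                   tol = 1e-12)$root
  }, numeric(1))
  kind <- ifelse(d[idx] > 0, "max", "min")  # + -> - is a maximum
  # systolic peak: the maximum closest to mu_s
  maxima <- roots[kind == "max"]
  peak <- maxima[which.min(abs(maxima - tpl$mu_s))]
  minima <- roots[kind == "min"]
  foot <- max(minima[minima < peak])
  # dicrotic notch: first minimum after the peak within the same period,
  # present only when the dicrotic lobe creates one
  after <- minima[minima > peak & minima < peak + 0.9 * T]
  # exclude the next inter-beat valley (it is the next beat's foot)
  next_foot <- foot + T
  after <- after[abs(after - next_foot) > 0.05 * T]
  notch <- if (length(after)) min(after) else NA_real_
  # rising steep: argmax of f' in (foot, peak); falling steep: first local
  # minimum of f' after the rising steep
  h <- 0.25 / fs
  d2 <- function(t) (tpl$df(t + h) - tpl$df(t - h)) / (2 * h)
  rising <- stats::optimize(tpl$df, lower = foot, upper = peak,
                            maximum = TRUE, tol = 1e-10)$maximum
  upper_fall <- if (is.na(notch)) peak + 3 * tpl$sigma_s else notch
  falling <- stats::optimize(tpl$df, lower = peak, upper = upper_fall,
                             tol = 1e-10)$minimum
  list(foot = foot, rising = rising, peak = peak,
       falling = falling, notch = notch)
}

#' Single-cycle beat template with analytic landmark truth
#'
#' Builds one period of the two-Gaussian-lobe beat model (systolic lobe plus
#' dicrotic lobe on a constant baseline) for a configuration, and returns the
#' landmark times (foot, rising steep, systolic peak, falling steep, dicrotic
#' notch) computed from the continuous template by root finding, i.e. exact up
#' to numerical tolerance rather than read off the sampled grid.
#'
#' @param config A [setup_config()] (or one row of [make_config_grid()]).
#' @param params A [generator_params()].
#' @return A list with `time`, `signal` (one sampled period), `truth`
#'   (landmark times in seconds), `pp_true`, `zeta_true`, `period`.
#' @export
beat_template <- function(config, params = generator_params()) {
  T <- 60 / config$hr_bpm
  if (T * params$fs < 20) {
    stop("cycle not representable: fewer than 20 samples per period")
  }
  m <- .morph_targets(config, params)
  tpl <- .template_fun(T, m$pp, m$zeta, m$dic, params$mean_offset)
  lm_ <- .template_landmarks(tpl, params$fs)
  tt <- seq(0, T - 1 / params$fs, by = 1 / params$fs)
  zeta_true <- (lm_$falling - lm_$foot) / T
  list(time = tt, signal = tpl$f(tt), truth = lm_,
       pp_true = m$pp, zeta_true = zeta_true, period = T,
       fun = tpl$f)
}

# derive a per-config sub-seed stably from the master seed and grid position
.sub_seed <- function(seed, position) {
  as.integer((as.numeric(seed) * 1103L + position * 7919) %% 2147483647)
}

#' Generate one synthetic two-site waveform record
#'
#' Tiles the beat template over the record duration, forms the downstream
#' channels by delaying the clean upstream signal by the ground-truth transit
#' time (fractional-sample delay via linear interpolation) and scaling by an
#' attenuation factor, then adds the baseline drift sinusoid and white noise.
#' Channel geometry mirrors the phantom: pressure sensors `p1`/`p2` at the
#' segment ends (separation `distance`), capacitive sensors `c1`/`c2` at 1/6
#' and 5/6 of the separation.
#'
#' The ground-truth transit time is `distance / pwv_true`, with `pwv_true`
#' from the configured Shore-A-to-elasticity conversion and the Moens-Korteweg
#' relation evaluated at the configuration's hardness and wall thickness.
#'
#' @param config A [setup_config()] row.
#' @param params A [generator_params()].
#' @param position Grid position used to derive the per-record sub-seed.
#' @return A list of class `waveform_record` with elements `time`, `channels`
#'   (data.frame `p1`, `c1`, `c2`, `p2`), `fs`, `config` and `truth` (a
#'   ground-truth bundle: `elasticity` MPa, `pwv_true` m/s, `delay_true` s,
#'   `foot_times` s, `pp_true`, `zeta_true`, realized heart rate `hr_actual`).
#' @examples
#' rec <- generate_record(setup_config(10, 60, 1, 10),
#'                        generator_params(duration = 10, seed = 7))
#' rec$truth$pwv_true
#' @export
generate_record <- function(config, params = generator_params(), position = 1L) {
  E <- shore_to_elasticity(config$shore_a, params$conversion_model)
  pwv_true <- moens_korteweg(E, config$wall_mm, params$constants)
  delay <- params$distance / pwv_true
  T_nom <- 60 / config$hr_bpm
  if (delay >= T_nom) stop("unphysical configuration: transit time exceeds one cycle")

  seed <- .sub_seed(params$seed, position)
  set.seed(seed)

  # per-trial morphology jitter (material/assembly variability)
  m <- .morph_targets(config, params)
  pp <- m$pp * exp(stats::rnorm(1, 0, params$pp_jitter_sd))
  zeta <- min(max(m$zeta + stats::rnorm(1, 0, params$zeta_jitter_sd), 0.16), 0.59)
  hr_actual <- config$hr_bpm * exp(stats::rnorm(1, 0, params$hr_jitter_sd))
  T <- 60 / hr_actual
  if (T * params$fs < 20) stop("cycle not representable at this sampling rate")

  tpl <- .template_fun(T, pp, zeta, m$dic, params$mean_offset)
  lm_ <- .template_landmarks(tpl, params$fs)

  n <- round(params$duration * params$fs)
  tt <- (seq_len(n) - 1) / params$fs
  clean_at <- function(t) tpl$f(t %% T)  # template is T-periodic by construction
  up <- clean_at(tt)

  # fractional delay by linear interpolation on an extended grid
  pad <- ceiling((delay + T) * params$fs)
  text <- c(-(pad:1) / params$fs, tt)
  yext <- clean_at(text)
  delayed <- function(d, scale) {
    y <- stats::approx(text, yext, xout = tt - d)$y
    params$mean_offset + scale * (y - params$mean_offset)
  }
  ch <- data.frame(
    p1 = up,
    c1 = delayed(delay / 6, 1),
    c2 = delayed(delay * 5 / 6, 1),
    p2 = delayed(delay, params$attenuation)
  )

  drift <- params$drift_amp * sin(2 * pi * params$drift_freq * tt)
  noise_sd <- params$noise_sd * pp
  for (j in seq_along(ch)) {
    ch[[j]] <- ch[[j]] + drift +
      (if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else 0)
  }

  k_max <- floor((params$duration - lm_$foot) / T)
  foot_times <- lm_$foot + T * (0:max(k_max, 0))
  foot_times <- foot_times[foot_times < params$duration]

  structure(list(
    time = tt, channels = ch, fs = params$fs, config = config,
    truth = list(elasticity = E, pwv_true = pwv_true, delay_true = delay,
                 foot_times = foot_times, pp_true = pp,
                 zeta_true = (lm_$falling - lm_$foot) / T,
                 hr_actual = hr_actual, landmarks = lm_, period = T)
  ), class = "waveform_record")
}

#' @export
print.waveform_record <- function(x, ...) {
  cat("<waveform_record> fs =", x$fs, "Hz,", length(x$time), "samples,",
      ncol(x$channels), "channels\n")
  cat("  config: SV", x$config$sv_ml, "mL, HR", x$config$hr_bpm,
      "bpm, W", x$config$wall_mm, "mm, ShA", x$config$shore_a, "\n")
  if (!is.null(x$truth)) {
    cat(sprintf("  truth: PWV %.2f m/s, delay %.4f s, PP %.1f\n",
                x$truth$pwv_true, x$truth$delay_true, x$truth$pp_true))
  }
  invisible(x)
}

#' Generate a dataset of records over a configuration grid
#'
#' One record per grid row, each with a stable per-position sub-seed so the
#' whole dataset is reproducible and duplicate configurations differ only in
#' their noise realization.
#'
#' @param grid A configuration grid from [make_config_grid()].
#' @param params A [generator_params()].
#' @return A list with `records` (list of `waveform_record`) and `labels`
#'   (data.frame of per-trial ground truth keyed by configuration).
#' @export
generate_dataset <- function(grid, params = generator_params()) {
  if (is.null(nrow(grid)) || nrow(grid) == 0) stop("configuration grid is empty")
  records <- vector("list", nrow(grid))
  labels <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cfg <- setup_config(grid$sv_ml[i], grid$hr_bpm[i],
                        grid$wall_mm[i], grid$shore_a[i])
    rec <- generate_record(cfg, params, position = i)
    records[[i]] <- rec
    labels[[i]] <- data.frame(
      trial = i, sv_ml = cfg$sv_ml, hr_bpm = cfg$hr_bpm,
      wall_mm = cfg$wall_mm, shore_a = cfg$shore_a,
      elasticity = rec$truth$elasticity, pwv_true = rec$truth$pwv_true,
      delay_true = rec$truth$delay_true, pp_true = rec$truth$pp_true,
      zeta_true = rec$truth$zeta_true, hr_actual = rec$truth$hr_actual
    )
  }
  list(records = records, labels = do.call(rbind, labels))
}
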