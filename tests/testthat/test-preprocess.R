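test_that("baseline removal cancels DC and passes the pulse band", {
  fs <- 200
  t <- (0:(60 * fs - 1)) / fs
  # constant held pressure is annihilated
  y <- remove_baseline(rep(30, length(t)), fs)
  expect_lt(max(abs(y)), 1e-6)

  # a 1 Hz pulse-band sine survives with amplitude error < 1%
  y <- remove_baseline(30 + sin(2 * pi * 1 * t), fs)
  mid <- y[(20 * fs):(40 * fs)]
  expect_lt(abs(max(mid) - 1), 0.01)
  expect_lt(abs(min(mid) + 1), 0.01)

  # 0.05 Hz drift: the squared 4th-order Butterworth response at f/fc = 0.25
  # is (1 + (0.2/0.05)^8)^-1, about -96 dB, so >= 20 dB is comfortably met;
  # assert the measured attenuation
  y <- remove_baseline(sin(2 * pi * 0.05 * t), fs)
  expect_lt(max(abs(y[(20 * fs):(40 * fs)])), 10^(-20 / 20))

  expect_error(remove_baseline(rnorm(50), fs), "too short")
})

test_that("zero-phase filtering leaves landmark positions unchanged", {
  fs <- 200
  t <- (0:(30 * fs - 1)) / fs
  pulse <- exp(-(t - 15)^2 / (2 * 0.05^2))  # isolated synthetic pulse
  y <- lowpass_zero_phase(remove_baseline(pulse + 30, fs), fs, 8)
  expect_lt(abs(which.max(y) - which.max(pulse)), 2)
})

test_that("low-pass attenuates far stopband and passes the passband", {
  fs <- 200
  t <- (0:(40 * fs - 1)) / fs
  y <- lowpass_zero_phase(sin(2 * pi * 50 * t), fs, 6)
  expect_lt(max(abs(y[(10 * fs):(30 * fs)])), 10^(-40 / 20))

  xin <- sin(2 * pi * 1 * t) + 0.3 * sin(2 * pi * 2 * t)
  y <- lowpass_zero_phase(xin, fs, 6)
  mid <- (10 * fs):(30 * fs)
  expect_lt(max(abs(y[mid] - xin[mid])), 0.01 * diff(range(xin)))

  expect_error(lowpass_zero_phase(rnorm(1000), fs, 120), "Nyquist")
})

test_that("adaptive cutoff maps nominal rates and rejects fast rates", {
  expect_equal(select_cutoff(30), 3)
  expect_equal(select_cutoff(60), 6)
  expect_equal(select_cutoff(80), 8)
  expect_equal(select_cutoff(59.4), 6)   # nearest-nominal rule
  expect_equal(vapply(c(30, 60, 80), select_cutoff, numeric(1)), c(3, 6, 8))
  # every choice keeps >= 4 harmonics
  for (hr in c(30, 60, 80)) expect_lte(4 * hr / 60, select_cutoff(hr))
  expect_error(select_cutoff(150), "unsupported")
})

test_that("Welch fundamental estimation finds the pump rate", {
  fs <- 200
  t <- (0:(60 * fs - 1)) / fs
  sp <- estimate_fundamental(sin(2 * pi * 1 * t), fs)
  expect_equal(sp$f0, 1, tolerance = fs / (8 * fs))  # one bin width
  expect_false(sp$low_confidence)

  # synthetic HR=30 record has a 0.5 Hz fundamental
  rec <- generate_record(setup_config(10, 30, 1, 30),
                         quiet_params(duration = 40, seed = 2))
  sp <- estimate_fundamental(rec$channels$p1 - 30, rec$fs)
  expect_equal(sp$f0, 0.5, tolerance = 0.13)

  # white noise: no clear peak -> low-confidence flag
  set.seed(4)
  sp <- estimate_fundamental(rnorm(60 * fs), fs)
  expect_true(sp$low_confidence)

  expect_error(estimate_fundamental(rnorm(3 * fs), fs), "segments")
})

test_that("amplitude normalization is an affine [0,1] map", {
  y <- normalize_amplitude(c(2, 4, 6))
  expect_equal(as.numeric(y), c(0, 0.5, 1))
  expect_equal(as.numeric(y) * attr(y, "scale") + attr(y, "offset"),
               c(2, 4, 6))
  # idempotence
  set.seed(1)
  x <- rnorm(100)
  expect_equal(as.numeric(normalize_amplitude(as.numeric(normalize_amplitude(x)))),
               as.numeric(normalize_amplitude(x)))
  expect_error(normalize_amplitude(rep(5, 3)), "degenerate")
})

test_that("conditioning chain cancels the generator nuisance terms", {
  p <- generator_params(duration = 30, noise_sd = 0, drift_amp = 2,
                        drift_freq = 0.05, seed = 6,
                        pp_jitter_sd = 0, zeta_jitter_sd = 0, hr_jitter_sd = 0)
  rec <- generate_record(setup_config(10, 60, 1, 30), p)
  cond <- preprocess_record(rec)
  mid <- (5 * rec$fs):(25 * rec$fs)
  y <- cond$conditioned$p1[mid]
  # mean offset gone
  expect_lt(abs(mean(y)), 0.5)
  # residual drift power below 1% of pulse power: compare against the
  # noise-free drift-free reference
  ref <- generate_record(setup_config(10, 60, 1, 30),
                         quiet_params(duration = 30, seed = 6))
  yref <- preprocess_record(ref)$conditioned$p1[mid]
  expect_lt(mean((y - yref)^2), 0.01 * mean(yref^2))
})
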