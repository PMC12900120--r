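test_that("central-difference derivatives match closed forms", {
  fs <- 200
  t <- (0:999) / fs
  d <- derivatives(3 * t, fs)
  inner <- 2:999
  expect_equal(d$d1[inner], rep(3, length(inner)), tolerance = 1e-9)
  expect_lt(max(abs(d$d2[3:998])), 1e-9)

  d <- derivatives(sin(2 * pi * t), fs)
  expect_lt(max(abs(d$d1[inner] - 2 * pi * cos(2 * pi * t[inner]))) /
              (2 * pi), 0.01)

  d <- derivatives(rep(2, 100), fs)
  expect_true(all(d$d1 == 0) && all(d$d2 == 0) && all(d$d3 == 0))
  expect_error(derivatives(1:4, fs), "short")
})

test_that("beat segmentation finds one window per cycle", {
  rec <- generate_record(setup_config(10, 60, 1, 30),
                         quiet_params(duration = 60, seed = 3))
  rec <- preprocess_record(rec)
  beats <- segment_beats(rec$conditioned$p1, rec$fs, 60)
  expect_true(abs(length(beats) - 60) <= 1)

  expect_warning(out <- segment_beats(rep(0, 2000), 200, 60), "no peaks")
  expect_length(out, 0)

  # every truth peak matched by exactly one detected peak within 3 samples
  pt <- truth_times(rec, "peak")
  det <- vapply(beats, function(b) (b$peak - 1) / rec$fs, numeric(1))
  matches <- vapply(pt[pt > 1 & pt < 59], function(tp) {
    sum(abs(det - tp) <= 3 / rec$fs)
  }, numeric(1))
  expect_true(all(matches == 1))
})

test_that("fiducials on noise-free beats match the template truth", {
  for (sha in c(10, 30, 50)) {
    rec <- generate_record(setup_config(20, 60, 1.5, sha),
                           quiet_params(duration = 20, seed = 8))
    rec <- preprocess_record(rec)
    expect_lte(localization_error(rec, landmark = "foot", field = "foot"), 2)
    expect_lte(localization_error(rec, landmark = "peak",
                                  field = "systolic_peak"), 2)
    expect_lte(localization_error(rec, landmark = "falling",
                                  field = "falling_steep"), 2)
    expect_lte(localization_error(rec, landmark = "rising",
                                  field = "rising_steep"), 2)
  }
})

test_that("a beat without a dicrotic lobe yields no notch but stays valid", {
  p <- quiet_params(duration = 15, seed = 2,
                    dicrotic_base = 0, dicrotic_sha = 0)
  rec <- preprocess_record(generate_record(setup_config(10, 60, 1, 30), p))
  v <- valid_fiducials(rec$conditioned$p1, rec$fs, 60)
  expect_gt(length(v), 5)
  for (f in v[2:4]) {
    expect_false(is.na(f$foot))
    expect_false(is.na(f$systolic_peak))
    expect_false(is.na(f$falling_steep))
  }
})

test_that("a structureless window is flagged invalid", {
  x <- seq(0, 1, length.out = 200)  # monotone ramp
  d <- derivatives(x, 200)
  f <- detect_fiducials(list(start = 1L, end = 200L, peak = 100L), x, d, 200)
  expect_false(f$valid)
})

test_that("detection is translation-equivariant", {
  rec <- generate_record(setup_config(10, 60, 1, 20),
                         quiet_params(duration = 20, seed = 12))
  rec <- preprocess_record(rec)
  x <- rec$conditioned$p1
  k <- 37
  xs <- c(x[(k + 1):length(x)], x[1:k])  # periodic signal: rotation = shift
  f0 <- valid_fiducials(x, rec$fs, 60)
  f1 <- valid_fiducials(xs, rec$fs, 60)
  feet0 <- vapply(f0, function(f) as.numeric(f$foot), numeric(1))
  feet1 <- vapply(f1, function(f) as.numeric(f$foot), numeric(1))
  shifted <- feet0 - k
  shifted <- shifted[shifted > 200 & shifted < length(x) - 200]
  for (s in shifted) expect_true(min(abs(feet1 - s)) <= 1)
})

test_that("ordering invariant holds over random generator settings", {
  set.seed(99)
  for (rep in 1:6) {
    cfg <- setup_config(sample(c(10, 20), 1), sample(c(30, 60, 80), 1),
                        sample(c(1, 1.5, 2), 1), sample(seq(10, 50, 10), 1))
    p <- generator_params(duration = 12, seed = sample.int(1e6, 1),
                          noise_sd = runif(1, 0, 0.03))
    rec <- preprocess_record(generate_record(cfg, p))
    for (f in valid_fiducials(rec$conditioned$p1, rec$fs, cfg$hr_bpm)) {
      expect_true(f$foot < f$rising_steep)
      expect_true(f$rising_steep < f$systolic_peak)
      expect_true(f$systolic_peak < f$falling_steep)
      if (!is.na(f$dicrotic_notch)) {
        expect_true(f$dicrotic_notch > f$systolic_peak)
      }
    }
  }
})

test_that("detection rates are per-landmark percentages", {
  mk <- function(n, notch = TRUE) {
    lapply(seq_len(n), function(i) {
      structure(list(foot = 1L, rising_steep = 2L, systolic_peak = 3L,
                     falling_steep = 4L,
                     dicrotic_notch = if (notch || i > 1) 5L else NA_integer_,
                     valid = TRUE), class = "fiducial_set")
    })
  }
  r <- detection_rate(mk(60), 60)
  expect_true(all(r$success_rate == 100))
  sets <- mk(60); sets[[1]]$dicrotic_notch <- NA_integer_
  r <- detection_rate(sets, 60)
  expect_equal(unname(r$success_rate[["dicrotic_notch"]]), 98.33, tolerance = 1e-3)
  r <- detection_rate(list(), 10)
  expect_true(all(r$success_rate == 0))
  expect_error(detection_rate(list(), 0), "positive")
})
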