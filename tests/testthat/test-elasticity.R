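# Published two-decimal conversion values (rows: ShA 10..50; columns:
# DMA, Gent, RDA, Ruess, Secant), and the corresponding PWV grid.
golden_E <- matrix(c(
  0.45, 0.41, 0.29, 0.67, 0.28,
  0.88, 0.73, 0.51, 0.84, 0.48,
  1.69, 1.14, 0.92, 1.07, 0.82,
  3.26, 1.69, 1.64, 1.35, 1.41,
  6.29, 2.46, 2.93, 1.71, 2.41), nrow = 5, byrow = TRUE,
  dimnames = list(seq(10, 50, 10), c("DMA", "Gent", "RDA", "Ruess", "Secant")))

golden_pwv <- list(
  `1` = matrix(c(
    6.74, 6.42, 5.36, 8.17, 5.27,
    9.36, 8.56, 7.17, 9.18, 6.90,
    13.00, 10.69, 9.58, 10.33, 9.04,
    18.05, 13.00, 12.80, 11.62, 11.85,
    25.07, 15.67, 17.11, 13.06, 15.54), nrow = 5, byrow = TRUE),
  `1.5` = matrix(c(
    8.25, 7.87, 6.57, 10.00, 6.45,
    11.46, 10.48, 8.78, 11.25, 8.45,
    15.92, 13.09, 11.73, 12.65, 11.08,
    22.11, 15.92, 15.68, 14.23, 14.52,
    30.71, 19.19, 20.96, 16.00, 19.03), nrow = 5, byrow = TRUE),
  `2` = matrix(c(
    9.53, 9.08, 7.59, 11.55, 7.45,
    13.24, 12.10, 10.14, 12.99, 9.76,
    18.38, 15.12, 13.55, 14.61, 12.79,
    25.53, 18.38, 18.11, 16.43, 16.76,
    35.46, 22.16, 24.20, 18.48, 21.97), nrow = 5, byrow = TRUE))

test_that("all fifteen golden conversion values are reproduced at 2 dp", {
  sha <- seq(10, 50, 10)
  for (m in colnames(golden_E)) {
    expect_equal(round(shore_to_elasticity(sha, m), 2),
                 unname(golden_E[, m]), info = m)
  }
  expect_equal(shore_to_elasticity(0, "DMA") |> suppressWarnings(), 0.2354)
})

test_that("all 75 golden PWV values are reproduced at 2 dp", {
  tab <- theoretical_pwv_table()
  expect_equal(nrow(tab), 75)
  for (w in c("1", "1.5", "2")) {
    sub <- tab[tab$wall_mm == as.numeric(w), ]
    got <- matrix(sub$pwv_2dp, nrow = 5, byrow = TRUE)
    expect_equal(got, golden_pwv[[w]], info = paste("wall", w))
  }
  # monotone in hardness within every (wall, model)
  for (w in unique(tab$wall_mm)) for (m in unique(tab$model)) {
    v <- tab$pwv[tab$wall_mm == w & tab$model == m]
    expect_true(all(diff(v) > 0))
  }
})

test_that("Moens-Korteweg obeys closed form and scale property", {
  expect_equal(moens_korteweg(1, 1), 10)
  E <- 1.7
  expect_equal(moens_korteweg(4 * E, 1.5), 2 * moens_korteweg(E, 1.5))
  expect_error(moens_korteweg(-1, 1), "positive")
  expect_error(shore_to_elasticity(100, "Gent") |> suppressWarnings(), "pole")
  expect_error(shore_to_elasticity(30, "NoSuchModel"))
})

test_that("hardness-to-PWV estimation equals theory at the true hardness", {
  tab <- theoretical_pwv_table()
  est <- estimate_pwv_from_hardness(50, 2, "DMA", method_tag = "T")
  expect_equal(round(est$value, 2), 35.46)
  expect_equal(est$value,
               tab$pwv[tab$wall_mm == 2 & tab$shore_a == 50 &
                         tab$model == "DMA"])
  # a +-2 tolerance band around ShA 30 brackets the theoretical value
  lo <- suppressWarnings(estimate_pwv_from_hardness(28, 2, "Ruess"))$value
  hi <- suppressWarnings(estimate_pwv_from_hardness(32, 2, "Ruess"))$value
  expect_true(lo < 14.61 && 14.61 < hi)
  # exponential conversions stay positive and finite near zero hardness
  est0 <- suppressWarnings(estimate_pwv_from_hardness(0.001, 1, "DMA"))
  expect_true(is.finite(est0$value) && est0$value > 0)
})

test_that("reference PTT is the median of robustly paired foot delays", {
  up <- (0:59) * 1.0
  expect_equal(reference_ptt(up, up + 0.03), 0.03)
  down <- up + 0.03
  down[15] <- up[15] + 0.3  # one gross mis-detection
  expect_equal(reference_ptt(up, down), 0.03)
  expect_error(reference_ptt(numeric(0), 1), "non-empty")
  expect_error(reference_ptt(up, up - 0.05), "swapped")
})

test_that("reference PWV is distance over transit time", {
  expect_equal(reference_pwv(0.03)$value, 10)
  expect_equal(reference_pwv(0.015)$value, 20)
  expect_error(reference_pwv(0), "positive")
})

test_that("high-rate generator round-trip recovers the transit time", {
  p <- quiet_params(fs = 2000, duration = 12, seed = 17)
  rec <- preprocess_record(generate_record(setup_config(10, 60, 1, 10), p))
  foot_t <- function(ch) {
    vapply(valid_fiducials(rec$conditioned[[ch]], rec$fs, 60),
           function(f) (f$foot - 1) / rec$fs, numeric(1))
  }
  ptt <- reference_ptt(foot_t("p1"), foot_t("p2"))
  expect_lt(abs(ptt - rec$truth$delay_true), 1 / rec$fs)
  pwv <- reference_pwv(ptt)$value
  expect_lt(abs(pwv - 8.17) / 8.17, 0.02)
})

test_that("error analysis gates the location test on Shapiro-Wilk", {
  st <- error_analysis(rep(1, 10), rep(1, 10))
  expect_true(st$degenerate)
  expect_equal(st$median, 0)
  expect_equal(st$iqr, 0)

  # a clear shift with normal noise: t-test detects it at n = 45
  set.seed(20)
  ref <- rnorm(45, 10, 1)
  st <- error_analysis(ref + 5 + rnorm(45, 0, 1), ref)
  expect_equal(st$test_used, "t_test")
  expect_lt(st$p_value, 0.05)

  # heavy-tailed symmetric differences: normality rejected, Wilcoxon used,
  # and with no true shift the location test should usually not reject
  set.seed(21)
  hits <- 0
  for (r in 1:25) {
    d <- rt(60, df = 1)  # Cauchy-tailed
    st <- error_analysis(d, rep(0, 60))
    expect_identical(st$test_used,
                     if (st$shapiro_p >= 0.05) "t_test" else "wilcoxon")
    if (st$test_used == "wilcoxon" && st$p_value > 0.05) hits <- hits + 1
  }
  expect_gt(hits, 25 * 0.7)
})
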