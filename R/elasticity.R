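#' Physical constants for Moens-Korteweg PWV computation
#'
#' @param rho Fluid density in kg/m^3 (water, 1000).
#' @param d Inner diameter of the vessel in metres (0.010).
#' @param distance Separation of the two pressure sensors in metres (0.30).
#' @return A list of class `pwv_constants`.
#' @export
pwv_constants <- function(rho = 1000, d = 0.010, distance = 0.30) {
  if (any(c(rho, d, distance) <= 0)) stop("constants must be strictly positive")
  structure(list(rho = rho, d = d, distance = distance),
            class = "pwv_constants")
}

#' Names of the supported Shore-A-to-elasticity conversion models
#' @return Character vector of model names.
#' @export
conversion_models <- function() c("DMA", "Gent", "RDA", "Ruess", "Secant")

#' Convert Shore A hardness to Young's modulus
#'
#' Five empirical conversions for silicone elastomers:
#' \deqn{E_{DMA} = 0.2354\,e^{0.0657 S}}
#' \deqn{E_{Gent} = \frac{0.0981\,(56 + 7.62336 S)}{0.137505\,(254 - 2.54 S)}}
#' \deqn{E_{RDA} = 0.1611\,e^{0.058 S}}
#' \deqn{E_{Ruess} = e^{0.0235 S - 0.6403}}
#' \deqn{E_{Secant} = 0.1614\,e^{0.0541 S}}
#' All return megapascals. The Gent relation has a pole at S = 100 and is
#' rejected there. A warning is emitted outside the validated range 10-50.
#'
#' @param sha Shore A hardness value(s), positive.
#' @param model One of `"DMA"`, `"Gent"`, `"RDA"`, `"Ruess"`, `"Secant"`
#'   (case-insensitive).
#' @return Young's modulus in MPa, unrounded, vectorized over `sha`.
#' @examples
#' round(shore_to_elasticity(50, "DMA"), 2)   # 6.29
#' round(shore_to_elasticity(10, "Ruess"), 2) # 0.67
#' @export
shore_to_elasticity <- function(sha, model) {
  if (any(!is.finite(sha)) || any(sha < 0)) {
    stop("Shore A hardness must be finite and non-negative")
  }
  model <- match.arg(tolower(model), tolower(conversion_models()))
  if (any(sha < 10 | sha > 50)) {
    warning("Shore A outside the validated range [10, 50]")
  }
  switch(model,
    dma = 0.2354 * exp(0.0657 * sha),
    gent = {
      if (any(254 - 2.54 * sha < 1e-12)) {
        stop("Gent conversion undefined at Shore A >= 100 (denominator pole)")
      }
      0.0981 * (56 + 7.62336 * sha) / (0.137505 * (254 - 2.54 * sha))
    },
    rda = 0.1611 * exp(0.058 * sha),
    ruess = exp(0.0235 * sha - 0.6403),
    secant = 0.1614 * exp(0.0541 * sha)
  )
}

#' Moens-Korteweg pulse wave velocity
#'
#' \deqn{PWV = \sqrt{\frac{E\,W}{\rho\,d}}}
#' for a thin-walled elastic tube: `E` wall Young's modulus, `W` wall
#' thickness, `rho` fluid density, `d` inner diameter.
#'
#' @param E_mpa Young's modulus in MPa (unrounded values should be used).
#' @param wall_mm Wall thickness in mm.
#' @param constants A [pwv_constants()].
#' @return PWV in m/s, vectorized.
#' @examples
#' moens_korteweg(1, 1)  # 10 m/s
#' @export
moens_korteweg <- function(E_mpa, wall_mm, constants = pwv_constants()) {
  if (any(!is.finite(E_mpa)) || any(E_mpa <= 0) ||
      any(!is.finite(wall_mm)) || any(wall_mm <= 0)) {
    stop("E and wall thickness must be finite and positive")
  }
  sqrt(E_mpa * 1e6 * wall_mm * 1e-3 / (constants$rho * constants$d))
}

#' Theoretical PWV table over a wall-thickness x hardness x model grid
#'
#' Evaluates every conversion model at every (wall thickness, hardness)
#' combination and propagates the unrounded elasticity through the
#' Moens-Korteweg relation. The default grid is the study grid
#' (3 thicknesses x 5 hardness levels x 5 models = 75 values).
#'
#' @param wall_mm Wall thicknesses in mm.
#' @param sha Shore A hardness levels.
#' @param models Conversion model names.
#' @param constants A [pwv_constants()].
#' @return A data.frame with columns `wall_mm`, `shore_a`, `model`,
#'   `elasticity_mpa`, `pwv` (unrounded) and `pwv_2dp` (display rounding).
#' @export
theoretical_pwv_table <- function(wall_mm = c(1, 1.5, 2),
                                  sha = c(10, 20, 30, 40, 50),
                                  models = conversion_models(),
                                  constants = pwv_constants()) {
  g <- expand.grid(model = models, shore_a = sha, wall_mm = wall_mm,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g <- g[, c("wall_mm", "shore_a", "model")]
  g$elasticity_mpa <- mapply(function(s, m) shore_to_elasticity(s, m),
                             g$shore_a, g$model)
  g$pwv <- moens_korteweg(g$elasticity_mpa, g$wall_mm, constants)
  g$pwv_2dp <- round(g$pwv, 2)
  rownames(g) <- NULL
  g
}

#' PWV estimate from a hardness estimate
#'
#' Converts an estimated Shore A hardness to elasticity under the chosen
#' model, then to PWV via Moens-Korteweg. Tag the estimate by the method that
#' produced the hardness: `"R"` (regression), `"F"` (fuzzy/ANFIS), `"T"`
#' (theoretical, i.e. true hardness), `"M"` (measured transit time).
#'
#' @param sha_estimate Estimated Shore A hardness (positive).
#' @param wall_mm Wall thickness in mm.
#' @param model Conversion model name.
#' @param constants A [pwv_constants()].
#' @param method_tag One of `"R"`, `"F"`, `"T"`.
#' @return A list of class `pwv_estimate` with `value` (m/s), `method`,
#'   `conversion`.
#' @export
estimate_pwv_from_hardness <- function(sha_estimate, wall_mm, model,
                                       constants = pwv_constants(),
                                       method_tag = "R") {
  method_tag <- match.arg(method_tag, c("R", "F", "T"))
  E <- shore_to_elasticity(sha_estimate, model)
  structure(list(value = moens_korteweg(E, wall_mm, constants),
                 method = method_tag, conversion = model),
            class = "pwv_estimate")
}

#' Reference pulse transit time from foot times at two sites
#'
#' Pairs each upstream foot with the nearest downstream foot within half a
#' median cycle, and returns the median of the paired differences. The median
#' makes the trial-level PTT robust to occasional mis-detections.
#'
#' @param foot_times_upstream,foot_times_downstream Foot times in seconds.
#' @return Median PTT in seconds.
#' @export
reference_ptt <- function(foot_times_upstream, foot_times_downstream) {
  if (length(foot_times_upstream) == 0 || length(foot_times_downstream) == 0) {
    stop("foot time lists must be non-empty")
  }
  cyc <- stats::median(diff(sort(foot_times_upstream)))
  if (!is.finite(cyc)) cyc <- Inf  # single beat: accept any pairing
  window <- cyc / 2
  d <- vapply(foot_times_upstream, function(tu) {
    dn <- foot_times_downstream - tu
    dn <- dn[abs(dn) < window]
    if (length(dn) == 0) return(NA_real_)
    dn[which.min(abs(dn))]
  }, numeric(1))
  d <- d[!is.na(d)]
  if (length(d) == 0) stop("no pairable beats within half a cycle")
  ptt <- stats::median(d)
  if (ptt <= 0) stop("negative transit time: channels appear swapped")
  ptt
}

#' Reference PWV from a measured transit time
#'
#' `PWV = distance / PTT` for the known sensor separation.
#'
#' @param ptt Pulse transit time in seconds, positive.
#' @param constants A [pwv_constants()].
#' @return A `pwv_estimate` with method `"M"`.
#' @examples
#' reference_pwv(0.03)$value  # 10 m/s
#' @export
reference_pwv <- function(ptt, constants = pwv_constants()) {
  if (!is.finite(ptt) || ptt <= 0) stop("PTT must be finite and positive")
  structure(list(value = constants$distance / ptt, method = "M",
                 conversion = NA_character_),
            class = "pwv_estimate")
}

#' @export
print.pwv_estimate <- function(x, ...) {
  cat(sprintf("PWV(%s%s) = %.2f m/s\n", x$method,
              if (is.na(x$conversion)) "" else paste0(", ", x$conversion),
              x$value))
  invisible(x)
}

#' Paired error statistics between PWV estimates and references
#'
#' Computes paired differences (estimate minus reference), tests them for
#' normality with the Shapiro-Wilk test at alpha = 0.05, and then tests the
#' location against zero with a one-sample two-sided Student's t-test when
#' normality is not rejected, or a two-sided Wilcoxon signed-rank test when it
#' is (zero differences dropped; normal approximation for n > 25).
#'
#' @param estimates,references Equal-length numeric vectors of paired PWV
#'   values (m/s), n >= 3.
#' @param alpha Normality-gate significance level.
#' @return A list of class `error_stats`: `differences`, `shapiro_p`,
#'   `test_used` (`"t_test"` or `"wilcoxon"`), `statistic`, `p_value`,
#'   `median`, `iqr`, `mean`, `degenerate` (all differences zero).
#' @export
error_analysis <- function(estimates, references, alpha = 0.05) {
  if (length(estimates) != length(references)) stop("inputs must be paired")
  if (length(estimates) < 3) stop("need at least 3 pairs")
  d <- estimates - references
  out <- list(differences = d, median = stats::median(d),
              iqr = stats::IQR(d), mean = mean(d))
  if (all(d == 0)) {
    out$degenerate <- TRUE
    out$shapiro_p <- NA_real_
    out$test_used <- NA_character_
    out$statistic <- NA_real_
    out$p_value <- 1
    class(out) <- "error_stats"
    return(out)
  }
  out$degenerate <- FALSE
  out$shapiro_p <- stats::shapiro.test(d)$p.value
  if (out$shapiro_p >= alpha) {
    tt <- stats::t.test(d, mu = 0)
    out$test_used <- "t_test"
    out$statistic <- unname(tt$statistic)
    out$p_value <- tt$p.value
  } else {
    dz <- d[d != 0]
    wt <- stats::wilcox.test(dz, mu = 0, exact = length(dz) <= 25,
                             correct = TRUE)
    out$test_used <- "wilcoxon"
    out$statistic <- unname(wt$statistic)
    out$p_value <- wt$p.value
  }
  class(out) <- "error_stats"
  out
}

#' @export
print.error_stats <- function(x, ...) {
  cat("Paired PWV error statistics (n =", length(x$differences), ")\n")
  cat(sprintf("  median %.3f, IQR %.3f, mean %.3f m/s\n",
              x$median, x$iqr, x$mean))
  if (isTRUE(x$degenerate)) {
    cat("  all differences zero (location trivially 0)\n")
  } else {
    cat(sprintf("  Shapiro-Wilk p = %.3g -> %s: statistic %.3f, p = %.3g\n",
                x$shapiro_p, x$test_used, x$statistic, x$p_value))
  }
  invisible(x)
}
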