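#' Flag influential observations by Cook's distance
#'
#' Fits a full-data ordinary least squares model and flags observations with
#' Cook's distance above `4/n` in a single pass. Cook's distance combines the
#' standardized residual and leverage of each point,
#' `D_i = r_i^2 h_ii / (p s^2 (1 - h_ii)^2)`.
#'
#' @param X Numeric design matrix or data.frame of predictors (no intercept
#'   column; one is added).
#' @param y Response vector.
#' @param threshold Flagging threshold (default `4/n`).
#' @return Logical vector, TRUE for flagged outliers.
#' @export
cooks_filter <- function(X, y, threshold = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X) + 1
  if (n <= p) stop("need more observations than parameters for Cook's distance")
  fit <- stats::lm(y ~ X)
  if (fit$rank < p) stop("singular design matrix")
  s2 <- sum(stats::residuals(fit)^2) / (n - p)
  if (s2 <= .Machine$double.eps * max(stats::var(y), 1)) {
    return(rep(FALSE, n))  # exact fit: influence is numerically undefined
  }
  D <- stats::cooks.distance(fit)
  if (is.null(threshold)) threshold <- 4 / n
  unname(D > threshold)
}

#' Fit the hardness regression model
#'
#' Ordinary least squares for Shore A hardness on systole time (ST), pulse
#' pressure (PP), stroke volume (SV), heart rate (HR) and wall thickness (W),
#' optionally after removing influential observations by Cook's distance.
#'
#' @param data A data.frame containing columns `ST`, `PP`, `SV`, `HR`, `W`
#'   and the response `ShA` (or pass a feature table and use
#'   [hardness_data()] to rename).
#' @param apply_cooks Remove Cook's-distance outliers before the final fit
#'   (default TRUE).
#' @return An object of class `hardness_lm`: `coefficients`,
#'   `standard_errors`, `t_values`, `p_values`, `r_squared`, `n_used`,
#'   `outlier_mask`, and the underlying `lm` fit.
#' @export
fit_regression <- function(data, apply_cooks = TRUE) {
  need <- c("ST", "PP", "SV", "HR", "W", "ShA")
  if (!all(need %in% names(data))) {
    stop("data must contain columns ", paste(need, collapse = ", "))
  }
  X <- data[, c("ST", "PP", "SV", "HR", "W")]
  y <- data$ShA
  mask <- rep(FALSE, nrow(data))
  if (apply_cooks) mask <- cooks_filter(X, y)
  keep <- !mask
  if (sum(keep) <= 6) stop("too few observations after outlier removal")
  fit <- stats::lm(ShA ~ ST + PP + SV + HR + W, data = data[keep, , drop = FALSE])
  if (fit$rank < 6) {
    ali <- attr(stats::alias(fit)$Complete, "dimnames")[[1]]
    stop("rank-deficient design; aliased terms: ", paste(ali, collapse = ", "))
  }
  sm <- summary(fit)
  co <- sm$coefficients
  nm <- c("intercept", "ST", "PP", "SV", "HR", "W")
  structure(list(
    coefficients = stats::setNames(co[, 1], nm),
    standard_errors = stats::setNames(co[, 2], nm),
    t_values = stats::setNames(co[, 3], nm),
    p_values = stats::setNames(co[, 4], nm),
    r_squared = sm$r.squared,
    n_used = sum(keep),
    outlier_mask = mask,
    fit = fit
  ), class = "hardness_lm")
}

#' @export
print.hardness_lm <- function(x, digits = 3, ...) {
  cat("Hardness regression (OLS), n =", x$n_used,
      "(", sum(x$outlier_mask), "outliers removed )\n")
  tab <- cbind(Estimate = x$coefficients, `Std. Error` = x$standard_errors,
               `t value` = x$t_values, `p value` = x$p_values)
  print(round(tab, digits))
  cat(sprintf("R-squared: %.3f\n", x$r_squared))
  invisible(x)
}

#' @export
summary.hardness_lm <- function(object, ...) summary(object$fit, ...)

#' @export
coef.hardness_lm <- function(object, ...) object$coefficients

#' @export
residuals.hardness_lm <- function(object, ...) stats::residuals(object$fit)

#' Predict Shore A hardness from regression coefficients
#'
#' Affine evaluation `ShA = b0 + b_ST*ST + b_PP*PP + b_SV*SV + b_HR*HR +
#' b_W*W`. Accepts either a fitted `hardness_lm` or a named coefficient
#' vector with entries `intercept`, `ST`, `PP`, `SV`, `HR`, `W`.
#'
#' @param model A `hardness_lm` or named numeric coefficient vector.
#' @param ST,PP,SV,HR,W Predictor values (vectorized).
#' @return Estimated Shore A hardness.
#' @examples
#' b <- c(intercept = 42.5, ST = -24.8, PP = 1.1, SV = -1.8, HR = -0.1, W = -7.9)
#' predict_regression(b, ST = 0, PP = 0, SV = 0, HR = 0, W = 0)  # 42.5
#' @export
predict_regression <- function(model, ST, PP, SV, HR, W) {
  b <- if (inherits(model, "hardness_lm")) model$coefficients else model
  need <- c("intercept", "ST", "PP", "SV", "HR", "W")
  if (!all(need %in% names(b))) {
    stop("missing coefficient(s): ",
         paste(setdiff(need, names(b)), collapse = ", "))
  }
  b[["intercept"]] + b[["ST"]] * ST + b[["PP"]] * PP + b[["SV"]] * SV +
    b[["HR"]] * HR + b[["W"]] * W
}

#' @export
predict.hardness_lm <- function(object, newdata, ...) {
  predict_regression(object, ST = newdata$ST, PP = newdata$PP,
                     SV = newdata$SV, HR = newdata$HR, W = newdata$W)
}

#' Rename feature-table columns to the regression's predictor names
#'
#' Maps a [feature_table()] to the design expected by [fit_regression()]:
#' ST is the systole time as a fraction of the cycle, PP the pulse pressure,
#' SV/HR/W the setup parameters, ShA the hardness label.
#'
#' @param features A feature table.
#' @return A data.frame with columns `ST`, `PP`, `SV`, `HR`, `W`, `ShA`.
#' @export
hardness_data <- function(features) {
  data.frame(ST = features$systole_pct / 100, PP = features$pp,
             SV = features$sv, HR = features$hr, W = features$w,
             ShA = features$sha)
}
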