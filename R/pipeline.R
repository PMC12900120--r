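#' Write a waveform record to CSV with metadata header
#'
#' Plain-text dialect: comment lines `#key=value` carrying the sampling rate
#' and setup metadata, then columns `time_s,p1,c1,c2,p2`. Ground truth, when
#' present, goes to a sidecar JSON next to the CSV.
#'
#' @param record A `waveform_record`.
#' @param path Output CSV path.
#' @param truth_sidecar Write `<path>.truth.json` when the record carries a
#'   truth bundle (default TRUE).
#' @return `path`, invisibly.
#' @export
write_record_csv <- function(record, path, truth_sidecar = TRUE) {
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- c(fs = record$fs, sv_ml = record$config$sv_ml,
           hr_bpm = record$config$hr_bpm, wall_mm = record$config$wall_mm,
           shore_a = record$config$shore_a,
           distance_m = attr(record, "distance") %||% 0.30)
  writeLines(sprintf("#%s=%.10g", names(hdr), hdr), con)
  df <- data.frame(time_s = record$time, record$channels)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  if (truth_sidecar && !is.null(record$truth)) {
    tr <- record$truth
    tr$landmarks <- NULL
    jsonlite::write_json(tr, paste0(path, ".truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a waveform record written by [write_record_csv()]
#'
#' Validates the metadata header and the uniform time grid; reads the truth
#' sidecar when present.
#'
#' @param path CSV path.
#' @return A `waveform_record`.
#' @export
read_record_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  hdr_lines <- grep("^#", lines, value = TRUE)
  kv <- strsplit(sub("^#", "", hdr_lines), "=")
  meta <- stats::setNames(as.numeric(vapply(kv, `[`, "", 2)),
                          vapply(kv, `[`, "", 1))
  need <- c("fs", "sv_ml", "hr_bpm", "wall_mm", "shore_a")
  missing_keys <- setdiff(need, names(meta))
  if (length(missing_keys)) {
    stop("schema error: missing metadata key(s): ",
         paste(paste0("#", missing_keys, "="), collapse = ", "))
  }
  body <- lines[!grepl("^#", lines)]
  ncols <- length(strsplit(body[1], ",")[[1]])
  bad <- which(vapply(strsplit(body[-1], ","), length, integer(1)) != ncols)
  if (length(bad)) {
    stop("parse error: truncated row at line ",
         length(hdr_lines) + 1 + bad[1])
  }
  df <- utils::read.csv(text = body)
  if (!"time_s" %in% names(df)) stop("schema error: missing time_s column")
  dt <- diff(df$time_s)
  if (max(abs(dt - 1 / meta[["fs"]])) > 1e-6 / meta[["fs"]] + 1e-9) {
    stop("format error: time grid is not uniform at 1/fs")
  }
  truth <- NULL
  sidecar <- paste0(path, ".truth.json")
  if (file.exists(sidecar)) {
    truth <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  }
  structure(list(
    time = df$time_s,
    channels = df[, setdiff(names(df), "time_s"), drop = FALSE],
    fs = meta[["fs"]],
    config = setup_config(meta[["sv_ml"]], meta[["hr_bpm"]],
                          meta[["wall_mm"]], meta[["shore_a"]]),
    truth = truth
  ), class = "waveform_record")
}

#' Configuration for the end-to-end pipeline
#'
#' @param grid Configuration grid (default the full 90-trial factorial).
#' @param params A [generator_params()].
#' @param spec A [filter_spec()].
#' @param constants A [pwv_constants()].
#' @param conversion Conversion model for hardness-to-PWV estimation.
#' @param fit_anfis Train the ANFIS hardness model (default TRUE).
#' @param anfis_epochs,anfis_seed ANFIS training controls.
#' @param reference_fs Sampling rate of the reference transit-time records
#'   (default 2000, the validation mode).
#' @param seed Master seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(grid = make_config_grid(),
                            params = NULL,
                            spec = filter_spec(),
                            constants = pwv_constants(),
                            conversion = "Ruess",
                            fit_anfis = TRUE,
                            anfis_epochs = 30, anfis_seed = 42,
                            reference_fs = 2000,
                            seed = 1L) {
  if (is.null(params)) params <- generator_params(seed = seed)
  structure(list(grid = grid, params = params, spec = spec,
                 constants = constants, conversion = conversion,
                 fit_anfis = fit_anfis, anfis_epochs = anfis_epochs,
                 anfis_seed = anfis_seed, reference_fs = reference_fs,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the end-to-end PWV estimation pipeline on synthetic data
#'
#' Simulate -> condition -> fiducials -> features -> hardness models
#' (regression and optionally ANFIS) -> elasticity conversion ->
#' Moens-Korteweg PWV -> reference PWV at the validation sampling rate ->
#' paired error statistics. Every stage count is recorded in the returned
#' report.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `run_report`: `features` (trial table),
#'   `regression` (a `hardness_lm`), `anfis` (trained model or NULL), `pwv`
#'   (per-trial estimates by method), `errors` (per-method `error_stats`
#'   against the measured reference), `counts`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  ds <- generate_dataset(config$grid, config$params)
  feats <- feature_table(ds, config$spec)
  counts <- list(trials = nrow(feats))

  hdat <- hardness_data(feats)
  reg <- fit_regression(hdat)
  counts$regression_outliers <- sum(reg$outlier_mask)

  anfis_fit <- NULL
  sha_f <- NULL
  if (config$fit_anfis) {
    ad <- data.frame(st = hdat$ST, pp = hdat$PP, sv = hdat$SV,
                     hr = hdat$HR, w = hdat$W,
                     crest = feats$crest_pct / 100, sha = hdat$ShA)
    anfis_fit <- anfis(sha ~ st + pp + sv + hr + w + crest, ad,
                       epochs = config$anfis_epochs, seed = config$anfis_seed)
    sha_f <- predict(anfis_fit, ad)
  }
  sha_r <- predict(reg, hdat)

  # reference (measured) PWV from high-rate two-site records
  ref_params <- config$params
  ref_params$fs <- config$reference_fs
  ref <- numeric(nrow(config$grid))
  ds_ref <- generate_dataset(config$grid, ref_params)
  for (i in seq_along(ref)) {
    rec <- preprocess_record(ds_ref$records[[i]], config$spec)
    f_up <- detect_all_fiducials(rec$conditioned$p1, rec$fs,
                                 rec$config$hr_bpm)
    f_dn <- detect_all_fiducials(rec$conditioned$p2, rec$fs,
                                 rec$config$hr_bpm)
    foot_t <- function(fs_) {
      v <- Filter(function(f) isTRUE(f$valid), fs_)
      vapply(v, function(f) (f$foot - 1) / rec$fs, numeric(1))
    }
    ptt <- reference_ptt(foot_t(f_up), foot_t(f_dn))
    ref[i] <- reference_pwv(ptt, config$constants)$value
  }

  est <- data.frame(
    trial = seq_len(nrow(feats)),
    pwv_T = mapply(function(s, w)
      estimate_pwv_from_hardness(s, w, config$conversion, config$constants,
                                 "T")$value, feats$sha, feats$w),
    pwv_R = mapply(function(s, w)
      suppressWarnings(estimate_pwv_from_hardness(
        max(s, 1), w, config$conversion, config$constants, "R")$value),
      sha_r, feats$w),
    pwv_M = ref
  )
  if (!is.null(sha_f)) {
    est$pwv_F <- mapply(function(s, w)
      suppressWarnings(estimate_pwv_from_hardness(
        max(s, 1), w, config$conversion, config$constants, "F")$value),
      sha_f, feats$w)
  }
  errors <- list(T_vs_M = error_analysis(est$pwv_T, est$pwv_M),
                 R_vs_M = error_analysis(est$pwv_R, est$pwv_M))
  if (!is.null(sha_f)) errors$F_vs_M <- error_analysis(est$pwv_F, est$pwv_M)

  structure(list(features = feats, regression = reg, anfis = anfis_fit,
                 pwv = est, errors = errors, counts = counts,
                 labels = ds$labels),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("Pipeline run:", x$counts$trials, "trials;",
      x$counts$regression_outliers, "regression outliers removed\n")
  cat(sprintf("Regression R^2 = %.3f", x$regression$r_squared))
  if (!is.null(x$anfis)) {
    cat(sprintf("; ANFIS holdout R^2 = %.3f", x$anfis$r2_holdout))
  }
  cat("\nPWV error vs measured reference:\n")
  for (nm in names(x$errors)) {
    e <- x$errors[[nm]]
    cat(sprintf("  %-8s median %+.3f m/s (IQR %.3f), %s p = %.3g\n",
                nm, e$median, e$iqr,
                if (is.na(e$test_used)) "degenerate" else e$test_used,
                e$p_value))
  }
  invisible(x)
}
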