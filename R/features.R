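#' @title The 12 PDT summary features
#'
#' @description
#' Each subject contributes two angle series per wrist (drift and
#' pronation, weak and counter side).  Over the analysis window each
#' series is summarised by three statistics — AVG (mean), MAX (signed
#' maximum, i.e. the greatest downward drift or greatest pronation) and
#' OSC (root-mean-square of the linearly detrended series, capturing the
#' rapid jitter of arm movement independently of slow drift) — giving the
#' 12 features `{WEAK|CNT}-{DRT|PRN}-{AVG|MAX|OSC}`.
#'
#' @name pdt-features
NULL

#' Canonical order of the 12 PDT feature names
#' @export
pdt_feature_names <- c(
  "WEAK-DRT-AVG", "WEAK-DRT-MAX", "WEAK-DRT-OSC",
  "WEAK-PRN-AVG", "WEAK-PRN-MAX", "WEAK-PRN-OSC",
  "CNT-DRT-AVG",  "CNT-DRT-MAX",  "CNT-DRT-OSC",
  "CNT-PRN-AVG",  "CNT-PRN-MAX",  "CNT-PRN-OSC")

#' Analysis-window configuration
#'
#' The examination runs for `test_duration_s` seconds but analysis
#' starts later, excluding the initial dip — the transient downward
#' excursion at test start caused by device weight and postural
#' settling.
#'
#' @param test_duration_s total test duration in seconds (default 20).
#' @param analysis_start_s start of the analysed window (default 10).
#' @param analysis_end_s end of the analysed window; defaults to the
#'   test duration.
#' @return A list of class `pdt_window`.
#' @export
window_config <- function(test_duration_s = 20, analysis_start_s = 10,
                          analysis_end_s = test_duration_s) {
  if (!(analysis_start_s >= 0 && analysis_start_s < analysis_end_s &&
        analysis_end_s <= test_duration_s))
    stop_pdt("need 0 <= analysis_start_s < analysis_end_s <= test_duration_s",
             "pdt_config_error")
  structure(list(test_duration_s = test_duration_s,
                 analysis_start_s = analysis_start_s,
                 analysis_end_s = analysis_end_s),
            class = "pdt_window")
}

#' Restrict an angle series to the analysis window
#'
#' Keeps samples with `analysis_start_s <= t < analysis_end_s`
#' (half-open, so sample counts are deterministic).
#'
#' @param series a [pdt_angles()] series.
#' @param cfg a [window_config()].
#' @return The windowed [pdt_angles()] series.
#' @export
analysis_window <- function(series, cfg = window_config()) {
  stopifnot(inherits(series, "pdt_angles"))
  t <- series$t
  dt <- 1 / (attr(series, "rate_hz") %||% Inf)
  if (max(t) < cfg$analysis_end_s - dt - 1e-9)
    stop_pdt(sprintf(
      "series ends at %.3g s but the analysis window needs %.3g s (%.3g s missing)",
      max(t), cfg$analysis_end_s, cfg$analysis_end_s - dt - max(t)),
      "pdt_data_error")
  keep <- t >= cfg$analysis_start_s & t < cfg$analysis_end_s
  pdt_angles(t[keep], series$drift_deg[keep], series$pron_deg[keep],
             side = attr(series, "side"),
             subject_id = attr(series, "subject_id"),
             rate_hz = attr(series, "rate_hz"))
}

#' Summarise one angle series into (AVG, MAX, OSC)
#'
#' @param x numeric vector of angles in degrees.
#' @param osc `"rms_detrended"` (default): OSC is the RMS of the
#'   residuals after removing the least-squares line, in degrees RMS;
#'   `"reversals"`: OSC is the number of direction reversals per second
#'   (requires `rate_hz`).
#' @param rate_hz sampling rate, needed only for `osc = "reversals"`.
#' @return Named numeric vector `c(avg, max, osc)`.  `max` is the signed
#'   maximum (greatest downward drift / greatest pronation), not the
#'   maximum absolute value.
#' @export
summarize_angles <- function(x, osc = c("rms_detrended", "reversals"),
                             rate_hz = NULL) {
  osc <- match.arg(osc)
  if (length(x) == 0L)
    stop_pdt("cannot summarise an empty angle sequence", "pdt_contract_error")
  if (osc == "rms_detrended") {
    n <- length(x)
    if (n < 3L) {
      o <- 0
    } else {
      i <- seq_len(n)
      res <- lm.fit(cbind(1, i), x)$residuals
      o <- sqrt(mean(res^2))
    }
  } else {
    if (is.null(rate_hz))
      stop_pdt("osc = 'reversals' needs rate_hz", "pdt_parameter_error")
    d <- diff(x)
    d <- d[d != 0]
    o <- if (length(d) < 2L) 0 else
      sum(diff(sign(d)) != 0) / (length(x) / rate_hz)
  }
  c(avg = mean(x), max = max(x), osc = o)
}

#' Extract the 12 PDT features for one subject
#'
#' Applies [analysis_window()] then [summarize_angles()] to the drift and
#' pronation series of both wrists.  For healthy controls, who have no
#' weak side, the non-dominant arm is conventionally recorded as the
#' weak-equivalent side; that labelling is metadata of the cohort, not of
#' this function.
#'
#' @param weak angle series of the weak (or weak-equivalent) side.
#' @param counter angle series of the counter side.
#' @param cfg a [window_config()].
#' @param osc OSC statistic variant, see [summarize_angles()].
#' @return A named numeric vector of length 12 (class `pdt_features`,
#'   ordered as [pdt_feature_names]) with attribute `subject_id`.
#' @export
extract_features <- function(weak, counter, cfg = window_config(),
                             osc = "rms_detrended") {
  if (is.null(weak) || is.null(counter))
    stop_pdt("both weak and counter series are required", "pdt_data_error")
  stopifnot(inherits(weak, "pdt_angles"), inherits(counter, "pdt_angles"))
  id_w <- attr(weak, "subject_id"); id_c <- attr(counter, "subject_id")
  if (!is.na(id_w) && !is.na(id_c) && id_w != id_c)
    stop_pdt(sprintf("subject mismatch between sides: %s vs %s", id_w, id_c),
             "pdt_data_error")
  ww <- analysis_window(weak, cfg)
  cc <- analysis_window(counter, cfg)
  f <- c(summarize_angles(ww$drift_deg, osc, attr(ww, "rate_hz")),
         summarize_angles(ww$pron_deg,  osc, attr(ww, "rate_hz")),
         summarize_angles(cc$drift_deg, osc, attr(cc, "rate_hz")),
         summarize_angles(cc$pron_deg,  osc, attr(cc, "rate_hz")))
  names(f) <- pdt_feature_names
  structure(f, subject_id = if (!is.na(id_w)) id_w else id_c,
            class = "pdt_features")
}

#' @export
print.pdt_features <- function(x, ...) {
  cat(sprintf("<pdt_features> subject=%s\n", attr(x, "subject_id")))
  print(round(unclass(x), 3))
  invisible(x)
}

mrc_levels <- c("0", "1", "2", "3", "4", "4+", "5")

#' Validate a subject roster / feature matrix
#'
#' A feature matrix has one row per subject with columns `subject_id`,
#' `group` (`patient`/`control`), `mrc` (MRC muscle-power grade, one of
#' 0, 1, 2, 3, 4, 4+, 5) and the 12 feature columns in canonical order.
#'
#' @param df a data frame.
#' @param require_features check for the 12 feature columns too.
#' @return `df`, invisibly, after validation.
#' @export
validate_feature_matrix <- function(df, require_features = TRUE) {
  need <- c("subject_id", "group", "mrc")
  if (require_features) need <- c(need, pdt_feature_names)
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop_pdt(paste("feature matrix lacks columns:",
                   paste(missing, collapse = ", ")), "pdt_format_error")
  if (!all(df$group %in% c("patient", "control")))
    stop_pdt("group must be 'patient' or 'control'", "pdt_data_error")
  if (!all(as.character(df$mrc) %in% mrc_levels))
    stop_pdt("mrc grade must be one of 0,1,2,3,4,4+,5", "pdt_data_error")
  invisible(df)
}

#' Drop subjects too weak for the pronator drift test
#'
#' The test requires the subject to hold the arm against gravity plus the
#' device weight, so subjects graded MRC 0–3 are excluded from analysis.
#'
#' @param df a validated feature matrix.
#' @return The feature matrix restricted to MRC grades 4, 4+ and 5; a
#'   message reports how many subjects were dropped.
#' @export
exclude_low_mrc <- function(df) {
  validate_feature_matrix(df, require_features = FALSE)
  bad <- as.character(df$mrc) %in% c("0", "1", "2", "3")
  if (any(bad))
    message(sprintf("excluding %d subject(s) with MRC grade 0-3", sum(bad)))
  df[!bad, , drop = FALSE]
}

#' Write / read a feature matrix as delimited text
#'
#' Column order is fixed: `subject_id, group, mrc`, then the 12 features
#' in canonical order.
#'
#' @param df feature matrix data frame.
#' @param path file path.
#' @return `read_feature_matrix` returns the validated data frame.
#' @export
write_feature_matrix <- function(df, path) {
  validate_feature_matrix(df)
  df <- df[, c("subject_id", "group", "mrc", pdt_feature_names)]
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  df$mrc <- as.character(df$mrc)
  validate_feature_matrix(df)
  df
}

#' Build a labelled dataset from a feature matrix
#'
#' Applies the MRC 0–3 exclusion, then encodes patients as +1 and
#' controls as -1.
#'
#' @param df a feature matrix.
#' @return A [labeled_dataset()].
#' @export
as_labeled_dataset <- function(df) {
  df <- exclude_low_mrc(df)
  X <- as.matrix(df[, pdt_feature_names])
  rownames(X) <- df$subject_id
  labeled_dataset(X, ifelse(df$group == "patient", 1, -1),
                  feature_names = pdt_feature_names)
}
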