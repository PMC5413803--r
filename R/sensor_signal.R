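#' @title Accelerometer streams and tilt-derived angle series
#'
#' @description
#' A PDT recording is a uniformly sampled 3-axis acceleration stream from
#' a volar-mounted wrist device.  Axis convention (right arm): Y runs
#' along the forearm from wrist toward the fingers, X across the wrist
#' toward the thumb, Z out of the device face — so Z points at the
#' ceiling when the palm faces up.  Left-arm devices are mirrored in X at
#' load time so that positive pronation means palm-toward-prone on both
#' sides.
#'
#' @name sensor-signal
NULL

STANDARD_GRAVITY <- 9.80665  # m/s^2 per g

#' Construct a validated accelerometer stream
#'
#' @param t numeric vector of sample times in seconds, strictly increasing.
#' @param ax,ay,az acceleration components in units of g.
#' @param rate_hz sampling rate; inferred from the median spacing of `t`
#'   when `NULL`.
#' @param side `"weak"` or `"counter"`.
#' @param subject_id subject identifier (or `NA`).
#'
#' @details Timestamps must be strictly increasing and consistent with
#' `rate_hz` within 1%; irregular input should be resampled first (see
#' [load_stream()]).  All samples must be finite with non-zero norm.
#'
#' @return An object of class `pdt_stream`: a list with elements `t`,
#'   `ax`, `ay`, `az`, `rate_hz`, `side`, `subject_id`.
#' @export
pdt_stream <- function(t, ax, ay, az, rate_hz = NULL,
                       side = NA_character_, subject_id = NA_character_) {
  n <- length(t)
  if (n == 0L)
    stop_pdt("stream contains no samples", "pdt_data_error")
  if (length(ax) == 1L) ax <- rep(ax, n)
  if (length(ay) == 1L) ay <- rep(ay, n)
  if (length(az) == 1L) az <- rep(az, n)
  if (length(ax) != n || length(ay) != n || length(az) != n)
    stop_pdt("t, ax, ay, az must have equal length", "pdt_data_error")
  if (!all(is.finite(t)) || !all(is.finite(ax)) ||
      !all(is.finite(ay)) || !all(is.finite(az)))
    stop_pdt("stream contains non-finite values", "pdt_data_error")
  if (any(t < 0))
    stop_pdt("timestamps must be non-negative", "pdt_data_error")
  if (n > 1L && any(diff(t) <= 0))
    stop_pdt("timestamps are not strictly increasing", "pdt_data_error")
  nrm <- sqrt(ax^2 + ay^2 + az^2)
  if (any(nrm == 0))
    stop_pdt("stream contains zero-norm acceleration samples",
             "pdt_data_error")
  if (is.null(rate_hz)) {
    if (n < 2L)
      stop_pdt("cannot infer sampling rate from a single sample",
               "pdt_data_error")
    rate_hz <- 1 / median(diff(t))
  }
  if (n > 2L) {
    dt <- diff(t)
    if (max(abs(dt - 1 / rate_hz)) > 0.01 / rate_hz)
      stop_pdt(sprintf(
        "sample spacing deviates from %.4g Hz by more than 1%%; resample first",
        rate_hz), "pdt_data_error")
  }
  structure(
    list(t = as.numeric(t), ax = as.numeric(ax), ay = as.numeric(ay),
         az = as.numeric(az), rate_hz = rate_hz,
         side = side, subject_id = subject_id),
    class = "pdt_stream")
}

#' @export
print.pdt_stream <- function(x, ...) {
  cat(sprintf("<pdt_stream> subject=%s side=%s: %d samples @ %.4g Hz, %.4g s\n",
              x$subject_id, x$side, length(x$t), x$rate_hz,
              x$t[length(x$t)] - x$t[1]))
  invisible(x)
}

stream_duration <- function(stream) stream$t[length(stream$t)] - stream$t[1]

#' Read a raw sensor file into a stream
#'
#' Sensor files are delimited text with header `t,ax,ay,az`, one device
#' per file, named `<subject>_<side>.csv`.  Units are g by default; pass
#' `units = "ms2"` for files recorded in m/s^2.
#'
#' @param path path to the sensor file.
#' @param units `"g"` (default) or `"ms2"`.
#' @param side,subject_id override the values parsed from the file name.
#' @param hand `"right"` (default) or `"left"`; left-hand devices have
#'   their X axis mirrored so pronation is positive toward prone on both
#'   arms.
#' @param rate_hz target rate when resampling irregular input; default is
#'   the rate inferred from the median sample spacing.
#' @return A [pdt_stream()].
#' @export
load_stream <- function(path, units = c("g", "ms2"), side = NULL,
                        subject_id = NULL, hand = c("right", "left"),
                        rate_hz = NULL) {
  units <- match.arg(units)
  hand <- match.arg(hand)
  if (!file.exists(path))
    stop_pdt(sprintf("sensor file not found: %s", path), "pdt_format_error")
  df <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                 error = function(e)
                   stop_pdt(sprintf("cannot parse sensor file %s: %s",
                                    path, conditionMessage(e)),
                            "pdt_format_error"))
  need <- c("t", "ax", "ay", "az")
  if (!all(need %in% names(df)))
    stop_pdt(sprintf("sensor file %s lacks columns: %s", path,
                     paste(setdiff(need, names(df)), collapse = ", ")),
             "pdt_format_error")
  if (nrow(df) == 0L)
    stop_pdt(sprintf("sensor file %s is empty", path), "pdt_data_error")
  if (nrow(df) > 1L && any(diff(df$t) <= 0))
    stop_pdt(sprintf("sensor file %s has non-monotonic timestamps", path),
             "pdt_data_error")

  base <- sub("\\.[^.]*$", "", basename(path))
  parts <- strsplit(base, "_", fixed = TRUE)[[1]]
  if (is.null(subject_id))
    subject_id <- if (length(parts) >= 2) paste(head(parts, -1), collapse = "_")
                  else NA_character_
  if (is.null(side))
    side <- if (length(parts) >= 2) parts[length(parts)] else NA_character_

  scale <- if (units == "ms2") 1 / STANDARD_GRAVITY else 1
  ax <- df$ax * scale; ay <- df$ay * scale; az <- df$az * scale
  if (hand == "left") ax <- -ax

  t <- df$t
  # Resample onto a uniform grid when spacing is irregular (> 1%).
  if (length(t) > 2L) {
    dt <- diff(t)
    target <- if (is.null(rate_hz)) 1 / median(dt) else rate_hz
    if (max(abs(dt - 1 / target)) > 0.01 / target) {
      tu <- seq(t[1], t[length(t)], by = 1 / target)
      ax <- approx(t, ax, tu)$y
      ay <- approx(t, ay, tu)$y
      az <- approx(t, az, tu)$y
      t <- tu
      rate_hz <- target
    }
  }
  pdt_stream(t, ax, ay, az, rate_hz = rate_hz,
             side = side, subject_id = subject_id)
}

# Zero-phase order-2 Butterworth low-pass with odd-reflection padding at
# both ends, so constant or slowly varying signals carry no start-up
# transient into the retained segment.
lowpass_zero_phase <- function(x, rate_hz, cutoff_hz) {
  n <- length(x)
  filt <- signal::butter(2, cutoff_hz / (rate_hz / 2), type = "low")
  p <- min(n - 1L, ceiling(3 * rate_hz / cutoff_hz))
  if (p < 1L) return(x)
  pre  <- 2 * x[1] - x[(p + 1L):2L]
  post <- 2 * x[n] - x[(n - 1L):(n - p)]
  y <- signal::filtfilt(filt, c(pre, x, post))
  y[(p + 1L):(p + n)]
}

#' Estimate the per-sample gravity direction
#'
#' Isolates the quasi-static (gravitational) component of the stream by
#' zero-phase low-pass filtering each axis and normalising each sample
#' to unit length.  Postural drift and pronation live well below 1 Hz,
#' so the default cutoff preserves them while rejecting tremor and
#' sensor noise.
#'
#' @param stream a [pdt_stream()].
#' @param cutoff_hz low-pass cutoff in Hz; must be below the Nyquist
#'   frequency, and the stream must span at least `1/cutoff_hz` seconds.
#' @return An `n x 3` matrix with columns `gx`, `gy`, `gz`; every row has
#'   unit norm.
#' @export
estimate_gravity <- function(stream, cutoff_hz = 1) {
  stopifnot(inherits(stream, "pdt_stream"))
  if (cutoff_hz <= 0 || cutoff_hz >= stream$rate_hz / 2)
    stop_pdt("cutoff_hz must lie in (0, rate_hz/2)", "pdt_parameter_error")
  if (stream_duration(stream) < 1 / cutoff_hz)
    stop_pdt(sprintf(
      "stream spans %.3g s, shorter than the %.3g s filter warm-up (1/cutoff)",
      stream_duration(stream), 1 / cutoff_hz), "pdt_data_error")
  g <- cbind(
    gx = lowpass_zero_phase(stream$ax, stream$rate_hz, cutoff_hz),
    gy = lowpass_zero_phase(stream$ay, stream$rate_hz, cutoff_hz),
    gz = lowpass_zero_phase(stream$az, stream$rate_hz, cutoff_hz))
  nrm <- sqrt(rowSums(g^2))
  if (any(nrm < 1e-12))
    stop_pdt("low-pass filtered acceleration has zero norm", "pdt_data_error")
  g / nrm
}

as_gravity_matrix <- function(g) {
  if (is.null(dim(g))) g <- matrix(g, ncol = 3)
  if (ncol(g) != 3)
    stop_pdt("gravity input must have 3 components", "pdt_contract_error")
  nrm <- sqrt(rowSums(g^2))
  if (any(abs(nrm - 1) > 1e-6))
    stop_pdt("gravity vectors must be unit norm", "pdt_contract_error")
  g
}

#' Drift angle from a gravity direction
#'
#' Drift is the downward angular deviation of the extended forearm from
#' the horizontal plane: `asin(gy)` in degrees.  Zero when the forearm is
#' horizontal; positive when the hand drops below the horizontal plane.
#'
#' @param g unit-norm gravity vector(s): a length-3 vector or an
#'   `n x 3` matrix.
#' @return Drift angle(s) in degrees, in `[-90, 90]`.
#' @export
drift_angle <- function(g) {
  g <- as_gravity_matrix(g)
  asin(pmin(1, pmax(-1, g[, 2]))) * 180 / pi
}

#' Pronation angle from a gravity direction
#'
#' Pronation is the rotation of the forearm about its long axis from
#' palm-up toward palm-down: `atan2(gx, gz)` in degrees.  Zero when the
#' palm faces fully up; positive as it rotates toward prone.  When the
#' forearm is exactly vertical (`gx = gz = 0`) the pronation angle is
#' undefined and `NA` is returned with a warning; [stream_to_angles()]
#' holds the last valid value across such samples.
#'
#' @inheritParams drift_angle
#' @return Pronation angle(s) in degrees, in `[-180, 180]`.
#' @export
pronation_angle <- function(g) {
  g <- as_gravity_matrix(g)
  sing <- sqrt(g[, 1]^2 + g[, 3]^2) < 1e-9
  phi <- atan2(g[, 1], g[, 3]) * 180 / pi
  if (any(sing)) {
    warning("pronation undefined for vertical forearm; returning NA")
    phi[sing] <- NA_real_
  }
  phi
}

#' Construct an angle series
#'
#' @param t sample times in seconds, strictly increasing.
#' @param drift_deg drift angles in degrees, in `[-90, 90]`.
#' @param pron_deg pronation angles in degrees, in `[-180, 180]`.
#' @param side,subject_id metadata carried through from the stream.
#' @param rate_hz sampling rate.
#' @return A data frame of class `pdt_angles` with columns `t`,
#'   `drift_deg`, `pron_deg` and attributes `side`, `subject_id`,
#'   `rate_hz`.
#' @export
pdt_angles <- function(t, drift_deg, pron_deg, side = NA_character_,
                       subject_id = NA_character_, rate_hz = NULL) {
  n <- length(t)
  if (length(drift_deg) != n || length(pron_deg) != n)
    stop_pdt("t, drift_deg, pron_deg must have equal length",
             "pdt_data_error")
  if (n > 1L && any(diff(t) <= 0))
    stop_pdt("timestamps are not strictly increasing", "pdt_data_error")
  if (any(drift_deg < -90 - 1e-9 | drift_deg > 90 + 1e-9, na.rm = TRUE))
    stop_pdt("drift_deg outside [-90, 90]", "pdt_data_error")
  if (any(pron_deg < -180 - 1e-9 | pron_deg > 180 + 1e-9, na.rm = TRUE))
    stop_pdt("pron_deg outside [-180, 180]", "pdt_data_error")
  if (is.null(rate_hz)) rate_hz <- if (n > 1L) 1 / median(diff(t)) else NA_real_
  structure(
    data.frame(t = as.numeric(t), drift_deg = as.numeric(drift_deg),
               pron_deg = as.numeric(pron_deg)),
    side = side, subject_id = subject_id, rate_hz = rate_hz,
    class = c("pdt_angles", "data.frame"))
}

# carry forward the last valid value over NA runs; leading NAs take the
# first valid value, an all-NA series becomes 0
fill_hold_last <- function(x) {
  if (!anyNA(x)) return(x)
  if (all(is.na(x))) return(rep(0, length(x)))
  idx <- seq_along(x)
  ok <- !is.na(x)
  filled <- approx(idx[ok], x[ok], idx, method = "constant",
                   rule = 2, f = 0)$y
  filled
}

#' Convert a raw stream into drift and pronation angle series
#'
#' Composes [estimate_gravity()], [drift_angle()] and
#' [pronation_angle()]; sample count is preserved.  Samples where the
#' forearm is exactly vertical (pronation undefined) inherit the last
#' valid pronation value.
#'
#' @inheritParams estimate_gravity
#' @return A [pdt_angles()] series of the same length as the stream.
#' @export
stream_to_angles <- function(stream, cutoff_hz = 1) {
  g <- estimate_gravity(stream, cutoff_hz)
  drift <- drift_angle(g)
  pron <- withCallingHandlers(
    pronation_angle(g),
    warning = function(w) {
      if (grepl("pronation undefined", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  if (anyNA(pron)) {
    warning("vertical-forearm samples: holding last valid pronation value")
    pron <- fill_hold_last(pron)
  }
  pdt_angles(stream$t, drift, pron, side = stream$side,
             subject_id = stream$subject_id, rate_hz = stream$rate_hz)
}
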