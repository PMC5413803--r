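#' @title Ground-truthed synthetic PDT recordings
#'
#' @description
#' No public corpus of pronator-drift recordings exists, so the package
#' ships a forward simulator.  A subject with weakness severity
#' `s in [0, 1]` holds the palms-up posture for 20 s; the weak arm
#' drifts downward with an exponential approach to `s * drift_max_deg`,
#' pronates analogously toward `s * pron_max_deg`, oscillates at
#' `osc_freq_hz` with amplitude `s * osc_amp_deg`, and shows an initial
#' dip — a transient downward excursion in the first seconds caused by
#' device weight and postural settling.  The counter limb mirrors the
#' weak side's deterministic motion scaled by `counter_coupling`, with
#' its own noise.  Angle trajectories are converted to accelerometer
#' streams through the exact inverse of the tilt geometry used by
#' [stream_to_angles()], plus white sensor noise.
#'
#' @name synthetic-data
NULL

#' Simulation parameters
#'
#' @param severity weakness severity `s` in `[0, 1]`; 0 = healthy.
#' @param drift_max_deg asymptotic drift at `s = 1` (degrees).
#' @param pron_max_deg asymptotic pronation at `s = 1` (degrees).
#' @param drift_tau_s exponential approach time constant (seconds).
#' @param osc_amp_deg oscillation amplitude at `s = 1` (degrees).
#' @param osc_freq_hz oscillation frequency (Hz).
#' @param counter_coupling fraction of the weak side's motion mirrored
#'   by the counter limb, in `[0, 1)`.
#' @param accel_noise_sd_g white sensor noise SD per axis (g).
#' @param traj_noise_deg SD of the smooth (sub-hertz) postural wobble
#'   added to each angle trajectory (degrees).
#' @param rate_hz sampling rate (Hz).
#' @param duration_s recording length (seconds); must cover the
#'   analysis window.
#' @param initial_dip_deg peak depth of the initial dip (degrees).
#' @param dip_recovery_s the dip has fully recovered by this time
#'   (seconds).
#' @return A list of class `pdt_sim_params`.
#' @export
sim_params <- function(severity = 1, drift_max_deg = 30, pron_max_deg = 60,
                       drift_tau_s = 4, osc_amp_deg = 5, osc_freq_hz = 3,
                       counter_coupling = 0.3, accel_noise_sd_g = 0.02,
                       traj_noise_deg = 0.5, rate_hz = 50, duration_s = 20,
                       initial_dip_deg = 10, dip_recovery_s = 5) {
  p <- list(severity = severity, drift_max_deg = drift_max_deg,
            pron_max_deg = pron_max_deg, drift_tau_s = drift_tau_s,
            osc_amp_deg = osc_amp_deg, osc_freq_hz = osc_freq_hz,
            counter_coupling = counter_coupling,
            accel_noise_sd_g = accel_noise_sd_g,
            traj_noise_deg = traj_noise_deg, rate_hz = rate_hz,
            duration_s = duration_s, initial_dip_deg = initial_dip_deg,
            dip_recovery_s = dip_recovery_s)
  nonneg <- c("drift_max_deg", "pron_max_deg", "drift_tau_s", "osc_amp_deg",
              "osc_freq_hz", "accel_noise_sd_g", "traj_noise_deg",
              "initial_dip_deg", "dip_recovery_s")
  if (any(vapply(p[nonneg], function(v) v < 0, logical(1))))
    stop_pdt("magnitudes must be non-negative", "pdt_parameter_error")
  if (severity < 0 || severity > 1)
    stop_pdt("severity must lie in [0, 1]", "pdt_parameter_error")
  if (counter_coupling < 0 || counter_coupling >= 1)
    stop_pdt("counter_coupling must lie in [0, 1)", "pdt_parameter_error")
  if (rate_hz <= 0 || duration_s <= 0)
    stop_pdt("rate_hz and duration_s must be positive",
             "pdt_parameter_error")
  structure(p, class = "pdt_sim_params")
}

# half-sine initial dip: zero at t = 0 and t >= recovery, peak in between
dip_term <- function(t, depth_deg, recovery_s) {
  ifelse(t < recovery_s & recovery_s > 0,
         depth_deg * sin(pi * t / recovery_s), 0)
}

# smooth sub-hertz wobble: cubic spline through random knots every 0.5 s
smooth_noise <- function(t, sd_deg) {
  if (sd_deg == 0) return(rep(0, length(t)))
  knots <- seq(min(t), max(t), by = 0.5)
  if (length(knots) < 4L) return(rep(0, length(t)))
  spline(knots, rnorm(length(knots), sd = sd_deg), xout = t)$y
}

#' Simulated angle trajectory for one side
#'
#' The weak side follows
#' `theta(t) = dip(t) + s * drift_max * (1 - exp(-t / tau)) +
#'  s * osc_amp * sin(2 pi f t + phase) + wobble`, and pronation is
#' analogous with `pron_max` (no dip term — the dip is a drop of the
#' arm, not a rotation).  The counter side is the weak side's
#' deterministic trajectory scaled by `counter_coupling`, with
#' independent wobble.
#'
#' @param params a [sim_params()].
#' @param side `"weak"` or `"counter"`.
#' @param t time grid covering `[0, duration_s]`.
#' @param phases length-2 oscillation phases (drift, pronation) in
#'   radians; the counter side must share the weak side's phases.
#' @param seed optional RNG seed for the wobble; `NULL` uses the current
#'   RNG stream.
#' @return A [pdt_angles()] series (ground truth, noise-free sensor-wise).
#' @export
angle_trajectory <- function(params, side = c("weak", "counter"), t,
                             phases = c(0, 0), seed = NULL) {
  stopifnot(inherits(params, "pdt_sim_params"))
  side <- match.arg(side)
  if (length(t) < 2L || max(t) < params$duration_s - 1.5 / params$rate_hz)
    stop_pdt("time grid does not cover the recording duration",
             "pdt_contract_error")
  s <- params$severity
  gain <- if (side == "weak") 1 else params$counter_coupling
  base <- function(max_deg, phase, with_dip) {
    d <- if (with_dip) dip_term(t, params$initial_dip_deg,
                                params$dip_recovery_s) else 0
    d + s * max_deg * (1 - exp(-t / params$drift_tau_s)) +
      s * params$osc_amp_deg * sin(2 * pi * params$osc_freq_hz * t + phase)
  }
  gen <- function() {
    drift <- gain * base(params$drift_max_deg, phases[1], TRUE) +
      smooth_noise(t, params$traj_noise_deg)
    pron <- gain * base(params$pron_max_deg, phases[2], FALSE) +
      smooth_noise(t, params$traj_noise_deg)
    pdt_angles(t, pmin(90, pmax(-90, drift)),
               pmin(180, pmax(-180, pron)),
               side = side, rate_hz = params$rate_hz)
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Forward sensor model: angles to accelerometer stream
#'
#' The gravity-reaction vector at drift `theta` and pronation `phi` is
#' `g = (sin phi cos theta, sin theta, cos phi cos theta)` — the exact
#' inverse of [drift_angle()] / [pronation_angle()] — plus white noise
#' of SD `noise_sd` per axis.
#'
#' @param series a [pdt_angles()] series with `|drift| < 90`.
#' @param noise_sd per-axis white-noise SD in g.
#' @param seed optional RNG seed; `NULL` uses the current stream.
#' @param subject_id carried into the stream.
#' @return A [pdt_stream()].
#' @export
angles_to_accel <- function(series, noise_sd = 0, seed = NULL,
                            subject_id = attr(series, "subject_id")) {
  stopifnot(inherits(series, "pdt_angles"))
  if (any(abs(series$drift_deg) >= 90))
    stop_pdt("|drift| must stay below 90 degrees", "pdt_contract_error")
  th <- series$drift_deg * pi / 180
  ph <- series$pron_deg * pi / 180
  gen <- function() {
    n <- length(th)
    noise <- if (noise_sd > 0) matrix(rnorm(3 * n, sd = noise_sd), n, 3)
             else matrix(0, n, 3)
    pdt_stream(series$t,
               sin(ph) * cos(th) + noise[, 1],
               sin(th) + noise[, 2],
               cos(ph) * cos(th) + noise[, 3],
               rate_hz = attr(series, "rate_hz"),
               side = attr(series, "side"), subject_id = subject_id)
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

# MRC grade from severity: heavier weakness earns a lower grade
mrc_from_severity <- function(s) {
  ifelse(s == 0, "5",
  ifelse(s > 0.775, "4",
  ifelse(s > 0.5, "4+", "5")))
}

simulate_subject <- function(params, subject_id, group, seed) {
  with_seed(seed, {
    t <- seq(0, params$duration_s - 1 / params$rate_hz,
             by = 1 / params$rate_hz)
    phases <- runif(2, 0, 2 * pi)
    weak_ang <- angle_trajectory(params, "weak", t, phases)
    cnt_ang <- angle_trajectory(params, "counter", t, phases)
    attr(weak_ang, "subject_id") <- subject_id
    attr(cnt_ang, "subject_id") <- subject_id
    weak_str <- angles_to_accel(weak_ang, params$accel_noise_sd_g)
    cnt_str <- angles_to_accel(cnt_ang, params$accel_noise_sd_g)
    structure(list(
      subject_id = subject_id, group = group,
      mrc = if (group == "patient") mrc_from_severity(params$severity)
            else "5",
      severity = params$severity,
      weak_stream = weak_str, counter_stream = cnt_str,
      weak_angles = weak_ang, counter_angles = cnt_ang),
      class = "pdt_sim_subject")
  })
}

#' Simulate a PDT cohort
#'
#' Patients draw severity uniformly from `severity_range`; controls have
#' severity 0 (their non-dominant arm is recorded as the weak-equivalent
#' side).  MRC grades follow severity: `s > 0.775` is grade 4,
#' `0.5 < s <= 0.775` grade 4+, lower grade 5.  All randomness flows
#' from the single cohort seed through per-subject substreams, so any
#' subject is individually reproducible.
#'
#' @param n_patients,n_controls group sizes (defaults 16 and 10).
#' @param severity_range patient severity range (default `c(0.4, 1)`).
#' @param params a [sim_params()] template (its `severity` is
#'   overwritten per subject).
#' @param seed cohort RNG seed.
#' @return A list of `pdt_sim_subject` objects, class `pdt_cohort`, with
#'   attribute `usable_for_training` (FALSE when either group is empty).
#' @export
simulate_cohort <- function(n_patients = 16, n_controls = 10,
                            severity_range = c(0.4, 1),
                            params = sim_params(), seed = 1) {
  if (n_patients < 0 || n_controls < 0)
    stop_pdt("group sizes must be non-negative", "pdt_parameter_error")
  if (length(severity_range) != 2L || any(severity_range < 0) ||
      any(severity_range > 1) || severity_range[1] > severity_range[2])
    stop_pdt("severity_range must be an increasing pair within [0, 1]",
             "pdt_parameter_error")
  n <- n_patients + n_controls
  draws <- with_seed(seed, list(
    sev = runif(n_patients, severity_range[1], severity_range[2]),
    sub_seeds = sample.int(.Machine$integer.max - 1L, n)))
  ids <- c(sprintf("P%02d", seq_len(n_patients)),
           sprintf("C%02d", seq_len(n_controls)))
  groups <- rep(c("patient", "control"), c(n_patients, n_controls))
  sev <- c(draws$sev, rep(0, n_controls))
  subjects <- lapply(seq_len(n), function(i) {
    p <- params
    p$severity <- sev[i]
    simulate_subject(p, ids[i], groups[i], draws$sub_seeds[i])
  })
  structure(subjects, class = "pdt_cohort",
            usable_for_training = n_patients > 0 && n_controls > 0,
            seed = seed)
}

#' @export
print.pdt_cohort <- function(x, ...) {
  groups <- vapply(x, `[[`, character(1), "group")
  cat(sprintf("<pdt_cohort> %d subjects (%d patients, %d controls)%s\n",
              length(x), sum(groups == "patient"),
              sum(groups == "control"),
              if (!attr(x, "usable_for_training"))
                " [not usable for training]" else ""))
  invisible(x)
}

#' Extract the feature matrix of a simulated (or loaded) cohort
#'
#' Runs [stream_to_angles()] and [extract_features()] on every subject.
#'
#' @param cohort a `pdt_cohort` (or list with the same subject fields).
#' @param cutoff_hz gravity-isolation low-pass cutoff.
#' @param cfg a [window_config()].
#' @return A feature matrix data frame (see [validate_feature_matrix()]).
#' @export
cohort_features <- function(cohort, cutoff_hz = 1, cfg = window_config()) {
  rows <- lapply(cohort, function(sub) {
    weak <- stream_to_angles(sub$weak_stream, cutoff_hz)
    cnt <- stream_to_angles(sub$counter_stream, cutoff_hz)
    f <- extract_features(weak, cnt, cfg)
    cbind(data.frame(subject_id = sub$subject_id, group = sub$group,
                     mrc = sub$mrc, stringsAsFactors = FALSE),
          as.data.frame(as.list(stats::setNames(as.numeric(f), names(f))),
                        check.names = FALSE))
  })
  out <- do.call(rbind, rows)
  validate_feature_matrix(out)
  out
}

#' Write a simulated cohort to disk
#'
#' Produces one sensor file per device (`<subject>_<side>.csv`, header
#' `t,ax,ay,az`, units g), a roster file (`roster.csv`: subject_id,
#' group, mrc, severity) and a ground-truth angle file per subject.
#'
#' @param cohort a `pdt_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sub in cohort) {
    for (side in c("weak", "counter")) {
      st <- sub[[paste0(side, "_stream")]]
      write.csv(data.frame(t = st$t, ax = st$ax, ay = st$ay, az = st$az),
                file.path(dir, sprintf("%s_%s.csv", sub$subject_id, side)),
                row.names = FALSE)
      an <- sub[[paste0(side, "_angles")]]
      write.csv(as.data.frame(an),
                file.path(dir, sprintf("%s_%s_truth.csv",
                                       sub$subject_id, side)),
                row.names = FALSE)
    }
  }
  roster <- data.frame(
    subject_id = vapply(cohort, `[[`, character(1), "subject_id"),
    group = vapply(cohort, `[[`, character(1), "group"),
    mrc = vapply(cohort, `[[`, character(1), "mrc"),
    severity = vapply(cohort, `[[`, numeric(1), "severity"))
  write.csv(roster, file.path(dir, "roster.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a cohort previously written by [write_cohort()]
#'
#' @param dir directory containing `roster.csv` and the sensor files.
#' @return A `pdt_cohort` whose subjects carry streams (ground-truth
#'   angles are reloaded when the `_truth.csv` files are present).
#' @export
read_cohort <- function(dir) {
  roster_path <- file.path(dir, "roster.csv")
  if (!file.exists(roster_path))
    stop_pdt(sprintf("no roster.csv under %s", dir), "pdt_format_error")
  roster <- read.csv(roster_path, stringsAsFactors = FALSE)
  subjects <- lapply(seq_len(nrow(roster)), function(i) {
    id <- roster$subject_id[i]
    sub <- list(subject_id = id, group = roster$group[i],
                mrc = as.character(roster$mrc[i]),
                severity = roster$severity[i] %||% NA_real_)
    for (side in c("weak", "counter")) {
      sub[[paste0(side, "_stream")]] <-
        load_stream(file.path(dir, sprintf("%s_%s.csv", id, side)),
                    side = side, subject_id = id)
      tr <- file.path(dir, sprintf("%s_%s_truth.csv", id, side))
      if (file.exists(tr)) {
        a <- read.csv(tr)
        sub[[paste0(side, "_angles")]] <-
          pdt_angles(a$t, a$drift_deg, a$pron_deg, side = side,
                     subject_id = id)
      }
    }
    structure(sub, class = "pdt_sim_subject")
  })
  groups <- vapply(subjects, `[[`, character(1), "group")
  structure(subjects, class = "pdt_cohort",
            usable_for_training = all(c("patient", "control") %in% groups))
}
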