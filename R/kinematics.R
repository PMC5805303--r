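#' Butterworth filter specification
#'
#' First-order low-pass Butterworth with a 2.5 Hz cut-off at 50 Hz sampling,
#' the smoothing applied to all cursor data before measure extraction. By
#' default the filter is run forward and backward (zero-phase), so peak
#' velocity timing is not shifted by filter lag; single-pass mode is kept as a
#' switch.
#'
#' @param order Filter order (default 1).
#' @param cutoff_hz Cut-off frequency, Hz (must be below the Nyquist rate).
#' @param fs_hz Sampling rate, Hz.
#' @param zero_phase Apply forward-backward (`TRUE`, default) or single pass.
#' @return An object of class `"filter_spec"`.
#' @export
filter_spec <- function(order = 1, cutoff_hz = 2.5, fs_hz = 50,
                        zero_phase = TRUE) {
  if (!(cutoff_hz > 0 && cutoff_hz < fs_hz / 2))
    stop("'cutoff_hz' must lie in (0, fs/2)")
  structure(list(order = order, cutoff_hz = cutoff_hz, fs_hz = fs_hz,
                 zero_phase = isTRUE(zero_phase)),
            class = "filter_spec")
}

#' Low-pass filter a sampled position series
#'
#' Each coordinate is filtered independently with the Butterworth filter in
#' `spec`; the filter has unit DC gain, so constant series pass unchanged.
#'
#' @param series Numeric vector or n x 2 matrix of uniformly sampled positions.
#' @param spec A [filter_spec()].
#' @return Filtered series, same shape as the input.
#' @export
lowpass_filter <- function(series, spec = filter_spec()) {
  v <- if (is.matrix(series)) series else matrix(series, ncol = 1)
  if (nrow(v) < 5) stop("series too short to filter (need >= 5 samples)")
  bf <- signal::butter(spec$order, 2 * spec$cutoff_hz / spec$fs_hz, type = "low")
  # edge handling for the zero-phase pass: replicate end values so the
  # forward-backward transient decays into a constant, not a zero jump
  pad <- ceiling(3 * spec$fs_hz / spec$cutoff_hz)
  out <- apply(v, 2, function(col) {
    if (spec$zero_phase) {
      ext <- c(rep(col[1], pad), col, rep(col[length(col)], pad))
      fwd <- as.numeric(signal::filter(bf, ext))
      bwd <- rev(as.numeric(signal::filter(bf, rev(fwd))))
      bwd[(pad + 1):(pad + length(col))]
    } else {
      as.numeric(signal::filter(bf, col))
    }
  })
  if (is.matrix(series)) out else as.numeric(out)
}

#' Tangential speed profile
#'
#' Central differences in the interior, one-sided differences at the ends.
#'
#' @param xy n x 2 matrix of positions (cm), n >= 3, uniformly sampled.
#' @param fs Sampling rate, Hz.
#' @return Non-negative speed in cm/s, one value per sample.
#' @export
speed_profile <- function(xy, fs) {
  if (!is.matrix(xy)) xy <- matrix(xy, ncol = 1)
  n <- nrow(xy)
  if (n < 3) stop("need at least 3 samples for a speed profile")
  vel <- matrix(0, n, ncol(xy))
  vel[1, ] <- (xy[2, ] - xy[1, ]) * fs
  vel[n, ] <- (xy[n, ] - xy[n - 1, ]) * fs
  vel[2:(n - 1), ] <- (xy[3:n, , drop = FALSE] -
                       xy[1:(n - 2), , drop = FALSE]) * fs / 2
  sqrt(rowSums(vel^2))
}

#' Movement onset by velocity criterion
#'
#' Onset is the first sample at or above `fraction` of the global peak speed,
#' found by scanning backward from the peak: the latest below-threshold sample
#' before the peak, plus one. The criterion fraction is 0.10 for reach trials
#' and 0.33 for tracking trials.
#'
#' @param speed Speed profile (cm/s); its maximum must be positive.
#' @param fraction Threshold fraction of peak speed, in (0, 1).
#' @return Onset sample index.
#' @export
movement_onset <- function(speed, fraction) {
  if (!(fraction > 0 && fraction < 1)) stop("'fraction' must be in (0, 1)")
  if (max(speed) <= 0) stop("no movement: speed profile is all zero")
  peak <- which.max(speed)
  thr <- fraction * speed[peak]
  i <- peak
  while (i > 1 && speed[i - 1] >= thr) i <- i - 1
  as.integer(i)
}

#' Movement offset by velocity criterion
#'
#' The last sample before the speed first drops below `fraction` of the global
#' peak after the peak. If the speed never falls below the threshold the last
#' sample is returned, flagged with `attr(, "flagged") = TRUE`.
#'
#' @inheritParams movement_onset
#' @param fraction Threshold fraction of peak speed (default 0.33).
#' @return Offset sample index (possibly carrying a `flagged` attribute).
#' @export
movement_offset <- function(speed, fraction = 0.33) {
  if (!(fraction > 0 && fraction < 1)) stop("'fraction' must be in (0, 1)")
  if (max(speed) <= 0) stop("no movement: speed profile is all zero")
  peak <- which.max(speed)
  thr <- fraction * speed[peak]
  n <- length(speed)
  i <- peak
  while (i < n && speed[i + 1] >= thr) i <- i + 1
  if (i == n && speed[n] >= thr) structure(as.integer(n), flagged = TRUE)
  else as.integer(i)
}

#' Angular error at peak velocity
#'
#' The signed, CCW-positive angular difference between the cursor and the
#' target, both measured as directions from the home position, at the sample
#' of peak cursor speed (earliest sample on ties). Wrapped to (-180, 180].
#'
#' @param cursor_xy n x 2 cursor (or, on no-cursor trials, hand) positions.
#' @param target_xy Either a single target position (length 2) or an n x 2
#'   series; the sample at peak speed is used.
#' @param home Home position (default origin).
#' @param fs Sampling rate used to locate the peak (default 50).
#' @param speed Optional precomputed speed profile for `cursor_xy`.
#' @return Signed error in degrees.
#' @export
angular_error_at_peak_velocity <- function(cursor_xy, target_xy,
                                           home = c(0, 0), fs = 50,
                                           speed = NULL) {
  if (is.null(speed)) speed <- speed_profile(cursor_xy, fs)
  peak <- which.max(speed)
  cvec <- cursor_xy[peak, ] - home
  if (sqrt(sum(cvec^2)) < 1e-9)
    stop("cursor at home at peak velocity: direction undefined")
  tpos <- if (is.matrix(target_xy)) target_xy[peak, ] else target_xy
  tvec <- tpos - home
  if (sqrt(sum(tvec^2)) < 1e-9) stop("target at home: direction undefined")
  unname(wrap_angle((atan2(cvec[2], cvec[1]) - atan2(tvec[2], tvec[1])) * 180 / pi))
}

#' Tracking root-mean-square error
#'
#' Square root of the mean squared Euclidean cursor-to-target distance over
#' aligned samples. The caller windows the series (the standard window is
#' target-motion onset through target halt; see [trial_measures()]).
#'
#' @param cursor_xy,target_xy Equal-length n x 2 position series, n >= 1.
#' @return RMSE in cm.
#' @examples
#' tracking_rmse(cbind(0, c(0, 3, 4)), cbind(0, c(0, 0, 0)))
#' @export
tracking_rmse <- function(cursor_xy, target_xy) {
  if (!is.matrix(cursor_xy)) cursor_xy <- matrix(cursor_xy, ncol = 2)
  if (!is.matrix(target_xy)) target_xy <- matrix(target_xy, ncol = 2)
  if (nrow(cursor_xy) != nrow(target_xy) || nrow(cursor_xy) < 1)
    stop("cursor and target series must have equal, positive length")
  sqrt(mean(rowSums((cursor_xy - target_xy)^2)))
}

#' Pursuit timing descriptors for a tracking trial
#'
#' Computes, from the filtered cursor series of one tracking trajectory:
#' `pursuit_latency_ms`, the time from target-motion start (t = 0) to
#' cursor-movement onset at the 33 percent of peak speed criterion;
#' `onset_distance_cm`, the cursor-to-target Euclidean distance at that
#' sample; and `movement_time_ms`, the time from cursor onset to cursor offset
#' (33 percent criterion on both sides).
#'
#' @param traj A `"trial_trajectory"` from [simulate_track_trial()] (or any
#'   list with `t_ms`, `cursor_xy_cm`, `target_xy_cm`).
#' @param spec A [filter_spec()] applied to the cursor before the speed
#'   profile; `NULL` for no filtering.
#' @return A list with the three descriptors.
#' @export
pursuit_descriptors <- function(traj, spec = filter_spec()) {
  cur <- traj$cursor_xy_cm
  if (is.null(cur)) stop("pursuit descriptors need a cursor-visible trial")
  fs <- 1000 / diff(traj$t_ms[1:2])
  if (!is.null(spec)) cur <- lowpass_filter(cur, spec)
  sp <- speed_profile(cur, fs)
  onset <- movement_onset(sp, 0.33)
  offset <- movement_offset(sp, 0.33)
  list(pursuit_latency_ms = traj$t_ms[onset] - traj$t_ms[1],
       onset_distance_cm = sqrt(sum((cur[onset, ] - traj$target_xy_cm[onset, ])^2)),
       movement_time_ms = traj$t_ms[offset] - traj$t_ms[onset])
}

#' Kinematic measures for one trial
#'
#' Runs the standard per-trial pipeline: low-pass filtering of the effector
#' series (cursor when visible, hand on no-cursor trials), speed profile,
#' onset/offset detection (10 percent of peak speed for reaches, 33 percent
#' for tracking), angular error at peak velocity, and - for tracking trials -
#' the positional RMSE over the target-motion window (target onset through
#' target halt) plus the pursuit timing descriptors.
#'
#' @param traj A `"trial_trajectory"`.
#' @param spec A [filter_spec()]; `NULL` disables filtering.
#' @param home Home position (default origin).
#' @return A one-row data.frame of trial identifiers and measures.
#' @export
trial_measures <- function(traj, spec = filter_spec(), home = c(0, 0)) {
  s <- traj$spec
  is_track <- s$movement_type == "TRACK"
  eff <- if (!is.null(traj$cursor_xy_cm)) traj$cursor_xy_cm else traj$hand_xy_cm
  fs <- 1000 / diff(traj$t_ms[1:2])
  if (!is.null(spec)) eff <- lowpass_filter(eff, spec)
  sp <- speed_profile(eff, fs)
  onset <- movement_onset(sp, if (is_track) 0.33 else 0.10)
  offset <- movement_offset(sp, 0.33)
  peak <- which.max(sp)
  ang <- angular_error_at_peak_velocity(eff, traj$target_xy_cm, home, fs,
                                        speed = sp)
  rmse <- NA_real_
  lat <- ond <- mt <- NA_real_
  if (is_track) {
    halt <- min(floor(s$target_duration_ms * fs / 1000) + 1, nrow(eff))
    rmse <- tracking_rmse(eff[1:halt, , drop = FALSE],
                          traj$target_xy_cm[1:halt, , drop = FALSE])
    pd <- pursuit_descriptors(
      list(t_ms = traj$t_ms, cursor_xy_cm = eff, target_xy_cm = traj$target_xy_cm),
      spec = NULL)
    lat <- pd$pursuit_latency_ms; ond <- pd$onset_distance_cm
    mt <- pd$movement_time_ms
  }
  data.frame(index = s$index, design = s$design, phase = s$phase,
             movement_type = s$movement_type,
             target_angle_deg = s$target_angle_deg,
             rotation_deg = s$rotation_deg,
             peak_speed_cm_s = sp[peak], onset_index = onset,
             offset_index = as.integer(offset),
             offset_flagged = isTRUE(attr(offset, "flagged")),
             angular_error_deg = ang, rmse_cm = rmse,
             pursuit_latency_ms = lat, onset_distance_cm = ond,
             movement_time_ms = mt, stringsAsFactors = FALSE)
}

#' Measures table for a session (or group of sessions)
#'
#' @param x A `"session_data"` object or a list of them (e.g. from
#'   [simulate_group()]).
#' @param spec A [filter_spec()].
#' @return A data.frame with one row per trial, including a `participant_id`
#'   column.
#' @export
measures_table <- function(x, spec = filter_spec()) {
  if (inherits(x, "session_data")) x <- list(x)
  out <- lapply(x, function(sess) {
    m <- do.call(rbind, lapply(sess$trajectories, trial_measures, spec = spec))
    cbind(participant_id = sess$participant_id, m, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
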