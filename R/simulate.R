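FS_HZ <- 50
TRACK_CAP_MS <- 3000

# Minimum-jerk position fraction on [0, 1].
min_jerk <- function(tau) tau^3 * (10 - 15 * tau + 6 * tau^2)

new_trajectory <- function(t_ms, hand, cursor, target, spec, state,
                           error_signal = NA_real_) {
  structure(list(t_ms = t_ms, hand_xy_cm = hand, cursor_xy_cm = cursor,
                 target_xy_cm = target, spec = spec, hidden_state = state,
                 error_signal = error_signal),
            class = "trial_trajectory")
}

#' @export
print.trial_trajectory <- function(x, ...) {
  cat(sprintf("%s trial (%s, target %g deg, rotation %g deg): %d samples at %g Hz\n",
              x$spec$movement_type, x$spec$phase, x$spec$target_angle_deg,
              x$spec$rotation_deg, length(x$t_ms),
              1000 / diff(x$t_ms[1:2])))
  invisible(x)
}

spec_row <- function(spec) {
  if (inherits(spec, "data.frame")) as.list(spec[1, ]) else as.list(spec)
}

#' Simulate one reach (or no-cursor reach) trial
#'
#' The hand travels in a straight line from home along direction
#' `target_angle + z_shared + z_reach + aiming noise`, with a minimum-jerk
#' speed profile covering the target radius (12 cm) over `reach_duration_ms`.
#' On cursor-visible trials the cursor is the hand rotated about home by the
#' trial's rotation and the learner state is updated with the trial's angular
#' error at peak velocity; no-cursor trials leave the state untouched.
#'
#' Consumes the current RNG stream (one normal draw); seed handling is done by
#' [simulate_session()].
#'
#' @param spec A single trial row from [build_session()] (REACH or
#'   NOCURSOR_REACH).
#' @param state The pre-trial [learner_state()].
#' @param lp A [learner_params()].
#' @param np A [noise_params()].
#' @param geometry A [target_geometry()].
#' @param fs Sampling rate, Hz.
#' @return A `"trial_trajectory"` whose `hidden_state` is the post-trial state.
#' @export
simulate_reach_trial <- function(spec, state, lp = calibrate_defaults(),
                                 np = noise_params(), geometry = target_geometry(),
                                 fs = FS_HZ) {
  spec <- spec_row(spec)
  if (spec$movement_type == "TRACK") stop("TRACK spec passed to reach simulator")
  visible <- isTRUE(spec$cursor_visible)
  z <- state$z_shared + state$z_reach
  aim <- spec$target_angle_deg + z + rnorm(1, 0, np$aim_sd_deg)
  n <- floor(np$reach_duration_ms * fs / 1000) + 1
  t_ms <- (seq_len(n) - 1) * 1000 / fs
  d <- geometry$target_radius_cm * min_jerk(t_ms / np$reach_duration_ms)
  u <- unit_vec(aim)
  hand <- cbind(geometry$home[1] + d * u[1], geometry$home[2] + d * u[2])
  target <- matrix(target_position(spec$target_angle_deg, geometry), n, 2,
                   byrow = TRUE)
  cursor <- NULL
  err <- NA_real_
  if (visible) {
    cursor <- rotate_xy(hand, spec$rotation_deg, geometry$home)
    # angular error at peak velocity; exact for a straight-line reach
    err <- wrap_angle(aim + spec$rotation_deg - spec$target_angle_deg)
    state <- update_learner(state, "reach", err, lp)
  }
  new_trajectory(t_ms, hand, cursor, target, spec, state, err)
}

#' Simulate one pursuit tracking trial
#'
#' The target moves from home to its final position at constant speed over the
#' trial's target duration. The hand follows a first-order proportional pursuit
#' law, `hand velocity = pursuit_gain * (goal - hand)`, chasing a goal equal to
#' the target position `pursuit_lag_ms` in the past rotated about home by the
#' learner's tracking compensation (`z_shared + z_track`, plus per-trial
#' calibration noise). The cursor is the hand rotated by the trial rotation, so
#' its angular offset from the target is `rotation + compensation`, vanishing
#' as compensation approaches the negative rotation. Simulation continues past
#' target halt until the cursor overlaps the target or a 3 s cap. The learner
#' is updated with the mean signed cursor-to-target angular error between
#' cursor motion onset (33 percent of peak speed) and target halt, scaled by
#' `track_error_weight`.
#'
#' @inheritParams simulate_reach_trial
#' @param spec A single TRACK trial row from [build_session()].
#' @return A `"trial_trajectory"` whose `hidden_state` is the post-trial state.
#' @export
simulate_track_trial <- function(spec, state, lp = calibrate_defaults(),
                                 np = noise_params(), geometry = target_geometry(),
                                 fs = FS_HZ) {
  spec <- spec_row(spec)
  if (spec$movement_type != "TRACK") stop("non-TRACK spec passed to track simulator")
  duration <- spec$target_duration_ms
  dt_ms <- 1000 / fs
  n <- floor(TRACK_CAP_MS * fs / 1000) + 1
  t_ms <- (seq_len(n) - 1) * dt_ms
  tp <- target_path(spec, geometry, fs, duration_ms = duration)
  halt_idx <- nrow(tp$xy)
  target <- rbind(tp$xy, matrix(tp$xy[halt_idx, ], n - halt_idx, 2, byrow = TRUE))
  z <- state$z_shared + state$z_track + rnorm(1, 0, np$aim_sd_deg)
  lag_idx <- pmax(1, seq_len(n) - round(np$pursuit_lag_ms / dt_ms))
  goal <- rotate_xy(target[lag_idx, , drop = FALSE], z, geometry$home)
  a <- np$pursuit_gain * dt_ms / 1000
  a <- min(a, 1)
  hand <- cbind(
    as.numeric(stats::filter(a * goal[, 1], 1 - a, "recursive",
                             init = geometry$home[1])),
    as.numeric(stats::filter(a * goal[, 2], 1 - a, "recursive",
                             init = geometry$home[2])))
  cursor <- rotate_xy(hand, spec$rotation_deg, geometry$home)
  # stop once the cursor sits on the halted target (or at the cap)
  overlap <- (geometry$target_diameter_cm + geometry$cursor_diameter_cm) / 2
  dist <- sqrt(rowSums((cursor - target)^2))
  done <- which(seq_len(n) >= halt_idx & dist <= overlap)
  end <- if (length(done)) done[1] else n
  keep <- seq_len(end)
  t_ms <- t_ms[keep]; hand <- hand[keep, , drop = FALSE]
  cursor <- cursor[keep, , drop = FALSE]; target <- target[keep, , drop = FALSE]
  # error signal: mean signed angular misalignment, cursor onset -> target halt
  sp <- speed_profile(cursor, fs)
  err <- NA_real_
  if (max(sp) > 0) {
    onset <- movement_onset(sp, 0.33)
    win <- onset:min(halt_idx, length(t_ms))
    rc <- sqrt(rowSums(sweep(cursor, 2, geometry$home)^2))
    rt <- sqrt(rowSums(sweep(target, 2, geometry$home)^2))
    win <- win[rc[win] > 0.1 & rt[win] > 0.1]
    if (length(win)) {
      ang <- wrap_angle(
        atan2(cursor[win, 2] - geometry$home[2], cursor[win, 1] - geometry$home[1]) * 180 / pi -
        atan2(target[win, 2] - geometry$home[2], target[win, 1] - geometry$home[1]) * 180 / pi)
      err <- mean(ang) * lp$track_error_weight
      state <- update_learner(state, "track", err, lp)
    }
  }
  new_trajectory(t_ms, hand, cursor, target, spec, state, err)
}

#' Simulate a whole session
#'
#' Runs the learner through every trial of a session design in order,
#' generating one trajectory per trial. Hidden states evolve only on
#' cursor-visible trials; no-cursor trials neither update nor decay the state.
#' With `np$seed` set the whole session is reproducible and the caller's RNG
#' state is untouched.
#'
#' @param design A [build_session()] design.
#' @param lp A [learner_params()] (default [calibrate_defaults()]).
#' @param np A [noise_params()].
#' @param participant_id Identifier stored with the session (default 1).
#' @return An object of class `"session_data"`: list with `trajectories` (one
#'   `"trial_trajectory"` per trial), `design`, `state_audit` (data.frame of
#'   per-trial hidden states `trial`, `z_shared`, `z_reach`, `z_track`,
#'   `error_signal`), `participant_id`, and the parameter objects.
#' @examples
#' des <- build_session("SINGLE_REACH", seed = 1,
#'                      counts = list(aligned_reach = 5, aligned_reach_nc = 5,
#'                                    rotated = 10, rotated_nc = 5))
#' sess <- simulate_session(des, np = noise_params(seed = 1))
#' sess
#' @export
simulate_session <- function(design, lp = calibrate_defaults(),
                             np = noise_params(), participant_id = 1L) {
  stopifnot(inherits(design, "session_design"))
  geometry <- attr(design, "geometry")
  state <- learner_state()
  n <- nrow(design)
  trajs <- vector("list", n)
  audit <- matrix(NA_real_, n, 4)
  with_seed(np$seed, {
    for (i in seq_len(n)) {
      sp <- as.list(design[i, ])
      tr <- if (sp$movement_type == "TRACK")
        simulate_track_trial(sp, state, lp, np, geometry)
      else
        simulate_reach_trial(sp, state, lp, np, geometry)
      state <- tr$hidden_state
      trajs[[i]] <- tr
      audit[i, ] <- c(state$z_shared, state$z_reach, state$z_track,
                      tr$error_signal)
    }
  })
  structure(list(trajectories = trajs, design = design,
                 state_audit = data.frame(trial = seq_len(n),
                                          z_shared = audit[, 1],
                                          z_reach = audit[, 2],
                                          z_track = audit[, 3],
                                          error_signal = audit[, 4]),
                 participant_id = participant_id, learner = lp, noise = np),
            class = "session_data")
}

#' @export
print.session_data <- function(x, ...) {
  st <- utils::tail(x$state_audit, 1)
  cat(sprintf("Simulated %s session, participant %s: %d trials\n",
              x$design$design[1], x$participant_id, nrow(x$design)))
  cat(sprintf("  final hidden state: z_shared = %.2f, z_reach = %.2f, z_track = %.2f deg\n",
              st$z_shared, st$z_reach, st$z_track))
  invisible(x)
}

#' Simulate a group of participants on one design
#'
#' Each participant gets a distinct schedule seed and noise seed derived
#' deterministically from `seed`, so a group is reproducible from a single
#' integer.
#'
#' @param name Design name (see [build_session()]).
#' @param n_participants Number of simulated participants.
#' @param seed Base integer seed.
#' @param lp,np [learner_params()] and [noise_params()] shared by the group
#'   (`np$seed` is overridden per participant).
#' @param counts Optional count overrides passed to [build_session()].
#' @return A list of `"session_data"`, one per participant.
#' @export
simulate_group <- function(name, n_participants, seed,
                           lp = calibrate_defaults(), np = noise_params(),
                           counts = NULL) {
  lapply(seq_len(n_participants), function(i) {
    des_seed <- (as.numeric(seed) + 7919 * i) %% 2147483647
    np_i <- np
    np_i$seed <- (as.numeric(seed) + 104729 * i + 1) %% 2147483647
    des <- build_session(name, des_seed, counts = counts)
    simulate_session(des, lp, np_i, participant_id = i)
  })
}
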