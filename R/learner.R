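#' Parameters of the contextual state-space learner
#'
#' The simulated participant carries three adaptation states, all in degrees of
#' compensatory rotation: `z_shared`, expressed in every movement, and one
#' context-specific state per movement type (`z_reach`, `z_track`). After a
#' cursor-visible trial in context c with performance error e (degrees, the
#' angular error conventions of [angular_error_at_peak_velocity()]):
#' \deqn{z_{shared} \leftarrow A z_{shared} - B_s e, \quad
#'       z_c \leftarrow A z_c - B_c e,}
#' while the other context's state only decays by the retention factor A. Total
#' compensation expressed in context c is `z_shared + z_c`; under a constant
#' rotation r the single-context fixed point of total compensation is
#' \eqn{-r (B_s + B_c) / (1 - A + B_s + B_c)}.
#'
#' @param retention Retention factor A in (0, 1].
#' @param rate_shared Learning rate B_s of the shared state (>= 0).
#' @param rate_context Learning rate B_c of each context state (>= 0);
#'   `rate_shared + rate_context` must be < 1.
#' @param track_error_weight Scalar weight applied to the tracking-trial error
#'   signal before the update (default 1).
#' @return An object of class `"learner_params"`.
#' @seealso [calibrate_defaults()] for the package defaults.
#' @export
learner_params <- function(retention = 0.98, rate_shared = 0.02,
                           rate_context = 0.015, track_error_weight = 1) {
  stopifnot(retention > 0, retention <= 1,
            rate_shared >= 0, rate_context >= 0,
            rate_shared + rate_context < 1,
            track_error_weight >= 0)
  structure(list(retention = retention, rate_shared = rate_shared,
                 rate_context = rate_context,
                 track_error_weight = track_error_weight),
            class = "learner_params")
}

#' Default learner calibration
#'
#' Returns the package's default learner parameters, fixed by three
#' calibration targets taken from the behavioural findings the simulator
#' emulates: (i) asymptotic single-session reach compensation of about 19 of
#' the 30 deg rotation, which pins the total learning rate at
#' \eqn{B = (19/11)(1-A)} given the retention factor; (ii) partial transfer of
#' tracking adaptation to open-loop reaching, carried by the shared state; and
#' (iii) a dual-training reach aftereffect that is positive (same sign as the
#' reach-trained compensation) yet smaller than the tracking-transfer
#' aftereffect. The shared fraction \eqn{B_s/B = 0.57} is the smallest round
#' value for which the dual aftereffect drops below the tracking-transfer one
#' in this architecture; it yields noiseless aftereffects of about +19.0,
#' -10.8 and +8 deg for the three designs.
#'
#' @return A [learner_params()] object.
#' @examples
#' calibrate_defaults()
#' @export
calibrate_defaults <- function() {
  A <- 0.98
  B <- (19 / 11) * (1 - A)   # => 30 * B / (1 - A + B) = 19
  s <- 0.57
  learner_params(retention = A, rate_shared = s * B, rate_context = (1 - s) * B,
                 track_error_weight = 1)
}

#' @export
print.learner_params <- function(x, ...) {
  cat(sprintf(
    "Contextual state-space learner: A = %.4g, B_shared = %.4g, B_context = %.4g, track weight = %.3g\n",
    x$retention, x$rate_shared, x$rate_context, x$track_error_weight))
  cat(sprintf("  single-context asymptote: %.2f deg of a 30 deg rotation\n",
              30 * (x$rate_shared + x$rate_context) /
                (1 - x$retention + x$rate_shared + x$rate_context)))
  invisible(x)
}

#' Hidden adaptation state
#'
#' @param z_shared,z_reach,z_track State values in degrees (all 0 at session
#'   start).
#' @return An object of class `"learner_state"`.
#' @export
learner_state <- function(z_shared = 0, z_reach = 0, z_track = 0) {
  structure(list(z_shared = z_shared, z_reach = z_reach, z_track = z_track),
            class = "learner_state")
}

#' Trial-to-trial learner update
#'
#' @param state A [learner_state()].
#' @param context `"reach"` or `"track"` - the movement type of the trial.
#' @param error_deg Signed performance error in degrees (finite).
#' @param params A [learner_params()].
#' @return The updated [learner_state()].
#' @examples
#' update_learner(learner_state(), "reach", -30,
#'                learner_params(1, 0.1, 0.1))
#' @export
update_learner <- function(state, context = c("reach", "track"), error_deg,
                           params) {
  context <- match.arg(context)
  if (!is.finite(error_deg)) stop("'error_deg' must be finite")
  A <- params$retention
  st <- learner_state(
    z_shared = A * state$z_shared - params$rate_shared * error_deg,
    z_reach = A * state$z_reach,
    z_track = A * state$z_track)
  fld <- paste0("z_", context)
  st[[fld]] <- A * state[[fld]] - params$rate_context * error_deg
  st
}

#' Simulator noise and dynamics parameters
#'
#' @param aim_sd_deg SD of the per-trial Gaussian aiming (reach) or
#'   calibration (tracking) noise, degrees. Default 3.5.
#' @param reach_duration_ms Duration of the ballistic minimum-jerk reach.
#'   Default 1000 ms.
#' @param pursuit_lag_ms First-order pursuit delay: the hand chases the target
#'   position this many ms in the past. Default 400 ms.
#' @param pursuit_gain Proportional pursuit controller gain in 1/s (the inverse
#'   of the hand's response time constant). Default 6.
#' @param seed Optional integer seed for the session's noise draws.
#' @return An object of class `"noise_params"`.
#' @export
noise_params <- function(aim_sd_deg = 3.5, reach_duration_ms = 1000,
                         pursuit_lag_ms = 400, pursuit_gain = 6, seed = NULL) {
  stopifnot(aim_sd_deg >= 0, reach_duration_ms > 0, pursuit_lag_ms >= 0,
            pursuit_gain > 0)
  structure(list(aim_sd_deg = aim_sd_deg, reach_duration_ms = reach_duration_ms,
                 pursuit_lag_ms = pursuit_lag_ms, pursuit_gain = pursuit_gain,
                 seed = seed),
            class = "noise_params")
}
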