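noiseless <- function(seed = 1) noise_params(aim_sd_deg = 0, seed = seed)

test_that("learner update follows the retention/learning-rate rule", {
  lp <- learner_params(retention = 1, rate_shared = 0.1, rate_context = 0.1)
  st <- update_learner(learner_state(), "reach", -30, lp)
  expect_equal(st$z_shared, 3)
  expect_equal(st$z_reach, 3)
  expect_equal(st$z_track, 0)
  # error 0 => pure decay by A
  lp2 <- learner_params(retention = 0.9, rate_shared = 0.1, rate_context = 0.1)
  st2 <- update_learner(learner_state(2, 1, -1), "track", 0, lp2)
  expect_equal(unlist(unclass(st2)), c(z_shared = 1.8, z_reach = 0.9, z_track = -0.9))
  # the untrained context state only decays
  st3 <- update_learner(learner_state(0, 5, 5), "reach", -10, lp2)
  expect_equal(st3$z_track, 4.5)
  expect_equal(st3$z_reach, 5.5)
  expect_error(update_learner(learner_state(), "reach", NaN, lp), "finite")
})

test_that("single-context fixed point matches the closed form within 1% after 180 trials", {
  # A = 1: total compensation converges to the full rotation
  lp1 <- learner_params(retention = 1, rate_shared = 0.05, rate_context = 0.05)
  sess <- simulate_session(build_session("SINGLE_REACH", 5), lp1, noiseless(5))
  last_train <- max(which(sess$design$phase == "rotated_train"))
  z <- sess$state_audit[last_train, ]
  expect_equal(z$z_shared + z$z_reach, 30, tolerance = 0.01)
  # A < 1: -r (Bs+Bc) / (1 - A + Bs + Bc)
  lp2 <- calibrate_defaults()
  B <- lp2$rate_shared + lp2$rate_context
  expected <- 30 * B / (1 - lp2$retention + B)
  sess2 <- simulate_session(build_session("SINGLE_REACH", 5), lp2, noiseless(5))
  z2 <- sess2$state_audit[last_train, ]
  expect_equal(z2$z_shared + z2$z_reach, expected, tolerance = 0.01)
})

test_that("zero learning rates leave rotated errors at the rotation and aftereffects at zero", {
  lp0 <- learner_params(retention = 1, rate_shared = 0, rate_context = 0)
  sess <- simulate_session(build_session("SINGLE_REACH", 2), lp0, noiseless(2))
  errs <- sess$state_audit$error_signal[sess$design$phase == "rotated_train"]
  expect_equal(errs, rep(-30, 180))
  m <- measures_table(sess)
  expect_equal(group_aftereffects(m)$mean_deg, 0, tolerance = 1e-9)
  # with noise, the aftereffect stays within a few SEM of zero
  npn <- noise_params(aim_sd_deg = 3.5, seed = 3)
  mn <- measures_table(simulate_session(build_session("SINGLE_REACH", 2), lp0, npn))
  sem <- 3.5 * sqrt(2 / 5)
  expect_lt(abs(group_aftereffects(mn)$mean_deg), 3 * sem)
})

test_that("cursor equals the rotated hand on every visible sample", {
  sess <- simulate_session(build_session("DUAL", 3, counts = mini_counts()),
                           calibrate_defaults(), noise_params(seed = 3))
  for (tr in sess$trajectories) {
    if (is.null(tr$cursor_xy_cm)) {
      expect_equal(tr$spec$movement_type, "NOCURSOR_REACH")
      next
    }
    expect_equal(rotate_xy(tr$hand_xy_cm, tr$spec$rotation_deg),
                 tr$cursor_xy_cm, tolerance = 1e-12)
  }
})

test_that("reach trials cancel the rotation when compensation matches it", {
  spec <- list(index = 1L, design = "X", phase = "rotated_train",
               movement_type = "REACH", target_angle_deg = 90,
               rotation_deg = -30, target_duration_ms = NA_real_,
               cursor_visible = TRUE)
  lp <- calibrate_defaults()
  with_zero_noise <- noise_params(aim_sd_deg = 0)
  set.seed(1)
  tr0 <- simulate_reach_trial(spec, learner_state(), lp, with_zero_noise)
  expect_equal(tr0$error_signal, -30)
  tr1 <- simulate_reach_trial(spec, learner_state(z_shared = 20, z_reach = 10),
                              lp, with_zero_noise)
  expect_equal(tr1$error_signal, 0)
  # aligned, zero state: error 0
  spec$rotation_deg <- 0
  tr2 <- simulate_reach_trial(spec, learner_state(), lp, with_zero_noise)
  expect_equal(tr2$error_signal, 0)
  expect_error(simulate_track_trial(spec, learner_state(), lp, with_zero_noise),
               "non-TRACK")
})

test_that("unadapted tracking under a CCW rotation deviates CCW and lags by lag x speed", {
  spec <- list(index = 1L, design = "X", phase = "rotated_train",
               movement_type = "TRACK", target_angle_deg = 90,
               rotation_deg = 30, target_duration_ms = 1500,
               cursor_visible = TRUE)
  lp <- calibrate_defaults()
  set.seed(1)
  tr <- simulate_track_trial(spec, learner_state(), lp, noise_params(aim_sd_deg = 0))
  # mean signed cursor-target angle is positive (CCW of the target path), near +30
  expect_gt(tr$error_signal, 20)
  expect_error(simulate_reach_trial(spec, learner_state(), lp, noise_params()),
               "TRACK spec")
  # aligned pursuit with a 500 ms lag trails the target by about 4 cm
  spec$rotation_deg <- 0
  np_lag <- noise_params(aim_sd_deg = 0, pursuit_lag_ms = 500, pursuit_gain = 25)
  set.seed(1)
  tr2 <- simulate_track_trial(spec, learner_state(), lp, np_lag)
  mid <- 40:70  # steady state, target still moving
  gap <- sqrt(rowSums((tr2$target_xy_cm[mid, ] - tr2$cursor_xy_cm[mid, ])^2))
  expect_equal(mean(gap), 0.5 * 8, tolerance = 0.15)
  # converged compensation puts the cursor on the target by trial end
  set.seed(1)
  spec$rotation_deg <- 30
  tr3 <- simulate_track_trial(spec, learner_state(z_shared = -30), lp,
                              noise_params(aim_sd_deg = 0))
  n3 <- nrow(tr3$cursor_xy_cm)
  expect_lt(sqrt(sum((tr3$cursor_xy_cm[n3, ] - tr3$target_xy_cm[n3, ])^2)), 1.3)
  m3 <- trial_measures(tr3)
  set.seed(1)
  tr0 <- simulate_track_trial(spec, learner_state(), lp, noise_params(aim_sd_deg = 0))
  expect_lt(m3$rmse_cm, trial_measures(tr0)$rmse_cm)
})

test_that("sessions are deterministic under a fixed seed and differ across seeds", {
  des <- build_session("SINGLE_TRACK", 4, counts = list(
    aligned_reach = 5L, aligned_reach_nc = 5L, aligned_track = 5L,
    aligned_track_nc = 5L, rotated = 10L, rotated_nc = 5L))
  a <- simulate_session(des, np = noise_params(seed = 10))
  b <- simulate_session(des, np = noise_params(seed = 10))
  expect_identical(a$state_audit, b$state_audit)
  expect_identical(a$trajectories[[12]]$hand_xy_cm, b$trajectories[[12]]$hand_xy_cm)
  c <- simulate_session(des, np = noise_params(seed = 11))
  expect_false(identical(a$state_audit$error_signal, c$state_audit$error_signal))
})

test_that("opposing rotations drive the shared state toward zero and context states apart", {
  sess <- simulate_session(build_session("DUAL", 6), calibrate_defaults(),
                           noiseless(6))
  last_train <- max(which(sess$design$phase == "rotated_train"))
  z <- sess$state_audit[last_train, ]
  expect_gt(z$z_reach, 0)     # compensates the -30 reach rotation
  expect_lt(z$z_track, 0)     # compensates the +30 track rotation
  expect_lt(abs(z$z_shared), 0.3 * abs(z$z_reach))
})

test_that("blocked noiseless reach errors shrink monotonically and states freeze on no-cursor trials", {
  sess <- simulate_session(build_session("SINGLE_REACH", 8),
                           calibrate_defaults(), noiseless(8))
  m <- measures_table(sess)
  blocked <- block_means(abs(
    m$angular_error_deg[m$phase == "rotated_train"]))
  expect_true(all(diff(blocked$mean) < 1e-9))
  nc <- which(sess$design$phase == "rotated_nc")
  audit <- sess$state_audit
  expect_equal(audit$z_shared[nc], rep(audit$z_shared[nc[1] - 1], length(nc)))
  expect_equal(audit$z_reach[nc], rep(audit$z_reach[nc[1] - 1], length(nc)))
})

test_that("default calibration orders aftereffects as reach > track-transfer > dual, with opposite track sign", {
  lp <- calibrate_defaults()
  ae <- vapply(c("SINGLE_REACH", "SINGLE_TRACK", "DUAL"), function(nm) {
    m <- measures_table(simulate_session(build_session(nm, 9), lp, noiseless(9)))
    group_aftereffects(m)$mean_deg
  }, numeric(1))
  expect_gt(abs(ae["SINGLE_REACH"]), abs(ae["SINGLE_TRACK"]))
  expect_gt(abs(ae["SINGLE_TRACK"]), abs(ae["DUAL"]))
  expect_gt(abs(ae["DUAL"]), 0)
  expect_true(sign(ae["SINGLE_TRACK"]) != sign(ae["SINGLE_REACH"]))
  expect_true(sign(ae["DUAL"]) == sign(ae["SINGLE_REACH"]))
  # fully shared learning makes the track-transfer aftereffect equal the reach one
  lp_shared <- learner_params(retention = lp$retention,
                              rate_shared = lp$rate_shared + lp$rate_context,
                              rate_context = 0)
  ae2 <- vapply(c("SINGLE_REACH", "SINGLE_TRACK"), function(nm) {
    m <- measures_table(simulate_session(build_session(nm, 9), lp_shared, noiseless(9)))
    group_aftereffects(m)$mean_deg
  }, numeric(1))
  expect_equal(abs(ae2[["SINGLE_REACH"]]), abs(ae2[["SINGLE_TRACK"]]),
               tolerance = 1e-6)
})
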