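# Independent oracles used to check the packaged implementations.

# First-order low-pass Butterworth coefficients via bilinear transform with
# frequency prewarping (the closed form for H(s) = 1 / (s/wc + 1)).
oracle_butter_coefs <- function(cutoff_hz, fs_hz) {
  wc <- tan(pi * cutoff_hz / fs_hz)
  list(b = c(wc, wc) / (1 + wc), a = c(1, (wc - 1) / (1 + wc)))
}

# Direct-form difference equation y[n] = b0 x[n] + b1 x[n-1] - a1 y[n-1].
oracle_iir <- function(coefs, x) {
  y <- numeric(length(x))
  xm1 <- 0; ym1 <- 0
  for (n in seq_along(x)) {
    y[n] <- coefs$b[1] * x[n] + coefs$b[2] * xm1 - coefs$a[2] * ym1
    xm1 <- x[n]; ym1 <- y[n]
  }
  y
}

# Brute-force per-sample RMSE.
oracle_rmse <- function(cursor, target) {
  acc <- 0
  for (i in seq_len(nrow(cursor)))
    acc <- acc + sum((cursor[i, ] - target[i, ])^2)
  sqrt(acc / nrow(cursor))
}

# Exhaustive-search onset: smallest i <= peak such that every sample from i to
# the peak is at or above the threshold.
oracle_onset <- function(speed, fraction) {
  peak <- which.max(speed)
  thr <- fraction * speed[peak]
  for (i in seq_len(peak))
    if (all(speed[i:peak] >= thr)) return(i)
  peak
}

# Exhaustive-search offset: largest i >= peak such that every sample from the
# peak to i is at or above the threshold.
oracle_offset <- function(speed, fraction) {
  peak <- which.max(speed)
  thr <- fraction * speed[peak]
  n <- length(speed)
  for (i in rev(peak:n))
    if (all(speed[peak:i] >= thr)) return(i)
  peak
}

# Random unimodal speed profile: rises to a unique peak, then falls.
random_unimodal <- function(n = 30) {
  up <- sample(3:(n - 3), 1)
  peak <- runif(1, 5, 10)
  rise <- sort(runif(up - 1, 0, 0.98 * peak))
  fall <- sort(runif(n - up, 0, 0.98 * peak), decreasing = TRUE)
  c(rise, peak, fall)
}

# Pooled-variance independent two-sample t statistic.
oracle_t_ind <- function(x, y) {
  sp2 <- ((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
    (length(x) + length(y) - 2)
  (mean(x) - mean(y)) / sqrt(sp2 * (1 / length(x) + 1 / length(y)))
}

oracle_t_paired <- function(x, y) {
  d <- x - y
  mean(d) / (sd(d) / sqrt(length(d)))
}

# One-way between-groups F from sums of squares.
oracle_f_between <- function(value, group) {
  group <- factor(group)
  m <- mean(value)
  ssb <- sum(tapply(value, group, function(v) length(v) * (mean(v) - m)^2))
  ssw <- sum((value - ave(value, group))^2)
  k <- nlevels(group)
  (ssb / (k - 1)) / (ssw / (length(value) - k))
}

# One-way repeated-measures F (balanced).
oracle_f_rm <- function(value, level, subject) {
  level <- factor(level); subject <- factor(subject)
  m <- mean(value)
  l <- nlevels(level); n <- nlevels(subject)
  ss_level <- n * sum((tapply(value, level, mean) - m)^2)
  ss_subj <- l * sum((tapply(value, subject, mean) - m)^2)
  ss_err <- sum((value - m)^2) - ss_level - ss_subj
  (ss_level / (l - 1)) / (ss_err / ((l - 1) * (n - 1)))
}

# Mixed (between group x within level) ANOVA F statistics (balanced groups).
oracle_f_mixed <- function(value, group, level, subject) {
  group <- factor(group); level <- factor(level); subject <- factor(subject)
  k <- nlevels(group); l <- nlevels(level); ns <- nlevels(subject)
  m <- mean(value)
  subj_means <- tapply(value, subject, mean)
  subj_group <- tapply(as.character(group), subject, `[`, 1)
  ss_between <- l * sum((subj_means - m)^2)
  ss_group <- sum(tapply(value, group, function(v) length(v) * (mean(v) - m)^2))
  ss_subj_in_g <- ss_between - ss_group
  ss_level <- ns * sum((tapply(value, level, mean) - m)^2)
  cell <- tapply(value, list(group, level), mean)
  gm <- tapply(value, group, mean); lm_ <- tapply(value, level, mean)
  n_per_g <- table(subj_group)
  ss_gl <- 0
  for (g in levels(group)) for (le in levels(level))
    ss_gl <- ss_gl + n_per_g[[g]] * (cell[g, le] - gm[[g]] - lm_[[le]] + m)^2
  ss_err_w <- sum((value - m)^2) - ss_between - ss_level - ss_gl
  list(
    group = (ss_group / (k - 1)) / (ss_subj_in_g / (ns - k)),
    level = (ss_level / (l - 1)) / (ss_err_w / ((l - 1) * (ns - k))),
    interaction = (ss_gl / ((k - 1) * (l - 1))) / (ss_err_w / ((l - 1) * (ns - k))))
}

# Tiny synthetic tracking-style trajectory: target ramps outward at constant
# speed, cursor follows with a pure delay of `lag_samples`.
delayed_pursuit_traj <- function(duration_ms = 1500, lag_samples = 0, fs = 50,
                                 angle = 90, cap_ms = 2400) {
  n <- floor(cap_ms * fs / 1000) + 1
  t_ms <- (seq_len(n) - 1) * 1000 / fs
  u <- c(cos(angle * pi / 180), sin(angle * pi / 180))
  d <- pmin(t_ms / duration_ms, 1) * 12
  target <- cbind(d * u[1], d * u[2])
  ci <- pmax(1, seq_len(n) - lag_samples)
  cursor <- target[ci, , drop = FALSE]
  list(t_ms = t_ms, cursor_xy_cm = cursor, hand_xy_cm = cursor,
       target_xy_cm = target,
       spec = list(index = 1L, design = "TEST", phase = "aligned_track",
                   movement_type = "TRACK", target_angle_deg = angle,
                   rotation_deg = 0, target_duration_ms = duration_ms,
                   cursor_visible = TRUE))
}

mini_counts <- function() list(
  aligned_reach = 5L, aligned_reach_nc = 5L, aligned_track = 5L,
  aligned_track_nc = 5L, aligned_mixed_each = 5L, rotated_each = 10L,
  rotated_nc = 5L)
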