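#' @importFrom stats rnorm runif sd coef predict fitted residuals
NULL

# Evaluate expr under a temporary RNG seed, restoring global RNG state after.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' Pseudo-random target order as concatenated permutation blocks
#'
#' Targets are drawn so that every target direction appears once before any is
#' repeated: the sequence is a concatenation of independent random permutations
#' of the label set, truncated to `n`.
#'
#' @param n Number of trials to schedule.
#' @param labels Vector of target labels (typically the 5 target angles).
#' @param seed Optional integer; when given, the order is reproducible and the
#'   caller's RNG state is untouched. When `NULL`, the current RNG stream is
#'   consumed (used internally by [build_session()]).
#' @return A vector of `n` labels.
#' @examples
#' pseudo_random_order(10, c(60, 75, 90, 105, 120), seed = 1)
#' @export
pseudo_random_order <- function(n, labels, seed = NULL) {
  if (length(labels) == 0L) stop("'labels' must be non-empty")
  if (n < 0) stop("'n' must be non-negative")
  k <- length(labels)
  with_seed(seed, {
    blocks <- ceiling(n / k)
    out <- unlist(lapply(seq_len(max(blocks, 0L)), function(i) sample(labels, k)))
    out[seq_len(n)]
  })
}

#' Target movement duration for baseline tracking trials
#'
#' During the aligned (baseline) tracking phase the target movement time starts
#' at 1800 ms on trial 1 and shortens by 20 ms per trial until it reaches the
#' steady 1500 ms; from trial 16 onward (and on every rotated tracking trial)
#' the duration is always 1500 ms.
#'
#' @param baseline_ordinal 1-based ordinal among a design's aligned tracking
#'   trials (vectorised).
#' @return Duration(s) in ms.
#' @examples
#' track_duration(c(1, 15, 16, 65))
#' @export
track_duration <- function(baseline_ordinal) {
  if (any(baseline_ordinal < 1)) stop("'baseline_ordinal' must be >= 1")
  pmax(1500, 1800 - 20 * (baseline_ordinal - 1))
}

design_names <- c("SINGLE_REACH", "SINGLE_TRACK", "DUAL")

default_counts <- function(name) {
  switch(name,
    SINGLE_REACH = list(aligned_reach = 50L, aligned_reach_nc = 30L,
                        rotated = 180L, rotated_nc = 30L),
    SINGLE_TRACK = list(aligned_reach = 50L, aligned_reach_nc = 30L,
                        aligned_track = 65L, aligned_track_nc = 30L,
                        rotated = 180L, rotated_nc = 30L),
    DUAL = list(aligned_reach = 50L, aligned_reach_nc = 30L,
                aligned_track = 65L, aligned_track_nc = 30L,
                aligned_mixed_each = 25L, rotated_each = 180L,
                rotated_nc = 30L))
}

# One phase block of trial rows.
phase_rows <- function(phase, movement_type, n, targets, rotation_deg,
                       target_duration_ms = NA_real_) {
  if (n == 0L) return(NULL)
  data.frame(phase = phase, movement_type = movement_type,
             target_angle_deg = targets, rotation_deg = rotation_deg,
             target_duration_ms = target_duration_ms,
             cursor_visible = movement_type != "NOCURSOR_REACH",
             stringsAsFactors = FALSE)
}

# Interleave 180+180 REACH/TRACK rotated trials pseudo-randomly, never more
# than 2 consecutive trials of one movement type; restarts on dead ends.
interleave_types <- function(n_each, max_run = 2L, max_restart = 1000L) {
  for (attempt in seq_len(max_restart)) {
    left <- c(reach = n_each, track = n_each)
    out <- character(2 * n_each); last <- ""; run <- 0L; ok <- TRUE
    for (i in seq_along(out)) {
      allowed <- names(left)[left > 0 & !(names(left) == last & run >= max_run)]
      if (length(allowed) == 0L) { ok <- FALSE; break }
      ty <- if (length(allowed) == 1L) allowed else
        sample(allowed, 1L, prob = left[allowed])
      run <- if (ty == last) run + 1L else 1L
      last <- ty
      left[ty] <- left[ty] - 1L
      out[i] <- ty
    }
    if (ok) return(out)
  }
  stop("could not interleave trial types under the run-length constraint")
}

#' Build the trial schedule of one session design
#'
#' Constructs the complete ordered trial list for one of the three session
#' designs:
#' \describe{
#'   \item{SINGLE_REACH}{50 aligned reaches, 30 no-cursor reaches, 180 reaches
#'     under a -30 deg (CW) cursor rotation, 30 no-cursor reaches.}
#'   \item{SINGLE_TRACK}{the aligned reach baseline and its no-cursor block,
#'     then 65 aligned tracking trials (target duration ramping 1800 to 1500 ms
#'     over the first 16 trials), 30 no-cursor reaches, 180 tracking trials
#'     under a +30 deg (CCW) rotation, 30 no-cursor reaches.}
#'   \item{DUAL}{both aligned baselines and their no-cursor blocks, a mixed
#'     aligned block of 25 reaches alternating with 25 tracking trials, then
#'     360 rotated training trials (180 reaches at -30 deg interleaved
#'     pseudo-randomly with 180 tracking trials at +30 deg, never more than two
#'     consecutive trials of one type), and 30 no-cursor reaches.}
#' }
#' Within every training sub-block of five same-type trials each of the five
#' target directions occurs exactly once. The same seed always yields the same
#' schedule.
#'
#' @param name One of `"SINGLE_REACH"`, `"SINGLE_TRACK"`, `"DUAL"`.
#' @param seed Non-negative integer seed for the pseudo-random target and
#'   trial-type ordering.
#' @param geometry A [target_geometry()] object.
#' @param counts Optional named list overriding the per-phase trial counts
#'   (names as in the design defaults, e.g. `aligned_reach`, `rotated`,
#'   `rotated_each`, `aligned_mixed_each`); all counts must keep permutation
#'   blocks whole (multiples of 5). Used for scaled-down test sessions.
#' @return An object of class `"session_design"`: a data.frame with one row per
#'   trial (columns `index`, `design`, `phase`, `movement_type`,
#'   `target_angle_deg`, `rotation_deg`, `target_duration_ms`,
#'   `cursor_visible`) carrying the geometry and seed as attributes.
#' @examples
#' des <- build_session("SINGLE_REACH", seed = 1)
#' table(des$phase)
#' @export
build_session <- function(name, seed, geometry = target_geometry(),
                          counts = NULL) {
  name <- match.arg(name, design_names)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed) || seed < 0)
    stop("'seed' must be a single non-negative integer")
  cnt <- default_counts(name)
  if (!is.null(counts)) {
    bad <- setdiff(names(counts), names(cnt))
    if (length(bad)) stop("unknown count override(s): ", paste(bad, collapse = ", "))
    cnt[names(counts)] <- lapply(counts, as.integer)
  }
  k <- length(geometry$target_angles)
  if (any(unlist(cnt) %% k != 0))
    stop("all phase counts must be multiples of the number of targets (", k, ")")
  ang <- geometry$target_angles
  rows <- with_seed(seed, {
    ord <- function(n) pseudo_random_order(n, ang)
    blocks <- list()
    add <- function(b) blocks[[length(blocks) + 1L]] <<- b
    add(phase_rows("aligned_reach", "REACH", cnt$aligned_reach,
                   ord(cnt$aligned_reach), 0))
    add(phase_rows("aligned_reach_nc", "NOCURSOR_REACH", cnt$aligned_reach_nc,
                   ord(cnt$aligned_reach_nc), 0))
    if (name %in% c("SINGLE_TRACK", "DUAL")) {
      add(phase_rows("aligned_track", "TRACK", cnt$aligned_track,
                     ord(cnt$aligned_track), 0,
                     track_duration(seq_len(cnt$aligned_track))))
      add(phase_rows("aligned_track_nc", "NOCURSOR_REACH", cnt$aligned_track_nc,
                     ord(cnt$aligned_track_nc), 0))
    }
    if (name == "DUAL") {
      n_each <- cnt$aligned_mixed_each
      ty <- rep(c("REACH", "TRACK"), n_each)   # strict alternation, REACH first
      tr <- character(2 * n_each)
      tr[ty == "REACH"] <- ord(n_each)
      tr[ty == "TRACK"] <- ord(n_each)
      mixed <- phase_rows("aligned_mixed", ty, 2 * n_each, as.numeric(tr), 0)
      mixed$target_duration_ms <- ifelse(ty == "TRACK", 1500, NA_real_)
      add(mixed)
      ty <- toupper(interleave_types(cnt$rotated_each))
      tr <- character(2 * cnt$rotated_each)
      tr[ty == "REACH"] <- ord(cnt$rotated_each)
      tr[ty == "TRACK"] <- ord(cnt$rotated_each)
      rot <- phase_rows("rotated_train", ty, 2 * cnt$rotated_each,
                        as.numeric(tr), ifelse(ty == "REACH", -30, 30))
      rot$target_duration_ms <- ifelse(ty == "TRACK", 1500, NA_real_)
      add(rot)
    } else {
      mt <- if (name == "SINGLE_REACH") "REACH" else "TRACK"
      rot_deg <- if (mt == "REACH") -30 else 30
      add(phase_rows("rotated_train", mt, cnt$rotated, ord(cnt$rotated), rot_deg,
                     if (mt == "TRACK") 1500 else NA_real_))
    }
    add(phase_rows("rotated_nc", "NOCURSOR_REACH", cnt$rotated_nc,
                   ord(cnt$rotated_nc), 0))
    do.call(rbind, blocks)
  })
  rows <- cbind(index = seq_len(nrow(rows)), design = name, rows,
                stringsAsFactors = FALSE)
  structure(rows, class = c("session_design", "data.frame"),
            geometry = geometry, seed = as.integer(seed))
}

#' @export
print.session_design <- function(x, ...) {
  cat("Session design", x$design[1], "-", nrow(x), "trials (seed",
      attr(x, "seed"), ")\n")
  ph <- rle(x$phase)
  for (i in seq_along(ph$values)) {
    sel <- x$phase == ph$values[i]
    cat(sprintf("  %-18s %4d trials  [%s]\n", ph$values[i], ph$lengths[i],
                paste(unique(x$movement_type[sel]), collapse = "+")))
  }
  invisible(x)
}

#' Sampled target trajectory for one trial
#'
#' For a tracking trial the target travels in a straight radial line from home
#' to its final position at constant speed (12 cm over the trial's target
#' duration; 8 cm/s at the steady 1500 ms duration). For reach and no-cursor
#' trials the target is static at its final position.
#'
#' @param spec A single-row slice of a [build_session()] data.frame (or any
#'   list with `movement_type`, `target_angle_deg`, `target_duration_ms`).
#' @param geometry A [target_geometry()] object.
#' @param fs Sampling rate in Hz (default 50).
#' @param duration_ms Duration used for static (reach) targets, and override
#'   for tracking; defaults to the trial's `target_duration_ms` for tracking
#'   and 1000 ms for reaches.
#' @return A list with `t_ms` (sample times) and `xy` (n x 2 positions in cm);
#'   `n = floor(duration_ms * fs / 1000) + 1`.
#' @export
target_path <- function(spec, geometry = target_geometry(), fs = 50,
                        duration_ms = NULL) {
  if (fs <= 0) stop("'fs' must be positive")
  is_track <- spec$movement_type == "TRACK"
  if (is.null(duration_ms))
    duration_ms <- if (is_track) spec$target_duration_ms else 1000
  if (!is.finite(duration_ms) || duration_ms <= 0)
    stop("invalid target duration")
  n <- floor(duration_ms * fs / 1000) + 1
  t_ms <- (seq_len(n) - 1) * 1000 / fs
  fin <- target_position(spec$target_angle_deg, geometry)
  if (is_track) {
    frac <- pmin(t_ms / duration_ms, 1)
    xy <- cbind(geometry$home[1] + frac * (fin[1] - geometry$home[1]),
                geometry$home[2] + frac * (fin[2] - geometry$home[2]))
  } else {
    xy <- cbind(rep(fin[1], n), rep(fin[2], n))
  }
  list(t_ms = t_ms, xy = xy)
}

#' Audit a session design against its structural invariants
#'
#' Checks the permutation-block property (every training sub-block of five
#' same-type trials covers all five targets), the baseline tracking duration
#' ramp, rotation magnitudes, and the cursor-visibility rule. Errors on the
#' first violation; invisibly returns `TRUE`.
#'
#' @param design A `"session_design"` object.
#' @export
audit_session <- function(design) {
  stopifnot(inherits(design, "session_design"))
  geo <- attr(design, "geometry")
  k <- length(geo$target_angles)
  if (!all(design$rotation_deg %in% c(-30, 0, 30)))
    stop("rotation outside {-30, 0, +30}")
  if (!all(design$cursor_visible == (design$movement_type != "NOCURSOR_REACH")))
    stop("cursor_visible inconsistent with movement type")
  for (ph in unique(design$phase)) {
    for (mt in unique(design$movement_type[design$phase == ph])) {
      tg <- design$target_angle_deg[design$phase == ph & design$movement_type == mt]
      if (length(tg) %% k != 0) stop("partial permutation block in ", ph)
      for (b in seq_len(length(tg) / k)) {
        blk <- tg[((b - 1) * k + 1):(b * k)]
        if (!setequal(blk, geo$target_angles))
          stop("non-permutation block in phase ", ph)
      }
    }
  }
  tr <- design$target_duration_ms[design$phase == "aligned_track"]
  if (length(tr)) {
    steady <- tr[seq_along(tr) >= 16]
    if (any(diff(tr) > 0) || any(tr != track_duration(seq_along(tr))) ||
        any(steady != 1500))
      stop("baseline tracking duration ramp violated")
  }
  if (any(design$target_duration_ms[design$phase == "rotated_train" &
                                    design$movement_type == "TRACK"] != 1500))
    stop("rotated tracking trials must use 1500 ms targets")
  invisible(TRUE)
}
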