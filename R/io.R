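trajectory_columns <- c(
  "session_id", "participant_id", "trial_index", "design", "phase",
  "movement_type", "target_angle_deg", "rotation_deg", "t_ms",
  "hand_x_cm", "hand_y_cm", "cursor_x_cm", "cursor_y_cm",
  "target_x_cm", "target_y_cm", "cursor_visible")

#' Flatten a simulated session into a trajectory table
#'
#' One row per sample: trial identifiers plus hand, cursor and target planar
#' positions. Cursor columns are `NA` on no-cursor rows. Rows are ordered by
#' `(trial_index, t_ms)` and times are multiples of 20 ms (50 Hz).
#'
#' @param sess A `"session_data"` object.
#' @param session_id Session identifier (default the design name).
#' @return A data.frame in the trajectory-table schema.
#' @export
as_trajectory_table <- function(sess, session_id = NULL) {
  stopifnot(inherits(sess, "session_data"))
  if (is.null(session_id)) session_id <- sess$design$design[1]
  out <- lapply(sess$trajectories, function(tr) {
    s <- tr$spec
    n <- length(tr$t_ms)
    cur <- if (is.null(tr$cursor_xy_cm)) matrix(NA_real_, n, 2) else tr$cursor_xy_cm
    data.frame(session_id = session_id,
               participant_id = sess$participant_id,
               trial_index = s$index, design = s$design, phase = s$phase,
               movement_type = s$movement_type,
               target_angle_deg = s$target_angle_deg,
               rotation_deg = s$rotation_deg, t_ms = tr$t_ms,
               hand_x_cm = tr$hand_xy_cm[, 1], hand_y_cm = tr$hand_xy_cm[, 2],
               cursor_x_cm = cur[, 1], cursor_y_cm = cur[, 2],
               target_x_cm = tr$target_xy_cm[, 1],
               target_y_cm = tr$target_xy_cm[, 2],
               cursor_visible = isTRUE(s$cursor_visible),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

validate_trajectory_table <- function(tab) {
  miss <- setdiff(trajectory_columns, names(tab))
  if (length(miss))
    stop("trajectory table is missing column(s): ", paste(miss, collapse = ", "))
  key <- paste(tab$participant_id, tab$trial_index)
  for (k in unique(key)) {
    t_ms <- tab$t_ms[key == k]
    if (any(diff(t_ms) <= 0))
      stop("non-monotone sample times within trial ", k,
           " (first at row ", which(key == k)[which(diff(t_ms) <= 0)[1] + 1], ")")
    dt <- unique(round(diff(t_ms), 9))
    if (length(dt) > 1)
      stop("mixed sampling intervals within trial ", k, ": ",
           paste(dt, collapse = ", "), " ms")
    if (length(dt) == 1 && dt != 20)
      stop("trial ", k, " sampled at ", round(1000 / dt, 3),
           " Hz; the trajectory format requires 50 Hz (20 ms steps)")
  }
  nc <- !tab$cursor_visible
  if (any(!is.na(tab$cursor_x_cm[nc]) | !is.na(tab$cursor_y_cm[nc])))
    stop("cursor positions present on no-cursor rows")
  invisible(TRUE)
}

#' Write / read trajectory tables (CSV)
#'
#' Plain-CSV interchange (RFC 4180, UTF-8, '.' decimal) of the per-sample
#' trajectory table; numeric values round-trip at full precision. Reading
#' validates the schema (required columns, monotone 20 ms sample times per
#' trial, empty cursor on no-cursor rows) and fails with a row-level message
#' on violations.
#'
#' @param x A `"session_data"` or a trajectory-table data.frame.
#' @param path File path.
#' @return `read_trajectories` returns the validated data.frame;
#'   `write_trajectories` invisibly returns `path`.
#' @export
write_trajectories <- function(x, path) {
  tab <- if (inherits(x, "session_data")) as_trajectory_table(x) else x
  validate_trajectory_table(tab)
  data.table::fwrite(tab, path)
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- as.data.frame(data.table::fread(path))
  validate_trajectory_table(tab)
  tab
}

#' Rebuild per-trial trajectories from a trajectory table
#'
#' Inverse of [as_trajectory_table()]: splits the flat table into
#' `"trial_trajectory"` objects suitable for [trial_measures()]. For tracking
#' trials the target duration is recovered from the samples (the time at
#' which the target stops moving).
#'
#' @param tab A validated trajectory table.
#' @return A list of `"trial_trajectory"` objects in trial order.
#' @export
table_to_trajectories <- function(tab) {
  ord <- order(tab$participant_id, tab$trial_index, tab$t_ms)
  tab <- tab[ord, ]
  split_key <- interaction(tab$participant_id, tab$trial_index, drop = TRUE)
  idx <- split(seq_len(nrow(tab)), split_key)
  idx <- idx[order(vapply(idx, function(i) tab$trial_index[i[1]] +
                            tab$participant_id[i[1]] * 1e6, numeric(1)))]
  lapply(idx, function(i) {
    d <- tab[i, ]
    target <- cbind(d$target_x_cm, d$target_y_cm)
    dur <- NA_real_
    if (d$movement_type[1] == "TRACK") {
      moving <- which(rowSums(abs(diff(target))) > 1e-9)
      halt <- if (length(moving)) max(moving) + 1 else 1
      dur <- d$t_ms[halt] - d$t_ms[1]
    }
    cursor <- if (d$cursor_visible[1]) cbind(d$cursor_x_cm, d$cursor_y_cm) else NULL
    new_trajectory(
      t_ms = d$t_ms, hand = cbind(d$hand_x_cm, d$hand_y_cm), cursor = cursor,
      target = target,
      spec = list(index = d$trial_index[1], design = d$design[1],
                  phase = d$phase[1], movement_type = d$movement_type[1],
                  target_angle_deg = d$target_angle_deg[1],
                  rotation_deg = d$rotation_deg[1],
                  target_duration_ms = dur,
                  cursor_visible = d$cursor_visible[1]),
      state = NULL)
  })
}

#' Run configuration
#'
#' Bundles every knob of a simulation + analysis run: design, participant
#' count, seeds, learner and noise parameters, filter settings and analysis
#' options. All values are carried into the results bundle for provenance via
#' [config_hash()].
#'
#' @param design Design name.
#' @param participants Number of simulated participants.
#' @param seed Base seed.
#' @param learner,noise,filter Parameter objects (defaults:
#'   [calibrate_defaults()], [noise_params()], [filter_spec()]).
#' @param block_size Trials per block (default 5).
#' @param baseline_block Aftereffect baseline variant (`"final"` or
#'   `"first"`).
#' @param counts Optional schedule count overrides (scaled-down sessions).
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(design = "SINGLE_REACH", participants = 1L, seed = 1L,
                       learner = calibrate_defaults(), noise = noise_params(),
                       filter = filter_spec(), block_size = 5L,
                       baseline_block = "final", counts = NULL) {
  structure(list(design = design, participants = as.integer(participants),
                 seed = as.integer(seed), learner = unclass(learner),
                 noise = unclass(noise), filter = unclass(filter),
                 block_size = as.integer(block_size),
                 baseline_block = baseline_block, counts = counts),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Keys present in the file override the defaults of [run_config()]; nested
#' keys (`learner`, `noise`, `filter`) are merged field-wise.
#'
#' @param path YAML file path.
#' @return A `"run_config"`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- run_config()
  for (nm in names(y)) {
    if (nm %in% c("learner", "noise", "filter") && is.list(y[[nm]])) {
      cfg[[nm]][names(y[[nm]])] <- y[[nm]]
    } else cfg[[nm]] <- y[[nm]]
  }
  cfg
}

#' Hash of a run configuration
#'
#' MD5 of the canonical YAML serialisation; stamped into every result table
#' (`config_hash` column) so results can be traced to the exact configuration.
#'
#' @param cfg A `"run_config"` (or any list).
#' @return A 32-character hex string.
#' @export
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(cfg), tmp)
  unname(tools::md5sum(tmp))
}

#' Miniature deterministic sessions for tests
#'
#' Builds scaled-down session designs (5-trial phases) that preserve every
#' structural invariant: permutation blocks, the baseline tracking duration
#' ramp (truncated), rotation assignments and cursor-visibility rules.
#'
#' @param seed Integer seed.
#' @return Named list of `"session_design"` objects (`single_reach`,
#'   `single_track`, `dual`).
#' @export
make_fixtures <- function(seed = 1L) {
  list(
    single_reach = build_session("SINGLE_REACH", seed, counts = list(
      aligned_reach = 5L, aligned_reach_nc = 5L, rotated = 10L, rotated_nc = 5L)),
    single_track = build_session("SINGLE_TRACK", seed, counts = list(
      aligned_reach = 5L, aligned_reach_nc = 5L, aligned_track = 5L,
      aligned_track_nc = 5L, rotated = 10L, rotated_nc = 5L)),
    dual = build_session("DUAL", seed, counts = list(
      aligned_reach = 5L, aligned_reach_nc = 5L, aligned_track = 5L,
      aligned_track_nc = 5L, aligned_mixed_each = 5L, rotated_each = 10L,
      rotated_nc = 5L)))
}
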