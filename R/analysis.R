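#' Per-trial rotated-training series for one movement type
#'
#' Pulls, for every participant, the rotated-training trials of the given
#' movement type in trial order and the standard training measure for that
#' type: signed angular error at peak velocity for reaches, positional RMSE
#' for tracking.
#'
#' @param measures A [measures_table()] data.frame.
#' @param movement_type `"REACH"` or `"TRACK"`.
#' @return Long data.frame: `participant_id`, `ordinal` (1-based trial ordinal
#'   within the series), `value`.
#' @export
training_series <- function(measures, movement_type = c("REACH", "TRACK")) {
  movement_type <- match.arg(movement_type)
  sel <- measures$phase == "rotated_train" &
    measures$movement_type == movement_type
  m <- measures[sel, ]
  m <- m[order(m$participant_id, m$index), ]
  value <- if (movement_type == "REACH") m$angular_error_deg else m$rmse_cm
  ord <- stats::ave(seq_along(value), m$participant_id, FUN = seq_along)
  data.frame(participant_id = m$participant_id, ordinal = ord, value = value)
}

#' Per-participant block means of a training series
#'
#' @param series A [training_series()] data.frame.
#' @param block_size Trials per block (default 5).
#' @return Long data.frame: `participant_id`, `block`, `mean`.
#' @export
participant_blocks <- function(series, block_size = 5) {
  out <- lapply(split(series, series$participant_id), function(d) {
    b <- block_means(d$value[order(d$ordinal)], block_size)
    data.frame(participant_id = d$participant_id[1], block = b$block,
               mean = b$mean)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Group-mean block series
#'
#' Averages per-participant block means across participants, the series the
#' exponential learning curve is fitted to.
#'
#' @param pb A [participant_blocks()] data.frame.
#' @return A `"block_series"` data.frame (`block`, `mean`).
#' @export
group_mean_blocks <- function(pb) {
  m <- tapply(pb$mean, pb$block, mean)
  structure(data.frame(block = as.integer(names(m)), mean = as.numeric(m)),
            class = c("block_series", "data.frame"))
}

#' Per-participant learning milestones
#'
#' @param series A [training_series()] data.frame.
#' @return Long data.frame: `participant_id`, `milestone`
#'   (`first_trial`/`second_block`/`final_block`), `value`.
#' @export
milestones_table <- function(series) {
  out <- lapply(split(series, series$participant_id), function(d) {
    ms <- milestones(d$value[order(d$ordinal)])
    data.frame(participant_id = d$participant_id[1],
               milestone = names(ms), value = unlist(ms, use.names = FALSE))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out$milestone <- factor(out$milestone,
                          levels = c("first_trial", "second_block", "final_block"))
  out
}

#' Full learning analysis of one simulated (or loaded) group
#'
#' Convenience wrapper running the complete per-group analysis: kinematic
#' measures, per-participant and group-mean block series for each trained
#' movement type, milestones, the exponential learning-curve fit on the
#' group-mean blocks, and reach aftereffects.
#'
#' @param sessions A list of `"session_data"` (e.g. [simulate_group()]) or a
#'   precomputed measures data.frame.
#' @param spec A [filter_spec()].
#' @param baseline_block Aftereffect baseline variant, see [aftereffect()].
#' @return A list of class `"group_analysis"`: `measures`, and per movement
#'   type present in rotated training a list with `series`, `blocks`,
#'   `group_blocks`, `milestones`, `fit`; plus `aftereffects`.
#' @export
analyze_group <- function(sessions, spec = filter_spec(),
                          baseline_block = "final") {
  measures <- if (is.data.frame(sessions)) sessions
              else measures_table(sessions, spec)
  types <- unique(measures$movement_type[measures$phase == "rotated_train"])
  per_type <- lapply(types, function(ty) {
    ser <- training_series(measures, ty)
    pb <- participant_blocks(ser)
    gb <- group_mean_blocks(pb)
    list(series = ser, blocks = pb, group_blocks = gb,
         milestones = milestones_table(ser),
         fit = if (nrow(gb) >= 4) fit_exponential(gb) else NULL)
  })
  names(per_type) <- types
  structure(list(measures = measures, training = per_type,
                 aftereffects = group_aftereffects(measures, baseline_block)),
            class = "group_analysis")
}

#' @export
print.group_analysis <- function(x, ...) {
  cat("Group analysis of", x$measures$design[1], "-",
      length(unique(x$measures$participant_id)), "participant(s)\n")
  for (ty in names(x$training)) {
    if (is.null(x$training[[ty]]$fit)) next
    p <- coef(x$training[[ty]]$fit)
    cat(sprintf("  %s training fit: RD = %.2f exp(-%.3f x) + %.2f\n",
                ty, p[["b"]], p[["a"]], p[["c"]]))
  }
  cat(sprintf("  reach aftereffect: %.2f +/- %.2f deg\n",
              x$aftereffects$mean_deg, x$aftereffects$sem_deg))
  invisible(x)
}

#' Plot a blocked learning curve with its exponential fit
#'
#' @param group_blocks A `"block_series"` (group-mean blocks).
#' @param fit Optional `"exp_fit"` overlaid as a red dashed curve.
#' @param ylab,main Labels.
#' @export
plot_learning_curve <- function(group_blocks, fit = NULL,
                                ylab = "Measure", main = "Training") {
  graphics::plot(group_blocks$block, group_blocks$mean, type = "b", pch = 19,
                 xlab = "Block (5 trials)", ylab = ylab, main = main)
  if (!is.null(fit)) {
    xs <- seq(min(group_blocks$block), max(group_blocks$block), length.out = 200)
    graphics::lines(xs, predict(fit, data.frame(block = xs)), lty = 2,
                    col = "red", lwd = 2)
  }
  invisible(NULL)
}

#' Bar plot of group reach aftereffects with per-participant points
#'
#' @param ae Named list of `"aftereffect_result"` objects (one per group).
#' @param main Title.
#' @export
plot_aftereffects <- function(ae, main = "Reach aftereffects") {
  means <- vapply(ae, function(a) a$mean_deg, numeric(1))
  sems <- vapply(ae, function(a) a$sem_deg, numeric(1))
  ylim <- range(0, unlist(lapply(ae, function(a) a$per_participant$aftereffect_deg)),
                means + sems, means - sems)
  bp <- graphics::barplot(means, names.arg = names(ae), ylim = ylim * 1.1,
                          ylab = "Aftereffect (deg, CCW+)", main = main,
                          col = "grey85")
  for (i in seq_along(ae)) {
    pts <- ae[[i]]$per_participant$aftereffect_deg
    graphics::points(rep(bp[i], length(pts)) + seq(-0.15, 0.15, length.out = length(pts)),
                     pts, pch = 21, bg = "white")
    graphics::arrows(bp[i], means[i] - sems[i], bp[i], means[i] + sems[i],
                     angle = 90, code = 3, length = 0.05)
  }
  graphics::abline(h = 0)
  invisible(NULL)
}
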