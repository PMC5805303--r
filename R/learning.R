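#' Block means of a per-trial measure
#'
#' Training measures are averaged over non-overlapping blocks of five
#' consecutive trials, so that every block contains one movement to each of
#' the five targets.
#'
#' @param x Per-trial measure values, in trial order; length must be a
#'   multiple of `block_size`.
#' @param block_size Trials per block (default 5).
#' @param measure Optional measure name stored with the result.
#' @return A data.frame of class `"block_series"` with columns `block`
#'   (1-based block number, the x of the exponential learning-curve model) and
#'   `mean`.
#' @examples
#' block_means(1:10)
#' @export
block_means <- function(x, block_size = 5, measure = NULL) {
  n <- length(x)
  if (n == 0 || n %% block_size != 0)
    stop("series length (", n, ") must be a positive multiple of the block size (",
         block_size, ")")
  m <- colMeans(matrix(x, nrow = block_size))
  structure(data.frame(block = seq_along(m), mean = m),
            class = c("block_series", "data.frame"),
            block_size = block_size, measure = measure)
}

#' Learning milestones of a training series
#'
#' The three probes of the training curve: the raw value of the very first
#' trial (rapid early learning is masked by blocking), the mean of the second
#' block (trials 6-10, a rough estimate of learning rate), and the mean of the
#' final block of five trials (extent of learning).
#'
#' @param x Per-trial measure values in trial order (length >= 10).
#' @return A list with `first_trial`, `second_block`, `final_block`.
#' @export
milestones <- function(x) {
  if (length(x) < 10) stop("need at least 10 trials for milestones")
  list(first_trial = x[1],
       second_block = mean(x[6:10]),
       final_block = mean(utils::tail(x, 5)))
}

#' Reach aftereffect for one participant
#'
#' The aftereffect is the change in open-loop (no-cursor) reach errors caused
#' by rotated training: the mean of the first five no-cursor errors after
#' rotated training minus the baseline mean from the aligned no-cursor errors.
#' The baseline uses the final block of five aligned no-cursor trials
#' (`baseline_block = "final"`, the default) or the first block
#' (`baseline_block = "first"`).
#'
#' @param nc_rotated No-cursor angular errors (deg) following rotated
#'   training, in trial order (>= 5 values).
#' @param nc_aligned No-cursor angular errors following aligned training
#'   (>= 5 values).
#' @param baseline_block `"final"` or `"first"` aligned block as baseline.
#' @return Aftereffect in degrees (CCW-positive hand deviation).
#' @export
aftereffect <- function(nc_rotated, nc_aligned,
                        baseline_block = c("final", "first")) {
  baseline_block <- match.arg(baseline_block)
  if (length(nc_rotated) < 5 || length(nc_aligned) < 5)
    stop("need at least 5 no-cursor trials in each phase")
  base <- if (baseline_block == "final") utils::tail(nc_aligned, 5)
          else nc_aligned[1:5]
  mean(nc_rotated[1:5]) - mean(base)
}

#' Group reach aftereffects from a measures table
#'
#' Extracts per-participant no-cursor angular errors from a [measures_table()]
#' and computes each participant's aftereffect plus the group mean and SEM.
#' The aligned baseline phase is the no-cursor phase closest to rotated
#' training (`aligned_track_nc` when present, else `aligned_reach_nc`).
#'
#' @param measures A measures data.frame from [measures_table()].
#' @param baseline_block Passed to [aftereffect()].
#' @return A list of class `"aftereffect_result"` with `per_participant`
#'   (data.frame `participant_id`, `aftereffect_deg`), `mean_deg`, `sem_deg`.
#' @export
group_aftereffects <- function(measures, baseline_block = c("final", "first")) {
  baseline_block <- match.arg(baseline_block)
  base_phase <- if (any(measures$phase == "aligned_track_nc"))
    "aligned_track_nc" else "aligned_reach_nc"
  ids <- unique(measures$participant_id)
  vals <- vapply(ids, function(id) {
    m <- measures[measures$participant_id == id, ]
    aftereffect(m$angular_error_deg[m$phase == "rotated_nc"],
                m$angular_error_deg[m$phase == base_phase],
                baseline_block)
  }, numeric(1))
  structure(list(per_participant = data.frame(participant_id = ids,
                                              aftereffect_deg = vals),
                 mean_deg = mean(vals),
                 sem_deg = stats::sd(vals) / sqrt(length(vals))),
            class = "aftereffect_result")
}

#' @export
print.aftereffect_result <- function(x, ...) {
  cat(sprintf("Reach aftereffect: %.2f +/- %.2f deg (mean +/- SEM, n = %d)\n",
              x$mean_deg, x$sem_deg, nrow(x$per_participant)))
  invisible(x)
}

# --- exponential learning-curve model -------------------------------------

exp_model <- function(par, x) par[["b"]] * exp(-par[["a"]] * x) + par[["c"]]

#' Fit an exponential learning curve to blocked data
#'
#' Fits the three-parameter model \eqn{RD = b e^{-a x} + c} by bounded
#' least squares (Levenberg-Marquardt with an analytic Jacobian), where x is
#' the block number, a the learning rate, c the asymptote, and b the scaling
#' factor. Default initialisation: a = 0.1, b = first minus last block value,
#' c = last block value. Default bounds: a in [0, 5]; b and c unbounded
#' (tracking-error fits can carry negative b and c).
#'
#' @param blocks A [block_means()] data.frame, or any data.frame with columns
#'   `block` and `mean`; at least 4 blocks of finite values.
#' @param init Optional named numeric vector `c(a=, b=, c=)` overriding the
#'   default start.
#' @param lower,upper Named bounds on the parameters.
#' @param tol Convergence tolerance on the parameters (default 1e-10).
#' @return An object of class `"exp_fit"`: list with `coefficients` (a, b, c),
#'   `rss`, `converged`, `data`, `fitted.values`, `residuals`, and the
#'   optimizer `message`. Supports `print`, `summary`, `coef`, `predict`,
#'   `fitted`, `residuals` and `plot` methods.
#' @examples
#' x <- 1:36
#' y <- 16.72 * exp(-0.07 * x) + 1.65
#' fit <- fit_exponential(data.frame(block = x, mean = y))
#' coef(fit)
#' @export
fit_exponential <- function(blocks, init = NULL,
                            lower = c(a = 0, b = -Inf, c = -Inf),
                            upper = c(a = 5, b = Inf, c = Inf),
                            tol = 1e-10) {
  x <- blocks$block
  y <- blocks$mean
  if (length(x) < 4) stop("need at least 4 blocks to fit 3 parameters")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("non-finite block data")
  start <- c(a = 0.1, b = y[1] - y[length(y)], c = y[length(y)])
  if (!is.null(init)) start[names(init)] <- init
  start <- pmin(pmax(start, lower[names(start)]), upper[names(start)])
  resid_fn <- function(par) y - exp_model(par, x)
  jac_fn <- function(par) {
    e <- exp(-par[["a"]] * x)
    cbind(a = par[["b"]] * x * e, b = -e, c = rep(-1, length(x)))
  }
  fit <- minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                            fn = resid_fn, jac = jac_fn,
                            control = minpack.lm::nls.lm.control(
                              ptol = tol, ftol = tol, maxiter = 500))
  par <- stats::coef(fit)
  fitted <- exp_model(par, x)
  structure(list(coefficients = par, rss = sum((y - fitted)^2),
                 converged = fit$info %in% 1:4,
                 data = data.frame(block = x, mean = y),
                 fitted.values = fitted, residuals = y - fitted,
                 message = fit$message),
            class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, digits = 4, ...) {
  p <- x$coefficients
  cat(sprintf("Exponential learning curve: RD = %s * exp(-%s x) + %s\n",
              format(p[["b"]], digits = digits),
              format(p[["a"]], digits = digits),
              format(p[["c"]], digits = digits)))
  cat(sprintf("  %d blocks, RSS = %.4g, converged: %s\n",
              nrow(x$data), x$rss, x$converged))
  invisible(x)
}

#' @export
summary.exp_fit <- function(object, ...) {
  out <- list(coefficients = object$coefficients, rss = object$rss,
              sigma = sqrt(object$rss / max(1, nrow(object$data) - 3)),
              n_blocks = nrow(object$data), converged = object$converged)
  class(out) <- "summary.exp_fit"
  out
}

#' @export
print.summary.exp_fit <- function(x, ...) {
  cat("Exponential learning-curve fit\n")
  print(x$coefficients)
  cat(sprintf("blocks: %d, RSS: %.4g, residual sigma: %.4g, converged: %s\n",
              x$n_blocks, x$rss, x$sigma, x$converged))
  invisible(x)
}

#' @export
coef.exp_fit <- function(object, ...) object$coefficients

#' @export
fitted.exp_fit <- function(object, ...) object$fitted.values

#' @export
residuals.exp_fit <- function(object, ...) object$residuals

#' Predict from an exponential learning-curve fit
#'
#' @param object An `"exp_fit"`.
#' @param newdata Optional data.frame with a `block` column (defaults to the
#'   fitted blocks).
#' @param ... Unused.
#' @export
predict.exp_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$block else newdata$block
  exp_model(object$coefficients, x)
}

#' Plot an exponential learning-curve fit
#'
#' Blocked means with the fitted curve overlaid (dashed).
#'
#' @param x An `"exp_fit"`.
#' @param xlab,ylab,main Plot labels.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.exp_fit <- function(x, xlab = "Block (5 trials)", ylab = "Measure",
                         main = "Learning curve", ...) {
  graphics::plot(x$data$block, x$data$mean, pch = 19, xlab = xlab,
                 ylab = ylab, main = main, ...)
  xs <- seq(min(x$data$block), max(x$data$block), length.out = 200)
  graphics::lines(xs, exp_model(x$coefficients, xs), lty = 2, col = "red",
                  lwd = 2)
  invisible(x)
}

# --- statistical battery ---------------------------------------------------

#' Bonferroni adjustment
#'
#' Multiplies each p value by the number of comparisons, capped at 1.
#'
#' @param p Raw p values.
#' @param n_comparisons Number of comparisons (default `length(p)`).
#' @export
bonferroni_adjust <- function(p, n_comparisons = length(p)) {
  pmin(1, p * n_comparisons)
}

tidy_t <- function(ht, label) {
  data.frame(effect = label, statistic = unname(ht$statistic),
             df1 = unname(ht$parameter), df2 = NA_real_,
             p = ht$p.value, stringsAsFactors = FALSE)
}

#' Independent or paired t test (tidy row)
#'
#' @param x,y Numeric samples.
#' @param paired Paired test?
#' @param label Effect label carried into the result row.
#' @return One-row data.frame: `effect`, `statistic` (t), `df1` (dof), `p`.
#' @export
t_test_report <- function(x, y, paired = FALSE, label = "t") {
  if (length(x) < 2 || length(y) < 2) stop("each sample needs n >= 2")
  if (sd(c(x, y)) == 0)
    return(data.frame(effect = label, statistic = 0,
                      df1 = if (paired) length(x) - 1 else length(x) + length(y) - 2,
                      df2 = NA_real_, p = 1, stringsAsFactors = FALSE))
  tidy_t(stats::t.test(x, y, paired = paired, var.equal = TRUE), label)
}

aov_f_row <- function(tab, term, label) {
  i <- match(term, trimws(rownames(tab)))
  data.frame(effect = label, statistic = tab[i, "F value"],
             df1 = tab[i, "Df"], df2 = tab[nrow(tab), "Df"],
             p = tab[i, "Pr(>F)"], stringsAsFactors = FALSE)
}

#' One-way repeated-measures ANOVA
#'
#' @param value Measure values.
#' @param level Within-subject factor (e.g. milestone).
#' @param subject Subject identifier.
#' @param label Effect label.
#' @return One-row data.frame with F, df1 (effect), df2 (error), p.
#' @export
rm_anova_oneway <- function(value, level, subject, label = "within") {
  d <- data.frame(value = value, level = factor(level),
                  subject = factor(subject))
  if (any(table(d$subject) != nlevels(d$level)))
    stop("unbalanced repeated measures: each subject needs every level")
  fit <- stats::aov(value ~ level + Error(subject/level), data = d)
  tab <- summary(fit)[["Error: subject:level"]][[1]]
  data.frame(effect = label, statistic = tab["level", "F value"],
             df1 = tab["level", "Df"], df2 = tab["Residuals", "Df"],
             p = tab["level", "Pr(>F)"], stringsAsFactors = FALSE)
}

#' Mixed (between x within) ANOVA
#'
#' The 3 (block) x 2 (group) design: `group` varies between subjects, `level`
#' within. Returns F rows for the group main effect, the within main effect
#' and the interaction.
#'
#' @param value Measure values.
#' @param group Between-subjects factor.
#' @param level Within-subject factor.
#' @param subject Subject identifier (nested in group).
#' @return A data.frame with one row per effect.
#' @export
mixed_anova <- function(value, group, level, subject) {
  d <- data.frame(value = value, group = factor(group),
                  level = factor(level), subject = factor(subject))
  fit <- stats::aov(value ~ group * level + Error(subject/level), data = d)
  s <- summary(fit)
  btab <- s[["Error: subject"]][[1]]
  wtab <- s[["Error: subject:level"]][[1]]
  rn_b <- trimws(rownames(btab)); rn_w <- trimws(rownames(wtab))
  rbind(
    data.frame(effect = "group", statistic = btab[rn_b == "group", "F value"],
               df1 = btab[rn_b == "group", "Df"],
               df2 = btab[rn_b == "Residuals", "Df"],
               p = btab[rn_b == "group", "Pr(>F)"]),
    data.frame(effect = "level", statistic = wtab[rn_w == "level", "F value"],
               df1 = wtab[rn_w == "level", "Df"],
               df2 = wtab[rn_w == "Residuals", "Df"],
               p = wtab[rn_w == "level", "Pr(>F)"]),
    data.frame(effect = "group:level",
               statistic = wtab[rn_w == "group:level", "F value"],
               df1 = wtab[rn_w == "group:level", "Df"],
               df2 = wtab[rn_w == "Residuals", "Df"],
               p = wtab[rn_w == "group:level", "Pr(>F)"]))
}

#' One-way between-groups ANOVA
#'
#' @param value Measure values (one per subject).
#' @param group Group factor (e.g. the three designs for aftereffects).
#' @param label Effect label.
#' @return One-row data.frame with F, df1, df2, p.
#' @export
between_anova_oneway <- function(value, group, label = "group") {
  d <- data.frame(value = value, group = factor(group))
  if (any(table(d$group) < 2)) stop("each group needs n >= 2")
  tab <- summary(stats::aov(value ~ group, data = d))[[1]]
  aov_f_row(tab, "group", label)
}

#' The full statistical battery
#'
#' Reproduces the analysis battery applied to training milestones and
#' aftereffects: a 3 (milestone) x 2 (group) mixed ANOVA, a one-way
#' repeated-measures ANOVA per group, Bonferroni-corrected between-group t
#' tests at the second and final milestone, a one-way between-groups ANOVA on
#' aftereffects across the three designs, and Bonferroni-corrected pairwise t
#' tests between designs. Significance level alpha = .05.
#'
#' @param milestone_df Long data.frame: `participant`, `group` (two levels),
#'   `milestone` (`first_trial`/`second_block`/`final_block`), `value`.
#' @param aftereffect_df Data.frame: `participant`, `group` (three levels),
#'   `value` (per-participant aftereffect, deg).
#' @return A data.frame of test rows (`effect`, `statistic`, `df1`, `df2`,
#'   `p`, `p_bonferroni`).
#' @export
stats_battery <- function(milestone_df, aftereffect_df) {
  rows <- list()
  md <- milestone_df
  rows$mixed <- mixed_anova(md$value, md$group, md$milestone, md$participant)
  for (g in unique(md$group)) {
    sub <- md[md$group == g, ]
    rows[[paste0("rm_", g)]] <-
      rm_anova_oneway(sub$value, sub$milestone, sub$participant,
                      label = paste0("milestones within ", g))
  }
  groups <- unique(md$group)
  if (length(groups) == 2) {
    post <- lapply(c("second_block", "final_block"), function(ms) {
      a <- md$value[md$group == groups[1] & md$milestone == ms]
      b <- md$value[md$group == groups[2] & md$milestone == ms]
      t_test_report(a, b, label = paste0(ms, ": ", groups[1], " vs ", groups[2]))
    })
    post <- do.call(rbind, post)
    post$p_bonferroni <- bonferroni_adjust(post$p, nrow(post))
    rows$post <- post
  }
  ae <- aftereffect_df
  rows$ae_anova <- between_anova_oneway(ae$value, ae$group,
                                        label = "aftereffect group")
  pairs <- utils::combn(as.character(unique(ae$group)), 2, simplify = FALSE)
  ae_t <- do.call(rbind, lapply(pairs, function(pr) {
    t_test_report(ae$value[ae$group == pr[1]], ae$value[ae$group == pr[2]],
                  label = paste0("aftereffect: ", pr[1], " vs ", pr[2]))
  }))
  ae_t$p_bonferroni <- bonferroni_adjust(ae_t$p, nrow(ae_t))
  rows$ae_t <- ae_t
  out <- do.call(rbind, lapply(rows, function(r) {
    if (is.null(r$p_bonferroni)) r$p_bonferroni <- NA_real_
    r
  }))
  rownames(out) <- NULL
  out
}
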