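test_that("block means average non-overlapping five-trial blocks in order", {
  expect_equal(block_means(1:10)$mean, c(3, 8))
  expect_equal(block_means(rep(4.2, 25))$mean, rep(4.2, 5))
  b <- block_means(rnorm(180))
  expect_equal(nrow(b), 36)
  expect_equal(b$block, 1:36)
  expect_error(block_means(1:12), "multiple")
})

test_that("milestones extract first trial, second block and final block", {
  x <- c(30, 25, 22, 20, 18, 16, 15, 14, 13, 12, 5, 4, 3, 2, 1)
  ms <- milestones(x)
  expect_equal(ms$first_trial, 30)
  expect_equal(ms$second_block, 14)
  expect_equal(ms$final_block, 3)
  const <- milestones(rep(2, 20))
  expect_equal(unlist(const), c(first_trial = 2, second_block = 2, final_block = 2))
  dec <- milestones(50 * exp(-0.2 * (1:20)))
  expect_gt(abs(dec$first_trial), abs(dec$second_block))
  expect_gt(abs(dec$second_block), abs(dec$final_block))
  expect_error(milestones(1:5), "10 trials")
})

test_that("aftereffects difference rotated no-cursor errors against the aligned baseline", {
  expect_equal(aftereffect(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5)), 0)
  # baseline variant switch: final vs first aligned block
  nc_al <- c(rep(0, 5), rep(2, 5))
  nc_rot <- rep(10, 5)
  expect_equal(aftereffect(nc_rot, nc_al, "final"), 8)
  expect_equal(aftereffect(nc_rot, nc_al, "first"), 10)
  expect_error(aftereffect(1:3, 1:10), "at least 5")
  # noiseless simulated session: aftereffect equals the frozen hidden state
  sess <- simulate_session(build_session("SINGLE_REACH", 12),
                           calibrate_defaults(), noise_params(aim_sd_deg = 0, seed = 12))
  m <- measures_table(sess)
  ae <- group_aftereffects(m)$mean_deg
  last_train <- max(which(sess$design$phase == "rotated_train"))
  z <- sess$state_audit[last_train, ]
  expect_equal(ae, z$z_shared + z$z_reach, tolerance = 1e-6)
})

test_that("the exponential fitter recovers planted parameters and handles degenerate input", {
  x <- 1:36
  for (p in list(c(a = 0.07, b = 16.72, c = 1.65),
                 c(a = 0.18, b = -1.04, c = -0.88),
                 c(a = 0.5, b = 25, c = -3))) {
    y <- p[["b"]] * exp(-p[["a"]] * x) + p[["c"]]
    fit <- fit_exponential(data.frame(block = x, mean = y))
    expect_true(fit$converged)
    expect_equal(coef(fit), p, tolerance = 1e-4)
    expect_lt(fit$rss, 1e-10)
  }
  # constant series: b ~ 0, c ~ k
  cf <- coef(fit_exponential(data.frame(block = 1:10, mean = rep(7, 10))))
  expect_equal(cf[["b"]], 0, tolerance = 1e-6)
  expect_equal(cf[["c"]], 7, tolerance = 1e-6)
  expect_error(fit_exponential(data.frame(block = 1:3, mean = 1:3)), "4 blocks")
  expect_error(fit_exponential(data.frame(block = 1:5, mean = c(1, NA, 3, 4, 5))),
               "finite")
  # the rate bound holds
  ylow <- 5 * exp(-8 * (1:10)) + 1
  expect_lte(coef(fit_exponential(data.frame(block = 1:10, mean = ylow)))[["a"]], 5)
})

test_that("exp_fit behaves like a standard fitted-model object", {
  x <- 1:20
  set.seed(3)
  y <- 10 * exp(-0.3 * x) + 2 + rnorm(20, 0, 0.05)
  fit <- fit_exponential(data.frame(block = x, mean = y))
  expect_s3_class(fit, "exp_fit")
  expect_named(coef(fit), c("a", "b", "c"))
  expect_equal(fitted(fit) + residuals(fit), y)
  expect_equal(predict(fit), fitted(fit))
  expect_equal(predict(fit, data.frame(block = 0)),
               sum(coef(fit)[c("b", "c")]), tolerance = 1e-8)
  expect_output(print(fit), "Exponential learning curve")
  expect_output(print(summary(fit)), "RSS")
  tf <- tempfile(fileext = ".pdf")
  grDevices::pdf(tf); plot(fit); grDevices::dev.off()
  expect_true(file.exists(tf))
  unlink(tf)
})

test_that("noiseless training curves are exactly exponential in the learner's decay rate", {
  # per-trial error follows e_t = e_inf + C * lambda^t with lambda = A - (Bs+Bc),
  # so blocked means are an exact exponential in the block number
  lp <- calibrate_defaults()
  sess <- simulate_session(build_session("SINGLE_REACH", 13), lp,
                           noise_params(aim_sd_deg = 0, seed = 13))
  m <- measures_table(sess)
  blocks <- block_means(m$angular_error_deg[m$phase == "rotated_train"])
  fit <- fit_exponential(blocks)
  lambda <- lp$retention - (lp$rate_shared + lp$rate_context)
  B <- lp$rate_shared + lp$rate_context
  expect_equal(coef(fit)[["a"]], -5 * log(lambda), tolerance = 1e-6)
  expect_equal(coef(fit)[["c"]], -30 * (1 - lp$retention) / (1 - lp$retention + B),
               tolerance = 1e-6)
})

test_that("t tests, ANOVAs and Bonferroni match brute-force formula oracles", {
  expect_equal(bonferroni_adjust(0.02, 3), 0.06)
  expect_equal(bonferroni_adjust(c(0.5, 0.9)), pmin(1, c(1, 1.8)))
  x <- c(3.1, 4.2, 5.3); y <- c(2.0, 2.5, 4.1)
  tt <- t_test_report(x, y, label = "ind")
  expect_equal(tt$statistic, oracle_t_ind(x, y))
  expect_equal(tt$df1, 4)
  tp <- t_test_report(x, y, paired = TRUE, label = "pair")
  expect_equal(tp$statistic, oracle_t_paired(x, y))
  same <- t_test_report(c(1, 1, 1), c(1, 1, 1))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  # one-way between groups, n = 3 per group
  v <- c(1.2, 2.3, 1.8, 4.1, 3.9, 5.0, 7.7, 8.1, 6.9)
  g <- rep(c("a", "b", "c"), each = 3)
  fb <- between_anova_oneway(v, g)
  expect_equal(fb$statistic, oracle_f_between(v, g))
  expect_equal(c(fb$df1, fb$df2), c(2, 6))
  # repeated measures, 4 subjects x 3 levels
  set.seed(5)
  subj <- rep(1:4, each = 3); lev <- rep(c("l1", "l2", "l3"), 4)
  val <- rnorm(12) + rep(c(0, 1, 2), 4)
  fr <- rm_anova_oneway(val, lev, subj)
  expect_equal(fr$statistic, oracle_f_rm(val, lev, subj))
  expect_equal(c(fr$df1, fr$df2), c(2, 6))
  expect_error(rm_anova_oneway(val[-1], lev[-1], subj[-1]), "unbalanced")
  # mixed 2 groups x 3 levels, 3 subjects per group
  subj <- rep(1:6, each = 3)
  grp <- rep(c("g1", "g2"), each = 9)
  lev <- rep(c("l1", "l2", "l3"), 6)
  set.seed(8)
  val <- rnorm(18) + ifelse(grp == "g2", 1, 0) * rep(c(0, 1, 2), 6)
  fm <- mixed_anova(val, grp, lev, subj)
  orc <- oracle_f_mixed(val, grp, lev, subj)
  expect_equal(fm$statistic[fm$effect == "group"], orc$group)
  expect_equal(fm$statistic[fm$effect == "level"], orc$level)
  expect_equal(fm$statistic[fm$effect == "group:level"], orc$interaction)
  expect_error(between_anova_oneway(c(1, 2), c("a", "b")), "n >= 2")
})

test_that("the full battery produces the protocol's test set on tidy tables", {
  set.seed(9)
  ms <- expand.grid(participant = 1:4, group = c("SINGLE", "DUAL"),
                    milestone = c("first_trial", "second_block", "final_block"),
                    stringsAsFactors = FALSE)
  ms$participant <- paste(ms$group, ms$participant)
  ms$value <- rnorm(nrow(ms)) - 10 * (ms$milestone == "first_trial") -
    3 * (ms$milestone == "second_block") * (ms$group == "DUAL")
  ae <- data.frame(participant = 1:12,
                   group = rep(c("SINGLE_REACH", "SINGLE_TRACK", "DUAL"), each = 4),
                   value = c(rnorm(4, 19), rnorm(4, -9), rnorm(4, 7)))
  out <- stats_battery(ms, ae)
  expect_true(all(c("group:level", "aftereffect group") %in% out$effect))
  expect_equal(sum(grepl("aftereffect: ", out$effect)), 3)
  bonf <- out$p_bonferroni[grepl("aftereffect: ", out$effect)]
  expect_equal(bonf, pmin(1, out$p[grepl("aftereffect: ", out$effect)] * 3))
  expect_true(all(out$p[grepl("aftereffect: ", out$effect)] < 0.05))
})
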