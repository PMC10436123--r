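test_that("rank-sum test: identical samples, separated samples, errors", {
  w <- wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))
  expect_gt(w$p_value, 0.9)
  # fully separated small samples: exact two-tailed p = 2/20
  w2 <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(w2$p_value, 0.1)
  expect_equal(w2$method, "exact")
  expect_equal(w2$statistic, 6)            # ranks 1+2+3
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "non-empty")
})

test_that("exact rank-sum p equals the enumeration oracle (no ties, n <= 10)", {
  set.seed(41)
  for (i in 1:100) {
    nx <- sample(2:5, 1); ny <- sample(2:5, 1)
    v <- sample(1000, nx + ny)             # distinct values, no ties
    x <- v[1:nx] / 7; y <- v[-(1:nx)] / 7
    expect_equal(wilcoxon_rank_sum(x, y)$p_value,
                 wilcoxon_enum_oracle(x, y), tolerance = 1e-12)
  }
})

test_that("normal approximation tracks the exact distribution at n = 8", {
  # exhaustive over all C(8,4) rank splits; the corrected normal
  # approximation never strays beyond 0.035 from the exact two-tailed p
  combos <- utils::combn(8, 4)
  diffs <- apply(combos, 2, function(ix) {
    x <- (1:8)[ix] / 3; y <- (1:8)[-ix] / 3
    abs(wilcoxon_enum_oracle(x, y) -
          wilcoxon_rank_sum(x, y, exact_max = 0)$p_value)
  })
  expect_lt(max(diffs), 0.035)
  expect_lt(median(diffs), 0.02)
})

test_that("tied samples fall back to the corrected normal approximation", {
  x <- c(1, 2, 2, 3); y <- c(2, 3, 3, 4)
  w <- wilcoxon_rank_sum(x, y)
  expect_equal(w$method, "normal approximation")
  ref <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
  expect_equal(w$p_value, ref$p.value)
})

test_that("spearman: perfect monotone pairs, independence, small-n error", {
  x <- 1:10
  expect_equal(spearman_cor(x, exp(x))$rho, 1)
  expect_equal(spearman_cor(x, -x^3)$rho, -1)
  expect_equal(spearman_cor(x, exp(x))$p_value, 0)
  set.seed(43)
  s <- spearman_cor(rnorm(2000), rnorm(2000))
  expect_lt(abs(s$rho), 0.07)
  expect_false(s$follow_up)
  expect_error(spearman_cor(c(1, 2), c(3, 4)), "insufficient")
  expect_error(spearman_cor(c(1, 1, 1), c(1, 2, 3)), "constant")
})

test_that("spearman equals rank-then-Pearson and survives monotone maps", {
  set.seed(44)
  for (i in 1:100) {
    n <- sample(5:40, 1)
    x <- sample(round(rnorm(n), 1))        # plenty of ties
    y <- sample(round(rnorm(n), 1))
    s <- spearman_cor(x, y)
    expect_equal(s$rho, cor(rank(x), rank(y)), tolerance = 1e-12)
    ref <- suppressWarnings(cor.test(x, y, method = "spearman",
                                     exact = FALSE, continuity = FALSE))
    expect_equal(s$rho, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(s$p_value, ref$p.value, tolerance = 1e-10)
    # strictly monotone transforms leave rho untouched
    if (abs(s$rho) < 1) {
      s2 <- spearman_cor(exp(x / 2), y^3 + 2 * y)
      expect_equal(s2$rho, s$rho, tolerance = 1e-12)
    }
  }
})

test_that("follow-up flag fires exactly at |rho| >= 0.30", {
  s_hi <- spearman_cor(1:10, c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9))
  expect_equal(s_hi$follow_up, abs(s_hi$rho) >= 0.3)
  set.seed(45)
  for (i in 1:20) {
    s <- spearman_cor(rnorm(12), rnorm(12))
    expect_equal(s$follow_up, abs(s$rho) >= 0.30)
  }
})

test_that("two-level fit collapses to pooled OLS without cluster variance", {
  set.seed(46)
  n_id <- 12; nd <- 6
  d <- data.frame(participant_id = rep(sprintf("p%02d", 1:n_id), each = nd))
  x <- rnorm(n_id * nd)
  d$centered_log_ndvi <- unsplit(lapply(split(x, d$participant_id),
                                        function(v) v - mean(v)),
                                 d$participant_id)
  # same intercept for everyone: no between-person variance
  d$y <- 1.5 - 0.8 * d$centered_log_ndvi + rnorm(n_id * nd, 0, 0.3)
  fit <- fit_two_level(d, "y")
  ols <- coef(lm(y ~ centered_log_ndvi, data = d))
  row <- fit$fixed[fit$fixed$term == "centered_log_ndvi", ]
  expect_lt(abs(row$estimate - ols[["centered_log_ndvi"]]), 1e-6)
  expect_false(fit$converged)            # honest singular-fit flag
  expect_equal(row$std_estimate,
               row$estimate * sd(d$centered_log_ndvi) / sd(d$y))
  expect_true(row$ci_low <= row$estimate && row$estimate <= row$ci_high)
})

test_that("centering is validated; recentering restores shift invariance", {
  set.seed(47)
  d <- data.frame(participant_id = rep(c("a", "b", "c", "d"), each = 5),
                  centered_log_ndvi = rnorm(20), y = rnorm(20))
  d$centered_log_ndvi <- d$centered_log_ndvi + 0.5   # deliberately off-center
  expect_error(fit_two_level(d, "y"), "person-mean-centered")
  f1 <- fit_two_level(d, "y", recenter = TRUE)
  d2 <- d; d2$centered_log_ndvi <- d$centered_log_ndvi + 3
  f2 <- fit_two_level(d2, "y", recenter = TRUE)
  expect_equal(f1$fixed$estimate, f2$fixed$estimate, tolerance = 1e-8)
  expect_error(fit_two_level(d[1:6, ], "y"), "at least 2")
})

test_that("model recovers variance components and within-person slope", {
  set.seed(48)
  n_id <- 100; nd <- 8
  id <- rep(sprintf("p%03d", 1:n_id), each = nd)
  x <- rnorm(n_id * nd)
  xc <- unsplit(lapply(split(x, id), function(v) v - mean(v)), id)
  a <- rep(rnorm(n_id, 2, 0.7), each = nd)
  y <- a + 0.5 * xc + rnorm(n_id * nd, 0, 0.4)
  d <- data.frame(participant_id = id, centered_log_ndvi = xc, y = y)
  fit <- fit_two_level(d, "y")
  row <- fit$fixed[fit$fixed$term == "centered_log_ndvi", ]
  expect_lt(abs(row$estimate - 0.5), 0.05)
  expect_lt(abs(sqrt(fit$var_intercept) - 0.7), 0.12)
  expect_lt(abs(sqrt(fit$var_residual) - 0.4), 0.03)
  expect_true(fit$converged)
  expect_equal(fit$n_participants, 100)
  expect_lt(row$p_value, 1e-10)
})

test_that("association report assembles all three tables deterministically", {
  cfg <- quick_cfg(seed = 49, within_effect_b = c(anxious = -0.4))
  coh <- generate_cohort(cfg)
  expd <- cohort_daily_exposure(coh$traces, coh$raster, tz = cfg$tz)
  aff <- daily_mean_affect(validate_ema(coh$ema)$clean, tz = cfg$tz)
  seg <- segment_interactions(coh$transcripts)
  dsc <- aggregate_daily_scores(
    score_segments(seg, default_affect_lexicon(), tz = cfg$tz))
  rep1 <- analysis_report(expd$daily, aff, dsc, coh$groups,
                          time_at_home = coh$truth$time_at_home)
  rep2 <- analysis_report(expd$daily, aff, dsc, coh$groups,
                          time_at_home = coh$truth$time_at_home)
  expect_identical(rep1, rep2)
  expect_true(all(c("mean_happy", "mean_ndvi", "pct_anger", "hours_at_home")
                  %in% rep1$group_differences$variable))
  expect_true(all(rep1$correlations$follow_up ==
                    (abs(rep1$correlations$rho) >= 0.30)))
  expect_true(all(rep1$mlm$p_value >= 0 & rep1$mlm$p_value <= 1))
  # sensitivity reruns: dropping days and adjusting for time at home
  excl <- coh$truth$daily[1:3, c("participant_id", "date")]
  rep3 <- analysis_report(expd$daily, aff, dsc, coh$groups,
                          exclude_days = excl)
  expect_equal(rep1$n_days_used - rep3$n_days_used, 3)
  rep4 <- analysis_report(expd$daily, aff, dsc, coh$groups,
                          time_at_home = coh$truth$time_at_home,
                          adjust_time_at_home = TRUE)
  expect_s3_class(rep4, "association_report")
  expect_error(analysis_report(NULL, aff, dsc, coh$groups), "dependency")
})
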