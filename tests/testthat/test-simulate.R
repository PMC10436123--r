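test_that("raster generator hits the configured land statistics", {
  # degenerate configurations
  cfg0 <- quick_cfg(water_fraction = 0, seed = 1)
  r0 <- generate_ndvi_raster(cfg0)$raster
  expect_true(all(r0$values >= 0))
  cfg1 <- quick_cfg(water_fraction = 1, seed = 1)
  expect_true(all(generate_ndvi_raster(cfg1)$raster$values < 0))
  # land mean within 3 SE of the target over 10 seeds
  for (s in 1:10) {
    cfg <- sim_config(seed = s, raster_shape = c(100, 100),
                      water_fraction = 0, ndvi_mean = 0.14)
    v <- generate_ndvi_raster(cfg)$raster$values
    se <- cfg$ndvi_sd / sqrt(length(v))
    expect_lt(abs(mean(v) - 0.14), 3 * se)
    expect_true(all(v >= -1 & v <= 1))
  }
  # bit-identical under a fixed seed
  a <- generate_ndvi_raster(quick_cfg(seed = 5))
  b <- generate_ndvi_raster(quick_cfg(seed = 5))
  expect_identical(a$raster$values, b$raster$values)
  expect_identical(a$bands$nir, b$bands$nir)
  # invalid configurations are rejected
  expect_error(sim_config(raster_shape = c(1, 5)), "2x2")
  expect_error(sim_config(ndvi_sd = 0), "ndvi_sd")
})

test_that("NDVI computed from the generated band pair matches the surface", {
  rb <- generate_ndvi_raster(quick_cfg(seed = 2))
  expect_equal(compute_ndvi(rb$bands)$values, rb$raster$values)
})

test_that("GPS traces have one fix per epoch, nights at home", {
  cfg <- quick_cfg(seed = 3)
  rb <- generate_ndvi_raster(cfg)
  home <- c(cfg$raster_origin["lon"] + 0.03, cfg$raster_origin["lat"] + 0.03)
  set.seed(3)
  tr <- generate_gps_trace(cfg, "p1", rb$raster, home)
  expect_equal(nrow(tr), cfg$n_days * 24 * 60 / cfg$gps_epoch)  # 3 x 240
  expect_true(!is.unsorted(tr$timestamp))
  night <- in_clock_window(tr$timestamp, cfg$night_window, cfg$tz)
  d <- geosphere::distHaversine(cbind(tr$lon[night], tr$lat[night]),
                                c(home[1], home[2]))
  expect_lt(max(d), 60)      # home plus ~10 m jitter only
  # frozen mobility keeps daytime fixes at home too
  cfg0 <- quick_cfg(mobility_step_sd = 0, seed = 3)
  set.seed(4)
  tr0 <- generate_gps_trace(cfg0, "p1", rb$raster, home)
  d0 <- geosphere::distHaversine(cbind(tr0$lon, tr0$lat), c(home[1], home[2]))
  expect_lt(max(d0), 60)
  # a week at the default epoch is 1680 fixes
  cfg7 <- sim_config(seed = 1)
  expect_equal(cfg7$n_days * 24 * 60 / cfg7$gps_epoch, 1680)
  expect_error(generate_gps_trace(cfg, "p1", rb$raster, c(0, 0)),
               "outside raster extent")
})

test_that("prompt schedules respect windows and minimum gaps", {
  cfg <- sim_config(n_ssd = 3, n_control = 2, seed = 11)
  pr <- schedule_ema_prompts(cfg)
  expect_equal(nrow(pr), 5 * cfg$n_days * 3)
  mins <- local_clock_minutes(pr$time, cfg$tz)
  win <- vapply(cfg$prompt_windows, greenspaceEMA:::parse_clock, numeric(2))
  for (slot in 1:3) {
    m <- mins[pr$slot == slot]
    expect_true(all(m >= win[1, slot] & m <= win[2, slot]))
  }
  byday <- split(mins, paste(pr$participant_id, pr$date))
  expect_true(all(vapply(byday, length, integer(1)) == 3))
  gaps <- unlist(lapply(byday, function(m) diff(sort(m))))
  expect_true(all(gaps >= 90))
  # zero minimum gap accepts any in-window draw; infeasible configs error
  cfg0 <- sim_config(min_prompt_gap = 0, seed = 12)
  expect_silent(schedule_ema_prompts(cfg0))
  expect_error(schedule_ema_prompts(sim_config(min_prompt_gap = 600, seed = 1)),
               "min_prompt_gap")
})

test_that("EMA responses stay on the 0-5 scale and degenerate correctly", {
  cfg <- quick_cfg(seed = 13)
  truth <- data.frame(participant_id = rep(participant_ids(cfg)[1:7], each = 3),
                      date = as.Date("2023-05-01") + 0:2,
                      mean_ndvi = runif(21, 0.05, 0.4))
  pr <- schedule_ema_prompts(cfg, seed = 13)
  out <- generate_ema_responses(cfg, truth, pr, seed = 13)
  expect_true(all(out$records$response %in% 0:5))
  # no noise, no effects: all of a participant's responses are identical
  cfgd <- quick_cfg(residual_sd = 0, random_intercept_sd = 0, seed = 14)
  outd <- generate_ema_responses(cfgd, truth, pr, seed = 14)
  per <- tapply(outd$records$response,
                paste(outd$records$participant_id, outd$records$item),
                function(x) length(unique(x)))
  expect_true(all(per == 1))
})

test_that("injected within-person slope is recovered by an oracle regression", {
  # large-n check of the calibration: regress daily means on centered
  # exposure with person fixed effects (independent of the mixed-model path)
  cfg <- sim_config(n_ssd = 60, n_control = 60, n_days = 14,
                    within_effect_b = c(anxious = -0.4), seed = 15)
  sim <- simulate_daily_cohort(cfg, seed = 15)
  d <- sim$daily
  fit <- lm(mean_anxious ~ centered_log_ndvi + participant_id, data = d)
  raw <- coef(fit)[["centered_log_ndvi"]]
  b_std <- raw * sd(d$centered_log_ndvi) / sd(d$mean_anxious)
  expect_lt(abs(b_std - (-0.4)), 0.08)   # ~1680 days of MC error
  eff <- sim$effects
  expect_equal(eff$beta_latent[eff$item == "happy"], 0)
  expect_lt(abs(raw - eff$beta_observed[eff$item == "anxious"]), 0.25)
})

test_that("null effects leave exposure and affect uncorrelated", {
  cfg <- sim_config(n_ssd = 40, n_control = 40, n_days = 10, seed = 16)
  sim <- simulate_daily_cohort(cfg, seed = 16)
  r <- cor(sim$daily$centered_log_ndvi, sim$daily$mean_anxious)
  expect_lt(abs(r), 2.5 / sqrt(nrow(sim$daily)))
})

test_that("transcript word rates follow the configured binomial rates", {
  cfg <- quick_cfg(seed = 17, affect_word_rate_base = c(positive = 4,
                                                        anxiety = 0.15,
                                                        anger = 0.5,
                                                        sadness = 0.2))
  truth <- data.frame(participant_id = rep(participant_ids(cfg), each = 3),
                      date = as.Date("2023-05-01") + 0:2,
                      mean_ndvi = runif(21, 0.05, 0.4))
  tr <- generate_transcripts(cfg, truth, seed = 17)
  lex <- default_affect_lexicon()
  toks <- tokenize(tr$utterances$text)
  expect_gt(length(toks), 4000)
  s <- score_tokens(toks, lex)
  # base rate 4% positive words: binomial SE at this n is ~0.2 points
  expect_lt(abs(s$pct_positive - 4), 3 * sqrt(4 * 96 / length(toks)))
  # zero effect: rate independent of exposure (expected pct constant)
  expect_true(all(tr$expected$expected_pct[tr$expected$category == "positive"]
                  == 4))
  # lapses of 20 s or more occur, giving the segmenter something to split
  seg <- segment_interactions(tr$utterances)
  expect_gt(length(unique(seg$segment)),
            length(unique(format(tr$utterances$start, "%Y-%m-%d"))))
})

test_that("full cohorts are internally consistent and deterministic", {
  cfg <- quick_cfg(seed = 19)
  coh <- generate_cohort(cfg)
  expect_equal(length(unique(coh$traces$participant_id)), 7)
  expect_setequal(unique(coh$groups$group), c("control", "SSD"))
  expect_equal(sum(table(coh$groups$group)), cfg$n_ssd + cfg$n_control)
  # truth covers every participant-day that has retained GPS fixes
  expect_true(all(table(coh$truth$daily$participant_id) <= cfg$n_days))
  expect_true(all(coh$truth$daily$n_points >= 1))
  # defaults give the 34-participant study design
  expect_equal(nrow(cohort_groups(sim_config())), 34)
  # a 1-day cohort spans exactly one calendar day in every stream
  cfg1 <- quick_cfg(n_days = 1, seed = 20)
  coh1 <- generate_cohort(cfg1)
  expect_equal(unique(local_date(coh1$traces$timestamp, cfg1$tz)),
               as.Date(cfg1$start_date))
  expect_equal(unique(local_date(coh1$ema$timestamp, cfg1$tz)),
               as.Date(cfg1$start_date))
  expect_equal(unique(local_date(coh1$transcripts$start, cfg1$tz)),
               as.Date(cfg1$start_date))
})

test_that("cohorts round-trip through plain-text files exactly", {
  cfg <- quick_cfg(seed = 22)
  coh <- generate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  back <- read_cohort(dir, tz = cfg$tz)
  expect_identical(back$traces$lat, coh$traces$lat)
  expect_identical(back$traces$lon, coh$traces$lon)
  expect_true(all(back$traces$timestamp == coh$traces$timestamp))
  expect_identical(back$ema$response, coh$ema$response)
  expect_identical(back$transcripts$text, coh$transcripts$text)
  expect_identical(back$raster$values, coh$raster$values)
  expect_identical(back$truth_daily$mean_ndvi, coh$truth$daily$mean_ndvi)
})

test_that("fast-path cohorts expose centered, analysis-ready daily tables", {
  cfg <- sim_config(seed = 23)
  sim <- simulate_daily_cohort(cfg)
  d <- sim$daily
  expect_equal(nrow(d), 34 * 7)
  sums <- tapply(d$centered_log_ndvi, d$participant_id, sum)
  expect_true(all(abs(sums) < 1e-9))
  expect_true(all(d$mean_ndvi > 0 & d$mean_ndvi <= 1))
  expect_true(all(abs(d$log_ndvi -
                        (d$centered_log_ndvi + d$person_mean_log_ndvi)) < 1e-12))
  # same seed, same cohort
  expect_identical(simulate_daily_cohort(cfg)$daily, d)
})
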