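#' Daily-level fast-path cohort simulation
#'
#' Simulates the participant-day analysis table directly — true daily mean
#' NDVI plus EMA daily affect means — without per-fix GPS traces, rasters or
#' transcripts. Daily log exposure is person intercept plus day noise
#' (log-normal NDVI centered on the configured `ndvi_mean`), and responses use
#' exactly the same latent-affect sampler and slope calibration as the full
#' generator, so the injected standardized effects have the same meaning.
#' Intended for replication studies (parameter recovery, error rates) where
#' thousands of cohorts are fitted and only the daily table matters.
#'
#' @inheritParams generate_ndvi_raster
#' @param sd_between,sd_within SDs of the person-level and day-level
#'   components of log daily NDVI. Defaults mirror the spread the full
#'   generator produces at its own defaults.
#' @return list with `daily` (one row per participant-day: exposure columns as
#'   produced by [person_center()], affect daily means) and `effects`
#'   (per-item truth as in [generate_ema_responses()]).
#' @export
simulate_daily_cohort <- function(config, seed = config$seed,
                                  sd_between = 0.22, sd_within = 0.20) {
  validate_sim_config(config)
  if (!is.null(seed)) set.seed(seed)
  ids <- participant_ids(config)
  n_id <- length(ids); nd <- config$n_days
  mu_log <- log(config$ndvi_mean) - sd_between^2 / 2
  pm_true <- rnorm(n_id, mu_log, sd_between)
  daily_log <- rep(pm_true, each = nd) + rnorm(n_id * nd, 0, sd_within)
  daily <- data.frame(
    participant_id = rep(ids, each = nd),
    date = rep(as.Date(config$start_date) + seq_len(nd) - 1, n_id),
    mean_ndvi = pmin(exp(daily_log), 1),
    n_points = NA_integer_, stringsAsFactors = FALSE)
  daily$log_ndvi <- log(daily$mean_ndvi)
  pm_real <- tapply(daily$log_ndvi, daily$participant_id, mean)[daily$participant_id]
  daily$person_mean_log_ndvi <- as.vector(pm_real)
  daily$centered_log_ndvi <- daily$log_ndvi - daily$person_mean_log_ndvi

  # population SD of realized person-centered deviations (centering shrink)
  sd_z_pop <- sd_within * sqrt((nd - 1) / nd)
  effects <- ema_latent_effects(config, sd_z_pop)

  items <- effects$item
  pm_std <- if (n_id > 1) (pm_true - mean(pm_true)) / stats::sd(pm_true)
            else rep(0, n_id)
  a_i <- matrix(rnorm(n_id * length(items), 0, config$random_intercept_sd),
                n_id, length(items), dimnames = list(ids, items))
  npp <- config$prompts_per_day
  for (j in seq_along(items)) {
    it <- items[j]
    m <- config$item_intercepts[[it]] + a_i[daily$participant_id, it] +
      effects$beta_latent[j] * daily$centered_log_ndvi +
      config$between_effect_b * effects$sd_y[j] *
        pm_std[match(daily$participant_id, ids)]
    resp <- matrix(sample_responses(rep(m, npp), config$residual_sd,
                                    config$response_scale_max),
                   ncol = npp)
    daily[[paste0("mean_", it)]] <- rowMeans(resp)
  }
  daily$n_prompts_answered <- npp
  list(daily = daily, effects = effects, groups = cohort_groups(config))
}
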