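#' Simulation configuration for a synthetic cohort
#'
#' Bundles every knob of the synthetic-data generator. The defaults encode the
#' study design this package targets: two groups (20 SSD, 14 controls), 7 days,
#' 3 EMA prompts/day drawn inside the 10 AM-1 PM / 2-5 PM / 5-8 PM windows at
#' least 90 minutes apart, one GPS fix per 6-minute epoch, a nighttime window
#' of 9 PM-6 AM used for home detection, and a vegetation raster whose land
#' cells have mean NDVI 0.14 (SD 0.065).
#'
#' @param n_ssd,n_control participants per group.
#' @param n_days study length in days.
#' @param prompts_per_day EMA prompts per day (one per window).
#' @param prompt_windows list of `c(start, end)` clock strings, ordered and
#'   non-overlapping.
#' @param min_prompt_gap minimum gap between consecutive prompts, minutes.
#' @param gps_epoch minutes between GPS fixes.
#' @param night_window clock window (may cross midnight) used for home
#'   detection and nights-at-home simulation.
#' @param raster_shape `c(rows, cols)` of the NDVI grid.
#' @param raster_origin `c(lon, lat)` of the grid's lower-left corner.
#' @param pixel_size cell size, decimal degrees.
#' @param ndvi_mean,ndvi_sd target mean and SD of land-cell NDVI.
#' @param water_fraction share of cells that are water (negative NDVI).
#' @param home_coords optional 2-column matrix (lon, lat) of per-participant
#'   homes; drawn on land cells when `NULL`.
#' @param mobility_step_sd random-walk step SD during excursions, degrees.
#'   `0` keeps participants at home all day.
#' @param gps_jitter_m receiver noise SD in meters, applied to every fix.
#' @param provider_mix named sampling probabilities over the four location
#'   providers.
#' @param excursion_hours,excursion_hours_sd mean/SD of daily time away from
#'   home (hours); the complement is time at home (~16 h/day by default).
#' @param within_effect_b standardized within-person slope of daily affect on
#'   person-centered log NDVI, on the observed 0-5 daily-mean scale. A named
#'   vector over `c(happy, sad, anxious)`; a single unnamed number is applied
#'   to the anxiety item.
#' @param between_effect_b standardized between-person slope on the person
#'   mean (approximate; applied to the standardized person mean).
#' @param residual_sd prompt-level latent residual SD.
#' @param random_intercept_sd SD of the person-level latent intercepts.
#' @param item_intercepts latent scale locations per item (0-5 scale units).
#' @param affect_word_rate_base baseline percentage of words in each lexicon
#'   category (percent of tokens).
#' @param affect_word_effect percentage-point change in each category rate per
#'   SD of within-person exposure deviation.
#' @param ema_missing_rate completely-at-random EMA nonresponse probability.
#' @param response_scale_max top of the ordinal response scale (0-based, so 5
#'   means a 6-point scale).
#' @param tz single study time zone; days are local midnight-to-midnight.
#' @param start_date first local study day, `"YYYY-MM-DD"`.
#' @param home_radius_m radius used when computing true exposure (fixes within
#'   this distance of the true home do not count, mirroring preprocessing).
#' @param seed integer seed fixing all randomness of the generator.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_ssd = 20L, n_control = 14L, n_days = 7L,
                       prompts_per_day = 3L,
                       prompt_windows = list(c("10:00", "13:00"),
                                             c("14:00", "17:00"),
                                             c("17:00", "20:00")),
                       min_prompt_gap = 90,
                       gps_epoch = 6,
                       night_window = c("21:00", "06:00"),
                       raster_shape = c(120L, 120L),
                       raster_origin = c(lon = -122.52, lat = 37.70),
                       pixel_size = 0.001,
                       ndvi_mean = 0.14, ndvi_sd = 0.065,
                       water_fraction = 0.08,
                       home_coords = NULL,
                       mobility_step_sd = 0.002,
                       gps_jitter_m = 10,
                       provider_mix = c(gps = 0.70, fused = 0.20,
                                        `network-passive` = 0.05,
                                        `gps-passive` = 0.05),
                       excursion_hours = 8, excursion_hours_sd = 1.5,
                       within_effect_b = c(happy = 0, sad = 0, anxious = 0),
                       between_effect_b = 0,
                       residual_sd = 0.8,
                       random_intercept_sd = 0.5,
                       item_intercepts = c(happy = 2.9, sad = 0.65,
                                           anxious = 0.85),
                       affect_word_rate_base = c(positive = 4, anxiety = 0.15,
                                                 anger = 0.5, sadness = 0.2),
                       affect_word_effect = c(positive = 0, anxiety = 0,
                                              anger = 0, sadness = 0),
                       ema_missing_rate = 0,
                       response_scale_max = 5L,
                       tz = "America/Los_Angeles",
                       start_date = "2023-05-01",
                       home_radius_m = 100,
                       seed = 1L) {
  items <- c("happy", "sad", "anxious")
  if (is.null(names(within_effect_b))) {
    if (length(within_effect_b) != 1)
      stop("unnamed `within_effect_b` must be a single number (anxiety item)")
    within_effect_b <- c(happy = 0, sad = 0, anxious = unname(within_effect_b))
  } else {
    full <- c(happy = 0, sad = 0, anxious = 0)
    full[names(within_effect_b)] <- within_effect_b
    within_effect_b <- full
  }
  cfg <- list(n_ssd = as.integer(n_ssd), n_control = as.integer(n_control),
              n_days = as.integer(n_days),
              prompts_per_day = as.integer(prompts_per_day),
              prompt_windows = prompt_windows,
              min_prompt_gap = min_prompt_gap, gps_epoch = gps_epoch,
              night_window = night_window, raster_shape = as.integer(raster_shape),
              raster_origin = raster_origin, pixel_size = pixel_size,
              ndvi_mean = ndvi_mean, ndvi_sd = ndvi_sd,
              water_fraction = water_fraction, home_coords = home_coords,
              mobility_step_sd = mobility_step_sd, gps_jitter_m = gps_jitter_m,
              provider_mix = provider_mix,
              excursion_hours = excursion_hours,
              excursion_hours_sd = excursion_hours_sd,
              within_effect_b = within_effect_b[items],
              between_effect_b = between_effect_b,
              residual_sd = residual_sd,
              random_intercept_sd = random_intercept_sd,
              item_intercepts = item_intercepts[items],
              affect_word_rate_base = affect_word_rate_base,
              affect_word_effect = affect_word_effect,
              ema_missing_rate = ema_missing_rate,
              response_scale_max = as.integer(response_scale_max),
              tz = tz, start_date = start_date,
              home_radius_m = home_radius_m, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  counts <- c(cfg$n_ssd, cfg$n_control, cfg$n_days, cfg$prompts_per_day)
  if (any(counts < 1)) stop("configuration error: all counts must be >= 1")
  if (length(cfg$prompt_windows) != cfg$prompts_per_day)
    stop("configuration error: need one prompt window per prompt")
  w <- vapply(cfg$prompt_windows, parse_clock, numeric(2))
  if (any(w[1, ] >= w[2, ])) stop("configuration error: empty prompt window")
  if (cfg$prompts_per_day > 1 && any(w[2, -ncol(w)] > w[1, -1] + 1e-9) &&
      any(w[1, -1] < w[2, -ncol(w)] - 1e-9))
    stop("configuration error: prompt windows must be ordered and non-overlapping")
  if (cfg$water_fraction < 0 || cfg$water_fraction >= 1 + 1e-12)
    stop("configuration error: water_fraction must be in [0, 1]")
  if (cfg$ndvi_sd <= 0) stop("configuration error: ndvi_sd must be > 0")
  if (any(cfg$raster_shape < 2)) stop("configuration error: raster must be at least 2x2")
  if (cfg$pixel_size <= 0) stop("configuration error: pixel_size must be > 0")
  if (any(cfg$affect_word_rate_base < 0))
    stop("configuration error: negative affect_word_rate_base")
  if (cfg$ema_missing_rate < 0 || cfg$ema_missing_rate >= 1)
    stop("configuration error: ema_missing_rate must be in [0, 1)")
  if (any(abs(cfg$within_effect_b) >= 1) || abs(cfg$between_effect_b) >= 1)
    stop("configuration error: standardized effects must lie in (-1, 1)")
  invisible(cfg)
}

participant_ids <- function(cfg) {
  c(sprintf("ssd%02d", seq_len(cfg$n_ssd)),
    sprintf("ctl%02d", seq_len(cfg$n_control)))
}

#' Participant group labels implied by a configuration
#' @param config a [sim_config()].
#' @return data.frame with `participant_id` and `group` (`"SSD"`/`"control"`).
#' @export
cohort_groups <- function(config) {
  data.frame(participant_id = participant_ids(config),
             group = rep(c("SSD", "control"),
                         c(config$n_ssd, config$n_control)),
             stringsAsFactors = FALSE)
}
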