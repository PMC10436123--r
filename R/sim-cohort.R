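#' Generate a synthetic NDVI raster and its underlying band pair
#'
#' Builds a spatially correlated vegetation surface: a smoothed Gaussian field
#' is rank-transformed so that land cells follow a Beta distribution rescaled
#' to \eqn{[0, 1]} with mean `ndvi_mean` and SD `ndvi_sd` (the Beta has these
#' moments exactly, and the rank transform makes the realized land mean match
#' the target up to discretization), while the lowest-lying `water_fraction`
#' share of cells become water with NDVI drawn from \eqn{(-0.6, -0.05)}.
#' The returned band pair has constant total reflectance \eqn{NIR + VIS = 0.6}
#' so that [compute_ndvi()] recovers the surface exactly.
#'
#' @param config a [sim_config()].
#' @param seed optional seed; `NULL` continues the current random stream.
#' @return list with elements `raster` ([ndvi_raster()], equal to
#'   `compute_ndvi(bands)`) and `bands` ([band_pair()]).
#' @export
generate_ndvi_raster <- function(config, seed = config$seed) {
  validate_sim_config(config)
  if (!is.null(seed)) set.seed(seed)
  nr <- config$raster_shape[1]; nc <- config$raster_shape[2]
  m <- config$ndvi_mean; v <- config$ndvi_sd^2
  if (v >= m * (1 - m))
    stop("configuration error: ndvi_sd too large for a [0,1] Beta surface")
  k <- m * (1 - m) / v - 1
  a <- m * k; b <- (1 - m) * k

  field <- matrix(rnorm(nr * nc), nr, nc)
  field <- smooth_grid(field, width = 9L)
  r <- rank(c(field), ties.method = "first")
  n <- nr * nc
  n_water <- round(config$water_fraction * n)
  vals <- numeric(n)
  if (n_water > 0) {
    w <- r <= n_water
    vals[w] <- -0.6 + 0.55 * (r[w] - 0.5) / n_water
  }
  if (n_water < n) {
    l <- r > n_water
    vals[l] <- qbeta((r[l] - n_water - 0.5) / (n - n_water), a, b)
  }
  ndvi <- matrix(vals, nr, nc)
  bands <- band_pair(nir = 0.3 * (1 + ndvi), vis = 0.3 * (1 - ndvi),
                     xll = unname(config$raster_origin["lon"]),
                     yll = unname(config$raster_origin["lat"]),
                     cellsize = config$pixel_size)
  list(raster = compute_ndvi(bands), bands = bands)
}

# separable circular moving average applied twice (near-Gaussian kernel)
smooth_grid <- function(z, width = 9L) {
  k <- rep(1 / width, width)
  for (pass in 1:2) {
    z <- apply(z, 2, function(col) stats::filter(col, k, circular = TRUE))
    z <- t(apply(z, 1, function(row) stats::filter(row, k, circular = TRUE)))
  }
  z
}

# Draw per-participant homes on land cells away from the raster border.
assign_homes <- function(config, raster, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ids <- participant_ids(config)
  if (!is.null(config$home_coords)) {
    hc <- config$home_coords
    ext <- raster_extent(raster)
    if (any(hc[, 1] < ext["xmin"] | hc[, 1] >= ext["xmax"] |
            hc[, 2] < ext["ymin"] | hc[, 2] >= ext["ymax"]))
      stop("configuration error: home outside raster extent")
    return(data.frame(participant_id = ids,
                      home_lon = hc[, 1], home_lat = hc[, 2],
                      stringsAsFactors = FALSE))
  }
  nr <- nrow(raster$values); nc <- ncol(raster$values)
  margin <- max(2L, min(10L, nr %/% 6, nc %/% 6))
  rows <- (margin + 1):(nr - margin); cols <- (margin + 1):(nc - margin)
  land <- which(raster$values[rows, cols, drop = FALSE] >= 0, arr.ind = TRUE)
  if (nrow(land) < length(ids))
    stop("configuration error: not enough land cells to place homes")
  pick <- land[sample.int(nrow(land), length(ids)), , drop = FALSE]
  row_n <- rows[pick[, 1]]; col_n <- cols[pick[, 2]]
  cs <- raster$cellsize
  # cell centers: matrix row 1 is the northern edge
  lon <- raster$xll + (col_n - 0.5) * cs + runif(length(ids), -0.3, 0.3) * cs
  lat <- raster$yll + (nr - row_n + 0.5) * cs + runif(length(ids), -0.3, 0.3) * cs
  data.frame(participant_id = ids, home_lon = lon, home_lat = lat,
             stringsAsFactors = FALSE)
}

#' Generate one participant's GPS trace
#'
#' Home-anchored mobility: the participant sits at home (plus receiver jitter)
#' through the night window and outside a single daily excursion; during the
#' excursion the position follows a Brownian-bridge random walk that leaves
#' from and returns to home, clamped to the raster extent. One fix is emitted
#' per `gps_epoch` minutes (a multi-second burst is collapsed to one
#' representative fix). Providers are drawn from the configured mixture and
#' jitter is Gaussian with SD `gps_jitter_m`, applied in a local metric frame.
#'
#' @inheritParams generate_ndvi_raster
#' @param participant_id identifier used in the output rows.
#' @param raster the cohort's [ndvi_raster()] (defines the study extent).
#' @param home `c(lon, lat)`; must lie inside the raster extent.
#' @return data.frame with columns `participant_id`, `timestamp` (POSIXct),
#'   `lat`, `lon`, `accuracy_m`, `provider`.
#' @export
generate_gps_trace <- function(config, participant_id, raster, home,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ext <- raster_extent(raster)
  if (home[1] < ext["xmin"] || home[1] >= ext["xmax"] ||
      home[2] < ext["ymin"] || home[2] >= ext["ymax"])
    stop("configuration error: home outside raster extent")
  ep <- config$gps_epoch
  start <- as.POSIXct(paste(config$start_date, "00:00:00"), tz = config$tz)
  mins <- seq(0, config$n_days * 1440 - ep, by = ep)
  times <- start + mins * 60
  n <- length(mins)
  day <- mins %/% 1440 + 1L
  clock <- mins %% 1440

  lon <- rep(home[1], n); lat <- rep(home[2], n)
  night <- in_clock_window(times, config$night_window, config$tz)
  for (d in seq_len(config$n_days)) {
    dep <- runif(1, 450, 630)                       # leave 07:30-10:30
    dur <- 60 * max(1, min(14, rnorm(1, config$excursion_hours,
                                     config$excursion_hours_sd)))
    away <- which(day == d & !night & clock >= dep & clock < dep + dur)
    k <- length(away)
    if (k == 0 || config$mobility_step_sd == 0) next
    wx <- cumsum(rnorm(k, 0, config$mobility_step_sd))
    wy <- cumsum(rnorm(k, 0, config$mobility_step_sd))
    frac <- seq_len(k) / (k + 1)                    # bridge back to home
    lon[away] <- home[1] + wx - frac * wx[k]
    lat[away] <- home[2] + wy - frac * wy[k]
  }
  eps <- 1e-9
  lon <- pmin(pmax(lon, ext["xmin"]), ext["xmax"] - eps)
  lat <- pmin(pmax(lat, ext["ymin"]), ext["ymax"] - eps)

  m_per_deg_lat <- 111320
  m_per_deg_lon <- 111320 * cos(home[2] * pi / 180)
  lat <- lat + rnorm(n, 0, config$gps_jitter_m / m_per_deg_lat)
  lon <- lon + rnorm(n, 0, config$gps_jitter_m / m_per_deg_lon)
  providers <- sample(names(config$provider_mix), n, replace = TRUE,
                      prob = config$provider_mix)
  data.frame(participant_id = participant_id, timestamp = times,
             lat = unname(lat), lon = unname(lon),
             accuracy_m = round(runif(n, 5, 25), 1),
             provider = providers, stringsAsFactors = FALSE)
}

#' Randomized EMA prompt schedule
#'
#' Draws `prompts_per_day` prompt times per participant-day, one uniformly
#' inside each configured window, rejection-sampling each day until all
#' consecutive gaps are at least `min_prompt_gap` minutes. A greedy
#' feasibility check (earliest admissible time per window) rejects impossible
#' window/gap combinations up front.
#'
#' @inheritParams generate_ndvi_raster
#' @param seed optional seed; `NULL` continues the current random stream.
#' @return data.frame with `participant_id`, `date`, `slot`, `time` (POSIXct).
#' @export
schedule_ema_prompts <- function(config, seed = config$seed) {
  if (!is.null(seed)) set.seed(seed)
  w <- vapply(config$prompt_windows, parse_clock, numeric(2))
  gap <- config$min_prompt_gap
  t_feas <- -Inf
  for (j in seq_len(ncol(w))) {
    t_feas <- max(w[1, j], t_feas + gap)
    if (t_feas > w[2, j])
      stop("configuration error: prompt windows cannot honor min_prompt_gap")
  }
  ids <- participant_ids(config)
  grid <- expand.grid(day = seq_len(config$n_days), participant_id = ids,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[order(grid$participant_id, grid$day), ]
  nrow_g <- nrow(grid)
  draws <- matrix(NA_real_, nrow_g, ncol(w))
  todo <- rep(TRUE, nrow_g)
  for (iter in 1:10000) {
    idx <- which(todo)
    if (!length(idx)) break
    for (j in seq_len(ncol(w)))
      draws[idx, j] <- runif(length(idx), w[1, j], w[2, j])
    if (ncol(w) > 1) {
      gaps_ok <- rowSums(draws[idx, -1, drop = FALSE] -
                           draws[idx, -ncol(w), drop = FALSE] < gap) == 0
    } else gaps_ok <- rep(TRUE, length(idx))
    todo[idx[gaps_ok]] <- FALSE
  }
  if (any(todo)) stop("configuration error: prompt schedule rejection sampling failed")
  start <- as.POSIXct(paste(config$start_date, "00:00:00"), tz = config$tz)
  out <- data.frame(
    participant_id = rep(grid$participant_id, each = ncol(w)),
    date = rep(as.Date(config$start_date) + grid$day - 1, each = ncol(w)),
    slot = rep(seq_len(ncol(w)), nrow_g),
    time = start + rep((grid$day - 1) * 1440, each = ncol(w)) * 60 +
      round(c(t(draws))) * 60,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# Per-item latent effect calibration given the cohort's person-centered
# exposure SD. Returns a data.frame of truth values, one row per item.
ema_latent_effects <- function(config, sd_z) {
  items <- names(config$item_intercepts)
  rows <- lapply(items, function(it) {
    cal <- calibrate_cached(config$within_effect_b[[it]],
                            config$item_intercepts[[it]],
                            config$random_intercept_sd, config$residual_sd,
                            sd_z, config$response_scale_max,
                            config$prompts_per_day)
    data.frame(item = it, b_target = cal$b_target,
               beta_latent = cal$beta_latent,
               beta_observed = cal$beta_observed,
               sd_z = sd_z, sd_y = cal$sd_y, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Generate EMA responses from per-day exposure truth
#'
#' Implements the data-generating model the association stage assumes: for
#' each item, latent affect at a prompt is
#' `intercept_i + beta_latent * centered_log_ndvi + between + residual`,
#' rounded and clipped to the ordinal 0..5 scale. `beta_latent` is calibrated
#' so that the injected standardized within-person effect `within_effect_b`
#' holds on the observed daily-mean scale (see the methods vignette). Days in
#' the prompt schedule without exposure truth sit at the person mean
#' (centered deviation 0).
#'
#' @inheritParams generate_ndvi_raster
#' @param truth_daily data.frame with `participant_id`, `date`, `mean_ndvi`
#'   (daily true exposure; the log and centering are taken here).
#' @param prompts schedule from [schedule_ema_prompts()].
#' @param sd_z optional population SD of the centered log exposure; when
#'   `NULL`, the realized SD of `truth_daily` is used for calibration.
#' @return list with `records` (data.frame `participant_id`, `timestamp`,
#'   `item`, `response`) and `effects` (per-item truth: target standardized
#'   effect, calibrated latent and observed-scale raw slopes, SDs).
#' @export
generate_ema_responses <- function(config, truth_daily, prompts,
                                   sd_z = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  td <- truth_daily
  td$log_ndvi <- log(pmax(td$mean_ndvi, 1e-4))
  pm <- tapply(td$log_ndvi, td$participant_id, mean)
  td$z <- td$log_ndvi - as.vector(pm[td$participant_id])
  sd_real <- if (nrow(td) > 1) stats::sd(td$z) else 0
  if (is.null(sd_z)) sd_z <- sd_real
  effects <- ema_latent_effects(config, sd_z)

  key <- paste(prompts$participant_id, prompts$date)
  z <- td$z[match(key, paste(td$participant_id, td$date))]
  z[is.na(z)] <- 0
  ids <- participant_ids(config)
  pm_all <- pm[ids]; pm_all[is.na(pm_all)] <- mean(pm)
  pm_std <- if (length(ids) > 1 && stats::sd(pm_all) > 0)
    (pm_all - mean(pm_all)) / stats::sd(pm_all) else rep(0, length(ids))
  names(pm_std) <- ids

  items <- effects$item
  n_p <- nrow(prompts)
  a_i <- matrix(rnorm(length(ids) * length(items), 0,
                      config$random_intercept_sd),
                length(ids), length(items),
                dimnames = list(ids, items))
  recs <- vector("list", length(items))
  for (j in seq_along(items)) {
    it <- items[j]
    m <- config$item_intercepts[[it]] +
      a_i[prompts$participant_id, it] +
      effects$beta_latent[j] * z +
      config$between_effect_b * effects$sd_y[j] * pm_std[prompts$participant_id]
    recs[[j]] <- data.frame(participant_id = prompts$participant_id,
                            timestamp = prompts$time, item = it,
                            response = sample_responses(m, config$residual_sd,
                                                        config$response_scale_max),
                            stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, recs)
  records <- records[order(records$participant_id, records$timestamp,
                           records$item), ]
  rownames(records) <- NULL
  if (config$ema_missing_rate > 0) {
    pk <- unique(paste(records$participant_id, records$timestamp))
    drop <- pk[runif(length(pk)) < config$ema_missing_rate]
    records <- records[!(paste(records$participant_id, records$timestamp)
                         %in% drop), ]
    rownames(records) <- NULL
  }
  list(records = records, effects = effects)
}

# Vocabulary the transcript generator emits. Category words must match the
# shipped lexicon; fillers must match nothing (both asserted by tests).
sim_vocab <- function() {
  list(positive = c("happy", "glad", "good", "great", "fun", "love", "nice",
                    "hope", "joy", "relaxed"),
       anxiety = c("worried", "anxious", "nervous", "afraid", "scared",
                   "stressed", "tense"),
       anger = c("annoyed", "angry", "mad", "furious", "irritated",
                 "frustrated", "hate"),
       sadness = c("crying", "sad", "lonely", "miserable", "gloomy",
                   "tearful", "hopeless"),
       filler = c("the", "and", "we", "you", "i", "to", "a", "of", "it",
                  "that", "was", "for", "on", "are", "with", "they", "at",
                  "be", "this", "have", "from", "or", "had", "by", "but",
                  "some", "what", "there", "when", "your", "how", "said",
                  "each", "she", "do", "their", "if", "will", "about",
                  "out", "many", "then", "them", "these", "so"))
}

#' Generate time-stamped speech transcripts
#'
#' Emulates the ambient-audio design: 5-minute recording windows every 30
#' minutes through the waking day; a window contains a conversation with
#' probability 0.35, in which utterances alternate between the participant and
#' an interlocutor with mostly short (1-12 s) silence gaps and occasional
#' 20 s+ lapses that the downstream segmenter must split on. Each token is an
#' affect-category word with probability `affect_word_rate_base/100`,
#' shifted by `affect_word_effect` percentage points per SD of within-person
#' exposure deviation (truncated at zero), else a neutral filler.
#'
#' @inheritParams generate_ema_responses
#' @return list with `utterances` (data.frame `participant_id`, `speaker`,
#'   `start`, `end`, `text`) and `expected` (per participant-day expected
#'   category percentages implied by the configured rates).
#' @export
generate_transcripts <- function(config, truth_daily, sd_z = NULL,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (any(config$affect_word_rate_base < 0))
    stop("configuration error: negative affect_word_rate_base")
  vocab <- sim_vocab()
  cats <- c("positive", "anxiety", "anger", "sadness")
  base <- config$affect_word_rate_base[cats]
  eff <- config$affect_word_effect[cats]
  eff[is.na(eff)] <- 0

  td <- truth_daily
  td$log_ndvi <- log(pmax(td$mean_ndvi, 1e-4))
  pm <- tapply(td$log_ndvi, td$participant_id, mean)
  td$z <- td$log_ndvi - as.vector(pm[td$participant_id])
  sd_real <- if (nrow(td) > 1) stats::sd(td$z) else 0
  if (is.null(sd_z)) sd_z <- sd_real

  start0 <- as.POSIXct(paste(config$start_date, "00:00:00"), tz = config$tz)
  win_starts <- seq(9 * 60, 20.5 * 60, by = 30)     # minutes past midnight
  ids <- participant_ids(config)
  utt <- list(); expected <- list(); u_n <- 0
  for (pid in ids) {
    for (d in seq_len(config$n_days)) {
      date_d <- as.Date(config$start_date) + d - 1
      zi <- td$z[td$participant_id == pid & td$date == date_d]
      z_sd <- if (length(zi) == 1 && sd_z > 0) zi / sd_z else 0
      rate <- pmax(0, base + eff * z_sd)            # percent per category
      p_cat <- rate / 100
      expected[[length(expected) + 1]] <-
        data.frame(participant_id = pid, date = date_d, category = cats,
                   expected_pct = unname(rate), stringsAsFactors = FALSE)
      for (ws in win_starts) {
        if (runif(1) > 0.35) next
        n_utt <- sample(2:6, 1)
        t_cur <- start0 + ((d - 1) * 1440 + ws) * 60 + runif(1, 0, 60)
        for (k in seq_len(n_utt)) {
          n_words <- sample(4:15, 1)
          draw <- runif(n_words)
          cum <- cumsum(p_cat)
          cat_idx <- findInterval(draw, c(0, cum))   # 1..4 category, 5 filler
          words <- character(n_words)
          for (ci in seq_along(cats)) {
            sel <- cat_idx == ci
            if (any(sel)) words[sel] <- sample(vocab[[cats[ci]]], sum(sel),
                                               replace = TRUE)
          }
          sel <- cat_idx > length(cats)
          if (any(sel)) words[sel] <- sample(vocab$filler, sum(sel),
                                             replace = TRUE)
          dur <- 0.4 * n_words
          u_n <- u_n + 1
          utt[[u_n]] <- data.frame(
            participant_id = pid,
            speaker = if (k %% 2 == 1) "participant" else "other",
            start = t_cur, end = t_cur + dur,
            text = paste(words, collapse = " "), stringsAsFactors = FALSE)
          gap <- if (runif(1) < 0.1) runif(1, 21, 35) else runif(1, 1, 12)
          t_cur <- t_cur + dur + gap
        }
      }
    }
  }
  utterances <- if (u_n) do.call(rbind, utt) else
    data.frame(participant_id = character(), speaker = character(),
               start = as.POSIXct(character(), tz = config$tz),
               end = as.POSIXct(character(), tz = config$tz),
               text = character(), stringsAsFactors = FALSE)
  rownames(utterances) <- NULL
  list(utterances = utterances, expected = do.call(rbind, expected))
}

#' Generate a complete synthetic cohort
#'
#' Runs every generator stage under a single seeded random stream: raster and
#' band pair, per-participant homes and GPS traces, a per-day exposure truth
#' table (computed with the package's own preprocessing chain applied at the
#' *true* home), the EMA prompt schedule and responses, and speech
#' transcripts. Identical configurations produce identical cohorts.
#'
#' @inheritParams generate_ndvi_raster
#' @return an object of class `syn_cohort`: list with `config`, `raster`,
#'   `bands`, `groups`, `traces`, `ema`, `transcripts`, and `truth` (homes,
#'   daily exposure, time at home, injected effect values, expected word
#'   percentages).
#' @export
generate_cohort <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  rb <- generate_ndvi_raster(config, seed = NULL)
  homes <- assign_homes(config, rb$raster)
  traces <- do.call(rbind, lapply(seq_len(nrow(homes)), function(i) {
    generate_gps_trace(config, homes$participant_id[i], rb$raster,
                       c(homes$home_lon[i], homes$home_lat[i]))
  }))
  rownames(traces) <- NULL
  truth_daily <- true_daily_exposure(traces, homes, rb$raster, config)
  tah <- true_time_at_home(traces, homes, config)
  prompts <- schedule_ema_prompts(config, seed = NULL)
  ema <- generate_ema_responses(config, truth_daily, prompts, seed = NULL)
  tr <- generate_transcripts(config, truth_daily, seed = NULL)
  structure(list(config = config, raster = rb$raster, bands = rb$bands,
                 groups = cohort_groups(config), traces = traces,
                 ema = ema$records, transcripts = tr$utterances,
                 truth = list(homes = homes, daily = truth_daily,
                              time_at_home = tah, effects = ema$effects,
                              word_expected = tr$expected,
                              prompts = prompts)),
            class = "syn_cohort")
}

#' @export
print.syn_cohort <- function(x, ...) {
  cat(sprintf(paste0("<syn_cohort> %d participants (%d SSD / %d control), ",
                     "%d days, %d GPS fixes, %d EMA records\n"),
              x$config$n_ssd + x$config$n_control, x$config$n_ssd,
              x$config$n_control, x$config$n_days, nrow(x$traces),
              nrow(x$ema)))
  invisible(x)
}

# Truth = the preprocessing chain evaluated at the *true* home: provider
# filter, home removal, raster linkage, negative exclusion, daily mean.
true_daily_exposure <- function(traces, homes, raster, config) {
  out <- lapply(seq_len(nrow(homes)), function(i) {
    tr <- traces[traces$participant_id == homes$participant_id[i], ]
    tr <- filter_by_provider(tr)
    home <- list(latitude = homes$home_lat[i], longitude = homes$home_lon[i],
                 support = 1L, bin_precision = NA_integer_)
    class(home) <- "home_location"
    tr <- remove_home_points(tr, home, radius = config$home_radius_m)
    if (!nrow(tr)) return(NULL)
    linked <- link_trace(tr, raster)
    series <- exclude_negative(linked$series)
    if (!nrow(series)) return(NULL)
    daily_mean(series, tz = config$tz)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

true_time_at_home <- function(traces, homes, config) {
  out <- lapply(seq_len(nrow(homes)), function(i) {
    tr <- traces[traces$participant_id == homes$participant_id[i], ]
    home <- list(latitude = homes$home_lat[i], longitude = homes$home_lon[i],
                 support = 1L, bin_precision = NA_integer_)
    class(home) <- "home_location"
    compute_time_at_home(tr, home, radius = config$home_radius_m,
                         epoch = config$gps_epoch, tz = config$tz)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
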