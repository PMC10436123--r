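# Shared fixture builders. Everything is generated in code; tests that need
# randomness set their own seed first.

STUDY_TZ <- "America/Los_Angeles"

# a trace data.frame from vectors, with sensible defaults
make_trace <- function(times, lat, lon, provider = "gps",
                       participant_id = "p1", accuracy = 10) {
  n <- length(times)
  data.frame(participant_id = participant_id, timestamp = times,
             lat = rep_len(lat, n), lon = rep_len(lon, n),
             accuracy_m = rep_len(accuracy, n),
             provider = rep_len(provider, n), stringsAsFactors = FALSE)
}

# POSIXct helper in the study zone
t_at <- function(x, day = "2023-05-01") {
  as.POSIXct(paste(day, x), tz = STUDY_TZ)
}

# uniform-value test raster: nr x nc cells of `value` at origin (0, 0), 1-deg
flat_raster <- function(value = 0.5, nr = 4, nc = 4, cellsize = 1) {
  ndvi_raster(matrix(value, nr, nc), xll = 0, yll = 0, cellsize = cellsize)
}

# small, fast cohort configuration used by pipeline tests
quick_cfg <- function(...) {
  args <- list(n_ssd = 4, n_control = 3, n_days = 3,
               raster_shape = c(60L, 60L))
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

# utterance table builder: gaps[i] seconds between utterance i and i+1
make_utterances <- function(gaps, texts = NULL, speakers = "participant",
                            participant_id = "p1", dur = 5,
                            start = t_at("12:00:00")) {
  n <- length(gaps) + 1
  starts <- start + c(0, cumsum(gaps + dur))
  data.frame(participant_id = participant_id,
             speaker = rep_len(speakers, n),
             start = starts, end = starts + dur,
             text = if (is.null(texts)) paste("word", seq_len(n)) else
               rep_len(texts, n),
             stringsAsFactors = FALSE)
}

# independent enumeration oracle for the exact two-tailed rank-sum p-value:
# enumerate all C(n, nx) placements of x's ranks (no ties assumed)
wilcoxon_enum_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y); n <- nx + ny
  w_obs <- sum(rank(c(x, y))[seq_len(nx)])
  combos <- utils::combn(n, nx)
  w_all <- colSums(matrix(seq_len(n)[combos], nrow = nx))
  p_le <- mean(w_all <= w_obs); p_ge <- mean(w_all >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# brute-force interaction segmentation: linear scan over one participant's
# sorted utterances, splitting on gap >= 20 s, dropping participant-free runs
segment_oracle <- function(u, gap_s = 20) {
  n <- nrow(u)
  seg <- integer(n); cur <- 1L; seg[1] <- 1L
  for (i in seq_len(n - 1)) {
    gap <- as.numeric(difftime(u$start[i + 1], u$end[i], units = "secs"))
    if (gap >= gap_s) cur <- cur + 1L
    seg[i + 1] <- cur
  }
  keep <- seg %in% unique(seg[u$speaker == "participant"])
  split(which(keep), seg[keep])
}
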