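#' Link a GPS trace to raster NDVI values
#'
#' Samples the raster at every fix (nearest-cell lookup) and keeps one
#' `(timestamp, ndvi)` pair per in-extent, non-nodata fix. Out-of-extent and
#' nodata fixes are dropped and counted. The trace is expected to be
#' preprocessed (provider-filtered, home removed) but nothing is checked
#' beyond the trace contract.
#'
#' @param trace a GPS trace data.frame (see [geo_preprocess]).
#' @param raster an [ndvi_raster()].
#' @return list with `series` (data.frame `participant_id`, `timestamp`,
#'   `ndvi`) and `dropped` (named counts `outside`, `nodata`).
#' @export
link_trace <- function(trace, raster) {
  s <- sample_raster(raster, trace$lon, trace$lat)
  keep <- s$status == "ok"
  series <- data.frame(participant_id = trace$participant_id[keep],
                       timestamp = trace$timestamp[keep],
                       ndvi = s$value[keep], stringsAsFactors = FALSE)
  rownames(series) <- NULL
  list(series = series,
       dropped = c(outside = sum(s$status == "outside"),
                   nodata = sum(s$status == "nodata")))
}

#' Exclude negative NDVI values
#'
#' Negative NDVI indicates water; with little evidence linking water exposure
#' to the outcomes of interest, those point values are excluded before any
#' daily aggregation. Zero is retained. Applied per GPS point, so a day loses
#' only its water fixes, not the whole day.
#'
#' @param series point exposure series from [link_trace()].
#' @return the series restricted to `ndvi >= 0`; the number of removed points
#'   is in attribute `"n_excluded"`.
#' @export
exclude_negative <- function(series) {
  keep <- series$ndvi >= 0
  out <- series[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Daily mean NDVI per participant
#'
#' Unweighted arithmetic mean of the retained point NDVI values per local
#' calendar day (half-open midnight-to-midnight, shared across all modules).
#' Days with zero retained points are absent from the output.
#'
#' @inheritParams exclude_negative
#' @param tz study time zone.
#' @return data.frame `participant_id`, `date`, `mean_ndvi`, `n_points`.
#' @export
daily_mean <- function(series, tz = "America/Los_Angeles") {
  if (!nrow(series))
    return(data.frame(participant_id = character(), date = as.Date(character()),
                      mean_ndvi = numeric(), n_points = integer()))
  date <- local_date(series$timestamp, tz)
  key <- split(seq_len(nrow(series)),
               list(pid = series$participant_id, d = as.character(date)),
               drop = TRUE)
  rows <- lapply(key, function(i)
    data.frame(participant_id = series$participant_id[i[1]],
               date = date[i[1]],
               mean_ndvi = mean(series$ndvi[i]),
               n_points = length(i), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(out$participant_id, out$date), ]
  rownames(out) <- NULL
  out
}

#' Log-transform daily mean NDVI
#'
#' Daily mean NDVI is strongly right-skewed, so analyses use its natural log.
#' Zero-mean days (all retained fixes on NDVI-zero cells) would map to
#' negative infinity; they are floored at `floor` before the log and flagged
#' rather than dropped, so exposure level is not conflated with missingness.
#'
#' @param daily output of [daily_mean()].
#' @param floor small positive floor applied inside the log.
#' @return `daily` with columns `log_ndvi` and logical `floored`.
#' @export
log_transform <- function(daily, floor = 1e-4) {
  if (!is.numeric(floor) || length(floor) != 1 || floor <= 0)
    stop("`floor` must be a single positive number")
  if (any(daily$mean_ndvi < 0, na.rm = TRUE))
    stop("negative daily means: exclude negative NDVI before aggregation")
  daily$log_ndvi <- log(pmax(daily$mean_ndvi, floor))
  daily$floored <- daily$mean_ndvi < floor
  daily
}

#' Person-mean-center daily log exposure
#'
#' Splits each participant's daily log NDVI into a person mean (the
#' between-person component) and the within-person deviation from it, the
#' predictor of the two-level models. Per participant, the centered values sum
#' to zero by construction.
#'
#' @param daily output of [log_transform()].
#' @return `daily` with `person_mean_log_ndvi` and `centered_log_ndvi`.
#' @export
person_center <- function(daily) {
  pm <- tapply(daily$log_ndvi, daily$participant_id, mean)
  daily$person_mean_log_ndvi <- as.vector(pm[daily$participant_id])
  daily$centered_log_ndvi <- daily$log_ndvi - daily$person_mean_log_ndvi
  daily
}

#' Full daily exposure pipeline for one trace
#'
#' Provider filter, home detection (or a supplied home), home removal, raster
#' linkage, negative exclusion, daily mean, log transform. Person-centering is
#' left to the caller since it pools participants: run [person_center()] on
#' the row-bound daily tables of the whole cohort.
#'
#' @inheritParams link_trace
#' @param home optional `home_location`; detected from the trace when `NULL`.
#' @param home_radius removal radius, meters.
#' @param night_window,bin_precision,tz home-detection parameters, see
#'   [detect_home()].
#' @param floor see [log_transform()].
#' @return list `daily` (per-day exposure rows), `home`, `report` (drop
#'   counts per stage).
#' @export
daily_exposure <- function(trace, raster, home = NULL, home_radius = 100,
                           night_window = c("21:00", "06:00"),
                           bin_precision = 3, tz = "America/Los_Angeles",
                           floor = 1e-4) {
  check_trace(trace)
  filtered <- filter_by_provider(trace)
  if (is.null(home))
    home <- detect_home(filtered, night_window, bin_precision, tz)
  away <- remove_home_points(filtered, home, home_radius)
  linked <- link_trace(away, raster)
  series <- exclude_negative(linked$series)
  daily <- log_transform(daily_mean(series, tz), floor)
  list(daily = daily, home = home,
       report = list(n_input = nrow(trace),
                     n_after_provider_filter = nrow(filtered),
                     n_after_home_removal = nrow(away),
                     dropped_linkage = linked$dropped,
                     n_negative_excluded = attr(series, "n_excluded"),
                     n_days = nrow(daily)))
}

#' Cohort-level daily exposure table
#'
#' Applies [daily_exposure()] per participant and pools the result with
#' person-centering, giving the exposure table the association stage consumes.
#'
#' @param traces row-bound traces for several participants.
#' @param homes optional data.frame `participant_id`, `home_lon`, `home_lat`
#'   of known homes (e.g. a truth table); detected when `NULL`.
#' @inheritParams daily_exposure
#' @return list `daily` (centered cohort table), `homes` (detected or given),
#'   `reports` (per participant).
#' @export
cohort_daily_exposure <- function(traces, raster, homes = NULL,
                                  home_radius = 100,
                                  night_window = c("21:00", "06:00"),
                                  bin_precision = 3,
                                  tz = "America/Los_Angeles", floor = 1e-4) {
  ids <- unique(traces$participant_id)
  res <- lapply(ids, function(pid) {
    home <- NULL
    if (!is.null(homes)) {
      i <- match(pid, homes$participant_id)
      home <- structure(list(latitude = homes$home_lat[i],
                             longitude = homes$home_lon[i],
                             support = NA_integer_,
                             bin_precision = NA_integer_),
                        class = "home_location")
    }
    daily_exposure(traces[traces$participant_id == pid, , drop = FALSE],
                   raster, home, home_radius, night_window, bin_precision,
                   tz, floor)
  })
  daily <- person_center(do.call(rbind, lapply(res, `[[`, "daily")))
  rownames(daily) <- NULL
  homes_out <- data.frame(
    participant_id = ids,
    home_lon = vapply(res, function(r) r$home$longitude, numeric(1)),
    home_lat = vapply(res, function(r) r$home$latitude, numeric(1)),
    stringsAsFactors = FALSE)
  list(daily = daily, homes = homes_out,
       reports = lapply(res, `[[`, "report"))
}
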