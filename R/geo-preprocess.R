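#' GPS trace preprocessing
#'
#' A trace is a data.frame with one participant's time-ordered fixes:
#' `participant_id`, `timestamp` (POSIXct), `lat`, `lon` (WGS84 degrees),
#' optional `accuracy_m`, and `provider` (one of `gps`, `fused`,
#' `network-passive`, `gps-passive`). The functions below implement the
#' preprocessing chain applied before exposure linkage: drop passive-provider
#' fixes, detect the home as the modal nighttime coordinate bin, strip fixes
#' near home, flag days with fixes outside the study region, and compute the
#' time-at-home covariate.
#'
#' @name geo_preprocess
NULL

check_trace <- function(trace) {
  need <- c("participant_id", "timestamp", "lat", "lon", "provider")
  miss <- setdiff(need, names(trace))
  if (length(miss)) stop("trace is missing columns: ", paste(miss, collapse = ", "))
  if (length(unique(trace$participant_id)) > 1)
    stop("trace must contain a single participant")
  if (is.unsorted(trace$timestamp)) stop("trace timestamps must be non-decreasing")
  invisible(trace)
}

#' Drop passive-provider fixes
#'
#' Keeps exactly the fixes whose provider is not in `exclude` (by default the
#' `network-passive` and `gps-passive` providers, which report cached or
#' cell-tower positions of much lower quality), preserving order. An empty
#' result is legal.
#'
#' @param trace a GPS trace data.frame (see [geo_preprocess]).
#' @param exclude providers to remove.
#' @return the filtered trace.
#' @export
filter_by_provider <- function(trace,
                               exclude = c("network-passive", "gps-passive")) {
  out <- trace[!(trace$provider %in% exclude), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect the home location from nighttime fixes
#'
#' The home is the modal (lat, lon) coordinate bin among all fixes inside the
#' nighttime clock window, pooled over the whole study. Jittery GPS floats
#' almost never repeat exactly, so both coordinates are rounded to
#' `bin_precision` decimal degrees (3 decimals is roughly a 110 m bin) before
#' counting; the reported coordinates are the centroid of the fixes in the
#' winning bin. Ties are broken in favor of the bin whose first fix occurs
#' earliest.
#'
#' @inheritParams filter_by_provider
#' @param night_window clock window, may cross midnight (default 9 PM-6 AM).
#' @param bin_precision decimal places used for binning.
#' @param tz study time zone.
#' @return object of class `home_location`: `latitude`, `longitude`,
#'   `support` (fix count in the winning bin), `bin_precision`.
#' @export
detect_home <- function(trace, night_window = c("21:00", "06:00"),
                        bin_precision = 3, tz = "America/Los_Angeles") {
  check_trace(trace)
  if (!nrow(trace)) stop("empty trace: no fixes at all")
  night <- trace[in_clock_window(trace$timestamp, night_window, tz), ,
                 drop = FALSE]
  if (!nrow(night))
    stop("home undetectable: no fixes inside the night window")
  bin <- paste(round(night$lat, bin_precision),
               round(night$lon, bin_precision))
  counts <- table(bin)
  winners <- names(counts)[counts == max(counts)]
  if (length(winners) > 1) {
    first_row <- vapply(winners, function(b) which(bin == b)[1], integer(1))
    winners <- winners[which.min(first_row)]
  }
  sel <- bin == winners
  structure(list(latitude = mean(night$lat[sel]),
                 longitude = mean(night$lon[sel]),
                 support = sum(sel),
                 bin_precision = bin_precision),
            class = "home_location")
}

#' @export
print.home_location <- function(x, ...) {
  cat(sprintf("<home_location> (%.6f, %.6f), support %d fixes, %d-decimal bins\n",
              x$latitude, x$longitude, x$support, x$bin_precision))
  invisible(x)
}

#' Remove fixes at or near the home
#'
#' Drops every fix within `radius` great-circle meters (haversine on the WGS84
#' sphere) of the home, preserving order. `radius = 0` removes only
#' exact-coordinate matches.
#'
#' @inheritParams filter_by_provider
#' @param home a [detect_home()] result (or any list with `latitude`,
#'   `longitude`).
#' @param radius removal radius in meters.
#' @return the trace without at-home fixes (possibly empty).
#' @export
remove_home_points <- function(trace, home, radius = 100) {
  if (!is.numeric(radius) || length(radius) != 1 || radius < 0)
    stop("`radius` must be a single nonnegative number of meters")
  if (!nrow(trace)) return(trace)
  d <- geosphere::distHaversine(cbind(trace$lon, trace$lat),
                                c(home$longitude, home$latitude))
  out <- trace[d > radius, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Flag days with fixes outside the study region
#'
#' A participant-day is flagged when at least one of its fixes falls outside
#' the region bounding box; the participant-level flag is raised when every
#' day with fixes is flagged (e.g. cross-country travel for the whole study).
#' Flagged days feed the travel-day sensitivity rerun of the association
#' stage.
#'
#' @inheritParams filter_by_provider
#' @param region named numeric `c(xmin, xmax, ymin, ymax)` in degrees, e.g.
#'   from [raster_extent()].
#' @param tz study time zone.
#' @return list with `days` (data.frame `participant_id`, `date`) and
#'   `participant_excluded` (logical).
#' @export
flag_travel_days <- function(trace, region, tz = "America/Los_Angeles") {
  check_trace(trace)
  if (region["xmin"] >= region["xmax"] || region["ymin"] >= region["ymax"])
    stop("degenerate study region")
  if (!nrow(trace))
    return(list(days = data.frame(participant_id = character(),
                                  date = as.Date(character())),
                participant_excluded = FALSE))
  outside <- trace$lon < region["xmin"] | trace$lon >= region["xmax"] |
    trace$lat < region["ymin"] | trace$lat >= region["ymax"]
  date <- local_date(trace$timestamp, tz)
  flagged <- sort(unique(date[outside]))
  list(days = data.frame(participant_id = rep(trace$participant_id[1],
                                              length(flagged)),
                         date = flagged, stringsAsFactors = FALSE),
       participant_excluded = length(flagged) > 0 &&
         length(flagged) == length(unique(date)))
}

#' Hours per day spent at home
#'
#' Counts fixes within `radius` meters of the home and converts the count to
#' hours at one fix per `epoch` minutes: `hours = n_home_fixes * epoch / 60`.
#' Days without any fixes are absent from the output (missing, not zero).
#'
#' @inheritParams remove_home_points
#' @param epoch minutes between fixes.
#' @param tz study time zone.
#' @return data.frame `participant_id`, `date`, `hours_at_home`.
#' @export
compute_time_at_home <- function(trace, home, radius = 100, epoch = 6,
                                 tz = "America/Los_Angeles") {
  if (!is.numeric(epoch) || length(epoch) != 1 || epoch <= 0)
    stop("`epoch` must be a positive number of minutes")
  check_trace(trace)
  if (!nrow(trace))
    return(data.frame(participant_id = character(), date = as.Date(character()),
                      hours_at_home = numeric()))
  d <- geosphere::distHaversine(cbind(trace$lon, trace$lat),
                                c(home$longitude, home$latitude))
  date <- local_date(trace$timestamp, tz)
  n_home <- tapply(d <= radius, date, sum)
  data.frame(participant_id = trace$participant_id[1],
             date = as.Date(names(n_home)),
             hours_at_home = unname(n_home) * epoch / 60,
             stringsAsFactors = FALSE)
}

#' Run the full preprocessing chain on one trace
#'
#' Provider filter, home detection, home removal, travel-day flagging and
#' time-at-home, with a per-stage accounting report.
#'
#' @inheritParams detect_home
#' @inheritParams flag_travel_days
#' @param home_radius removal radius, meters.
#' @param epoch fix spacing, minutes.
#' @return list `trace` (cleaned), `home`, `time_at_home`, `travel`,
#'   `report` (point counts per stage, JSON-serializable).
#' @export
preprocess_trace <- function(trace, region,
                             night_window = c("21:00", "06:00"),
                             bin_precision = 3, home_radius = 100,
                             epoch = 6, tz = "America/Los_Angeles") {
  check_trace(trace)
  n0 <- nrow(trace)
  filtered <- filter_by_provider(trace)
  home <- detect_home(filtered, night_window, bin_precision, tz)
  # time at home uses the unfiltered trace: hours are fixes x epoch, and every
  # epoch has exactly one fix only before provider filtering
  tah <- compute_time_at_home(trace, home, home_radius, epoch, tz)
  travel <- flag_travel_days(filtered, region, tz)
  cleaned <- remove_home_points(filtered, home, home_radius)
  list(trace = cleaned, home = home, time_at_home = tah, travel = travel,
       report = list(participant_id = trace$participant_id[1],
                     n_input = n0,
                     n_after_provider_filter = nrow(filtered),
                     n_after_home_removal = nrow(cleaned),
                     home = c(lat = home$latitude, lon = home$longitude),
                     home_support = home$support,
                     n_travel_days = nrow(travel$days),
                     participant_excluded = travel$participant_excluded))
}
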