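#' @keywords internal
#' @import stats
#' @importFrom utils read.csv write.csv
"_PACKAGE"

#' Local calendar day of a timestamp
#'
#' All modules share one day convention: days are local-time, half-open
#' midnight-to-midnight intervals \code{[00:00, 24:00)} in the cohort's single
#' time zone. Aggregating exposure, EMA and speech by the same rule keeps
#' participant-days aligned across data streams.
#'
#' @param time POSIXct vector (any time zone).
#' @param tz Olson time-zone name of the study site.
#' @return `Date` vector of local calendar days.
#' @export
local_date <- function(time, tz) {
  stopifnot(inherits(time, "POSIXct"))
  as.Date(format(time, "%Y-%m-%d", tz = tz))
}

#' Minutes past local midnight
#' @inheritParams local_date
#' @return numeric vector in [0, 1440).
#' @export
local_clock_minutes <- function(time, tz) {
  stopifnot(inherits(time, "POSIXct"))
  as.numeric(format(time, "%H", tz = tz)) * 60 +
    as.numeric(format(time, "%M", tz = tz)) +
    as.numeric(format(time, "%S", tz = tz)) / 60
}

# "21:00" -> 1260 minutes
parse_clock <- function(x) {
  parts <- strsplit(x, ":", fixed = TRUE)
  vapply(parts, function(p) as.numeric(p[1]) * 60 + as.numeric(p[2]), numeric(1))
}

#' Membership in a clock-time window that may cross midnight
#'
#' A window like 21:00--06:00 is interpreted by clock time regardless of date:
#' a fix belongs to it when its local clock time is at or after the start or
#' strictly before the end. Windows that do not cross midnight use the usual
#' half-open rule `[start, end)`.
#'
#' @param time POSIXct vector.
#' @param window character of length 2, e.g. `c("21:00", "06:00")`.
#' @param tz study time zone.
#' @return logical vector.
#' @export
in_clock_window <- function(time, window, tz) {
  m <- local_clock_minutes(time, tz)
  a <- parse_clock(window[1]); b <- parse_clock(window[2])
  if (a <= b) m >= a & m < b else m >= a | m < b
}

iso8601 <- function(time, tz) format(time, "%Y-%m-%dT%H:%M:%S%z", tz = tz)

parse_iso8601 <- function(x, tz) {
  out <- as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%S%z", tz = tz)
  bad <- is.na(out) & !is.na(x)
  if (any(bad)) { # fall back to space-separated / zone-less strings
    out[bad] <- as.POSIXct(x[bad], tz = tz,
                           tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S"))
  }
  out
}
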