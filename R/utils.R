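# Internal time helpers. The engine uses a single local clock per
# participant at minute resolution; all timestamps are POSIXct in UTC and
# clock times are minutes since midnight.

#' @noRd
parse_hhmm <- function(x) {
  out <- vapply(as.character(x), function(s) {
    m <- regmatches(s, regexec("^\\s*([0-9]{1,2})[:.]([0-9]{2})\\s*$", s))[[1]]
    if (length(m) == 0) return(NA_integer_)
    h <- as.integer(m[2]); mn <- as.integer(m[3])
    if (h > 23 || mn > 59) return(NA_integer_)
    h * 60L + mn
  }, integer(1))
  unname(out)
}

#' @noRd
fmt_hhmm <- function(minutes) {
  sprintf("%02d:%02d", minutes %/% 60L, minutes %% 60L)
}

#' @noRd
as_utc <- function(x) {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- "UTC"
    return(x)
  }
  as.POSIXct(x, tz = "UTC")
}

# clock time (minutes past midnight) of a timestamp
#' @noRd
clock_minutes <- function(ts) {
  lt <- as.POSIXlt(ts, tz = "UTC")
  lt$hour * 60L + lt$min
}

#' @noRd
local_day <- function(ts) as.Date(ts, tz = "UTC")

# timestamp at `minutes` past midnight on `day`
#' @noRd
at_clock <- function(day, minutes) {
  as.POSIXct(as.Date(day), tz = "UTC") + as.numeric(minutes) * 60
}

# round half-up to integer (SMS glucose replies are integers)
#' @noRd
round_half_up <- function(x) floor(x + 0.5)

# day-of-week helpers, locale-independent: 1 = Monday ... 7 = Sunday
.day_names <- c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun")

#' @noRd
day_number <- function(x) {
  if (is.numeric(x)) {
    d <- as.integer(x)
  } else {
    d <- match(substr(as.character(x), 1, 3), .day_names)
  }
  if (any(is.na(d) | d < 1 | d > 7)) {
    stop("day of week must be 1-7 or one of ", paste(.day_names, collapse = ", "))
  }
  d
}

#' @noRd
weekday_of <- function(day) as.integer(format(as.Date(day), "%u"))

#' @noRd
fmt_ts <- function(ts) format(as_utc(ts), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

#' @noRd
parse_ts <- function(x) {
  if (inherits(x, "POSIXct")) return(as_utc(x))
  x <- sub("Z$", "", sub("T", " ", as.character(x)))
  out <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M",
                                   "%Y-%m-%d"))
  out
}
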