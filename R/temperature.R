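# Hourly ambient temperature series: reading station exports, synthesizing
# hourly values from daily extremes with a two-term Fourier diurnal shape, and
# gap-filling from climatology.

#' Construct an hourly temperature series
#'
#' A contiguous hourly grid of ambient temperatures anchored to a calendar
#' start. Missing hours are `NA` and tracked by a mask; the simulator requires
#' a fully observed (gap-filled) series.
#'
#' @param values Numeric vector of hourly temperatures in degrees C; `NA`
#'   marks a missing hour.
#' @param start POSIXct timestamp (hour resolution) of the first value.
#' @return An object of class `temperature_series` with fields `start`,
#'   `temp`, and `missing`.
#' @export
temperature_series <- function(values,
                               start = as.POSIXct("2009-01-01 00:00:00", tz = "UTC")) {
  values <- as.numeric(values)
  if (!length(values)) stop("temperature series must contain at least one hour")
  out <- list(start = start, temp = values, missing = is.na(values))
  class(out) <- "temperature_series"
  out
}

#' @export
length.temperature_series <- function(x) length(x$temp)

#' @export
print.temperature_series <- function(x, ...) {
  cat(sprintf("Hourly temperature series: %d hours (%.1f days) from %s\n",
              length(x$temp), length(x$temp) / 24, format(x$start)))
  cat(sprintf("  range %.1f to %.1f C; %d missing hour(s)\n",
              suppressWarnings(min(x$temp, na.rm = TRUE)),
              suppressWarnings(max(x$temp, na.rm = TRUE)), sum(x$missing)))
  invisible(x)
}

#' Daily temperature extremes
#'
#' @param date Vector of class `Date`, one entry per consecutive day.
#' @param tmin,tmax Daily minimum and maximum temperatures in degrees C.
#' @return A `data.frame` of class `daily_extremes`.
#' @export
daily_extremes <- function(date, tmin, tmax) {
  date <- as.Date(date)
  if (any(tmin > tmax)) stop("daily minimum exceeds maximum on ",
                             paste(date[tmin > tmax], collapse = ", "))
  out <- data.frame(date = date, tmin = as.numeric(tmin), tmax = as.numeric(tmax))
  class(out) <- c("daily_extremes", "data.frame")
  out
}

#' Read an hourly temperature CSV export
#'
#' Expects one row per observed hour. The returned series spans a contiguous
#' hourly grid from the first to the last timestamp; hours with no row (or an
#' `NA` temperature) are flagged missing.
#'
#' @param path CSV file path.
#' @param timestamp_col,temp_col Column names for the ISO 8601 timestamp and
#'   the temperature in degrees C.
#' @param tz Time zone for parsing timestamps.
#' @return A [temperature_series()].
#' @export
read_hourly_csv <- function(path, timestamp_col = "timestamp",
                            temp_col = "temp_c", tz = "UTC") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c(timestamp_col, temp_col))
    if (!col %in% names(df)) stop("column '", col, "' not found in ", path)
  raw <- gsub("T", " ", as.character(df[[timestamp_col]]), fixed = TRUE)
  ts <- NULL
  for (fmt in c("%Y-%m-%d %H:%M:%S", "%Y-%m-%d %H:%M", "%Y-%m-%d %H")) {
    ts <- as.POSIXct(strptime(raw, fmt, tz = tz))
    if (!anyNA(ts)) break
  }
  if (anyNA(ts)) stop("unparseable timestamp(s): ",
                      paste(utils::head(raw[is.na(ts)], 3), collapse = ", "))
  ts <- as.POSIXct(trunc(ts, units = "hours"))
  if (anyDuplicated(as.numeric(ts))) stop("duplicated hour(s) in ", path)
  if (is.unsorted(as.numeric(ts))) stop("timestamps are not monotone increasing")
  grid <- seq(ts[1], ts[length(ts)], by = "1 hour")
  values <- rep(NA_real_, length(grid))
  values[match(as.numeric(ts), as.numeric(grid))] <- as.numeric(df[[temp_col]])
  temperature_series(values, start = grid[1])
}

#' Write an hourly temperature series to CSV
#'
#' @param series A [temperature_series()].
#' @param path Output file.
#' @param timestamp_col,temp_col Output column names.
#' @return `path`, invisibly.
#' @export
write_hourly_csv <- function(series, path, timestamp_col = "timestamp",
                             temp_col = "temp_c") {
  stamps <- series$start + 3600 * (seq_along(series$temp) - 1L)
  df <- data.frame(format(stamps, "%Y-%m-%dT%H:%M:%S"), series$temp)
  names(df) <- c(timestamp_col, temp_col)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Diurnal weighting function
#'
#' Two-term Fourier fit to the mean diurnal temperature cycle:
#' `Gamma(t) = 0.44 - 0.46 sin(w t + 0.9) + 0.11 sin(2 w t + 0.9)`, with `t`
#' the local clock hour (solar noon at t = 12). The weight is applied verbatim
#' (not clamped), so interpolated hours can overshoot the daily extremes by the
#' small margin by which `Gamma` exits `[0, 1]`.
#'
#' @param t Hour of day, 0-24 (periodic with period 24 when `omega = pi/12`).
#' @param omega Angular frequency in radians per hour; `pi/12` gives the
#'   24-hour period.
#' @return Dimensionless weight(s) applied to the daily maximum.
#' @export
#' @examples
#' gamma_diurnal(12)           # afternoon, near the daily maximum
#' gamma_diurnal(c(0, 24))     # equal: the cycle is periodic
gamma_diurnal <- function(t, omega = pi / 12) {
  0.44 - 0.46 * sin(omega * t + 0.9) + 0.11 * sin(2 * omega * t + 0.9)
}

# day-offset pairing for one day's 24 hourly slots (t = 0..23):
#   t in (0, 5]  : previous day's maximum with today's minimum
#   t in (5, 14] : today's maximum with today's minimum
#   t in (14, 24): today's maximum with next day's minimum
# t = 0 is the wrap of t = 24 of the previous day and therefore uses the
# previous day's maximum with today's minimum, the same pairing as branch one.
.estimate_day <- function(tx_prev, tx, tn, tn_next, omega) {
  t <- 0:23
  g <- gamma_diurnal(t, omega)
  tx_used <- ifelse(t <= 5, tx_prev, tx)
  tn_used <- ifelse(t > 14, tn_next, tn)
  g * tx_used + (1 - g) * tn_used
}

#' Estimate hourly temperatures from daily extremes
#'
#' Sinusoidal (two-term Fourier) interpolation of the diurnal cycle. Early
#' hours of a day are paired with the previous day's maximum and late hours
#' with the next day's minimum; at the series edges the same day's value is
#' substituted.
#'
#' @param extremes A [daily_extremes()] table covering consecutive days.
#' @param omega Angular frequency passed to [gamma_diurnal()].
#' @return A [temperature_series()] of length `24 * nrow(extremes)` starting at
#'   midnight of the first day.
#' @export
estimate_hourly <- function(extremes, omega = pi / 12) {
  n <- nrow(extremes)
  if (is.null(n) || n < 1) stop("at least one day of extremes is required")
  vals <- numeric(24 * n)
  for (i in seq_len(n)) {
    tx_prev <- extremes$tmax[max(1L, i - 1L)]
    tn_next <- extremes$tmin[min(n, i + 1L)]
    vals[(24 * (i - 1) + 1):(24 * i)] <-
      .estimate_day(tx_prev, extremes$tmax[i], extremes$tmin[i], tn_next, omega)
  }
  temperature_series(vals, start = as.POSIXct(paste(extremes$date[1], "00:00:00"),
                                              tz = "UTC"))
}

#' Fill missing hours from daily climatology
#'
#' Replaces each missing hour with the [estimate_hourly()] value for its
#' calendar day, computed from the supplied daily min/max climatology.
#' Observed hours are never modified.
#'
#' @param series A [temperature_series()] possibly containing missing hours.
#' @param climatology A [daily_extremes()] table covering every day that
#'   contains a missing hour.
#' @return A gap-free [temperature_series()].
#' @export
fill_gaps <- function(series, climatology) {
  if (!any(series$missing)) return(series)
  stamps <- series$start + 3600 * (seq_along(series$temp) - 1L)
  days <- as.Date(format(stamps, "%Y-%m-%d"))
  need <- unique(days[series$missing])
  if (length(bad <- setdiff(as.character(need), as.character(climatology$date))))
    stop("no climatology for day(s) with missing hours: ",
         paste(bad, collapse = ", "))
  est <- estimate_hourly(climatology)
  est_stamps <- est$start + 3600 * (seq_along(est$temp) - 1L)
  idx <- match(as.numeric(stamps[series$missing]), as.numeric(est_stamps))
  if (anyNA(idx)) stop("climatology does not align with the series' hourly grid")
  out <- series
  out$temp[series$missing] <- est$temp[idx]
  out$missing <- is.na(out$temp)
  out
}

#' Synthesize an hourly temperature fixture
#'
#' Deterministic (given a seed) synthetic series with a realistic diurnal
#' shape: daily extremes jitter around the supplied base values and are then
#' interpolated with [estimate_hourly()]. An optional cold snap depresses both
#' extremes for a run of days, emulating the winter cold snaps that drive
#' steep mortality in coastal Southern California outbreaks.
#'
#' @param days Number of days (>= 1).
#' @param base_T_n,base_T_x Baseline daily minimum and maximum in degrees C.
#' @param cold_snap `NULL`, or a list/vector with elements `start` (first snap
#'   day, 1-based), `length` (days) and `depth` (degrees C subtracted from both
#'   extremes).
#' @param seed Integer seed for the daily jitter.
#' @param jitter_sd Standard deviation of the day-to-day jitter on each
#'   extreme (0 gives an exactly periodic series).
#' @param start Calendar start (midnight of day 1).
#' @return A [temperature_series()] of length `24 * days`.
#' @export
#' @examples
#' s <- synthesize_fixture(30, 10, 25, seed = 1)
#' range(s$temp)
synthesize_fixture <- function(days, base_T_n, base_T_x, cold_snap = NULL,
                               seed = 1L, jitter_sd = 0.8,
                               start = as.POSIXct("2009-01-01 00:00:00", tz = "UTC")) {
  if (days < 1) stop("days must be >= 1")
  if (base_T_n > base_T_x) stop("base_T_n must not exceed base_T_x")
  set.seed(seed)
  tn <- base_T_n + stats::rnorm(days, 0, jitter_sd)
  tx <- base_T_x + stats::rnorm(days, 0, jitter_sd)
  tx <- pmax(tx, tn + 0.5)
  if (!is.null(cold_snap)) {
    cs <- as.list(cold_snap)
    idx <- seq(cs$start, min(days, cs$start + cs$length - 1L))
    tn[idx] <- tn[idx] - cs$depth
    tx[idx] <- tx[idx] - cs$depth
  }
  # daily_extremes() errors if any tmin ends up above its tmax
  ext <- daily_extremes(seq(as.Date(start), by = "day", length.out = days), tn, tx)
  out <- estimate_hourly(ext)
  out$start <- start
  out
}
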