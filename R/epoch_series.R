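#' Epoch-count activity series
#'
#' The central container of the package: an actigraphy recording stored as
#' non-negative integer activity counts accumulated over fixed-length epochs
#' (1 min by default, the Actiwatch export convention), together with the
#' housing light schedule that defines daytime and nighttime.
#'
#' @param counts integer vector of non-negative activity counts, one per epoch.
#' @param start_time POSIXct (or ISO-8601 string, parsed as UTC) timestamp of
#'   the first epoch.
#' @param epoch_length epoch duration in minutes (positive integer).
#' @param subject_id subject identifier.
#' @param lights_on,lights_off clock times ("HH:MM") bounding the light period;
#'   defaults encode the 12:12 light-dark schedule starting 07:00.
#'
#' @return An object of class \code{epoch_series}.
#' @export
epoch_series <- function(counts, start_time, epoch_length = 1L,
                         subject_id = "subject", lights_on = "07:00",
                         lights_off = "19:00") {
  if (is.character(start_time)) {
    start_time <- parse_timestamp(start_time)
    if (is.na(start_time)) stop("start_time could not be parsed as ISO-8601")
  }
  stopifnot(inherits(start_time, "POSIXct"))
  epoch_length <- as.integer(epoch_length)
  if (is.na(epoch_length) || epoch_length < 1L) {
    stop("epoch_length must be a positive integer number of minutes")
  }
  if (length(counts) < 1L) stop("series must contain at least one epoch")
  if (anyNA(counts)) stop("counts must not contain NA")
  if (any(counts < 0)) stop("activity counts must be non-negative")
  if (any(counts != floor(counts))) stop("activity counts must be integers")
  on_min <- parse_clock(lights_on); off_min <- parse_clock(lights_off)
  if (on_min == off_min) stop("lights_on and lights_off must differ")
  structure(
    list(subject_id = as.character(subject_id),
         start_time = as.POSIXct(start_time, tz = "UTC"),
         epoch_length = epoch_length,
         counts = as.numeric(counts),
         lights_on = on_min,
         lights_off = off_min),
    class = "epoch_series")
}

parse_timestamp <- function(x) {
  out <- as.POSIXct(x, tz = "UTC", format = "%Y-%m-%dT%H:%M:%S")
  fallback <- is.na(out)
  if (any(fallback)) {
    out[fallback] <- as.POSIXct(x[fallback], tz = "UTC",
                                format = "%Y-%m-%d %H:%M:%S")
  }
  out
}

#' @export
print.epoch_series <- function(x, ...) {
  cat(sprintf("<epoch_series> subject %s: %d epochs x %d min from %s\n",
              x$subject_id, length(x$counts), x$epoch_length,
              format(x$start_time, "%Y-%m-%d %H:%M", tz = "UTC")))
  cat(sprintf("  lights %s-%s | mean count %.1f\n",
              format_clock(x$lights_on), format_clock(x$lights_off),
              mean(x$counts)))
  invisible(x)
}

#' @export
length.epoch_series <- function(x) length(x$counts)

# Minute-of-day (0..1439) of each epoch start.
minute_of_day <- function(series) {
  start_mod <- as.integer(format(series$start_time, "%H", tz = "UTC")) * 60L +
    as.integer(format(series$start_time, "%M", tz = "UTC"))
  (start_mod + (seq_along(series$counts) - 1L) * series$epoch_length) %% 1440L
}

# Calendar-day index (0-based, day 0 = day containing the first epoch,
# boundaries at local midnight) of each epoch.
day_index <- function(series) {
  start_mod <- as.integer(format(series$start_time, "%H", tz = "UTC")) * 60L +
    as.integer(format(series$start_time, "%M", tz = "UTC"))
  abs_min <- start_mod + (seq_along(series$counts) - 1L) * series$epoch_length
  abs_min %/% 1440L
}

# Logical mask: TRUE for epochs whose start lies in [lights_on, lights_off).
daytime_mask <- function(series) {
  m <- minute_of_day(series)
  if (series$lights_on < series$lights_off) {
    m >= series$lights_on & m < series$lights_off
  } else {
    m >= series$lights_on | m < series$lights_off
  }
}

# Indices of days that are completely covered (midnight-to-midnight).
complete_days <- function(series) {
  d <- day_index(series)
  per_day <- 1440L %/% series$epoch_length
  tab <- table(d)
  as.integer(names(tab)[tab == per_day])
}

#' Split a series into daytime and nighttime views
#'
#' Partitions the epochs of a recording by the light schedule: the day view
#' covers \code{[lights_on, lights_off)} on every calendar day, the night view
#' the complement. The two views always partition the series.
#'
#' @param series an \code{epoch_series}.
#' @return list with components \code{day} and \code{night}, each a list
#'   holding \code{counts}, the epoch \code{index} into the parent series, and
#'   \code{minute_of_day}.
#' @export
split_day_night <- function(series) {
  stopifnot(inherits(series, "epoch_series"))
  mask <- daytime_mask(series)
  m <- minute_of_day(series)
  view <- function(keep) {
    list(counts = series$counts[keep], index = which(keep),
         minute_of_day = m[keep])
  }
  list(day = view(mask), night = view(!mask))
}

#' Basic distribution statistics of activity counts
#'
#' Mean, standard deviation (sample, n-1), sample skewness and excess kurtosis
#' of the per-epoch counts, computed either on the full recording
#' (\code{include_nocturnal = TRUE}) or on the daytime epochs only.
#' Kurtosis is reported as excess kurtosis (normal = 0); skewness is the
#' moment estimator m3 / m2^(3/2). On a zero-variance subset the shape
#' statistics are returned as NA and flagged \code{degenerate}.
#'
#' @param series an \code{epoch_series}.
#' @param include_nocturnal if FALSE, restrict to the lights-on period.
#' @return list of class \code{summary_stats} with fields \code{mean},
#'   \code{sd}, \code{skewness}, \code{kurtosis} (excess), \code{n},
#'   \code{includes_nocturnal}, \code{kurtosis_convention}, \code{degenerate}.
#' @export
summary_stats <- function(series, include_nocturnal = TRUE) {
  stopifnot(inherits(series, "epoch_series"))
  x <- if (include_nocturnal) series$counts else
    series$counts[daytime_mask(series)]
  if (length(x) == 0L) stop("selected subset is empty")
  if (length(x) < 2L) stop("at least 2 epochs are required for sd")
  s <- sd(x)
  structure(
    list(mean = mean(x), sd = s,
         skewness = if (s == 0) NA_real_ else moment_skewness(x),
         kurtosis = if (s == 0) NA_real_ else moment_kurtosis_excess(x),
         n = length(x),
         includes_nocturnal = include_nocturnal,
         kurtosis_convention = "excess",
         degenerate = s == 0),
    class = "summary_stats")
}

#' Mean hourly activity profile (T0-T23)
#'
#' For every clock hour, the per-day hourly activity totals are averaged over
#' all completely recorded calendar days. Hour bins are [h:00, h+1:00), local
#' time, labeled T0..T23.
#'
#' @param series an \code{epoch_series}.
#' @return list of class \code{hourly_profile}: \code{per_hour_mean}
#'   (named numeric of length 24; hours never observed are NA),
#'   \code{n_days} complete days used, \code{subject_id}.
#' @export
hourly_profile <- function(series) {
  stopifnot(inherits(series, "epoch_series"))
  days <- complete_days(series)
  if (length(days) == 0L) stop("no complete (midnight-to-midnight) day of data")
  d <- day_index(series); hr <- minute_of_day(series) %/% 60L
  keep <- d %in% days
  totals <- tapply(series$counts[keep],
                   list(day = d[keep], hour = factor(hr[keep], levels = 0:23)),
                   sum)
  per_hour <- colMeans(totals, na.rm = FALSE)
  names(per_hour) <- paste0("T", 0:23)
  structure(list(per_hour_mean = per_hour, n_days = length(days),
                 subject_id = series$subject_id),
            class = "hourly_profile")
}

#' Average daily activity
#'
#' Default convention: mean of the per-epoch counts over complete calendar
#' days (so the value is on the same counts-per-epoch scale as
#' \code{summary_stats}). The per-day-total convention is also exposed.
#'
#' @param series an \code{epoch_series}.
#' @param statistic \code{"per_epoch_mean"} (default) or
#'   \code{"per_day_total"}.
#' @return a single number; attribute \code{day_totals} carries the per-day
#'   totals over complete days.
#' @export
mean_daily_activity <- function(series,
                                statistic = c("per_epoch_mean",
                                              "per_day_total")) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(series, "epoch_series"))
  days <- complete_days(series)
  if (length(days) == 0L) stop("no complete (midnight-to-midnight) day of data")
  d <- day_index(series)
  keep <- d %in% days
  totals <- tapply(series$counts[keep], d[keep], sum)
  out <- if (statistic == "per_epoch_mean") {
    mean(series$counts[keep])
  } else {
    mean(totals)
  }
  attr(out, "day_totals") <- as.numeric(totals)
  out
}
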