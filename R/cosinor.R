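# Fixed angular frequencies (rad/min) of the circadian and semi-circadian
# components; periods are fixed at 24 h and 12 h, not estimated.
OMEGA24 <- 2 * pi / 1440
OMEGA12 <- 2 * pi / 720

#' Aggregate an epoch series into wider clock-aligned bins
#'
#' Sums counts into non-overlapping bins of \code{width} minutes aligned to
#' the clock (bin boundaries at multiples of \code{width} from midnight).
#' Leading epochs before the first aligned boundary and trailing epochs that
#' do not fill a bin are dropped. Cosinor fitting conventionally uses 10-min
#' aggregation.
#'
#' @param series an \code{epoch_series}.
#' @param width target bin width in minutes; must be a multiple of the
#'   current epoch length.
#' @return an \code{epoch_series} with \code{epoch_length = width}.
#' @export
aggregate_epochs <- function(series, width = 10L) {
  stopifnot(inherits(series, "epoch_series"))
  width <- as.integer(width)
  if (width %% series$epoch_length != 0L) {
    stop("epoch_length (", series$epoch_length,
         " min) must divide the aggregation width (", width, " min)")
  }
  k <- width %/% series$epoch_length
  m <- minute_of_day(series)
  # first epoch landing on an aligned boundary
  first <- which(m %% width == 0L)[1]
  if (is.na(first)) stop("series too short to form one aligned bin")
  idx <- first:length(series$counts)
  n_bins <- length(idx) %/% k
  if (n_bins < 1L) stop("series too short to form one aligned bin")
  used <- idx[seq_len(n_bins * k)]
  binned <- colSums(matrix(series$counts[used], nrow = k))
  epoch_series(binned,
               series$start_time + (first - 1) * 60 * series$epoch_length,
               epoch_length = width, subject_id = series$subject_id,
               lights_on = format_clock(series$lights_on),
               lights_off = format_clock(series$lights_off))
}

#' @rdname aggregate_epochs
#' @export
aggregate_10min <- function(series) aggregate_epochs(series, 10L)

#' Single- or double-component cosinor fit
#'
#' Fits \eqn{y(t) = M + A_{24}\cos(\omega_{24}t + \varphi_{24})} and, for the
#' double model, an additional 12 h harmonic
#' \eqn{A_{12}\cos(\omega_{12}t + \varphi_{12})}, by ordinary least squares on
#' the linearization \eqn{y = M + a\cos\omega t + b\sin\omega t} per
#' component, with \eqn{A = \sqrt{a^2+b^2}} and
#' \eqn{\varphi = \mathrm{atan2}(-b, a)} mapped to \eqn{[0, 2\pi)}. Time t is
#' measured in minutes from local midnight of the first recorded day.
#'
#' @param series an \code{epoch_series} (typically 10-min aggregated).
#' @param components \code{"single"} (24 h only) or \code{"double"}
#'   (24 h + 12 h).
#' @return object of class \code{cosinor_fit}: \code{mesor}, \code{amp24},
#'   \code{phi24}, \code{amp12}, \code{phi12} (NA for the single model),
#'   \code{rss}, \code{n}, \code{components}, and \code{peak_time_24} (clock
#'   minutes of the fitted 24 h peak). An amplitude of exactly zero yields an
#'   NA acrophase.
#' @export
fit_cosinor <- function(series, components = c("double", "single")) {
  components <- match.arg(components)
  stopifnot(inherits(series, "epoch_series"))
  m0 <- minute_of_day(series)[1]
  t <- m0 + (seq_along(series$counts) - 1) * series$epoch_length
  cosinor_lm(t, series$counts, components)
}

#' Cosinor least squares on raw time/value vectors
#'
#' The estimator underlying [fit_cosinor()], exposed for data that is not an
#' integer-count \code{epoch_series} (e.g. model curves or residual series).
#'
#' @param t time in minutes from local midnight (may continue across days).
#' @param y numeric response.
#' @param components \code{"single"} or \code{"double"}.
#' @return a \code{cosinor_fit}; see [fit_cosinor()].
#' @export
cosinor_lm <- function(t, y, components = c("double", "single")) {
  components <- match.arg(components)
  stopifnot(length(t) == length(y))
  n_min <- if (components == "single") 6L else 10L
  if (length(y) < n_min) {
    stop("need at least ", n_min, " points for the ", components,
         " cosinor model")
  }
  if (diff(range(t)) < 720) {
    stop("data must span at least half of the longest period (12 h)")
  }
  X <- cbind(c24 = cos(OMEGA24 * t), s24 = sin(OMEGA24 * t))
  if (components == "double") {
    X <- cbind(X, c12 = cos(OMEGA12 * t), s12 = sin(OMEGA12 * t))
  }
  fit <- lm(y ~ X)
  if (anyNA(coef(fit))) stop("rank-deficient cosinor design")
  cf <- coef(fit)
  # amplitudes at numerical-noise level count as zero (undefined acrophase)
  tol <- 1e-10 * max(1, abs(cf[1]), stats::sd(y))
  amp_phase <- function(a, b) {
    A <- sqrt(a^2 + b^2)
    if (A < tol) return(c(0, NA_real_))
    c(A, atan2(-b, a) %% (2 * pi))
  }
  ap24 <- amp_phase(cf[["Xc24"]], cf[["Xs24"]])
  ap12 <- if (components == "double") {
    amp_phase(cf[["Xc12"]], cf[["Xs12"]])
  } else c(NA_real_, NA_real_)
  structure(
    list(mesor = unname(cf[1]), amp24 = ap24[1], phi24 = ap24[2],
         amp12 = ap12[1], phi12 = ap12[2],
         omega24 = OMEGA24, omega12 = OMEGA12,
         rss = sum(fit$residuals^2), n = length(y), components = components,
         peak_time_24 = if (is.na(ap24[2])) NA_real_ else
           ((2 * pi - ap24[2]) / OMEGA24) %% 1440),
    class = "cosinor_fit")
}

#' Per-day cosinor fits on raw vectors, averaged
#'
#' Splits \code{(t, y)} into calendar days (t %/% 1440), fits each day with
#' [cosinor_lm()] and averages parameters as in [daily_cosinor_summary()].
#' Days failing fit preconditions are skipped and counted.
#'
#' @inheritParams cosinor_lm
#' @return a \code{cosinor_summary}.
#' @export
cosinor_daily <- function(t, y, components = c("double", "single")) {
  components <- match.arg(components)
  stopifnot(length(t) == length(y))
  day <- t %/% 1440
  fits <- list(); skipped <- 0L
  for (dd in sort(unique(day))) {
    idx <- day == dd
    f <- tryCatch(cosinor_lm(t[idx], y[idx], components),
                  error = function(e) NULL)
    if (is.null(f)) skipped <- skipped + 1L else fits[[length(fits) + 1L]] <- f
  }
  if (length(fits) == 0L) stop("no day could be fitted")
  summarize_daily_fits(fits, skipped, components)
}

summarize_daily_fits <- function(fits, skipped, components) {
  g <- function(field) vapply(fits, `[[`, numeric(1), field)
  structure(
    list(per_day_fits = fits,
         mean_mesor = mean(g("mesor")),
         mean_amp24 = mean(g("amp24")),
         mean_phi24 = circular_mean(g("phi24")),
         mean_amp12 = if (components == "double") mean(g("amp12")) else NA_real_,
         mean_phi12 = if (components == "double") circular_mean(g("phi12")) else NA_real_,
         n_days = length(fits), n_skipped = skipped,
         components = components),
    class = "cosinor_summary")
}

#' @export
print.cosinor_fit <- function(x, ...) {
  cat(sprintf("<cosinor_fit %s> M=%.2f A24=%.2f phi24=%.3f rad", x$components,
              x$mesor, x$amp24, x$phi24))
  if (x$components == "double") {
    cat(sprintf(" A12=%.2f phi12=%.3f rad", x$amp12, x$phi12))
  }
  cat(sprintf(" (n=%d, rss=%.3g)\n", x$n, x$rss))
  invisible(x)
}

#' Per-day cosinor fits averaged per subject
#'
#' Aggregates to 10-min bins, fits the cosinor model separately to every
#' complete calendar day, then averages the fitted parameters: mesor and
#' amplitudes arithmetically, acrophases by the circular (resultant-vector)
#' mean. Days failing fit preconditions are skipped and counted, never
#' imputed.
#'
#' @param series an \code{epoch_series}.
#' @param components passed to [fit_cosinor()].
#' @param aggregate if TRUE (default) aggregate to 10-min bins first.
#' @return object of class \code{cosinor_summary}: per-day fits plus
#'   \code{mean_mesor}, \code{mean_amp24}, \code{mean_phi24},
#'   \code{mean_amp12}, \code{mean_phi12}, \code{n_days}, \code{n_skipped}.
#' @export
daily_cosinor_summary <- function(series, components = c("double", "single"),
                                  aggregate = TRUE) {
  components <- match.arg(components)
  stopifnot(inherits(series, "epoch_series"))
  if (aggregate && series$epoch_length != 10L) series <- aggregate_10min(series)
  days <- complete_days(series)
  if (length(days) == 0L) stop("no complete (midnight-to-midnight) day of data")
  d <- day_index(series)
  t <- minute_of_day(series) + d * 1440L
  keep <- d %in% days
  cosinor_daily(t[keep], series$counts[keep], components)
}

#' @export
print.cosinor_summary <- function(x, ...) {
  cat(sprintf(
    "<cosinor_summary %s> %d days (%d skipped): M=%.2f A24=%.2f phi24=%.3f",
    x$components, x$n_days, x$n_skipped, x$mean_mesor, x$mean_amp24,
    x$mean_phi24))
  if (x$components == "double") {
    cat(sprintf(" A12=%.2f phi12=%.3f", x$mean_amp12, x$mean_phi12))
  }
  cat("\n")
  invisible(x)
}
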