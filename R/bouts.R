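#' Activity threshold separating rest from active epochs
#'
#' The threshold is the mean of the nonzero activity counts. By default it is
#' computed once over the whole recording ("overall" mode), which makes the
#' rest/active dichotomy reproducible across days; a per-day mode returning
#' one threshold per complete calendar day is also provided.
#'
#' @param series an \code{epoch_series}.
#' @param mode \code{"overall"} (default) or \code{"per_day"}.
#' @return a single threshold, or a named vector of per-day thresholds.
#' @export
activity_threshold <- function(series, mode = c("overall", "per_day")) {
  mode <- match.arg(mode)
  stopifnot(inherits(series, "epoch_series"))
  if (all(series$counts == 0)) stop("all counts are zero; threshold undefined")
  if (mode == "overall") {
    return(mean(series$counts[series$counts > 0]))
  }
  d <- day_index(series)
  days <- complete_days(series)
  out <- vapply(days, function(dd) {
    x <- series$counts[d == dd]
    x <- x[x > 0]
    if (length(x) == 0L) NA_real_ else mean(x)
  }, numeric(1))
  setNames(out, days)
}

#' Extract rest and active bouts
#'
#' A rest epoch has count strictly below the threshold; an active epoch has
#' count at or above it. Maximal runs of same-state epochs become bouts with
#' duration = run length x epoch length (minutes). Under the default
#' \code{drop_censored} policy the first and last runs are discarded because
#' their durations are truncated by the recording window.
#'
#' @param series an \code{epoch_series}.
#' @param threshold activity threshold (counts), from [activity_threshold()].
#' @param boundary \code{"drop_censored"} (default) or \code{"keep_all"}.
#' @return object of class \code{bout_sequence}: \code{rest_durations},
#'   \code{active_durations} (minutes), \code{threshold},
#'   \code{boundary_policy}.
#' @export
extract_bouts <- function(series, threshold,
                          boundary = c("drop_censored", "keep_all")) {
  boundary <- match.arg(boundary)
  stopifnot(inherits(series, "epoch_series"), threshold > 0)
  active <- series$counts >= threshold
  r <- rle(active)
  keep <- rep(TRUE, length(r$lengths))
  if (boundary == "drop_censored" && length(r$lengths) > 0L) {
    keep[1] <- FALSE
    keep[length(keep)] <- FALSE
  }
  dur <- r$lengths * series$epoch_length
  structure(
    list(rest_durations = dur[keep & !r$values],
         active_durations = dur[keep & r$values],
         threshold = threshold, boundary_policy = boundary,
         epoch_length = series$epoch_length),
    class = "bout_sequence")
}

#' Empirical survival curve of bout durations
#'
#' The cumulative probability \eqn{P(x \ge a)} = (number of durations >= a)/n,
#' evaluated at every distinct observed duration.
#'
#' @param durations bout durations in minutes.
#' @return object of class \code{survival_curve}: sorted \code{durations},
#'   \code{p_ge} (non-increasing, starts at 1), \code{n_bouts}.
#' @export
survival_curve <- function(durations) {
  durations <- durations[!is.na(durations)]
  if (length(durations) == 0L) stop("no durations supplied")
  a <- sort(unique(durations))
  n <- length(durations)
  srt <- sort(durations)
  # findInterval(left.open = TRUE) counts sample values strictly below each a,
  # so p is exactly (#durations >= a)/n even under heavy ties
  p <- (n - findInterval(a, srt, left.open = TRUE)) / n
  structure(list(durations = a, p_ge = p, n_bouts = n),
            class = "survival_curve")
}

#' Power-law fit to a rest-duration survival curve
#'
#' Fits \eqn{P(x \ge a) = A a^{-\gamma}} by ordinary least squares of
#' \eqn{\log P} on \eqn{\log a} over the distinct durations inside
#' \code{fit_range} (default 3-30 min, the region where rest durations scale).
#'
#' @param curve a \code{survival_curve}.
#' @param fit_range inclusive duration range (minutes) used for fitting.
#' @return object of class \code{rest_fit}: \code{gamma}, \code{prefactor_A},
#'   \code{fit_range}, \code{r_squared}, \code{n_points}.
#' @export
fit_rest_powerlaw <- function(curve, fit_range = c(3, 30)) {
  stopifnot(inherits(curve, "survival_curve"), length(fit_range) == 2L,
            fit_range[1] < fit_range[2])
  sel <- curve$durations >= fit_range[1] & curve$durations <= fit_range[2] &
    curve$p_ge > 0
  if (sum(sel) < 3L) {
    stop("need at least 3 distinct durations inside the fit range")
  }
  x <- log(curve$durations[sel]); y <- log(curve$p_ge[sel])
  fit <- lm(y ~ x)
  structure(
    list(gamma = -unname(coef(fit)[2]),
         prefactor_A = exp(unname(coef(fit)[1])),
         fit_range = fit_range,
         r_squared = log_fit_r2(fit, y),
         n_points = sum(sel)),
    class = "rest_fit")
}

#' Stretched-exponential fit to an active-duration survival curve
#'
#' Fits \eqn{P(x \ge a) = \exp(-\alpha a^{\beta})} by ordinary least squares
#' of \eqn{\log(-\log P)} on \eqn{\log a} over distinct durations inside
#' \code{fit_range} (default 10-100 min). Points with P = 1 are excluded
#' (their double log is undefined).
#'
#' @param curve a \code{survival_curve}.
#' @param fit_range inclusive duration range (minutes).
#' @return object of class \code{active_fit}: \code{alpha}, \code{beta},
#'   \code{fit_range}, \code{r_squared}, \code{n_points}.
#' @export
fit_active_stretched_exp <- function(curve, fit_range = c(10, 100)) {
  stopifnot(inherits(curve, "survival_curve"), length(fit_range) == 2L,
            fit_range[1] < fit_range[2])
  sel <- curve$durations >= fit_range[1] & curve$durations <= fit_range[2] &
    curve$p_ge > 0 & curve$p_ge < 1
  if (sum(sel) < 3L) {
    stop("need at least 3 distinct in-range durations with 0 < P < 1")
  }
  x <- log(curve$durations[sel]); y <- log(-log(curve$p_ge[sel]))
  fit <- lm(y ~ x)
  structure(
    list(beta = unname(coef(fit)[2]),
         alpha = exp(unname(coef(fit)[1])),
         fit_range = fit_range,
         r_squared = log_fit_r2(fit, y),
         n_points = sum(sel)),
    class = "active_fit")
}

# R^2 of a log-space OLS fit, computed directly so that perfect noiseless
# fits do not trigger summary.lm()'s essentially-perfect-fit warning.
log_fit_r2 <- function(fit, y) {
  tss <- sum((y - mean(y))^2)
  if (tss == 0) return(1)
  1 - sum(fit$residuals^2) / tss
}

#' Hill-type maximum-likelihood exponent (cross-check utility)
#'
#' Continuous-Pareto MLE of the survival exponent for durations at or above
#' \code{xmin}: \eqn{\hat\gamma = n / \sum \log(x_i / xmin)}. Provided as an
#' independent cross-check on the log-log OLS estimate, not as the default
#' estimator.
#'
#' @param durations bout durations.
#' @param xmin lower cutoff.
#' @return the MLE exponent.
#' @export
hill_exponent <- function(durations, xmin = 3) {
  x <- durations[durations >= xmin]
  if (length(x) < 2L) stop("need at least 2 durations at or above xmin")
  length(x) / sum(log(x / xmin))
}
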