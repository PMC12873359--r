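#' z-normalize a sequence
#'
#' Centers to mean 0 and scales to standard deviation 1 using the sample
#' (n-1) standard deviation. Constant sequences are an error: entropy is
#' undefined on zero-variance input.
#'
#' @param x numeric vector, length >= 2.
#' @return normalized numeric vector.
#' @export
zscore <- function(x) {
  if (length(x) < 2L) stop("need at least 2 values to normalize")
  s <- sd(x)
  if (is.na(s) || s == 0) stop("constant sequence: z-score undefined")
  (x - mean(x)) / s
}

#' Sample Entropy
#'
#' SampEn(m, r) = -ln(A/B), where B is the number of pairs of distinct
#' m-point templates lying within Chebyshev tolerance r of each other and A
#' the number of those pairs that remain within r when extended to m+1
#' points; self-matches are excluded. Both counts run over the N - m
#' templates that have a defined extension (Richman-Moorman convention), so
#' A/B is a proper conditional probability and SampEn is non-negative
#' whenever defined. When no template pair matches (B = 0) or no extension
#' matches (A = 0) the statistic is undefined and NA is returned with
#' attribute \code{undefined = TRUE}.
#'
#' @param x numeric sequence, length >= m + 2.
#' @param m template length (default 2).
#' @param r tolerance (default 0.2); with \code{normalize = TRUE} this is in
#'   units of the sequence SD.
#' @param normalize z-score the input first (default TRUE).
#' @return a non-negative number, or NA (undefined).
#' @export
sample_entropy <- function(x, m = 2L, r = 0.2, normalize = TRUE) {
  if (length(x) < m + 2L) stop("sequence too short: need length >= m + 2")
  if (normalize) x <- zscore(x)
  ab <- sampen_counts(as.numeric(x), as.integer(m), as.numeric(r))
  if (ab[["B"]] == 0 || ab[["A"]] == 0) {
    return(structure(NA_real_, undefined = TRUE))
  }
  -log(ab[["A"]] / ab[["B"]])
}

#' Daytime Sample Entropy, per day
#'
#' For every complete calendar day, takes the daytime
#' (lights-on to lights-off) epoch counts, z-normalizes them, and computes
#' SampEn(m, r); the per-day values are averaged. Days on which the
#' statistic is undefined (constant counts, or no template matches) are
#' excluded from the mean and counted. A concatenated mode computing one
#' value over all daytime epochs joined end to end is available, but the
#' per-day default avoids spurious template matches across day boundaries.
#'
#' @param series an \code{epoch_series}.
#' @param m,r Sample Entropy parameters (defaults 2 and 0.2).
#' @param scope \code{"per_day"} (default) or \code{"concatenated"}.
#' @return object of class \code{entropy_result}: \code{per_day_values},
#'   \code{mean_sampen}, \code{n_days} (days contributing),
#'   \code{n_undefined}, \code{m}, \code{r}.
#' @export
daytime_sampen <- function(series, m = 2L, r = 0.2,
                           scope = c("per_day", "concatenated")) {
  scope <- match.arg(scope)
  stopifnot(inherits(series, "epoch_series"))
  days <- complete_days(series)
  if (length(days) == 0L) stop("no complete (midnight-to-midnight) day of data")
  d <- day_index(series)
  mask <- daytime_mask(series)
  day_values <- function(dd) series$counts[mask & d == dd]
  one <- function(x) {
    if (length(x) < m + 2L) return(structure(NA_real_, undefined = TRUE))
    tryCatch(sample_entropy(x, m = m, r = r, normalize = TRUE),
             error = function(e) structure(NA_real_, undefined = TRUE))
  }
  if (scope == "per_day") {
    vals <- vapply(days, function(dd) as.numeric(one(day_values(dd))),
                   numeric(1))
  } else {
    vals <- as.numeric(one(unlist(lapply(days, day_values))))
  }
  defined <- !is.na(vals)
  if (!any(defined)) stop("Sample Entropy undefined on every eligible day")
  structure(
    list(per_day_values = vals,
         mean_sampen = mean(vals[defined]),
         n_days = sum(defined),
         n_undefined = sum(!defined),
         m = as.integer(m), r = r, scope = scope),
    class = "entropy_result")
}

# O(N^2) reference implementation used by tests and available as an
# explicit cross-check; intentionally independent of the compiled kernel.
sampen_bruteforce <- function(x, m = 2L, r = 0.2) {
  n <- length(x)
  stopifnot(n >= m + 2L)
  A <- 0L; B <- 0L
  nt <- n - m
  for (i in seq_len(nt - 1L)) {
    for (j in (i + 1L):nt) {
      if (max(abs(x[i:(i + m - 1L)] - x[j:(j + m - 1L)])) <= r) {
        B <- B + 1L
        if (abs(x[i + m] - x[j + m]) <= r) A <- A + 1L
      }
    }
  }
  if (B == 0L || A == 0L) return(structure(NA_real_, undefined = TRUE))
  -log(A / B)
}
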