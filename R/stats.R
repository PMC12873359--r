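#' Two-sample pooled-variance (Student) t-test
#'
#' The classical Student t with pooled variance and df = n_a + n_b - 2,
#' two-tailed. A Welch variant is available by flag. When both groups have
#' zero variance, equal means give t = 0, p = 1; unequal means make the
#' statistic degenerate and are flagged.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @param welch use the Welch (unequal-variance) statistic instead.
#' @return object of class \code{t_test_result}: \code{t}, \code{df},
#'   \code{p}, \code{group_means}, \code{group_sds}, \code{degenerate}.
#' @export
two_sample_t <- function(a, b, welch = FALSE) {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  na <- length(a); nb <- length(b)
  ma <- mean(a); mb <- mean(b); va <- var(a); vb <- var(b)
  degenerate <- FALSE
  if (welch) {
    se2 <- va / na + vb / nb
    if (se2 == 0) {
      tt <- 0; df <- na + nb - 2; p <- 1
      if (ma != mb) degenerate <- TRUE
    } else {
      tt <- (ma - mb) / sqrt(se2)
      df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
      p <- 2 * pt(-abs(tt), df)
    }
  } else {
    df <- na + nb - 2
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / df
    if (sp2 == 0) {
      if (ma == mb) { tt <- 0; p <- 1 } else {
        tt <- NA_real_; p <- NA_real_; degenerate <- TRUE
      }
    } else {
      tt <- (ma - mb) / sqrt(sp2 * (1 / na + 1 / nb))
      p <- 2 * pt(-abs(tt), df)
    }
  }
  structure(list(t = tt, df = df, p = p,
                 group_means = c(ma, mb), group_sds = c(sqrt(va), sqrt(vb)),
                 welch = welch, degenerate = degenerate),
            class = "t_test_result")
}

#' Pearson correlation with regression F statistic
#'
#' Pearson's r together with the equivalent simple-regression F test:
#' \eqn{F = r^2 (n-2) / (1 - r^2)} on (1, n - 2) degrees of freedom, the
#' reporting style "F(1, df) = ..., r = ..., p = ...". A perfect correlation
#' yields an infinite F and p = 0.
#'
#' @param x,y numeric vectors of equal length >= 3, each with positive
#'   variance.
#' @return object of class \code{correlation_result}: \code{r}, \code{F},
#'   \code{df1} (= 1), \code{df2} (= n - 2), \code{p}, \code{n}.
#' @export
pearson_with_F <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- !(is.na(x) | is.na(y))
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  if (var(x) == 0 || var(y) == 0) stop("zero variance in x or y")
  r <- stats::cor(x, y)
  df2 <- n - 2L
  if (abs(r) >= 1) {
    FF <- Inf; p <- 0
  } else {
    FF <- r^2 * df2 / (1 - r^2)
    p <- pf(FF, 1, df2, lower.tail = FALSE)
  }
  structure(list(r = r, F = FF, df1 = 1L, df2 = df2, p = p, n = n),
            class = "correlation_result")
}

#' Invert a printed F statistic to the correlation magnitude
#'
#' Closed-form inversion \eqn{|r| = \sqrt{F / (F + df2)}} of the simple
#' regression relation, used to check the internal consistency of reported
#' (F, r) pairs.
#'
#' @param F F statistic on (1, df2) degrees of freedom.
#' @param df2 denominator degrees of freedom (n - 2).
#' @return the implied |r|.
#' @export
r_from_F <- function(F, df2) {
  stopifnot(F >= 0, df2 > 0)
  sqrt(F / (F + df2))
}

#' Mixed two-factor (group x hour) repeated-measures ANOVA
#'
#' Split-plot decomposition with group as the between-subject factor, clock
#' hour as the within-subject factor, and subject nested in group as the
#' between error stratum: F(group) = MS_group / MS_subject(group);
#' F(hour) and F(group x hour) use the residual within-stratum mean square.
#' Requires a balanced design (equal subjects per group) and complete
#' profiles; missing hours are an error, never imputed. No sphericity
#' correction is applied by default; Greenhouse-Geisser is available.
#' Post hoc: per-hour pooled two-sample t-tests, Bonferroni-adjusted over
#' the 24 hourly comparisons.
#'
#' @param profiles numeric matrix, subjects x 24 hours (columns T0..T23).
#' @param group factor/character of group labels, one per row.
#' @param gg_correction apply Greenhouse-Geisser epsilon to the
#'   within-factor tests.
#' @return object of class \code{anova_result}: \code{effects} (data.frame
#'   with F, df_num, df_den, p per effect), \code{posthoc} (per-hour raw and
#'   Bonferroni-adjusted p), \code{epsilon} (GG epsilon, reported even when
#'   unused).
#' @export
group_hour_anova <- function(profiles, group, gg_correction = FALSE) {
  profiles <- as.matrix(profiles)
  if (anyNA(profiles)) stop("missing hours in a profile; no imputation")
  group <- as.factor(group)
  H <- ncol(profiles)
  stopifnot(nrow(profiles) == length(group), H >= 2L)
  ng <- table(group)
  if (length(ng) < 2L) stop("need at least 2 groups")
  if (any(ng < 2L)) stop("need at least 2 subjects per group")
  if (length(unique(ng)) != 1L) stop("design must be balanced")
  N <- nrow(profiles); G <- length(ng); n <- ng[[1]]

  grand <- mean(profiles)
  subj_mean <- rowMeans(profiles)
  hour_mean <- colMeans(profiles)
  grp_mean <- tapply(subj_mean, group, mean)
  cell_mean <- apply(profiles, 2, function(col) tapply(col, group, mean))

  ss_group <- H * sum(ng * (grp_mean - grand)^2)
  ss_subj <- H * sum((subj_mean - grp_mean[group])^2)
  ss_hour <- N * sum((hour_mean - grand)^2)
  ss_int <- sum(n * (cell_mean - outer(grp_mean, rep(1, H)) -
                       outer(rep(1, G), hour_mean) + grand)^2)
  ss_tot <- sum((profiles - grand)^2)
  ss_err <- ss_tot - ss_group - ss_subj - ss_hour - ss_int

  df_group <- G - 1; df_subj <- N - G
  df_hour <- H - 1; df_int <- (G - 1) * (H - 1); df_err <- (N - G) * (H - 1)
  ms <- function(ss, df) ss / df
  eps <- gg_epsilon(profiles, group)
  k <- if (gg_correction) eps else 1
  eff <- data.frame(
    effect = c("group", "hour", "group_x_hour"),
    F = c(ms(ss_group, df_group) / ms(ss_subj, df_subj),
          ms(ss_hour, df_hour) / ms(ss_err, df_err),
          ms(ss_int, df_int) / ms(ss_err, df_err)),
    df_num = c(df_group, df_hour * k, df_int * k),
    df_den = c(df_subj, df_err * k, df_err * k),
    stringsAsFactors = FALSE)
  eff$p <- pf(eff$F, eff$df_num, eff$df_den, lower.tail = FALSE)

  lv <- levels(group)
  raw <- vapply(seq_len(H), function(h) {
    two_sample_t(profiles[group == lv[1], h], profiles[group == lv[2], h])$p
  }, numeric(1))
  posthoc <- data.frame(hour = paste0("T", seq_len(H) - 1L),
                        p_raw = raw,
                        p_bonferroni = pmin(1, raw * H),
                        stringsAsFactors = FALSE)
  structure(list(effects = eff, posthoc = posthoc, epsilon = eps,
                 gg_correction = gg_correction,
                 ss = c(group = ss_group, subject = ss_subj, hour = ss_hour,
                        interaction = ss_int, error = ss_err, total = ss_tot)),
            class = "anova_result")
}

# Greenhouse-Geisser epsilon from the pooled within-group covariance of the
# repeated measures.
gg_epsilon <- function(profiles, group) {
  H <- ncol(profiles)
  covs <- lapply(split(seq_len(nrow(profiles)), group), function(idx) {
    if (length(idx) < 2L) return(NULL)
    stats::cov(profiles[idx, , drop = FALSE])
  })
  covs <- covs[!vapply(covs, is.null, logical(1))]
  S <- Reduce(`+`, covs) / length(covs)
  d <- mean(diag(S)); sbar <- mean(S)
  num <- (H * (d - sbar))^2
  den <- (H - 1) * (sum(S^2) - 2 * H * sum(rowMeans(S)^2) + H^2 * sbar^2)
  if (den <= 0) return(1)
  max(1 / (H - 1), min(1, num / den))
}

#' Social preference index
#'
#' SPI = (percent time in the stranger chamber - percent time in the empty
#' chamber) / 100; values near 1 indicate strong preference for the social
#' chamber. Always within [-1, 1].
#'
#' @param pct_stranger,pct_empty dwell percentages (vectorized).
#' @return numeric SPI.
#' @export
social_preference_index <- function(pct_stranger, pct_empty) {
  (pct_stranger - pct_empty) / 100
}

#' Three-chamber cohort report
#'
#' Reduces trial-level records to per-subject means (SPI, dwell percentages,
#' transitions), compares groups on SPI and transitions with the pooled
#' t-test, and correlates per-subject mean transitions with mean stranger
#' dwell via [pearson_with_F()].
#'
#' @param trials data.frame in the three-chamber dialect (see
#'   [read_three_chamber_csv()]).
#' @param subjects data.frame mapping \code{animal_id} to \code{group};
#'   omitted if \code{trials} already carries a \code{group} column.
#' @return list of class \code{three_chamber_report}: \code{per_subject},
#'   \code{t_spi}, \code{t_transitions},
#'   \code{cor_transitions_stranger}.
#' @export
three_chamber_report <- function(trials, subjects = NULL) {
  if (!"group" %in% names(trials)) {
    if (is.null(subjects)) stop("need a subjects table with group labels")
    trials <- merge(trials, subjects[, c("animal_id", "group")],
                    by = "animal_id")
  }
  trials$spi <- social_preference_index(trials$pct_stranger,
                                        trials$pct_empty)
  per <- aggregate(cbind(spi, pct_stranger, pct_empty, pct_center,
                         transitions) ~ animal_id + group,
                   data = trials, FUN = mean)
  per <- per[order(per$group, per$animal_id), ]
  a <- per[per$group == "UE", ]; b <- per[per$group == "VPA", ]
  structure(
    list(per_subject = per,
         t_spi = two_sample_t(a$spi, b$spi),
         t_transitions = two_sample_t(a$transitions, b$transitions),
         cor_transitions_stranger =
           tryCatch(pearson_with_F(per$transitions, per$pct_stranger),
                    error = function(e) NULL)),
    class = "three_chamber_report")
}
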