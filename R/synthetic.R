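#' Configuration for the synthetic actigraphy cohort generator
#'
#' The generator emulates home-cage marmoset recordings as an alternating
#' rest/active renewal process modulated by a double-cosinor diurnal
#' envelope under a 12:12 light-dark schedule starting 07:00. Group defaults
#' encode the published cohort: rest-bout survival exponents gamma = 1.10
#' (UE) / 1.38 (VPA), stretched-exponential active bouts with
#' (alpha, beta) = (0.86, 0.60) / (0.67, 0.67), and mesor / 24 h cosinor
#' truth from the group parameter table (per-minute scale, i.e. the
#' 10-min-aggregated values divided by 10). The default 12 h harmonic
#' (A12 = 120/140, phi12 = 2.50) is deliberately stronger than the fitted
#' table value: the fitted 12 h amplitude is just below the bimodality
#' threshold A24/4, and the generator's stated world is a bimodal day
#' (morning rise, dip near 13:00, evening peak), which these defaults
#' produce. Recording length defaults to 22 days, the cohort average
#' wearing time.
#'
#' @param n_subjects_per_group subjects per group (default 5).
#' @param n_days complete recording days per subject (default 22).
#' @param epoch_length epoch length in minutes (default 1).
#' @param cosinor_truth named list (UE, VPA) of c(M, A24, phi24, A12, phi12)
#'   on the counts-per-minute scale.
#' @param rest_gamma named vector of per-group rest survival exponents.
#' @param rest_min,rest_max truncation range of rest durations (minutes).
#' @param active_alpha,active_beta named per-group stretched-exponential
#'   parameters of active-bout durations.
#' @param active_gain multiplier applied to the cosinor envelope to obtain
#'   the within-active-bout mean count (compensates the active duty cycle).
#' @param rest_intensity mean count inside rest bouts (kept far below the
#'   rest/active threshold).
#' @param dispersion negative-binomial size of within-bout count noise
#'   (smaller = more overdispersed), per group.
#' @param night_suppression multiplicative factor in [0, 1] applied to count
#'   intensities during lights-off.
#' @param activity_cv log-scale SD of the subject-level activity multiplier
#'   (between-subject heterogeneity; the published between-subject CV of
#'   mean activity is about 0.19).
#' @param cortisol_intercept,cortisol_slope linear coupling of salivary
#'   cortisol (ug/dL) to mean hourly activity (counts/h).
#' @param cortisol_target_r population cortisol-activity correlation the
#'   noise SD is calibrated to (default 0.72); ignored when
#'   \code{cortisol_noise_sd} is given explicitly.
#' @param cortisol_noise_sd explicit Gaussian noise SD (ug/dL), or NULL.
#' @param seed master seed; each subject derives its own substream so
#'   cohorts are extensible without perturbing existing subjects.
#' @param start_time,lights_on,lights_off recording start and light schedule.
#' @return validated list of class \code{synth_config}.
#' @export
synth_config <- function(n_subjects_per_group = 5L,
                         n_days = 22L,
                         epoch_length = 1L,
                         cosinor_truth = list(
                           UE = c(M = 156.93, A24 = 187.52, phi24 = 2.86,
                                  A12 = 120, phi12 = 2.50),
                           VPA = c(M = 199.16, A24 = 220.63, phi24 = 2.88,
                                   A12 = 140, phi12 = 2.50)),
                         rest_gamma = c(UE = 1.10, VPA = 1.38),
                         rest_min = 2L, rest_max = 480L,
                         active_alpha = c(UE = 0.86, VPA = 0.67),
                         active_beta = c(UE = 0.60, VPA = 0.67),
                         active_gain = 3,
                         rest_intensity = 5,
                         dispersion = c(UE = 2, VPA = 2),
                         night_suppression = 0.2,
                         activity_cv = 0.2,
                         cortisol_intercept = 2,
                         cortisol_slope = 5e-4,
                         cortisol_target_r = 0.72,
                         cortisol_noise_sd = NULL,
                         seed = 1L,
                         start_time = "2024-03-01T00:00:00",
                         lights_on = "07:00", lights_off = "19:00") {
  cfg <- list(n_subjects_per_group = as.integer(n_subjects_per_group),
              n_days = as.integer(n_days),
              epoch_length = as.integer(epoch_length),
              cosinor_truth = cosinor_truth,
              rest_gamma = rest_gamma, rest_min = as.integer(rest_min),
              rest_max = as.integer(rest_max),
              active_alpha = active_alpha, active_beta = active_beta,
              active_gain = active_gain, rest_intensity = rest_intensity,
              dispersion = dispersion,
              night_suppression = night_suppression,
              activity_cv = activity_cv,
              cortisol_intercept = cortisol_intercept,
              cortisol_slope = cortisol_slope,
              cortisol_target_r = cortisol_target_r,
              cortisol_noise_sd = cortisol_noise_sd,
              seed = as.integer(seed), start_time = start_time,
              lights_on = lights_on, lights_off = lights_off)
  stopifnot(cfg$n_subjects_per_group >= 1L, cfg$n_days >= 1L,
            cfg$epoch_length >= 1L,
            all(cfg$rest_gamma > 0), all(cfg$active_beta > 0),
            all(cfg$active_alpha > 0),
            cfg$night_suppression >= 0, cfg$night_suppression <= 1,
            cfg$rest_min >= 1L)
  if (cfg$rest_min > cfg$rest_max) stop("rest_min exceeds rest_max")
  for (g in c("UE", "VPA")) {
    if (!all(c("M", "A24", "phi24", "A12", "phi12") %in%
             names(cfg$cosinor_truth[[g]]))) {
      stop("cosinor_truth$", g, " must name M, A24, phi24, A12, phi12")
    }
  }
  structure(cfg, class = "synth_config")
}

#' Truncated-Pareto rest durations (integer minutes)
#'
#' Inverse-CDF sampling of a continuous Pareto with survival exponent
#' \code{gamma} truncated to \code{[lower, upper + 1)}, then floored to whole
#' minutes. Flooring preserves the survival function exactly at integers:
#' \eqn{P(X \ge k) \propto k^{-\gamma} - (upper+1)^{-\gamma}} for
#' k = lower..upper, so log-log fits of the empirical survival curve are
#' unbiased apart from upper truncation.
#'
#' @param n number of draws.
#' @param gamma survival exponent (> 0).
#' @param lower,upper integer duration bounds (minutes).
#' @param discrete floor to integer minutes (default TRUE).
#' @return numeric vector of durations.
#' @export
rtrunc_pareto <- function(n, gamma, lower = 2, upper = 480, discrete = TRUE) {
  stopifnot(gamma > 0, lower >= 1, upper >= lower)
  hi <- if (discrete) upper + 1 else upper
  u <- runif(n)
  s_lo <- lower^(-gamma); s_hi <- hi^(-gamma)
  x <- (s_lo - u * (s_lo - s_hi))^(-1 / gamma)
  if (discrete) floor(x) else x
}

#' Stretched-exponential (Weibull) active durations
#'
#' Draws from the law \eqn{P(X \ge a) = \exp(-\alpha a^{\beta})}
#' conditioned on \eqn{X \ge 1} and floored to whole minutes, so every
#' active bout lasts at least one epoch.
#'
#' @param n number of draws.
#' @param alpha,beta stretched-exponential parameters (> 0).
#' @param discrete floor to integer minutes (default TRUE).
#' @return numeric vector of durations (>= 1).
#' @export
rstretched_active <- function(n, alpha, beta, discrete = TRUE) {
  stopifnot(alpha > 0, beta > 0)
  u <- runif(n)
  # conditional on X >= 1: S(x)/S(1) = u  =>  x = ((alpha - log u)/alpha)^(1/beta)
  x <- ((alpha - log(u)) / alpha)^(1 / beta)
  if (discrete) floor(x) else x
}

# Double-cosinor intensity envelope (counts/min), clipped at zero.
cosinor_envelope <- function(t_min, truth) {
  pmax(0, truth[["M"]] +
         truth[["A24"]] * cos(OMEGA24 * t_min + truth[["phi24"]]) +
         truth[["A12"]] * cos(OMEGA12 * t_min + truth[["phi12"]]))
}

#' Generate one synthetic subject recording
#'
#' Builds an alternating rest/active bout chain (truncated-Pareto rests,
#' stretched-exponential active bouts), then draws counts: negative-binomial
#' noise around the double-cosinor envelope inside active bouts, low-rate
#' Poisson counts inside rest bouts, with lights-off intensities multiplied
#' by \code{night_suppression}. Deterministic given
#' \code{(config$seed, subject_seed)}.
#'
#' @param config a \code{synth_config}.
#' @param group \code{"UE"} or \code{"VPA"}.
#' @param subject_seed integer distinguishing the subject's RNG substream.
#' @return an \code{epoch_series} of \code{n_days} complete days starting at
#'   local midnight.
#' @export
generate_subject <- function(config, group = c("UE", "VPA"),
                             subject_seed = 1L) {
  group <- match.arg(group)
  stopifnot(inherits(config, "synth_config"))
  set.seed(mix_seed(config$seed, subject_seed))
  n_epochs <- config$n_days * (1440L %/% config$epoch_length)
  f <- exp(rnorm(1, 0, config$activity_cv))

  # alternating bout chain covering the recording; TRUE marks rest epochs.
  # Each chunk appends complete (first-state, second-state) bout pairs so
  # alternation is preserved across chunks.
  start_active <- runif(1) < 0.5
  is_rest <- logical(0)
  while (length(is_rest) < n_epochs) {
    k <- 4000L
    rests <- rtrunc_pareto(k, config$rest_gamma[[group]],
                           config$rest_min, config$rest_max)
    actives <- rstretched_active(k, config$active_alpha[[group]],
                                 config$active_beta[[group]])
    rests <- pmax(1L, as.integer(round(rests / config$epoch_length)))
    actives <- pmax(1L, as.integer(round(actives / config$epoch_length)))
    durs <- integer(2L * k); states <- logical(2L * k)
    odd <- seq(1L, 2L * k, by = 2L); even <- odd + 1L
    if (start_active) {
      durs[odd] <- actives; states[odd] <- FALSE
      durs[even] <- rests; states[even] <- TRUE
    } else {
      durs[odd] <- rests; states[odd] <- TRUE
      durs[even] <- actives; states[even] <- FALSE
    }
    is_rest <- c(is_rest, rep(states, times = durs))
  }
  is_rest <- is_rest[seq_len(n_epochs)]

  t_min <- (seq_len(n_epochs) - 1L) * config$epoch_length
  env <- cosinor_envelope(t_min %% 1440, config$cosinor_truth[[group]])
  mod <- t_min %% 1440
  on <- parse_clock(config$lights_on); off <- parse_clock(config$lights_off)
  night <- !(mod >= on & mod < off)
  fac <- ifelse(night, config$night_suppression, 1)

  counts <- integer(n_epochs)
  act_idx <- which(!is_rest)
  mu_act <- env[act_idx] * f * config$active_gain * fac[act_idx]
  counts[act_idx] <- rnbinom(length(act_idx),
                             size = config$dispersion[[group]],
                             mu = mu_act)
  rest_idx <- which(is_rest)
  counts[rest_idx] <- rpois(length(rest_idx),
                            config$rest_intensity * f * fac[rest_idx])
  epoch_series(counts, config$start_time,
               epoch_length = config$epoch_length,
               subject_id = sprintf("%s%02d", group, subject_seed),
               lights_on = config$lights_on, lights_off = config$lights_off)
}

#' Generate a full synthetic cohort
#'
#' Generates \code{n_subjects_per_group} recordings per group plus a subject
#' metadata table and per-subject salivary cortisol records linearly coupled
#' to mean hourly activity. When \code{cortisol_noise_sd} is NULL the noise
#' SD is calibrated from the realized between-subject SD of activity so that
#' the population correlation equals \code{cortisol_target_r}.
#'
#' @param config a \code{synth_config}.
#' @return list with \code{series} (named list of \code{epoch_series}),
#'   \code{subjects} (data.frame), \code{cortisol} (per-sample data.frame in
#'   the cortisol CSV dialect) and \code{truth} (per-subject generator-level
#'   values useful for recovery tests).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  groups <- rep(c("UE", "VPA"), each = config$n_subjects_per_group)
  seeds <- c(seq_len(config$n_subjects_per_group),
             100L + seq_len(config$n_subjects_per_group))
  series <- Map(function(g, s) generate_subject(config, g, s), groups, seeds)
  ids <- unname(vapply(series, function(s) s$subject_id, character(1)))
  names(series) <- ids

  set.seed(mix_seed(config$seed, 900001L))
  subjects <- data.frame(
    animal_id = ids, group = groups,
    sex = "M",
    age_weeks = round(runif(length(ids), 104, 252)),
    weight_g = round(rnorm(length(ids), 420, 50), 1),
    stringsAsFactors = FALSE)

  act <- unname(vapply(series, function(s) 60 * mean(s$counts), numeric(1)))
  noise_sd <- config$cortisol_noise_sd
  r_t <- config$cortisol_target_r
  if (is.null(noise_sd)) {
    s_act <- sd(act)
    noise_sd <- if (is.na(s_act) || s_act == 0 || is.null(r_t) || r_t >= 1) 0
      else config$cortisol_slope * s_act * sqrt(1 / r_t^2 - 1)
  }
  cort_mean <- config$cortisol_intercept + config$cortisol_slope * act +
    rnorm(length(act), 0, noise_sd)
  cort_mean <- pmax(cort_mean, 0.01)
  cortisol <- do.call(rbind, lapply(seq_along(ids), function(i) {
    jit <- rnorm(3, 0, 0.05)
    jit <- jit - mean(jit)  # samples average exactly to the subject value
    data.frame(animal_id = ids[i],
               label = paste0("month", 1:3),
               value_ugdl = pmax(cort_mean[i] + jit, 0),
               stringsAsFactors = FALSE)
  }))
  list(series = series, subjects = subjects, cortisol = cortisol,
       truth = data.frame(animal_id = ids, group = groups,
                          mean_hourly_activity = unname(act),
                          cortisol_ugdl = unname(cort_mean),
                          stringsAsFactors = FALSE))
}

#' Generate synthetic three-chamber trials
#'
#' Dwell-time percentages are Dirichlet draws around group propensities
#' (stranger, empty, center), with subject-level propensity heterogeneity;
#' transition counts are Poisson with a group rate optionally coupled to the
#' subject's stranger propensity (negative coupling reproduces the observed
#' inverse transitions-sociability relation).
#'
#' @param n_per_group subjects per group (default 5).
#' @param n_trials trials per subject (default 5, weekly at ages 15-19
#'   weeks).
#' @param preference_truth named list (UE, VPA) of propensities
#'   c(stranger, empty, center) summing to 1.
#' @param transition_rate named per-group mean transition count.
#' @param transition_coupling log-linear coupling of the subject transition
#'   rate to (subject - group) stranger propensity; negative by default.
#' @param concentration_subject,concentration_trial Dirichlet concentrations
#'   controlling between-subject and between-trial dwell variability.
#' @param seed RNG seed.
#' @return data.frame in the three-chamber CSV dialect plus \code{group},
#'   \code{sex} and \code{age_weeks} columns (ages 15..19 across trials).
#' @export
generate_three_chamber <- function(n_per_group = 5L, n_trials = 5L,
                                   preference_truth = list(
                                     UE = c(stranger = 0.50, empty = 0.25,
                                            center = 0.25),
                                     VPA = c(stranger = 0.35, empty = 0.33,
                                             center = 0.32)),
                                   transition_rate = c(UE = 40, VPA = 65),
                                   transition_coupling = -6,
                                   concentration_subject = 60,
                                   concentration_trial = 120,
                                   seed = 1L) {
  for (g in names(preference_truth)) {
    if (abs(sum(preference_truth[[g]]) - 1) > 1e-8) {
      stop("propensities for group ", g, " must sum to 1")
    }
  }
  set.seed(mix_seed(seed, 777L))
  rdirichlet1 <- function(alpha) {
    g <- rgamma(length(alpha), shape = alpha)
    g / sum(g)
  }
  sexes <- c("M", "M", "F", "F", "F")
  rows <- list()
  for (g in c("UE", "VPA")) {
    p_g <- preference_truth[[g]]
    for (i in seq_len(n_per_group)) {
      p_i <- rdirichlet1(concentration_subject * p_g)
      lam <- transition_rate[[g]] *
        exp(transition_coupling * (p_i[1] - p_g[["stranger"]]))
      for (tr in seq_len(n_trials)) {
        p_t <- rdirichlet1(concentration_trial * p_i)
        rows[[length(rows) + 1L]] <- data.frame(
          animal_id = sprintf("J%s%02d", g, i), group = g,
          sex = sexes[(i - 1L) %% length(sexes) + 1L],
          trial = tr, age_weeks = 14L + tr,
          pct_stranger = 100 * p_t[1], pct_empty = 100 * p_t[2],
          pct_center = 100 * p_t[3],
          transitions = rpois(1, lam),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
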