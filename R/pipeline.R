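#' Run configuration for the end-to-end pipeline
#'
#' Bundles the input mode (synthetic cohort or a directory of CSV files)
#' with the per-module parameter blocks. All blocks are validated before any
#' computation starts.
#'
#' @param input_mode \code{"synthetic"} or \code{"csv_dir"}.
#' @param synth a \code{synth_config} (required in synthetic mode).
#' @param csv_dir directory holding \code{activity_<id>.csv} files plus
#'   \code{subjects.csv} and optionally \code{cortisol.csv} (csv_dir mode).
#' @param cosinor_components,cosinor_per_day cosinor block.
#' @param rest_range,active_range,threshold_mode,boundary bout block.
#' @param entropy_m,entropy_r,entropy_scope entropy block.
#' @param seed master seed (overrides \code{synth$seed} when given).
#' @return validated list of class \code{run_config}.
#' @export
run_config <- function(input_mode = c("synthetic", "csv_dir"),
                       synth = synth_config(),
                       csv_dir = NULL,
                       cosinor_components = "double",
                       cosinor_per_day = TRUE,
                       rest_range = c(3, 30),
                       active_range = c(10, 100),
                       threshold_mode = "overall",
                       boundary = "drop_censored",
                       entropy_m = 2L, entropy_r = 0.2,
                       entropy_scope = "per_day",
                       seed = NULL) {
  input_mode <- match.arg(input_mode)
  if (input_mode == "synthetic") {
    stopifnot(inherits(synth, "synth_config"))
    if (!is.null(seed)) synth$seed <- as.integer(seed)
  } else {
    if (is.null(csv_dir) || !dir.exists(csv_dir)) {
      stop("csv_dir mode requires an existing directory")
    }
  }
  stopifnot(cosinor_components %in% c("single", "double"),
            length(rest_range) == 2L, length(active_range) == 2L,
            threshold_mode %in% c("overall", "per_day"),
            boundary %in% c("drop_censored", "keep_all"),
            entropy_m >= 1L, entropy_r > 0,
            entropy_scope %in% c("per_day", "concatenated"))
  structure(list(input_mode = input_mode, synth = synth, csv_dir = csv_dir,
                 cosinor_components = cosinor_components,
                 cosinor_per_day = cosinor_per_day,
                 rest_range = rest_range, active_range = active_range,
                 threshold_mode = threshold_mode, boundary = boundary,
                 entropy_m = as.integer(entropy_m), entropy_r = entropy_r,
                 entropy_scope = entropy_scope,
                 seed = if (is.null(seed)) synth$seed else as.integer(seed)),
            class = "run_config")
}

# All activity parameters of one subject, as a one-row data.frame.
analyze_subject <- function(series, cfg) {
  stats_all <- summary_stats(series, include_nocturnal = TRUE)
  stats_day <- summary_stats(series, include_nocturnal = FALSE)
  cs <- daily_cosinor_summary(series, components = "single")
  cd <- daily_cosinor_summary(series, components = "double")
  thr <- activity_threshold(series, mode = cfg$threshold_mode)
  thr_use <- if (cfg$threshold_mode == "overall") thr else
    mean(thr, na.rm = TRUE)
  bouts <- extract_bouts(series, thr_use, boundary = cfg$boundary)
  rest_fit <- tryCatch(
    fit_rest_powerlaw(survival_curve(bouts$rest_durations), cfg$rest_range),
    error = function(e) NULL)
  active_fit <- tryCatch(
    fit_active_stretched_exp(survival_curve(bouts$active_durations),
                             cfg$active_range),
    error = function(e) NULL)
  ent <- daytime_sampen(series, m = cfg$entropy_m, r = cfg$entropy_r,
                        scope = cfg$entropy_scope)
  data.frame(
    animal_id = series$subject_id,
    mean = stats_all$mean, sd = stats_all$sd,
    skewness = stats_all$skewness, kurtosis = stats_all$kurtosis,
    mean_day = stats_day$mean, sd_day = stats_day$sd,
    skewness_day = stats_day$skewness, kurtosis_day = stats_day$kurtosis,
    mean_hourly_activity = 60 * stats_all$mean,
    M_single = cs$mean_mesor, A24_single = cs$mean_amp24,
    phi24_single = cs$mean_phi24,
    M = cd$mean_mesor, A24 = cd$mean_amp24, phi24 = cd$mean_phi24,
    A12 = cd$mean_amp12, phi12 = cd$mean_phi12,
    threshold = thr_use,
    gamma = if (is.null(rest_fit)) NA_real_ else rest_fit$gamma,
    alpha = if (is.null(active_fit)) NA_real_ else active_fit$alpha,
    beta = if (is.null(active_fit)) NA_real_ else active_fit$beta,
    sampen = ent$mean_sampen,
    stringsAsFactors = FALSE)
}

#' Run the full analysis pipeline
#'
#' Synthesizes or ingests a cohort, runs every analysis stage (basic
#' statistics, single and double cosinor, bout-distribution fits, daytime
#' Sample Entropy), and writes per-subject tables, a group summary in the
#' style of the published parameter table (group mean +/- SD and pooled-t
#' p-value per parameter), a cortisol correlation table, and a JSON
#' manifest. Identical config and seed produce identical outputs.
#'
#' @param config a \code{run_config}.
#' @param out_dir output directory (created if needed).
#' @return (invisibly) list with \code{per_subject}, \code{group_summary},
#'   \code{correlations}, \code{manifest}.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (config$input_mode == "synthetic") {
    cohort <- generate_cohort(config$synth)
    series_list <- cohort$series
    subjects <- cohort$subjects
    cort <- cortisol_subject_means(cohort$cortisol)
  } else {
    subjects <- read_subjects_csv(file.path(config$csv_dir, "subjects.csv"))
    series_list <- lapply(subjects$animal_id, function(id) {
      f <- file.path(config$csv_dir, paste0("activity_", id, ".csv"))
      tryCatch(read_epoch_csv(f, subject_id = id),
               error = function(e) stop("stage ingest, subject ", id, ": ",
                                        conditionMessage(e)))
    })
    names(series_list) <- subjects$animal_id
    cort_path <- file.path(config$csv_dir, "cortisol.csv")
    cort <- if (file.exists(cort_path)) {
      cortisol_subject_means(read_cortisol_csv(cort_path))
    } else NULL
  }

  per_subject <- do.call(rbind, lapply(names(series_list), function(id) {
    tryCatch(analyze_subject(series_list[[id]], config),
             error = function(e) stop("stage analyze, subject ", id, ": ",
                                      conditionMessage(e)))
  }))
  per_subject <- merge(subjects[, c("animal_id", "group")], per_subject,
                       by = "animal_id")

  params <- c("mean", "sd", "skewness", "kurtosis",
              "mean_day", "sd_day", "skewness_day", "kurtosis_day",
              "M_single", "A24_single", "phi24_single",
              "M", "A24", "phi24", "A12", "phi12",
              "gamma", "alpha", "beta", "sampen")
  ue <- per_subject[per_subject$group == "UE", ]
  vpa <- per_subject[per_subject$group == "VPA", ]
  group_summary <- do.call(rbind, lapply(params, function(p) {
    x <- ue[[p]]; y <- vpa[[p]]
    tt <- if (sum(!is.na(x)) >= 2 && sum(!is.na(y)) >= 2) {
      two_sample_t(x[!is.na(x)], y[!is.na(y)])
    } else NULL
    data.frame(parameter = p,
               UE_mean = mean(x, na.rm = TRUE), UE_sd = sd(x[!is.na(x)]),
               VPA_mean = mean(y, na.rm = TRUE), VPA_sd = sd(y[!is.na(y)]),
               p_value = if (is.null(tt)) NA_real_ else tt$p,
               stringsAsFactors = FALSE)
  }))

  correlations <- NULL
  if (!is.null(cort)) {
    m <- merge(per_subject, cort, by = "animal_id")
    cor_row <- function(label, x, y) {
      ok <- !(is.na(x) | is.na(y))
      if (sum(ok) < 3) return(NULL)
      cr <- pearson_with_F(x[ok], y[ok])
      data.frame(pair = label, r = cr$r, F = cr$F, df1 = cr$df1,
                 df2 = cr$df2, p = cr$p, n = cr$n, stringsAsFactors = FALSE)
    }
    correlations <- rbind(
      cor_row("cortisol_vs_mean_hourly_activity",
              m$mean_ugdl, m$mean_hourly_activity),
      cor_row("cortisol_vs_sampen", m$mean_ugdl, m$sampen),
      cor_row("cortisol_vs_gamma", m$mean_ugdl, m$gamma))
  }

  write.csv(per_subject, file.path(out_dir, "per_subject.csv"),
            row.names = FALSE)
  write.csv(group_summary, file.path(out_dir, "group_summary.csv"),
            row.names = FALSE)
  if (!is.null(correlations)) {
    write.csv(correlations, file.path(out_dir, "correlations.csv"),
              row.names = FALSE)
  }
  cfg_for_hash <- config
  cfg_for_hash$synth <- unclass(cfg_for_hash$synth)
  cfg_json <- jsonlite::toJSON(unclass(cfg_for_hash), auto_unbox = TRUE,
                               digits = NA, null = "null")
  manifest <- list(
    package = "restact",
    version = as.character(utils::packageVersion("restact")),
    seed = config$seed,
    config_hash = fnv1a32(as.character(cfg_json)),
    config = jsonlite::fromJSON(cfg_json),
    n_subjects = nrow(per_subject),
    outputs = c("per_subject.csv", "group_summary.csv",
                if (!is.null(correlations)) "correlations.csv"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(per_subject = per_subject, group_summary = group_summary,
                 correlations = correlations, manifest = manifest))
}
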