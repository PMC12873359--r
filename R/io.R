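#' Read a minute-epoch activity CSV
#'
#' Reads the plain-text export dialect used throughout the package: a header
#' \code{timestamp,count}, ISO-8601 timestamps, integer counts. Timestamps
#' must be strictly increasing and equally spaced at \code{epoch_length}
#' minutes; gaps are an error (they are never silently filled).
#'
#' @param path file path.
#' @param epoch_length declared epoch length in minutes.
#' @param subject_id subject identifier; defaults to the file name stem.
#' @param lights_on,lights_off light schedule, as in [epoch_series()].
#' @return an \code{epoch_series}.
#' @export
read_epoch_csv <- function(path, epoch_length = 1L, subject_id = NULL,
                           lights_on = "07:00", lights_off = "19:00") {
  if (!file.exists(path)) stop("file does not exist: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("timestamp", "count") %in% names(df))) {
    stop("expected columns 'timestamp,count' in ", path)
  }
  ts <- parse_timestamp(df$timestamp)
  if (anyNA(ts)) {
    stop("malformed timestamp at data row ", which(is.na(ts))[1], " of ", path)
  }
  cnt <- suppressWarnings(as.numeric(df$count))
  if (anyNA(cnt) || any(cnt != floor(cnt))) {
    stop("malformed count at data row ",
         which(is.na(cnt) | cnt != floor(cnt))[1], " of ", path)
  }
  if (any(cnt < 0)) {
    stop("negative activity count at data row ", which(cnt < 0)[1], " of ", path)
  }
  if (length(ts) > 1L) {
    gaps <- as.numeric(diff(ts), units = "mins")
    bad <- which(gaps != epoch_length)
    if (length(bad) > 0L) {
      stop(sprintf(
        "irregular epoch spacing at data row %d of %s: expected %d min, found %g min",
        bad[1] + 1L, path, as.integer(epoch_length), gaps[bad[1]]))
    }
  }
  if (is.null(subject_id)) subject_id <- sub("\\.[^.]*$", "", basename(path))
  epoch_series(cnt, ts[1], epoch_length = epoch_length,
               subject_id = subject_id, lights_on = lights_on,
               lights_off = lights_off)
}

#' Write an epoch series to CSV
#'
#' Inverse of [read_epoch_csv()]; the round trip is lossless.
#'
#' @param series an \code{epoch_series}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_epoch_csv <- function(series, path) {
  stopifnot(inherits(series, "epoch_series"))
  ts <- series$start_time +
    (seq_along(series$counts) - 1) * 60 * series$epoch_length
  df <- data.frame(
    timestamp = format(ts, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    count = as.integer(series$counts))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a subject metadata table
#'
#' Columns: \code{animal_id,group,sex,age_weeks,weight_g}; one row per subject
#' (or per repeated weighing, as in longitudinal juvenile records, in which
#' case an extra grouping column such as \code{trial} is carried through).
#'
#' @param path file path.
#' @return validated data.frame.
#' @export
read_subjects_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("animal_id", "group", "sex", "age_weeks", "weight_g")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (!all(df$group %in% c("VPA", "UE"))) {
    stop("group must be 'VPA' or 'UE'")
  }
  if (!all(df$sex %in% c("M", "F"))) stop("sex must be 'M' or 'F'")
  if (any(df$age_weeks <= 0) || any(df$weight_g <= 0)) {
    stop("age_weeks and weight_g must be positive")
  }
  df$animal_id <- as.character(df$animal_id)
  df
}

#' Read per-sample salivary cortisol records
#'
#' Columns \code{animal_id,label,value_ugdl}; values in micrograms per
#' deciliter, non-negative.
#'
#' @param path file path.
#' @return data.frame of samples.
#' @export
read_cortisol_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("animal_id", "label", "value_ugdl")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (any(df$value_ugdl < 0)) stop("cortisol values must be non-negative")
  df$animal_id <- as.character(df$animal_id)
  df
}

#' Per-subject mean cortisol
#'
#' Averages each subject's samples, the per-subject reduction used in the
#' cortisol-activity correlation analysis.
#'
#' @param samples data.frame as returned by [read_cortisol_csv()].
#' @return data.frame with \code{animal_id}, \code{n_samples},
#'   \code{mean_ugdl}.
#' @export
cortisol_subject_means <- function(samples) {
  agg <- aggregate(value_ugdl ~ animal_id, data = samples,
                   FUN = function(v) c(n = length(v), m = mean(v)))
  data.frame(animal_id = agg$animal_id,
             n_samples = as.integer(agg$value_ugdl[, "n"]),
             mean_ugdl = as.numeric(agg$value_ugdl[, "m"]),
             stringsAsFactors = FALSE)
}

#' Read three-chamber trial records
#'
#' Columns \code{animal_id,trial,pct_stranger,pct_empty,pct_center,transitions}.
#' Dwell times are percentages of trial time; transitions are non-negative
#' integers.
#'
#' @param path file path.
#' @return validated data.frame.
#' @export
read_three_chamber_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("animal_id", "trial", "pct_stranger", "pct_empty", "pct_center",
           "transitions")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  pct <- df$pct_stranger + df$pct_empty + df$pct_center
  if (any(df$pct_stranger < 0 | df$pct_empty < 0 | df$pct_center < 0)) {
    stop("dwell percentages must be non-negative")
  }
  if (any(pct > 100 + 1e-6)) stop("dwell percentages exceed 100% in a trial")
  if (any(df$transitions < 0 | df$transitions != floor(df$transitions))) {
    stop("transitions must be non-negative integers")
  }
  df$animal_id <- as.character(df$animal_id)
  df
}
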