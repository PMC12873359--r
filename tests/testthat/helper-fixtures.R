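# Fixture builders shared across test files. Everything is generated in code;
# no stored binary data.

MIDNIGHT <- "2024-01-01T00:00:00"
SEVEN_AM <- "2024-01-01T07:00:00"

make_series <- function(counts, start = MIDNIGHT, epoch = 1L, id = "S1",
                        on = "07:00", off = "19:00") {
  epoch_series(counts, start, epoch_length = epoch, subject_id = id,
               lights_on = on, lights_off = off)
}

# One or more days of the double-cosinor model evaluated on a 10-min grid,
# as raw (t, y) vectors. Truth is c(M, A24, phi24, A12, phi12).
model_xy <- function(truth, days = 1, step = 10, noise_sd = 0) {
  t <- seq(0, days * 1440 - step, by = step)
  y <- truth[1] +
    truth[2] * cos(2 * pi / 1440 * t + truth[3]) +
    truth[4] * cos(2 * pi / 720 * t + truth[5])
  if (noise_sd > 0) y <- y + rnorm(length(y), 0, noise_sd)
  list(t = t, y = y)
}

# Published group parameter row used as generator truth in recovery tests
# (10-min aggregated scale).
UE_COSINOR_TRUTH <- c(M = 1569.3, A24 = 1875.2, phi24 = 2.86,
                      A12 = 550.2, phi12 = 3.04)

write_epoch_fixture <- function(lines, path = tempfile(fileext = ".csv")) {
  writeLines(c("timestamp,count", lines), path)
  path
}

# Small but analysis-ready synthetic configuration (fast to generate).
quick_config <- function(seed = 1, n_days = 3, n = 2, ...) {
  synth_config(n_subjects_per_group = n, n_days = n_days, seed = seed, ...)
}
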