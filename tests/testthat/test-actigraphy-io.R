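test_that("read_epoch_csv reads well-formed files and rejects bad ones", {
  p <- write_epoch_fixture(c("2024-01-01T07:00:00,0",
                             "2024-01-01T07:01:00,5",
                             "2024-01-01T07:02:00,2"))
  s <- read_epoch_csv(p)
  expect_s3_class(s, "epoch_series")
  expect_length(s, 3L)
  expect_equal(s$counts, c(0, 5, 2))

  p_neg <- write_epoch_fixture(c("2024-01-01T07:00:00,0",
                                 "2024-01-01T07:01:00,-1"))
  expect_error(read_epoch_csv(p_neg), "negative")

  p_gap <- write_epoch_fixture(c("2024-01-01T07:00:00,1",
                                 "2024-01-01T07:01:00,1",
                                 "2024-01-01T07:03:00,1"))
  expect_error(read_epoch_csv(p_gap), "row 3")

  p_bad <- write_epoch_fixture(c("2024-01-01T07:00:00,1",
                                 "not-a-time,1"))
  expect_error(read_epoch_csv(p_bad), "malformed")
})

test_that("epoch CSV round trip is lossless", {
  set.seed(42)
  s <- make_series(rpois(200, 30), start = "2024-01-03T22:15:00")
  p <- tempfile(fileext = ".csv")
  write_epoch_csv(s, p)
  s2 <- read_epoch_csv(p, subject_id = s$subject_id)
  expect_equal(s2$counts, s$counts)
  expect_equal(s2$start_time, s$start_time)
  expect_equal(s2$epoch_length, s$epoch_length)
})

test_that("split_day_night partitions by the 12:12 light schedule", {
  s <- make_series(rep(1L, 1440), start = SEVEN_AM)
  dn <- split_day_night(s)
  expect_length(dn$day$counts, 720L)
  expect_length(dn$night$counts, 720L)

  # entirely inside 08:00-09:00 -> no night epochs
  s2 <- make_series(rep(2L, 60), start = "2024-01-01T08:00:00")
  dn2 <- split_day_night(s2)
  expect_length(dn2$night$counts, 0L)

  # 48 h -> day view has 1440 epochs
  s3 <- make_series(rep(0L, 2880), start = SEVEN_AM)
  expect_length(split_day_night(s3)$day$counts, 1440L)
})

test_that("split_day_night partition property holds for arbitrary series", {
  set.seed(7)
  for (i in 1:20) {
    n <- sample(10:3000, 1)
    start <- as.POSIXct("2024-01-01", tz = "UTC") + sample(0:86000, 1)
    s <- epoch_series(rpois(n, 5), start)
    dn <- split_day_night(s)
    expect_equal(length(dn$day$counts) + length(dn$night$counts), n)
    expect_length(intersect(dn$day$index, dn$night$index), 0L)
  }
})

test_that("summary_stats follows the documented conventions", {
  # hand-computed: mean 3, sample sd 6
  s <- make_series(c(0, 0, 0, 12))
  st <- summary_stats(s)
  expect_equal(st$mean, 3)
  expect_equal(st$sd, 6)
  expect_equal(st$kurtosis_convention, "excess")

  # constant series: shape statistics undefined, flagged
  sc <- summary_stats(make_series(rep(7L, 100)))
  expect_equal(sc$mean, 7)
  expect_equal(sc$sd, 0)
  expect_true(sc$degenerate)
  expect_true(is.na(sc$skewness) && is.na(sc$kurtosis))

  # day-only recording: with/without nocturnal subsets coincide
  sd_only <- make_series(rpois(120, 20), start = "2024-01-01T09:00:00")
  a <- summary_stats(sd_only, include_nocturnal = TRUE)
  b <- summary_stats(sd_only, include_nocturnal = FALSE)
  expect_equal(a$mean, b$mean)
  expect_equal(a$sd, b$sd)
  expect_equal(a$skewness, b$skewness)

  # order-free: moments agree with direct computation on the vector
  set.seed(1)
  x <- rpois(500, 15)
  s3 <- make_series(x)
  st3 <- summary_stats(s3)
  expect_equal(st3$mean, mean(x))
  expect_equal(st3$sd, sd(x))
})

test_that("hourly_profile averages per-day hourly totals over complete days", {
  # two days; hour T8 totals 100 and 140 -> mean 120
  counts <- integer(2880)
  t8_day1 <- (8 * 60 + 1):(9 * 60)
  counts[t8_day1] <- c(rep(2L, 50), rep(0L, 10))          # total 100
  counts[1440 + t8_day1] <- c(rep(4L, 35), rep(0L, 25))   # total 140
  s <- make_series(counts)
  hp <- hourly_profile(s)
  expect_equal(unname(hp$per_hour_mean[["T8"]]), 120)
  expect_equal(hp$n_days, 2L)

  # single day equals that day's totals
  one <- make_series(rep(1L, 1440))
  expect_equal(unname(hourly_profile(one)$per_hour_mean), rep(60, 24))

  # shifting by exactly 24 h leaves the profile unchanged
  set.seed(3)
  x <- rpois(2880, 10)
  s1 <- make_series(x)
  s2 <- make_series(x, start = "2024-01-02T00:00:00")
  expect_equal(hourly_profile(s1)$per_hour_mean,
               hourly_profile(s2)$per_hour_mean)

  # incomplete day is excluded
  s3 <- make_series(c(x, rep(1000L, 100)))
  expect_equal(hourly_profile(s3)$n_days, 2L)
})

test_that("mean_daily_activity supports both conventions", {
  # day totals 1440 and 2880 -> per-day-total mean 2160, per-epoch mean 1.5
  x <- c(rep(1L, 1440), rep(2L, 1440))
  s <- make_series(x)
  expect_equal(as.numeric(mean_daily_activity(s, "per_day_total")), 2160)
  expect_equal(as.numeric(mean_daily_activity(s, "per_epoch_mean")), 1.5)
  expect_equal(attr(mean_daily_activity(s), "day_totals"), c(1440, 2880))

  # identical days equal the single-day value; all-zero gives 0
  s2 <- make_series(rep(c(0L, 6L), 1440))
  expect_equal(as.numeric(mean_daily_activity(s2)), 3)
  expect_equal(as.numeric(mean_daily_activity(make_series(rep(0L, 1440)))), 0)
  expect_error(mean_daily_activity(make_series(rep(1L, 100))), "complete")
})

test_that("metadata and cortisol readers validate their dialects", {
  adult <- read_subjects_csv(system.file("extdata", "subjects_adult.csv",
                                         package = "restact"))
  expect_equal(nrow(adult), 10L)
  expect_setequal(unique(adult$group), c("VPA", "UE"))

  p <- tempfile(fileext = ".csv")
  writeLines(c("animal_id,label,value_ugdl", "a,m1,2.0", "a,m2,4.0",
               "b,m1,3.0"), p)
  cort <- read_cortisol_csv(p)
  cm <- cortisol_subject_means(cort)
  expect_equal(cm$mean_ugdl[cm$animal_id == "a"], 3.0)
  expect_equal(cm$n_samples, c(2L, 1L))

  writeLines(c("animal_id,label,value_ugdl", "a,m1,-2.0"), p)
  expect_error(read_cortisol_csv(p), "non-negative")
})
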