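test_that("generation is deterministic and respects basic invariants", {
  cfg <- quick_config(seed = 5, n_days = 2)
  a <- generate_subject(cfg, "UE", 3L)
  b <- generate_subject(cfg, "UE", 3L)
  expect_identical(a$counts, b$counts)
  expect_false(identical(generate_subject(cfg, "UE", 4L)$counts, a$counts))

  expect_length(a, 2 * 1440L)
  expect_true(all(a$counts >= 0))
  expect_true(all(a$counts == floor(a$counts)))
  expect_equal(a$lights_on, 7 * 60L)
  expect_equal(a$lights_off, 19 * 60L)
  expect_length(restact:::complete_days(a), 2L)
})

test_that("night_suppression = 0 silences the dark period", {
  cfg <- quick_config(seed = 6, n_days = 1, night_suppression = 0)
  s <- generate_subject(cfg, "VPA", 1L)
  night <- split_day_night(s)$night
  expect_true(all(night$counts == 0))
})

test_that("infeasible configurations are rejected", {
  expect_error(synth_config(rest_min = 100, rest_max = 50), "rest_min")
  expect_error(synth_config(night_suppression = 1.5), "night_suppression")
  expect_error(synth_config(rest_gamma = c(UE = -1, VPA = 1)), "rest_gamma")
})

test_that("sampled rest durations recover the survival exponent within 0.1", {
  # a 10-subject, 22-day cohort yields roughly n_bouts rest draws; emulate
  # that scale directly from the duration law, over 3 seeds
  for (seed in 1:3) {
    set.seed(seed)
    d <- rtrunc_pareto(15000, 1.38, 2, 480)
    g <- fit_rest_powerlaw(survival_curve(d))$gamma
    expect_equal(g, 1.38, tolerance = 0.1 / 1.38)
  }
})

test_that("cohort cortisol coupling behaves at the slope extremes", {
  # zero noise, positive slope -> r = 1 up to rounding
  cfg0 <- quick_config(seed = 8, n_days = 1, n = 3, cortisol_noise_sd = 0)
  co <- generate_cohort(cfg0)
  m <- merge(cortisol_subject_means(co$cortisol), co$truth, by = "animal_id")
  expect_equal(pearson_with_F(m$mean_ugdl, m$mean_hourly_activity)$r, 1,
               tolerance = 1e-6)

  # slope = 0 decouples cortisol from activity: |r| mostly small at n = 6
  rs <- vapply(1:20, function(sd) {
    cfg <- quick_config(seed = sd, n_days = 1, n = 3, cortisol_slope = 0,
                        cortisol_noise_sd = 1)
    co <- generate_cohort(cfg)
    m <- merge(cortisol_subject_means(co$cortisol), co$truth,
               by = "animal_id")
    pearson_with_F(m$mean_ugdl, m$mean_hourly_activity)$r
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.35)
  # null-correlation magnitudes are rarely extreme at n = 6
  expect_gt(mean(abs(rs) < 0.9), 0.8)
})

test_that("default cohort hourly profile is bimodal with the dip nearest T13", {
  # envelope oracle: the hourly argmin of the generating envelope sits at T13
  cfg <- synth_config(seed = 9)
  t <- 0:1439
  env <- restact:::cosinor_envelope(t, cfg$cosinor_truth$UE)
  env_hour <- tapply(env, t %/% 60, mean)[10:18]  # T9..T17
  expect_equal(as.integer(names(which.min(env_hour))), 13L)

  # a full-scale cohort group (5 subjects x 22 days) reproduces it within the
  # 1 h bin discretization
  profs <- vapply(1:5, function(i) {
    hourly_profile(generate_subject(cfg, "UE", i))$per_hour_mean
  }, numeric(24))
  gm <- rowMeans(profs)
  interior <- gm[paste0("T", 9:17)]
  expect_true(names(which.min(interior)) %in% c("T12", "T13", "T14"))
  # morning rise: T9 above the midday dip
  expect_gt(gm[["T9"]], gm[["T13"]])
})

test_that("three-chamber generator honors propensities and coupling", {
  # near-zero noise: SPI forced to 0.4 by the (0.6, 0.2, 0.2) propensities
  tr <- generate_three_chamber(
    n_per_group = 2, preference_truth = list(
      UE = c(stranger = .6, empty = .2, center = .2),
      VPA = c(stranger = .6, empty = .2, center = .2)),
    concentration_subject = 1e7, concentration_trial = 1e7, seed = 1)
  spi <- social_preference_index(tr$pct_stranger, tr$pct_empty)
  expect_equal(spi, rep(0.4, nrow(tr)), tolerance = 1e-2)

  # equal propensities: mean SPI near 0
  spis <- vapply(1:10, function(sd) {
    tr <- generate_three_chamber(
      preference_truth = list(UE = c(stranger = 1, empty = 1, center = 1) / 3,
                              VPA = c(stranger = 1, empty = 1, center = 1) / 3),
      seed = sd)
    mean(social_preference_index(tr$pct_stranger, tr$pct_empty))
  }, numeric(1))
  expect_lt(abs(mean(spis)), 0.05)

  # negative transition-propensity coupling -> negative recovered correlation
  signs <- vapply(1:10, function(sd) {
    tr <- generate_three_chamber(seed = sd, transition_coupling = -8)
    rep3 <- three_chamber_report(tr)
    sign(rep3$cor_transitions_stranger$r)
  }, numeric(1))
  expect_gte(mean(signs < 0), 0.9)

  expect_error(generate_three_chamber(
    preference_truth = list(UE = c(stranger = .5, empty = .2, center = .2),
                            VPA = c(stranger = .4, empty = .3, center = .3))),
    "sum to 1")
})

test_that("cohort output tables are consistent with each other", {
  cfg <- quick_config(seed = 10, n_days = 1, n = 2)
  co <- generate_cohort(cfg)
  expect_length(co$series, 4L)
  expect_setequal(co$subjects$animal_id, names(co$series))
  expect_equal(nrow(co$cortisol), 12L)  # 3 samples per subject
  cm <- cortisol_subject_means(co$cortisol)
  m <- merge(cm, co$truth, by = "animal_id")
  expect_equal(m$mean_ugdl, m$cortisol_ugdl, tolerance = 1e-9)
})
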