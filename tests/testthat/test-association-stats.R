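test_that("pooled t-test matches closed forms and the reference oracle", {
  r0 <- two_sample_t(c(5, 6, 7), c(5, 6, 7))
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)

  r1 <- two_sample_t(c(1, 2, 3), c(2, 3, 4))
  expect_equal(r1$t, -1.2247, tolerance = 1e-4)
  expect_equal(r1$df, 4)
  expect_equal(r1$p, 0.2878, tolerance = 1e-3)

  # oracle: stats::t.test with var.equal = TRUE on random data
  set.seed(30)
  for (i in 1:10) {
    a <- rnorm(sample(3:12, 1)); b <- rnorm(sample(3:12, 1), 0.5)
    ours <- two_sample_t(a, b)
    ref <- t.test(a, b, var.equal = TRUE)
    expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
    w <- two_sample_t(a, b, welch = TRUE)
    refw <- t.test(a, b)
    expect_equal(w$t, unname(refw$statistic), tolerance = 1e-12)
    expect_equal(w$df, unname(refw$parameter), tolerance = 1e-9)
  }

  # degenerate: zero variance with unequal means
  dg <- two_sample_t(c(1, 1), c(2, 2))
  expect_true(dg$degenerate)
  expect_true(is.na(dg$p))
})

test_that("pearson_with_F reports the F-equivalent of Pearson r", {
  x <- 1:6
  pf1 <- pearson_with_F(x, 2 * x + 3)
  expect_equal(pf1$r, 1)
  expect_equal(pf1$F, Inf)
  expect_equal(pf1$p, 0)

  # printed-caption consistency: F(1,7) = 7.6770 implies r = 0.72
  expect_equal(round(r_from_F(7.6770, 7), 2), 0.72)

  # oracle: full regression F test on random 9-point data
  set.seed(31)
  for (i in 1:10) {
    x <- rnorm(9); y <- 0.7 * x + rnorm(9)
    ours <- pearson_with_F(x, y)
    ref <- summary(lm(y ~ x))
    expect_equal(ours$F, unname(ref$fstatistic[1]), tolerance = 1e-10)
    expect_equal(ours$p, unname(pf(ref$fstatistic[1], 1, 7,
                                   lower.tail = FALSE)), tolerance = 1e-10)
    expect_equal(abs(ours$r), sqrt(ref$r.squared), tolerance = 1e-10)
    # symmetry and internal consistency
    sym <- pearson_with_F(y, x)
    expect_equal(sym$r, ours$r, tolerance = 1e-12)
    expect_equal(sym$F, ours$F, tolerance = 1e-9)
    expect_equal(ours$F, ours$r^2 * ours$df2 / (1 - ours$r^2),
                 tolerance = 1e-9)
  }
  expect_error(pearson_with_F(rep(1, 5), rnorm(5)), "variance")
})

test_that("group_hour_anova matches the aov split-plot oracle", {
  set.seed(32)
  n <- 4; H <- 6
  profiles <- matrix(rnorm(2 * n * H, 100, 10), ncol = H)
  profiles[5:8, 2] <- profiles[5:8, 2] + 15  # some group x hour structure
  grp <- rep(c("UE", "VPA"), each = n)
  ours <- group_hour_anova(profiles, grp)

  long <- data.frame(
    y = as.vector(profiles),
    hour = factor(rep(seq_len(H), each = 2 * n)),
    group = factor(rep(grp, H)),
    subject = factor(rep(seq_len(2 * n), H)))
  ref <- summary(aov(y ~ group * hour + Error(subject / hour), data = long))
  f_between <- ref[["Error: subject"]][[1]]
  f_within <- ref[["Error: subject:hour"]][[1]]
  expect_equal(ours$effects$F[ours$effects$effect == "group"],
               f_between["group", "F value"], tolerance = 1e-9)
  expect_equal(ours$effects$F[ours$effects$effect == "hour"],
               f_within["hour", "F value"], tolerance = 1e-9)
  expect_equal(ours$effects$F[ours$effects$effect == "group_x_hour"],
               f_within["group:hour", "F value"], tolerance = 1e-9)
  expect_equal(unname(ours$ss["error"]),
               f_within["Residuals", "Sum Sq"], tolerance = 1e-9)
})

test_that("group_hour_anova degenerate and structured cases behave", {
  set.seed(33)
  # identical group compositions -> group and interaction SS exactly 0
  base <- matrix(rnorm(4 * 24, 50, 5), ncol = 24)
  profiles <- rbind(base, base)
  grp <- rep(c("UE", "VPA"), each = 4)
  res <- group_hour_anova(profiles, grp)
  expect_equal(res$effects$F[1], 0, tolerance = 1e-12)
  expect_equal(res$effects$F[3], 0, tolerance = 1e-12)
  expect_gt(res$effects$p[3], 0.999)

  # pure hour effect: hour significant, group/interaction not (most seeds)
  hits <- replicate(10, {
    hour_eff <- sin(seq_len(24) / 3) * 5
    pr <- t(replicate(10, 100 + hour_eff + rnorm(24, 0, 1))) +
      rnorm(10, 0, 1)  # subject offsets
    g <- rep(c("UE", "VPA"), each = 5)
    res <- group_hour_anova(pr, g)
    p <- res$effects$p
    (p[2] < 0.05) && (p[1] > 0.05) && (p[3] > 0.05)
  })
  expect_gte(mean(hits), 0.7)

  # validation
  expect_error(group_hour_anova(matrix(NA_real_, 4, 24),
                                rep(c("a", "b"), 2)), "missing")
  expect_error(group_hour_anova(matrix(1, 3, 4), c("a", "a", "b")),
               "2 subjects")
})

test_that("Bonferroni post hoc p-values bracket the raw ones", {
  set.seed(34)
  profiles <- matrix(rnorm(10 * 24, 100, 10), ncol = 24)
  res <- group_hour_anova(profiles, rep(c("UE", "VPA"), each = 5))
  expect_true(all(res$posthoc$p_bonferroni >= res$posthoc$p_raw))
  expect_true(all(res$posthoc$p_bonferroni <= 1))
  expect_equal(res$posthoc$p_bonferroni,
               pmin(1, res$posthoc$p_raw * 24))
  expect_true(res$epsilon >= 1 / 23 && res$epsilon <= 1)
})

test_that("social preference index follows its defining formula", {
  expect_equal(social_preference_index(60, 20), 0.4)
  expect_equal(social_preference_index(35, 35), 0)
  expect_equal(social_preference_index(100, 0), 1)
  set.seed(35)
  ps <- runif(50, 0, 100); pe <- runif(50, 0, 100 - ps)
  expect_true(all(abs(social_preference_index(ps, pe)) <= 1))
})

test_that("three_chamber_report reduces trials and compares groups", {
  trials <- data.frame(
    animal_id = rep(c("u1", "u2", "v1", "v2"), each = 1),
    group = rep(c("UE", "UE", "VPA", "VPA")),
    trial = 1L,
    pct_stranger = c(60, 50, 30, 35), pct_empty = c(20, 25, 30, 33),
    pct_center = c(20, 25, 40, 32), transitions = c(20L, 24L, 40L, 44L))
  rep3 <- three_chamber_report(trials)
  # single-trial subjects: per-subject means equal the trial values
  expect_equal(rep3$per_subject$pct_stranger, c(60, 50, 30, 35))
  expect_equal(rep3$per_subject$spi,
               social_preference_index(c(60, 50, 30, 35), c(20, 25, 30, 33)))
  expect_lt(rep3$cor_transitions_stranger$r, 0)
  expect_lt(rep3$t_transitions$t, 0)

  # identical groups -> t = 0, p = 1
  same <- trials
  same$pct_stranger <- 50; same$pct_empty <- 25; same$transitions <- 30L
  reps <- three_chamber_report(same)
  expect_equal(reps$t_spi$t, 0)
  expect_equal(reps$t_spi$p, 1)
})
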