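test_that("intensity classification uses strict cut-points and wear-day denominators", {
  ep <- epochs_from_counts(rep(0, 1440))
  ci <- classify_intensity(ep)
  expect_equal(ci$minutes[["sedentary"]], 1440)
  ## boundary: the higher level starts strictly above the cut-point
  ep2 <- epochs_from_counts(c(100, 101, 2295, 2296, 4011, 4012))
  lv <- classify_intensity(ep2)$level
  expect_equal(as.character(lv),
               c("sedentary", "light", "light", "moderate", "moderate",
                 "vigorous"))
  expect_error(classify_intensity(ep, cutpoints = c(100, 100, 50)),
               "increasing")
})

test_that("bout statistics follow run structure and are sequence-sensitive", {
  ep <- epochs_from_counts(c(rep(0, 5), rep(3000, 3), rep(0, 5)))
  lv <- classify_intensity(ep)$level
  bs <- bout_statistics(lv, ep)
  expect_equal(nrow(bs$bouts), 1)
  expect_equal(bs$mean_bout_s, 180)
  ## no moderate+ epochs -> NaN
  ep0 <- epochs_from_counts(rep(10, 20))
  expect_true(is.nan(bout_statistics(classify_intensity(ep0)$level,
                                     ep0)$mean_bout_s))
  ## alternating moderate/sedentary: 60 s bouts, one per moderate epoch
  ep_alt <- epochs_from_counts(rep(c(3000, 0), 10))
  bs_alt <- bout_statistics(classify_intensity(ep_alt)$level, ep_alt)
  expect_equal(bs_alt$mean_bout_s, 60)
  expect_equal(nrow(bs_alt$bouts), 10)
  ## grouping the same epochs changes the bout structure
  ep_blk <- epochs_from_counts(c(rep(3000, 10), rep(0, 10)))
  bs_blk <- bout_statistics(classify_intensity(ep_blk)$level, ep_blk)
  expect_false(bs_blk$mean_bout_s == bs_alt$mean_bout_s)
})

test_that("Weibull MLE recovers parameters and degenerate limits", {
  set.seed(101)
  x <- rweibull(5000, shape = 1.5, scale = 12.5)
  fit <- weibull_scale(x)
  expect_equal(fit$scale, 12.5, tolerance = 0.3 / 12.5)
  ## independent oracle: MASS::fitdistr on the same sample
  or <- suppressWarnings(MASS::fitdistr(x, "weibull"))
  expect_equal(fit$scale, unname(or$estimate["scale"]), tolerance = 1e-3)
  expect_equal(fit$shape, unname(or$estimate["shape"]), tolerance = 1e-3)
  ## all-equal durations: scale tends to the common value
  fit_d <- weibull_scale(rep(7, 50))
  expect_gt(fit_d$scale, 0.8 * 7)
  expect_lt(fit_d$scale, 1.2 * 7)
  ## exponential special case: scale ~ mean
  set.seed(102)
  e <- rexp(20000, rate = 1 / 10)
  expect_equal(weibull_scale(e)$scale, 10, tolerance = 0.03)
  ## too few bouts
  expect_true(is.nan(weibull_scale(rexp(5))$scale))
})

test_that("Cole-Kripke scores zero counts asleep and isolated spikes awake", {
  expect_true(all(cole_kripke(rep(0, 60))))
  ## one extreme epoch in a zero background: hand-evaluate the weighted score
  counts <- rep(0, 30)
  counts[15] <- 10000
  got <- cole_kripke(counts)
  w <- c(106, 54, 58, 76, 230, 74, 67)
  expected_wake <- vapply(seq_along(counts), function(j) {
    idx <- (j - 4):(j + 2)
    a <- ifelse(idx >= 1 & idx <= 30, counts[pmax(pmin(idx, 30), 1)], 0)
    a[idx < 1 | idx > 30] <- 0
    sum(w * a) * 1e-5 >= 1
  }, TRUE)
  expect_equal(!got, expected_wake)
})

test_that("sleep metrics reproduce hand-built nights", {
  ## two days of epochs; sleep 23:00-07:00 with wake elsewhere (wake counts
  ## of 300/min score awake without bleeding into neighbouring sleep epochs)
  n <- 2 * 1440
  counts <- rep(300, n)
  sl <- (23 * 60):(31 * 60 - 1)              # minutes 1380..1859
  counts[sl + 1] <- 0
  ep <- epochs_from_counts(counts, vm = counts)
  sm <- sleep_period_and_metrics(cole_kripke(counts), ep)
  expect_equal(nrow(sm$nights), 1)
  expect_equal(sm$summary[["tst_min"]], 480)
  expect_equal(sm$summary[["sleep_eff_pct"]], 100)
  expect_equal(sm$summary[["wakeup_min"]], 420)
  ## two 10-min awakenings: efficiency 100*460/480
  counts2 <- counts
  counts2[(24 * 60):(24 * 60 + 9) + 1] <- 300
  counts2[(26 * 60):(26 * 60 + 9) + 1] <- 300
  sm2 <- sleep_period_and_metrics(cole_kripke(counts2),
                                  epochs_from_counts(counts2, vm = counts2))
  expect_equal(sm2$summary[["awake_min"]], 20)
  expect_equal(sm2$summary[["time_per_awakening_min"]], 10)
  expect_equal(sm2$summary[["sleep_eff_pct"]], 100 * 460 / 480,
               tolerance = 1e-6)
})

test_that("rendered wake-up time is recovered within one epoch", {
  cfg <- small_config(seed = 37)
  p <- profile_with(truth = c(wakeup_min = 388), seed = 37, config = cfg)
  f <- actigraphy_features(render_actigraphy(p, cfg))
  expect_lt(abs(f[["wakeup_min"]] - 388), 1 + 1e-9)
  ## group-level direction: later wake-up renders recover a later time
  p2 <- profile_with(truth = c(wakeup_min = 438), seed = 38, group = "controlled",
                     config = small_config(seed = 38))
  f2 <- actigraphy_features(render_actigraphy(p2, small_config(seed = 38)))
  expect_gt(f2[["wakeup_min"]], f[["wakeup_min"]] + 30)
})

test_that("scoring agrees with rendered sleep states and zero awakenings give 100% efficiency", {
  cfg <- small_config(seed = 41)
  p <- profile_with(seed = 41, config = cfg)
  p$n_awakenings <- 1L
  p$truth["awake_min"] <- 1
  p$truth["tst_min"] <- 480
  act <- render_actigraphy(p, cfg)
  truth <- attr(act, "truth")
  sl <- cole_kripke(act$axis1)
  ## epoch-level agreement on the sleep windows
  night <- which(truth$state %in% c("sleep", "awakening"))
  agree <- mean(sl[night] == truth$asleep[night])
  expect_gte(agree, 0.9)
  f <- actigraphy_features(act)
  expect_gte(f[["sleep_eff_pct"]], 99)
})

test_that("estimated total sleep time tracks the truth across subjects", {
  cfg <- cohort_config(group_sizes = c(uncontrolled = 40, controlled = 40,
                                       non_asthmatic = 40), seed = 43)
  prof <- generate_cohort(cfg)
  est <- numeric(length(prof)); tru <- numeric(length(prof))
  for (i in seq_along(prof)) {
    f <- actigraphy_features(render_actigraphy(prof[[i]], cfg))
    est[i] <- f[["tst_min"]]
    tru[i] <- prof[[i]]$truth[["tst_min"]]
  }
  slope <- coef(lm(est ~ tru))[2]
  expect_gt(slope, 0.9)
  expect_lt(slope, 1.1)
})

test_that("sleep metrics ignore appended fully non-worn days", {
  cfg <- small_config(seed = 47)
  p <- profile_with(seed = 47, config = cfg)
  act <- render_actigraphy(p, cfg)
  f1 <- actigraphy_features(act)
  extra <- act[1:1440, ]
  extra$epoch_start_s <- max(act$epoch_start_s) + 60 * seq_len(1440)
  extra$wear <- FALSE
  act2 <- rbind(act, extra)
  class(act2) <- class(act)
  f2 <- actigraphy_features(act2)
  keep <- c("wakeup_min", "tst_min", "awake_min", "sleep_eff_pct",
            "moderate_min", "vigorous_min")
  expect_equal(f1[keep], f2[keep], tolerance = 1e-8)
})
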