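test_that("cohort generation is deterministic given config and seed", {
  cfg <- small_config(seed = 11)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$features, b$features)
  expect_identical(a$bundles[[1]]$ecg$segments$day$samples,
                   b$bundles[[1]]$ecg$segments$day$samples)
  expect_identical(a$bundles[[2]]$actigraphy$axis1,
                   b$bundles[[2]]$actigraphy$axis1)
  expect_identical(a$bundles[[3]]$inhaler, b$bundles[[3]]$inhaler)
})

test_that("zero-scale specs collapse every subject onto the location", {
  cfg <- small_config(seed = 2)
  cfg$specs$p2 <- 0
  prof <- generate_cohort(cfg)
  unc <- Filter(function(p) p$group == "uncontrolled", prof)
  v <- vapply(unc, function(p) p$truth[["pre_fev1_pct"]], 0)
  expect_true(all(v == v[1]))
  expect_equal(v[1], 82.2)
  ## lognormal at sdlog 0 gives the median
  w <- vapply(unc, function(p) p$truth[["rr_recovery_s"]], 0)
  expect_equal(unname(w), rep(60.7, length(w)), tolerance = 1e-6)
})

test_that("group means and medians converge to the configured values", {
  cfg <- cohort_config(group_sizes = c(uncontrolled = 1000, controlled = 1000,
                                       non_asthmatic = 1000), seed = 31)
  pf <- profile_features(generate_cohort(cfg))
  unc <- pf[pf$group == "uncontrolled", ]
  ctl <- pf[pf$group == "controlled", ]
  ## mean FEV1 variation within 3 SE of its configured 18.0 (uncontrolled)
  se <- 10.3 / sqrt(nrow(unc))
  expect_lt(abs(mean(unc$fev1_variation_pct) - 18.0), 3 * se + 0.35)
  ## normal-family parameters: means within 3 SE (+ small truncation slack)
  checks <- list(c("pre_fev1_pct", 82.2, 16.0), c("moderate_min", 97, 35),
                 c("daytime_rr", 19.7, 2.9), c("night_rr", 17.5, 2.6),
                 c("awake_min", 59.9, 19.9))
  for (ch in checks) {
    m <- mean(unc[[ch[1]]])
    tol <- 3 * as.numeric(ch[3]) / sqrt(nrow(unc)) + 0.05 * as.numeric(ch[3])
    expect_lt(abs(m - as.numeric(ch[2])), tol)
  }
  ## log-normal parameters: medians near the configured medians
  expect_lt(abs(median(unc$rr_recovery_s) - 60.7), 6)
  expect_lt(abs(median(ctl$rr_recovery_s) - 23.1), 2.5)
  expect_lt(abs(median(unc$wakeup_min) - 388), 5)
  expect_lt(abs(median(ctl$wakeup_min) - 438), 5)
  expect_lt(abs(median(unc$reliever_total) - 16.5), 4)
})

test_that("missingness injection masks the exact cell count", {
  x <- as.data.frame(matrix(rnorm(590), 59, 10))
  x$subject_id <- sprintf("S%02d", 1:59)
  x0 <- apply_missingness(x, 0)
  expect_identical(x0[, 1:10], x[, 1:10])
  x1 <- apply_missingness(x, 0.115, seed = 5)
  expect_equal(sum(is.na(x1[, 1:10])), 68)   # round(0.115 * 590)
  expect_false(anyNA(x1$subject_id))
  x2 <- apply_missingness(x, 0.115, seed = 5)
  expect_identical(x1, x2)                    # deterministic given seed
})

test_that("monotone missingness passes the monotonicity check", {
  x <- matrix(rnorm(300), 30, 10)
  xm <- apply_missingness(x, 0.2, seed = 9, pattern = "monotone")
  expect_equal(sum(is.na(xm)), 60)
  chk <- monotonicity_check(is.na(xm))
  expect_true(chk$monotone)
})

test_that("spirometry attempt volume and acceptance match the study conditions", {
  cfg <- cohort_config(group_sizes = c(uncontrolled = 200, controlled = 200,
                                       non_asthmatic = 200), seed = 13)
  prof <- generate_cohort(cfg)
  att <- 0; acc <- 0; per_subj <- numeric(length(prof))
  for (i in seq_along(prof)) {
    inh <- render_inhaler_log(prof[[i]], cfg)
    sp <- render_spirometry_events(prof[[i]], cfg,
                                   inh$time_s[inh$type == "reliever"])
    qc <- qc_maneuver(sp)
    att <- att + nrow(sp)
    acc <- acc + sum(qc$accepted)
    per_subj[i] <- nrow(sp)
  }
  ## ~nine attempts per child over the two weeks
  expect_gt(mean(per_subj), 7)
  expect_lt(mean(per_subj), 11)
  ## acceptance rate 73.9% +/- 1.5 percentage points at ~1600 attempts
  expect_gt(att, 1000)
  expect_lt(abs(100 * acc / att - 73.9), 1.5)
})

test_that("controller adherence recovery: rendered mean tracks an 81.1% target", {
  cfg <- cohort_config(group_sizes = c(uncontrolled = 500, controlled = 0,
                                       non_asthmatic = 0), seed = 17)
  prof <- generate_cohort(cfg)
  vals <- vapply(prof, function(p) {
    p$truth["controller_adherence_pct"] <- 81.1
    ev <- render_inhaler_log(p, cfg)
    controller_adherence(ev, cfg$inhaler$doses_per_day,
                         p$monitoring_days)$adherence_pct
  }, 0)
  expect_lt(abs(mean(vals) - 81.1), 2)
})

test_that("inhaler renderer honours perfect adherence exactly", {
  p <- profile_with(truth = c(controller_adherence_pct = 100,
                              reliever_total = 0,
                              reliever_before_activity = 0,
                              reliever_after_activity = 0))
  ev <- render_inhaler_log(p, small_config())
  expect_equal(sum(ev$type == "controller"), 28)   # 2/day x 14 days
})

test_that("ECG rendering validates its window preconditions", {
  p <- profile_with(seed = 3)
  p$exercise_schedule$start_s <- p$exercise_schedule$start_s + 5 * 86400
  p$exercise_schedule$end_s <- p$exercise_schedule$end_s + 5 * 86400
  expect_error(render_ecg(p, small_config()), "ECG window|bout")
  p2 <- profile_with(seed = 3)
  p2$ecg_days <- 0.5
  p2$exercise_schedule$end_s[1] <-
    p2$exercise_schedule$start_s[1] + 0.3 * 86400
  expect_error(render_ecg(p2, small_config()))
})

test_that("sensor bundles survive a CSV round trip", {
  cfg <- small_config(seed = 19, sizes = c(uncontrolled = 1, controlled = 0,
                                           non_asthmatic = 0))
  sim <- simulate_cohort(cfg)
  dir <- file.path(tempdir(), "bundle-rt")
  write_sensor_bundle(sim$bundles[[1]], dir)
  back <- read_sensor_bundle(dir)
  f1 <- extract_features(sim$bundles[[1]], cfg)
  f2 <- extract_features(back, cfg)
  expect_equal(f1, f2, tolerance = 1e-3)
  unlink(dir, recursive = TRUE)
})
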