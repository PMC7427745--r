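test_that("band-pass filter keeps the pass band and kills wander and DC", {
  fs <- 250
  t <- seq(0, 40, by = 1 / fs)
  in_band <- sin(2 * pi * 10 * t)
  y <- bandpass_filter(in_band, fs)
  mid <- seq(10 * fs, 30 * fs)
  expect_lt(abs(max(abs(y[mid])) - 1), 0.01)          # in-band preserved
  wander <- sin(2 * pi * 0.1 * t)
  yw <- bandpass_filter(wander, fs)
  expect_lt(max(abs(yw[mid])), 10^(-20 / 20))          # >= 20 dB attenuation
  dc <- rep(1, length(t))
  expect_lt(abs(mean(bandpass_filter(dc, fs))), 0.01)  # DC removed
  expect_error(bandpass_filter(in_band, 70), "Nyquist")
})

test_that("filter is linear and length-preserving", {
  fs <- 250
  set.seed(4)
  x <- rnorm(20 * fs)
  y1 <- bandpass_filter(x, fs)
  y3 <- bandpass_filter(3 * x, fs)
  expect_equal(y3, 3 * y1, tolerance = 1e-10)
  expect_length(y1, length(x))
})

test_that("beat detection recovers a synthetic train and its RS amplitudes", {
  fs <- 250
  x <- synth_ecg_train(120, hr = 60, fs = fs, r_amp = 1.0, s_amp = 0.3)
  beats <- detect_beats(x, fs)
  expect_lt(abs(nrow(beats) - 120), 2)
  expect_equal(median(beats$rs_amp), 1.3, tolerance = 0.02)
  expect_equal(median(beats$r_amp), 1.0, tolerance = 0.02)
  ## flat signal: empty series, not an error
  expect_equal(nrow(detect_beats(rep(0.1, 10 * fs), fs)), 0)
})

test_that("beat detection is near-perfect on rendered ECG", {
  cfg <- small_config(seed = 23)
  prof <- generate_cohort(cfg)
  sens <- vapply(prof[1:5], function(p) {
    rec <- render_ecg(p, cfg, noise = TRUE)
    seg <- rec$segments$day
    beats <- detect_beats(bandpass_filter(seg$samples, rec$fs), rec$fs,
                          t0 = seg$start_s)
    hits <- vapply(seg$truth_beats, function(b)
      any(abs(beats$time - b) <= 0.05), TRUE)
    mean(hits)
  }, 0)
  expect_gte(min(sens), 0.99)
})

test_that("RS-amplitude respiration recovers the modulation frequency", {
  beats <- structure(data.frame(time = 0:119,
                                r_amp = 1 + 0.3 * sin(2 * pi * 0.25 * 0:119),
                                s_amp = 0,
                                rs_amp = 1 + 0.3 * sin(2 * pi * 0.25 * 0:119)),
                     class = c("beat_series", "data.frame"))
  resp <- derive_respiration(beats)
  expect_equal(median(resp$rr$rr), 15, tolerance = 0.5)
  ## spectral peak of the 50 Hz signal at 0.25 Hz
  v <- resp$signal$value - mean(resp$signal$value)
  sp <- Mod(fft(v))^2
  freq <- (seq_along(v) - 1) / length(v) * 50
  pk <- freq[freq > 0.05 & freq < 2][which.max(sp[freq > 0.05 & freq < 2])]
  expect_equal(pk, 0.25, tolerance = 0.03)
  ## constant RS amplitude: no breaths
  cst <- beats
  cst$rs_amp <- rep(1, nrow(cst))
  expect_equal(nrow(derive_respiration(cst)$rr), 0)
  expect_error(derive_respiration(beats[1:3, ]), "4 beats")
})

test_that("constant-rate segment yields the constructed beat count and EDR", {
  opts <- small_config()$ecg
  seg <- asthmon:::render_ecg_segment(0, 61, function(t) rep(60, length(t)),
                                      function(t) rep(15, length(t)),
                                      opts, noise = FALSE)
  beats <- detect_beats(bandpass_filter(seg$samples[1:(60 * opts$fs)],
                                        opts$fs), opts$fs)
  expect_lt(abs(nrow(beats) - 60), 2)
  resp <- derive_respiration(beats)
  expect_equal(median(resp$rr$rr), 15, tolerance = 0.5)
})

test_that("recovery time matches the analytic 5%-band crossing", {
  mk <- function(tau, b = 20, p = 35, shift = 0) {
    t <- 0:1500
    x <- ifelse(t < 400, b, ifelse(t < 600, p, b + (p - b) *
                                     exp(-(t - 600) / tau))) + shift
    structure(data.frame(t = t, hr = x, rr = x),
              class = c("rate_series", "data.frame"))
  }
  r20 <- recovery_time(mk(20), 400, 600, what = "rr")
  expect_true(r20$converged)
  expect_equal(r20$time_s, -20 * log(0.05), tolerance = 5)
  ## monotone in tau
  taus <- c(10, 20, 40)
  times <- vapply(taus, function(tau)
    recovery_time(mk(tau), 400, 600, what = "rr")$time_s, 0)
  expect_true(all(diff(times) > 0))
  ## invariant under additive shifts
  r_sh <- recovery_time(mk(20, shift = 7), 400, 600, what = "rr")
  expect_equal(r_sh$time_s, r20$time_s)
  ## peak at baseline recovers instantly
  flat <- mk(20, p = 20)
  r0 <- recovery_time(flat, 400, 600, what = "rr")
  expect_equal(r0$time_s, 0)
  expect_true(r0$converged)
})

test_that("day/night summaries average within windows and flag empty ones", {
  t <- c(9 * 3600 + 0:599, 2 * 3600 + 0:599)   # day and night samples
  rates <- structure(data.frame(t = t, hr = rep(80, length(t)),
                                rr = rep(16, length(t))),
                     class = c("rate_series", "data.frame"))
  s <- day_night_summaries(rates)
  expect_equal(unname(s), c(80, 16, 80, 16))
  rates$hr[1:600] <- NA                         # fully masked day window
  s2 <- day_night_summaries(rates)
  expect_true(is.nan(s2[["daytime_hr"]]))
  expect_equal(s2[["night_hr"]], 80)
})

test_that("completeness gate is inclusive at exactly 75%", {
  expect_true(completeness_gate(rep(1, 100)))
  x <- c(rep(1, 749), rep(NA, 251))
  expect_false(completeness_gate(x))
  y <- c(rep(1, 750), rep(NA, 250))
  expect_true(completeness_gate(y))
})

test_that("rendered night respiratory rate is recovered closely", {
  cfg <- small_config(seed = 29)
  p <- profile_with(truth = c(night_rr = 17.5), seed = 29, config = cfg)
  rec <- render_ecg(p, cfg, noise = FALSE)
  f <- ecg_features(rec)
  expect_equal(f[["night_rr"]], 17.5, tolerance = 0.5)
})
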