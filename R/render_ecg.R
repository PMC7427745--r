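## ---------------------------------------------------------------------------
## ECG renderer: stylised single-lead ECG whose beat times follow the
## subject's instantaneous heart rate and whose R/S amplitudes are
## sinusoidally modulated at the instantaneous respiratory rate, so that the
## RS-amplitude respiration surrogate carries a known ground truth.
## ---------------------------------------------------------------------------

## beat times for an instantaneous heart-rate function (bpm) over [t0, t1]
beat_times_from_hr <- function(t0, t1, hrfun) {
  out <- numeric(ceiling((t1 - t0) / (60 / 220)) + 2L)
  t <- t0
  k <- 0L
  while (t < t1) {
    k <- k + 1L
    out[k] <- t
    t <- t + 60 / hrfun(t)
  }
  out[seq_len(k)]
}

## cumulative respiratory phase (rad) for a respiratory-rate function
## (breaths/min) evaluated on a 1 Hz grid, interpolated at arbitrary times
phase_interpolator <- function(t0, t1, rrfun) {
  grid <- seq(t0, t1 + 1, by = 1)
  phase <- 2 * pi * cumsum(rrfun(grid) / 60)  # rad, 1-s steps
  function(t) stats::approx(grid, phase, t, rule = 2)$y
}

## one contiguous ECG segment: QRS-like wavelets (Gaussian R spike, delayed
## Gaussian S dip) at the generated beat times
render_ecg_segment <- function(t0, t1, hrfun, rrfun, opts, noise = TRUE,
                               bout = NULL) {
  fs <- opts$fs
  n <- floor((t1 - t0) * fs)
  tt <- t0 + (seq_len(n) - 1) / fs
  beats <- beat_times_from_hr(t0, t1 - 0.2, hrfun)
  phi <- phase_interpolator(t0, t1, rrfun)
  modb <- 1 + opts$mod_depth * sin(phi(beats))
  r_amp <- opts$r_amp * modb
  s_amp <- opts$s_amp * modb

  x <- numeric(n)
  sd_w <- 0.008                      # s, QRS wavelet width
  half <- ceiling(4 * sd_w * fs)
  offs <- (-half):half
  gauss <- exp(-((offs / fs)^2) / (2 * sd_w^2))
  s_delay <- round(0.040 * fs)       # S dip 40 ms after R
  for (i in seq_along(beats)) {
    c0 <- round((beats[i] - t0) * fs) + 1L
    idx <- c0 + offs
    ok <- idx >= 1L & idx <= n
    x[idx[ok]] <- x[idx[ok]] + r_amp[i] * gauss[ok]
    idx2 <- idx + s_delay
    ok2 <- idx2 >= 1L & idx2 <= n
    x[idx2[ok2]] <- x[idx2[ok2]] - s_amp[i] * gauss[ok2]
  }
  if (noise) {
    x <- x + stats::rnorm(n, 0, opts$noise_sd) +
      opts$wander_amp * sin(2 * pi * opts$wander_freq * tt +
                              stats::runif(1, 0, 2 * pi))
  }
  tg <- seq(t0, t1, by = 1)
  list(start_s = t0, fs = fs, samples = x,
       truth = data.frame(t = tg, hr = hrfun(tg), rr = rrfun(tg)),
       truth_beats = beats,
       bout = bout)
}

## piecewise trajectory: baseline -> linear ramp during the bout -> plateau ->
## exponential return to baseline with time constant tau after bout end
exertion_trajectory <- function(baseline, peak, bout_start, bout_end, tau,
                                ramp_s) {
  force(baseline); force(peak); force(bout_start); force(bout_end)
  force(tau); force(ramp_s)
  function(t) {
    y <- rep(baseline, length(t))
    ramp_end <- min(bout_start + ramp_s, bout_end)
    in_ramp <- t >= bout_start & t < ramp_end
    y[in_ramp] <- baseline + (peak - baseline) *
      (t[in_ramp] - bout_start) / (ramp_end - bout_start)
    in_plateau <- t >= ramp_end & t < bout_end
    y[in_plateau] <- peak
    post <- t >= bout_end
    y[post] <- baseline + (peak - baseline) * exp(-(t[post] - bout_end) / tau)
    y
  }
}

#' Render the ambulatory ECG of a subject
#'
#' Produces a stylised single-lead ECG (default 250 Hz) covering a daytime
#' segment around one exercise bout inside the ECG window (baseline before
#' the bout, heart/respiratory-rate rise during it, exponential return to
#' baseline afterwards) and a night segment. The exponential time constants
#' are chosen as `recovery_time / log(20)` so that the subject's true
#' recovery times correspond exactly to the 5%-of-excursion baseline-crossing
#' definition used by [recovery_time()]. R and S amplitudes are modulated at
#' the instantaneous respiratory rate, which makes the RS-amplitude
#' respiration surrogate recoverable downstream. Gaussian measurement noise
#' and sub-0.45 Hz baseline wander are added unless `noise = FALSE`.
#'
#' @param profile a subject profile.
#' @param config a [cohort_config()]; `config$ecg` holds the renderer options.
#' @param noise add measurement noise and baseline wander?
#' @return object of class `ecg_record`: sampling rate, list of contiguous
#'   segments (`start_s`, `samples` in mV, ground-truth rate traces and beat
#'   times), and the exercise bout covered by the day segment.
#' @export
render_ecg <- function(profile, config = cohort_config(), noise = TRUE) {
  opts <- config$ecg
  tr <- profile$truth
  win_end <- profile$ecg_days * 86400
  sched <- profile$exercise_schedule
  pre_s <- opts$pre_min * 60
  post_s <- opts$post_min * 60
  ok <- sched$start_s - pre_s >= 0 & sched$end_s + post_s <= win_end
  if (!any(ok))
    stop("no exercise bout (with pre/post margins) inside the ECG window")
  longest <- max(sched$end_s - sched$start_s)
  if (win_end < 2 * longest)
    stop("ECG window shorter than twice the longest exercise bout")
  bout <- sched[which(ok)[1], ]

  set.seed(profile$seed + 11L)
  tau_hr <- tr["hr_recovery_s"] / log(20)
  tau_rr <- tr["rr_recovery_s"] / log(20)
  hr_peak <- clip(tr["daytime_hr"] + opts$hr_peak_delta, 60, 215)
  rr_peak <- clip(tr["daytime_rr"] + opts$rr_peak_delta, 10, 58)

  day <- render_ecg_segment(
    bout$start_s - pre_s, bout$end_s + post_s,
    hrfun = exertion_trajectory(tr["daytime_hr"], hr_peak,
                                bout$start_s, bout$end_s, tau_hr, opts$ramp_s),
    rrfun = exertion_trajectory(tr["daytime_rr"], rr_peak,
                                bout$start_s, bout$end_s, tau_rr, opts$ramp_s),
    opts = opts, noise = noise,
    bout = c(start_s = bout$start_s, end_s = bout$end_s))

  night_t0 <- 86400 + opts$night_start_min * 60   # second night, 01:00
  if (night_t0 + opts$night_min * 60 > win_end)
    night_t0 <- opts$night_start_min * 60
  night <- render_ecg_segment(
    night_t0, night_t0 + opts$night_min * 60,
    hrfun = function(t) rep(tr["night_hr"], length(t)),
    rrfun = function(t) rep(tr["night_rr"], length(t)),
    opts = opts, noise = noise)

  structure(list(fs = opts$fs, segments = list(day = day, night = night),
                 bout = c(start_s = bout$start_s, end_s = bout$end_s)),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  tot <- sum(vapply(x$segments, function(s) length(s$samples), 0)) / x$fs
  cat("<ecg_record>", length(x$segments), "segment(s),", x$fs, "Hz,",
      sprintf("%.1f min total\n", tot / 60))
  invisible(x)
}
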