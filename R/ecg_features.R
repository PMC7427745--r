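## ---------------------------------------------------------------------------
## ECG feature extraction: Kaiser-window FIR band-pass, QRS detection,
## RS-amplitude respiration surrogate, uniform heart-/respiratory-rate series,
## day/night summaries and post-exertion recovery times.
## ---------------------------------------------------------------------------

.filter_cache <- new.env(parent = emptyenv())

#' Zero-phase FIR band-pass filter for raw ECG
#'
#' Kaiser-window FIR band-pass (default 0.45-39 Hz) designed for 60 dB
#' stop-band attenuation with a 0.3 Hz transition at the low edge, applied
#' forward with group-delay compensation, so the output is aligned with the
#' input and has the same length.
#'
#' @param x numeric vector of ECG samples (mV).
#' @param fs sampling rate (Hz); must exceed twice the upper cut-off.
#' @param low,high band edges (Hz).
#' @param atten_db stop-band attenuation used for the Kaiser design.
#' @param trans_hz transition bandwidth at the low edge (Hz).
#' @return filtered vector, `length(x)`.
#' @export
bandpass_filter <- function(x, fs, low = 0.45, high = 39, atten_db = 60,
                            trans_hz = 0.3) {
  if (fs <= 2 * high)
    stop("sampling rate ", fs, " Hz is below the Nyquist bound for a ",
         high, " Hz cut-off")
  key <- sprintf("%g_%g_%g_%g_%g", fs, low, high, atten_db, trans_hz)
  b <- .filter_cache[[key]]
  if (is.null(b)) {
    beta <- 0.1102 * (atten_db - 8.7)
    dw <- 2 * pi * trans_hz / fs
    n <- ceiling((atten_db - 7.95) / (2.285 * dw))
    if (n %% 2L == 1L) n <- n + 1L
    b <- signal::fir1(n, c(low, high) / (fs / 2), type = "pass",
                      window = signal::kaiser(n + 1, beta))
    .filter_cache[[key]] <- b
  }
  gd <- (length(b) - 1L) / 2L          # linear-phase group delay, samples
  y <- signal::fftfilt(b, c(x, numeric(gd)))
  y[(gd + 1L):(gd + length(x))]
}

#' Detect QRS complexes and their R/S amplitudes
#'
#' Derivative-energy detector (squared, smoothed first difference with an
#' adaptive threshold and a 200 ms refractory period). For each detection the
#' R amplitude is the local maximum within +/-50 ms and the S amplitude the
#' local minimum within 100 ms after the R wave; the RS amplitude is their
#' difference. A flat signal yields an empty series.
#'
#' @param x filtered ECG samples (mV).
#' @param fs sampling rate (Hz).
#' @param t0 time (s) of the first sample.
#' @param refractory_s minimum beat spacing (s).
#' @return data.frame of class `beat_series`: `time`, `r_amp`, `s_amp`,
#'   `rs_amp` (only beats with positive RS amplitude are kept).
#' @export
detect_beats <- function(x, fs, t0 = 0, refractory_s = 0.2) {
  empty <- structure(data.frame(time = numeric(0), r_amp = numeric(0),
                                s_amp = numeric(0), rs_amp = numeric(0)),
                     class = c("beat_series", "data.frame"))
  n <- length(x)
  if (n < fs) return(empty)
  e <- c(0, diff(x))^2
  k <- max(3L, round(0.08 * fs))
  es <- as.numeric(stats::filter(e, rep(1 / k, k), sides = 2))
  es[is.na(es)] <- 0
  if (max(es) < 1e-12) return(empty)
  thr <- 0.18 * stats::quantile(es, 0.995, names = FALSE)
  cand <- local_maxima(es)
  cand <- cand[es[cand] > thr]
  if (length(cand) > 1L) {
    ## enforce the refractory period in time order on thresholded candidates
    ref_n <- refractory_s * fs
    keep <- integer(length(cand))
    k <- 0L
    last <- -Inf
    for (i in cand) {
      if (i - last >= ref_n) {
        k <- k + 1L
        keep[k] <- i
        last <- i
      } else if (k > 0L && es[i] > es[keep[k]]) {
        keep[k] <- i
        last <- i
      }
    }
    cand <- keep[seq_len(k)]
  }
  if (!length(cand)) return(empty)

  w50 <- round(0.05 * fs)
  w100 <- round(0.10 * fs)
  r_idx <- vapply(cand, function(i) {
    lo <- max(1L, i - w50); hi <- min(n, i + w50)
    as.integer(lo + which.max(x[lo:hi]) - 1L)
  }, 0L)
  r_idx <- sort(unique(r_idx))
  ## enforce refractory on refined R times
  keep <- rep(TRUE, length(r_idx))
  last <- -Inf
  for (j in seq_along(r_idx)) {
    if ((r_idx[j] - last) / fs < refractory_s) keep[j] <- FALSE
    else last <- r_idx[j]
  }
  r_idx <- r_idx[keep]
  s_amp <- vapply(r_idx, function(i) {
    hi <- min(n, i + w100)
    if (hi <= i) return(NA_real_)
    min(x[(i + 1L):hi])
  }, 0)
  out <- data.frame(time = t0 + (r_idx - 1L) / fs, r_amp = x[r_idx],
                    s_amp = s_amp, rs_amp = x[r_idx] - s_amp)
  out <- out[!is.na(out$rs_amp) & out$rs_amp > 0, ]
  rownames(out) <- NULL
  structure(out, class = c("beat_series", "data.frame"))
}

#' Respiration surrogate from per-beat RS amplitudes
#'
#' Interpolates the RS amplitudes onto a uniform 50 Hz grid with a cubic
#' spline and detects breath cycles as signal peaks separated by at least
#' `min_cycle_s`, requiring a peak-to-trough excursion of at least
#' `prominence_frac` times the signal IQR. A constant RS amplitude yields no
#' breaths (respiratory rate undefined and masked downstream).
#'
#' @param beats a `beat_series` with at least 4 beats.
#' @param fs_out output rate of the respiratory signal (Hz).
#' @param prominence_frac minimum cycle excursion, fraction of the signal IQR.
#' @param min_cycle_s minimum breath-cycle length (s).
#' @return list with `signal` (data.frame `t`, `value`), `breath_times`, and
#'   `rr` (data.frame `t`, `rr` of instantaneous respiratory rate,
#'   breaths/min, at cycle midpoints).
#' @export
derive_respiration <- function(beats, fs_out = 50, prominence_frac = 0.2,
                               min_cycle_s = 0.75) {
  if (nrow(beats) < 4)
    stop("at least 4 beats are required for spline interpolation")
  grid <- seq(beats$time[1], beats$time[nrow(beats)], by = 1 / fs_out)
  sig <- stats::spline(beats$time, beats$rs_amp, xout = grid,
                       method = "fmm")$y
  prom <- prominence_frac * stats::IQR(sig)
  none <- list(signal = data.frame(t = grid, value = sig),
               breath_times = numeric(0),
               rr = data.frame(t = numeric(0), rr = numeric(0)))
  if (prom <= 1e-9) return(none)
  pk <- local_maxima(sig, min_dist = as.integer(min_cycle_s * fs_out))
  if (length(pk) < 2) return(none)
  ## require a prominent drop between consecutive peaks
  ok <- rep(TRUE, length(pk))
  for (j in seq_len(length(pk) - 1L)) {
    trough <- min(sig[pk[j]:pk[j + 1L]])
    if (min(sig[pk[j]], sig[pk[j + 1L]]) - trough < prom) {
      drop <- if (sig[pk[j]] < sig[pk[j + 1L]]) j else j + 1L
      ok[drop] <- FALSE
    }
  }
  pk <- pk[ok]
  if (length(pk) < 2) return(none)
  bt <- grid[pk]
  per <- diff(bt)
  list(signal = data.frame(t = grid, value = sig),
       breath_times = bt,
       rr = data.frame(t = bt[-length(bt)] + per / 2, rr = 60 / per))
}

#' Uniform 1 Hz heart- and respiratory-rate series
#'
#' Converts beat intervals and breath-cycle intervals into instantaneous
#' rates, linearly resampled to a uniform 1 Hz grid. Values outside the
#' physiological bands (HR 30-250 bpm, RR 4-80 breaths/min) are masked.
#'
#' @param beats a `beat_series`.
#' @param resp output of [derive_respiration()] (optional; if missing, RR is
#'   all-NA).
#' @param step grid step (s).
#' @return data.frame of class `rate_series`: `t`, `hr`, `rr`.
#' @export
rate_series <- function(beats, resp = NULL, step = 1) {
  if (nrow(beats) < 3) return(structure(
    data.frame(t = numeric(0), hr = numeric(0), rr = numeric(0)),
    class = c("rate_series", "data.frame")))
  tb <- beats$time
  hr_t <- tb[-length(tb)] + diff(tb) / 2
  hr <- 60 / diff(tb)
  grid <- seq(ceiling(tb[1]), floor(tb[length(tb)]), by = step)
  hr_g <- stats::approx(hr_t, hr, grid, rule = 2)$y
  rr_g <- rep(NA_real_, length(grid))
  if (!is.null(resp) && nrow(resp$rr) >= 2)
    rr_g <- stats::approx(resp$rr$t, resp$rr$rr, grid, rule = 2)$y
  hr_g[hr_g < 30 | hr_g > 250] <- NA_real_
  rr_g[rr_g < 4 | rr_g > 80] <- NA_real_
  structure(data.frame(t = grid, hr = hr_g, rr = rr_g),
            class = c("rate_series", "data.frame"))
}

in_window <- function(t, win_h) {
  s <- sec_of_day(t)
  s >= win_h[1] * 3600 & s < win_h[2] * 3600
}

#' Average daytime and night-time heart and respiratory rate
#'
#' Arithmetic means of the masked-in rate samples inside the configured
#' day and night windows. A window whose masked-in coverage (non-missing
#' fraction of its available samples) is below 50% yields NaN. Spans listed
#' in `exclude` (e.g. exercise bouts and their recovery) are removed from
#' both numerator and denominator.
#'
#' @param rates a [rate_series()].
#' @param day_window,night_window window bounds, hours of day.
#' @param exclude optional 2-column matrix of absolute time intervals (s) to
#'   drop before averaging.
#' @return named vector `daytime_hr`, `daytime_rr`, `night_hr`, `night_rr`.
#' @export
day_night_summaries <- function(rates, day_window = c(8, 20),
                                night_window = c(0, 6), exclude = NULL) {
  keep <- rep(TRUE, nrow(rates))
  if (!is.null(exclude) && length(exclude))
    for (i in seq_len(nrow(exclude)))
      keep <- keep & !(rates$t >= exclude[i, 1] & rates$t <= exclude[i, 2])
  r <- rates[keep, , drop = FALSE]
  win_mean <- function(x) {
    if (!length(x) || mean(!is.na(x)) < 0.5) return(NaN)
    mean(x, na.rm = TRUE)
  }
  d <- in_window(r$t, day_window)
  n <- in_window(r$t, night_window)
  c(daytime_hr = win_mean(r$hr[d]), daytime_rr = win_mean(r$rr[d]),
    night_hr = win_mean(r$hr[n]), night_rr = win_mean(r$rr[n]))
}

#' Post-exertion recovery time of a rate series
#'
#' Baseline is the median rate over the 5 minutes preceding the bout start;
#' the peak is the maximum over one minute either side of the bout end.
#' The recovery time is the first time at or after the peak at which the
#' 10-s moving median stays within baseline + 5% of the excursion for at
#' least 10 consecutive seconds, reported relative to the bout end. If the
#' band is not reached within the search window the result is NaN with
#' `converged = FALSE`; a peak at or below baseline recovers instantly.
#'
#' @param rates a [rate_series()].
#' @param bout_start,bout_end exercise bout boundaries (s).
#' @param what `"hr"` or `"rr"`.
#' @param band fraction of the peak-baseline excursion defining recovery.
#' @param baseline_s,peak_s,hold_s,search_s window constants (s).
#' @return list of class `recovery_result`: `exertion_end`, `peak`,
#'   `baseline`, `time_s`, `converged`.
#' @export
recovery_time <- function(rates, bout_start, bout_end, what = "rr",
                          band = 0.05, baseline_s = 300, peak_s = 60,
                          hold_s = 10, search_s = 900) {
  t <- rates$t
  x <- rates[[what]]
  pre <- x[t >= bout_start - baseline_s & t < bout_start]
  post_n <- sum(t >= bout_end & t <= bout_end + 600 & !is.na(x))
  if (sum(!is.na(pre)) < baseline_s / 2 || post_n < 300)
    stop("recovery_time needs >= 5 min of pre-bout and >= 10 min of ",
         "post-bout rate data")
  baseline <- stats::median(pre, na.rm = TRUE)
  pk_win <- which(t >= bout_end - peak_s & t <= bout_end + peak_s & !is.na(x))
  peak <- max(x[pk_win])
  peak_t <- t[pk_win[which.max(x[pk_win])]]
  res <- list(exertion_end = bout_end, peak = peak, baseline = baseline,
              time_s = NaN, converged = FALSE)
  class(res) <- "recovery_result"
  if (peak <= baseline) {
    res$time_s <- 0
    res$converged <- TRUE
    return(res)
  }
  ## 10-s moving median on a gap-filled copy of the series
  xf <- x
  if (anyNA(xf)) {
    obs <- which(!is.na(xf))
    if (length(obs) >= 2) xf <- stats::approx(t[obs], xf[obs], t, rule = 2)$y
  }
  step <- if (length(t) > 1) stats::median(diff(t)) else 1
  k <- max(3L, 2L * floor(hold_s / step / 2L) + 1L)
  mm <- stats::runmed(xf, k)
  thr <- baseline + band * (peak - baseline)
  idx <- which(t >= peak_t & t <= bout_end + search_s)
  below <- mm[idx] <= thr
  r <- runs_true(below)
  hold_n <- ceiling(hold_s / step)
  r <- r[r$length >= hold_n, , drop = FALSE]
  if (nrow(r)) {
    res$time_s <- max(0, t[idx[r$start[1]]] - bout_end)
    res$converged <- TRUE
  }
  res
}

#' Completeness gate for continuous streams
#'
#' A continuous stream is eligible for analysis only if at least 75% of its
#' required samples are present (inclusive threshold).
#'
#' @param x vector with NA marking missing samples.
#' @param required_n nominal number of samples the stream should contain.
#' @return TRUE (accept) or FALSE (reject).
#' @export
completeness_gate <- function(x, required_n = length(x)) {
  if (required_n <= 0) return(FALSE)
  sum(!is.na(x)) / required_n >= 0.75 - 1e-9
}

#' Extract all ECG-domain features of one subject
#'
#' Runs the full pipeline (band-pass filter, beat detection, RS-amplitude
#' respiration, 1 Hz rate series) on every ECG segment and computes the four
#' day/night summaries plus the two post-exertion recovery times. Exercise
#' spans (one minute before bout start to 15 minutes after bout end) are
#' excluded from the day/night means. If the record fails the 75%
#' completeness gate all features are NaN.
#'
#' @param record an `ecg_record` (see [render_ecg()] / [read_ecg_csv()]).
#' @return named numeric vector: `daytime_hr`, `daytime_rr`, `night_hr`,
#'   `night_rr`, `hr_recovery_s`, `rr_recovery_s`.
#' @export
ecg_features <- function(record) {
  feats <- c(daytime_hr = NaN, daytime_rr = NaN, night_hr = NaN,
             night_rr = NaN, hr_recovery_s = NaN, rr_recovery_s = NaN)
  n_tot <- sum(vapply(record$segments, function(s) length(s$samples), 0))
  n_obs <- sum(vapply(record$segments, function(s) sum(!is.na(s$samples)), 0))
  if (n_tot == 0 || n_obs / n_tot < 0.75 - 1e-9) return(feats)
  rate_list <- lapply(record$segments, function(seg) {
    x <- seg$samples
    x[is.na(x)] <- 0
    xf <- bandpass_filter(x, record$fs)
    beats <- detect_beats(xf, record$fs, t0 = seg$start_s)
    resp <- if (nrow(beats) >= 4) derive_respiration(beats) else NULL
    rate_series(beats, resp)
  })
  rates <- do.call(rbind, rate_list)
  if (!nrow(rates)) return(feats)
  excl <- NULL
  if (!is.null(record$bout))
    excl <- matrix(c(record$bout[["start_s"]] - 60,
                     record$bout[["end_s"]] + 900), nrow = 1)
  feats[1:4] <- day_night_summaries(rates, exclude = excl)
  if (!is.null(record$bout)) {
    for (w in c("hr", "rr")) {
      rec <- tryCatch(
        recovery_time(rates, record$bout[["start_s"]],
                      record$bout[["end_s"]], what = w),
        error = function(e) NULL)
      if (!is.null(rec) && rec$converged)
        feats[paste0(w, "_recovery_s")] <- rec$time_s
    }
  }
  feats
}
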