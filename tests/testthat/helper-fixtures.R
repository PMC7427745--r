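## shared fixtures: small configs and hand-built streams

## compact cohort for rendering tests: short ECG segments, fewer subjects
small_config <- function(seed = 1L, sizes = c(uncontrolled = 3,
                                              controlled = 3,
                                              non_asthmatic = 3), ...) {
  cohort_config(group_sizes = sizes, seed = seed,
                ecg = list(night_min = 8, pre_min = 6, post_min = 12), ...)
}

## one profile with selected truth values overridden
profile_with <- function(truth = NULL, seed = 1L, group = "uncontrolled",
                         config = small_config(seed)) {
  prof <- generate_cohort(config)
  p <- prof[[which(vapply(prof, `[[`, "", "group") == group)[1]]]
  if (!is.null(truth)) p$truth[names(truth)] <- truth
  p
}

## raw ECG of a constant-rate beat train with Gaussian R and S waves
synth_ecg_train <- function(duration_s, hr = 60, fs = 250, r_amp = 1.0,
                            s_amp = 0.3, rs_mod = NULL) {
  n <- duration_s * fs
  x <- numeric(n)
  beats <- seq(0.5, duration_s - 0.5, by = 60 / hr)
  sd_w <- 0.008
  offs <- -ceiling(4 * sd_w * fs):ceiling(4 * sd_w * fs)
  g <- exp(-((offs / fs)^2) / (2 * sd_w^2))
  for (i in seq_along(beats)) {
    m <- if (is.null(rs_mod)) 1 else 1 + rs_mod * sin(2 * pi * 0.25 * beats[i])
    c0 <- round(beats[i] * fs) + 1L
    idx <- c0 + offs
    ok <- idx >= 1 & idx <= n
    x[idx[ok]] <- x[idx[ok]] + r_amp * m * g[ok]
    idx2 <- idx + round(0.04 * fs)
    ok2 <- idx2 >= 1 & idx2 <= n
    x[idx2[ok2]] <- x[idx2[ok2]] - s_amp * m * g[ok2]
  }
  x
}

## epoch series scaffold: counts vector starting at a given day minute
epochs_from_counts <- function(axis1, start_min = 0, vm = NULL,
                               wear = TRUE) {
  n <- length(axis1)
  out <- data.frame(epoch_start_s = (start_min + seq_len(n) - 1) * 60,
                    axis1 = axis1, axis2 = 0, axis3 = 0,
                    vm = if (is.null(vm)) axis1 else vm,
                    wear = rep_len(wear, n))
  class(out) <- c("epoch_series", "data.frame")
  out
}

## mean absolute error between extracted RR and the renderer's truth trace
edr_rr_mae <- function(profile, config) {
  rec <- render_ecg(profile, config, noise = FALSE)
  errs <- unlist(lapply(rec$segments, function(seg) {
    xf <- bandpass_filter(seg$samples, rec$fs)
    beats <- detect_beats(xf, rec$fs, t0 = seg$start_s)
    if (nrow(beats) < 4) return(NULL)
    resp <- derive_respiration(beats)
    rates <- rate_series(beats, resp)
    ok <- !is.na(rates$rr)
    if (!any(ok)) return(NULL)
    truth <- stats::approx(seg$truth$t, seg$truth$rr, rates$t[ok],
                           rule = 2)$y
    abs(rates$rr[ok] - truth)
  }))
  mean(errs)
}
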