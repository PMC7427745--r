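## ---------------------------------------------------------------------------
## Actigraphy features: intensity minutes under count cut-points, bout
## statistics and Weibull scale of moderate-plus activity, Cole-Kripke
## sleep/wake scoring, main-sleep-period detection and all sleep summaries.
## ---------------------------------------------------------------------------

#' Classify epoch intensity and summarise minutes per level
#'
#' Assigns each worn epoch to sedentary / light / moderate / vigorous by
#' strict count thresholds (an epoch moves to the higher level only when its
#' count exceeds the cut-point) and averages minutes per level over monitored
#' (worn) days. Non-wear epochs are excluded from both numerator and
#' denominator.
#'
#' @param epochs an `epoch_series`.
#' @param cutpoints strictly increasing named vector
#'   `c(sedentary, light, moderate)`: upper count bounds of the lower three
#'   levels (defaults are the Evenson youth cut-points).
#' @return list with `level` (factor per epoch, NA when not worn) and
#'   `minutes` (named vector of mean minutes/day per level).
#' @export
classify_intensity <- function(epochs,
                               cutpoints = c(sedentary = 100, light = 2295,
                                             moderate = 4011)) {
  if (any(diff(cutpoints) <= 0))
    stop("intensity cut-points must be strictly increasing")
  lvls <- c("sedentary", "light", "moderate", "vigorous")
  lv <- cut(epochs$axis1, c(-Inf, cutpoints, Inf), labels = lvls)
  lv[!epochs$wear] <- NA
  day <- floor(epochs$epoch_start_s / 86400)
  worn_days <- unique(day[epochs$wear])
  n_days <- max(1L, length(worn_days))
  minutes <- vapply(lvls, function(l)
    sum(lv == l, na.rm = TRUE) / n_days, 0)
  list(level = lv, minutes = minutes)
}

#' Bout statistics of moderate-plus activity
#'
#' A bout is a maximal run of consecutive worn epochs at moderate or vigorous
#' level. Returns every bout with its duration and the mean bout duration in
#' seconds (mean across bouts of each monitored day, averaged over days).
#'
#' @param level per-epoch intensity factor from [classify_intensity()].
#' @param epochs the matching `epoch_series`.
#' @param epoch_s epoch length (s).
#' @return list with `bouts` (data.frame `start_idx`, `n_epochs`,
#'   `duration_s`, `day`) and `mean_bout_s` (NaN when no bouts exist).
#' @export
bout_statistics <- function(level, epochs, epoch_s = 60) {
  modplus <- !is.na(level) & level %in% c("moderate", "vigorous")
  r <- runs_true(modplus)
  if (!nrow(r))
    return(list(bouts = data.frame(start_idx = integer(0),
                                   n_epochs = integer(0),
                                   duration_s = numeric(0), day = integer(0)),
                mean_bout_s = NaN))
  bouts <- data.frame(start_idx = r$start, n_epochs = r$length,
                      duration_s = r$length * epoch_s,
                      day = floor(epochs$epoch_start_s[r$start] / 86400))
  per_day <- tapply(bouts$duration_s, bouts$day, mean)
  list(bouts = bouts, mean_bout_s = mean(per_day))
}

#' Maximum-likelihood Weibull scale of bout durations
#'
#' Two-parameter Weibull fit by profile maximum likelihood: the shape solves
#' `sum(x^k log x)/sum(x^k) - 1/k - mean(log x) = 0`, and the scale is
#' `(mean(x^k))^(1/k)`. When every duration is (numerically) identical the
#' shape diverges and the scale tends to that common duration, which is what
#' the capped solver returns. Requires at least 10 bouts.
#'
#' @param durations bout durations (any fixed unit; the scale is reported in
#'   the same unit).
#' @param min_bouts minimum number of bouts required.
#' @return list with `scale`, `shape`, `n` (`scale = NaN` with
#'   `insufficient = TRUE` below `min_bouts`).
#' @export
weibull_scale <- function(durations, min_bouts = 10L) {
  x <- durations[is.finite(durations) & durations > 0]
  if (length(x) < min_bouts)
    return(list(scale = NaN, shape = NaN, n = length(x),
                insufficient = TRUE))
  ## work on x / max(x) so large shapes cannot overflow x^k
  cx <- max(x)
  z <- x / cx
  lz <- log(z)
  f <- function(k) {
    zk <- z^k
    sum(zk * lz) / sum(zk) - 1 / k - mean(lz)
  }
  k_max <- 500
  k <- if (f(k_max) < 0) k_max else
    stats::uniroot(f, c(1e-2, k_max), tol = 1e-9)$root
  list(scale = cx * mean(z^k)^(1 / k), shape = k, n = length(x),
       insufficient = FALSE)
}

#' Cole-Kripke sleep/wake scoring of 60-s epochs
#'
#' Weighted seven-epoch moving score of the one-minute count formulation:
#' `D = scale * (w[1] A[-4] + ... + w[5] A[0] + ... + w[7] A[+2])` with
#' activity `A` in counts/min; an epoch is scored sleep when `D < 1`. The
#' default weights and scale are the published one-minute coefficients with
#' counts divided by 100. Webster-style rescoring of sleep onsets after long
#' wake episodes can be toggled on.
#'
#' @param counts axis-1 counts per 60-s epoch.
#' @param weights seven weights for epochs -4 ... +2 around the scored epoch.
#' @param scale multiplier applied to the weighted sum (default `0.001/100`:
#'   the published 0.001 factor with counts rescaled by 100).
#' @param rescore apply the rescoring rules (wake episodes of at least 4, 10,
#'   15 min force the following 1, 3, 4 min to wake)?
#' @return logical vector, TRUE = asleep.
#' @export
cole_kripke <- function(counts,
                        weights = c(106, 54, 58, 76, 230, 74, 67),
                        scale = 1e-5, rescore = FALSE) {
  n <- length(counts)
  a <- c(rep(0, 4), counts, rep(0, 2))
  d <- numeric(n)
  for (j in 1:7) d <- d + weights[j] * a[j:(j + n - 1L)]
  asleep <- scale * d < 1
  if (rescore && n > 1) {
    r <- rle(asleep)
    ends <- cumsum(r$lengths)
    for (i in seq_along(r$values)) {
      if (r$values[i] || i == length(r$values)) next
      wake_len <- r$lengths[i]
      fix <- if (wake_len >= 15) 4L else if (wake_len >= 10) 3L
        else if (wake_len >= 4) 1L else 0L
      if (fix > 0L) {
        span <- (ends[i] + 1L):min(n, ends[i] + fix)
        asleep[span] <- FALSE
      }
    }
  }
  asleep
}

#' Main sleep period detection and sleep summaries
#'
#' For every night (18:00 to noon of the next day, only nights fully covered
#' by the recording) sleep runs separated by less than `block_gap_min`
#' minutes of wake are merged into sleep-dominated blocks; the longest block
#' is the candidate main sleep period. Within it, the period starts at the
#' first of `onset_run` consecutive sleep epochs and ends at the last epoch
#' of the final `offset_run` consecutive sleep epochs. Wake-up time is the minute
#' after midnight of the end of that period; total sleep time counts sleep
#' epochs within it; efficiency is their percentage; awakenings are wake runs
#' inside the period; restlessness is the mean vector-magnitude count over
#' the 60 minutes ending at wake-up. Nights without a detectable period are
#' excluded and reported in `nights_excluded`.
#'
#' @param asleep logical sleep/wake vector from [cole_kripke()].
#' @param epochs the matching `epoch_series`.
#' @param onset_run,offset_run consecutive-epoch rules for period bounds.
#' @param block_gap_min wake gaps shorter than this merge adjacent sleep runs
#'   into one block.
#' @return list of class `sleep_summary`: per-night table and across-night
#'   averages (`tst_min`, `wakeup_min`, `sleep_eff_pct`, `awake_min`,
#'   `time_per_awakening_min`, `restlessness_counts`).
#' @export
sleep_period_and_metrics <- function(asleep, epochs, onset_run = 5L,
                                     offset_run = 10L, block_gap_min = 20L) {
  n <- nrow(epochs)
  t_min <- epochs$epoch_start_s / 60
  n_days <- ceiling((t_min[n] + 1) / 1440)
  nights <- list()
  excluded <- 0L
  for (d in seq_len(n_days - 1L)) {
    w0 <- (d - 1L) * 1440L + 18L * 60L
    w1 <- d * 1440L + 12L * 60L
    idx <- which(t_min >= w0 & t_min < w1)
    if (!length(idx) || t_min[idx[length(idx)]] < w1 - 1 ||
        mean(epochs$wear[idx]) < 0.5) {
      excluded <- excluded + 1L
      next
    }
    s <- asleep[idx]
    r <- runs_true(s)
    if (!nrow(r)) {
      excluded <- excluded + 1L
      next
    }
    ## merge sleep runs across short wake gaps into blocks
    block <- cumsum(c(1L, diff(r$start) - r$length[-nrow(r)] >=
                        block_gap_min))
    sleep_per_block <- tapply(r$length, block, sum)
    bi <- as.integer(names(sleep_per_block)[which.max(sleep_per_block)])
    rb <- r[block == bi, , drop = FALSE]
    r_on <- rb[rb$length >= onset_run, , drop = FALSE]
    r_off <- rb[rb$length >= offset_run, , drop = FALSE]
    if (!nrow(r_on) || !nrow(r_off)) {
      excluded <- excluded + 1L
      next
    }
    p0 <- r_on$start[1]
    p1 <- max(r_off$end)
    if (p1 <= p0) {
      excluded <- excluded + 1L
      next
    }
    period <- s[p0:p1]
    tst <- sum(period)
    plen <- length(period)
    wake_runs <- runs_true(!period)
    n_awake <- nrow(wake_runs)
    awake_min <- sum(!period)
    wake_min_abs <- t_min[idx[p1]] + 1   # minute after the last sleep epoch
    wakeup <- wake_min_abs %% 1440
    rest_idx <- idx[max(1L, p1 - 59L):p1]
    nights[[length(nights) + 1L]] <- data.frame(
      night = d, onset_min = t_min[idx[p0]] %% 1440, wakeup_min = wakeup,
      tst_min = tst, period_min = plen,
      sleep_eff_pct = 100 * tst / plen,
      awake_min = awake_min, n_awakenings = n_awake,
      time_per_awakening_min = if (n_awake) awake_min / n_awake else NaN,
      restlessness_counts = mean(epochs$vm[rest_idx]))
  }
  if (!length(nights)) {
    out <- list(nights = NULL, nights_excluded = excluded,
                summary = c(tst_min = NaN, wakeup_min = NaN,
                            sleep_eff_pct = NaN, awake_min = NaN,
                            time_per_awakening_min = NaN,
                            restlessness_counts = NaN))
    class(out) <- "sleep_summary"
    return(out)
  }
  tab <- do.call(rbind, nights)
  out <- list(
    nights = tab, nights_excluded = excluded,
    summary = c(tst_min = mean(tab$tst_min),
                wakeup_min = mean(tab$wakeup_min),
                sleep_eff_pct = mean(tab$sleep_eff_pct),
                awake_min = mean(tab$awake_min),
                time_per_awakening_min =
                  mean(tab$time_per_awakening_min, na.rm = TRUE),
                restlessness_counts = mean(tab$restlessness_counts)))
  class(out) <- "sleep_summary"
  out
}

#' Extract all actigraphy-domain features of one subject
#'
#' Intensity minutes, bout statistics (with the Weibull scale fitted to bout
#' durations in minutes), Cole-Kripke sleep scoring and the sleep summaries.
#' Sleep scoring is restricted to worn epochs; the record must pass the 75%
#' wear completeness gate, otherwise all features are NaN.
#'
#' @param epochs an `epoch_series`.
#' @param cutpoints intensity cut-points, see [classify_intensity()].
#' @return named numeric vector: `sedentary_min`, `light_min`,
#'   `moderate_min`, `vigorous_min`, `bout_len_s`, `weibull_scale`,
#'   `wakeup_min`, `awake_min`, `time_per_awakening_min`, `sleep_eff_pct`,
#'   `tst_min`, `restlessness_counts`.
#' @export
actigraphy_features <- function(epochs,
                                cutpoints = c(sedentary = 100, light = 2295,
                                              moderate = 4011)) {
  feats <- stats::setNames(rep(NaN, 12),
                           c("sedentary_min", "light_min", "moderate_min",
                             "vigorous_min", "bout_len_s", "weibull_scale",
                             "wakeup_min", "awake_min",
                             "time_per_awakening_min", "sleep_eff_pct",
                             "tst_min", "restlessness_counts"))
  if (!completeness_gate(ifelse(epochs$wear, 1, NA))) return(feats)
  ci <- classify_intensity(epochs, cutpoints)
  feats[c("sedentary_min", "light_min", "moderate_min", "vigorous_min")] <-
    ci$minutes
  bs <- bout_statistics(ci$level, epochs)
  feats["bout_len_s"] <- bs$mean_bout_s
  feats["weibull_scale"] <- weibull_scale(bs$bouts$duration_s / 60)$scale
  sl <- cole_kripke(epochs$axis1)
  sl[!epochs$wear] <- FALSE            # non-worn epochs never count as sleep
  sm <- sleep_period_and_metrics(sl, epochs)
  feats[names(sm$summary)] <- sm$summary
  feats
}
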