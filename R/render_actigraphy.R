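## ---------------------------------------------------------------------------
## Actigraphy renderer: 60-s epoch counts over the full monitoring period with
## a night architecture (sleep onset, awakenings, wake-up time, pre-wake
## restlessness) and daytime intensity levels matching the subject's targets
## under the configured cut-points.
## ---------------------------------------------------------------------------

## count ranges per rendered state (axis-1 counts/min). "quiet" wake epochs
## flank the sleep period so the scoring boundary stays crisp: they score
## wake under the Cole-Kripke weights without dragging neighbouring sleep
## epochs over the threshold.
.act_count_range <- list(
  sedentary = c(0, 100), light = c(150, 2295), moderate = c(2350, 4011),
  vigorous = c(4100, 7500), awakening = c(480, 640), quiet = c(480, 640))

#' Render the wrist actigraphy of a subject
#'
#' Produces 60-s epochs of axis counts and vector magnitude over the whole
#' monitoring period. Nights follow the profile's architecture: sleep onset at
#' `wake-up time - (TST + awake minutes)`, the profile's number of awakenings
#' (each of its per-awakening duration, kept clear of the first 15 and last
#' 60 minutes of the night), and elevated vector-magnitude counts in the final
#' pre-wake hour whose mean equals the profile's restlessness. Daytime epochs
#' realise the light/moderate/vigorous minute targets under the configured
#' cut-points, with exercise bouts rendered as contiguous moderate-vigorous
#' runs; sedentary time is the remainder of the waking day.
#'
#' @param profile a subject profile.
#' @param config a [cohort_config()].
#' @return data.frame of class `epoch_series` (`epoch_start_s`, `axis1`,
#'   `axis2`, `axis3`, `vm`, `wear`) with a `truth` attribute carrying the
#'   rendered sleep states and night table.
#' @export
render_actigraphy <- function(profile, config = cohort_config()) {
  set.seed(profile$seed + 22L)
  days <- profile$monitoring_days
  N <- days * 1440L
  tr <- profile$truth
  state <- rep("day", N)

  W <- round(tr[["wakeup_min"]])
  awake_tot <- max(1L, round(tr[["awake_min"]]))
  k <- profile$n_awakenings
  tst_r <- round(tr[["tst_min"]])
  tib <- tst_r + awake_tot
  ## awakening durations: integers summing to awake_tot
  dur <- rep(awake_tot %/% k, k)
  extra <- awake_tot - sum(dur)
  if (extra > 0) dur[seq_len(extra)] <- dur[seq_len(extra)] + 1L
  dur <- dur[dur > 0]

  place_night <- function(onset, wake, awakenings = TRUE) {
    onset <- max(onset, 0L); wake <- min(wake, N)
    if (wake <= onset) return(invisible(NULL))
    state[(onset + 1L):wake] <<- "sleep"   # minutes onset .. wake-1 (1-based)
    if (awakenings && length(dur)) {
      lo <- onset + 15L
      hi <- wake - 60L - max(dur)
      if (hi > lo) {
        used <- integer(0)
        for (d_a in dur) {
          for (try in 1:50) {
            s <- sample(lo:hi, 1L)
            span <- s:(s + d_a - 1L)
            if (!any(span %in% used)) {
              state[span + 1L] <<- "awakening"
              used <- c(used, (s - 2L):(s + d_a + 1L))
              break
            }
          }
        }
      }
    }
    ## wind-down / morning-routine buffers: wake-level counts around the
    ## sleep period so quiet sedentary time does not blur its boundaries
    q1 <- (onset - 30L):(onset - 1L); q1 <- q1[q1 >= 0L]
    if (length(q1)) state[q1 + 1L] <<- "quiet"
    q2 <- wake:(wake + 29L); q2 <- q2[q2 < N]
    state[q2 + 1L] <<- "quiet"
    invisible(NULL)
  }

  for (n in seq_len(days - 1L))
    place_night(n * 1440L + W - tib, n * 1440L + W)
  place_night(0L, W, awakenings = FALSE)              # truncated first morning
  place_night((days - 1L) * 1440L + 1440L + W - tib, N)  # truncated last night

  ## --- daytime intensity levels ------------------------------------------
  level <- rep("sedentary", N)
  v_target <- round(tr[["vigorous_min"]])
  m_target <- round(tr[["moderate_min"]])
  l_target <- round(tr[["light_min"]])
  sched <- profile$exercise_schedule
  for (d in seq_len(days) - 1L) {
    day_idx <- which(state == "day" &
                       (seq_len(N) - 1L) %/% 1440L == d)
    if (l_target + m_target + v_target > length(day_idx))
      stop("target activity minutes exceed the available day length")
    ## exercise bout -> vigorous head, moderate tail
    b <- sched[sched$day == d, ]
    bout_idx <- integer(0)
    if (nrow(b)) {
      bout_idx <- (floor(b$start_s[1] / 60)):(floor(b$end_s[1] / 60) - 1L) + 1L
      bout_idx <- intersect(bout_idx, day_idx)
      nv <- min(v_target, length(bout_idx))
      if (nv > 0) level[bout_idx[seq_len(nv)]] <- "vigorous"
      if (length(bout_idx) > nv)
        level[bout_idx[(nv + 1L):length(bout_idx)]] <- "moderate"
    }
    free <- setdiff(day_idx, bout_idx)
    ## residual moderate minutes in short runs (2-5 epochs)
    m_left <- max(0L, m_target - sum(level[bout_idx] == "moderate"))
    while (m_left > 0L && length(free) > 3L) {
      run <- min(sample(2:5, 1L), m_left)
      s <- sample(seq_len(max(1L, length(free) - run)), 1L)
      pick <- free[s:(s + run - 1L)]
      pick <- pick[!is.na(pick)]
      level[pick] <- "moderate"
      free <- setdiff(free, pick)
      m_left <- m_left - length(pick)
    }
    v_left <- max(0L, v_target - sum(level[day_idx] == "vigorous"))
    if (v_left > 0L && length(free) >= v_left) {
      pick <- sample(free, v_left)
      level[pick] <- "vigorous"
      free <- setdiff(free, pick)
    }
    if (l_target > 0L && length(free) >= 1L) {
      pick <- sample(free, min(l_target, length(free)))
      level[pick] <- "light"
    }
  }

  ## --- counts -------------------------------------------------------------
  axis1 <- numeric(N)
  vm <- numeric(N)
  is_day <- state == "day"
  for (lv in c("sedentary", "light", "moderate", "vigorous")) {
    idx <- which(is_day & level == lv)
    rg <- .act_count_range[[lv]]
    axis1[idx] <- round(stats::runif(length(idx), rg[1], rg[2]))
    vm[idx] <- round(axis1[idx] * stats::runif(length(idx), 1.15, 1.45))
  }
  for (st in c("awakening", "quiet")) {
    idx <- which(state == st)
    rg <- .act_count_range[[st]]
    axis1[idx] <- round(stats::runif(length(idx), rg[1], rg[2]))
    vm[idx] <- round(axis1[idx] * 1.2)
  }
  sl <- which(state == "sleep")
  axis1[sl] <- stats::rpois(length(sl), 1)
  vm[sl] <- round(stats::rlnorm(length(sl),
                                log(max(tr[["restlessness_counts"]], 0.5) / 2),
                                0.4), 2)
  ## pre-wake hour: exact-mean restlessness in the 60 min ending at wake-up
  for (n in seq_len(days - 1L)) {
    wk <- n * 1440L + W
    win <- (wk - 60L):(wk - 1L) + 1L
    win <- win[state[win] == "sleep"]
    if (length(win) < 2) next
    v <- stats::rlnorm(length(win), log(tr[["restlessness_counts"]]), 0.3)
    vm[win] <- round(v * tr[["restlessness_counts"]] / mean(v), 3)
  }
  axis1[sl] <- pmin(axis1[sl], floor(vm[sl]))

  wear <- rep(TRUE, N)
  nw <- config$actigraphy$nonwear_min_per_day
  if (nw > 0) {
    for (d in seq_len(days) - 1L) {
      s <- d * 1440L + hm2min(13, 0)
      wear[(s + 1L):min(N, s + nw)] <- FALSE
    }
  }
  axis2 <- round(sqrt(pmax(vm^2 - axis1^2, 0)), 2)
  out <- data.frame(epoch_start_s = (seq_len(N) - 1L) * 60,
                    axis1 = axis1, axis2 = axis2, axis3 = 0,
                    vm = vm, wear = wear)
  attr(out, "truth") <- list(
    asleep = state == "sleep",
    state = state, level = ifelse(is_day, level, NA_character_),
    wakeup_min = W, tib_min = tib, tst_min = tst_r, awake_min = awake_tot)
  class(out) <- c("epoch_series", "data.frame")
  out
}
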