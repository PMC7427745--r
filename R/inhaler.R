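## ---------------------------------------------------------------------------
## Smart-inhaler event log: renderer, controller adherence and reliever-use
## counts (total / before-activity / after-activity).
## ---------------------------------------------------------------------------

#' Render the smart-inhaler event log of a subject
#'
#' Controller inhalations are placed at the prescribed dose times (default
#' 08:00 and 20:00), with random omissions so the taken count equals
#' `round(adherence/100 * prescribed)`; over-adherent subjects get extra
#' doses. Reliever inhalations realise the subject's true total with the
#' true before-activity and after-activity counts placed 3-28 minutes before
#' a bout start / after a bout end, and the remainder kept at least 45
#' minutes away from any bout. Non-asthmatic subjects have no inhaler, so
#' the log is empty.
#'
#' @param profile a subject profile.
#' @param config a [cohort_config()].
#' @return data.frame of class `inhaler_log`: `time_s`, `type`
#'   (`"controller"` / `"reliever"`), sorted by time.
#' @export
render_inhaler_log <- function(profile, config = cohort_config()) {
  empty <- structure(data.frame(time_s = numeric(0), type = character(0),
                                stringsAsFactors = FALSE),
                     class = c("inhaler_log", "data.frame"))
  if (profile$group == "non_asthmatic") return(empty)
  set.seed(profile$seed + 44L)
  tr <- profile$truth
  days <- profile$monitoring_days
  dpd <- config$inhaler$doses_per_day

  ## controller: prescribed slots, omissions to match adherence
  slot_min <- hm2min(8, 0) + (seq_len(dpd) - 1L) * (720 / max(1, dpd - 1))
  if (dpd == 1) slot_min <- hm2min(8, 0)
  slots <- as.vector(outer(slot_min * 60, (seq_len(days) - 1L) * 86400, "+"))
  n_rx <- length(slots)
  n_take <- round(tr[["controller_adherence_pct"]] / 100 * n_rx)
  ctrl <- if (n_take <= n_rx) {
    sort(sample(slots, n_take))
  } else {
    sort(c(slots, sample(slots, n_take - n_rx) + 600))
  }

  ## reliever: before / after / unassociated placements
  sched <- profile$exercise_schedule
  n_tot <- tr[["reliever_total"]]
  n_b <- tr[["reliever_before_activity"]]
  n_a <- tr[["reliever_after_activity"]]
  rel <- numeric(0)
  if (n_b > 0) {
    b <- sched[sample(nrow(sched), n_b, replace = n_b > nrow(sched)), ]
    rel <- c(rel, b$start_s - stats::runif(n_b, 3, 28) * 60)
  }
  if (n_a > 0) {
    a <- sched[sample(nrow(sched), n_a, replace = n_a > nrow(sched)), ]
    rel <- c(rel, a$end_s + stats::runif(n_a, 3, 28) * 60)
  }
  n_r <- n_tot - n_b - n_a
  while (n_r > 0) {
    t <- (sample(days, 1L) - 1L) * 86400 +
      stats::runif(1, hm2min(7, 0), hm2min(22, 0)) * 60
    clear <- all(t < sched$start_s - 45 * 60 | t > sched$end_s + 45 * 60)
    if (clear && (!length(rel) || min(abs(rel - t)) > 90)) {
      rel <- c(rel, t)
      n_r <- n_r - 1L
    }
  }
  out <- data.frame(
    time_s = c(ctrl, rel),
    type = rep(c("controller", "reliever"), c(length(ctrl), length(rel))),
    stringsAsFactors = FALSE)
  out <- out[order(out$time_s), ]
  rownames(out) <- NULL
  class(out) <- c("inhaler_log", "data.frame")
  out
}

## merge actuations of the same type closer than dedup_s (double puffs)
dedup_events <- function(events, dedup_s = 60) {
  if (!nrow(events)) return(events)
  keep <- unlist(lapply(split(seq_len(nrow(events)), events$type),
    function(idx) {
      t <- events$time_s[idx]
      k <- rep(TRUE, length(t))
      last <- -Inf
      for (i in order(t)) {
        if (t[i] - last < dedup_s) k[i] <- FALSE else last <- t[i]
      }
      idx[k]
    }))
  out <- events[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Controller adherence
#'
#' `100 * controller inhalations / (doses per day x monitoring days)`; values
#' above 100 are reported as such and flagged. A subject without a
#' prescription yields NaN (flagged when events exist anyway).
#'
#' @param events an `inhaler_log`.
#' @param doses_per_day prescribed controller doses per day.
#' @param days monitoring days.
#' @param dedup_s actuations of the same type closer than this are merged.
#' @return list with `adherence_pct`, `taken`, `prescribed`, `flag`.
#' @export
controller_adherence <- function(events, doses_per_day, days,
                                 dedup_s = 60) {
  ev <- dedup_events(events, dedup_s)
  taken <- sum(ev$type == "controller")
  rx <- doses_per_day * days
  if (rx == 0)
    return(list(adherence_pct = NaN, taken = taken, prescribed = 0,
                flag = if (taken > 0) "events without prescription" else NA))
  pct <- 100 * taken / rx
  list(adherence_pct = pct, taken = taken, prescribed = rx,
       flag = if (pct > 100) "over-use (>100%)" else NA)
}

#' Reliever-use counts
#'
#' Total reliever inhalations over the monitoring period plus the counts
#' falling within `window_min` minutes before a bout start (before-activity)
#' or after a bout end (after-activity). An event matching both windows is
#' counted once and assigned to the nearer bout boundary (ties go to
#' before-activity).
#'
#' @param events an `inhaler_log`.
#' @param schedule exercise schedule (`start_s`, `end_s`).
#' @param window_min association window (minutes).
#' @param dedup_s actuations closer than this are merged.
#' @return named vector `total`, `before`, `after`.
#' @export
reliever_counts <- function(events, schedule, window_min = 30,
                            dedup_s = 60) {
  ev <- dedup_events(events, dedup_s)
  t <- ev$time_s[ev$type == "reliever"]
  w <- window_min * 60
  before <- 0L
  after <- 0L
  for (x in t) {
    db <- schedule$start_s - x
    da <- x - schedule$end_s
    d_before <- suppressWarnings(min(db[db >= 0 & db <= w]))
    d_after <- suppressWarnings(min(da[da >= 0 & da <= w]))
    if (is.finite(d_before) && is.finite(d_after)) {
      if (d_before <= d_after) before <- before + 1L else after <- after + 1L
    } else if (is.finite(d_before)) {
      before <- before + 1L
    } else if (is.finite(d_after)) {
      after <- after + 1L
    }
  }
  c(total = length(t), before = before, after = after)
}

#' Extract all inhaler-domain features of one subject
#'
#' @param events an `inhaler_log` (empty for subjects without an inhaler,
#'   which yields NaN medication features).
#' @param schedule exercise schedule of the subject.
#' @param config a [cohort_config()].
#' @param days monitoring days.
#' @return named numeric vector: `reliever_total`,
#'   `reliever_before_activity`, `reliever_after_activity`,
#'   `controller_adherence_pct`.
#' @export
inhaler_features <- function(events, schedule, config = cohort_config(),
                             days = 14) {
  feats <- stats::setNames(rep(NaN, 4),
                           c("reliever_total", "reliever_before_activity",
                             "reliever_after_activity",
                             "controller_adherence_pct"))
  if (is.null(events) || !nrow(events)) return(feats)
  rc <- reliever_counts(events, schedule,
                        window_min = config$inhaler$window_min,
                        dedup_s = config$inhaler$dedup_s)
  feats[1:3] <- rc
  feats["controller_adherence_pct"] <-
    controller_adherence(events, config$inhaler$doses_per_day, days,
                         dedup_s = config$inhaler$dedup_s)$adherence_pct
  feats
}
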