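## ---------------------------------------------------------------------------
## Subject profiles: per-subject ground-truth parameter values drawn from the
## per-group distribution specs, plus demographics, exercise schedule and the
## clinical reference items (symptom-control items, exercise-challenge fall)
## that define the asthma-control label.
## ---------------------------------------------------------------------------

## draw one truncated value: redraw up to 50 times, then clip
draw_truncated <- function(family, p1, p2, lower, upper, n = 1L) {
  out <- draw_spec(family, p1, p2, n)
  for (i in 1:50) {
    bad <- out < lower | out > upper
    if (!any(bad)) break
    out[bad] <- draw_spec(family, p1, p2, sum(bad))
  }
  clip(out, lower, upper)
}

draw_group_truth <- function(specs, group, bounds) {
  rows <- specs[specs$group == group, ]
  truth <- stats::setNames(rep(NA_real_, length(FEATURE_NAMES)), FEATURE_NAMES)
  for (i in seq_len(nrow(rows))) {
    p <- rows$parameter[i]
    truth[p] <- draw_truncated(rows$family[i], rows$p1[i], rows$p2[i],
                               bounds[p, "lower"], bounds[p, "upper"])
  }
  truth
}

## exercise-challenge fall distributions (median, q25, q75) per context
draw_bpt_fall <- function(kind) {
  q <- switch(kind,
              positive = c(27.9, 17.3, 32.8),   # uncontrolled, challenge-positive
              negative = c(6.0, 3.8, 9.8),      # controlled-like response
              healthy  = c(3.1, 0.6, 5.1))
  p <- lognormal_from_quartiles(q[1], q[2], q[3])
  lim <- if (kind == "positive") c(12.0001, 60) else c(0, 12)
  draw_truncated("lognormal", p$meanlog, p$sdlog, lim[1], lim[2])
}

#' Generate a cohort of subject profiles
#'
#' Draws one [subject profile][generate_cohort] per subject: group membership,
#' demographics (sex, age, height), ground-truth values for every
#' home-monitoring parameter (independently per subject from the group's
#' distribution spec, truncated to physiological bounds), a two-week exercise
#' schedule, and the outpatient reference items (four symptom-control items
#' over the past four weeks and the maximal exercise-challenge FEV1 fall)
#' consistent with the group.
#'
#' Sleep efficiency is derived as `100 * TST / (TST + awake minutes)`;
#' reliever counts are integers with the before/after-activity split drawn
#' from the configured association fractions.
#'
#' @param config a [cohort_config()].
#' @return list of `subject_profile` objects.
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  set.seed(config$seed)
  n_total <- sum(config$group_sizes)
  groups <- rep(names(config$group_sizes), config$group_sizes)
  subj_seeds <- sample.int(2^31 - 1, n_total)
  male_prob <- c(uncontrolled = 0.77, controlled = 0.84, non_asthmatic = 0.53)
  age_mu <- c(uncontrolled = 8.2, controlled = 9.5, non_asthmatic = 9.3)
  age_sd <- c(uncontrolled = 2.8, controlled = 2.6, non_asthmatic = 2.9)

  lapply(seq_len(n_total), function(i) {
    g <- groups[i]
    truth <- draw_group_truth(config$specs, g, config$bounds)

    ## internal consistency of the night architecture
    tib_max <- truth["wakeup_min"] + 330   # sleep onset not before 18:30
    tst <- min(truth["tst_min"], tib_max - truth["awake_min"])
    truth["tst_min"] <- max(tst, 180)
    truth["sleep_eff_pct"] <-
      100 * truth["tst_min"] / (truth["tst_min"] + truth["awake_min"])
    n_awakenings <- max(1L, round(truth["awake_min"] /
                                    truth["time_per_awakening_min"]))
    truth["time_per_awakening_min"] <- truth["awake_min"] / n_awakenings

    ## integer reliever counts with before/after-activity split
    if (g == "non_asthmatic") {
      truth[c("reliever_total", "reliever_before_activity",
              "reliever_after_activity")] <- NA_real_
    } else {
      tot <- round(truth["reliever_total"])
      before <- stats::rbinom(1, tot, config$exercise$p_before[[g]])
      after <- stats::rbinom(1, tot - before, config$exercise$p_after[[g]])
      truth["reliever_total"] <- tot
      truth["reliever_before_activity"] <- before
      truth["reliever_after_activity"] <- after
    }

    ## demographics; height grows ~5.5 cm/y in this age range
    sex <- if (stats::runif(1) < male_prob[[g]]) "male" else "female"
    age <- clip(stats::rnorm(1, age_mu[[g]], age_sd[[g]]), 4, 14)
    height <- clip(88 + 5.5 * age + stats::rnorm(1, 0, 6), 95, 185)

    ## exercise schedule: bouts/day at after-school times
    ex <- config$exercise
    sched <- do.call(rbind, lapply(seq_len(config$monitoring_days) - 1L,
      function(day) {
        k <- ex$bouts_per_day
        start_min <- ex$start_min +
          stats::runif(k, -ex$start_jitter_min, ex$start_jitter_min)
        dur_min <- stats::runif(k, ex$min_min, ex$max_min)
        data.frame(day = day,
                   start_s = day * 86400 + start_min * 60,
                   end_s = day * 86400 + (start_min + dur_min) * 60)
      }))
    sched <- sched[order(sched$start_s), ]
    rownames(sched) <- NULL

    ## clinical reference: symptom-control items + exercise-challenge fall
    if (g == "uncontrolled") {
      basis <- sample(c("BPT", "GINA", "both"), 1, prob = c(13, 3, 11) / 27)
      n_items <- if (basis %in% c("GINA", "both")) sample(3:4, 1) else
        sample(0:2, 1)
      fall <- if (basis %in% c("BPT", "both")) draw_bpt_fall("positive") else
        draw_bpt_fall("negative")
    } else if (g == "controlled") {
      basis <- "n/a"
      n_items <- sample(0:2, 1)
      fall <- draw_bpt_fall("negative")
    } else {
      basis <- "n/a"
      n_items <- 0L
      fall <- draw_bpt_fall("healthy")
    }
    gina <- stats::setNames(seq_len(4) %in% sample(4, n_items),
                            c("daytime_symptoms", "reliever_gt2", "nocturnal",
                              "activity_limitation"))

    structure(list(
      subject_id = sprintf("S%03d", i),
      group = g,
      sex = sex, age = age, height = height,
      truth = truth,
      n_awakenings = n_awakenings,
      exercise_schedule = sched,
      gina = gina,
      bpt_fall = fall,
      bpt_basis = basis,
      monitoring_days = config$monitoring_days,
      ecg_days = config$ecg_days,
      seed = subj_seeds[i]), class = "subject_profile")
  })
}

#' @export
print.subject_profile <- function(x, ...) {
  cat("<subject_profile>", x$subject_id, "-", x$group,
      sprintf("(%s, %.1f y, %.0f cm)\n", x$sex, x$age, x$height))
  cat("  ", x$monitoring_days, "monitoring days,",
      nrow(x$exercise_schedule), "exercise bouts\n")
  invisible(x)
}

#' Ground-truth feature matrix of a cohort
#'
#' Assembles the per-subject true parameter values into a feature matrix
#' (subjects x parameters) without rendering any raw sensor stream. Used for
#' fast model-level simulation; the raw-signal path goes through
#' [render_sensors()] and [extract_features()].
#'
#' @param profiles list of subject profiles from [generate_cohort()].
#' @return data.frame with `subject_id`, `group`, and one column per
#'   home-monitoring parameter.
#' @export
profile_features <- function(profiles) {
  m <- do.call(rbind, lapply(profiles, function(p) p$truth))
  out <- data.frame(subject_id = vapply(profiles, `[[`, "", "subject_id"),
                    group = vapply(profiles, `[[`, "", "group"),
                    m, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
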