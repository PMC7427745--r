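## ---------------------------------------------------------------------------
## Home spirometry: reference equations, manoeuvre QC, %-predicted conversion,
## pre-exercise summaries, FEV1 variation and exercise/symptom changes, plus
## the manoeuvre renderer.
## ---------------------------------------------------------------------------

#' Paediatric reference equations for spirometry indices
#'
#' Config-driven linear-in-height reference table (litres, or litres/second
#' for flows), one row per index and sex, supported for ages 4-14 years and
#' heights 95-185 cm. The defaults are linear approximations of published
#' paediatric reference values; the table can be swapped wholesale for any
#' other source with the same columns.
#'
#' @return data.frame with `index`, `sex`, `intercept`, `slope`.
#' @export
reference_equations <- function() {
  data.frame(
    index = rep(c("fev1", "fvc", "pef", "fef2575"), each = 2),
    sex = rep(c("male", "female"), 4),
    intercept = c(-2.92, -2.80, -3.51, -3.37, -5.60, -5.50, -3.10, -3.00),
    slope = c(0.0348, 0.0336, 0.0409, 0.0393, 0.0720, 0.0700,
              0.0400, 0.0390))
}

predicted_value <- function(index, sex, age, height,
                            ref = reference_equations()) {
  if (age < 4 || age > 14)
    stop("age ", age, " outside the supported reference range (4-14 y)")
  if (height < 95 || height > 185)
    stop("height ", height, " outside the supported reference range")
  row <- ref[ref$index == index & ref$sex == sex, ]
  if (nrow(row) != 1) stop("no reference equation for ", index, "/", sex)
  p <- row$intercept + row$slope * height
  if (p <= 0) stop("non-positive predicted value")
  p
}

#' Percent of predicted for a spirometry value
#'
#' `100 * value / predicted(index, sex, age, height)` with the predicted
#' value taken from a [reference_equations()] table.
#'
#' @param value measured value (L or L/s).
#' @param index one of `"fev1"`, `"fvc"`, `"pef"`, `"fef2575"`.
#' @param sex `"male"` or `"female"`.
#' @param age years; must be within the reference support (4-14).
#' @param height cm.
#' @param ref reference table.
#' @return percent predicted.
#' @export
percent_predicted <- function(value, index, sex, age, height,
                              ref = reference_equations()) {
  100 * value / predicted_value(index, sex, age, height, ref)
}

#' Quality control of a spirometry manoeuvre
#'
#' Reduced acceptability screen on the stored summary indices: back-
#' extrapolated volume at most `max(0.15 L, 5% of FVC)`, forced expiratory
#' time at least `min_fet_s` (paediatric relaxation of the adult criterion),
#' and a renderer-provided PEF rise-time plausibility flag.
#'
#' @param maneuvers data.frame with columns `fev1_l`, `fvc_l`, `fet_s`,
#'   `bev_l`, `rise_ok`.
#' @param min_fet_s minimum forced expiratory time (s).
#' @return data.frame with `accepted` (logical) and `reason` (NA when
#'   accepted; otherwise a comma-separated list).
#' @export
qc_maneuver <- function(maneuvers, min_fet_s = 3) {
  bev_ok <- maneuvers$bev_l <= pmax(0.15, 0.05 * maneuvers$fvc_l)
  fet_ok <- maneuvers$fet_s >= min_fet_s
  rise_ok <- if ("rise_ok" %in% names(maneuvers)) maneuvers$rise_ok else TRUE
  reason <- mapply(function(b, f, r) {
    why <- c(if (!b) "high back-extrapolated volume",
             if (!f) "short expiration",
             if (!r) "implausible PEF rise")
    if (length(why)) paste(why, collapse = ", ") else NA_character_
  }, bev_ok, fet_ok, rise_ok)
  data.frame(accepted = bev_ok & fet_ok & rise_ok, reason = reason,
             stringsAsFactors = FALSE)
}

#' Variation in pre-exercise FEV1
#'
#' Absolute difference between the highest and lowest accepted pre-exercise
#' FEV1 in percent predicted over the monitoring period; NaN when fewer than
#' two accepted manoeuvres exist.
#'
#' @param pre_pct accepted pre-exercise FEV1 values, percent predicted.
#' @return variation in percent-predicted points.
#' @export
fev1_variation <- function(pre_pct) {
  pre_pct <- pre_pct[is.finite(pre_pct)]
  if (length(pre_pct) < 2) return(NaN)
  max(pre_pct) - min(pre_pct)
}

#' Mean FEV1 change after exercise
#'
#' Pairs every accepted post-exercise manoeuvre with the nearest accepted
#' pre-exercise manoeuvre in the preceding `pair_window_s`, computes
#' `100 * (post - pre) / pre` per session (falls are negative) and averages
#' across sessions. Sessions without an accepted pre manoeuvre are excluded.
#'
#' @param maneuvers data.frame with `time_s`, `tag`, `fev1_l` and an
#'   `accepted` column.
#' @param pair_window_s maximum pre-to-post spacing (s).
#' @return list with `mean_change_pct`, per-session table and the number of
#'   excluded post manoeuvres.
#' @export
exercise_change <- function(maneuvers, pair_window_s = 45 * 60) {
  acc <- maneuvers[maneuvers$accepted, ]
  pre <- acc[acc$tag == "pre-exercise", ]
  post <- acc[acc$tag == "post-exercise", ]
  if (!nrow(post) || !nrow(pre))
    return(list(mean_change_pct = NaN, sessions = NULL, excluded = nrow(post)))
  rows <- lapply(seq_len(nrow(post)), function(i) {
    dt <- post$time_s[i] - pre$time_s
    ok <- dt > 0 & dt <= pair_window_s
    if (!any(ok)) return(NULL)
    j <- which(ok)[which.min(dt[ok])]
    data.frame(pre_t = pre$time_s[j], post_t = post$time_s[i],
               change_pct = 100 * (post$fev1_l[i] - pre$fev1_l[j]) /
                 pre$fev1_l[j])
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab))
    return(list(mean_change_pct = NaN, sessions = NULL, excluded = nrow(post)))
  list(mean_change_pct = mean(tab$change_pct), sessions = tab,
       excluded = nrow(post) - nrow(tab))
}

#' Mean FEV1 change during symptoms
#'
#' Change of every accepted symptom manoeuvre relative to the subject's mean
#' accepted pre-exercise FEV1 (the baseline), averaged across symptom events;
#' NaN when the subject has no accepted symptom manoeuvres.
#'
#' @param maneuvers data.frame with `time_s`, `tag`, `fev1_l`, `accepted`.
#' @return mean percent change (negative = fall).
#' @export
symptom_change <- function(maneuvers) {
  acc <- maneuvers[maneuvers$accepted, ]
  sym <- acc$fev1_l[acc$tag == "symptom"]
  base <- mean(acc$fev1_l[acc$tag == "pre-exercise"])
  if (!length(sym) || !is.finite(base)) return(NaN)
  mean(100 * (sym - base) / base)
}

## helper: k fractions in [0,1] with mean exactly 1/2 and range exactly 1
spread_fractions <- function(k) {
  if (k == 1) return(0.5)
  u <- c(0, 1)
  extra <- k - 2L
  if (extra > 0) {
    half <- extra %/% 2L
    v <- stats::runif(half, 0.05, 0.95)
    u <- c(u, v, 1 - v)
    if (extra %% 2L == 1L) u <- c(u, 0.5)
  }
  sample(u)
}

#' Render the home-spirometry manoeuvres of a subject
#'
#' For each of the configured exercise sessions a pre-exercise manoeuvre
#' (10 min before the bout) and a post-exercise manoeuvre (3-6 min after it)
#' are rendered; symptom manoeuvres are placed just before reliever
#' inhalations that are not activity-associated. Pre-exercise FEV1
#' percent-predicted values are constructed so that their mean equals the
#' subject's true pre-exercise FEV1 and their range equals the true FEV1
#' variation; post and symptom values realise the true exercise and symptom
#' changes exactly. Each planned manoeuvre is preceded by a geometric number
#' of QC-failing attempts (short expiration or excessive back-extrapolated
#' volume) with per-attempt failure probability
#' `config$spirometry$qc_fail_fraction`.
#'
#' @param profile a subject profile.
#' @param config a [cohort_config()].
#' @param reliever_times_s reliever inhalation times from
#'   [render_inhaler_log()] (used to place symptom manoeuvres).
#' @return data.frame of class `spirometry_maneuvers`: `time_s`, `tag`,
#'   `fev1_l`, `fvc_l`, `pef_ls`, `fef2575_ls`, `fet_s`, `bev_l`, `rise_ok`.
#' @export
render_spirometry_events <- function(profile, config = cohort_config(),
                                     reliever_times_s = numeric(0)) {
  set.seed(profile$seed + 33L)
  sp <- config$spirometry
  tr <- profile$truth
  ref <- reference_equations()
  pred <- vapply(c("fev1", "fvc", "pef", "fef2575"), predicted_value,
                 0, sex = profile$sex, age = profile$age,
                 height = profile$height, ref = ref)

  sched <- profile$exercise_schedule
  k <- min(sp$sessions, nrow(sched))
  days <- sort(sample(unique(sched$day), k))
  bouts <- sched[match(days, sched$day), ]

  u <- spread_fractions(k)
  pre_fev1_pct <- tr[["pre_fev1_pct"]] + tr[["fev1_variation_pct"]] * (u - 0.5)
  jig <- function(n, sd) { j <- stats::rnorm(n, 0, sd); j - mean(j) }
  pre_fef_pct <- tr[["pre_fef2575_pct"]] + jig(k, 2)
  pre_pef_pct <- tr[["pre_pef_pct"]] + jig(k, 2)

  mk <- function(time_s, tag, fev1_pct, fef_pct, pef_pct) {
    fev1 <- fev1_pct / 100 * pred[["fev1"]]
    data.frame(time_s = time_s, tag = tag, fev1_l = fev1,
               fvc_l = fev1 / sp$fvc_ratio,
               pef_ls = pef_pct / 100 * pred[["pef"]],
               fef2575_ls = fef_pct / 100 * pred[["fef2575"]],
               fet_s = sp$fet_s, bev_l = sp$bev_l, rise_ok = TRUE,
               stringsAsFactors = FALSE)
  }

  out <- list()
  for (i in seq_len(k)) {
    out[[length(out) + 1L]] <-
      mk(bouts$start_s[i] - 600, "pre-exercise", pre_fev1_pct[i],
         pre_fef_pct[i], pre_pef_pct[i])
    post_pct <- pre_fev1_pct[i] * (1 + tr[["fev1_change_exercise_pct"]] / 100)
    out[[length(out) + 1L]] <-
      mk(bouts$end_s[i] + sp$post_delay_s, "post-exercise", post_pct,
         pre_fef_pct[i] * (1 + tr[["fev1_change_exercise_pct"]] / 100),
         pre_pef_pct[i] * (1 + tr[["fev1_change_exercise_pct"]] / 100))
  }

  ## symptom manoeuvres just before non-activity reliever use
  if (length(reliever_times_s) && is.finite(tr[["fev1_change_symptom_pct"]])) {
    near_bout <- vapply(reliever_times_s, function(t)
      any(t >= sched$start_s - 45 * 60 & t <= sched$end_s + 45 * 60), TRUE)
    st <- utils::head(reliever_times_s[!near_bout], sp$max_symptom)
    base_pct <- mean(pre_fev1_pct)
    for (t in st) {
      sym_pct <- base_pct * (1 + tr[["fev1_change_symptom_pct"]] / 100)
      out[[length(out) + 1L]] <- mk(t - 120, "symptom", sym_pct,
                                    pre_fef_pct[1], pre_pef_pct[1])
    }
  }
  good <- do.call(rbind, out)

  ## failed attempts preceding each successful manoeuvre
  fails <- list()
  n_fail <- stats::rgeom(nrow(good), 1 - sp$qc_fail_fraction)
  for (i in seq_len(nrow(good))) {
    if (n_fail[i] == 0) next
    for (j in seq_len(n_fail[i])) {
      f <- good[i, ]
      f$time_s <- f$time_s - 120 * j
      f$fev1_l <- f$fev1_l * stats::runif(1, 0.55, 0.9)
      if (stats::runif(1) < 0.8) {
        f$fet_s <- stats::runif(1, 0.8, 2.5)
      } else {
        f$bev_l <- pmax(0.16, 0.06 * f$fvc_l) + 0.05
      }
      fails[[length(fails) + 1L]] <- f
    }
  }
  res <- rbind(good, do.call(rbind, fails))
  res <- res[order(res$time_s), ]
  rownames(res) <- NULL
  class(res) <- c("spirometry_maneuvers", "data.frame")
  res
}

#' Extract all spirometry-domain features of one subject
#'
#' Applies manoeuvre QC, converts to percent predicted and computes the
#' pre-exercise means, the FEV1 variation and the exercise and symptom
#' changes.
#'
#' @param maneuvers a `spirometry_maneuvers` data.frame.
#' @param sex,age,height subject covariates for the reference equations.
#' @param ref reference table (see [reference_equations()]).
#' @return named numeric vector: `pre_fev1_pct`, `pre_fef2575_pct`,
#'   `pre_pef_pct`, `fev1_variation_pct`, `fev1_change_exercise_pct`,
#'   `fev1_change_symptom_pct`.
#' @export
spirometry_features <- function(maneuvers, sex, age, height,
                                ref = reference_equations()) {
  feats <- stats::setNames(rep(NaN, 6),
                           c("pre_fev1_pct", "pre_fef2575_pct", "pre_pef_pct",
                             "fev1_variation_pct", "fev1_change_exercise_pct",
                             "fev1_change_symptom_pct"))
  if (is.null(maneuvers) || !nrow(maneuvers)) return(feats)
  qc <- qc_maneuver(maneuvers)
  m <- cbind(maneuvers, accepted = qc$accepted)
  pre <- m[m$accepted & m$tag == "pre-exercise", ]
  if (nrow(pre)) {
    feats["pre_fev1_pct"] <- mean(percent_predicted(pre$fev1_l, "fev1", sex,
                                                    age, height, ref))
    feats["pre_fef2575_pct"] <- mean(percent_predicted(pre$fef2575_ls,
                                                       "fef2575", sex, age,
                                                       height, ref))
    feats["pre_pef_pct"] <- mean(percent_predicted(pre$pef_ls, "pef", sex,
                                                   age, height, ref))
    feats["fev1_variation_pct"] <- fev1_variation(
      percent_predicted(pre$fev1_l, "fev1", sex, age, height, ref))
  }
  feats["fev1_change_exercise_pct"] <- exercise_change(m)$mean_change_pct
  feats["fev1_change_symptom_pct"] <- symptom_change(m)
  feats
}
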