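## ---------------------------------------------------------------------------
## Cohort configuration: per-group distribution specs for every home-monitoring
## parameter, plus renderer settings. The default calibration reproduces the
## group-level summaries of a two-week paediatric asthma home-monitoring study
## (27 uncontrolled / 32 controlled / 30 non-asthmatic children).
## ---------------------------------------------------------------------------

GROUPS <- c("uncontrolled", "controlled", "non_asthmatic")

#' Names of the home-monitoring parameters
#'
#' The full set of per-subject parameters extracted from the four device
#' streams (spirometry, activity, sleep, medication, heart/respiratory rate).
#' @format character vector.
#' @export
FEATURE_NAMES <- c(
  "pre_fev1_pct", "pre_fef2575_pct", "pre_pef_pct", "fev1_variation_pct",
  "fev1_change_exercise_pct", "fev1_change_symptom_pct",
  "sedentary_min", "light_min", "moderate_min", "vigorous_min",
  "bout_len_s", "weibull_scale",
  "wakeup_min", "awake_min", "time_per_awakening_min", "sleep_eff_pct",
  "tst_min", "restlessness_counts",
  "reliever_total", "reliever_before_activity", "reliever_after_activity",
  "controller_adherence_pct",
  "daytime_hr", "daytime_rr", "night_hr", "night_rr",
  "hr_recovery_s", "rr_recovery_s")

## physiological bounds per parameter (also the imputation constraints)
feature_bounds <- function() {
  b <- rbind(
    pre_fev1_pct            = c(20, 160),
    pre_fef2575_pct         = c(20, 180),
    pre_pef_pct             = c(20, 180),
    fev1_variation_pct      = c(0, 80),
    fev1_change_exercise_pct = c(-80, 50),
    fev1_change_symptom_pct = c(-90, 50),
    sedentary_min           = c(0, 1440),
    light_min               = c(0, 1440),
    moderate_min            = c(0, 600),
    vigorous_min            = c(0, 300),
    bout_len_s              = c(1, 1800),
    weibull_scale           = c(0.5, 60),
    wakeup_min              = c(240, 720),
    awake_min               = c(5, 300),
    time_per_awakening_min  = c(0.5, 30),
    sleep_eff_pct           = c(50, 100),
    tst_min                 = c(180, 840),
    restlessness_counts     = c(0, 100),
    reliever_total          = c(0, 120),
    reliever_before_activity = c(0, 60),
    reliever_after_activity = c(0, 60),
    controller_adherence_pct = c(0, 150),
    daytime_hr              = c(40, 220),
    daytime_rr              = c(8, 60),
    night_hr                = c(40, 220),
    night_rr                = c(8, 60),
    hr_recovery_s           = c(0, 900),
    rr_recovery_s           = c(0, 900))
  colnames(b) <- c("lower", "upper")
  b
}

spec_row <- function(parameter, group, family, p1, p2) {
  data.frame(parameter = parameter, group = group, family = family,
             p1 = p1, p2 = p2, stringsAsFactors = FALSE)
}

norm_spec <- function(parameter, means, sds, groups = GROUPS) {
  do.call(rbind, Map(function(g, m, s) spec_row(parameter, g, "normal", m, s),
                     groups, means, sds))
}

lnorm_spec <- function(parameter, med, q25, q75, groups = GROUPS) {
  do.call(rbind, Map(function(g, md, a, b) {
    p <- lognormal_from_quartiles(md, a, b)
    spec_row(parameter, g, "lognormal", p$meanlog, p$sdlog)
  }, groups, med, q25, q75))
}

#' Default per-group distribution specifications
#'
#' One row per (parameter, group): distribution family (`normal`, `lognormal`
#' or `poisson`) with its two parameters (`mean`/`sd`, `meanlog`/`sdlog`, or
#' `lambda`/ignored). Approximately normal parameters are modelled as
#' truncated normals at the physiological bounds; right-skewed positive
#' parameters (wake-up time, sleep restlessness, reliever counts, recovery
#' times) as log-normals matched to the reported median and IQR. Medication
#' and symptom parameters have no specification for the non-asthmatic group.
#'
#' Sleep efficiency carries a spec for reference but is *derived* for each
#' subject as `100 * TST / (TST + awake minutes)` so that the rendered night
#' architecture stays internally consistent (the calibration summaries are
#' mutually consistent to within 0.3 percentage points).
#'
#' @return data.frame with columns `parameter`, `group`, `family`, `p1`, `p2`.
#' @export
default_parameter_specs <- function() {
  asthma <- c("uncontrolled", "controlled")
  rbind(
    ## (a) spirometry ------------------------------------------------ %pred
    norm_spec("pre_fev1_pct",     c(82.2, 86.1, 98.0), c(16.0, 8.9, 9.5)),
    norm_spec("pre_fef2575_pct",  c(66.9, 75.3, 90.0), c(20.9, 17.7, 20.5)),
    norm_spec("pre_pef_pct",      c(77.4, 81.7, 98.1), c(22.2, 14.4, 18.2)),
    norm_spec("fev1_variation_pct", c(18.0, 9.4, 7.6), c(10.3, 5.4, 4.3)),
    norm_spec("fev1_change_exercise_pct", c(-11.5, -0.6, -1.6),
              c(11.9, 7.6, 3.7)),
    norm_spec("fev1_change_symptom_pct", c(-30.2, -6.1), c(21.4, 8.1),
              groups = asthma),
    ## (b) activity ------------------------------------------------ min/day
    norm_spec("sedentary_min", c(568, 566, 573), c(97, 90, 89)),
    norm_spec("light_min",     c(270, 274, 270), c(50, 51, 47)),
    norm_spec("moderate_min",  c(97, 88, 92),    c(35, 33, 30)),
    norm_spec("vigorous_min",  c(7.4, 6.0, 9.4), c(8.5, 7.9, 9.2)),
    norm_spec("bout_len_s",    c(22.7, 21.9, 22.5), c(2.3, 2.4, 2.3)),
    norm_spec("weibull_scale", c(12.9, 12.2, 12.7), c(1.9, 1.9, 1.8)),
    ## (c) sleep ------------------------------------------------------------
    lnorm_spec("wakeup_min",
               med = c(hm2min(6, 28), hm2min(7, 18), hm2min(7, 1)),
               q25 = c(hm2min(6, 17), hm2min(7, 0),  hm2min(6, 45)),
               q75 = c(hm2min(6, 59), hm2min(7, 34), hm2min(7, 20))),
    norm_spec("awake_min", c(59.9, 51.6, 53.1), c(19.9, 16.5, 17.5)),
    norm_spec("time_per_awakening_min", c(2.66, 2.40, 2.36),
              c(0.82, 0.87, 0.53)),
    norm_spec("sleep_eff_pct", c(89.0, 91.2, 90.4), c(3.8, 5.0, 3.0)),
    norm_spec("tst_min", c(496, 514, 498), c(62, 81, 54)),
    lnorm_spec("restlessness_counts",
               med = c(3.37, 2.79, 2.76), q25 = c(2.56, 1.91, 2.48),
               q75 = c(4.87, 4.12, 3.18)),
    ## (d) medication (asthmatic groups only) --------------------------------
    lnorm_spec("reliever_total", med = c(16.5, 3), q25 = c(1, 0),
               q75 = c(34, 5), groups = asthma),
    norm_spec("controller_adherence_pct", c(81.1, 92.7), c(30.9, 19.1),
              groups = asthma),
    ## (e) heart rate & respiratory rate -------------------------------------
    norm_spec("daytime_hr", c(101, 97, 102), c(17, 16, 10)),
    norm_spec("daytime_rr", c(19.7, 18.5, 19.3), c(2.9, 2.2, 2.0)),
    norm_spec("night_hr",  c(79, 72, 71), c(16, 14, 9)),
    norm_spec("night_rr",  c(17.5, 15.6, 15.2), c(2.6, 1.6, 2.2)),
    lnorm_spec("hr_recovery_s", med = c(54.4, 27.5, 29.0),
               q25 = c(36.2, 22.0, 20.2), q75 = c(111.5, 51.5, 35.1)),
    lnorm_spec("rr_recovery_s", med = c(60.7, 23.1, 16.2),
               q25 = c(35.8, 15.7, 11.1), q75 = c(101.3, 30.5, 20.3)))
}

#' Cohort configuration
#'
#' Assembles and validates the configuration consumed by [generate_cohort()]
#' and the sensor renderers.
#'
#' @param group_sizes named integer vector with counts for `uncontrolled`,
#'   `controlled` and `non_asthmatic` subjects.
#' @param specs distribution specification table
#'   (see [default_parameter_specs()]).
#' @param missingness_fraction proportion of feature cells set missing in the
#'   assembled feature matrix (default 0.115).
#' @param monitoring_days length of the home-monitoring period (days).
#' @param ecg_days number of days covered by the ambulatory ECG.
#' @param seed integer seed making the whole simulation deterministic.
#' @param ecg,actigraphy,spirometry,inhaler,exercise renderer settings;
#'   entries supplied here override the defaults (see the package vignette).
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(group_sizes = c(uncontrolled = 27, controlled = 32,
                                          non_asthmatic = 30),
                          specs = default_parameter_specs(),
                          missingness_fraction = 0.115,
                          monitoring_days = 14,
                          ecg_days = 2,
                          seed = 1L,
                          ecg = list(), actigraphy = list(),
                          spirometry = list(), inhaler = list(),
                          exercise = list()) {
  cfg <- list(
    group_sizes = group_sizes,
    specs = specs,
    missingness_fraction = missingness_fraction,
    monitoring_days = monitoring_days,
    ecg_days = ecg_days,
    seed = as.integer(seed),
    bounds = feature_bounds(),
    ecg = utils::modifyList(list(
      fs = 250,                 # Hz
      night_start_min = hm2min(1, 0),  # night segment start, min after midnight
      night_min = 20,           # rendered night segment length (min)
      pre_min = 6,              # rendered baseline before the exercise bout
      post_min = 16,            # rendered recovery window after the bout
      r_amp = 0.80, s_amp = 0.25,      # mV, baseline R / S magnitudes
      mod_depth = 0.25,         # respiratory amplitude modulation depth
      noise_sd = 0.015,         # mV additive Gaussian noise
      wander_amp = 0.10,        # mV baseline wander amplitude
      wander_freq = 0.18,       # Hz, below the 0.45 Hz high-pass edge
      hr_peak_delta = 65, rr_peak_delta = 13,  # exercise rises over baseline
      ramp_s = 90), ecg),
    actigraphy = utils::modifyList(list(
      epoch_s = 60,
      ## Evenson youth cut-points, counts/min, strict "greater than"
      cutpoints = c(sedentary = 100, light = 2295, moderate = 4011),
      sleep_onset_jitter_min = 20,
      wake_axis1 = c(300, 3000),  # waking-sleep-period count range (awakenings)
      nonwear_min_per_day = 0), actigraphy),
    spirometry = utils::modifyList(list(
      sessions = 3,             # exercise sessions with pre+post manoeuvres
      max_symptom = 2,          # symptom manoeuvres rendered (if relievers)
      qc_fail_fraction = 0.261, # per-attempt probability of a failed blow
      fvc_ratio = 0.85,         # FEV1/FVC used for rendered manoeuvres
      fet_s = 6, bev_l = 0.08,  # accepted-manoeuvre QC fields
      post_delay_s = 240), spirometry),  # post manoeuvre 3-6 min after bout
    inhaler = utils::modifyList(list(
      doses_per_day = 2,        # controller prescription
      window_min = 30,          # activity-association window
      dedup_s = 60), inhaler),
    exercise = utils::modifyList(list(
      bouts_per_day = 1,
      min_min = 6, max_min = 30,
      start_min = hm2min(16, 0),      # typical after-school start
      start_jitter_min = 60,
      ## per-group probability a reliever event is placed before / after a bout
      p_before = c(uncontrolled = 0.10, controlled = 0.05),
      p_after = c(uncontrolled = 0.14, controlled = 0.05)), exercise))
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  gs <- cfg$group_sizes
  if (!all(GROUPS %in% names(gs)))
    stop("group_sizes must name uncontrolled, controlled and non_asthmatic")
  if (any(gs < 0)) stop("group sizes must be >= 0")
  if (cfg$missingness_fraction < 0 || cfg$missingness_fraction >= 1)
    stop("missingness_fraction must lie in [0, 1)")
  sp <- cfg$specs
  bad <- setdiff(unique(sp$family), c("normal", "lognormal", "poisson"))
  if (length(bad)) stop("unknown distribution family: ", paste(bad, collapse = ", "))
  if (any(sp$family == "normal" & sp$p2 < 0))
    stop("normal scale parameters must be >= 0")
  if (any(sp$family == "lognormal" & sp$p2 < 0))
    stop("lognormal sdlog must be >= 0")
  ## every parameter must be specified for every applicable group
  med <- c("fev1_change_symptom_pct", "reliever_total",
           "reliever_before_activity", "reliever_after_activity",
           "controller_adherence_pct")
  derived <- c("reliever_before_activity", "reliever_after_activity")
  for (p in setdiff(FEATURE_NAMES, derived)) {
    need <- if (p %in% med) c("uncontrolled", "controlled") else GROUPS
    have <- sp$group[sp$parameter == p]
    if (!all(need %in% have))
      stop("parameter '", p, "' lacks a spec for group(s): ",
           paste(setdiff(need, have), collapse = ", "))
  }
  invisible(cfg)
}

## draw n values from one spec row
draw_spec <- function(family, p1, p2, n) {
  switch(family,
         normal    = stats::rnorm(n, p1, p2),
         lognormal = stats::rlnorm(n, p1, p2),
         poisson   = stats::rpois(n, p1),
         stop("unknown distribution family: ", family))
}
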