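## ---------------------------------------------------------------------------
## Sensor bundles: render all four device streams for one subject, extract
## the full feature vector, and plain-text (CSV) import/export.
## ---------------------------------------------------------------------------

#' Render the full sensor bundle of one subject
#'
#' Runs all four device renderers (inhaler first, because symptom spirometry
#' manoeuvres are placed at reliever times) and packs their outputs with the
#' subject metadata and the ground-truth exercise schedule.
#'
#' @param profile a subject profile from [generate_cohort()].
#' @param config a [cohort_config()].
#' @param noise add ECG measurement noise / baseline wander?
#' @return object of class `sensor_bundle`.
#' @export
render_sensors <- function(profile, config = cohort_config(), noise = TRUE) {
  inhaler <- render_inhaler_log(profile, config)
  rel <- inhaler$time_s[inhaler$type == "reliever"]
  structure(list(
    subject_id = profile$subject_id,
    group = profile$group,
    sex = profile$sex, age = profile$age, height = profile$height,
    monitoring_days = profile$monitoring_days,
    ecg = render_ecg(profile, config, noise = noise),
    actigraphy = render_actigraphy(profile, config),
    spirometry = render_spirometry_events(profile, config,
                                          reliever_times_s = rel),
    inhaler = inhaler,
    exercise_schedule = profile$exercise_schedule,
    gina = profile$gina, bpt_fall = profile$bpt_fall),
    class = "sensor_bundle")
}

#' @export
print.sensor_bundle <- function(x, ...) {
  cat("<sensor_bundle>", x$subject_id, "-", x$group, "\n")
  cat("  actigraphy:", nrow(x$actigraphy), "epochs; spirometry:",
      nrow(x$spirometry), "manoeuvres; inhaler:", nrow(x$inhaler),
      "events\n")
  invisible(x)
}

#' Extract the full home-monitoring feature vector of one subject
#'
#' Runs the four feature modules (ECG, actigraphy, spirometry, inhaler) on a
#' sensor bundle and returns all home-monitoring parameters as one named
#' vector.
#'
#' @param bundle a `sensor_bundle`.
#' @param config a [cohort_config()].
#' @return named numeric vector over [FEATURE_NAMES] (missing/unavailable
#'   features are NaN).
#' @export
extract_features <- function(bundle, config = cohort_config()) {
  out <- stats::setNames(rep(NaN, length(FEATURE_NAMES)), FEATURE_NAMES)
  sp <- spirometry_features(bundle$spirometry, bundle$sex, bundle$age,
                            bundle$height)
  act <- actigraphy_features(bundle$actigraphy,
                             cutpoints = config$actigraphy$cutpoints)
  inh <- inhaler_features(bundle$inhaler, bundle$exercise_schedule, config,
                          days = bundle$monitoring_days)
  ecg <- ecg_features(bundle$ecg)
  for (v in list(sp, act, inh, ecg)) out[names(v)] <- v
  out
}

#' Simulate a full cohort
#'
#' Generates subject profiles, optionally renders every sensor bundle, and
#' (when rendering) extracts the feature matrix from the raw streams.
#'
#' @param config a [cohort_config()].
#' @param render render raw sensor streams and extract features from them?
#'   If FALSE only profiles (and the ground-truth feature matrix) are
#'   returned.
#' @param noise ECG noise toggle, see [render_sensors()].
#' @return list with `profiles`, `bundles` (NULL when `render = FALSE`) and
#'   `features` (extracted when rendered, ground truth otherwise; columns
#'   `subject_id`, `group`, then one per parameter).
#' @export
simulate_cohort <- function(config = cohort_config(), render = TRUE,
                            noise = TRUE) {
  profiles <- generate_cohort(config)
  if (!render)
    return(list(profiles = profiles, bundles = NULL,
                features = profile_features(profiles)))
  bundles <- lapply(profiles, render_sensors, config = config, noise = noise)
  feats <- do.call(rbind, lapply(bundles, extract_features, config = config))
  features <- data.frame(
    subject_id = vapply(bundles, `[[`, "", "subject_id"),
    group = vapply(bundles, `[[`, "", "group"),
    feats, stringsAsFactors = FALSE)
  rownames(features) <- NULL
  list(profiles = profiles, bundles = bundles, features = features)
}

## ---- plain-text export / import -------------------------------------------

#' Write a sensor bundle as per-subject CSV files
#'
#' One directory per subject: `ecg.csv` (`time_s`, `mv`), `ecg_meta.csv`
#' (sampling rate and covered exercise bout), `actigraphy.csv`
#' (`epoch_start_iso`, axis counts, `vector_magnitude`, `wear`),
#' `spirometry.csv` (manoeuvre summaries), `inhaler.csv`
#' (`timestamp`, `inhaler_type`), `exercise.csv` and `labels.csv`.
#'
#' @param bundle a `sensor_bundle`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sensor_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ecg <- do.call(rbind, lapply(bundle$ecg$segments, function(s)
    data.frame(time_s = s$start_s + (seq_along(s$samples) - 1) / bundle$ecg$fs,
               mv = round(s$samples, 5))))
  utils::write.csv(ecg, file.path(dir, "ecg.csv"), row.names = FALSE)
  utils::write.csv(data.frame(fs = bundle$ecg$fs,
                              bout_start_s = bundle$ecg$bout[["start_s"]],
                              bout_end_s = bundle$ecg$bout[["end_s"]]),
                   file.path(dir, "ecg_meta.csv"), row.names = FALSE)
  act <- bundle$actigraphy
  utils::write.csv(data.frame(epoch_start_iso = iso_time(act$epoch_start_s),
                              axis1 = act$axis1, axis2 = act$axis2,
                              axis3 = act$axis3, vector_magnitude = act$vm,
                              wear = act$wear),
                   file.path(dir, "actigraphy.csv"), row.names = FALSE)
  spiro <- bundle$spirometry
  utils::write.csv(data.frame(timestamp = iso_time(spiro$time_s), tag = spiro$tag,
                              FEV1_L = round(spiro$fev1_l, 4),
                              FVC_L = round(spiro$fvc_l, 4),
                              PEF_Ls = round(spiro$pef_ls, 4),
                              FEF2575_Ls = round(spiro$fef2575_ls, 4),
                              FET_s = round(spiro$fet_s, 2),
                              BEV_L = round(spiro$bev_l, 3),
                              rise_ok = spiro$rise_ok),
                   file.path(dir, "spirometry.csv"), row.names = FALSE)
  utils::write.csv(data.frame(timestamp = iso_time(bundle$inhaler$time_s),
                              inhaler_type = bundle$inhaler$type),
                   file.path(dir, "inhaler.csv"), row.names = FALSE)
  utils::write.csv(bundle$exercise_schedule, file.path(dir, "exercise.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(subject_id = bundle$subject_id,
                              group = bundle$group, sex = bundle$sex,
                              age = bundle$age, height = bundle$height,
                              monitoring_days = bundle$monitoring_days,
                              t(as.integer(bundle$gina)),
                              bpt_fall = bundle$bpt_fall),
                   file.path(dir, "labels.csv"), row.names = FALSE)
  invisible(dir)
}

iso_to_sec <- function(x) {
  as.numeric(difftime(as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
                      as.POSIXct(MONITOR_ORIGIN, tz = "UTC"), units = "secs"))
}

#' Read a sensor bundle written by [write_sensor_bundle()]
#'
#' @param dir subject directory.
#' @return a `sensor_bundle`.
#' @export
read_sensor_bundle <- function(dir) {
  meta <- utils::read.csv(file.path(dir, "ecg_meta.csv"))
  ecg_df <- utils::read.csv(file.path(dir, "ecg.csv"))
  fs <- meta$fs
  ## split into contiguous segments at gaps larger than two sample periods
  brk <- c(0L, which(diff(ecg_df$time_s) > 2 / fs), nrow(ecg_df))
  segments <- lapply(seq_len(length(brk) - 1L), function(i) {
    rows <- (brk[i] + 1L):brk[i + 1L]
    list(start_s = ecg_df$time_s[rows[1]], fs = fs,
         samples = ecg_df$mv[rows])
  })
  ecg <- structure(list(fs = fs, segments = segments,
                        bout = c(start_s = meta$bout_start_s,
                                 end_s = meta$bout_end_s)),
                   class = "ecg_record")
  act_df <- utils::read.csv(file.path(dir, "actigraphy.csv"))
  act <- data.frame(epoch_start_s = iso_to_sec(act_df$epoch_start_iso),
                    axis1 = act_df$axis1, axis2 = act_df$axis2,
                    axis3 = act_df$axis3, vm = act_df$vector_magnitude,
                    wear = act_df$wear)
  class(act) <- c("epoch_series", "data.frame")
  sp_df <- utils::read.csv(file.path(dir, "spirometry.csv"))
  spiro <- data.frame(time_s = iso_to_sec(sp_df$timestamp), tag = sp_df$tag,
                      fev1_l = sp_df$FEV1_L, fvc_l = sp_df$FVC_L,
                      pef_ls = sp_df$PEF_Ls, fef2575_ls = sp_df$FEF2575_Ls,
                      fet_s = sp_df$FET_s, bev_l = sp_df$BEV_L,
                      rise_ok = sp_df$rise_ok, stringsAsFactors = FALSE)
  class(spiro) <- c("spirometry_maneuvers", "data.frame")
  inh_df <- utils::read.csv(file.path(dir, "inhaler.csv"))
  inhaler <- data.frame(time_s = iso_to_sec(inh_df$timestamp),
                        type = inh_df$inhaler_type, stringsAsFactors = FALSE)
  class(inhaler) <- c("inhaler_log", "data.frame")
  lab <- utils::read.csv(file.path(dir, "labels.csv"))
  structure(list(subject_id = lab$subject_id, group = lab$group,
                 sex = lab$sex, age = lab$age, height = lab$height,
                 monitoring_days = lab$monitoring_days,
                 ecg = ecg, actigraphy = act, spirometry = spiro,
                 inhaler = inhaler,
                 exercise_schedule = utils::read.csv(file.path(dir,
                                                               "exercise.csv")),
                 gina = as.logical(unlist(lab[paste0("X", 1:4)])),
                 bpt_fall = lab$bpt_fall),
            class = "sensor_bundle")
}

#' Write a whole simulated cohort to disk
#'
#' One directory per subject plus a `manifest.csv` listing subject id, group
#' and directory.
#'
#' @param cohort result of [simulate_cohort()].
#' @param dir output directory.
#' @return path of the manifest file, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort$bundles, function(b) {
    sub <- file.path(dir, b$subject_id)
    write_sensor_bundle(b, sub)
    data.frame(subject_id = b$subject_id, group = b$group,
               dir = b$subject_id)
  })
  manifest <- do.call(rbind, rows)
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}
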