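## ---------------------------------------------------------------------------
## End-to-end pipeline: feature matrix -> labels -> multiple imputation ->
## stepwise multivariate model -> classification metrics.
## ---------------------------------------------------------------------------

## skewed parameters modelled on the log scale inside the imputation model
LOG_SCALE_FEATURES <- c("reliever_total", "reliever_before_activity",
                        "reliever_after_activity", "restlessness_counts",
                        "hr_recovery_s", "rr_recovery_s")

#' Label every subject of a cohort
#'
#' Applies the asthma-control labelling rule to the asthmatic subjects of a
#' cohort; non-asthmatic subjects keep their group label.
#'
#' @param profiles subject profiles (or sensor bundles carrying `gina` /
#'   `bpt_fall` and `group`).
#' @return data.frame with `subject_id`, `group`, `label`, `basis`.
#' @export
label_cohort <- function(profiles) {
  rows <- lapply(profiles, function(p) {
    if (p$group == "non_asthmatic") {
      lab <- list(label = "non_asthmatic", basis = "n/a")
    } else {
      lab <- label_control(p$gina, p$bpt_fall)
    }
    data.frame(subject_id = p$subject_id, group = p$group,
               label = lab$label, basis = lab$basis,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Fit the asthma-control model on a cohort feature matrix
#'
#' Restricts to the asthmatic subjects (the model is built only on them, with
#' the controlled group as reference), multiply imputes the feature matrix
#' under the physiological bounds, runs the stepwise forward likelihood-ratio
#' selection and pools the final model, then classifies the training subjects
#' by the across-imputation mean predicted probability.
#'
#' @param features feature matrix with `subject_id`, `group` columns (e.g.
#'   from [simulate_cohort()]), possibly with injected missingness.
#' @param labels binary outcome for the asthmatic rows, or NULL to use the
#'   `group` column (uncontrolled = 1).
#' @param config a [cohort_config()] (provides the imputation bounds).
#' @param m,seed imputation count and seed.
#' @param entry,removal stepwise probabilities.
#' @param threshold classification threshold.
#' @return list of class `control_fit`: `model`, `imputed`, `metrics`
#'   (in-sample classification), `labels`, `scores`.
#' @export
fit_control_pipeline <- function(features, labels = NULL,
                                 config = cohort_config(), m = 5,
                                 seed = 1L, entry = 0.10, removal = 0.20,
                                 threshold = 0.5) {
  asth <- features$group %in% c("uncontrolled", "controlled")
  fa <- features[asth, , drop = FALSE]
  y <- if (is.null(labels)) as.numeric(fa$group == "uncontrolled") else
    as.numeric(labels[asth])
  num <- vapply(fa, is.numeric, TRUE)
  X <- as.matrix(fa[, num, drop = FALSE])
  ## drop columns unusable for imputation (almost entirely missing)
  keep <- colSums(!is.na(X)) >= max(3, 0.2 * nrow(X))
  X <- X[, keep, drop = FALSE]
  bounds <- config$bounds[colnames(X), , drop = FALSE]
  imp <- impute(X, m = m, seed = seed, bounds = bounds,
                log_cols = intersect(LOG_SCALE_FEATURES, colnames(X)))
  model <- stepwise_logistic(imp, y, entry = entry, removal = removal)
  ## in-sample classification: mean predicted probability across imputations
  p_mat <- vapply(imp$imputations, function(d)
    score_control(model, as.data.frame(d), threshold = threshold)$p,
    numeric(length(y)))
  p_bar <- rowMeans(p_mat)
  pred_unc <- p_bar > threshold
  metrics <- classification_metrics(tp = sum(pred_unc & y == 1),
                                    fn = sum(!pred_unc & y == 1),
                                    fp = sum(pred_unc & y == 0),
                                    tn = sum(!pred_unc & y == 0))
  out <- list(model = model, imputed = imp, metrics = metrics,
              labels = y, scores = p_bar,
              subject_id = fa$subject_id)
  class(out) <- "control_fit"
  out
}

#' @export
print.control_fit <- function(x, ...) {
  print(x$model)
  print(x$metrics)
  invisible(x)
}

#' Serialise a control model to JSON
#'
#' @param model a `control_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_control_model <- function(model, path) {
  jsonlite::write_json(list(
    features = model$features,
    coefficients = as.list(model$coefficients),
    se = as.list(model$se),
    nagelkerke_r2 = model$nagelkerke_r2,
    firth = model$firth, n = model$n, m = model$m),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a control model written by [write_control_model()]
#'
#' @param path JSON file.
#' @return a `control_model`.
#' @export
read_control_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- list(features = j$features,
                coefficients = unlist(j$coefficients),
                se = unlist(j$se), pooled = NULL,
                nagelkerke_r2 = j$nagelkerke_r2 %||% NA_real_,
                firth = isTRUE(j$firth), selection = NULL,
                n = j$n %||% NA_integer_, m = j$m %||% 0L)
  class(model) <- "control_model"
  model
}
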