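## ---------------------------------------------------------------------------
## Asthma-control labelling, collinearity screen, stepwise forward
## likelihood-ratio logistic regression on multiply-imputed data (pooled by
## Rubin's rules, model choice by Nagelkerke R^2), odds ratios, scoring and
## diagnostic validity measures.
## ---------------------------------------------------------------------------

#' Label asthma control from symptom items and the exercise challenge
#'
#' An asthmatic child is labelled uncontrolled when at least 3 of the 4
#' symptom-control items of the past four weeks are present (frequent daytime
#' symptoms, frequent reliever use, nocturnal symptoms, activity limitation)
#' OR when the exercise bronchoprovocation challenge is positive (maximal
#' FEV1 fall strictly greater than 12%); controlled otherwise. The basis
#' records which clause fired.
#'
#' @param gina logical vector of length 4 (the four symptom items), or a
#'   count of positive items.
#' @param bpt_fall maximal post-exercise FEV1 fall (%), positive = fall.
#' @return list of class `control_label`: `label` (`"uncontrolled"` /
#'   `"controlled"`) and `basis` (`"GINA"`, `"BPT"`, `"both"`, `"n/a"`).
#' @export
label_control <- function(gina, bpt_fall) {
  n_items <- if (is.logical(gina)) sum(gina) else as.numeric(gina)
  if (is.logical(gina) && length(gina) != 4)
    stop("gina must supply all four symptom items")
  if (bpt_fall < -20 || bpt_fall > 100)
    stop("bpt_fall outside the plausible range [-20, 100]")
  g <- n_items >= 3
  b <- bpt_fall > 12
  label <- if (g || b) "uncontrolled" else "controlled"
  basis <- if (g && b) "both" else if (g) "GINA" else if (b) "BPT" else "n/a"
  structure(list(label = label, basis = basis), class = "control_label")
}

#' Screen features for pairwise multi-collinearity
#'
#' Flags feature pairs whose absolute pairwise-complete Pearson correlation
#' exceeds the threshold (strictly); the stepwise selection never holds both
#' members of a flagged pair in the same model.
#'
#' @param x numeric feature matrix / data.frame.
#' @param threshold correlation magnitude above which a pair is flagged.
#' @return data.frame of flagged pairs (`var1`, `var2`, `r`).
#' @export
collinearity_screen <- function(x, threshold = 0.8) {
  xm <- as.matrix(x)
  r <- suppressWarnings(stats::cor(xm, use = "pairwise.complete.obs"))
  idx <- which(abs(r) > threshold & upper.tri(r), arr.ind = TRUE)
  data.frame(var1 = colnames(r)[idx[, 1]], var2 = colnames(r)[idx[, 2]],
             r = r[idx], stringsAsFactors = FALSE)
}

## ---- logistic fitting helpers ---------------------------------------------

logistic <- function(eta) 1 / (1 + exp(-eta))

## Firth-penalised logistic regression (Jeffreys prior), used as fallback
## under (quasi-)separation
firth_logistic <- function(X, y, max_iter = 100, tol = 1e-8) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- as.vector(X %*% beta)
    p <- logistic(eta)
    w <- p * (1 - p)
    XW <- X * sqrt(w)
    info <- crossprod(XW)
    inv <- solve(info + diag(1e-10, ncol(X)))
    h <- rowSums((XW %*% inv) * XW)
    u <- as.vector(t(X) %*% (y - p + h * (0.5 - p)))
    step <- inv %*% u
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  eta <- as.vector(X %*% beta)
  p <- logistic(eta)
  w <- p * (1 - p)
  info <- crossprod(X * sqrt(w))
  ll <- sum(y * log(pmax(p, 1e-12)) + (1 - y) * log(pmax(1 - p, 1e-12)))
  list(coef = as.vector(beta), vcov = solve(info + diag(1e-10, ncol(X))),
       loglik = ll, fitted = p, firth = TRUE)
}

separated <- function(fit) {
  any(abs(stats::coef(fit)) > 15) ||
    !fit$converged ||
    any(fit$fitted.values > 1 - 1e-8) || any(fit$fitted.values < 1e-8)
}

## fit logistic y ~ terms on data (data.frame), with Firth fallback
fit_logistic <- function(data, y, terms) {
  X <- cbind(`(Intercept)` = 1,
             as.matrix(data[, terms, drop = FALSE]))
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial()))
  if (separated(fit)) {
    f <- firth_logistic(X, y)
    return(list(coef = stats::setNames(f$coef, colnames(X)),
                vcov = f$vcov, loglik = f$loglik, fitted = f$fitted,
                firth = TRUE, n = length(y)))
  }
  p <- fit$fitted.values
  ll <- sum(y * log(pmax(p, 1e-12)) + (1 - y) * log(pmax(1 - p, 1e-12)))
  w <- p * (1 - p)
  info <- crossprod(X * sqrt(w))
  list(coef = stats::coef(fit), vcov = solve(info + diag(1e-12, ncol(X))),
       loglik = ll, fitted = p, firth = FALSE, n = length(y))
}

loglik_null <- function(y) {
  p <- mean(y)
  sum(y * log(pmax(p, 1e-12)) + (1 - y) * log(pmax(1 - p, 1e-12)))
}

#' Nagelkerke pseudo R-squared
#'
#' Cox-Snell R-squared rescaled by its maximum:
#' `(1 - (L0/L1)^(2/n)) / (1 - L0^(2/n))`, computed from the log-likelihoods
#' of the null and fitted model.
#'
#' @param ll1 log-likelihood of the fitted model.
#' @param ll0 log-likelihood of the intercept-only model.
#' @param n number of observations.
#' @return value in `[0, 1]`.
#' @export
nagelkerke_r2 <- function(ll1, ll0, n) {
  cs <- 1 - exp((2 / n) * (ll0 - ll1))
  cs_max <- 1 - exp((2 / n) * ll0)
  if (cs_max <= 0) return(0)
  max(0, min(1, cs / cs_max))
}

## one stepwise forward-LR selection with backward removal on one dataset
stepwise_one <- function(data, y, candidates, entry, removal, banned_pairs) {
  selected <- character(0)
  ll_curr <- loglik_null(y)
  trace <- list()
  conflicted <- function(cand, sel) {
    if (!nrow(banned_pairs)) return(FALSE)
    any((banned_pairs$var1 == cand & banned_pairs$var2 %in% sel) |
          (banned_pairs$var2 == cand & banned_pairs$var1 %in% sel))
  }
  repeat {
    pool <- setdiff(candidates, selected)
    pool <- pool[!vapply(pool, conflicted, TRUE, sel = selected)]
    if (!length(pool)) break
    ps <- vapply(pool, function(cand) {
      fit <- fit_logistic(data, y, c(selected, cand))
      stats::pchisq(2 * (fit$loglik - ll_curr), df = 1, lower.tail = FALSE)
    }, 0)
    best <- names(ps)[which.min(ps)]
    if (ps[best] >= entry) break
    selected <- c(selected, best)
    ll_curr <- fit_logistic(data, y, selected)$loglik
    trace[[length(trace) + 1L]] <- list(action = "add", term = best,
                                        p = unname(ps[best]))
    ## backward pass: drop terms whose LR p exceeds the removal threshold
    repeat {
      if (length(selected) < 2L) break
      drop_p <- vapply(selected, function(term) {
        rest <- setdiff(selected, term)
        ll_red <- if (length(rest)) fit_logistic(data, y, rest)$loglik else
          loglik_null(y)
        stats::pchisq(2 * (ll_curr - ll_red), df = 1, lower.tail = FALSE)
      }, 0)
      worst <- names(drop_p)[which.max(drop_p)]
      if (drop_p[worst] <= removal) break
      selected <- setdiff(selected, worst)
      ll_curr <- if (length(selected)) fit_logistic(data, y, selected)$loglik
        else loglik_null(y)
      trace[[length(trace) + 1L]] <- list(action = "remove", term = worst,
                                          p = unname(drop_p[worst]))
    }
  }
  list(selected = selected, trace = trace)
}

## pooled refit of a fixed feature set across imputations
pool_fit <- function(imps, y, terms) {
  m <- length(imps)
  k <- length(terms) + 1L
  est <- matrix(NA_real_, m, k)
  vs <- matrix(NA_real_, m, k)
  r2 <- numeric(m)
  firth_any <- FALSE
  ll0 <- loglik_null(y)
  for (i in seq_len(m)) {
    d <- as.data.frame(imps[[i]])
    fit <- if (length(terms)) fit_logistic(d, y, terms) else
      list(coef = stats::setNames(stats::qlogis(mean(y)), "(Intercept)"),
           vcov = matrix(1 / (length(y) * mean(y) * (1 - mean(y)))),
           loglik = ll0, firth = FALSE)
    est[i, ] <- fit$coef[seq_len(k)]
    vs[i, ] <- diag(fit$vcov)[seq_len(k)]
    r2[i] <- nagelkerke_r2(fit$loglik, ll0, length(y))
    firth_any <- firth_any || isTRUE(fit$firth)
  }
  colnames(est) <- colnames(vs) <- c("(Intercept)", terms)
  pooled <- pool_rubin(est, vs)
  list(pooled = pooled, r2 = mean(r2), r2_per_imp = r2, firth = firth_any)
}

#' Stepwise multivariate logistic model on multiply-imputed data
#'
#' Within each imputed dataset, forward stepwise selection adds the candidate
#' with the smallest likelihood-ratio p-value while it is below the entry
#' probability, then removes any term whose likelihood-ratio p-value exceeds
#' the removal probability; flagged collinear pairs are never held jointly.
#' Candidate feature sets (each per-imputation selection plus the
#' majority-vote set) are refit on all imputations, their coefficients pooled
#' by Rubin's rules, and the set with the highest pooled Nagelkerke R-squared
#' is retained (ties broken by fewer terms). Separation is handled by a
#' Firth-penalised refit and flagged.
#'
#' @param imputed an [impute()] result (or a list of completed matrices).
#' @param labels binary outcome (1 = uncontrolled, 0 = controlled; the
#'   controlled group is the reference); non-asthmatic subjects must be
#'   excluded before calling.
#' @param entry,removal likelihood-ratio entry / removal probabilities.
#' @param candidates candidate feature names (default: all columns).
#' @param collinearity_threshold see [collinearity_screen()].
#' @return object of class `control_model`: selected features, pooled
#'   coefficients and covariance diagonal, per-imputation selection trace,
#'   pooled Nagelkerke R-squared.
#' @export
stepwise_logistic <- function(imputed, labels, entry = 0.10, removal = 0.20,
                              candidates = NULL,
                              collinearity_threshold = 0.8) {
  imps <- if (inherits(imputed, "imputed_set")) imputed$imputations else
    imputed
  y <- as.numeric(labels)
  stopifnot(all(y %in% c(0, 1)), nrow(imps[[1]]) == length(y))
  candidates <- candidates %||% colnames(imps[[1]])
  banned <- collinearity_screen(imps[[1]][, candidates, drop = FALSE],
                                collinearity_threshold)

  sels <- lapply(imps, function(d)
    stepwise_one(as.data.frame(d), y, candidates, entry, removal, banned))
  sets <- lapply(sels, `[[`, "selected")
  votes <- table(unlist(sets))
  majority <- names(votes)[votes >= ceiling(length(imps) / 2)]
  cand_sets <- unique(c(lapply(sets, sort),
                        if (length(majority)) list(sort(majority))))
  cand_sets <- Filter(length, cand_sets)
  if (!length(cand_sets)) cand_sets <- list(character(0))

  fits <- lapply(cand_sets, function(s) pool_fit(imps, y, s))
  r2s <- vapply(fits, `[[`, 0, "r2")
  sizes <- lengths(cand_sets)
  best <- order(-r2s, sizes)[1]

  fit <- fits[[best]]
  model <- list(features = cand_sets[[best]],
                coefficients = stats::setNames(fit$pooled$estimate,
                                               rownames(fit$pooled)),
                se = stats::setNames(fit$pooled$se, rownames(fit$pooled)),
                pooled = fit$pooled,
                nagelkerke_r2 = fit$r2,
                firth = fit$firth,
                selection = list(per_imputation = sets, majority = majority,
                                 candidate_sets = cand_sets, r2 = r2s,
                                 trace = lapply(sels, `[[`, "trace")),
                n = length(y), m = length(imps))
  class(model) <- "control_model"
  model
}

#' Construct a control-classification model from fixed coefficients
#'
#' Builds a `control_model` directly from known per-feature log-odds
#' coefficients (and optionally an intercept and standard errors), e.g. to
#' score subjects with a previously fitted model.
#'
#' @param coefficients named numeric vector of feature coefficients
#'   (log-odds per unit).
#' @param intercept optional intercept.
#' @param se optional named standard errors.
#' @return a `control_model`.
#' @export
control_model <- function(coefficients, intercept = NULL, se = NULL) {
  stopifnot(!is.null(names(coefficients)))
  co <- c(`(Intercept)` = intercept %||% NA_real_, coefficients)
  model <- list(features = names(coefficients), coefficients = co,
                se = se, pooled = NULL, nagelkerke_r2 = NA_real_,
                firth = FALSE, selection = NULL, n = NA_integer_, m = 0L)
  class(model) <- "control_model"
  model
}

#' @export
print.control_model <- function(x, digits = 3, ...) {
  cat("<control_model>", length(x$features), "feature(s)")
  if (is.finite(x$nagelkerke_r2))
    cat(sprintf(", Nagelkerke R^2 = %.2f", x$nagelkerke_r2))
  if (isTRUE(x$firth)) cat(" [Firth-penalised]")
  cat("\n")
  tab <- odds_ratios(x)
  print(round(tab[, c("coef", "or", "lower", "upper")], digits))
  invisible(x)
}

#' Odds ratios and confidence intervals of a control model
#'
#' `OR = exp(beta)` with Wald 95% limits `exp(beta +/- 1.96 se)`; the inverse
#' odds ratio `exp(-beta)` is also reported, which is the natural reading for
#' negatively coded features (e.g. odds per minute *earlier* wake-up time).
#'
#' @param model a `control_model`.
#' @param conf confidence level.
#' @return data.frame with `coef`, `se`, `or`, `lower`, `upper`,
#'   `inverse_or`, one row per feature.
#' @export
odds_ratios <- function(model, conf = 0.95) {
  feats <- model$features
  beta <- model$coefficients[feats]
  se <- if (!is.null(model$se)) model$se[feats] else rep(NA_real_,
                                                         length(feats))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  data.frame(coef = beta, se = se, or = exp(beta),
             lower = exp(beta - z * se), upper = exp(beta + z * se),
             inverse_or = exp(-beta), row.names = feats)
}

#' Score subjects with a control model
#'
#' `p = logistic(b0 + sum(beta_j x_j))`; a subject is classified uncontrolled
#' when `p` is strictly greater than the threshold.
#'
#' @param model a `control_model`; its intercept must be available or
#'   supplied via `intercept`.
#' @param features data.frame / matrix containing the model's features
#'   (imputed; no missing values among them).
#' @param threshold classification threshold on the probability scale.
#' @param intercept overrides / supplies the intercept.
#' @return data.frame with `p` and `class` (`"uncontrolled"` /
#'   `"controlled"`).
#' @export
score_control <- function(model, features, threshold = 0.5,
                          intercept = NULL) {
  b0 <- intercept %||% model$coefficients[["(Intercept)"]]
  if (is.null(b0) || is.na(b0))
    stop("model has no intercept; supply one via `intercept`")
  X <- as.matrix(as.data.frame(features)[, model$features, drop = FALSE])
  eta <- b0 + as.vector(X %*% model$coefficients[model$features])
  p <- logistic(eta)
  data.frame(p = p,
             class = ifelse(p > threshold, "uncontrolled", "controlled"),
             stringsAsFactors = FALSE)
}

#' Diagnostic validity measures from a 2x2 classification matrix
#'
#' Sensitivity, specificity, positive and negative predictive value from the
#' confusion-matrix cell counts.
#'
#' @param tp,fn,fp,tn cell counts (true/false positives/negatives), or a 2x2
#'   matrix as first argument with predictions in rows (positive first) and
#'   truth in columns (positive first).
#' @return list of class `classification_metrics` with proportions
#'   (`sensitivity`, ...) and percentages rounded to 1 decimal (`*_pct`).
#' @export
classification_metrics <- function(tp, fn = NULL, fp = NULL, tn = NULL) {
  if (is.matrix(tp)) {
    m <- tp
    fp <- m[1, 2]; fn <- m[2, 1]; tn <- m[2, 2]; tp <- m[1, 1]
  }
  stopifnot(tp >= 0, fn >= 0, fp >= 0, tn >= 0)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  ppv <- tp / (tp + fp)
  npv <- tn / (tn + fn)
  out <- list(matrix = matrix(c(tp, fn, fp, tn), 2, 2,
                              dimnames = list(predicted = c("uncontrolled",
                                                            "controlled"),
                                              truth = c("uncontrolled",
                                                        "controlled"))),
              sensitivity = sens, specificity = spec, ppv = ppv, npv = npv,
              sensitivity_pct = round(100 * sens, 1),
              specificity_pct = round(100 * spec, 1),
              ppv_pct = round(100 * ppv, 1),
              npv_pct = round(100 * npv, 1))
  class(out) <- "classification_metrics"
  out
}

#' @export
print.classification_metrics <- function(x, ...) {
  print(x$matrix)
  cat(sprintf("sensitivity %.1f%%  specificity %.1f%%  PPV %.1f%%  NPV %.1f%%\n",
              x$sensitivity_pct, x$specificity_pct, x$ppv_pct, x$npv_pct))
  invisible(x)
}

#' Reference four-parameter control-classification model
#'
#' The pre-specified reference model associating home-monitoring parameters
#' with uncontrolled asthma: per-unit log-odds of 0.292 for the variation in
#' pre-exercise FEV1 (percent-predicted points), -0.053 for wake-up time
#' (minutes after midnight; i.e. higher odds per minute earlier), 0.100 for
#' the two-week reliever-use count, and 0.113 for the respiratory-rate
#' recovery time (seconds). The original fit does not publish an intercept;
#' scoring therefore requires one. `calibrate_intercept()` refits only the
#' intercept (offsetting the fixed coefficients) on a labelled dataset, and
#' `default_intercept = TRUE` installs a value calibrated that way on this
#' package's own synthetic cohort (a synthetic calibration, not part of the
#' original model).
#'
#' @param default_intercept install the synthetic-calibration intercept?
#' @return a `control_model`.
#' @export
reference_control_model <- function(default_intercept = FALSE) {
  m <- control_model(
    coefficients = c(fev1_variation_pct = 0.292, wakeup_min = -0.053,
                     reliever_total = 0.100, rr_recovery_s = 0.113),
    se = c(`(Intercept)` = NA_real_, fev1_variation_pct = 0.1162,
           wakeup_min = 0.0210, reliever_total = 0.0364,
           rr_recovery_s = 0.0346))
  if (default_intercept)
    m$coefficients[["(Intercept)"]] <- .synthetic_reference_intercept
  m
}

## Intercept for the reference model calibrated once on this package's
## default synthetic cohort (seed 20201, intercept-only refit with the four
## reference coefficients as offset). Synthetic calibration - not a published
## model parameter.
.synthetic_reference_intercept <- 11.666

#' Calibrate the intercept of a fixed-coefficient model
#'
#' Fits an intercept-only logistic regression with the model's linear
#' predictor as offset, leaving the feature coefficients untouched.
#'
#' @param model a `control_model`.
#' @param features data (must contain the model's features, complete).
#' @param labels binary outcome (1 = uncontrolled).
#' @return the model with the calibrated intercept filled in.
#' @export
calibrate_intercept <- function(model, features, labels) {
  X <- as.matrix(as.data.frame(features)[, model$features, drop = FALSE])
  off <- as.vector(X %*% model$coefficients[model$features])
  keep <- stats::complete.cases(X) & !is.na(labels)
  fit <- stats::glm(labels[keep] ~ 1 + offset(off[keep]),
                    family = stats::binomial())
  model$coefficients[["(Intercept)"]] <- unname(stats::coef(fit)[1])
  model
}
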