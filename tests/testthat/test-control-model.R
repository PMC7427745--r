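test_that("control labelling implements the symptom-OR-challenge rule", {
  l1 <- label_control(c(TRUE, TRUE, TRUE, FALSE), 5)
  expect_equal(l1$label, "uncontrolled")
  expect_equal(l1$basis, "GINA")
  ## boundary: a 12.0% fall is NOT positive (strict >)
  l2 <- label_control(c(FALSE, FALSE, FALSE, FALSE), 12.0)
  expect_equal(l2$label, "controlled")
  l3 <- label_control(c(TRUE, TRUE, TRUE, FALSE), 27.9)
  expect_equal(l3$basis, "both")
  l4 <- label_control(c(FALSE, FALSE, FALSE, FALSE), 12.1)
  expect_equal(l4$label, "uncontrolled")
  expect_equal(l4$basis, "BPT")
  expect_error(label_control(c(TRUE, TRUE, TRUE), 5), "four")
})

test_that("labelling is monotone in symptoms and challenge fall", {
  for (k in 0:3) {
    for (fall in c(0, 8, 12, 20)) {
      a <- label_control(seq_len(4) <= k, fall)$label
      b <- label_control(seq_len(4) <= (k + 1), fall)$label
      c_ <- label_control(seq_len(4) <= k, fall + 5)$label
      ranks <- c(controlled = 0, uncontrolled = 1)
      expect_gte(ranks[b], ranks[a])
      expect_gte(ranks[c_], ranks[a])
    }
  }
})

test_that("collinearity screen flags strictly above the threshold", {
  set.seed(12)
  x <- matrix(rnorm(3000), 1000, 3, dimnames = list(NULL, c("a", "b", "c")))
  expect_equal(nrow(collinearity_screen(x)), 0)
  xd <- cbind(x, d = x[, "a"])
  fl <- collinearity_screen(xd)
  expect_equal(nrow(fl), 1)
  expect_setequal(unlist(fl[1, 1:2]), c("a", "d"))
  ## strictness: a pair at the threshold is not flagged
  y <- cbind(u = x[, 1], v = 0.85 * scale(x[, 1]) +
               sqrt(1 - 0.85^2) * scale(resid(lm(x[, 2] ~ x[, 1]))))
  r <- abs(cor(y)[1, 2])
  expect_equal(nrow(collinearity_screen(y, threshold = r)), 0)
  expect_equal(nrow(collinearity_screen(y, threshold = r - 1e-6)), 1)
})

test_that("Nagelkerke R-squared matches the rescaled Cox-Snell formula", {
  n <- 4
  ll0 <- n * log(0.5)
  expect_equal(nagelkerke_r2(ll0, ll0, n), 0)
  ## hand-computed toy likelihoods
  ll1 <- log(0.9) + log(0.9) + log(0.8) + log(0.7)
  cs <- 1 - exp((2 / n) * (ll0 - ll1))
  expect_equal(nagelkerke_r2(ll1, ll0, n), cs / (1 - exp((2 / n) * ll0)))
  ## perfectly separable fit approaches 1
  expect_gte(nagelkerke_r2(-1e-9, ll0, n), 0.999)
})

test_that("odds-ratio arithmetic and exp/log round trip", {
  m <- reference_control_model()
  or <- odds_ratios(m)
  expect_equal(round(or["fev1_variation_pct", "or"], 2), 1.34)
  expect_equal(round(or["wakeup_min", "or"], 3), 0.948)
  expect_equal(round(or["wakeup_min", "inverse_or"], 2), 1.05)
  expect_equal(round(or["reliever_total", "or"], 2), 1.11)
  expect_equal(round(or["rr_recovery_s", "or"], 2), 1.12)
  ## beta = 0 -> OR 1
  m0 <- control_model(c(x = 0), intercept = 0)
  expect_equal(odds_ratios(m0)["x", "or"], 1)
  ## round trip: log(OR) returns beta
  expect_equal(log(or$or), unname(m$coefficients[m$features]))
})

test_that("scoring uses a strict probability threshold and the model odds", {
  m0 <- control_model(c(x = 0), intercept = 0)
  s <- score_control(m0, data.frame(x = c(-5, 0, 5)))
  expect_equal(s$p, rep(0.5, 3))
  expect_equal(s$class, rep("controlled", 3))   # p == 0.5 is not > 0.5
  ## one extra reliever inhalation multiplies the odds by exp(0.100)
  m <- reference_control_model(default_intercept = TRUE)
  base <- data.frame(fev1_variation_pct = 15, wakeup_min = 400,
                     reliever_total = 10, rr_recovery_s = 40)
  plus <- base
  plus$reliever_total <- 11
  p1 <- score_control(m, base)$p
  p2 <- score_control(m, plus)$p
  odds <- function(p) p / (1 - p)
  expect_equal(odds(p2) / odds(p1), exp(0.100), tolerance = 1e-9)
  ## +10.5% risk of uncontrolled asthma per inhalation
  expect_equal(round(100 * (exp(0.100) - 1), 1), 10.5)
  expect_error(score_control(reference_control_model(), base), "intercept")
})

test_that("classification metrics cover degenerate matrices", {
  perfect <- classification_metrics(10, 0, 0, 12)
  expect_equal(perfect$sensitivity_pct, 100)
  expect_equal(perfect$npv_pct, 100)
  wrong <- classification_metrics(0, 10, 12, 0)
  expect_equal(wrong$sensitivity_pct, 0)
  expect_equal(wrong$specificity_pct, 0)
  ## matrix input matches cell input
  m <- classification_metrics(matrix(c(24, 3, 3, 29), 2, 2))
  expect_equal(m$sensitivity, 24 / 27)
})

test_that("stepwise selection returns an empty model for pure noise", {
  set.seed(14)
  n <- 80
  x <- matrix(rnorm(n), n, 1, dimnames = list(NULL, "noise"))
  y <- rbinom(n, 1, 0.5)
  ## pick a draw where the single feature is clearly unrelated
  while (summary(glm(y ~ x, family = binomial()))$coef[2, 4] < 0.3) {
    x[] <- rnorm(n)
    y <- rbinom(n, 1, 0.5)
  }
  imp <- impute(x, m = 3, seed = 15)
  mod <- stepwise_logistic(imp, y)
  expect_length(mod$features, 0)
  expect_equal(mod$nagelkerke_r2, 0)
})

test_that("model JSON serialisation round-trips", {
  m <- reference_control_model(default_intercept = TRUE)
  path <- tempfile(fileext = ".json")
  write_control_model(m, path)
  back <- read_control_model(path)
  expect_equal(back$features, m$features)
  expect_equal(back$coefficients, m$coefficients)
  unlink(path)
})

test_that("univariate report gates tests by normality and detects separation", {
  set.seed(16)
  g <- rep(c("a", "b", "c"), each = 100)
  feats <- data.frame(
    same = rnorm(300),                          # same distribution everywhere
    shifted = rnorm(300, rep(c(0, 3, 6), each = 100)),  # 3-SD separated means
    skewed = rexp(300, rep(c(1, 1, 0.3), each = 100)))  # non-normal column
  rep_ <- univariate_report(feats, g)
  expect_gt(rep_$p[rep_$parameter == "same"], 0.05)
  expect_lt(rep_$p[rep_$parameter == "shifted"], 0.001)
  expect_match(rep_$test[rep_$parameter == "skewed"], "Kruskal")
  ## categorical column routes to chi-square
  feats2 <- data.frame(flag = rep(c(TRUE, FALSE), 150))
  rep2 <- univariate_report(feats2, g)
  expect_equal(rep2$test, "chi-square")
})

test_that("held-out classification of simulated cohorts stays in a plausible band", {
  set.seed(17)
  sens <- spec <- numeric(12)
  for (r in 1:12) {
    cfg <- cohort_config(group_sizes = c(uncontrolled = 41, controlled = 48,
                                         non_asthmatic = 0), seed = 1700 + r)
    f <- simulate_cohort(cfg, render = FALSE)$features
    f <- apply_missingness(f, 0.115, seed = 2700 + r)
    test_idx <- c(1:14, 42:57)               # hold out a third of each group
    train <- f[-test_idx, ]
    test <- f[test_idx, ]
    fit <- fit_control_pipeline(train, config = cfg, m = 3,
                                seed = 3700 + r)
    ## score held-out subjects on their imputed feature values
    imp_te <- impute(as.matrix(test[, vapply(test, is.numeric, TRUE)]),
                     m = 3, seed = 4700 + r,
                     bounds = cfg$bounds, burnin = 80, thin = 5,
                     log_cols = intersect(asthmon:::LOG_SCALE_FEATURES,
                                          names(test)))
    p <- rowMeans(vapply(imp_te$imputations, function(d)
      score_control(fit$model, as.data.frame(d))$p,
      numeric(nrow(test))))
    truth <- test$group == "uncontrolled"
    sens[r] <- mean(p[truth] > 0.5)
    spec[r] <- mean(p[!truth] <= 0.5)
  }
  expect_gte(median(sens), 0.7)
  expect_gte(median(spec), 0.7)
})
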