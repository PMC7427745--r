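## ---------------------------------------------------------------------------
## Univariate group comparisons: normality/variance-homogeneity gate routing
## each parameter to ANOVA + Tukey HSD or Kruskal-Wallis + Games-Howell;
## chi-square for categoricals. Reporting plumbing over standard routines.
## ---------------------------------------------------------------------------

## Games-Howell pairwise comparisons (Welch t statistics against the
## studentised-range distribution)
games_howell <- function(x, g) {
  g <- factor(g)
  lev <- levels(g)
  stats_by <- lapply(lev, function(l) {
    v <- x[g == l & !is.na(x)]
    c(n = length(v), m = mean(v), v = stats::var(v))
  })
  names(stats_by) <- lev
  pairs <- utils::combn(lev, 2, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    a <- stats_by[[pr[1]]]; b <- stats_by[[pr[2]]]
    se2 <- a["v"] / a["n"] + b["v"] / b["n"]
    t_stat <- (a["m"] - b["m"]) / sqrt(se2)
    df <- se2^2 / ((a["v"] / a["n"])^2 / (a["n"] - 1) +
                     (b["v"] / b["n"])^2 / (b["n"] - 1))
    p <- stats::ptukey(abs(t_stat) * sqrt(2), nmeans = length(lev),
                       df = df, lower.tail = FALSE)
    data.frame(group1 = pr[1], group2 = pr[2], diff = unname(a["m"] - b["m"]),
               p = unname(p))
  })
  do.call(rbind, rows)
}

#' Univariate comparison of home-monitoring parameters across groups
#'
#' For each numeric parameter, Shapiro-Wilk normality per group and Levene's
#' test of variance homogeneity gate the comparison: all groups normal and
#' variances homogeneous routes to one-way ANOVA with Tukey HSD post-hoc
#' tests, otherwise to Kruskal-Wallis with Games-Howell post-hoc tests.
#' Logical/factor parameters are compared with a chi-square test. Medication
#' parameters absent in a group (all NA) are compared across the remaining
#' groups.
#'
#' @param features data.frame of parameters.
#' @param groups group factor (same length as `nrow(features)`).
#' @param alpha significance level for the gate and flags.
#' @return data.frame of class `univariate_report`: per parameter the test
#'   used, the p-value, group summaries and significant post-hoc pairs.
#' @export
univariate_report <- function(features, groups, alpha = 0.05) {
  groups <- factor(groups)
  rows <- lapply(names(features), function(par) {
    x <- features[[par]]
    if (is.logical(x) || is.factor(x) || is.character(x)) {
      tab <- table(x, droplevels(groups[!is.na(x)]))
      p <- tryCatch(suppressWarnings(stats::chisq.test(tab)$p.value),
                    error = function(e) NA_real_)
      return(data.frame(parameter = par, test = "chi-square", p = p,
                        posthoc = NA_character_, summary = NA_character_,
                        stringsAsFactors = FALSE))
    }
    ok <- !is.na(x)
    g <- droplevels(groups[ok])
    v <- x[ok]
    if (length(unique(g)) < 2 || length(v) < 6)
      return(data.frame(parameter = par, test = "none", p = NA_real_,
                        posthoc = NA_character_, summary = NA_character_,
                        stringsAsFactors = FALSE))
    normal <- all(vapply(split(v, g), function(z) {
      if (length(z) < 3 || stats::sd(z) == 0) return(FALSE)
      stats::shapiro.test(z)$p.value > alpha
    }, TRUE))
    homo <- tryCatch(
      car::leveneTest(v ~ g)[1, "Pr(>F)"] > alpha,
      error = function(e) FALSE)
    if (normal && homo) {
      fit <- stats::aov(v ~ g)
      p <- summary(fit)[[1]]["g", "Pr(>F)"]
      ph <- as.data.frame(stats::TukeyHSD(fit)$g)
      sig <- rownames(ph)[ph$`p adj` < alpha]
      test <- "ANOVA/Tukey"
      summ <- paste(vapply(split(v, g), function(z)
        sprintf("%.1f±%.1f", mean(z), stats::sd(z)), ""), collapse = " / ")
    } else {
      p <- stats::kruskal.test(v, g)$p.value
      gh <- games_howell(v, g)
      sig <- paste0(gh$group2, "-", gh$group1)[gh$p < alpha]
      test <- "Kruskal-Wallis/Games-Howell"
      summ <- paste(vapply(split(v, g), function(z)
        sprintf("%.1f (%.1f-%.1f)", stats::median(z),
                stats::quantile(z, 0.25), stats::quantile(z, 0.75)), ""),
        collapse = " / ")
    }
    data.frame(parameter = par, test = test, p = p,
               posthoc = paste(sig, collapse = "; "), summary = summ,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("univariate_report", "data.frame")
  out
}
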