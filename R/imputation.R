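## ---------------------------------------------------------------------------
## Multiple imputation: missingness-pattern analysis, multivariate-normal
## data-augmentation MCMC (random patterns) or sequential regression (monotone
## patterns) under per-parameter bounds, and Rubin pooling.
## ---------------------------------------------------------------------------

#' Analyse a missingness mask for monotonicity
#'
#' A pattern is monotone when the columns can be ordered so that missingness
#' of a column implies missingness of every later column in every row, i.e.
#' the sets of rows missing each column are pairwise nested. Columns are
#' ordered by missing count; pairwise nesting of the row sets is then
#' checked directly.
#'
#' @param mask logical matrix, TRUE = missing.
#' @return list with `monotone` (logical) and `order` (column order
#'   achieving monotonicity, NULL when the pattern is random).
#' @export
monotonicity_check <- function(mask) {
  mask <- as.matrix(mask)
  p <- ncol(mask)
  ord <- order(colSums(mask))
  for (a in seq_len(p - 1L)) {
    for (b in (a + 1L):p) {
      ## rows missing the earlier column must also miss the later one
      if (any(mask[, ord[a]] & !mask[, ord[b]]))
        return(list(monotone = FALSE, order = NULL))
    }
  }
  list(monotone = TRUE, order = ord)
}

## conditional MVN draw of the missing entries of one row
draw_conditional <- function(x, mis, mu, sigma) {
  obs <- !mis
  if (!any(obs)) {
    ch <- chol(sigma)
    return(mu + as.vector(t(ch) %*% stats::rnorm(length(mu))))
  }
  s_oo <- sigma[obs, obs, drop = FALSE]
  s_mo <- sigma[mis, obs, drop = FALSE]
  w <- s_mo %*% solve(s_oo)
  cond_mu <- mu[mis] + as.vector(w %*% (x[obs] - mu[obs]))
  cond_s <- sigma[mis, mis, drop = FALSE] - w %*% t(s_mo)
  cond_s <- (cond_s + t(cond_s)) / 2
  ev <- eigen(cond_s, symmetric = TRUE)
  rot <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)),
                             length(ev$values))
  as.vector(cond_mu + rot %*% stats::rnorm(length(cond_mu)))
}

## one bounded redraw cycle for the missing cells of a completed matrix
enforce_bounds_row <- function(draw_fun, lower, upper, max_tries = 100) {
  x <- draw_fun()
  for (i in seq_len(max_tries)) {
    bad <- x < lower | x > upper
    if (!any(bad)) return(x)
    x2 <- draw_fun()
    x[bad] <- x2[bad]
  }
  clip(x, lower, upper)
}

#' Multiply impute a feature matrix
#'
#' Monotone missingness patterns are imputed by sequential Bayesian linear
#' regression in the monotone column order; random patterns by
#' data-augmentation MCMC under a multivariate-normal working model
#' (posterior draws of mean and covariance between imputation steps, inverse-
#' Wishart/normal with the standard non-informative prior). Skewed columns
#' can be log-transformed for the working model. Draws violating the
#' per-column bounds are redrawn (up to `max_tries`) and finally truncated,
#' which keeps imputations physiologically plausible (e.g. no negative lung
#' function). Observed cells are never altered.
#'
#' @param x numeric matrix or data.frame of features (NA = missing); every
#'   column needs at least 2 observed values.
#' @param m number of imputed datasets.
#' @param seed integer seed; the result is deterministic given the seed.
#' @param bounds optional 2-column matrix (`lower`, `upper`) with one row per
#'   column of `x`.
#' @param log_cols names (or indices) of columns modelled on the log scale.
#' @param burnin,thin MCMC burn-in and between-imputation thinning.
#' @param pattern `"auto"` detects monotonicity; `"mcmc"` or `"monotone"`
#'   force a branch.
#' @param max_tries bounded-redraw attempts before truncation.
#' @return object of class `imputed_set`: list of `m` completed matrices,
#'   the missingness mask, the branch used and the seed.
#' @export
impute <- function(x, m = 5, seed = 1L, bounds = NULL, log_cols = NULL,
                   burnin = 200L, thin = 10L,
                   pattern = c("auto", "mcmc", "monotone"),
                   max_tries = 100L) {
  pattern <- match.arg(pattern)
  xm <- as.matrix(x)
  storage.mode(xm) <- "double"
  n <- nrow(xm)
  p <- ncol(xm)
  mask <- is.na(xm)
  if (any(colSums(!mask) < 2))
    stop("every column needs at least 2 observed values")
  if (is.null(bounds)) {
    bounds <- cbind(lower = rep(-Inf, p), upper = rep(Inf, p))
    rownames(bounds) <- colnames(xm)
  }
  bounds <- bounds[colnames(xm) %||% seq_len(p), , drop = FALSE]

  if (!any(mask)) {
    out <- list(imputations = replicate(m, xm, simplify = FALSE),
                mask = mask, method = "none", seed = seed)
    class(out) <- "imputed_set"
    return(out)
  }
  set.seed(seed)

  ## working scale
  log_idx <- if (is.character(log_cols)) match(log_cols, colnames(xm)) else
    log_cols
  log_idx <- log_idx[!is.na(log_idx)]
  fwd <- function(z) {
    for (j in log_idx) z[, j] <- log(pmax(z[, j], 1e-6) + 1)
    z
  }
  bwd <- function(z) {
    for (j in log_idx) z[, j] <- exp(z[, j]) - 1
    z
  }
  w <- fwd(xm)

  mono <- monotonicity_check(mask)
  use_mono <- (pattern == "monotone") ||
    (pattern == "auto" && mono$monotone && any(mask))

  imps <- vector("list", m)
  if (use_mono) {
    ord <- mono$order %||% order(colSums(mask))
    for (k in seq_len(m)) {
      wk <- w
      done <- integer(0)
      for (j in ord) {
        mis_j <- mask[, j]
        done_obs <- done
        X <- cbind(1, wk[, done_obs, drop = FALSE])
        obs <- !mis_j
        fit_X <- X[obs, , drop = FALSE]
        fit_y <- wk[obs, j]
        xtx <- crossprod(fit_X)
        xtx <- xtx + diag(1e-8, ncol(xtx))
        beta_hat <- solve(xtx, crossprod(fit_X, fit_y))
        resid <- fit_y - fit_X %*% beta_hat
        df <- max(1L, sum(obs) - ncol(fit_X))
        if (any(mis_j)) {
          draw_fun <- function() {
            sig2 <- sum(resid^2) / stats::rchisq(1, df)
            beta <- beta_hat + backsolve(
              chol(xtx), stats::rnorm(ncol(fit_X))) * sqrt(sig2)
            as.vector(X[mis_j, , drop = FALSE] %*% beta) +
              stats::rnorm(sum(mis_j), 0, sqrt(sig2))
          }
          lo <- fwd(matrix(bounds[j, 1], 1, p))[1, j]
          hi <- fwd(matrix(bounds[j, 2], 1, p))[1, j]
          wk[mis_j, j] <- enforce_bounds_row(draw_fun, lo, hi, max_tries)
        }
        done <- c(done, j)
      }
      imps[[k]] <- bwd(wk)
    }
    method <- "monotone"
  } else {
    ## data augmentation under an MVN working model
    wl <- fwd(matrix(bounds[, 1], n, p, byrow = TRUE))[1, ]
    wu <- fwd(matrix(bounds[, 2], n, p, byrow = TRUE))[1, ]
    wk <- w
    for (j in seq_len(p))                     # initialise at column means
      wk[mask[, j], j] <- mean(w[, j], na.rm = TRUE)
    mis_rows <- which(rowSums(mask) > 0)
    kept <- 0L
    it <- 0L
    while (kept < m) {
      it <- it + 1L
      ## P-step: posterior draw of (mu, sigma)
      xbar <- colMeans(wk)
      S <- stats::cov(wk) * (n - 1)
      S <- S + diag(1e-6 * (diag(S) + 1e-8))
      sigma <- solve(stats::rWishart(1, n - 1, solve(S))[, , 1])
      sigma <- (sigma + t(sigma)) / 2
      mu <- xbar + as.vector(t(chol(sigma)) %*% stats::rnorm(p)) / sqrt(n)
      ## I-step: bounded conditional draws per incomplete row
      for (i in mis_rows) {
        mis <- mask[i, ]
        draw_fun <- function() draw_conditional(wk[i, ], mis, mu, sigma)
        wk[i, mis] <- enforce_bounds_row(draw_fun, wl[mis], wu[mis],
                                         max_tries)
      }
      if (it > burnin && (it - burnin) %% thin == 0L) {
        kept <- kept + 1L
        imps[[kept]] <- bwd(wk)
      }
    }
    method <- "mcmc"
  }
  ## observed cells are restored verbatim (transform round-trips included)
  for (k in seq_len(m)) imps[[k]][!mask] <- xm[!mask]
  out <- list(imputations = imps, mask = mask, method = method, seed = seed,
              m = m)
  class(out) <- "imputed_set"
  out
}

#' @export
print.imputed_set <- function(x, ...) {
  cat("<imputed_set>", x$m %||% length(x$imputations),
      "imputations via", x$method, "-",
      sum(x$mask), "imputed cells\n")
  invisible(x)
}

#' Pool estimates across imputations (Rubin's rules)
#'
#' Pooled point estimate `Qbar = mean(Q)`, between-imputation variance `B`,
#' mean within-imputation variance `Ubar`, total variance
#' `T = Ubar + (1 + 1/m) B`, and t-based confidence intervals with Rubin's
#' degrees of freedom `(m - 1) (1 + Ubar / ((1 + 1/m) B))^2`.
#'
#' @param estimates m x k matrix (or vector) of per-imputation estimates.
#' @param variances matching matrix of squared standard errors.
#' @param conf confidence level.
#' @return data.frame with `estimate`, `B`, `Ubar`, `T`, `se`, `df`, `lower`,
#'   `upper` per parameter.
#' @export
pool_rubin <- function(estimates, variances, conf = 0.95) {
  q <- if (is.matrix(estimates)) estimates else matrix(estimates, ncol = 1)
  u <- if (is.matrix(variances)) variances else matrix(variances, ncol = 1)
  stopifnot(all(dim(q) == dim(u)))
  m <- nrow(q)
  qbar <- colMeans(q)
  b <- if (m > 1) apply(q, 2, stats::var) else rep(0, ncol(q))
  ubar <- colMeans(u)
  tv <- ubar + (1 + 1 / m) * b
  df <- ifelse(b > 0 & m > 1,
               (m - 1) * (1 + ubar / ((1 + 1 / m) * b))^2, Inf)
  alpha <- 1 - conf
  tq <- stats::qt(1 - alpha / 2, df)
  data.frame(estimate = qbar, B = b, Ubar = ubar, T = tv, se = sqrt(tv),
             df = df, lower = qbar - tq * sqrt(tv),
             upper = qbar + tq * sqrt(tv),
             row.names = colnames(q) %||% seq_along(qbar))
}
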