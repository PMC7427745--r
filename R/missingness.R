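## ---------------------------------------------------------------------------
## Feature-matrix missingness injection (MCAR or monotone); labels and
## identifiers are never masked.
## ---------------------------------------------------------------------------

#' Inject missingness into a feature matrix
#'
#' Masks exactly `round(fraction * n_cells)` feature cells, either completely
#' at random (default) or as a monotone pattern (each affected row loses a
#' suffix of the column order, grown one cell at a time on randomly chosen
#' rows). Non-feature columns (e.g. `subject_id`, `group`) are untouched.
#'
#' @param features data.frame or matrix; masking applies to its numeric
#'   feature columns.
#' @param fraction proportion of feature cells to mask, in `[0, 1)`.
#' @param seed optional integer seed.
#' @param pattern `"mcar"` or `"monotone"`.
#' @return the input with masked cells set to NA; the logical mask is
#'   attached as attribute `miss_mask`.
#' @export
apply_missingness <- function(features, fraction = 0.115, seed = NULL,
                              pattern = c("mcar", "monotone")) {
  pattern <- match.arg(pattern)
  stopifnot(fraction >= 0, fraction < 1)
  if (!is.null(seed)) set.seed(seed)
  is_df <- is.data.frame(features)
  feat_cols <- if (is_df) which(vapply(features, is.numeric, TRUE)) else
    seq_len(ncol(features))
  n <- nrow(features)
  p <- length(feat_cols)
  target <- round(fraction * n * p)
  mask <- matrix(FALSE, n, p)
  if (target > 0) {
    if (pattern == "mcar") {
      mask[sample(n * p, target)] <- TRUE
    } else {
      ## grow monotone suffixes: row i missing columns > (p - k_i)
      n_miss <- integer(n)
      for (s in seq_len(target)) {
        open <- which(n_miss < p)
        i <- if (length(open) == 1L) open else sample(open, 1L)
        n_miss[i] <- n_miss[i] + 1L
      }
      for (i in which(n_miss > 0L))
        mask[i, (p - n_miss[i] + 1L):p] <- TRUE
    }
  }
  for (j in seq_len(p))
    features[mask[, j], feat_cols[j]] <- NA
  dimnames(mask) <- list(NULL, if (is_df) names(features)[feat_cols] else
    colnames(features))
  attr(features, "miss_mask") <- mask
  features
}
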