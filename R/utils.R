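#' @keywords internal
"_PACKAGE"

## NULL-default helper
`%||%` <- function(a, b) if (is.null(a)) b else a

## clamp a numeric vector to [lo, hi]; NA passes through
clip <- function(x, lo = -Inf, hi = Inf) pmin(pmax(x, lo), hi)

#' Convert a median and interquartile range to log-normal parameters
#'
#' Matches a log-normal distribution to a reported median and IQR:
#' `meanlog = log(median)`, `sdlog = log(q75/q25) / (2 * qnorm(0.75))`.
#' For count-like variables whose reported lower quartile sits at or near
#' zero (below a tenth of the median) no log-normal can reproduce both
#' quartiles; the upper quartile is matched instead:
#' `sdlog = log(q75/median) / qnorm(0.75)`, which preserves the median and
#' the upper tail that drives group separation.
#'
#' @param median,q25,q75 reported median and quartiles (median and q75 > 0).
#' @return list with `meanlog` and `sdlog`.
#' @export
lognormal_from_quartiles <- function(median, q25, q75) {
  stopifnot(median > 0, q75 > 0, q75 >= median)
  z75 <- stats::qnorm(0.75)
  sdlog <- if (q25 > median / 10) log(q75 / q25) / (2 * z75) else
    log(q75 / median) / z75
  list(meanlog = log(median), sdlog = sdlog)
}

## hours:minutes -> minutes after midnight
hm2min <- function(h, m) h * 60 + m

## seconds since cohort origin -> second-of-day
sec_of_day <- function(t) t %% 86400

## ISO timestamp for CSV export; fixed civil origin (a Monday)
MONITOR_ORIGIN <- "2017-03-06 00:00:00"

iso_time <- function(t_sec) {
  format(as.POSIXct(MONITOR_ORIGIN, tz = "UTC") + t_sec,
         "%Y-%m-%dT%H:%M:%S", tz = "UTC")
}

## simple local-maximum finder with minimum spacing (indices); when two
## maxima are closer than min_dist the earlier-kept one wins and the larger
## of a directly adjacent conflict is preferred
local_maxima <- function(x, min_dist = 1L) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  idx <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  if (length(idx) < 2L || min_dist <= 1L) return(idx)
  keep <- integer(length(idx))
  k <- 0L
  last <- -Inf
  for (i in idx) {
    if (i - last >= min_dist) {
      k <- k + 1L
      keep[k] <- i
      last <- i
    } else if (k > 0L && x[i] > x[keep[k]]) {
      keep[k] <- i     # replace the previous peak by a larger close one
      last <- i
    }
  }
  keep[seq_len(k)]
}

## run-length helper: start/end indices of runs where flag is TRUE
runs_true <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values],
             length = r$lengths[r$values])
}
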