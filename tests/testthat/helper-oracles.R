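# Independent oracles used across the suite. These deliberately avoid the
# package's own RSS/DP code paths: segment fits go through lm(), and optimal
# segmentations come from exhaustive enumeration of admissible break vectors.

# OLS residual sum of squares of one segment, via lm()
oracle_segment_rss <- function(y, X, i, j) {
  d <- as.data.frame(X[i:j, , drop = FALSE])
  d$y <- y[i:j]
  sum(stats::resid(stats::lm(y ~ . - 1, data = d))^2)
}

# all strictly increasing m-break vectors with segment lengths >= h_abs
oracle_break_vectors <- function(n, m, h_abs) {
  if (m == 0) return(list(integer(0)))
  pos <- seq_len(n - 1)
  combs <- utils::combn(pos, m, simplify = FALSE)
  Filter(function(b) all(diff(c(0L, b, n)) >= h_abs), combs)
}

# exhaustive minimum-RSS segmentation; first minimum in lexicographic order
oracle_partition <- function(y, X, m, h_abs) {
  best <- NULL
  for (b in oracle_break_vectors(length(y), m, h_abs)) {
    starts <- c(1L, b + 1L)
    ends <- c(b, length(y))
    rss <- sum(mapply(function(i, j) oracle_segment_rss(y, X, i, j),
                      starts, ends))
    if (is.null(best) || rss < best$rss - 1e-9 * (1 + abs(best$rss)))
      best <- list(breaks = b, rss = rss)
  }
  best
}

# a piecewise-linear series from segment start values and slopes
make_piecewise <- function(n, breaks, intercepts, slopes) {
  starts <- c(1L, breaks + 1L)
  ends <- c(breaks, n)
  y <- numeric(n)
  for (s in seq_along(starts)) {
    idx <- starts[s]:ends[s]
    y[idx] <- intercepts[s] + slopes[s] * idx
  }
  y
}
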