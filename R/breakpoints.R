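#' Regression series for structural-change analysis
#'
#' Bundles a response with its per-observation design for segmented linear
#' regression. The design always contains an intercept; the default adds a
#' linear time trend (p = 2), which is the model family behind piecewise
#' linear fits of smoothed ventilation channels against test time.
#'
#' @param y numeric response, no missing values.
#' @param time numeric covariate for the trend column, strictly increasing;
#'   defaults to the observation index.
#' @param design `"trend"` for intercept + time per segment, `"constant"`
#'   for intercept only.
#' @return An object of class `regression_series`: list with `y`, `time`,
#'   design matrix `X` (n x p), `p` and `design`.
#' @export
regression_series <- function(y, time = seq_along(y),
                              design = c("trend", "constant")) {
  design <- match.arg(design)
  y <- as.numeric(y)
  time <- as.numeric(time)
  if (length(y) != length(time)) stop("y and time must have equal length")
  if (anyNA(y) || anyNA(time)) stop("missing values are not allowed")
  if (any(diff(time) <= 0)) stop("time must be strictly increasing")
  X <- if (design == "trend") cbind(intercept = 1, time = time)
       else cbind(intercept = rep(1, length(y)))
  structure(list(y = y, time = time, X = X, p = ncol(X), design = design),
            class = "regression_series")
}

#' Residual sum of squares of every admissible segment
#'
#' Computes the OLS residual sum of squares `rss(i, j)` of the segment
#' regression restricted to observations `i..j`, for every pair with
#' `j - i + 1 >= max(h_abs, p)` where `h_abs = ceiling(h_frac * n)` is the
#' minimum segment length. This table is the substrate of the
#' dynamic-programming search for optimal segmentations.
#'
#' Two computation routes are available: `"updating"` accumulates running
#' cross-products so each segment costs O(1) (closed form for the intercept
#' and intercept+trend designs), and `"direct"` solves the normal equations
#' per segment. They agree to numerical tolerance; the updating route is the
#' default.
#'
#' @param series a [regression_series()].
#' @param h_frac minimum segment length as a fraction of n, in (0, 0.5].
#' @param method `"updating"` or `"direct"`.
#' @return An object of class `rss_triangle`: list with matrix `rss`
#'   (inadmissible cells are `Inf`), `h_abs`, `n`, `p`, and the input series.
#' @export
rss_triangle <- function(series, h_frac = 0.15,
                         method = c("updating", "direct")) {
  stopifnot(inherits(series, "regression_series"))
  method <- match.arg(method)
  if (h_frac <= 0 || h_frac > 0.5) stop("h_frac must be in (0, 0.5]")
  n <- length(series$y)
  p <- series$p
  h_abs <- max(ceiling(h_frac * n), p)
  if (n < 2 * h_abs)
    stop("series too short: n = ", n, " < 2 * h_abs = ", 2 * h_abs)
  rss <- if (method == "updating") .rss_updating(series, h_abs)
         else .rss_direct(series, h_abs)
  # exact interpolation and numerical fuzz both clamp to zero
  rss[rss < 0] <- 0
  structure(list(rss = rss, h_abs = h_abs, n = n, p = p, series = series),
            class = "rss_triangle")
}

# closed-form RSS over all segments from cumulative cross-products
.rss_updating <- function(series, h_abs) {
  y <- series$y; t <- series$time; n <- length(y); p <- series$p
  cy  <- c(0, cumsum(y));  cy2 <- c(0, cumsum(y^2))
  ct  <- c(0, cumsum(t));  ct2 <- c(0, cumsum(t^2))
  cty <- c(0, cumsum(t * y))
  rss <- matrix(Inf, n, n)
  minlen <- max(h_abs, p)
  for (i in seq_len(n - minlen + 1)) {
    j <- (i + minlen - 1):n
    nn <- j - i + 1
    Sy  <- cy[j + 1] - cy[i]
    Sy2 <- cy2[j + 1] - cy2[i]
    r <- Sy2 - Sy^2 / nn
    if (series$design == "trend") {
      St  <- ct[j + 1] - ct[i]
      St2 <- ct2[j + 1] - ct2[i]
      Sty <- cty[j + 1] - cty[i]
      Stt <- St2 - St^2 / nn       # centered sum of squares of time
      if (any(Stt <= 1e-12 * pmax(St2, 1)))
        stop("rank-deficient design on segment starting at ", i)
      r <- r - (Sty - St * Sy / nn)^2 / Stt
    }
    rss[i, j] <- r
  }
  rss
}

# per-segment normal-equation solves; reference route
.rss_direct <- function(series, h_abs) {
  y <- series$y; X <- series$X; n <- length(y); p <- series$p
  rss <- matrix(Inf, n, n)
  minlen <- max(h_abs, p)
  for (i in seq_len(n - minlen + 1)) {
    for (j in (i + minlen - 1):n) {
      Xi <- X[i:j, , drop = FALSE]
      qrX <- qr(Xi)
      if (qrX$rank < p)
        stop("rank-deficient design on segment ", i, "..", j)
      res <- qr.resid(qrX, y[i:j])
      rss[i, j] <- sum(res^2)
    }
  }
  rss
}

# DP tables: H[k, i] = minimal cost of covering i..n with exactly k segments
.dp_tables <- function(C, n, h_abs, kmax) {
  H <- matrix(Inf, kmax, n)
  H[1, ] <- C[, n]
  if (kmax >= 2) {
    for (k in 2:kmax) {
      for (i in seq_len(n - k * h_abs + 1)) {
        b <- (i + h_abs - 1):(n - (k - 1) * h_abs)
        H[k, i] <- min(C[i, b] + H[k - 1, b + 1])
      }
    }
  }
  H
}

# reconstruct the lexicographically smallest optimal break vector
.dp_backtrack <- function(C, H, n, h_abs, m) {
  breaks <- integer(0)
  i <- 1L
  for (k in (m + 1):2) {
    b <- (i + h_abs - 1):(n - (k - 2) * h_abs - h_abs)
    cost <- C[i, b] + H[k - 1, b + 1]
    best <- min(cost)
    tol <- 1e-8 * (1 + abs(best))
    bstar <- b[which(cost <= best + tol)[1]]
    breaks <- c(breaks, bstar)
    i <- bstar + 1L
  }
  breaks
}

#' Minimum-RSS segmentation with a fixed number of breaks
#'
#' Bellman dynamic programming over the segment-RSS table: among all
#' segmentations of `1..n` into `m + 1` segments of length at least `h_abs`,
#' returns the one with the smallest total residual sum of squares. Ties are
#' broken by the lexicographically smallest break vector, so the output is
#' deterministic.
#'
#' @param triangle an [rss_triangle()].
#' @param m number of breaks (>= 0). A break index is the last observation
#'   of its segment.
#' @return An object of class `segmentation`: list with `m`, integer vector
#'   `breaks`, `coefficients` (p x (m+1) matrix), per-segment `segment_rss`,
#'   `total_rss`, `n` and `h_abs`.
#' @export
optimal_partition <- function(triangle, m) {
  stopifnot(inherits(triangle, "rss_triangle"))
  m <- as.integer(m)
  n <- triangle$n; h <- triangle$h_abs
  if (m < 0) stop("m must be >= 0")
  if ((m + 1) * h > n)
    stop("infeasible number of breaks: m = ", m, " needs n >= ",
         (m + 1) * h, " with h_abs = ", h)
  if (m == 0) {
    breaks <- integer(0)
    total <- triangle$rss[1, n]
  } else {
    H <- .dp_tables(triangle$rss, n, h, m + 1)
    total <- H[m + 1, 1]
    breaks <- .dp_backtrack(triangle$rss, H, n, h, m)
  }
  starts <- c(1L, breaks + 1L)
  ends <- c(breaks, n)
  series <- triangle$series
  coefs <- matrix(NA_real_, series$p, m + 1,
                  dimnames = list(colnames(series$X), NULL))
  seg_rss <- numeric(m + 1)
  for (s in seq_len(m + 1)) {
    rows <- starts[s]:ends[s]
    fit <- stats::lm.fit(series$X[rows, , drop = FALSE], series$y[rows])
    coefs[, s] <- fit$coefficients
    seg_rss[s] <- sum(fit$residuals^2)
  }
  structure(list(m = m, breaks = breaks, coefficients = coefs,
                 segment_rss = seg_rss, total_rss = total,
                 n = n, h_abs = h, series = series),
            class = "segmentation")
}

#' @export
print.segmentation <- function(x, ...) {
  cat("Segmentation with", x$m, "break(s)")
  if (x$m > 0) cat(" at index", paste(x$breaks, collapse = ", "))
  cat(sprintf("; total RSS %.6g over n = %d\n", x$total_rss, x$n))
  invisible(x)
}

#' Scan the number of breaks and select it by BIC
#'
#' Computes the optimal segmentation RSS for each number of breaks
#' `m = 0..m_max` and the corresponding Bayesian information criterion
#' `BIC(m) = n log(rss_m / n) + k_m log(n)` with
#' `k_m = (m + 1) p + m + 1` free parameters (segment coefficients, break
#' dates, and the error variance). The selected number of breaks minimises
#' the BIC; ties go to the smaller m. The RSS sequence is non-increasing in
#' m by construction and is reported alongside for diagnostic plots.
#'
#' @param series a [regression_series()].
#' @param h_frac minimum segment length fraction, see [rss_triangle()].
#' @param m_max largest number of breaks to consider; must be feasible
#'   given the minimum segment length.
#' @param method RSS computation route, see [rss_triangle()].
#' @return An object of class `breakpoint_scan`: list with data frame `table`
#'   (columns `m`, `rss`, `bic`), `selected_m`, `h_abs`, and the `triangle`.
#' @export
breakpoint_scan <- function(series, h_frac = 0.15, m_max = 5,
                            method = c("updating", "direct")) {
  triangle <- rss_triangle(series, h_frac, method = match.arg(method))
  n <- triangle$n; p <- triangle$p; h <- triangle$h_abs
  m_max <- as.integer(m_max)
  if (m_max < 0) stop("m_max must be >= 0")
  if ((m_max + 1) * h > n)
    stop("infeasible m_max = ", m_max, " for n = ", n, ", h_abs = ", h)
  H <- .dp_tables(triangle$rss, n, h, m_max + 1)
  rss_m <- H[seq_len(m_max + 1), 1]
  k_m <- (seq(0, m_max) + 1) * p + seq(0, m_max) + 1
  bic <- n * log(rss_m / n) + k_m * log(n)
  bic[rss_m <= 0] <- -Inf
  tab <- data.frame(m = 0:m_max, rss = rss_m, bic = bic)
  structure(list(table = tab, selected_m = tab$m[which.min(tab$bic)],
                 h_abs = h, triangle = triangle),
            class = "breakpoint_scan")
}

#' @export
print.breakpoint_scan <- function(x, ...) {
  cat("Breakpoint scan (h_abs =", x$h_abs, "):\n")
  print(x$table, row.names = FALSE)
  cat("selected m =", x$selected_m, "(BIC minimum)\n")
  invisible(x)
}

#' Limit distribution of the break-date estimator
#'
#' Distribution function and quantile function of the asymptotic
#' distribution of a structural-break date estimator: the argmax of a
#' two-sided standard Brownian motion with triangular drift `-|s|/2`
#' (symmetric, homoskedastic case). Used to build confidence intervals for
#' break dates; the 97.5% quantile is 11.03.
#'
#' @param q,p quantile / probability (vectorised).
#' @return `pbreakdate` the CDF value; `qbreakdate` the quantile.
#' @export
pbreakdate <- function(q) {
  pos <- function(x)
    1 + sqrt(x / (2 * pi)) * exp(-x / 8) -
      ((x + 5) / 2) * stats::pnorm(-sqrt(x) / 2) +
      (3 / 2) * exp(x + stats::pnorm(-3 * sqrt(x) / 2, log.p = TRUE))
  ifelse(q >= 0, pos(pmax(q, 0)), 1 - pos(pmax(-q, 0)))
}

#' @rdname pbreakdate
#' @export
qbreakdate <- function(p) {
  stopifnot(all(p > 0 & p < 1))
  vapply(p, function(pp) {
    if (pp == 0.5) return(0)
    flip <- pp < 0.5
    if (flip) pp <- 1 - pp
    r <- stats::uniroot(function(x) pbreakdate(x) - pp,
                        interval = c(0, 1e4), tol = 1e-10)$root
    if (flip) -r else r
  }, numeric(1))
}

#' Confidence intervals for break dates
#'
#' Asymptotic confidence intervals for each break of a segmentation, from
#' the limit distribution of the break-date estimator ([pbreakdate()]). For
#' break b with coefficient change `dbeta` across it, the interval half-width
#' is the limit-distribution quantile at `(1 + level)/2` scaled by
#' `sigma2 / (dbeta' Q dbeta)`, where `Q` is the regressor second-moment
#' matrix over the two adjacent segments and `sigma2` the pooled residual
#' variance (homoskedastic). Endpoints are rounded outward to integers and
#' clamped to `1..n`.
#'
#' If the coefficient change across a break is numerically zero the interval
#' is unidentified; a warning is raised and the interval is clamped to the
#' neighbouring break positions.
#'
#' @param seg a [optimal_partition()] segmentation.
#' @param level confidence level in (0, 1), default 0.95.
#' @return An object of class `breakpoint_ci`: data frame with columns
#'   `break_index`, `lower`, `upper`, plus attribute `level`.
#' @export
break_confidence_interval <- function(seg, level = 0.95) {
  stopifnot(inherits(seg, "segmentation"))
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  if (seg$m == 0) {
    out <- data.frame(break_index = integer(0), lower = integer(0),
                      upper = integer(0))
    attr(out, "level") <- level
    class(out) <- c("breakpoint_ci", "data.frame")
    return(out)
  }
  series <- seg$series
  n <- seg$n; p <- series$p
  df <- n - (seg$m + 1) * p
  sigma2 <- seg$total_rss / max(df, 1)
  q <- qbreakdate((1 + level) / 2)
  starts <- c(1L, seg$breaks + 1L)
  ends <- c(seg$breaks, n)
  lower <- upper <- integer(seg$m)
  for (r in seq_len(seg$m)) {
    b <- seg$breaks[r]
    rows <- starts[r]:ends[r + 1]
    Q <- crossprod(series$X[rows, , drop = FALSE]) / length(rows)
    dbeta <- seg$coefficients[, r + 1] - seg$coefficients[, r]
    d <- drop(t(dbeta) %*% Q %*% dbeta)
    if (!is.finite(d) || d <= .Machine$double.eps * max(1, sigma2)) {
      warning("no coefficient change across break ", b,
              "; confidence interval is unbounded and has been clamped")
      lower[r] <- if (r == 1) 1L else seg$breaks[r - 1]
      upper[r] <- if (r == seg$m) n else seg$breaks[r + 1]
    } else {
      half <- q * sigma2 / d
      lower[r] <- max(1L, as.integer(floor(b - half)))
      upper[r] <- min(n, as.integer(ceiling(b + half)))
    }
  }
  out <- data.frame(break_index = seg$breaks, lower = lower, upper = upper)
  attr(out, "level") <- level
  class(out) <- c("breakpoint_ci", "data.frame")
  out
}

#' Write a plain-text summary of a breakpoint analysis
#'
#' Serialises the scan table, selected segmentation and break confidence
#' intervals to a tab-delimited text file with commented section headers.
#'
#' @param scan a [breakpoint_scan()].
#' @param seg a [optimal_partition()] result.
#' @param ci a [break_confidence_interval()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_breakpoint_summary <- function(scan, seg, ci, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# selected_m\t%d", scan$selected_m), con)
  writeLines("# scan", con)
  utils::write.table(scan$table, con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  writeLines("# breaks", con)
  utils::write.table(as.data.frame(ci), con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
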