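#' Algorithmic V-slope anaerobic threshold
#'
#' Two-limb regression of VCO2 on VO2 over the incremental phase: an
#' exhaustive search over admissible split points fits both limbs by
#' ordinary least squares and keeps the split with the smallest pooled RSS
#' among those where the upper limb is strictly steeper than the lower limb
#' (the knee where CO2 output starts rising faster than O2 uptake). The
#' threshold location is the intersection of the two fitted lines; the AT in
#' watts is taken from the test time of the data point nearest the knee.
#'
#' Steepness is assessed on standardised data (both channels scaled to unit
#' variance) with a slack of 1e-6, so noise-level "knees" on a straight line
#' do not qualify; if no admissible split exists the result is "no AT".
#' If the two fitted lines intersect outside the observed VO2 range the knee
#' is flagged as extrapolated and the split boundary point is used instead.
#'
#' @param series a `binned_series` (or data frame) with `t`, `VO2`, `VCO2`.
#' @param protocol a [ramp_protocol()] for the watt conversion.
#' @param min_limb minimum number of points per limb, default 5.
#' @param window incremental-phase time window, default ramp start to ramp
#'   end.
#' @return An object of class `vslope_fit`: list with `status`, `split`
#'   (index of the last lower-limb point), limb slopes `s1`, `s2`, `knee`
#'   (VO2, VCO2 coordinates), `knee_extrapolated`, pooled `rss`,
#'   `single_rss` of the one-line fit, `at_time`, `at_watts`, and the point
#'   data used.
#' @export
vslope_at <- function(series, protocol = ramp_protocol(), min_limb = 5,
                      window = c(protocol$ramp_start, protocol$ramp_end)) {
  stopifnot(is.data.frame(series),
            all(c("t", "VO2", "VCO2") %in% names(series)), min_limb >= 2)
  keep <- series$t >= window[1] & series$t <= window[2]
  d <- series[keep, c("t", "VO2", "VCO2")]
  if (any(d$VO2 <= 0) || any(d$VCO2 <= 0))
    stop("V-slope requires positive VO2 and VCO2")
  n <- nrow(d)
  if (n < 2 * min_limb)
    stop("too few points for two limbs: n = ", n, " < ", 2 * min_limb)
  x <- d$VO2; y <- d$VCO2
  sdx <- stats::sd(x); sdy <- stats::sd(y)
  if (sdx == 0) stop("degenerate (vertical) V-slope plot: constant VO2")
  single <- stats::lm.fit(cbind(1, x), y)
  single_rss <- sum(single$residuals^2)
  fit_limb <- function(rows) {
    if (stats::sd(x[rows]) == 0) return(NULL)   # vertical limb
    f <- stats::lm.fit(cbind(1, x[rows]), y[rows])
    list(a = f$coefficients[1], b = f$coefficients[2],
         rss = sum(f$residuals^2))
  }
  best <- NULL
  for (s in min_limb:(n - min_limb)) {
    f1 <- fit_limb(1:s)
    f2 <- fit_limb((s + 1):n)
    if (is.null(f1) || is.null(f2)) next
    if ((f2$b - f1$b) * sdx / sdy <= 1e-6) next   # upper limb not steeper
    rss <- f1$rss + f2$rss
    if (is.null(best) || rss < best$rss - 1e-12 * (1 + best$rss))
      best <- list(split = s, f1 = f1, f2 = f2, rss = rss)
  }
  shift <- right_shift_flag(d)
  if (is.null(best))
    return(structure(list(status = "no AT", split = NA_integer_,
                          s1 = NA_real_, s2 = NA_real_,
                          knee = c(VO2 = NA_real_, VCO2 = NA_real_),
                          knee_extrapolated = NA, rss = NA_real_,
                          single_rss = single_rss, at_time = NA_real_,
                          at_watts = NA_real_, shift = shift, data = d),
                     class = "vslope_fit"))
  s <- best$split
  kx <- (best$f1$a - best$f2$a) / (best$f2$b - best$f1$b)
  ky <- best$f1$a + best$f1$b * kx
  extrap <- kx < min(x) || kx > max(x)
  if (extrap) { kx <- x[s]; ky <- y[s] }
  dist2 <- (x - kx)^2 + (y - ky)^2
  nearest <- which.min(dist2)
  at_time <- d$t[nearest]
  structure(list(status = "ok", split = s,
                 s1 = unname(best$f1$b), s2 = unname(best$f2$b),
                 knee = c(VO2 = unname(kx), VCO2 = unname(ky)),
                 knee_extrapolated = extrap, rss = best$rss,
                 single_rss = single_rss, at_time = at_time,
                 at_watts = time_to_watts(at_time, protocol),
                 shift = shift, data = d),
            class = "vslope_fit")
}

#' @export
print.vslope_fit <- function(x, ...) {
  cat("V-slope fit: ")
  if (x$status != "ok") {
    cat(x$status, "\n")
  } else {
    cat(sprintf("knee at VO2 = %.2f, slopes %.3f -> %.3f, AT %g W (t = %g s)\n",
                x$knee["VO2"], x$s1, x$s2, x$at_watts, x$at_time))
  }
  if (x$shift$flag)
    cat(sprintf("  right shift: %.0f%% of points below the R = 1 diagonal\n",
                100 * x$shift$fraction))
  invisible(x)
}

#' Right-shift diagnostic relative to the R = 1 diagonal
#'
#' Fraction of V-slope points lying below the identity line VCO2 = VO2
#' (respiratory quotient below 1). A trace displaced to the right of the
#' diagonal is associated with failed threshold detection by the apparatus.
#'
#' @param series data frame with `VO2` and `VCO2` (same mass-specific units).
#' @param threshold flag when the fraction reaches this value, default 0.8.
#' @return List with `fraction` and logical `flag`.
#' @export
right_shift_flag <- function(series, threshold = 0.8) {
  stopifnot(is.data.frame(series),
            all(c("VO2", "VCO2") %in% names(series)))
  if (nrow(series) == 0) stop("empty V-slope plot")
  fraction <- mean(series$VCO2 < series$VO2)
  list(fraction = fraction, flag = fraction >= threshold)
}
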