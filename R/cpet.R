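#' Read breath-by-breath CPET data
#'
#' Reads a delimited text export (comma- or tab-separated, auto-detected)
#' with one row per breath. Required columns: `t_s` (seconds from test
#' start, strictly increasing), `VE` (L/min), `VO2` and `VCO2` (ml/kg/min).
#' Optional: `RQ`, `PETO2`, `PETCO2` (mmHg), `HR` (bpm).
#'
#' @param path path to the file.
#' @return A data frame of class `cpet_breaths` with column `t` plus the
#'   channels present.
#' @export
read_cpet <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  req <- c("t_s", "VE", "VO2", "VCO2")
  miss <- setdiff(req, names(d))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  names(d)[names(d) == "t_s"] <- "t"
  as_cpet_breaths(d)
}

#' Validate a breath-by-breath record table
#'
#' @param d data frame with column `t` and channels `VE`, `VO2`, `VCO2`
#'   (plus optional `RQ`, `PETO2`, `PETCO2`, `HR`).
#' @return `d` with class `cpet_breaths`.
#' @export
as_cpet_breaths <- function(d) {
  stopifnot(is.data.frame(d), all(c("t", "VE", "VO2", "VCO2") %in% names(d)))
  if (nrow(d) == 0) stop("empty breath record")
  if (any(diff(d$t) <= 0)) stop("breath times must be strictly increasing")
  for (ch in c("VE", "VO2", "VCO2"))
    if (any(d[[ch]] < 0)) stop(ch, " must be non-negative")
  class(d) <- c("cpet_breaths", "data.frame")
  d
}

#' Write breath-by-breath CPET data
#'
#' Tab-delimited writer using the canonical column names accepted by
#' [read_cpet()].
#'
#' @param breaths a `cpet_breaths` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cpet <- function(breaths, path) {
  d <- as.data.frame(breaths)
  names(d)[names(d) == "t"] <- "t_s"
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

.cpet_channels <- c("VE", "VO2", "VCO2", "RQ", "PETO2", "PETCO2", "HR")

#' Average breaths into fixed-width time bins
#'
#' Each channel value of bin k is the arithmetic mean of the breath values
#' whose time falls in `[k w, (k+1) w)` (default w = 10 s). Interior bins
#' with no breath are filled by linear interpolation between neighbouring
#' bins and flagged; more than two consecutive empty bins is an error.
#'
#' @param breaths a `cpet_breaths` data frame.
#' @param width bin width in seconds.
#' @return A data frame of class `binned_series` with bin-centre time `t`,
#'   one column per channel, and logical `interpolated`; attributes `width`
#'   and `smoothed = FALSE`.
#' @export
bin_average <- function(breaths, width = 10) {
  stopifnot(inherits(breaths, "cpet_breaths"), width > 0)
  chs <- intersect(.cpet_channels, names(breaths))
  k <- floor(breaths$t / width)
  kk <- seq(min(k), max(k))
  out <- data.frame(t = (kk + 0.5) * width)
  fk <- factor(k, levels = kk)
  counts <- as.integer(table(fk))
  empty <- counts == 0
  r <- rle(empty)
  if (any(r$lengths[r$values] > 2))
    stop("more than two consecutive empty bins; data gap too large")
  for (ch in chs) {
    v <- as.numeric(tapply(breaths[[ch]], fk, mean))
    if (any(empty))
      v[empty] <- stats::approx(out$t[!empty], v[!empty],
                                xout = out$t[empty], rule = 2)$y
    out[[ch]] <- v
  }
  out$interpolated <- empty
  attr(out, "width") <- width
  attr(out, "smoothed") <- FALSE
  class(out) <- c("binned_series", "data.frame")
  out
}

#' Simple moving-average smoothing
#'
#' Centred moving average of the channel columns of a binned series
#' (default window 3). Series length is preserved: the windows are shortened
#' at the edges to the mean of the available neighbours.
#'
#' @param series a `binned_series`.
#' @param window odd window length, default 3.
#' @return The smoothed series (attribute `smoothed = TRUE`).
#' @export
smooth_sma <- function(series, window = 3) {
  stopifnot(inherits(series, "binned_series"),
            window >= 1, window %% 2 == 1)
  n <- nrow(series)
  if (n < window) stop("series shorter than the smoothing window")
  hw <- (window - 1) / 2
  for (ch in intersect(.cpet_channels, names(series))) {
    x <- series[[ch]]
    series[[ch]] <- vapply(seq_len(n), function(i)
      mean(x[max(1, i - hw):min(n, i + hw)]), numeric(1))
  }
  attr(series, "smoothed") <- TRUE
  series
}

#' Add the respiratory quotient channel
#'
#' RQ = VCO2 / VO2 per bin. Bins with non-positive VO2 are flagged
#' (`rq_excluded`) and their RQ set to `NA`.
#'
#' @param series a `binned_series` with `VO2` and `VCO2`.
#' @return The series with columns `RQ` and `rq_excluded` added.
#' @export
compute_rq <- function(series) {
  stopifnot(inherits(series, "binned_series"),
            all(c("VO2", "VCO2") %in% names(series)))
  bad <- series$VO2 <= 0
  series$RQ <- ifelse(bad, NA_real_, series$VCO2 / series$VO2)
  series$rq_excluded <- bad
  if (any(bad))
    warning(sum(bad), " bin(s) with non-positive VO2 excluded from RQ")
  series
}

#' Detect the anaerobic threshold in one ventilation channel
#'
#' Runs the structural-change machinery on a smoothed, binned ventilation
#' channel regressed on time over the loaded phase of the test (warm-up
#' start through ramp end by default; rest and cool-down are excluded). The
#' number of breaks is selected by BIC; among the detected breaks, the AT is
#' the ramp-phase break with the largest positive slope increase, matching
#' the defining "nonlinear increase" of the threshold. Breaks at the
#' warm-up-to-ramp transition (within one tread of the ramp start) are
#' protocol-induced and not AT candidates, but all candidates are reported.
#'
#' A break time is the midpoint between the last bin of its segment and the
#' first bin of the next; confidence-interval endpoints are the bin times of
#' the outward-rounded index bounds. Times are converted to watts with
#' [time_to_watts()].
#'
#' @param series a smoothed `binned_series`.
#' @param channel channel to analyse: `"VE"`, `"VCO2"` or `"RQ"`.
#' @param protocol a [ramp_protocol()].
#' @param h_frac minimum segment fraction for the segmentation.
#' @param m_max largest number of breaks scanned (clamped to feasibility).
#' @param level confidence level for break-date intervals.
#' @param window analysis window `c(start, end)` in seconds.
#' @return An object of class `at_estimate`: list with `status`
#'   (`"ok"` or `"no AT detected"`), `channel`, `at_time`, `at_watts`,
#'   `ci_time`, `ci_watts`, `selected_m`, `scan` table and a data frame
#'   `candidates` (one row per detected break with slopes and watt
#'   conversions).
#' @export
detect_at <- function(series, channel = c("VE", "VCO2", "RQ"),
                      protocol = ramp_protocol(), h_frac = 0.15, m_max = 5,
                      level = 0.95,
                      window = c(protocol$rest_dur, protocol$ramp_end)) {
  stopifnot(inherits(series, "binned_series"))
  channel <- match.arg(channel)
  if (!channel %in% names(series)) stop("channel not present: ", channel)
  keep <- series$t >= window[1] & series$t <= window[2]
  t <- series$t[keep]
  y <- series[[channel]][keep]
  if (anyNA(y)) stop("missing values in channel ", channel,
                     " inside the analysis window")
  rs <- regression_series(y, time = t, design = "trend")
  n <- length(y)
  h_abs <- max(ceiling(h_frac * n), rs$p)
  m_feas <- floor(n / h_abs) - 1
  scan <- breakpoint_scan(rs, h_frac = h_frac, m_max = min(m_max, m_feas))
  no_at <- function(cand) {
    structure(list(status = "no AT detected", channel = channel,
                   at_time = NA_real_, at_watts = NA_real_,
                   ci_time = c(NA_real_, NA_real_),
                   ci_watts = c(NA_real_, NA_real_),
                   selected_m = scan$selected_m, scan = scan$table,
                   candidates = cand, protocol = protocol),
              class = "at_estimate")
  }
  empty <- data.frame(break_index = integer(0), time = numeric(0),
                      lower_time = numeric(0), upper_time = numeric(0),
                      slope_before = numeric(0), slope_after = numeric(0),
                      slope_change = numeric(0), watts = numeric(0))
  if (scan$selected_m == 0) return(no_at(empty))
  seg <- optimal_partition(scan$triangle, scan$selected_m)
  ci <- break_confidence_interval(seg, level = level)
  b <- seg$breaks
  slope_before <- seg$coefficients["time", seq_len(seg$m)]
  slope_after <- seg$coefficients["time", seq_len(seg$m) + 1]
  bt <- (t[b] + t[pmin(b + 1L, n)]) / 2
  cand <- data.frame(break_index = b, time = bt,
                     lower_time = t[ci$lower], upper_time = t[ci$upper],
                     slope_before = slope_before, slope_after = slope_after,
                     slope_change = slope_after - slope_before,
                     watts = time_to_watts(pmin(bt, protocol$total_dur),
                                           protocol))
  in_ramp <- cand$time > protocol$ramp_start + protocol$step_dur &
    cand$time <= protocol$ramp_end
  ok <- in_ramp & cand$slope_change > 0
  if (!any(ok)) return(no_at(cand))
  at <- which(ok)[which.max(cand$slope_change[ok])]
  structure(list(status = "ok", channel = channel,
                 at_time = cand$time[at],
                 at_watts = cand$watts[at],
                 ci_time = c(cand$lower_time[at], cand$upper_time[at]),
                 ci_watts = time_to_watts(
                   c(cand$lower_time[at], cand$upper_time[at]), protocol),
                 selected_m = scan$selected_m, scan = scan$table,
                 candidates = cand, protocol = protocol),
            class = "at_estimate")
}

#' @export
print.at_estimate <- function(x, ...) {
  cat("AT estimate (channel ", x$channel, "): ", sep = "")
  if (x$status != "ok") {
    cat(x$status, "\n")
  } else {
    cat(sprintf("%g W at t = %g s (95%% CI %g-%g W), %d break(s)\n",
                x$at_watts, x$at_time, x$ci_watts[1], x$ci_watts[2],
                x$selected_m))
  }
  invisible(x)
}

#' One result row in the published table schema
#'
#' Formats an AT estimate as a per-subject row with the confidence interval
#' and point estimate converted to watts.
#'
#' @param x an [detect_at()] result.
#' @param subject subject identifier.
#' @return Data frame with columns `subject`, `ci_lo_W`, `ci_hi_W`,
#'   `median_W`, `channel`, `status`.
#' @export
as_subject_row <- function(x, subject = "S1") {
  stopifnot(inherits(x, "at_estimate"))
  data.frame(subject = subject,
             ci_lo_W = x$ci_watts[1], ci_hi_W = x$ci_watts[2],
             median_W = x$at_watts, channel = x$channel, status = x$status)
}
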