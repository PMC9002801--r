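#' Read a per-subject anaerobic-threshold table
#'
#' Reads a tab-delimited per-subject AT comparison table with columns
#' `subject`, `sc_lo`, `sc_hi` (structural-change 95% CI in watts, possibly
#' degenerate), `sc_median` (point estimate, W), `metabolic` (apparatus AT
#' in W, `NA` when not detected) and `vslope` (manual V-slope AT, W).
#' Copies of the published comparison tables for the VE, VCO2 and RQ
#' channels ship with the package under `inst/extdata`.
#'
#' @param path path to the file.
#' @return A data frame of class `at_table`.
#' @examples
#' tab <- read_at_table(system.file("extdata", "table_ve.tsv",
#'                                  package = "atseg"))
#' @export
read_at_table <- function(path) {
  if (!file.exists(path)) stop("table file not found: ", path)
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, na.strings = "NA")
  req <- c("subject", "sc_lo", "sc_hi", "sc_median", "metabolic", "vslope")
  miss <- setdiff(req, names(d))
  if (length(miss))
    stop("malformed AT table, missing column(s): ",
         paste(miss, collapse = ", "))
  if (nrow(d) == 0) stop("empty AT table")
  if (any(d$sc_lo > d$sc_hi)) stop("interval with sc_lo > sc_hi")
  class(d) <- c("at_table", "data.frame")
  d
}

#' Interval containment, endpoints inclusive
#'
#' Does a closed interval `[lo, hi]` contain `value`? Degenerate intervals
#' (`lo == hi`) are allowed. All arguments are vectorised and recycled.
#'
#' @param lo,hi interval endpoints, `lo <= hi`.
#' @param value value(s) to test.
#' @return Logical vector; `NA` where `value` is missing.
#' @examples
#' ci_contains(100, 110, 110)  # TRUE
#' ci_contains(110, 110, 100)  # FALSE
#' @export
ci_contains <- function(lo, hi, value) {
  if (any(lo > hi, na.rm = TRUE)) stop("invalid interval: lo > hi")
  lo <= value & value <= hi
}

#' Count subjects whose comparator AT falls in the structural-change CI
#'
#' For each subject with a comparator value present, tests whether that
#' value lies in the subject's structural-change confidence interval
#' (endpoint-inclusive). Subjects without a comparator value (apparatus
#' "not detected") are excluded from the denominator.
#'
#' @param tab an [read_at_table()] table.
#' @param comparator `"metabolic"` or `"vslope"`.
#' @return An object of class `agreement_summary`: list with `comparator`,
#'   `numerator`, `denominator` and the agreeing `subjects`.
#' @export
count_ci_agreement <- function(tab, comparator = c("metabolic", "vslope")) {
  stopifnot(inherits(tab, "at_table"))
  comparator <- match.arg(comparator)
  v <- tab[[comparator]]
  present <- !is.na(v)
  agree <- present & ci_contains(tab$sc_lo, tab$sc_hi, v)
  structure(list(comparator = paste0("sc_ci vs ", comparator),
                 numerator = sum(agree), denominator = sum(present),
                 subjects = tab$subject[which(agree)]),
            class = "agreement_summary")
}

#' Count subjects with exactly equal AT values in two columns
#'
#' Exact numeric equality between two watt columns, over the subjects with
#' both values present.
#'
#' @param tab an [read_at_table()] table.
#' @param a,b column names to compare.
#' @return An `agreement_summary`.
#' @export
count_equal <- function(tab, a = "metabolic", b = "vslope") {
  stopifnot(inherits(tab, "at_table"), a %in% names(tab), b %in% names(tab))
  present <- !is.na(tab[[a]]) & !is.na(tab[[b]])
  agree <- present & tab[[a]] == tab[[b]]
  structure(list(comparator = paste0(a, " == ", b),
                 numerator = sum(agree), denominator = sum(present),
                 subjects = tab$subject[which(agree)]),
            class = "agreement_summary")
}

#' @export
print.agreement_summary <- function(x, ...) {
  cat(sprintf("%s: %d of %d", x$comparator, x$numerator, x$denominator))
  if (length(x$subjects))
    cat(" (", paste(x$subjects, collapse = ", "), ")", sep = "")
  cat("\n")
  invisible(x)
}

#' Column mean and standard deviation with a stated divisor
#'
#' Arithmetic mean and standard deviation of a watt column. The divisor of
#' the variance is explicit because published table summaries mix the
#' sample (`n-1`) and population (`n`) conventions between columns.
#'
#' @param x numeric values; `NA`s are dropped.
#' @param sd_divisor `"n-1"` (sample) or `"n"` (population).
#' @return List with `mean`, `sd` and `n`.
#' @export
column_summary <- function(x, sd_divisor = c("n-1", "n")) {
  sd_divisor <- match.arg(sd_divisor)
  x <- x[!is.na(x)]
  if (!length(x)) stop("no values to summarise")
  n <- length(x)
  ss <- sum((x - mean(x))^2)
  s <- if (sd_divisor == "n-1") {
    if (n > 1) sqrt(ss / (n - 1)) else NA_real_
  } else sqrt(ss / n)
  list(mean = mean(x), sd = s, n = n)
}

#' Intraclass correlation ICC(2,k) with a lower confidence bound
#'
#' Two-way random-effects, absolute-agreement intraclass correlation from
#' the standard mean-square decomposition (between-targets `BMS`,
#' between-raters `JMS`, residual `EMS`), in the Shrout-Fleiss formulation.
#' Both the single-measure ICC(2,1) and the average-measure ICC(2,k) are
#' returned; `icc` is the average-measure value, the reliability of the
#' mean of the k raters. The one-sided lower confidence bound at level
#' `1 - alpha` uses the Shrout-Fleiss F-based construction with
#' Satterthwaite degrees of freedom, transformed to the average-measure
#' scale by the Spearman-Brown step-up. The point estimate is also labelled
#' with its Landis-Koch agreement category.
#'
#' @param x complete numeric matrix, n targets x k raters (n, k >= 2).
#' @param alpha significance level of the one-sided lower bound,
#'   default 0.1 (a 90% lower confidence limit).
#' @return List with `icc` (average measures), `icc_single`, `lower_bound`,
#'   `lower_bound_single`, `category`, `n`, `k` and the mean squares.
#' @export
icc2k <- function(x, alpha = 0.1) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("rater matrix must be complete")
  n <- nrow(x); k <- ncol(x)
  if (n < 2 || k < 2) stop("need at least 2 targets and 2 raters")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  rowm <- rowMeans(x); colm <- colMeans(x); gm <- mean(x)
  if (stats::var(rowm) <= .Machine$double.eps * max(1, gm^2))
    stop("zero between-target variance: ICC undefined")
  BMS <- k * sum((rowm - gm)^2) / (n - 1)
  JMS <- n * sum((colm - gm)^2) / (k - 1)
  EMS <- (sum((x - gm)^2) - k * sum((rowm - gm)^2) -
            n * sum((colm - gm)^2)) / ((n - 1) * (k - 1))
  icc1 <- (BMS - EMS) / (BMS + (k - 1) * EMS + k * (JMS - EMS) / n)
  icck <- (BMS - EMS) / (BMS + (JMS - EMS) / n)
  # Shrout-Fleiss lower bound for ICC(2,1), stepped up to ICC(2,k)
  Fj <- JMS / EMS
  a <- k * icc1 * Fj + n * (1 + (k - 1) * icc1) - k * icc1
  v <- (k - 1) * (n - 1) * a^2 /
    ((n - 1) * k^2 * icc1^2 * Fj^2 + (n * (1 + (k - 1) * icc1) - k * icc1)^2)
  FU <- stats::qf(1 - alpha, n - 1, v)
  L1 <- n * (BMS - FU * EMS) /
    (FU * (k * JMS + (k * n - k - n) * EMS) + n * BMS)
  Lk <- L1 * k / (1 + L1 * (k - 1))
  list(icc = icck, icc_single = icc1, lower_bound = Lk,
       lower_bound_single = L1, category = landis_koch(icck),
       n = n, k = k, BMS = BMS, JMS = JMS, EMS = EMS)
}

#' Landis-Koch agreement category
#'
#' The conventional verbal bands for a reliability coefficient:
#' poor (< 0), slight (0-0.20), fair (0.21-0.40), moderate (0.41-0.60),
#' substantial (0.61-0.80), almost perfect (0.81-1).
#'
#' @param icc a reliability coefficient.
#' @return Character label.
#' @examples
#' landis_koch(0.4449)  # "moderate"
#' @export
landis_koch <- function(icc) {
  stopifnot(is.numeric(icc), length(icc) == 1, icc <= 1)
  if (icc < 0) "poor"
  else if (icc <= 0.20) "slight"
  else if (icc <= 0.40) "fair"
  else if (icc <= 0.60) "moderate"
  else if (icc <= 0.80) "substantial"
  else "almost perfect"
}
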