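test_that("time-to-watts follows the ramp protocol", {
  p <- ramp_protocol()
  expect_equal(time_to_watts(c(0, 100, 179.9), p), c(0, 0, 0))
  expect_equal(time_to_watts(200, p), 20)
  expect_equal(time_to_watts(360, p), 30)
  expect_equal(time_to_watts(929, p), 210)
  expect_equal(time_to_watts(c(950, 1110), p), c(0, 0))
  expect_error(time_to_watts(-1, p), "outside")
  expect_error(time_to_watts(1111, p), "outside")
  # non-decreasing staircase with 30-s treads over the loaded phase
  t <- seq(0, 929.5, by = 0.5)
  w <- time_to_watts(t, p)
  expect_true(all(diff(w) >= 0))
  expect_true(all(w[t >= 360] %in% seq(30, 210, by = 10)))
  runs <- rle(w[t >= 360 & t < 930])
  expect_true(all(runs$lengths == 60))   # 30 s at 0.5-s spacing
})

test_that("load onset time inverts time-to-watts on the whole grid", {
  p <- ramp_protocol()
  expect_equal(load_onset_time(30, p), p$ramp_start)
  for (w in seq(30, 210, by = 10)) {
    t <- load_onset_time(w, p)
    expect_equal(time_to_watts(t, p), w)
    expect_equal(time_to_watts(t - 0.01, p), w - 10)
  }
  expect_error(load_onset_time(25, p), "grid")
  expect_error(load_onset_time(220, p), "grid")
})

test_that("bin averaging takes per-bin means and interpolates short gaps", {
  b <- as_cpet_breaths(data.frame(t = 1:10, VE = 20, VO2 = 10, VCO2 = 9))
  expect_equal(bin_average(b)$VE[1], 20)
  b2 <- as_cpet_breaths(data.frame(t = c(2, 7), VE = c(18, 22),
                                   VO2 = 10, VCO2 = 9))
  expect_equal(bin_average(b2)$VE, 20)
  # a linear channel bins to the line at the mean breath time of each bin
  set.seed(71)
  t <- sort(runif(300, 0, 200))
  b3 <- as_cpet_breaths(data.frame(t = t, VE = 5 + 0.3 * t,
                                   VO2 = 10, VCO2 = 9))
  binned <- bin_average(b3)
  k <- floor(t / 10)
  tbar <- tapply(t, factor(k, levels = unique(sort(k))), mean)
  expect_equal(binned$VE, as.numeric(5 + 0.3 * tbar), tolerance = 1e-10)
  # one empty interior bin is interpolated and flagged
  b4 <- as_cpet_breaths(data.frame(t = c(5, 25), VE = c(10, 30),
                                   VO2 = 10, VCO2 = 9))
  binned4 <- bin_average(b4)
  expect_equal(binned4$VE, c(10, 20, 30))
  expect_identical(binned4$interpolated, c(FALSE, TRUE, FALSE))
  # more than two consecutive empty bins is a data gap
  b5 <- as_cpet_breaths(data.frame(t = c(5, 45), VE = 1, VO2 = 1, VCO2 = 1))
  expect_error(bin_average(b5), "consecutive empty bins")
})

test_that("moving-average smoothing preserves constants, length and variance/3", {
  mk <- function(x) {
    d <- data.frame(t = seq_along(x) * 10 - 5, VE = x, VO2 = 1, VCO2 = 1,
                    interpolated = FALSE)
    attr(d, "width") <- 10; attr(d, "smoothed") <- FALSE
    class(d) <- c("binned_series", "data.frame")
    d
  }
  expect_equal(smooth_sma(mk(rep(4, 10)))$VE, rep(4, 10))
  s <- smooth_sma(mk(c(0, 3, 6, 9)))
  expect_equal(s$VE[2:3], c(3, 6))
  expect_equal(s$VE[1], 1.5)   # shortened edge window
  expect_true(attr(s, "smoothed"))
  set.seed(81)
  x <- rnorm(1e4)
  v <- var(smooth_sma(mk(x))$VE[3:9998])
  expect_equal(v, 1 / 3, tolerance = 0.05)
  expect_error(smooth_sma(mk(c(1, 2)), window = 3), "shorter")
})

test_that("respiratory quotient is the per-bin VCO2/VO2 ratio", {
  d <- data.frame(t = 1:5 * 10 - 5, VE = 1, VO2 = c(2, 4, 5, 0, 8),
                  VCO2 = c(2, 3.2, 5.5, 1, 6), interpolated = FALSE)
  class(d) <- c("binned_series", "data.frame")
  expect_warning(r <- compute_rq(d), "non-positive VO2")
  expect_equal(r$RQ, ifelse(d$VO2 > 0, d$VCO2 / d$VO2, NA))
  expect_identical(r$rq_excluded, d$VO2 <= 0)
  d$VO2 <- d$VCO2
  expect_equal(compute_rq(d)$RQ, rep(1, 5))
})

test_that("the breath reader and writer round-trip and validate input", {
  cfg <- synthetic_config(seed = 5)
  breaths <- generate_breaths(cfg)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_cpet(breaths, f)
  back <- read_cpet(f)
  expect_equal(as.data.frame(back), as.data.frame(breaths),
               tolerance = 1e-12)
  writeLines("t_s,VE\n1,2", f2 <- withr::local_tempfile(fileext = ".csv"))
  expect_error(read_cpet(f2), "missing required column")
  expect_error(as_cpet_breaths(data.frame(t = c(1, 1), VE = 1, VO2 = 1,
                                          VCO2 = 1)), "increasing")
})

test_that("a noise-free subject yields the exact threshold on every channel", {
  cfg <- synthetic_config(at_watts = 100, seed = 3)
  cfg$channels <- lapply(cfg$channels, function(cc) {
    cc$noise_sd <- 0; cc
  })
  s <- smooth_sma(bin_average(generate_breaths(cfg)))
  for (ch in c("VE", "VCO2")) {
    at <- detect_at(s, ch)
    expect_identical(at$status, "ok")
    expect_equal(at$at_watts, 100)
    expect_true(at$ci_watts[1] <= 100 && 100 <= at$ci_watts[2])
  }
  at_rq <- detect_at(compute_rq(s), "RQ")
  expect_identical(at_rq$status, "ok")
  expect_equal(at_rq$at_watts, 100)
})

test_that("detection reports its contract cases and candidate breaks", {
  # slope decreases only: a channel that flattens mid-ramp has no AT
  t <- seq(185, 925, by = 10)
  ve <- ifelse(t <= 570, 10 + 0.09 * (t - 185),
               10 + 0.09 * (570 - 185) + 0.02 * (t - 570))
  s <- data.frame(t = t, VE = ve, interpolated = FALSE)
  class(s) <- c("binned_series", "data.frame")
  at <- detect_at(s, "VE")
  expect_identical(at$status, "no AT detected")
  expect_true(is.na(at$at_watts))
  # candidates carry slopes and watt conversions
  cfg <- synthetic_config(at_watts = 100, seed = 7)
  at2 <- detect_at(smooth_sma(bin_average(generate_breaths(cfg))), "VE")
  expect_identical(at2$status, "ok")
  expect_true(all(c("slope_before", "slope_after", "slope_change", "watts")
                  %in% names(at2$candidates)))
  expect_gte(at2$at_watts, 20)
  expect_lte(at2$at_watts, 210)
  expect_true(at2$ci_watts[1] <= at2$at_watts &&
                at2$at_watts <= at2$ci_watts[2])
  # on-grid output
  expect_true(at2$at_watts %in% seq(20, 210, by = 10))
  row <- as_subject_row(at2, "K")
  expect_identical(row$subject, "K")
  expect_equal(row$median_W, at2$at_watts)
})

test_that("the pipeline is deterministic for a fixed input", {
  cfg <- synthetic_config(at_watts = 110, seed = 13)
  run <- function() {
    at <- detect_at(smooth_sma(bin_average(generate_breaths(cfg))), "VE")
    c(at$at_watts, at$ci_watts, at$selected_m)
  }
  expect_identical(run(), run())
})
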