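#' Configuration for the synthetic CPET generator
#'
#' Defines a simulated ramp test with a known ground-truth anaerobic
#' threshold. Each ventilation channel follows a piecewise-linear response
#' in time: a rest level, a warm-up level, a ramp rising at the pre-AT
#' per-watt slope (times the ramp rate of the protocol) until the threshold
#' onset time, a steeper post-AT slope beyond it, and a linear cool-down
#' decay back to the rest level. Breath-by-breath samples add independent
#' Gaussian noise per channel.
#'
#' Default channel parameters emulate a healthy young adult of about 70 kg:
#' VE in L/min (rest 8, loaded base 10, slopes 0.25 then 0.55 L/min/W,
#' breath-level noise sd 2), VCO2 and VO2 in ml/kg/min. VO2 has a single
#' slope throughout (about 10 ml/min/W mass-normalised), so the respiratory
#' quotient rises after the threshold. The VE and VCO2 post-AT slopes must
#' exceed their pre-AT slopes (the defining nonlinear increase).
#'
#' @param at_watts ground-truth AT load, on the protocol's load grid.
#' @param protocol a [ramp_protocol()].
#' @param channels named list of per-channel parameter lists with fields
#'   `rest`, `base`, `slope_pre`, `slope_post` (per watt) and `noise_sd`.
#' @param breath_mean mean breath interval, seconds.
#' @param breath_jitter half-width of the uniform jitter on the interval.
#' @param seed integer seed; fully determines the generated data.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(at_watts = 100, protocol = ramp_protocol(),
                             channels = list(
                               VE = list(rest = 8, base = 10,
                                         slope_pre = 0.25, slope_post = 0.55,
                                         noise_sd = 2.0),
                               VCO2 = list(rest = 2.5, base = 3.2,
                                           slope_pre = 0.13, slope_post = 0.20,
                                           noise_sd = 0.8),
                               VO2 = list(rest = 3.5, base = 6.4,
                                          slope_pre = 0.143, slope_post = 0.143,
                                          noise_sd = 1.0)),
                             breath_mean = 3, breath_jitter = 1, seed = 1) {
  stopifnot(inherits(protocol, "ramp_protocol"),
            breath_mean > 0, breath_jitter >= 0,
            breath_jitter < breath_mean)
  load_onset_time(at_watts, protocol)  # validates the grid position
  for (ch in c("VE", "VCO2", "VO2")) {
    cc <- channels[[ch]]
    if (is.null(cc)) stop("missing channel parameters: ", ch)
    stopifnot(cc$rest >= 0, cc$base >= 0, cc$noise_sd >= 0)
    if (ch != "VO2" && cc$slope_post <= cc$slope_pre)
      stop(ch, ": post-AT slope must exceed pre-AT slope")
  }
  structure(list(at_watts = at_watts, protocol = protocol,
                 channels = channels, breath_mean = breath_mean,
                 breath_jitter = breath_jitter, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Noise-free channel response of a synthetic test
#'
#' Evaluates the piecewise-linear mean response of every channel at the
#' given times. The ramp segment rises at `slope * ramp_rate` per second
#' (ramp rate = increment / tread duration), with the slope change at the
#' threshold onset time; the cool-down decays linearly to the rest level.
#'
#' @param t times in seconds, within the protocol.
#' @param config a [synthetic_config()].
#' @return Numeric matrix, one column per channel (`VE`, `VO2`, `VCO2`).
#' @export
cpet_response <- function(t, config) {
  stopifnot(inherits(config, "synthetic_config"))
  p <- config$protocol
  rate <- p$step_increment / p$step_dur      # W per second, continuous ramp
  t_at <- load_onset_time(config$at_watts, p)
  out <- sapply(c("VE", "VO2", "VCO2"), function(ch) {
    cc <- config$channels[[ch]]
    ramp_val <- function(tt)
      cc$base + cc$slope_pre * rate * (pmin(tt, t_at) - p$ramp_start) +
        cc$slope_post * rate * pmax(tt - t_at, 0)
    end_val <- ramp_val(p$ramp_end)
    v <- numeric(length(t))
    rest <- t < p$rest_dur
    warm <- t >= p$rest_dur & t < p$ramp_start
    ramp <- t >= p$ramp_start & t < p$ramp_end
    cool <- t >= p$ramp_end
    v[rest] <- cc$rest
    v[warm] <- cc$base
    v[ramp] <- ramp_val(t[ramp])
    v[cool] <- end_val + (cc$rest - end_val) *
      pmin((t[cool] - p$ramp_end) / p$cooldown_dur, 1)
    v
  })
  out[, c("VE", "VO2", "VCO2"), drop = FALSE]
}

#' Generate a synthetic breath-by-breath test
#'
#' Draws breath times across the whole protocol from the configured
#' interval model (uniform jitter around the mean interval), evaluates the
#' noise-free response at each breath, and adds independent Gaussian noise
#' per channel. Negative draws are clamped at zero. The generator is fully
#' determined by the seed in the configuration; the caller's random-number
#' state is left untouched.
#'
#' @param config a [synthetic_config()].
#' @return A `cpet_breaths` data frame with `t`, `VE`, `VO2`, `VCO2`.
#' @export
generate_breaths <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(config$seed)
  total <- config$protocol$total_dur
  n_max <- ceiling(total / max(config$breath_mean - config$breath_jitter,
                               0.1)) + 2
  gaps <- stats::runif(n_max, config$breath_mean - config$breath_jitter,
                       config$breath_mean + config$breath_jitter)
  t <- cumsum(gaps)
  t <- t[t < total]
  mu <- cpet_response(t, config)
  d <- data.frame(t = t)
  for (ch in c("VE", "VO2", "VCO2")) {
    sd <- config$channels[[ch]]$noise_sd
    d[[ch]] <- pmax(mu[, ch] + stats::rnorm(length(t), 0, sd), 0)
  }
  as_cpet_breaths(d)
}

#' Ground-truth threshold of a synthetic test
#'
#' The threshold onset time and load implied by the configuration;
#' inverse-consistent with [time_to_watts()].
#'
#' @param config a [synthetic_config()].
#' @return List with `time` (s) and `watts`.
#' @examples
#' true_at(synthetic_config(at_watts = 100))  # time 570 s, 100 W
#' @export
true_at <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  list(time = load_onset_time(config$at_watts, config$protocol),
       watts = config$at_watts)
}
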