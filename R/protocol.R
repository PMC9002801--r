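#' Ramp ergometer test protocol
#'
#' Describes the timing and loading of an incremental (ramp) cycle-ergometer
#' test: a seated rest, a constant-load warm-up, a stepped ramp in which the
#' load increases by a fixed increment on a fixed tread duration, and an
#' unloaded cool-down. The default protocol is 3 min rest, 3 min warm-up at
#' 20 W, +10 W every 30 s for 9 min 30 s (peak 210 W), and 3 min cool-down,
#' for a total of 18 min 30 s at 50 rpm.
#'
#' @param rest_dur rest duration in seconds.
#' @param warmup_dur warm-up duration in seconds.
#' @param warmup_load warm-up load in watts.
#' @param step_increment load increment per ramp step, watts.
#' @param step_dur ramp step (tread) duration, seconds.
#' @param ramp_dur total ramp duration, seconds.
#' @param cooldown_dur cool-down duration, seconds.
#' @param cadence pedal cadence, rpm (descriptive only).
#' @param subject_age subject age in years; sets the maximum-heart-rate
#'   termination criterion `hr_max = 220 - age`.
#'
#' @return An object of class `ramp_protocol`: a list with the arguments plus
#'   derived fields `ramp_start`, `ramp_end`, `total_dur`, `max_load`
#'   (the load on the final tread) and `hr_max`.
#' @examples
#' p <- ramp_protocol()
#' p$total_dur   # 1110 s = 18 min 30 s
#' p$max_load    # 210 W
#' @export
ramp_protocol <- function(rest_dur = 180, warmup_dur = 180, warmup_load = 20,
                          step_increment = 10, step_dur = 30, ramp_dur = 570,
                          cooldown_dur = 180, cadence = 50, subject_age = 21) {
  stopifnot(rest_dur >= 0, warmup_dur >= 0, warmup_load >= 0,
            step_increment > 0, step_dur > 0, ramp_dur >= step_dur,
            cooldown_dur >= 0, subject_age > 0)
  p <- list(rest_dur = rest_dur, warmup_dur = warmup_dur,
            warmup_load = warmup_load, step_increment = step_increment,
            step_dur = step_dur, ramp_dur = ramp_dur,
            cooldown_dur = cooldown_dur, cadence = cadence,
            subject_age = subject_age)
  p$ramp_start <- rest_dur + warmup_dur
  p$ramp_end <- p$ramp_start + ramp_dur
  p$total_dur <- p$ramp_end + cooldown_dur
  p$max_load <- warmup_load + step_increment * floor(ramp_dur / step_dur)
  p$hr_max <- 220 - subject_age
  class(p) <- "ramp_protocol"
  p
}

#' @export
print.ramp_protocol <- function(x, ...) {
  cat("Ramp protocol:",
      sprintf("rest %ds | warm-up %ds @ %dW | ramp +%dW/%ds to %dW | cool-down %ds",
              x$rest_dur, x$warmup_dur, x$warmup_load, x$step_increment,
              x$step_dur, x$max_load, x$cooldown_dur),
      sprintf("\n  total %ds, HRmax criterion %d bpm\n", x$total_dur, x$hr_max))
  invisible(x)
}

#' Convert test time to ergometer load
#'
#' Maps a time point of the ramp test to the load (watts) active on the
#' ergometer at that time: 0 W at rest, the warm-up load during warm-up, the
#' stepped ramp load during the ramp (the first tread is one increment above
#' the warm-up load), and 0 W in the cool-down.
#'
#' @param t time in seconds from test start; vectorised.
#' @param protocol a [ramp_protocol()].
#' @return Numeric vector of loads in watts.
#' @examples
#' p <- ramp_protocol()
#' time_to_watts(c(200, 360, 929), p)  # 20, 30, 210
#' @export
time_to_watts <- function(t, protocol = ramp_protocol()) {
  stopifnot(inherits(protocol, "ramp_protocol"))
  if (any(t < 0 | t > protocol$total_dur))
    stop("time outside the protocol range [0, ", protocol$total_dur, "] s")
  w <- numeric(length(t))
  warm <- t >= protocol$rest_dur & t < protocol$ramp_start
  ramp <- t >= protocol$ramp_start & t < protocol$ramp_end
  w[warm] <- protocol$warmup_load
  w[ramp] <- pmin(protocol$max_load,
                  protocol$warmup_load + protocol$step_increment *
                    (1 + floor((t[ramp] - protocol$ramp_start) / protocol$step_dur)))
  w
}

#' Time at which the ramp first reaches a given load
#'
#' Inverse of [time_to_watts()] on the ramp phase: the start of the tread on
#' which `watts` becomes the active load.
#'
#' @param watts a load on the protocol grid, between one increment above the
#'   warm-up load and the peak load.
#' @param protocol a [ramp_protocol()].
#' @return Time in seconds.
#' @examples
#' load_onset_time(100)              # 570
#' time_to_watts(load_onset_time(100))  # 100
#' @export
load_onset_time <- function(watts, protocol = ramp_protocol()) {
  stopifnot(inherits(protocol, "ramp_protocol"))
  steps <- (watts - protocol$warmup_load) / protocol$step_increment
  if (any(steps < 1) || any(watts > protocol$max_load) ||
      any(abs(steps - round(steps)) > 1e-9))
    stop("load must lie on the protocol grid between ",
         protocol$warmup_load + protocol$step_increment, " and ",
         protocol$max_load, " W")
  protocol$ramp_start + protocol$step_dur * (round(steps) - 1)
}
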