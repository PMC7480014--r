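#' Fetal heart rhythm settings
#'
#' Parameterizes the RR-interval generator: a mean fetal heart rate with
#' Gaussian beat-to-beat jitter, optionally overlaid with one acceleration or
#' deceleration episode (a trapezoidal heart-rate ramp with 20% rise and fall
#' time).
#'
#' @param mean_hr mean heart rate in beats/min. Guarded to a configurable
#'   physiological fetal range.
#' @param hrv_std beat-to-beat heart-rate jitter (standard deviation,
#'   beats/min).
#' @param event `"none"`, `"acceleration"` or `"deceleration"`.
#' @param event_onset onset of the episode in seconds.
#' @param event_magnitude absolute heart-rate change of the episode in
#'   beats/min (sign is taken from `event`).
#' @param event_duration duration of the episode in seconds.
#' @param hr_range allowed (min, max) for `mean_hr`, beats/min.
#' @param seed optional RNG seed.
#' @return a list of class `rhythm_config`.
#' @export
rhythm_config <- function(mean_hr = 140, hrv_std = 3,
                          event = c("none", "acceleration", "deceleration"),
                          event_onset = 0, event_magnitude = 20,
                          event_duration = 15,
                          hr_range = c(60, 240), seed = NULL) {
  event <- match.arg(event)
  if (mean_hr < hr_range[1] || mean_hr > hr_range[2])
    abort(sprintf("`mean_hr` = %g outside the physiological range [%g, %g] bpm.",
                  mean_hr, hr_range[1], hr_range[2]))
  if (hrv_std < 0) abort("`hrv_std` must be >= 0.")
  if (event != "none" && (event_magnitude <= 0 || event_duration <= 0))
    abort("event magnitude and duration must be positive.")
  structure(list(mean_hr = mean_hr, hrv_std = hrv_std, event = event,
                 event_onset = event_onset, event_magnitude = event_magnitude,
                 event_duration = event_duration, seed = seed),
            class = "rhythm_config")
}

# Heart-rate offset of the configured episode at time t (bpm), trapezoid
# with 20% ramps.
.event_delta <- function(config, t) {
  if (config$event == "none") return(0)
  sgn <- if (config$event == "acceleration") 1 else -1
  t0 <- config$event_onset
  d <- config$event_duration
  ramp <- 0.2 * d
  if (t < t0 || t > t0 + d) return(0)
  u <- t - t0
  frac <- if (u < ramp) u / ramp else if (u > d - ramp) (d - u) / ramp else 1
  sgn * config$event_magnitude * frac
}

#' Generate a series of RR intervals
#'
#' Beats are emitted until the cumulative time reaches `duration` (the last
#' interval may overshoot). The instantaneous heart rate of each beat is
#' `mean_hr + N(0, hrv_std) + event ramp`, clamped to stay positive.
#'
#' @param config a [rhythm_config].
#' @param duration required total duration in seconds.
#' @return numeric vector of RR intervals in seconds, `sum(rr) >= duration`.
#' @export
generate_rr_series <- function(config = rhythm_config(), duration) {
  stopifnot(inherits(config, "rhythm_config"))
  if (duration <= 0) abort("`duration` must be positive.")
  with_seed(config$seed, {
    rr <- numeric(0)
    t <- 0
    while (t < duration) {
      hr <- config$mean_hr + .event_delta(config, t)
      if (config$hrv_std > 0) hr <- hr + rnorm(1L, 0, config$hrv_std)
      hr <- max(hr, 20) # hard positivity guard
      rr <- c(rr, 60 / hr)
      t <- t + 60 / hr
    }
    rr
  })
}
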