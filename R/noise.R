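#' Composite noise settings
#'
#' Describes the additive noise mixed into clean simulated fetal ECG. Four
#' spectrally distinct components are available, each generated with unit
#' power and combined with the given weights before the mixture is rescaled
#' to hit the target per-channel SNR exactly:
#'
#' * `white`: broadband Gaussian sensor noise, independent per channel;
#' * `baseline`: baseline wander, a mixture of slow sinusoids (0.05-0.9 Hz
#'   with random phases) plus a smoothed random walk;
#' * `emg`: muscle-artifact-like noise, white noise band-passed to
#'   20-150 Hz;
#' * `powerline`: 50 Hz interference with a slowly drifting amplitude.
#'
#' The three structured components model physical sources (maternal
#' movement and respiration, maternal/uterine muscle, mains pickup) that
#' every abdominal electrode measures simultaneously; each record therefore
#' draws *one* realization of each structured source and mixes it into
#' every channel with its own standard-normal gain, the same way the
#' electrical sources themselves project onto electrodes. Only the white
#' sensor noise is independent per channel. The cross-channel correlation
#' this induces is what makes multi-channel denoising physically
#' advantageous; set `shared_sources = FALSE` for fully independent
#' per-channel noise.
#'
#' @param target_snr_db target SNR in dB, a scalar (applied to every channel)
#'   or one value per channel. `Inf` means "no noise".
#' @param weights named non-negative weights for
#'   `c(white, baseline, emg, powerline)`; at least one must be positive.
#' @param shared_sources draw one realization of each structured component
#'   per record and project it to all channels with random gains (default),
#'   or draw every component independently per channel.
#' @param seed optional RNG seed.
#' @return a list of class `noise_config`.
#' @export
noise_config <- function(target_snr_db = 0,
                         weights = c(white = 0.3, baseline = 0.3,
                                     emg = 0.3, powerline = 0.1),
                         shared_sources = TRUE,
                         seed = NULL) {
  need <- c("white", "baseline", "emg", "powerline")
  if (is.null(names(weights)) || !all(need %in% names(weights)))
    abort("`weights` must be named white, baseline, emg, powerline.")
  weights <- weights[need]
  if (any(weights < 0) || sum(weights) <= 0)
    abort("`weights` must be >= 0 with at least one positive.")
  if (any(is.na(target_snr_db)))
    abort("`target_snr_db` must be finite (or Inf for no noise).")
  structure(list(target_snr_db = target_snr_db, weights = weights,
                 shared_sources = isTRUE(shared_sources), seed = seed),
            class = "noise_config")
}

# One unit-power realization of each noise component, n samples at fs.
.noise_components <- function(n, fs) {
  t <- (0:(n - 1)) / fs
  unit <- function(x) {
    p <- signal_power(x)
    if (p <= 0) x else x / sqrt(p)
  }
  white <- rnorm(n)
  freqs <- runif(5L, 0.05, 0.9)
  amps <- runif(5L, 0.5, 1)
  phases <- runif(5L, 0, 2 * pi)
  bw <- rowSums(vapply(
    seq_len(5L),
    function(i) amps[i] * sin(2 * pi * freqs[i] * t + phases[i]),
    numeric(n)
  ))
  walk <- cumsum(rnorm(n)) / sqrt(n)
  walk <- walk - mean(walk)
  baseline <- unit(bw) + 0.5 * unit(walk)
  bf <- signal::butter(2L, c(20, min(150, 0.45 * fs)) / (fs / 2), type = "pass")
  emg <- zero_phase(bf$b, bf$a, rnorm(n))
  drift <- 1 + 0.5 * sin(2 * pi * runif(1L, 0.1, 0.3) * t + runif(1L, 0, 2 * pi))
  powerline <- drift * sin(2 * pi * 50 * t + runif(1L, 0, 2 * pi))
  list(white = unit(white), baseline = unit(baseline),
       emg = unit(emg), powerline = unit(powerline))
}

#' Add SNR-calibrated composite noise to a clean signal
#'
#' Per channel, a composite noise realization is scaled so that
#' `10 * log10(P_signal / P_noise)` equals the configured target exactly
#' (within floating-point arithmetic), and the achieved SNR is recorded. An
#' infinite target returns the clean signal unchanged.
#'
#' @param clean an [mcecg] with finite, nonzero-power channels.
#' @param config a [noise_config].
#' @param provenance optional list stored alongside the record (template id,
#'   seeds, projection matrix ...).
#' @return a `simulated_record`: list with elements `clean`, `noisy` (both
#'   [mcecg]), `r_peaks`, `target_snr_db`, `achieved_snr_db` (per channel)
#'   and `provenance`.
#' @export
add_calibrated_noise <- function(clean, config = noise_config(),
                                 provenance = list()) {
  stopifnot(inherits(clean, "mcecg"), inherits(config, "noise_config"))
  n <- n_samples(clean)
  k <- n_channels(clean)
  target <- rep_len(config$target_snr_db, k)
  psig <- apply(clean$samples, 2L, signal_power)
  if (any(psig <= 0))
    abort("a channel of `clean` has zero power; SNR is undefined.")
  noisy <- clean$samples
  achieved <- numeric(k)
  with_seed(config$seed, {
    w <- config$weights
    shared <- if (config$shared_sources) .noise_components(n, clean$fs)
              else NULL
    for (ch in seq_len(k)) {
      if (is.infinite(target[ch])) {
        achieved[ch] <- Inf
        next
      }
      if (config$shared_sources) {
        g <- rnorm(3L) # projection gains of the shared structured sources
        noise <- w[["white"]] * rnorm(n) +
          w[["baseline"]] * g[1L] * shared$baseline +
          w[["emg"]] * g[2L] * shared$emg +
          w[["powerline"]] * g[3L] * shared$powerline
      } else {
        comp <- .noise_components(n, clean$fs)
        noise <- w[["white"]] * comp$white + w[["baseline"]] * comp$baseline +
          w[["emg"]] * comp$emg + w[["powerline"]] * comp$powerline
      }
      pn <- signal_power(noise)
      alpha <- sqrt(psig[ch] / (pn * 10^(target[ch] / 10)))
      noise <- alpha * noise
      noisy[, ch] <- clean$samples[, ch] + noise
      achieved[ch] <- 10 * log10(psig[ch] / signal_power(noise))
    }
  })
  structure(
    list(
      clean = clean,
      noisy = mcecg(noisy, clean$fs, clean$r_peaks),
      r_peaks = clean$r_peaks,
      target_snr_db = target,
      achieved_snr_db = achieved,
      provenance = provenance
    ),
    class = "simulated_record"
  )
}

#' @export
print.simulated_record <- function(x, ...) {
  cat(sprintf(
    "<simulated_record> %d samples x %d ch @ %g Hz, SNR [%s] dB\n",
    n_samples(x$clean), n_channels(x$clean), x$clean$fs,
    paste(sprintf("%.1f", x$achieved_snr_db), collapse = ", ")
  ))
  invisible(x)
}
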