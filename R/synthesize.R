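#' Synthesize a 3-lead vectorcardiogram from a beat template
#'
#' Phase-domain Gaussian-sum synthesis: within each beat the cardiac phase
#' sweeps linearly from -pi to pi over the RR interval and each lead's
#' amplitude is the sum of the template's Gaussians evaluated at the wrapped
#' phase difference. R-peaks are annotated at the phase of the
#' largest-amplitude R-labelled Gaussian.
#'
#' @param template a [vcg_template].
#' @param rr_intervals vector of RR intervals in seconds (all positive).
#' @param fs sampling frequency in Hz (>= 250).
#' @return an [mcecg] with 3 channels, `round(fs * sum(rr))` samples and one
#'   R-peak per beat.
#' @export
synthesize_vcg <- function(template, rr_intervals, fs = 500) {
  stopifnot(inherits(template, "vcg_template"))
  if (length(rr_intervals) == 0L) abort("`rr_intervals` is empty.")
  if (any(rr_intervals <= 0)) abort("RR intervals must be positive.")
  if (fs < 250) abort("`fs` must be >= 250 Hz.")

  edges <- round(fs * cumsum(c(0, rr_intervals)))
  n <- edges[length(edges)]
  theta <- numeric(n)
  r_peaks <- integer(length(rr_intervals))
  rw <- template$waves[template$waves$wave == "R", ]
  theta_r <- if (nrow(rw)) rw$theta[which.max(abs(rw$a))] else 0
  for (i in seq_along(rr_intervals)) {
    a <- edges[i]; b <- edges[i + 1L]
    len <- b - a
    if (len < 1L) abort("an RR interval is shorter than one sample.")
    theta[(a + 1L):b] <- -pi + 2 * pi * (0:(len - 1L)) / len
    r_peaks[i] <- a + 1L + round((theta_r + pi) / (2 * pi) * (len - 1L))
  }

  out <- matrix(0, nrow = n, ncol = 3L)
  w <- template$waves
  for (i in seq_len(nrow(w))) {
    d <- theta - w$theta[i]
    d <- atan2(sin(d), cos(d)) # wrapped phase difference
    out[, w$lead[i]] <- out[, w$lead[i]] +
      w$a[i] * exp(-d^2 / (2 * w$b[i]^2))
  }
  mcecg(out, fs, r_peaks = r_peaks)
}

#' Synthesize a VCG with beat-to-beat morphology variation
#'
#' Real fetal ECG morphology is not identical from beat to beat. This
#' wrapper draws a slightly perturbed copy of the template for every beat
#' (via [vary_morphology()] with a small shift/scale range) and synthesizes
#' the beats in sequence, so consecutive beats share the template's overall
#' shape but differ in wave timing and amplitude — variation that averaging
#' denoisers flatten and that a good denoiser must preserve.
#'
#' @param template a [vcg_template].
#' @param rr_intervals vector of RR intervals in seconds.
#' @param fs sampling frequency (Hz).
#' @param beat_variation a [morphology_config] with the per-beat
#'   perturbation ranges (its seed field is ignored; pass `seed`).
#' @param seed optional RNG seed for the per-beat draws.
#' @return an [mcecg] with 3 channels and one R-peak per beat.
#' @export
synthesize_vcg_varying <- function(template, rr_intervals, fs = 500,
                                   beat_variation =
                                     morphology_config(0.03, c(0.85, 1.15)),
                                   seed = NULL) {
  stopifnot(inherits(template, "vcg_template"),
            inherits(beat_variation, "morphology_config"))
  if (length(rr_intervals) == 0L) abort("`rr_intervals` is empty.")
  with_seed(seed, {
    parts <- lapply(rr_intervals, function(rr) {
      tpl_b <- vary_morphology(template, morphology_config(
        beat_variation$boundary_shift, beat_variation$amplitude_scale))
      synthesize_vcg(tpl_b, rr, fs = fs)
    })
    samples <- do.call(rbind, lapply(parts, function(p) p$samples))
    offsets <- cumsum(c(0L, vapply(parts, n_samples, integer(1))))
    r_peaks <- unlist(lapply(seq_along(parts), function(i)
      parts[[i]]$r_peaks + offsets[i]))
    mcecg(samples, fs, r_peaks = as.integer(r_peaks))
  })
}

#' Project a 3-lead VCG onto four abdominal leads
#'
#' Each abdominal channel is a fixed linear combination of the three
#' vectorcardiogram leads; varying the mixing matrix between records emulates
#' varying electrode placement. When no matrix is supplied one is drawn with
#' independent standard-normal entries, rejecting rank-deficient or
#' near-singular draws.
#'
#' @param vcg an [mcecg] with 3 channels.
#' @param projection optional 4x3 numeric mixing matrix.
#' @param seed optional RNG seed for the random matrix.
#' @return an [mcecg] with 4 channels; R-peak annotations are carried over.
#'   The mixing matrix used is attached as attribute `"projection"`.
#' @export
project_to_abdominal_leads <- function(vcg, projection = NULL, seed = NULL) {
  stopifnot(inherits(vcg, "mcecg"))
  if (n_channels(vcg) != 3L) abort("`vcg` must have exactly 3 channels.")
  if (is.null(projection)) {
    projection <- with_seed(seed, {
      repeat {
        m <- matrix(rnorm(12L), nrow = 4L, ncol = 3L)
        sv <- svd(m)$d
        if (sv[3L] > 1e-3 * sv[1L]) break
      }
      m
    })
  }
  projection <- as.matrix(projection)
  if (!all(dim(projection) == c(4L, 3L)))
    abort("`projection` must be a 4x3 matrix.")
  if (any(!is.finite(projection))) abort("`projection` must be finite.")
  sv <- svd(projection)$d
  if (sv[3L] <= 1e-9 * max(sv[1L], .Machine$double.eps))
    abort("`projection` is rank-deficient; abdominal leads would be degenerate.")
  out <- mcecg(vcg$samples %*% t(projection), vcg$fs, vcg$r_peaks)
  attr(out, "projection") <- projection
  out
}
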