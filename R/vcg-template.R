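#' Gaussian-sum vectorcardiogram beat template
#'
#' One heartbeat is modelled in the phase domain: the cardiac phase sweeps
#' `(-pi, pi]` over each RR interval and every lead of the 3-lead
#' vectorcardiogram (VCG) is a sum of Gaussians
#' `sum_i a_i * exp(-(theta - theta_i)^2 / (2 b_i^2))`, each Gaussian
#' belonging to one of the P, Q, R, S, T waves. Wave boundaries (onset and
#' offset phase of the P wave, the QRS complex and the T wave) are annotated
#' on the template so that morphology randomization can shift and rescale
#' whole waves coherently.
#'
#' @param waves data frame with columns `lead` (1..3), `wave` (one of
#'   "P","Q","R","S","T"), `a` (amplitude, arbitrary units), `b` (Gaussian
#'   width, radians, > 0) and `theta` (centre phase, radians in `(-pi, pi]`).
#' @param boundaries data frame with columns `wave` ("P","QRS","T"), `onset`
#'   and `offset` (radians). Intervals must be ordered and disjoint:
#'   P before QRS before T.
#' @param id optional template identifier string.
#' @return an object of class `vcg_template`.
#' @export
vcg_template <- function(waves, boundaries, id = "custom") {
  waves <- as.data.frame(waves)
  boundaries <- as.data.frame(boundaries)
  need_w <- c("lead", "wave", "a", "b", "theta")
  if (!all(need_w %in% names(waves)))
    abort("`waves` must have columns lead, wave, a, b, theta.")
  if (!all(c("wave", "onset", "offset") %in% names(boundaries)))
    abort("`boundaries` must have columns wave, onset, offset.")
  if (!setequal(boundaries$wave, c("P", "QRS", "T")))
    abort("`boundaries` must annotate exactly the P, QRS and T waves.")
  if (any(waves$b <= 0)) abort("Gaussian widths `b` must be positive.")
  if (!all(waves$wave %in% c("P", "Q", "R", "S", "T")))
    abort("wave labels must be P, Q, R, S or T.")
  bd <- boundaries[match(c("P", "QRS", "T"), boundaries$wave), ]
  seqs <- c(rbind(bd$onset, bd$offset))
  if (any(diff(seqs) < 0) || bd$onset[1] <= -pi || bd$offset[3] > pi)
    abort("wave intervals must be ordered, disjoint and inside (-pi, pi].")
  interval_of <- c(P = "P", Q = "QRS", R = "QRS", S = "QRS", T = "T")
  for (i in seq_len(nrow(waves))) {
    iv <- bd[match(interval_of[[waves$wave[i]]], bd$wave), ]
    if (waves$theta[i] < iv$onset || waves$theta[i] > iv$offset)
      abort(sprintf(
        "Gaussian %d (wave %s, theta = %.3f) lies outside its wave interval [%.3f, %.3f].",
        i, waves$wave[i], waves$theta[i], iv$onset, iv$offset
      ))
  }
  structure(list(waves = waves, boundaries = bd, id = id),
            class = "vcg_template")
}

#' @export
print.vcg_template <- function(x, ...) {
  cat(sprintf("<vcg_template '%s'> %d Gaussians on 3 leads\n",
              x$id, nrow(x$waves)))
  b <- x$boundaries
  cat(sprintf("  %s: (%.2f, %.2f) rad\n", b$wave, b$onset, b$offset))
  invisible(x)
}

# Gaussian rows for one lead of one wave; amplitudes relative to the lead's
# R amplitude, widths/centres in radians.
.wave_rows <- function(lead, wave, a, b, theta) {
  data.frame(lead = lead, wave = wave, a = a, b = b, theta = theta)
}

#' Built-in vectorcardiogram beat templates
#'
#' Three hand-authored, physiologically plausible Gaussian-sum templates with
#' differing PQRST geometry, intended as morphology seeds for the simulator:
#' `"typical"` (textbook fetal morphology), `"broad_t"` (longer QT with a
#' wide, tall T wave) and `"small_p"` (low-amplitude P, deep S). Amplitudes
#' are scaled so that an abdominal-lead projection yields R peaks of order
#' 10 microvolts, the magnitude expected for extracted fetal ECG.
#'
#' @param name one of `"typical"`, `"broad_t"`, `"small_p"`.
#' @return a [vcg_template].
#' @export
vcg_template_preset <- function(name = c("typical", "broad_t", "small_p")) {
  name <- match.arg(name)
  mk <- function(bounds, lead_spec) {
    waves <- do.call(rbind, lapply(seq_along(lead_spec), function(l) {
      s <- lead_spec[[l]]
      do.call(rbind, lapply(names(s), function(w) {
        p <- s[[w]]
        .wave_rows(l, w, p[1], p[2], p[3])
      }))
    }))
    vcg_template(waves, bounds, id = name)
  }
  if (name == "typical") {
    bounds <- data.frame(
      wave = c("P", "QRS", "T"),
      onset = c(-1.75, -0.45, 0.90),
      offset = c(-0.85, 0.45, 2.30)
    )
    spec1 <- list( # (a, b, theta)
      P = c(1.2, 0.25, -1.30), Q = c(-1.0, 0.10, -0.22),
      R = c(10.0, 0.10, 0.00), S = c(-1.5, 0.10, 0.24),
      T = c(2.5, 0.40, 1.55)
    )
    spec2 <- list(
      P = c(0.7, 0.25, -1.28), Q = c(-0.6, 0.10, -0.20),
      R = c(6.0, 0.11, 0.02), S = c(-1.0, 0.10, 0.26),
      T = c(1.8, 0.42, 1.60)
    )
    spec3 <- list(
      P = c(-0.4, 0.25, -1.32), Q = c(0.4, 0.10, -0.24),
      R = c(-3.0, 0.10, -0.02), S = c(0.8, 0.10, 0.22),
      T = c(-0.9, 0.40, 1.50)
    )
    return(mk(bounds, list(spec1, spec2, spec3)))
  }
  if (name == "broad_t") {
    bounds <- data.frame(
      wave = c("P", "QRS", "T"),
      onset = c(-1.95, -0.50, 1.05),
      offset = c(-1.00, 0.50, 2.70)
    )
    spec1 <- list(
      P = c(1.0, 0.28, -1.45), Q = c(-0.8, 0.11, -0.25),
      R = c(9.0, 0.11, 0.00), S = c(-2.0, 0.11, 0.26),
      T = c(3.5, 0.55, 1.85)
    )
    spec2 <- list(
      P = c(0.8, 0.26, -1.50), Q = c(-0.5, 0.11, -0.28),
      R = c(7.5, 0.12, 0.03), S = c(-1.2, 0.11, 0.28),
      T = c(2.6, 0.50, 1.90)
    )
    spec3 <- list(
      P = c(0.5, 0.27, -1.40), Q = c(0.3, 0.11, -0.22),
      R = c(-4.0, 0.11, -0.03), S = c(1.0, 0.11, 0.24),
      T = c(-1.5, 0.52, 1.80)
    )
    return(mk(bounds, list(spec1, spec2, spec3)))
  }
  # small_p
  bounds <- data.frame(
    wave = c("P", "QRS", "T"),
    onset = c(-1.60, -0.40, 0.80),
    offset = c(-0.80, 0.40, 2.10)
  )
  spec1 <- list(
    P = c(0.4, 0.20, -1.18), Q = c(-1.2, 0.09, -0.18),
    R = c(11.0, 0.09, 0.00), S = c(-3.0, 0.09, 0.20),
    T = c(2.0, 0.38, 1.40)
  )
  spec2 <- list(
    P = c(0.3, 0.20, -1.20), Q = c(-0.8, 0.09, -0.16),
    R = c(5.0, 0.10, 0.02), S = c(-2.0, 0.09, 0.22),
    T = c(1.4, 0.36, 1.45)
  )
  spec3 <- list(
    P = c(-0.25, 0.20, -1.15), Q = c(0.5, 0.09, -0.20),
    R = c(-4.5, 0.09, -0.01), S = c(1.5, 0.09, 0.18),
    T = c(-1.0, 0.36, 1.35)
  )
  mk(bounds, list(spec1, spec2, spec3))
}

#' Morphology variation settings
#'
#' Controls the random per-wave perturbations applied by [vary_morphology()]:
#' every onset and offset of the P, QRS and T intervals is shifted
#' independently by a uniform draw on `[-boundary_shift, boundary_shift]`
#' radians (so wave lengths vary too, since the two ends move independently),
#' and each wave's Gaussians are multiplied by one uniform amplitude factor
#' drawn from `amplitude_scale`.
#'
#' @param boundary_shift maximum absolute boundary shift in radians.
#' @param amplitude_scale length-2 numeric, (min, max) multiplicative factor.
#' @param seed optional RNG seed for reproducible draws.
#' @return a list of class `morphology_config`.
#' @export
morphology_config <- function(boundary_shift = 0.1,
                              amplitude_scale = c(0.7, 1.3),
                              seed = NULL) {
  if (boundary_shift < 0) abort("`boundary_shift` must be >= 0.")
  if (length(amplitude_scale) != 2L || amplitude_scale[1] <= 0 ||
      diff(amplitude_scale) < 0)
    abort("`amplitude_scale` must be (min, max) with min > 0.")
  structure(list(boundary_shift = boundary_shift,
                 amplitude_scale = amplitude_scale, seed = seed),
            class = "morphology_config")
}

#' Randomize the morphology of a beat template
#'
#' Draws a perturbed copy of a [vcg_template]: wave boundaries are shifted
#' independently (uniform on the configured range), each wave's Gaussians are
#' re-centred and re-widened by the affine map that carries the old wave
#' interval onto the new one, and all Gaussians of a wave are rescaled by one
#' per-wave amplitude factor. Draws that would break the P < QRS < T ordering
#' are resampled (up to 100 times) before erroring.
#'
#' @param template a [vcg_template].
#' @param config a [morphology_config].
#' @return a new [vcg_template].
#' @export
vary_morphology <- function(template, config = morphology_config()) {
  stopifnot(inherits(template, "vcg_template"),
            inherits(config, "morphology_config"))
  with_seed(config$seed, {
    bd <- template$boundaries
    r <- config$boundary_shift
    new_bd <- NULL
    for (try in seq_len(100L)) {
      cand <- bd
      cand$onset <- bd$onset + runif(3L, -r, r)
      cand$offset <- bd$offset + runif(3L, -r, r)
      seqs <- c(rbind(cand$onset, cand$offset))
      if (all(diff(seqs) > 0) && cand$onset[1] > -pi && cand$offset[3] <= pi) {
        new_bd <- cand
        break
      }
    }
    if (is.null(new_bd))
      abort("could not draw wave boundaries preserving P < QRS < T ordering; reduce `boundary_shift`.")
    scales <- stats::setNames(
      runif(3L, config$amplitude_scale[1], config$amplitude_scale[2]),
      c("P", "QRS", "T")
    )
    interval_of <- c(P = "P", Q = "QRS", R = "QRS", S = "QRS", T = "QRS")
    interval_of["T"] <- "T"
    waves <- template$waves
    for (i in seq_len(nrow(waves))) {
      iv <- interval_of[[waves$wave[i]]]
      j <- match(iv, bd$wave)
      o1 <- bd$onset[j]; o2 <- bd$offset[j]
      n1 <- new_bd$onset[j]; n2 <- new_bd$offset[j]
      sc <- (n2 - n1) / (o2 - o1)
      waves$theta[i] <- n1 + (waves$theta[i] - o1) * sc
      waves$b[i] <- waves$b[i] * sc
      waves$a[i] <- waves$a[i] * scales[[iv]]
    }
    vcg_template(waves, new_bd, id = paste0(template$id, "*"))
  })
}
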