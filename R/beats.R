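#' Pan-Tompkins QRS detection
#'
#' The classical real-time QRS detection chain: 5-15 Hz band-pass
#' (zero-phase Butterworth), five-point derivative, squaring and 150 ms
#' moving-window integration, followed by adaptive signal/noise thresholds
#' (`THRESHOLD = NPKI + 0.25 (SPKI - NPKI)`) with a 1.66-RR search-back at
#' half threshold and a 200 ms refractory period. Each detection is refined
#' to the largest magnitude of the band-passed signal in the 150 ms
#' preceding the integrator peak, which compensates the filter group delay.
#'
#' @param x numeric vector (single channel) or an [mcecg] (first channel is
#'   used).
#' @param fs sampling rate in Hz (>= 250); taken from the `mcecg` if given.
#' @return integer vector of R-peak sample indices (possibly empty).
#' @export
detect_r_peaks <- function(x, fs = NULL) {
  if (inherits(x, "mcecg")) {
    fs <- x$fs
    x <- x$samples[, 1L]
  }
  if (is.null(fs)) abort("`fs` is required for a plain numeric signal.")
  if (fs < 250) abort("`fs` must be >= 250 Hz.")
  n <- length(x)
  if (n < 2 * fs) abort("need at least 2 s of signal.")
  if (all(x == x[1L])) return(integer(0)) # flat signal

  bf <- signal::butter(2L, c(5, 15) / (fs / 2), type = "pass")
  bp <- zero_phase(bf$b, bf$a, x)
  # five-point derivative, gain 1/8
  der <- stats::filter(bp, c(2, 1, 0, -1, -2) / 8, sides = 2L)
  der[is.na(der)] <- 0
  sq <- as.numeric(der)^2
  w <- max(1L, round(0.15 * fs))
  mwi <- stats::filter(sq, rep(1 / w, w), sides = 2L)
  mwi[is.na(mwi)] <- 0
  mwi <- as.numeric(mwi)

  refractory <- round(0.2 * fs)
  # candidate local maxima of the integrated signal; maxima closer together
  # than the refractory period are collapsed to the largest of their cluster
  # so a shoulder bump cannot pre-empt (and then refractory-mask) the true
  # QRS maximum
  cand <- which(diff(sign(diff(mwi))) < 0) + 1L
  if (!length(cand)) return(integer(0))
  keep <- integer(0)
  cur <- cand[1L]
  for (p in cand[-1L]) {
    if (p - cur < refractory) {
      if (mwi[p] > mwi[cur]) cur <- p
    } else {
      keep <- c(keep, cur)
      cur <- p
    }
  }
  cand <- c(keep, cur)

  spki <- max(mwi[seq_len(min(n, 2L * fs))]) * 0.5
  npki <- mean(mwi[seq_len(min(n, 2L * fs))]) * 0.5
  peaks <- integer(0)
  rr_hist <- numeric(0)
  last <- -Inf
  i <- 1L
  while (i <= length(cand)) {
    p <- cand[i]
    thr <- npki + 0.25 * (spki - npki)
    if (mwi[p] >= thr && p - last >= refractory) {
      peaks <- c(peaks, p)
      if (is.finite(last)) rr_hist <- c(rr_hist, p - last)
      last <- p
      spki <- 0.125 * mwi[p] + 0.875 * spki
    } else if (mwi[p] < thr) {
      npki <- 0.125 * mwi[p] + 0.875 * npki
      # search-back: no peak for 1.66x the running mean RR
      if (length(rr_hist) >= 2L) {
        rr_mean <- mean(tail(rr_hist, 8L))
        if (p - last > 1.66 * rr_mean) {
          seg <- cand[cand > last + refractory & cand <= p]
          if (length(seg)) {
            q <- seg[which.max(mwi[seg])]
            if (mwi[q] >= 0.5 * thr) {
              peaks <- c(peaks, q)
              rr_hist <- c(rr_hist, q - last)
              last <- q
              spki <- 0.25 * mwi[q] + 0.75 * spki
            }
          }
        }
      }
    }
    i <- i + 1L
  }
  if (!length(peaks)) return(integer(0))
  # refine to the true R apex on a wide-band (baseline-free) version of the
  # signal; the 5-15 Hz detection band distorts the narrow QRS peak.
  hf <- signal::butter(2L, 2 / (fs / 2), type = "high")
  wide <- zero_phase(hf$b, hf$a, x)
  refined <- vapply(peaks, function(p) {
    a <- max(1L, as.integer(p - round(0.15 * fs)))
    b <- min(n, as.integer(p + round(0.05 * fs)))
    a + which.max(abs(wide[a:b])) - 1L
  }, integer(1))
  refined <- sort(unique(refined))
  refined[c(TRUE, diff(refined) >= refractory)]
}

# R-aligned beat matrix: rows are offsets -half..half, columns beats; out-of-
# range samples are NA.
.beat_matrix <- function(x, r_peaks, half) {
  offs <- (-half):half
  sapply(r_peaks, function(r) {
    idx <- r + offs
    v <- rep(NA_real_, length(offs))
    ok <- idx >= 1L & idx <= length(x)
    v[ok] <- x[idx[ok]]
    v
  })
}

# Shared core of beat averaging and the running-median reference: replace
# each beat by a running summary (mean or median) over a centred window of
# n_beats R-aligned windows, then rebuild the signal by taper-weighted
# overlap-add. Samples not covered by any beat window keep their original
# value.
.beat_running_summary <- function(x, r_peaks, n_beats, fs, fun) {
  nb <- length(r_peaks)
  half <- max(1L, round(0.5 * median(diff(r_peaks))))
  bm <- .beat_matrix(x, r_peaks, half)
  w_half <- n_beats %/% 2L
  taper <- 1 - abs((-half):half) / (half + 1)
  num <- numeric(length(x))
  den <- numeric(length(x))
  for (i in seq_len(nb)) {
    lo <- max(1L, i - w_half + 1L)
    hi <- min(nb, i + (n_beats - w_half))
    avg <- apply(bm[, lo:hi, drop = FALSE], 1L, fun, na.rm = TRUE)
    idx <- r_peaks[i] + ((-half):half)
    ok <- idx >= 1L & idx <= length(x) & is.finite(avg)
    num[idx[ok]] <- num[idx[ok]] + taper[ok] * avg[ok]
    den[idx[ok]] <- den[idx[ok]] + taper[ok]
  }
  out <- x
  covered <- den > 0
  out[covered] <- num[covered] / den[covered]
  out
}

#' Beat-to-beat averaging denoiser
#'
#' The traditional fetal ECG enhancement method: every beat is replaced by
#' the running average of `n_beats` R-aligned beat windows centred on it
#' (truncated near the record edges). Windows span half the median RR
#' interval on each side of each R-peak and are blended back with a
#' triangular taper so adjacent averaged beats cross-fade linearly.
#' Averaging suppresses uncorrelated noise by about
#' `10 log10(n_beats)` dB at the cost of flattening beat-to-beat
#' morphological variation.
#'
#' @param signal an [mcecg].
#' @param r_peaks R-peak sample indices (strictly increasing); defaults to
#'   the signal's own annotations, falling back to [detect_r_peaks()] on
#'   channel 1.
#' @param n_beats number of beats averaged (default 30).
#' @return an [mcecg] of identical shape and rate.
#' @export
beat_average <- function(signal, r_peaks = NULL, n_beats = 30L) {
  stopifnot(inherits(signal, "mcecg"))
  if (is.null(r_peaks)) r_peaks <- signal$r_peaks
  if (is.null(r_peaks)) r_peaks <- detect_r_peaks(signal)
  r_peaks <- as.integer(r_peaks)
  if (length(r_peaks) < n_beats)
    abort(sprintf("need at least %d R-peaks, have %d.", n_beats,
                  length(r_peaks)))
  if (any(diff(r_peaks) <= 0)) abort("`r_peaks` must be strictly increasing.")
  out <- apply(signal$samples, 2L, .beat_running_summary,
               r_peaks = r_peaks, n_beats = n_beats, fs = signal$fs,
               fun = mean)
  mcecg(matrix(out, ncol = n_channels(signal)), signal$fs, r_peaks)
}

#' Running-median surrogate clean reference
#'
#' When no ground truth exists, a surrogate "clean" signal is built as the
#' pointwise running median of `n_beats` R-aligned heartbeats (default 100).
#' The median is robust to transient artifacts, at the cost of flattening
#' all physiological beat-to-beat variation.
#'
#' @param signal an [mcecg].
#' @param r_peaks R-peak sample indices; defaults as in [beat_average()].
#' @param n_beats window size in beats (default 100); the signal must
#'   contain at least this many R-peaks.
#' @return an [mcecg] of identical shape and rate.
#' @export
running_median_reference <- function(signal, r_peaks = NULL, n_beats = 100L) {
  stopifnot(inherits(signal, "mcecg"))
  if (is.null(r_peaks)) r_peaks <- signal$r_peaks
  if (is.null(r_peaks)) r_peaks <- detect_r_peaks(signal)
  r_peaks <- as.integer(r_peaks)
  if (length(r_peaks) < n_beats)
    abort(sprintf("insufficient beats: need >= %d R-peaks, have %d.",
                  n_beats, length(r_peaks)))
  out <- apply(signal$samples, 2L, .beat_running_summary,
               r_peaks = r_peaks, n_beats = n_beats, fs = signal$fs,
               fun = median)
  mcecg(matrix(out, ncol = n_channels(signal)), signal$fs, r_peaks)
}
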