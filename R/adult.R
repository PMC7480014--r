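#' Convert adult ECG morphology toward fetal morphology
#'
#' The fetal heart beats roughly twice as fast as the adult heart, with
#' correspondingly compressed intervals. An adult record is made
#' fetal-like by (1) zero-phase high-pass filtering at 1 Hz (4th-order
#' Butterworth applied forward-backward) to remove baseline drift, (2)
#' Savitzky-Golay smoothing of polynomial order 8 and window length 31, and
#' (3) resampling to half the original rate, which halves all ECG intervals
#' relative to the new time base. Amplitudes are left untouched since signals
#' are z-normalized downstream.
#'
#' @param signal an [mcecg] with more than 62 samples.
#' @return an [mcecg] with `ceiling(n/2)` samples and `fs/2` sampling rate.
#'   R-peak annotations, whose sample indices would be invalidated, are
#'   dropped.
#' @export
adult_to_fetal <- function(signal) {
  stopifnot(inherits(signal, "mcecg"))
  if (signal$fs <= 2) abort("`fs` must exceed 2 Hz for a 1 Hz high-pass.")
  if (n_samples(signal) <= 62L) abort("signal too short (need > 62 samples).")
  out <- apply(signal$samples, 2L, function(x) {
    x <- highpass(x, signal$fs, cutoff = 1, order = 4L)
    x <- signal::sgolayfilt(x, p = 8L, n = 31L)
    signal::resample(x, 1L, 2L)
  })
  mcecg(matrix(out, ncol = n_channels(signal)), signal$fs / 2)
}

#' Randomly combine adult leads into a four-channel record
#'
#' Draws 4 distinct source channels uniformly among all subsets satisfying
#' the constraint that at most two come from the first six channels (the limb
#' leads of a standard 12/15-lead layout), and returns the corresponding
#' 4-channel record.
#'
#' @param record an [mcecg] with at least 7 channels. At least two non-limb
#'   channels (index > 6) must exist for the constraint to be satisfiable.
#' @param seed optional RNG seed.
#' @return an [mcecg] with 4 channels; the selected source channels are
#'   attached as attribute `"leads"`.
#' @export
combine_adult_leads <- function(record, seed = NULL) {
  stopifnot(inherits(record, "mcecg"))
  k <- n_channels(record)
  if (k < 7L) abort("`record` must have at least 7 channels.")
  n_limb <- min(k, 6L)
  if (k - n_limb < 2L)
    abort("infeasible lead layout: need at least two non-limb channels to pick 4 leads with at most 2 limb leads.")
  leads <- with_seed(seed, {
    repeat {
      pick <- sort(sample.int(k, 4L))
      if (sum(pick <= 6L) <= 2L) break
    }
    pick
  })
  out <- mcecg(record$samples[, leads, drop = FALSE], record$fs, record$r_peaks)
  attr(out, "leads") <- leads
  out
}
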