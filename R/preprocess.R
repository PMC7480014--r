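#' Resample a record to the canonical 500 Hz rate
#'
#' Rational polyphase resampling by `500 / fs`. A 500 Hz input is returned
#' unchanged. The sampling rate must be a positive rational number of Hz with
#' a reasonable denominator (it is rounded to 3 decimals).
#'
#' @param signal an [mcecg].
#' @return an [mcecg] at 500 Hz. R-peak annotations are rescaled to the new
#'   rate (rounded to the nearest sample).
#' @export
resample_to_500 <- function(signal) {
  stopifnot(inherits(signal, "mcecg"))
  if (signal$fs == 500) return(signal)
  fs_m <- round(signal$fs * 1000)
  g <- gcd(500000, fs_m)
  p <- 500000 / g
  q <- fs_m / g
  out <- apply(signal$samples, 2L, signal::resample, p = p, q = q)
  rp <- if (is.null(signal$r_peaks)) NULL else
    pmax(1L, round((signal$r_peaks - 1L) * 500 / signal$fs) + 1L)
  out <- matrix(out, ncol = n_channels(signal))
  if (!is.null(rp)) rp <- rp[rp <= nrow(out)]
  mcecg(out, 500, rp)
}

#' Cut a four-channel record into fixed-length segments
#'
#' Divides the signal into consecutive windows of `length` samples (hop
#' `hop`, non-overlapping by default); the trailing remainder is dropped, and
#' each segment's source offset is recorded so the cut is auditable.
#'
#' @param signal an [mcecg] with exactly 4 channels and at least `length`
#'   samples.
#' @param length segment length in samples (canonical network window: 1920).
#' @param hop hop between segment starts; defaults to `length`.
#' @return a `segment_batch`: list with `segments` (array n_seg x length x
#'   4), `offsets` (0-based start samples), `fs`, and `norm` (NULL until
#'   [normalize_segments()] is applied).
#' @export
segment_ecg <- function(signal, length = 1920L, hop = length) {
  stopifnot(inherits(signal, "mcecg"))
  if (n_channels(signal) != 4L)
    abort("`signal` must have exactly 4 channels; select channels upstream.")
  n <- n_samples(signal)
  if (n < length) abort(sprintf("signal too short: %d < %d samples.", n, length))
  starts <- seq(1L, n - length + 1L, by = hop)
  segs <- array(0, dim = c(base::length(starts), length, 4L))
  for (i in seq_along(starts))
    segs[i, , ] <- signal$samples[starts[i]:(starts[i] + length - 1L), ]
  structure(
    list(segments = segs, offsets = starts - 1L, fs = signal$fs, norm = NULL),
    class = "segment_batch"
  )
}

#' @export
print.segment_batch <- function(x, ...) {
  d <- dim(x$segments)
  cat(sprintf("<segment_batch> %d segment(s) of %d x %d @ %g Hz%s\n",
              d[1], d[2], d[3], x$fs,
              if (is.null(x$norm)) "" else ", normalized"))
  invisible(x)
}

#' Z-normalize segments per channel
#'
#' Each channel of each segment is centred and scaled to zero mean and unit
#' standard deviation; the (mean, sd) pairs are retained in the batch so
#' results can be mapped back to physical units with
#' [denormalize_segments()].
#'
#' @param batch a `segment_batch`.
#' @return the batch with normalized `segments` and a `norm` field (array
#'   n_seg x 4 x 2 of means and sds in original units).
#' @export
normalize_segments <- function(batch) {
  stopifnot(inherits(batch, "segment_batch"))
  if (!is.null(batch$norm)) abort("batch is already normalized.")
  d <- dim(batch$segments)
  norm <- array(0, dim = c(d[1], d[3], 2L))
  for (i in seq_len(d[1])) {
    for (ch in seq_len(d[3])) {
      x <- batch$segments[i, , ch]
      m <- mean(x)
      s <- sd(x)
      if (!is.finite(s) || s <= 0)
        abort(sprintf("segment %d channel %d has zero variance; cannot normalize.", i, ch))
      batch$segments[i, , ch] <- (x - m) / s
      norm[i, ch, ] <- c(m, s)
    }
  }
  batch$norm <- norm
  batch
}

#' Undo segment normalization
#'
#' @param batch a normalized `segment_batch` (possibly with its `segments`
#'   replaced by a denoiser's output of the same shape).
#' @return the batch in original units, `norm` cleared.
#' @export
denormalize_segments <- function(batch) {
  stopifnot(inherits(batch, "segment_batch"))
  if (is.null(batch$norm)) abort("batch is not normalized.")
  d <- dim(batch$segments)
  for (i in seq_len(d[1]))
    for (ch in seq_len(d[3]))
      batch$segments[i, , ch] <-
        batch$segments[i, , ch] * batch$norm[i, ch, 2] + batch$norm[i, ch, 1]
  batch$norm <- NULL
  batch
}

#' Reassemble segments into a contiguous multi-channel signal
#'
#' Concatenates non-overlapping segments back onto their source offsets.
#' Samples not covered by any segment (the dropped remainder) are absent
#' from the output.
#'
#' @param batch a `segment_batch` in original units.
#' @return an [mcecg].
#' @export
reassemble_segments <- function(batch) {
  stopifnot(inherits(batch, "segment_batch"))
  if (!is.null(batch$norm))
    abort("denormalize the batch before reassembling.")
  d <- dim(batch$segments)
  ord <- order(batch$offsets)
  out <- do.call(rbind, lapply(ord, function(i)
    matrix(batch$segments[i, , ], ncol = d[3])))
  mcecg(out, batch$fs)
}
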