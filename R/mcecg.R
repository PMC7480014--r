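#' Multi-channel ECG container
#'
#' The universal currency of the package: a sampled multi-channel signal with
#' its sampling rate and (optionally) R-peak annotations. Samples are stored
#' as a numeric matrix, time in rows and channels in columns, in whatever
#' amplitude units the source uses (microvolts for the simulator).
#'
#' @param samples numeric matrix (time x channels) or a vector for a
#'   single-channel signal.
#' @param fs sampling frequency in Hz (positive scalar).
#' @param r_peaks optional integer vector of R-peak sample indices (1-based,
#'   strictly increasing).
#' @return an object of class `mcecg`.
#' @examples
#' x <- mcecg(matrix(rnorm(1000), ncol = 2), fs = 500)
#' n_samples(x)
#' @export
mcecg <- function(samples, fs, r_peaks = NULL) {
  if (is.vector(samples)) samples <- matrix(samples, ncol = 1L)
  if (!is.matrix(samples) || !is.numeric(samples))
    abort("`samples` must be a numeric matrix (time x channels).")
  if (ncol(samples) < 1L) abort("`samples` needs at least one channel.")
  if (any(!is.finite(samples))) abort("`samples` contains non-finite values.")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    abort("`fs` must be a positive scalar (Hz).")
  if (!is.null(r_peaks)) {
    r_peaks <- as.integer(r_peaks)
    if (length(r_peaks) && any(diff(r_peaks) <= 0L))
      abort("`r_peaks` must be strictly increasing.")
    if (length(r_peaks) && (min(r_peaks) < 1L || max(r_peaks) > nrow(samples)))
      abort("`r_peaks` indices fall outside the signal.")
  }
  structure(
    list(samples = unname(samples), fs = as.numeric(fs), r_peaks = r_peaks),
    class = "mcecg"
  )
}

#' @export
print.mcecg <- function(x, ...) {
  cat(sprintf(
    "<mcecg> %d samples x %d channel(s) @ %g Hz (%.2f s)%s\n",
    nrow(x$samples), ncol(x$samples), x$fs, nrow(x$samples) / x$fs,
    if (is.null(x$r_peaks)) "" else sprintf(", %d R-peaks", length(x$r_peaks))
  ))
  invisible(x)
}

#' Number of samples / channels of a multi-channel ECG
#' @param x an [mcecg] object.
#' @return an integer scalar.
#' @export
n_samples <- function(x) nrow(x$samples)

#' @rdname n_samples
#' @export
n_channels <- function(x) ncol(x$samples)

#' Duration of a multi-channel ECG in seconds
#' @param x an [mcecg] object.
#' @return a numeric scalar (seconds).
#' @export
duration <- function(x) nrow(x$samples) / x$fs

#' Tidy a multi-channel ECG into a long tibble
#'
#' @param x an [mcecg] object.
#' @param ... unused.
#' @return a tibble with columns `time` (s), `channel` (factor) and
#'   `amplitude`.
#' @export
as_tibble.mcecg <- function(x, ...) {
  n <- nrow(x$samples)
  k <- ncol(x$samples)
  tibble(
    time = rep((seq_len(n) - 1) / x$fs, times = k),
    channel = factor(rep(seq_len(k), each = n)),
    amplitude = as.vector(x$samples)
  )
}

#' Plot a multi-channel ECG, one facet per channel
#'
#' @param object an [mcecg] object.
#' @param max_seconds plot at most this many seconds from the start.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.mcecg <- function(object, max_seconds = 10, ...) {
  keep <- seq_len(min(n_samples(object), ceiling(max_seconds * object$fs)))
  df <- as_tibble(mcecg(object$samples[keep, , drop = FALSE], object$fs))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$amplitude)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$channel), scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "amplitude")
  if (!is.null(object$r_peaks)) {
    rp <- object$r_peaks[object$r_peaks <= max(keep)]
    if (length(rp))
      p <- p + ggplot2::geom_vline(
        xintercept = (rp - 1) / object$fs,
        colour = "red", alpha = 0.3, linewidth = 0.2
      )
  }
  p
}

# Apply a per-channel function, keeping fs and annotations.
map_channels <- function(x, f, ...) {
  out <- apply(x$samples, 2L, f, ...)
  mcecg(matrix(out, ncol = ncol(x$samples)), x$fs, x$r_peaks)
}
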