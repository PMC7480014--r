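#' SNR improvement of a denoiser
#'
#' The primary benchmark metric: per channel,
#' `SNRimp = 10 log10( sum |noisy - clean|^2 / sum |denoised - clean|^2 )`
#' in dB, positive when denoising moved the signal toward the clean
#' reference. When the denominator underflows (essentially perfect
#' denoising) the value is capped at `cap` dB and flagged.
#'
#' @param noisy,denoised,clean [mcecg] objects or matrices of identical
#'   shape.
#' @param cap ceiling in dB for degenerate denominators (default 100).
#' @return a tibble with one row per channel (`channel`, `snr_imp_db`,
#'   `capped`) plus attribute `mean_db`, also reported by
#'   `summary`-friendly column ordering.
#' @export
snr_improvement <- function(noisy, denoised, clean, cap = 100) {
  m <- function(x) if (inherits(x, "mcecg")) x$samples else as.matrix(x)
  noisy <- m(noisy); denoised <- m(denoised); clean <- m(clean)
  if (!all(dim(noisy) == dim(clean)) || !all(dim(denoised) == dim(clean)))
    abort("all three signals must have identical dimensions.")
  k <- ncol(clean)
  out <- tibble(channel = seq_len(k), snr_imp_db = NA_real_, capped = FALSE)
  for (ch in seq_len(k)) {
    num <- sum((noisy[, ch] - clean[, ch])^2)
    den <- sum((denoised[, ch] - clean[, ch])^2)
    if (den <= num * 10^(-cap / 10)) {
      out$snr_imp_db[ch] <- cap
      out$capped[ch] <- TRUE
    } else {
      out$snr_imp_db[ch] <- 10 * log10(num / den)
    }
  }
  attr(out, "mean_db") <- mean(out$snr_imp_db)
  out
}

#' Least-squares scalp-lead estimate from abdominal channels
#'
#' The scalp electrode measures a different lead than the abdominal
#' channels, so the two are compared through a fitted linear combination:
#' on each window, `a = (X X^T)^-1 X x_scalp^T` with `X` the 4 x K matrix of
#' abdominal channels, and the estimate is `a^T X`. Windows are half a
#' second (K = 250 samples at 500 Hz). If a window's Gram matrix is
#' ill-conditioned the pseudo-inverse is used with a warning.
#'
#' @param denoised an [mcecg] with 4 channels (or K x 4 matrix for a single
#'   window).
#' @param scalp numeric vector, same length as `denoised`.
#' @param window window length in samples (default 250). The trailing
#'   remainder shorter than one window is dropped.
#' @param cond_tol condition-number guard on the Gram matrix.
#' @return a list of class `scalp_estimate`: `estimate` (numeric vector,
#'   length = number of windows x `window`), `coefficients` (tibble with
#'   one row per window and columns `window`, `a1..a4`).
#' @export
estimate_scalp <- function(denoised, scalp, window = 250L, cond_tol = 1e8) {
  X_full <- if (inherits(denoised, "mcecg")) denoised$samples else
    as.matrix(denoised)
  if (ncol(X_full) != 4L) abort("`denoised` must have 4 channels.")
  if (length(scalp) != nrow(X_full))
    abort("`scalp` and `denoised` must have equal length.")
  n_win <- nrow(X_full) %/% window
  if (n_win < 1L) abort("signal shorter than one window.")
  est <- numeric(n_win * window)
  coefs <- matrix(0, nrow = n_win, ncol = 4L)
  for (w in seq_len(n_win)) {
    idx <- ((w - 1L) * window + 1L):(w * window)
    X <- t(X_full[idx, , drop = FALSE]) # 4 x K
    y <- scalp[idx]
    G <- X %*% t(X)
    ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
    if (ev[1L] <= 0 || ev[1L] / max(ev[4L], .Machine$double.xmin) > cond_tol) {
      warn(sprintf("window %d: ill-conditioned Gram matrix, using pseudo-inverse.", w))
      s <- svd(X)
      keep <- s$d > max(s$d) * 1e-10
      a <- s$u[, keep, drop = FALSE] %*%
        ((t(s$u[, keep, drop = FALSE]) %*% (X %*% y)) / s$d[keep]^2)
      a <- as.vector(a)
    } else {
      a <- as.vector(solve(G, X %*% y))
    }
    coefs[w, ] <- a
    est[idx] <- as.vector(t(a) %*% X)
  }
  structure(
    list(
      estimate = est,
      coefficients = tibble(window = seq_len(n_win),
                            a1 = coefs[, 1], a2 = coefs[, 2],
                            a3 = coefs[, 3], a4 = coefs[, 4]),
      window = window
    ),
    class = "scalp_estimate"
  )
}

#' Scalp comparison metrics
#'
#' The four quantitative measures used to compare a (denoised) scalp lead
#' with its estimate from abdominal channels: Pearson correlation
#' `R = cov(est, scalp) / (sd(est) sd(scalp))`, mean squared error, mean
#' absolute error, and `SNR = 10 log10( sum |scalp|^2 /
#' sum |scalp - est|^2 )` dB. MSE and MAE are in squared and plain signal
#' units (microvolts for the simulator).
#'
#' @param scalp numeric reference vector.
#' @param estimate numeric vector of equal length.
#' @param cap dB ceiling for a vanishing SNR denominator.
#' @return a one-row tibble with columns `r`, `mse`, `mae`, `snr_db`.
#' @export
comparison_metrics <- function(scalp, estimate, cap = 100) {
  if (length(scalp) != length(estimate))
    abort("`scalp` and `estimate` must have equal length.")
  if (sd(scalp) == 0 || sd(estimate) == 0)
    abort("constant signal: Pearson correlation undefined.")
  den <- sum((scalp - estimate)^2)
  num <- sum(scalp^2)
  snr <- if (den <= num * 10^(-cap / 10)) cap else 10 * log10(num / den)
  tibble(
    r = stats::cov(estimate, scalp) / (sd(estimate) * sd(scalp)),
    mse = mean((scalp - estimate)^2),
    mae = mean(abs(scalp - estimate)),
    snr_db = snr
  )
}

#' Denoise a scalp reference lead
#'
#' The reference-lead cleanup used before scalp comparison: zero-phase 1 Hz
#' high-pass filtering followed by 30-complex beat averaging.
#'
#' @param scalp numeric vector or single-channel [mcecg].
#' @param r_peaks R-peak indices on the scalp lead.
#' @param fs sampling rate (Hz); taken from the `mcecg` if given.
#' @param n_beats averaging width (default 30).
#' @return a single-channel [mcecg].
#' @export
scalp_denoise_reference <- function(scalp, r_peaks, fs = NULL, n_beats = 30L) {
  if (inherits(scalp, "mcecg")) {
    fs <- scalp$fs
    scalp <- scalp$samples[, 1L]
  }
  if (is.null(fs)) abort("`fs` is required.")
  x <- highpass(scalp, fs, cutoff = 1, order = 4L)
  beat_average(mcecg(x, fs), r_peaks = r_peaks, n_beats = n_beats)
}

#' Evaluate a denoiser on simulated records
#'
#' Applies a denoising function to every record of a dataset and tabulates
#' per-channel input SNR, output SNR and SNR improvement against the known
#' clean signal.
#'
#' @param records a list of `simulated_record`s or an `fecg_dataset`.
#' @param denoiser a function `mcecg -> mcecg` applied to each noisy record
#'   (e.g. `function(x) denoise(model, x)` or [wavelet_denoise()]).
#' @param cap dB cap for degenerate denominators.
#' @return an `eval_report`: tibble with one row per record and channel
#'   (`record`, `channel`, `snr_in_db`, `snr_out_db`, `snr_imp_db`,
#'   `target_snr_db`).
#' @export
evaluate_denoiser <- function(records, denoiser, cap = 100) {
  if (inherits(records, "fecg_dataset")) records <- records$records
  rows <- vector("list", length(records))
  for (i in seq_along(records)) {
    rec <- records[[i]]
    den <- denoiser(rec$noisy)
    dm <- if (inherits(den, "mcecg")) den$samples else as.matrix(den)
    imp <- snr_improvement(rec$noisy, dm, rec$clean, cap = cap)
    k <- n_channels(rec$clean)
    snr_in <- snr_out <- numeric(k)
    for (ch in seq_len(k)) {
      ps <- sum(rec$clean$samples[, ch]^2)
      snr_in[ch] <- 10 * log10(ps / sum((rec$noisy$samples[, ch] -
                                           rec$clean$samples[, ch])^2))
      eo <- sum((dm[, ch] - rec$clean$samples[, ch])^2)
      snr_out[ch] <- if (eo <= ps * 10^(-cap / 10)) cap else 10 * log10(ps / eo)
    }
    rows[[i]] <- tibble(
      record = i, channel = seq_len(k),
      snr_in_db = snr_in, snr_out_db = snr_out,
      snr_imp_db = imp$snr_imp_db,
      target_snr_db = rep_len(rec$target_snr_db, k)
    )
  }
  structure(dplyr::bind_rows(rows), class = c("eval_report", "tbl_df", "tbl",
                                              "data.frame"))
}

#' Summarize an evaluation report
#'
#' @param x an `eval_report` from [evaluate_denoiser()].
#' @param ... unused.
#' @return `glance()`: a one-row tibble with the mean input SNR, output SNR
#'   and SNR improvement over all channels and records.
#' @export
glance.eval_report <- function(x, ...) {
  tibble(
    n_records = length(unique(x$record)),
    n_channels = length(unique(x$channel)),
    mean_snr_in_db = mean(x$snr_in_db),
    mean_snr_out_db = mean(x$snr_out_db),
    mean_snr_imp_db = mean(x$snr_imp_db)
  )
}

#' Plot SNR improvement against input SNR
#'
#' @param object an `eval_report`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.eval_report <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$snr_in_db,
                                       y = .data$snr_imp_db)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_smooth(method = "loess", formula = y ~ x, se = FALSE) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = "input SNR (dB)", y = "SNR improvement (dB)")
}
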