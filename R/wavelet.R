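# Orthogonal wavelet filter bank coefficients (decomposition low-pass).
# Standard published Daubechies/symlet values; the high-pass and
# reconstruction filters follow from the quadrature-mirror relations
# g[n] = (-1)^(n+1) h[F-1-n], rec = reversed dec.
.wavelet_filters <- list(
  sym4 = c(-0.0757657147892733, -0.0296355276459985, 0.4976186676320155,
           0.8037387518059161, 0.2978577956052774, -0.0992195435768472,
           -0.0126039672620378, 0.0322231006040427),
  sym8 = c(-0.0033824159510061, -0.0005421323317911, 0.0316950878114930,
           0.0076074873249176, -0.1432942383508097, -0.0612733590676585,
           0.4813596512583722, 0.7771857517005235, 0.3644418948353314,
           -0.0519458381077090, -0.0272190299170560, 0.0491371796736075,
           0.0038087520138906, -0.0149522583370482, -0.0003029205147214,
           0.0018899503327595),
  db4 = c(-0.0105974017850690, 0.0328830116668852, 0.0308413818355608,
          -0.1870348117190931, -0.0279837694168599, 0.6308807679298589,
          0.7148465705529157, 0.2303778133088965)
)

.get_filters <- function(wavelet) {
  h <- .wavelet_filters[[wavelet]]
  if (is.null(h))
    abort(sprintf("unsupported wavelet '%s'; available: %s.", wavelet,
                  paste(names(.wavelet_filters), collapse = ", ")))
  f <- length(h)
  g <- (-1)^(seq_len(f)) * rev(h)
  list(lo = h, hi = g, len = f)
}

# One level of the periodized discrete wavelet transform.
# cA[k] = sum_n lo[n] x[(2k + F/2 + 1 - n) mod L], k = 1..ceil(L/2)
# (circularly extended; odd-length inputs are extended by their last sample).
.dwt_step <- function(x, filt) {
  L <- length(x)
  if (L %% 2L == 1L) {
    x <- c(x, x[L])
    L <- L + 1L
  }
  f <- filt$len
  half <- L %/% 2L
  # index matrix: rows k, cols n
  idx <- outer(2L * seq_len(half) - 2L + f %/% 2L + 1L, seq_len(f) - 1L, "-")
  idx <- ((idx - 1L) %% L) + 1L
  xm <- matrix(x[idx], nrow = half)
  list(cA = as.vector(xm %*% filt$lo), cD = as.vector(xm %*% filt$hi))
}

# Adjoint (= inverse, filters being orthogonal) of one periodized step.
.idwt_step <- function(cA, cD, filt, out_len = 2L * length(cA)) {
  L <- 2L * length(cA)
  f <- filt$len
  x <- numeric(L)
  for (k in seq_along(cA)) {
    pos <- ((2L * k - 2L + f %/% 2L + 1L - (seq_len(f) - 1L) - 1L) %% L) + 1L
    x[pos] <- x[pos] + filt$lo * cA[k] + filt$hi * cD[k]
  }
  x[seq_len(out_len)]
}

#' Multi-level discrete wavelet transform (periodized)
#'
#' Mallat pyramid decomposition with circular (periodized) boundary
#' handling, used by the wavelet denoising baseline. `wavelet_dwt()` returns
#' the approximation at the coarsest level plus the detail coefficients per
#' level; `wavelet_idwt()` inverts it exactly.
#'
#' @param x numeric vector.
#' @param wavelet filter name: `"sym4"` (default), `"sym8"` or `"db4"`.
#' @param level decomposition depth; the signal must have at least
#'   `2^level` samples.
#' @return a list with `cA` (coarse approximation) and `details` (list of
#'   detail coefficient vectors, finest first), plus the bookkeeping needed
#'   for reconstruction.
#' @export
wavelet_dwt <- function(x, wavelet = "sym4", level = 6L) {
  filt <- .get_filters(wavelet)
  if (length(x) < 2L^level)
    abort(sprintf("signal of length %d too short for %d-level decomposition.",
                  length(x), level))
  if (length(x) < filt$len)
    abort("signal shorter than the wavelet filter support.")
  details <- vector("list", level)
  lens <- integer(level)
  cur <- x
  for (lv in seq_len(level)) {
    lens[lv] <- length(cur)
    s <- .dwt_step(cur, filt)
    details[[lv]] <- s$cD
    cur <- s$cA
  }
  structure(list(cA = cur, details = details, lens = lens, wavelet = wavelet,
                 n = length(x)),
            class = "wavelet_decomposition")
}

#' @rdname wavelet_dwt
#' @param decomposition a `wavelet_decomposition` from `wavelet_dwt()`.
#' @export
wavelet_idwt <- function(decomposition) {
  stopifnot(inherits(decomposition, "wavelet_decomposition"))
  filt <- .get_filters(decomposition$wavelet)
  cur <- decomposition$cA
  for (lv in rev(seq_along(decomposition$details)))
    cur <- .idwt_step(cur, decomposition$details[[lv]], filt,
                      out_len = decomposition$lens[lv])
  cur
}

#' Fixed minimax wavelet-shrinkage threshold
#'
#' The threshold minimizing worst-case risk for wavelet shrinkage:
#' `lambda = sigma * (0.3936 + 0.1829 * log2(N))` for `N > 32`, where
#' `sigma` is the noise level and `N` the signal length.
#'
#' @param n signal length.
#' @param sigma noise standard deviation estimate.
#' @return the threshold (numeric scalar).
#' @export
minimax_threshold <- function(n, sigma = 1) {
  if (n <= 32) return(0)
  sigma * (0.3936 + 0.1829 * log2(n))
}

#' Robust noise-level estimate from finest detail coefficients
#'
#' `sigma_hat = median(|d1|) / 0.6745`, the classical MAD estimator on the
#' finest-scale wavelet details.
#'
#' @param d1 finest-level detail coefficients.
#' @return estimated noise standard deviation.
#' @export
mad_sigma <- function(d1) median(abs(d1)) / 0.6745

.soft_threshold <- function(x, lambda) sign(x) * pmax(abs(x) - lambda, 0)
.hard_threshold <- function(x, lambda) x * (abs(x) > lambda)

#' Wavelet denoising with a fixed minimax threshold
#'
#' Classical wavelet shrinkage: each channel is decomposed with a symlet
#' wavelet, all detail coefficients are thresholded with one fixed threshold
#' `lambda = sigma_hat * (0.3936 + 0.1829 * log2(N))` (the minimax rule,
#' with `sigma_hat` the MAD estimate from the finest details), and the
#' signal is reconstructed. Approximation coefficients are untouched.
#'
#' @param signal an [mcecg].
#' @param wavelet filter name, default `"sym4"`.
#' @param level decomposition depth, default 6 (at 500 Hz this puts the
#'   approximation band below about 4 Hz).
#' @param mode `"soft"` (default) or `"hard"` thresholding.
#' @return an [mcecg] of identical shape and rate.
#' @export
wavelet_denoise <- function(signal, wavelet = "sym4", level = 6L,
                            mode = c("soft", "hard")) {
  stopifnot(inherits(signal, "mcecg"))
  mode <- match.arg(mode)
  thr <- if (mode == "soft") .soft_threshold else .hard_threshold
  map_channels(signal, function(x) {
    dec <- wavelet_dwt(x, wavelet = wavelet, level = level)
    lambda <- minimax_threshold(length(x), mad_sigma(dec$details[[1L]]))
    dec$details <- lapply(dec$details, thr, lambda = lambda)
    wavelet_idwt(dec)
  })
}
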