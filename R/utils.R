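#' Derive a stage seed from a master seed
#'
#' All stochastic stages of the pipeline (morphology variation, rhythm, lead
#' projection, noise, training batch order ...) draw their own seed from one
#' master seed so that a whole dataset or pipeline run is reproducible
#' bit-for-bit from a single integer. The derivation is a fixed affine map in
#' 31-bit integer arithmetic: `(master * 2654435761 + index * 40503 + offset)
#' mod (2^31 - 1)`, using the Knuth multiplicative constant so that
#' neighbouring record indices receive well-separated seeds.
#'
#' @param master integer master seed.
#' @param index record or stage index (non-negative integer).
#' @param offset stage discriminator (non-negative integer).
#' @return an integer seed in `[1, 2^31 - 2]`, safe to pass to [set.seed()].
#' @export
derive_seed <- function(master, index = 0L, offset = 0L) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  m <- 2147483647 # 2^31 - 1, prime
  s <- (as.double(master) %% m) * (2654435761 %% m) %% m
  s <- (s + as.double(index) * 40503 + as.double(offset)) %% m
  s <- floor(s)
  if (s < 1) s <- s + 1
  as.integer(s)
}

# Evaluate expr with a temporarily seeded RNG; NULL seed means "use the
# current RNG stream" so callers can either pin results or stay inside an
# outer set.seed().
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Zero-phase IIR filtering with reflective padding at both ends. filtfilt
# alone leaves visible edge transients; padding by reflection (scipy-style,
# odd extension about the end points) suppresses them.
zero_phase <- function(b, a, x, pad = NULL) {
  n <- length(x)
  if (is.null(pad)) pad <- max(3L * (max(length(a), length(b)) - 1L), 250L)
  pad <- min(n - 1L, as.integer(pad))
  left <- 2 * x[1] - x[seq(pad + 1L, 2L)]
  right <- 2 * x[n] - x[seq(n - 1L, n - pad)]
  ext <- c(left, x, right)
  y <- signal::filtfilt(signal::Arma(b = b, a = a), ext)
  y[seq(pad + 1L, pad + n)]
}

# Zero-phase Butterworth high-pass, cutoff in Hz. The filter is applied as
# a cascade of second-order sections: a single high-order transfer function
# is badly conditioned at cutoffs far below Nyquist and leaks DC. Padding
# covers several filter time constants so low cutoffs settle.
highpass <- function(x, fs, cutoff = 1, order = 4L) {
  n_sections <- max(1L, order %/% 2L)
  bf <- signal::butter(2L, cutoff / (fs / 2), type = "high")
  for (i in seq_len(n_sections))
    x <- zero_phase(bf$b, bf$a, x, pad = round(3 * fs / cutoff))
  x
}

signal_power <- function(x) mean(x^2)

# Greatest common divisor (for rational resampling ratios).
gcd <- function(a, b) {
  while (b > 0) { t <- a %% b; a <- b; b <- t }
  a
}
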