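#' Denoiser architecture settings
#'
#' Describes the 8+8 layer convolutional encoder-decoder. The full-width
#' reference architecture uses encoder filter counts
#' (64, 128, 256, 256, 512, 512, 1024, 2048) with strides
#' (1, 2, 2, 2, 2, 2, 2, 2), kernel size 15 and LeakyReLU slope 0.2, on
#' input windows of 1920 samples x 4 channels; the decoder mirrors the
#' encoder with transposed convolutions (strides reversed, so the last layer
#' has stride 1) and ends in a linear 1920 x 4 output. Additive skip
#' junctions are placed after decoder layers 2, 4, 6 and 8, before their
#' activation, sourcing the size-matched encoder outputs; the final junction
#' adds the raw network input. With seven stride-2 stages the bottleneck
#' length is `1920 / 2^7 = 15` samples.
#'
#' `width_scale` multiplies all filter counts (floored, minimum 1) to give
#' desk-scale variants of the same topology; `width_scale = 0.125` is the
#' preset used for CPU-scale training experiments.
#'
#' @param width_scale positive scale factor on all filter counts.
#' @param kernel_size convolution kernel length in samples.
#' @param seg_len input window length in samples.
#' @param in_channels number of input/output channels (4 for the
#'   multi-channel denoiser, 1 for the single-channel variant).
#' @param leaky_slope negative-part slope of the LeakyReLU activations.
#' @param base_filters encoder filter schedule before scaling.
#' @param strides encoder stride schedule.
#' @return a list of class `network_config`.
#' @export
network_config <- function(width_scale = 1,
                           kernel_size = 15L,
                           seg_len = 1920L,
                           in_channels = 4L,
                           leaky_slope = 0.2,
                           base_filters = c(64L, 128L, 256L, 256L,
                                            512L, 512L, 1024L, 2048L),
                           strides = c(1L, 2L, 2L, 2L, 2L, 2L, 2L, 2L)) {
  if (width_scale <= 0) abort("`width_scale` must be positive.")
  filters <- pmax(1L, as.integer(floor(base_filters * width_scale)))
  div <- prod(strides)
  if (seg_len %% div != 0L)
    abort("`seg_len` must be divisible by the product of the strides.")
  structure(
    list(width_scale = width_scale, kernel_size = as.integer(kernel_size),
         seg_len = as.integer(seg_len), in_channels = as.integer(in_channels),
         leaky_slope = leaky_slope, filters = filters,
         strides = as.integer(strides),
         bottleneck_len = seg_len %/% div),
    class = "network_config"
  )
}

#' Build a denoiser model
#'
#' Allocates and He-initializes the weights of the encoder-decoder described
#' by a [network_config]. The model lives behind an external pointer; use
#' [get_weights()] / [set_weights()] to serialize it.
#'
#' @param config a [network_config].
#' @param seed integer seed for the weight initialization.
#' @return an object of class `fecg_denoiser`.
#' @export
build_model <- function(config = network_config(), seed = 1L) {
  stopifnot(inherits(config, "network_config"))
  ptr <- .nn_create(config$filters, config$strides, config$kernel_size,
                    config$in_channels, config$seg_len, config$leaky_slope,
                    as.integer(seed))
  structure(list(ptr = ptr, config = config, seed = as.integer(seed),
                 history = NULL),
            class = "fecg_denoiser")
}

#' @export
print.fecg_denoiser <- function(x, ...) {
  cat(sprintf(
    "<fecg_denoiser> width %g, %d + %d layers, %s parameters, input %d x %d\n",
    x$config$width_scale, length(x$config$filters), length(x$config$filters),
    format(.nn_num_params(x$ptr), big.mark = ","),
    x$config$seg_len, x$config$in_channels
  ))
  if (!is.null(x$history))
    cat(sprintf("  trained %d epoch(s), final val loss %.4g\n",
                nrow(x$history), utils::tail(x$history$val_loss, 1L)))
  invisible(x)
}

#' Per-layer output shapes of a model
#'
#' @param model an `fecg_denoiser`.
#' @return a tibble with one row per layer: `layer`, `stage`
#'   (encoder/decoder), `length` (temporal), `channels`, `stride`.
#' @export
model_shapes <- function(model) {
  stopifnot(inherits(model, "fecg_denoiser"))
  s <- .nn_shapes(model$ptr)
  n <- nrow(s)
  tibble(
    layer = seq_len(n),
    stage = rep(c("encoder", "decoder"), each = n / 2),
    length = s[, "length"],
    channels = s[, "channels"],
    stride = s[, "stride"]
  )
}

#' Extract / restore model weights
#'
#' @param model an `fecg_denoiser`.
#' @return `get_weights()` returns a list of per-layer `W`/`b` matrices (in
#'   double precision); `set_weights()` writes such a list back into the
#'   model and returns it invisibly.
#' @export
get_weights <- function(model) {
  stopifnot(inherits(model, "fecg_denoiser"))
  .nn_get_weights(model$ptr)
}

#' @rdname get_weights
#' @param weights a list as returned by `get_weights()`.
#' @export
set_weights <- function(model, weights) {
  stopifnot(inherits(model, "fecg_denoiser"))
  .nn_set_weights(model$ptr, weights)
  invisible(model)
}

#' Save / load a model checkpoint
#'
#' Checkpoints embed the full [network_config], the weights (in double
#' precision) and the training history, so a loaded model is ready for
#' inference or further training.
#'
#' @param model an `fecg_denoiser`.
#' @param path checkpoint file path (RDS).
#' @return `save_model()` returns `path` invisibly; `load_model()` returns
#'   an `fecg_denoiser`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "fecg_denoiser"))
  saveRDS(list(config = model$config, seed = model$seed,
               weights = get_weights(model), history = model$history,
               train_config = model$train_config), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  ck <- readRDS(path)
  model <- build_model(ck$config, seed = ck$seed)
  set_weights(model, ck$weights)
  model$history <- ck$history
  model$train_config <- ck$train_config
  model
}

#' Zero all model weights (identity-skip diagnostic)
#'
#' With every weight and bias zero the only surviving path through the
#' network is the final additive skip from the input, so the model computes
#' the identity map. Mainly useful for testing the skip topology.
#'
#' @param model an `fecg_denoiser`.
#' @return the model, invisibly.
#' @export
zero_weights <- function(model) {
  stopifnot(inherits(model, "fecg_denoiser"))
  .nn_zero_weights(model$ptr)
  invisible(model)
}

#' Normalized mean squared error loss
#'
#' The training loss of the denoiser: the squared error between clean and
#' denoised segments, normalized per segment and channel by the mean squared
#' clean amplitude, averaged over batch, channels and time:
#' `L = 1/(N L M) * sum_{n,l,m} (X_clean - X_denoised)^2 / msq(n, l)` with
#' `msq(n, l) = mean_m X_clean(n, l, m)^2`. The loss is dimensionless,
#' non-negative, zero iff the signals are equal, and invariant under common
#' rescaling of both arguments.
#'
#' @param clean,denoised numeric arrays of identical shape: `(N, M, L)`
#'   (segments x time x channels), a time x channels matrix, or vectors.
#' @return a non-negative scalar.
#' @export
nmse_loss <- function(clean, denoised) {
  if (is.null(dim(clean))) clean <- array(clean, dim = c(1L, length(clean), 1L))
  if (is.null(dim(denoised)))
    denoised <- array(denoised, dim = c(1L, length(denoised), 1L))
  if (length(dim(clean)) == 2L)
    clean <- array(clean, dim = c(1L, dim(clean)))
  if (length(dim(denoised)) == 2L)
    denoised <- array(denoised, dim = c(1L, dim(denoised)))
  if (!all(dim(clean) == dim(denoised)))
    abort("`clean` and `denoised` must have identical shapes.")
  d <- dim(clean)
  msq <- apply(clean^2, c(1L, 3L), mean)
  if (any(msq <= 0)) abort("zero-power clean segment-channel; loss undefined.")
  se <- apply((clean - denoised)^2, c(1L, 3L), mean)
  mean(se / msq)
}

#' Analytic receptive field of the denoiser
#'
#' Computes the extent (in input samples) of the region of the input that
#' one output sample depends on, by the standard recursion over the layer
#' schedule: through a convolution the field grows by `(k - 1) * jump` and
#' the jump multiplies by the stride; through a transposed convolution the
#' jump divides by the stride first. For the full-width reference schedule
#' this exceeds 1500 samples (about 7 s at 500 Hz).
#'
#' @param config a [network_config].
#' @return the receptive field in samples (integer).
#' @export
receptive_field <- function(config = network_config()) {
  stopifnot(inherits(config, "network_config"))
  k <- config$kernel_size
  rf <- 1
  jump <- 1
  for (s in config$strides) {        # encoder
    rf <- rf + (k - 1) * jump
    jump <- jump * s
  }
  for (s in rev(config$strides)) {   # decoder (mirrored strides)
    jump <- jump / s
    rf <- rf + (k - 1) * jump
  }
  as.integer(rf)
}

#' Apply a model to segment arrays
#'
#' Low-level inference on an already-normalized array of segments.
#'
#' @param model an `fecg_denoiser`.
#' @param segments array `(n_segments, seg_len, channels)`.
#' @return array of the same shape.
#' @export
predict_segments <- function(model, segments) {
  stopifnot(inherits(model, "fecg_denoiser"))
  d <- dim(segments)
  if (length(d) != 3L) abort("`segments` must be a 3-d array (N, M, L).")
  .nn_forward(model$ptr, as.numeric(segments), as.integer(d))
}

#' Denoise a multi-channel ECG record
#'
#' End-to-end inference: the record is resampled to 500 Hz if needed, cut
#' into non-overlapping windows of the model's input length, z-normalized
#' per segment and channel, pushed through the network, denormalized back to
#' the input units and re-concatenated. The trailing remainder shorter than
#' one window is passed through untouched so the output has the same length
#' as the input.
#'
#' @param model an `fecg_denoiser` with 4 input channels.
#' @param signal an [mcecg] with 4 channels.
#' @return an [mcecg] of the same length, rate and units as the input.
#' @export
denoise <- function(model, signal) {
  stopifnot(inherits(model, "fecg_denoiser"), inherits(signal, "mcecg"))
  if (model$config$in_channels == 1L) return(denoise_single_channel(model, signal))
  signal500 <- resample_to_500(signal)
  len <- model$config$seg_len
  n <- n_samples(signal500)
  if (n < len) abort(sprintf("signal too short to denoise: %d < %d samples.", n, len))
  batch <- segment_ecg(signal500, length = len)
  batch <- normalize_segments(batch)
  batch$segments <- predict_segments(model, batch$segments)
  batch <- denormalize_segments(batch)
  out <- reassemble_segments(batch)
  covered <- n_samples(out)
  if (covered < n) {
    out <- mcecg(rbind(out$samples,
                       signal500$samples[(covered + 1L):n, , drop = FALSE]),
                 500)
  }
  mcecg(out$samples, 500, signal500$r_peaks)
}

# Single-channel variant: each channel is denoised independently by a model
# with in_channels = 1.
denoise_single_channel <- function(model, signal) {
  stopifnot(model$config$in_channels == 1L)
  signal500 <- resample_to_500(signal)
  out <- signal500$samples
  for (ch in seq_len(ncol(out))) {
    one <- mcecg(out[, ch, drop = FALSE], 500)
    den <- denoise_one_channel_signal(model, one)
    out[, ch] <- den$samples[, 1L]
  }
  mcecg(out, 500, signal500$r_peaks)
}

denoise_one_channel_signal <- function(model, signal) {
  len <- model$config$seg_len
  n <- n_samples(signal)
  if (n < len) abort("signal too short to denoise.")
  starts <- seq(1L, n - len + 1L, by = len)
  segs <- array(0, dim = c(length(starts), len, 1L))
  norm <- matrix(0, nrow = length(starts), ncol = 2L)
  for (i in seq_along(starts)) {
    x <- signal$samples[starts[i]:(starts[i] + len - 1L), 1L]
    norm[i, ] <- c(mean(x), sd(x))
    if (norm[i, 2L] <= 0) abort("zero-variance window; cannot normalize.")
    segs[i, , 1L] <- (x - norm[i, 1L]) / norm[i, 2L]
  }
  pred <- predict_segments(model, segs)
  out <- signal$samples
  for (i in seq_along(starts))
    out[starts[i]:(starts[i] + len - 1L), 1L] <-
      pred[i, , 1L] * norm[i, 2L] + norm[i, 1L]
  mcecg(out, signal$fs)
}
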