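#' Training settings for the denoiser
#'
#' Adam optimization of the normalized MSE loss ([nmse_loss()]) on paired
#' clean/noisy normalized segments. The reference run uses batch size 64 and
#' learning rate 1e-5; desk-scale training on a width-reduced network uses a
#' larger learning rate (around 1e-3) and far fewer epochs, with the best
#' validation checkpoint retained.
#'
#' @param batch_size segments per gradient step (>= 1).
#' @param learning_rate Adam step size (> 0).
#' @param epochs number of passes over the training set.
#' @param seed RNG seed for batch shuffling.
#' @param clip_norm global gradient-norm clipping threshold (0 disables);
#'   very low-SNR batches occasionally produce huge gradients that would
#'   otherwise destabilize training.
#' @return a list of class `train_config`.
#' @export
train_config <- function(batch_size = 64L, learning_rate = 1e-5,
                         epochs = 21L, seed = 1L, clip_norm = 5) {
  if (batch_size < 1L) abort("`batch_size` must be >= 1.")
  if (learning_rate <= 0) abort("`learning_rate` must be positive.")
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 clip_norm = clip_norm),
            class = "train_config")
}

#' Train a denoiser on paired clean/noisy segments
#'
#' Runs seeded minibatch Adam on the normalized MSE loss. After every epoch
#' the validation loss is evaluated; the weights achieving the best
#' validation loss are restored at the end (early-stopping by checkpoint).
#' The loss history is recorded on the returned model.
#'
#' @param model an `fecg_denoiser`.
#' @param noisy,clean arrays `(N, seg_len, channels)` of normalized training
#'   segments.
#' @param val_noisy,val_clean validation arrays of the same shape family
#'   (may have a different N); pass NULL to train without validation.
#' @param config a [train_config].
#' @return the model, with `history` set to a tibble of per-epoch
#'   train/validation loss.
#' @export
train_denoiser <- function(model, noisy, clean,
                           val_noisy = NULL, val_clean = NULL,
                           config = train_config()) {
  stopifnot(inherits(model, "fecg_denoiser"), inherits(config, "train_config"))
  d <- dim(noisy)
  if (is.null(d) || length(d) != 3L || !all(dim(clean) == d))
    abort("`noisy` and `clean` must be (N, M, L) arrays of identical shape.")
  if (is.null(val_noisy)) {
    val_noisy <- array(0, dim = c(0L, d[2], d[3]))
    val_clean <- val_noisy
  }
  vd <- dim(val_noisy)
  hist <- .nn_train(model$ptr,
                    as.numeric(noisy), as.numeric(clean), as.integer(d),
                    as.numeric(val_noisy), as.numeric(val_clean),
                    as.integer(vd),
                    config$batch_size, config$learning_rate,
                    config$epochs, config$seed,
                    if (is.null(config$clip_norm)) 5 else config$clip_norm)
  model$history <- tibble(
    epoch = seq_len(nrow(hist)),
    train_loss = hist[, "train_loss"],
    val_loss = hist[, "val_loss"]
  )
  model$train_config <- config
  model
}

#' Build normalized training segments from a simulated dataset
#'
#' Segments every record of a dataset into the model input window,
#' z-normalizes noisy and clean sides with the *noisy* statistics (at
#' inference time only the noisy signal is available, so the clean target
#' must live on the same scale), and stacks them into arrays.
#'
#' @param dataset an `fecg_dataset` from [build_dataset()].
#' @param seg_len window length in samples.
#' @return list with arrays `noisy` and `clean`, both
#'   `(n_segments, seg_len, 4)`.
#' @export
dataset_segments <- function(dataset, seg_len = 1920L) {
  stopifnot(inherits(dataset, "fecg_dataset"))
  arrs <- .dataset_arrays(dataset$records, n_target = seg_len)
  n <- dim(arrs$noisy)[1]
  for (i in seq_len(n)) {
    for (ch in 1:4) {
      m <- mean(arrs$noisy[i, , ch])
      s <- sd(arrs$noisy[i, , ch])
      if (s <= 0) abort("zero-variance noisy channel in dataset.")
      arrs$noisy[i, , ch] <- (arrs$noisy[i, , ch] - m) / s
      arrs$clean[i, , ch] <- (arrs$clean[i, , ch] - m) / s
    }
  }
  arrs
}

#' Per-layer gradient norms for one batch
#'
#' Diagnostic for gradient flow: runs one forward/backward pass and returns
#' the Frobenius norm of the weight gradient of every layer. A healthy
#' skip-connected network shows non-zero gradient down to the first encoder
#' layer.
#'
#' @param model an `fecg_denoiser`.
#' @param noisy,clean segment arrays `(N, M, L)`.
#' @return a tibble with `layer`, `stage` and `grad_norm`.
#' @export
gradient_norms <- function(model, noisy, clean) {
  stopifnot(inherits(model, "fecg_denoiser"))
  d <- dim(noisy)
  g <- .nn_grad_norms(model$ptr, as.numeric(noisy), as.numeric(clean),
                      as.integer(d))
  n <- length(g)
  tibble(layer = seq_len(n),
         stage = rep(c("encoder", "decoder"), each = n / 2),
         grad_norm = g)
}

#' Tidy / summarize a denoiser
#'
#' `tidy()` returns one row per layer (shapes and parameter counts);
#' `glance()` returns a one-row model summary.
#'
#' @param x an `fecg_denoiser`.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.fecg_denoiser <- function(x, ...) {
  sh <- model_shapes(x)
  w <- get_weights(x)
  sh$n_params <- vapply(w, function(l) length(l$W) + length(l$b), numeric(1))
  sh
}

#' @rdname tidy.fecg_denoiser
#' @export
glance.fecg_denoiser <- function(x, ...) {
  tibble(
    width_scale = x$config$width_scale,
    n_layers = length(x$config$filters) * 2L,
    n_params = .nn_num_params(x$ptr),
    seg_len = x$config$seg_len,
    in_channels = x$config$in_channels,
    receptive_field = receptive_field(x$config),
    bottleneck_len = x$config$bottleneck_len,
    trained = !is.null(x$history),
    final_val_loss = if (is.null(x$history)) NA_real_
                     else utils::tail(x$history$val_loss, 1L)
  )
}

#' Generic tidiers
#'
#' Broom-style generics re-exported for the package's fitted objects.
#' @param x object to tidy.
#' @param ... passed to methods.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidy
#' @export
glance <- function(x, ...) UseMethod("glance")

#' Plot a training history
#'
#' @param object an `fecg_denoiser` that has been trained.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.fecg_denoiser <- function(object, ...) {
  if (is.null(object$history)) abort("model has no training history.")
  df <- tidyr::pivot_longer(object$history, -"epoch",
                            names_to = "series", values_to = "loss")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "epoch", y = "normalized MSE loss", colour = NULL)
}
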