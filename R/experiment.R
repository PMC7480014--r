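#' Observed layer shapes from an actual forward pass
#'
#' Pushes a batch through the network and reports the temporal length and
#' channel count of every layer's activation as they actually occurred (as
#' opposed to [model_shapes()], which reports the configured geometry).
#'
#' @param model an `fecg_denoiser`.
#' @param segments array `(N, seg_len, channels)`.
#' @return a tibble with `layer`, `stage`, `length`, `channels`.
#' @export
forward_shapes <- function(model, segments) {
  stopifnot(inherits(model, "fecg_denoiser"))
  d <- dim(segments)
  s <- .nn_forward_dims(model$ptr, as.numeric(segments), as.integer(d))
  n <- nrow(s)
  tibble(layer = seq_len(n),
         stage = rep(c("encoder", "decoder"), each = n / 2),
         length = s[, "length"], channels = s[, "channels"])
}

#' The packaged desk-scale denoising experiment
#'
#' Runs the package's standard CPU-scale experiment end to end: simulate
#' training/validation data with target SNR uniform in -15..15 dB, train a
#' width-1/8 multi-channel denoiser and an identically budgeted
#' single-channel variant (same architecture with `in_channels = 1`, same
#' number of gradient steps, trained on one rotating channel per record),
#' and evaluate both — plus the wavelet and 30-beat-averaging baselines — on
#' held-out records whose target SNR is drawn from `test_snr_range_db`
#' (default -15..0 dB, the low-quality regime where multi-channel
#' information matters most).
#'
#' @param master_seed integer seed; every dataset, initialization and batch
#'   order is derived from it.
#' @param n_train training records (one 1920 x 4 segment each; >= 2000 for
#'   the standard run).
#' @param n_val,n_test validation / held-out record counts.
#' @param epochs training epochs for both networks.
#' @param width_scale width of both networks.
#' @param learning_rate,batch_size optimizer settings for both networks.
#' @param test_snr_range_db target-SNR range of the held-out records.
#' @param baselines also evaluate the wavelet and averaging baselines.
#' @return a list with `model` (multi-channel), `model_single`, `reports`
#'   (named list of `eval_report`s), and `summary` (tibble of mean SNR
#'   improvement per method).
#' @export
desk_scale_experiment <- function(master_seed = 1L,
                                  n_train = 2000L,
                                  n_val = 100L,
                                  n_test = 60L,
                                  epochs = 16L,
                                  width_scale = 0.125,
                                  learning_rate = 2e-3,
                                  batch_size = 16L,
                                  test_snr_range_db = c(-15, 0),
                                  baselines = TRUE) {
  train_ds <- build_dataset(n_train, master_seed = derive_seed(master_seed, 0L, 10L))
  val_ds <- build_dataset(n_val, master_seed = derive_seed(master_seed, 0L, 11L))
  test_ds <- build_dataset(n_test, snr_range_db = test_snr_range_db,
                           master_seed = derive_seed(master_seed, 0L, 12L))
  tr <- dataset_segments(train_ds)
  va <- dataset_segments(val_ds)

  model <- build_model(network_config(width_scale = width_scale),
                       seed = derive_seed(master_seed, 0L, 20L))
  model <- train_denoiser(model, tr$noisy, tr$clean, va$noisy, va$clean,
                          train_config(batch_size, learning_rate, epochs,
                                       seed = derive_seed(master_seed, 0L, 21L)))

  one_channel <- function(arrs, offset = 0L) {
    n <- dim(arrs$noisy)[1]
    no <- array(0, dim = c(n, dim(arrs$noisy)[2], 1L))
    cl <- no
    for (i in seq_len(n)) {
      ch <- ((i - 1L + offset) %% 4L) + 1L
      no[i, , 1L] <- arrs$noisy[i, , ch]
      cl[i, , 1L] <- arrs$clean[i, , ch]
    }
    list(noisy = no, clean = cl)
  }
  tr1 <- one_channel(tr)
  va1 <- one_channel(va)
  model_single <- build_model(
    network_config(width_scale = width_scale, in_channels = 1L),
    seed = derive_seed(master_seed, 0L, 20L)
  )
  model_single <- train_denoiser(
    model_single, tr1$noisy, tr1$clean, va1$noisy, va1$clean,
    train_config(batch_size, learning_rate, epochs,
                 seed = derive_seed(master_seed, 0L, 21L))
  )

  reports <- list(
    multi_channel = evaluate_denoiser(test_ds, function(x) denoise(model, x)),
    single_channel = evaluate_denoiser(test_ds,
                                       function(x) denoise(model_single, x))
  )
  if (isTRUE(baselines)) {
    reports$wavelet <- evaluate_denoiser(test_ds, wavelet_denoise)
    if (all(vapply(test_ds$records, function(r) length(r$r_peaks),
                   integer(1)) >= 30L))
      reports$averaging <- evaluate_denoiser(
        test_ds, function(x) beat_average(x, n_beats = 30L))
  }
  summary <- dplyr::bind_rows(lapply(names(reports), function(nm)
    dplyr::mutate(glance(reports[[nm]]), method = nm, .before = 1L)))
  list(model = model, model_single = model_single, reports = reports,
       summary = summary, test_ds = test_ds)
}
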