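test_that("SNR improvement matches the power-ratio algebra", {
  set.seed(1)
  n <- 1000
  clean <- matrix(rnorm(n * 2), ncol = 2)
  noise <- matrix(rnorm(n * 2), ncol = 2)
  noisy <- clean + noise
  # identity denoiser: 0 dB
  r0 <- snr_improvement(noisy, noisy, clean)
  expect_equal(r0$snr_imp_db, c(0, 0))
  # constructed case: denoised = clean + (noisy - clean)/sqrt(10) -> 10 dB
  den <- clean + noise / sqrt(10)
  r10 <- snr_improvement(noisy, den, clean)
  expect_equal(r10$snr_imp_db, c(10, 10), tolerance = 1e-12)
  # perfect denoising hits the documented cap and is flagged
  rp <- snr_improvement(noisy, clean, clean)
  expect_equal(rp$snr_imp_db, c(100, 100))
  expect_true(all(rp$capped))
  # antisymmetry under swapping noisy <-> denoised
  ra <- snr_improvement(noisy, den, clean)
  rb <- snr_improvement(den, noisy, clean)
  expect_equal(ra$snr_imp_db, -rb$snr_imp_db, tolerance = 1e-12)
})

test_that("SNR improvement agrees with a brute-force recomputation", {
  set.seed(2)
  clean <- matrix(rnorm(400), ncol = 4)
  noisy <- clean + matrix(rnorm(400), ncol = 4)
  den <- clean + 0.3 * matrix(rnorm(400), ncol = 4)
  r <- snr_improvement(noisy, den, clean)
  for (ch in 1:4) {
    brute <- 10 * log10(sum(abs(noisy[, ch] - clean[, ch])^2) /
                          sum(abs(den[, ch] - clean[, ch])^2))
    expect_equal(r$snr_imp_db[ch], brute, tolerance = 1e-10)
  }
  expect_equal(attr(r, "mean_db"), mean(r$snr_imp_db))
})

test_that("running median reference reproduces identical beats and needs 100 of them", {
  rec <- constant_beat_record(n_beats = 120, seed = 3)
  ref <- running_median_reference(rec, n_beats = 100)
  mid <- rec$r_peaks[55]:rec$r_peaks[70]
  expect_equal(ref$samples[mid, ], rec$samples[mid, ], tolerance = 1e-9)
  few <- constant_beat_record(n_beats = 50, seed = 3)
  expect_error(running_median_reference(few, n_beats = 100), "insufficient")
})

test_that("median reference beats mean reference under heavy-tailed noise", {
  set.seed(4)
  cl <- constant_beat_record(n_beats = 120, seed = 5)
  mid <- cl$r_peaks[55]:cl$r_peaks[70]
  wins <- replicate(30, {
    noise <- matrix(stats::rt(length(cl$samples), df = 1.5), ncol = 4)
    noisy <- mcecg(cl$samples + noise, 500, cl$r_peaks)
    med <- running_median_reference(noisy, n_beats = 100)
    avg <- beat_average(noisy, n_beats = 100)
    mse_med <- mean((med$samples[mid, ] - cl$samples[mid, ])^2)
    mse_avg <- mean((avg$samples[mid, ] - cl$samples[mid, ])^2)
    mse_med < mse_avg
  })
  expect_gt(mean(wins), 0.9)
})

test_that("windowed least squares recovers exact and orthogonal cases", {
  set.seed(5)
  X <- matrix(rnorm(250 * 4), ncol = 4)
  # scalp equal to channel 2
  fit <- estimate_scalp(X, X[, 2])
  expect_equal(fit$coefficients$a2, 1, tolerance = 1e-8)
  expect_equal(unlist(fit$coefficients[1, c("a1", "a3", "a4")]),
               c(a1 = 0, a3 = 0, a4 = 0), tolerance = 1e-8)
  expect_equal(fit$estimate, X[, 2], tolerance = 1e-8)
  # scalp orthogonal to all channels
  y <- rnorm(250)
  y_orth <- y - X %*% solve(crossprod(X), crossprod(X, y))
  fit0 <- estimate_scalp(X, as.vector(y_orth))
  expect_equal(unlist(fit0$coefficients[1, c("a1", "a2", "a3", "a4")]),
               c(a1 = 0, a2 = 0, a3 = 0, a4 = 0), tolerance = 1e-8)
  expect_equal(max(abs(fit0$estimate)), 0, tolerance = 1e-8)
})

test_that("least-squares coefficients match a brute-force normal-equations solver", {
  set.seed(6)
  X4 <- matrix(rnorm(1000 * 4), ncol = 4)
  y <- rnorm(1000)
  fit <- estimate_scalp(X4, y, window = 250)
  for (w in 1:4) {
    idx <- ((w - 1) * 250 + 1):(w * 250)
    Xw <- t(X4[idx, ])
    a_brute <- solve(Xw %*% t(Xw)) %*% (Xw %*% y[idx])
    expect_equal(as.numeric(fit$coefficients[w, c("a1", "a2", "a3", "a4")]),
                 as.vector(a_brute), tolerance = 1e-8)
    # residual orthogonal to every channel
    res <- y[idx] - as.vector(t(a_brute) %*% Xw)
    expect_lt(max(abs(Xw %*% res)) / sum(abs(y[idx])), 1e-8)
  }
})

test_that("least-squares residual norm shrinks as channels are added", {
  set.seed(7)
  X <- matrix(rnorm(250 * 4), ncol = 4)
  y <- rnorm(250)
  rss <- sapply(1:4, function(k) {
    Xk <- X[, 1:k, drop = FALSE]
    sum((y - Xk %*% solve(crossprod(Xk), crossprod(Xk, y)))^2)
  })
  expect_true(all(diff(rss) <= 1e-10))
  expect_lte(sqrt(rss[4]), sqrt(sum(y^2)) + 1e-12)
})

test_that("ill-conditioned windows fall back to the pseudo-inverse", {
  X <- matrix(rnorm(250 * 4), ncol = 4)
  X[, 2] <- X[, 1] # rank deficient
  expect_warning(fit <- estimate_scalp(X, rnorm(250)), "pseudo-inverse")
  expect_true(all(is.finite(unlist(fit$coefficients))))
})

test_that("comparison metrics reproduce hand computations", {
  s <- c(1, 2, 3, 4)
  e <- c(1, 2, 3, 5)
  m <- comparison_metrics(s, e)
  expect_equal(m$mse, 0.25)
  expect_equal(m$mae, 0.25)
  expect_equal(m$r, stats::cov(e, s) / (sd(e) * sd(s)), tolerance = 1e-12)
  expect_equal(m$snr_db, 10 * log10(sum(s^2) / sum((s - e)^2)),
               tolerance = 1e-12)
  # degenerate and sign cases
  perfect <- comparison_metrics(s, s)
  expect_equal(perfect$r, 1)
  expect_equal(perfect$mse, 0)
  expect_equal(perfect$snr_db, 100)
  anti <- comparison_metrics(s - mean(s), -(s - mean(s)))
  expect_equal(anti$r, -1)
  expect_error(comparison_metrics(c(1, 1, 1), c(1, 2, 3)), "constant")
})

test_that("scalp reference denoising gains the averaging factor on white noise", {
  gains <- sapply(1:40, function(i) {
    set.seed(i)
    cl <- constant_beat_record(n_beats = 60, seed = 8)
    scalp_clean <- cl$samples[, 1]
    scalp_noisy <- scalp_clean + rnorm(length(scalp_clean))
    den <- scalp_denoise_reference(scalp_noisy, r_peaks = cl$r_peaks,
                                   fs = 500, n_beats = 30)
    mid <- cl$r_peaks[16]:cl$r_peaks[45]
    10 * log10(sum((scalp_noisy[mid] - scalp_clean[mid])^2) /
                 sum((den$samples[mid, 1] - scalp_clean[mid])^2))
  })
  expect_equal(mean(gains), 10 * log10(30), tolerance = 1.5)
})

test_that("evaluation report is consistent: improvement = out - in", {
  set.seed(9)
  ds <- build_dataset(5, master_seed = 17)
  rep <- evaluate_denoiser(ds, wavelet_denoise)
  expect_equal(nrow(rep), 20L)
  expect_equal(rep$snr_imp_db, rep$snr_out_db - rep$snr_in_db,
               tolerance = 1e-9)
  g <- glance(rep)
  expect_equal(g$mean_snr_imp_db, mean(rep$snr_imp_db))
  # averaging over records equals the mean of per-record values
  per_record <- tapply(rep$snr_imp_db, rep$record, mean)
  expect_equal(mean(per_record), g$mean_snr_imp_db, tolerance = 1e-12)
})
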