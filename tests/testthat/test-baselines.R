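test_that("periodized DWT reproduces frozen reference coefficients", {
  # Reference values computed with an independent wavelet implementation
  # (PyWavelets 1.9, mode = "periodization") on x = round(3 sin(0.7 k), 6).
  x <- round(sin((0:15) * 0.7) * 3, 6)
  d <- wavelet_dwt(x, "sym4", level = 1)
  expect_equal(d$cA,
    c(3.178149041, 3.4145419124, -1.8487108217, -4.0657459647,
      0.4666244729, 4.2243678318, 0.7468190212, -2.7616483026),
    tolerance = 1e-9)
  expect_equal(d$details[[1]],
    c(-0.6144107742, -0.2458843783, -0.0526073085, 0.2815242923,
      0.1483076047, -0.2311098793, -0.3215261997, 0.3057051584),
    tolerance = 1e-9)
})

test_that("DWT/IDWT is a perfect-reconstruction pair for all filters", {
  set.seed(1)
  for (w in c("sym4", "sym8", "db4")) {
    x <- rnorm(256)
    d <- wavelet_dwt(x, w, level = 5)
    expect_equal(wavelet_idwt(d), x, tolerance = 1e-10)
  }
  # odd length
  xo <- rnorm(99)
  do <- wavelet_dwt(xo, "sym4", level = 2)
  expect_equal(wavelet_idwt(do), xo, tolerance = 1e-10)
  expect_error(wavelet_dwt(rnorm(100), "sym3"), "unsupported")
  expect_error(wavelet_dwt(rnorm(16), "sym4", level = 5), "too short")
})

test_that("minimax threshold matches its closed form", {
  # lambda = sigma (0.3936 + 0.1829 log2 N); independently evaluated
  expect_equal(minimax_threshold(1920, 1), 0.3936 + 0.1829 * log2(1920),
               tolerance = 1e-12)
  expect_equal(minimax_threshold(1920, 2.5), 2.5 * (0.3936 + 0.1829 * log2(1920)))
  expect_equal(minimax_threshold(32, 1), 0)
  # MAD noise estimate is unbiased for Gaussian noise
  set.seed(2)
  d1 <- rnorm(1e5, sd = 3)
  expect_equal(mad_sigma(d1), 3, tolerance = 0.05)
})

test_that("wavelet denoising: zero in, zero out; length and rate preserved", {
  z <- mcecg(matrix(0, 1920, 4), 500)
  out <- wavelet_denoise(z)
  expect_equal(out$samples, z$samples)
  set.seed(3)
  x <- mcecg(matrix(rnorm(1999 * 2), ncol = 2), 250)
  y <- wavelet_denoise(x, level = 5)
  expect_equal(dim(y$samples), dim(x$samples))
  expect_equal(y$fs, 250)
})

test_that("wavelet denoising improves 0 dB records and degrades very clean ones", {
  set.seed(4)
  vcg <- synthesize_vcg(vcg_template_preset("typical"), rep(0.45, 20), fs = 500)
  rec0 <- project_to_abdominal_leads(vcg, seed = 2)
  imp_at <- function(snr, n = 6) {
    mean(sapply(seq_len(n), function(i) {
      rec <- add_calibrated_noise(
        rec0, noise_config(snr, weights = c(white = 1, baseline = 0,
                                            emg = 0, powerline = 0),
                           seed = 100 + i))
      den <- wavelet_denoise(rec$noisy)
      attr(snr_improvement(rec$noisy, den, rec$clean), "mean_db")
    }))
  }
  expect_gt(imp_at(0), 0)
  expect_lt(imp_at(33), 0)
})

test_that("soft and hard thresholding behave as documented", {
  expect_equal(fecgdenoise:::.soft_threshold(c(-3, -1, 0.5, 2), 1),
               c(-2, 0, 0, 1))
  expect_equal(fecgdenoise:::.hard_threshold(c(-3, -1, 0.5, 2), 1),
               c(-3, 0, 0, 2))
})

test_that("beat averaging reproduces identical noiseless beats exactly", {
  rec <- constant_beat_record(n_beats = 40, seed = 5)
  avg <- beat_average(rec, n_beats = 30)
  mid <- rec$r_peaks[5]:rec$r_peaks[36]
  expect_equal(avg$samples[mid, ], rec$samples[mid, ], tolerance = 1e-9)
})

test_that("30-beat averaging gains about 10 log10(30) dB on white noise", {
  gains <- sapply(1:100, function(i) {
    set.seed(i)
    cl <- constant_beat_record(n_beats = 60, seed = 3)
    noisy <- mcecg(cl$samples + matrix(rnorm(length(cl$samples)), ncol = 4),
                   500, cl$r_peaks)
    avg <- beat_average(noisy, n_beats = 30)
    # steady-state region: beats with a full 30-beat neighbourhood
    mid <- cl$r_peaks[16]:cl$r_peaks[45]
    num <- sum((noisy$samples[mid, ] - cl$samples[mid, ])^2)
    den <- sum((avg$samples[mid, ] - cl$samples[mid, ])^2)
    10 * log10(num / den)
  })
  expect_equal(mean(gains), 10 * log10(30), tolerance = 1)
})

test_that("averaging suppresses alternating beat-to-beat morphology", {
  # beats alternate A, B, A, B ... ; averaging flattens the A/B contrast
  tplA <- single_r_template(a = 1, b = 0.08)
  tplB <- single_r_template(a = 0.6, b = 0.08)
  fs <- 500
  a <- synthesize_vcg(tplA, rep(0.5, 1), fs)$samples
  b <- synthesize_vcg(tplB, rep(0.5, 1), fs)$samples
  nb <- 40
  sig <- do.call(rbind, rep(list(a, b), nb / 2))
  r_peaks <- as.integer(seq(126, by = 250, length.out = nb))
  x <- mcecg(sig[, 1, drop = FALSE], fs)
  avg <- beat_average(x, r_peaks = r_peaks, n_beats = 30)
  beat_amp <- function(s) s$samples[r_peaks, 1]
  contrast_before <- sd(beat_amp(x))
  contrast_after <- sd(beat_amp(avg))
  expect_lt(contrast_after, 0.2 * contrast_before)
})

test_that("averaging guards: too few beats, non-increasing peaks", {
  rec <- constant_beat_record(n_beats = 10, seed = 5)
  expect_error(beat_average(rec, n_beats = 30), "at least 30")
  expect_error(beat_average(rec, r_peaks = c(10, 5, 20), n_beats = 2),
               "increasing")
})

test_that("Pan-Tompkins finds nearly all R peaks on clean synthetic records", {
  for (nm in c("typical", "broad_t", "small_p")) {
    x <- synthesize_vcg(vcg_template_preset(nm), rep(0.4, 120), fs = 500)
    det <- detect_r_peaks(x$samples[, 1], 500)
    tol <- round(0.02 * 500) # +/- 20 ms
    tp <- sum(vapply(det, function(p) any(abs(x$r_peaks - p) <= tol),
                     logical(1)))
    f1 <- 2 * tp / (length(det) + length(x$r_peaks))
    expect_gte(f1, 0.99)
  }
})

test_that("Pan-Tompkins edge cases: flat signal, beat count at 120 bpm", {
  expect_identical(detect_r_peaks(rep(0, 3000), 500), integer(0))
  x <- synthesize_vcg(vcg_template_preset("typical"), rep(0.5, 120), fs = 500)
  det <- detect_r_peaks(x$samples[, 1], 500)
  expect_lte(abs(length(det) - 120L), 1L)
  expect_error(detect_r_peaks(rnorm(100), 500), "2 s")
  expect_error(detect_r_peaks(rnorm(1000), 100), "250")
})

test_that("baseline denoisers never change length or sampling rate", {
  set.seed(6)
  rec <- constant_beat_record(n_beats = 35, seed = 7)
  noisy <- mcecg(rec$samples + 0.5 * matrix(rnorm(length(rec$samples)),
                                            ncol = 4), 500, rec$r_peaks)
  for (den in list(wavelet_denoise(noisy),
                   beat_average(noisy, n_beats = 30))) {
    expect_equal(dim(den$samples), dim(noisy$samples))
    expect_equal(den$fs, noisy$fs)
  }
})
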