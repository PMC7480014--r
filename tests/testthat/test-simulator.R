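test_that("Gaussian-sum synthesis matches the closed form evaluated per sample", {
  tpl <- single_r_template(a = 1, b = 0.1, theta = 0)
  x <- synthesize_vcg(tpl, rr_intervals = 1, fs = 500)
  expect_equal(n_samples(x), 500L)
  # independent closed-form evaluation on the same phase grid
  theta <- -pi + 2 * pi * (0:499) / 500
  expected <- exp(-theta^2 / (2 * 0.1^2))
  expect_equal(x$samples[, 1], expected, tolerance = 1e-12)
  expect_equal(x$samples[, 2], rep(0, 500))
  # global maximum at mid-beat, value ~ 1
  expect_equal(which.max(x$samples[, 1]), 251L)
  expect_equal(max(x$samples[, 1]), 1, tolerance = 1e-6)
  expect_equal(x$r_peaks, 251L)
})

test_that("zero-amplitude template produces an all-zero signal of correct length", {
  x <- synthesize_vcg(zero_template(), rep(0.5, 4), fs = 500)
  expect_equal(n_samples(x), 1000L)
  expect_equal(max(abs(x$samples)), 0)
})

test_that("a run of beats yields one detectable R peak per beat", {
  tpl <- single_r_template(a = 1, b = 0.05)
  x <- synthesize_vcg(tpl, rep(0.4, 10), fs = 500)
  expect_equal(n_samples(x), 2000L)
  expect_length(x$r_peaks, 10L)
  # count maxima above half the R amplitude, as an independent peak count
  v <- x$samples[, 1]
  above <- v > 0.5
  runs <- rle(above)
  expect_equal(sum(runs$values), 10L)
})

test_that("synthesis rejects degenerate inputs", {
  tpl <- single_r_template()
  expect_error(synthesize_vcg(tpl, numeric(0)), "empty")
  expect_error(synthesize_vcg(tpl, c(0.5, -0.1)), "positive")
  expect_error(synthesize_vcg(tpl, 0.5, fs = 100), "250")
})

test_that("template validation enforces ordering, widths and centre placement", {
  tpl <- vcg_template_preset("typical")
  bad <- tpl$waves
  bad$b[1] <- 0
  expect_error(vcg_template(bad, tpl$boundaries), "positive")
  bad <- tpl$waves
  bad$theta[bad$wave == "P"][1] <- 0 # P centre inside QRS interval
  expect_error(vcg_template(bad, tpl$boundaries), "outside")
  bad_bounds <- tpl$boundaries
  bad_bounds$onset[bad_bounds$wave == "T"] <- -3 # T before QRS
  expect_error(vcg_template(tpl$waves, bad_bounds), "ordered")
})

test_that("all built-in templates are valid and distinct", {
  tpls <- lapply(c("typical", "broad_t", "small_p"), vcg_template_preset)
  for (t in tpls) expect_s3_class(t, "vcg_template")
  expect_false(identical(tpls[[1]]$waves, tpls[[2]]$waves))
  expect_false(identical(tpls[[2]]$waves, tpls[[3]]$waves))
})

test_that("morphology variation: identity, determinism, uniform boundary shifts", {
  tpl <- vcg_template_preset("typical")
  # identity configuration
  same <- vary_morphology(tpl, morphology_config(0, c(1, 1), seed = 1))
  expect_equal(same$waves, tpl$waves, tolerance = 1e-12)
  expect_equal(same$boundaries, tpl$boundaries, tolerance = 1e-12)
  # determinism under a fixed seed
  a <- vary_morphology(tpl, morphology_config(0.05, c(0.8, 1.2), seed = 99))
  b <- vary_morphology(tpl, morphology_config(0.05, c(0.8, 1.2), seed = 99))
  expect_identical(a$waves, b$waves)
  # empirical distribution of the P-onset shift is uniform on +/- 0.1
  set.seed(4)
  shifts <- replicate(1000, {
    v <- vary_morphology(tpl, morphology_config(0.1, c(1, 1)))
    v$boundaries$onset[1] - tpl$boundaries$onset[1]
  })
  ks <- suppressWarnings(stats::ks.test(shifts, "punif", -0.1, 0.1))
  expect_gt(ks$p.value, 0.01)
})

test_that("morphology variation preserves P < QRS < T ordering over many draws", {
  tpl <- vcg_template_preset("small_p")
  set.seed(10)
  for (i in 1:200) {
    v <- vary_morphology(tpl, morphology_config(0.15, c(0.5, 1.5)))
    b <- v$boundaries
    expect_true(all(diff(c(rbind(b$onset, b$offset))) > 0))
  }
})

test_that("RR generation: constant case, determinism and event shape", {
  rr <- generate_rr_series(rhythm_config(mean_hr = 120, hrv_std = 0), 10)
  expect_equal(rr, rep(0.5, 20))
  a <- generate_rr_series(rhythm_config(seed = 5), 30)
  b <- generate_rr_series(rhythm_config(seed = 5), 30)
  expect_identical(a, b)
  expect_gte(sum(a), 30)
  # deceleration lengthens RR inside the event window
  cfg <- rhythm_config(mean_hr = 140, hrv_std = 0, event = "deceleration",
                       event_onset = 10, event_magnitude = 30,
                       event_duration = 10)
  rr <- generate_rr_series(cfg, 30)
  t_mid <- cumsum(rr) - rr / 2
  inside <- rr[t_mid > 12 & t_mid < 18] # plateau region
  outside <- rr[t_mid < 9 | t_mid > 21]
  expect_gt(mean(inside), mean(outside))
})

test_that("rhythm guards reject unphysiological configurations", {
  expect_error(rhythm_config(mean_hr = 30), "physiological")
  expect_error(generate_rr_series(rhythm_config(), duration = 0), "positive")
})

test_that("lead projection is the stated linear map and rejects degenerate matrices", {
  tpl <- vcg_template_preset("typical")
  vcg <- synthesize_vcg(tpl, rep(0.5, 4), fs = 500)
  pr <- rbind(diag(3), c(1, 0, 0))
  y <- project_to_abdominal_leads(vcg, projection = pr)
  expect_equal(y$samples[, 1:3], vcg$samples)
  expect_equal(y$samples[, 4], vcg$samples[, 1])
  expect_identical(y$r_peaks, vcg$r_peaks)
  expect_error(project_to_abdominal_leads(vcg, projection = matrix(0, 4, 3)),
               "rank")
  # linearity
  pr2 <- matrix(rnorm(12), 4, 3)
  va <- project_to_abdominal_leads(vcg, projection = pr2)
  vcg3 <- mcecg(3 * vcg$samples, vcg$fs)
  vb <- project_to_abdominal_leads(vcg3, projection = pr2)
  expect_equal(vb$samples, 3 * va$samples, tolerance = 1e-12)
})

test_that("SNR calibration hits the target exactly across the full range", {
  rec0 <- constant_beat_record(n_beats = 8, seed = 2)
  for (target in c(-30, -10, 0, 10, 30)) {
    rec <- add_calibrated_noise(rec0, noise_config(target, seed = 3))
    expect_equal(rec$achieved_snr_db, rep(target, 4), tolerance = 0.1)
    # independent power recomputation
    for (ch in 1:4) {
      ps <- mean(rec$clean$samples[, ch]^2)
      pn <- mean((rec$noisy$samples[, ch] - rec$clean$samples[, ch])^2)
      expect_equal(10 * log10(ps / pn), target, tolerance = 0.1)
    }
  }
})

test_that("0 dB and -10 dB targets give the expected power ratios", {
  rec0 <- constant_beat_record(n_beats = 8, seed = 2)
  r0 <- add_calibrated_noise(rec0, noise_config(0, seed = 1))
  ps <- mean(r0$clean$samples[, 1]^2)
  pn <- mean((r0$noisy$samples[, 1] - r0$clean$samples[, 1])^2)
  expect_equal(pn / ps, 1, tolerance = 0.02)
  r10 <- add_calibrated_noise(rec0, noise_config(-10, seed = 1))
  pn10 <- mean((r10$noisy$samples[, 1] - r10$clean$samples[, 1])^2)
  expect_equal(pn10 / ps, 10, tolerance = 0.2)
})

test_that("infinite SNR target is a no-noise pass-through and zero power errors", {
  rec0 <- constant_beat_record(n_beats = 8, seed = 2)
  r <- add_calibrated_noise(rec0, noise_config(Inf, seed = 1))
  expect_identical(r$noisy$samples, rec0$samples)
  flat <- mcecg(matrix(0, 1000, 2), 500)
  expect_error(add_calibrated_noise(flat, noise_config(0, seed = 1)), "zero power")
})

test_that("adult-to-fetal conversion: DC removal, length contract, band response", {
  fs <- 1000
  n <- 4000
  dc <- mcecg(matrix(5, n, 1), fs)
  out <- adult_to_fetal(dc)
  expect_equal(n_samples(out), n / 2)
  expect_equal(out$fs, 500)
  expect_lt(max(abs(out$samples)), 1e-6)
  t <- (0:(n - 1)) / fs
  slow <- mcecg(matrix(sin(2 * pi * 0.2 * t), ncol = 1), fs)
  fast <- mcecg(matrix(sin(2 * pi * 10 * t), ncol = 1), fs)
  att_slow <- sd(adult_to_fetal(slow)$samples[, 1]) / sd(slow$samples[, 1])
  att_fast <- sd(adult_to_fetal(fast)$samples[, 1]) / sd(fast$samples[, 1])
  expect_lt(20 * log10(att_slow), -20) # >= 20 dB attenuation at 0.2 Hz
  expect_gt(20 * log10(att_fast), -1)  # within 1 dB at 10 Hz
  expect_error(adult_to_fetal(mcecg(matrix(rnorm(40), ncol = 1), fs)), "short")
})

test_that("adult lead combination honours the limb-lead constraint", {
  x <- mcecg(matrix(rnorm(100 * 9), ncol = 9), 1000)
  set.seed(3)
  for (i in 1:500) {
    y <- combine_adult_leads(x)
    expect_lte(sum(attr(y, "leads") <= 6), 2L)
    expect_equal(n_channels(y), 4L)
  }
  a <- combine_adult_leads(x, seed = 8)
  b <- combine_adult_leads(x, seed = 8)
  expect_identical(attr(a, "leads"), attr(b, "leads"))
  # 7 channels, 6 of them limb: 4 picks with <= 2 limb is impossible
  x7 <- mcecg(matrix(rnorm(100 * 7), ncol = 7), 1000)
  expect_error(combine_adult_leads(x7), "infeasible")
})

test_that("datasets are bit-reproducible and respect the SNR range", {
  d1 <- build_dataset(4, master_seed = 42)
  d2 <- build_dataset(4, master_seed = 42)
  expect_identical(
    lapply(d1$records, function(r) r$noisy$samples),
    lapply(d2$records, function(r) r$noisy$samples)
  )
  expect_equal(n_samples(d1$records[[1]]$clean), 1920L)
  targets <- d1$manifest$records$target_snr_db
  expect_true(all(targets >= -15 & targets <= 15))
})

test_that("dataset target SNRs are uniform over the configured range", {
  d <- build_dataset(400, duration = 0.5, master_seed = 9,
                     snr_range_db = c(-15, 15))
  targets <- d$manifest$records$target_snr_db
  ks <- suppressWarnings(stats::ks.test(targets, "punif", -15, 15))
  expect_gt(ks$p.value, 0.01)
})
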