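test_that("segmentation follows the 300-beat / 50 % overlap policy", {
  segs <- segment_systogram(rnorm(900), 300, 0.5)
  expect_length(segs, 5)
  expect_true(all(lengths(segs) == 300))
  expect_length(segment_systogram(rnorm(300), 300, 0.5), 1)
  expect_warning(s299 <- segment_systogram(rnorm(299), 300, 0.5),
                 "shorter")
  expect_length(s299[[1]], 299)
})

test_that("Levinson-Durbin solves closed-form low-order cases", {
  m <- levinson_durbin(c(1, 0.5), 1)
  expect_equal(m$a, 0.5)
  expect_equal(m$sigma2, 0.75)
  m0 <- levinson_durbin(c(2, 0.5), 0)
  expect_equal(m0$sigma2, 2)
  expect_length(m0$a, 0)
  expect_error(levinson_durbin(c(0, 0.5), 1), "positive")
  expect_error(levinson_durbin(c(1, 1.5), 1), "positive definite")
})

test_that("Levinson-Durbin recovers a known AR(2) from its exact ACF", {
  a_true <- c(0.5, -0.3)
  rho <- stats::ARMAacf(ar = a_true, lag.max = 2)
  g0 <- ar_process_variance(a_true)          # unit innovation variance
  m <- levinson_durbin(g0 * rho, 2)
  expect_equal(m$a, a_true, tolerance = 1e-8)
  expect_equal(m$sigma2, 1, tolerance = 1e-8)
})

test_that("Levinson-Durbin agrees with a generic Yule-Walker solve", {
  set.seed(42)
  for (i in 1:25) {
    p <- sample(1:12, 1)
    r <- random_pd_acov(p)
    m <- levinson_durbin(r, p)
    expect_equal(m$a, yw_solve(r, p), tolerance = 1e-8)
    expect_true(all(abs(m$k) < 1))
    expect_true(all(diff(m$sigma2_path) <= 1e-12))
  }
})

test_that("Akaike order selection behaves on noise, structure and constants", {
  set.seed(7)
  orders <- vapply(1:100, function(i)
    select_order(rnorm(300), 4, 24)$order, numeric(1))
  expect_gte(mean(orders <= 8), 0.9)
  ar2 <- vapply(1:20, function(i)
    select_order(as.numeric(
      arima.sim(list(ar = c(1.2, -0.6)), 400)), 2, 24)$order, numeric(1))
  expect_true(all(ar2 >= 2))
  flat <- select_order(rep(5, 300))
  expect_true(flat$zero_variance)
  expect_equal(flat$order, 4)
  expect_error(select_order(rnorm(40), 4, 24), "too short")
})

test_that("AR spectrum is flat for white noise and monotone for AR(1)", {
  white <- levinson_durbin(c(1), 0)
  sp <- ar_spectrum(white, fs = 2, n_freq = 512)
  expect_true(all(abs(sp$psd - 1) < 1e-12))
  expect_equal(pracma::trapz(sp$freq, sp$psd), 1, tolerance = 1e-9)
  ar1 <- structure(list(order = 1L, a = 0.9, k = 0.9,
                        sigma2 = 1, sigma2_path = c(NA, 1)),
                   class = "ar_model")
  psd <- ar_spectrum(ar1, fs = 2, n_freq = 512)$psd
  expect_true(all(diff(psd) < 0))
  bad <- structure(list(order = 1L, a = 1.05, sigma2 = 1),
                   class = "ar_model")
  expect_error(ar_spectrum(bad, 2), "unstable")
})

test_that("one-sided PSD integrates to the theoretical process variance", {
  set.seed(11)
  for (i in 1:10) {
    p <- sample(1:24, 1)
    a <- random_stable_ar(p)
    m <- structure(list(order = p, a = a, sigma2 = 1,
                        sigma2_path = rep(NA, p + 1)), class = "ar_model")
    sp <- ar_spectrum(m, fs = 5.4, n_freq = 8192)
    expect_equal(pracma::trapz(sp$freq, sp$psd), ar_process_variance(a),
                 tolerance = 0.01)
  }
})

test_that("band power integrates the PSD over the requested band", {
  flat <- list(freq = seq(0, 2.5, length.out = 1001),
               psd = rep(1, 1001))
  expect_equal(band_power(flat, c(0.2, 0.6)), 0.4, tolerance = 1e-9)
  zero <- list(freq = seq(0, 2.5, length.out = 101), psd = rep(0, 101))
  expect_equal(band_power(zero, c(0.2, 0.6)), 0)
  expect_warning(bp <- band_power(flat, c(0.6, 3.0)), "Nyquist")
  expect_equal(bp, 2.5 - 0.6, tolerance = 1e-9)
})

test_that("systogram variability recovers injected band variances", {
  w <- sim_ap_waveform(900 / 325 * 60, 500, hr_bpm = 325,
                       lf_sd_mmHg = 2, noise_sd_mmHg = 0.5, seed = 3)
  h <- summarize_hemodynamics(beat_series(w, detect_beats(w)))
  sv <- sap_variability(h)
  expect_equal(sv$lf_power, 4, tolerance = 0.15)
  expect_lt(sv$hf_power, 0.4)                       # < 10 % leakage
  # HF injection mirrors it
  w2 <- sim_ap_waveform(900 / 325 * 60, 500, hr_bpm = 325,
                        hf_sd_mmHg = 2, noise_sd_mmHg = 0.5, seed = 4)
  h2 <- summarize_hemodynamics(beat_series(w2, detect_beats(w2)))
  sv2 <- sap_variability(h2)
  expect_equal(sv2$hf_power, 4, tolerance = 0.15)
  expect_lt(sv2$lf_power, 0.4)
})

test_that("variability analysis handles constants and scales quadratically", {
  flat <- sap_variability(rep(120, 400), mean_beat_rate = 5.4)
  expect_equal(flat$variance, 0)
  expect_equal(flat$lf_power, 0)
  set.seed(9)
  x <- 120 + as.numeric(arima.sim(list(ar = 0.6), 600))
  a <- sap_variability(x, mean_beat_rate = 5.4)
  b <- sap_variability(120 + 2 * (x - 120), mean_beat_rate = 5.4)
  expect_equal(b$variance, 4 * a$variance)
  expect_equal(b$lf_power, 4 * a$lf_power, tolerance = 1e-8)
  expect_equal(b$hf_power, 4 * a$hf_power, tolerance = 1e-8)
})
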