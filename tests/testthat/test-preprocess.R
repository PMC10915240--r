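test_that("soft and hard thresholding follow their definitions", {
  expect_equal(threshold_coefficients(3.0, 1.0, "soft"), 2.0)
  expect_equal(threshold_coefficients(-0.5, 1.0, "soft"), 0.0)
  expect_equal(threshold_coefficients(-3.0, 1.0, "soft"), -2.0)
  expect_equal(threshold_coefficients(3.0, 1.0, "hard"), 3.0)
  expect_equal(threshold_coefficients(0.5, 1.0, "hard"), 0.0)
})

test_that("periodized DWT matches reference coefficients and inverts exactly", {
  # frozen reference: db4, periodization mode, x = sin(1:16) + 0.1*(1:16)
  x <- sin(1:16) + 0.1 * (1:16)
  co <- ecscbf:::wavelet_dwt(x, "db4", level = 1)
  expect_equal(co$a,
               c(2.6885576191, 1.7115173619, 0.3854585605, -0.5262534463,
                 2.0574331503, 1.6198527745, 0.1993053024, 2.645940257),
               tolerance = 1e-9)
  expect_equal(co$d,
               list(c(-0.3381569657, 0.28791415, -0.0113344138, -0.2923854049,
                      0.2546849364, 0.0804127437, -0.3683483502, 0.472993289)),
               tolerance = 1e-9)
  co2 <- ecscbf:::wavelet_dwt(x, "db4", level = 2)
  expect_equal(co2$a,
               c(1.7623542, 3.8134842434, 0.0419541954, 2.0060994426),
               tolerance = 1e-9)

  # exact reconstruction at several lengths and wavelets
  for (w in c("haar", "db2", "db4")) for (n in c(16, 64, 1200)) {
    y <- sin(seq_len(n) / 3) + cos(seq_len(n) / 7)
    cc <- ecscbf:::wavelet_dwt(y, w, level = 4)
    expect_equal(ecscbf:::wavelet_idwt(cc), y, tolerance = 1e-9)
  }
})

test_that("denoise with zero threshold is the identity", {
  tr <- generate_rf_trace(pulsation_params(seed = 3), equivalent_circuit(), 60)
  out <- wavelet_denoise(tr, rule = "manual", threshold = 0)
  expect_equal(out$values, tr$values, tolerance = 1e-9)
  # including non-dyadic lengths (padding path)
  x <- rnorm(77)
  expect_equal(wavelet_denoise(x, level = 3, rule = "manual", threshold = 0),
               x, tolerance = 1e-9)
})

test_that("wavelet denoising reduces the noise floor of a pulse signal", {
  t <- seq(0, 60, by = 1 / 20)
  clean <- sin(2 * pi * t)
  rmse <- function(a, b) sqrt(mean((a - b)^2))

  # hard thresholding keeps in-band coefficients untouched and improves the
  # reconstruction across noise levels
  for (sigma in c(0.1, 0.3, 1)) {
    set.seed(5)
    noisy <- clean + rnorm(length(t), 0, sigma)
    expect_lt(rmse(wavelet_denoise(noisy, mode = "hard"), clean),
              rmse(noisy, clean))
  }

  # soft thresholding also shrinks the signal band by the threshold, so it
  # pays off once the noise dominates the in-band coefficients
  set.seed(5)
  noisy <- clean + rnorm(length(t), 0, 1)
  expect_lt(rmse(wavelet_denoise(noisy, mode = "soft"), clean),
            rmse(noisy, clean))

  expect_error(wavelet_denoise(noisy, wavelet = "sym8"), "unknown wavelet")
  expect_error(wavelet_denoise(rnorm(8), level = 6), "too short")
})

test_that("pulse detection counts pulses and rejects ripple", {
  expect_length(detect_pulses(rep(1, 100))$peaks, 0)

  tr <- generate_rf_trace(pulsation_params(noise_sd = 0, drift_sd = 0),
                          equivalent_circuit(), 60)
  np <- length(detect_pulses(tr)$peaks)
  expect_gte(np, 59)
  expect_lte(np, 61)

  # 1 Hz tone with a faint 10 Hz ripple: refractory keeps ~60 peaks
  t <- seq(0, 60 - 0.05, by = 0.05)
  x <- sin(2 * pi * t) + 0.05 * sin(2 * pi * 10 * t)
  np2 <- length(detect_pulses(x, min_period = 0.5, fs = 20)$peaks)
  expect_gte(np2, 59)
  expect_lte(np2, 61)

  # alternating structure: troughs strictly between consecutive peaks
  p <- detect_pulses(tr)
  expect_length(p$troughs, length(p$peaks) - 1)
  expect_true(all(p$troughs > head(p$peaks, -1) & p$troughs < p$peaks[-1]))
})

test_that("pulse amplitude measures peak-to-trough excursion", {
  t <- seq(0, 30 - 0.05, by = 0.05)
  A <- 0.7
  x <- A * sin(2 * pi * t)
  pa <- pulse_amplitude(x, fs = 20)
  expect_equal(pa$amplitude, 2 * A, tolerance = 0.01)

  circ <- equivalent_circuit()
  amp_of <- function(pv) pulse_amplitude(generate_rf_trace(
    pulsation_params(pulse_volume = pv, noise_sd = 0, drift_sd = 0),
    circ, 60))$amplitude
  expect_equal(amp_of(2) / amp_of(1), 2, tolerance = 0.05)

  expect_error(pulse_amplitude(rep(5, 100)), "no pulses")
})

test_that("CRA is a signed, scale-invariant percent change", {
  expect_equal(cra(2.0, 1.0), -50.0)
  expect_equal(cra(2.0, 2.0), 0.0)
  expect_equal(cra(1.5, 3.0), 100.0)
  for (k in c(0.5, 2, 100)) expect_equal(cra(2 * k, 1 * k), cra(2, 1))
  expect_error(cra(0, 1), "positive")
  expect_error(cra(-1, 1), "positive")
})

test_that("cohort CRA recovers the programmed amplitude decay", {
  traces <- fixture_decay_cohort()
  cc <- cohort_cra(cohort_amplitudes(traces))
  post <- cc[cc$state == "post_caffeine", ]
  # closed form of the programmed decay at 30 min: 100*(exp(-0.6)-1)
  m30 <- mean(post$cra_percent[post$minute_mark == 30])
  expect_equal(m30, 100 * (exp(-0.6) - 1), tolerance = 0.15)
  # pooled rate estimate within 15% of the programmed 0.02/min
  r <- estimate_decay_rate(post$minute_mark, post$cra_percent)
  expect_equal(r, 0.02, tolerance = 0.15)
})

test_that("CRA trajectory tracks a flow-velocity trend driven by the same decay", {
  traces <- fixture_decay_cohort()
  cc <- cohort_cra(cohort_amplitudes(traces))
  post <- cc[cc$state == "post_caffeine", ]
  mean_cra <- tapply(post$cra_percent, post$minute_mark, mean)
  minutes <- as.numeric(names(mean_cra))
  vm_trend <- 60 * exp(-0.02 * minutes)   # emulated mean velocity (cm/s)
  s <- spearman_rho(vm_trend, as.numeric(mean_cra))
  expect_gt(s$rho, 0.8)
  expect_lt(s$p_value, 0.05)
})

test_that("dominant frequency finds the principal tone", {
  t <- seq(0, 60 - 0.05, by = 0.05)
  f1 <- dominant_frequency(sin(2 * pi * t), fs = 20)
  expect_equal(as.numeric(f1), 1.0)
  expect_equal(attr(f1, "resolution"), 20 / length(t))

  x <- sin(2 * pi * t) + 0.2 * sin(2 * pi * 3 * t)
  expect_equal(as.numeric(dominant_frequency(x, fs = 20)), 1.0)

  tr <- generate_rf_trace(pulsation_params(seed = 2), equivalent_circuit(), 60)
  expect_equal(as.numeric(dominant_frequency(tr)), 1.0)

  expect_error(dominant_frequency(rep(2, 50)), "no nonzero")
})

test_that("spearman correlation handles monotone, reversed and tied data", {
  expect_equal(spearman_rho(c(1, 2, 3), c(10, 20, 30))$rho, 1.0)
  expect_equal(spearman_rho(c(1, 2, 3), c(30, 20, 10))$rho, -1.0)

  # tie case against the average-rank formula computed by hand:
  # ranks of (1,1,3,4) are (1.5, 1.5, 3, 4); Pearson on ranks
  rho_hand <- cor(c(1, 2, 3, 4), c(1.5, 1.5, 3, 4))
  s <- spearman_rho(c(1, 2, 3, 4), c(1, 1, 3, 4))
  expect_equal(s$rho, rho_hand)
  expect_identical(s$method, "exact permutation")

  # t-approximation branch agrees with cor(..., method = "spearman")
  set.seed(9)
  x <- rnorm(30)
  y <- x + rnorm(30)
  s2 <- spearman_rho(x, y)
  expect_equal(s2$rho, cor(x, y, method = "spearman"))
  expect_identical(s2$method, "t-approximation")
  expect_lt(s2$p_value, 0.01)

  expect_error(spearman_rho(1:3, 1:4), "length mismatch")
})
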