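sine_trials <- function(freq, fs = 128, n_s = 256, n_tr = 20, amp = 1,
                        phase = NULL, seed = 1) {
  set.seed(seed)
  t <- (seq_len(n_s) - 1) / fs
  sapply(seq_len(n_tr), function(i) {
    ph <- if (is.null(phase)) runif(1, 0, 2 * pi) else phase
    amp * sin(2 * pi * freq * t + ph)
  })
}

test_that("the default frequency grid spans 3-256 Hz in 100 steps", {
  f <- tf_freqs()
  expect_length(f, 100)
  expect_equal(f[1], 3)
  expect_equal(f[100], 256)
  expect_true(all(diff(f) > 0))
  expect_true(all(tf_freqs(truncate = 45) <= 45))
})

test_that("wavelet magnitude peaks at the stimulus frequency", {
  # octave-spaced probe grid: the 185 ms window cannot resolve finer
  # spacing than a few Hz, so 3 dB selectivity is asserted per octave
  fs <- 128
  freqs <- c(3, 6, 12, 24, 48)
  f0 <- 12
  x <- sine_trials(f0, fs, 256, 5)
  co <- morlet_coeffs(x, fs, freqs)
  prof <- rowMeans(apply(abs(unclass(co)), c(1, 2), mean))
  pk <- which.max(prof)
  expect_equal(attr(co, "freqs")[pk], f0)
  expect_gt(20 * log10(prof[pk] / prof[pk - 1]), 3)
  expect_gt(20 * log10(prof[pk] / prof[pk + 1]), 3)

  # linearity: scaling the input scales the coefficients
  co3 <- morlet_coeffs(3 * x, fs, freqs)
  expect_equal(abs(unclass(co3)), 3 * abs(unclass(co)), tolerance = 1e-10)

  # amplitude normalization: |coeff| ~ amplitude of the sinusoid
  expect_lt(abs(prof[pk] - 1), 0.1)
})

test_that("wavelet windows stay within the 185 ms cap", {
  fs <- 512
  x <- matrix(rnorm(1024 * 2), 1024, 2)
  co <- morlet_coeffs(x, fs, tf_freqs(20, 3, 45), t0_ms = -1000)
  times <- attr(co, "times")
  # full support: trimmed by at most half the 185 ms cap plus a sample
  expect_lte(times[1] - (-1000), 185 / 2 + 1000 / fs)
  # above 64.9 Hz the 12-cycle rule is the binding cap
  w <- p3source:::wavelet_window(c(3, 10, 64, 100, 256), list(kind = "cap"))
  expect_true(all(w <= 0.185 + 1e-12))
  expect_equal(w[5], 12 / 256)
})

test_that("ersp converts amplitude ratios to the exact dB values", {
  fs <- 128
  t <- (seq_len(384) - 1) / fs - 1       # epoch -1000..2000 ms
  n_tr <- 30
  set.seed(4)
  mk <- function(gain) sapply(seq_len(n_tr), function(i) {
    ph <- runif(1, 0, 2 * pi)
    a <- ifelse(t >= 0.25 & t <= 2, gain, 1)
    a * sin(2 * pi * 10 * t + ph)
  })
  co2 <- morlet_coeffs(mk(2), fs, tf_freqs(20, 4, 30), t0_ms = -1000)
  e2 <- ersp(co2, baseline_window = c(-800, -200))
  fi <- which.min(abs(attr(co2, "freqs") - 10))
  ti <- which(attr(co2, "times") >= 800 & attr(co2, "times") <= 1500)
  expect_equal(mean(e2[fi, ti]), 10 * log10(4), tolerance = 0.1)

  coh <- morlet_coeffs(mk(0.5), fs, tf_freqs(20, 4, 30), t0_ms = -1000)
  eh <- ersp(coh, baseline_window = c(-800, -200))
  expect_equal(mean(eh[fi, ti]), -10 * log10(4), tolerance = 0.1)

  expect_error(ersp(co2, baseline_window = c(-5000, -4000)), "baseline")
})

test_that("ersp of a stationary process stays within sampling noise", {
  fs <- 128
  set.seed(9)
  # mean-power sampling noise shrinks as 1/sqrt(trials): at 1000 trials
  # the everywhere-bound of 0.5 dB corresponds to ~3.5 sigma
  x <- matrix(rnorm(256 * 1000), 256, 1000)
  co <- morlet_coeffs(x, fs, tf_freqs(15, 4, 40), t0_ms = -1000)
  e <- ersp(co, baseline_window = c(-900, -100))
  expect_lt(max(abs(e)), 0.5)
})

test_that("itc is exact for identical trials and calibrated under the null", {
  fs <- 128
  x1 <- sine_trials(8, fs, 256, 10, phase = 0.3)
  co1 <- morlet_coeffs(x1, fs, tf_freqs(10, 4, 20))
  expect_lt(max(abs(itc(co1) - 1)), 1e-10)

  # uniform phases: compare the mean ITC at the stimulus frequency with
  # a Monte-Carlo estimate of the expected resultant length at n trials
  n_tr <- 200
  x2 <- sine_trials(8, fs, 256, n_tr, seed = 11)
  co2 <- morlet_coeffs(x2, fs, tf_freqs(10, 4, 20))
  z2 <- itc(co2)
  fi <- which.min(abs(attr(co2, "freqs") - 8))

  set.seed(12)
  draws <- replicate(1e4, abs(mean(exp(2i * pi * runif(n_tr)))))
  null_mean <- mean(draws); null_sd <- sd(draws)
  expect_lt(abs(mean(z2[fi, ]) - null_mean), 3 * null_sd)

  # amplitude rescaling per trial leaves ITC unchanged
  gains <- runif(n_tr, 0.5, 5)
  co3 <- morlet_coeffs(sweep(x2, 2, gains, `*`), fs, tf_freqs(10, 4, 20))
  expect_equal(itc(co3), z2, tolerance = 1e-10)

  expect_error(itc(morlet_coeffs(x2[, 1], fs, tf_freqs(10, 4, 20))), "2 trials")
})

test_that("trial order does not matter for either measure", {
  fs <- 128
  set.seed(5)
  x <- sine_trials(6, fs, 256, 40) + matrix(rnorm(256 * 40, 0, 0.3), 256)
  co <- morlet_coeffs(x, fs, tf_freqs(12, 4, 20), t0_ms = -1000)
  cos <- morlet_coeffs(x[, sample(40)], fs, tf_freqs(12, 4, 20), t0_ms = -1000)
  expect_equal(ersp(co, c(-900, -500)), ersp(cos, c(-900, -500)),
               tolerance = 1e-10)
  expect_equal(itc(co), itc(cos), tolerance = 1e-10)
})

test_that("unusable frequencies are dropped with a warning", {
  fs <- 64
  x <- matrix(rnorm(128 * 3), 128, 3)
  expect_warning(co <- morlet_coeffs(x, fs, tf_freqs(20, 3, 100)), "dropping")
  expect_true(all(attr(co, "freqs") < 32))
})

test_that("band summaries aggregate the conventional bands", {
  co <- quick_cohort()
  sim <- simulate_cohort(co, theta_source())$subjects[[1]]
  ep <- epoch_simulated(sim, co)
  tf <- time_frequency(ep$data[1, , ], co$sampling_rate,
                       freqs = tf_freqs(20, 3, 45), t0_ms = -500)
  bs <- band_summary(tf)
  expect_setequal(unique(bs$band), c("theta", "alpha", "beta"))
  expect_equal(sum(bs$band == "theta"), length(tf$times))
})
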