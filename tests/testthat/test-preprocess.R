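test_that("bandpass and notch filtering meet their attenuation contracts", {
  fs <- 256
  t <- seq(0, 8, by = 1 / fs)[-1]
  rms <- function(x) sqrt(mean(x^2))

  s50 <- sin(2 * pi * 50 * t)
  expect_lt(rms(bandpass_notch(s50, fs, 1, 95, c(50, 60))), 0.1 * rms(s50))

  s10 <- sin(2 * pi * 10 * t)
  out10 <- bandpass_notch(s10, fs, 1, 95, c(50, 60))
  mid <- seq(fs, length(t) - fs)   # ignore filter edges
  expect_lt(abs(rms(out10[mid]) - rms(s10[mid])) / rms(s10[mid]), 0.05)

  # spectral contract on white noise: >= 20 dB down at 0.5 Hz vs 10 Hz
  set.seed(1)
  wn <- rnorm(fs * 60)
  fw <- bandpass_notch(wn, fs, 1, 95, numeric())
  pg <- function(x, f) {
    sp <- Mod(fft(x))^2
    fr <- (seq_along(x) - 1) / length(x) * fs
    mean(sp[fr > f - 0.2 & fr < f + 0.2])
  }
  expect_gt(10 * log10(pg(fw, 10) / pg(fw, 0.5)), 20)

  expect_error(bandpass_notch(s10, fs, 1, 200), "Nyquist")
  expect_warning(bandpass_notch(s10, fs, 1, 95, notches = 130), "skipped")
})

test_that("average referencing zeroes the channel mean per sample", {
  x <- matrix(rnorm(5 * 100), 5, 100)
  xr <- average_reference(x)
  expect_lt(max(abs(colSums(xr))), 1e-10 * max(abs(x)))

  const <- matrix(7, 4, 50)
  expect_equal(average_reference(const), matrix(0, 4, 50))

  already <- sweep(x, 2, colMeans(x))
  expect_equal(average_reference(already), already, tolerance = 1e-12)

  # referencing a channel subset leaves the rest untouched
  xr2 <- average_reference(x, channels = 1:3)
  expect_equal(xr2[4:5, ], x[4:5, ])
  expect_lt(max(abs(colSums(xr2[1:3, ]))), 1e-10 * max(abs(x)))
})

test_that("epoching yields the printed sample count and drops edge events", {
  fs <- 512
  nch <- 3
  cont <- matrix(rnorm(nch * fs * 30), nch)
  events <- data.frame(latency_s = c(0, 2, 5, 8, 29.9),
                       label = c("target", "nontarget", "target",
                                 "nontarget", "target"))
  expect_message(
    ep <- epoch_and_baseline(cont, fs, events),
    "dropped 2")
  expect_equal(dim(ep$data)[2], 768)     # (-500, 1000) ms at 512 Hz
  expect_equal(dim(ep$data)[3], 3)
  expect_equal(ep$dropped_events, c(1L, 5L))

  # per-trial baseline means are zero
  times <- epoch_times(ep)
  bidx <- which(times >= -200 & times < 0)
  bmeans <- apply(ep$data[, bidx, , drop = FALSE], c(1, 3), mean)
  expect_lt(max(abs(bmeans)), 1e-12)

  # a constant channel baselines to exactly zero
  cont2 <- matrix(5, 1, fs * 10)
  ep2 <- epoch_and_baseline(cont2, fs, data.frame(latency_s = 4, label = "target"))
  expect_equal(max(abs(ep2$data)), 0)
})

test_that("statistical rejection removes exactly the constructed outlier", {
  set.seed(2)
  dat <- array(rnorm(4 * 64 * 50), c(4, 64, 50))
  dat[, , 17] <- dat[, , 17] * 10
  ep <- epoched_eeg(dat, 128, c(-100, 400))
  out <- reject_epochs(ep, 3)
  expect_equal(out$rejected_trials, 17L)
  expect_equal(dim(out$data)[3], 49)

  # identical trials: degenerate z maps to zero, nothing rejected
  same <- array(rep(rnorm(4 * 64), 10), c(4, 64, 10))
  eps <- epoched_eeg(same, 128, c(-100, 400))
  expect_equal(length(reject_epochs(eps, 3)$rejected_trials), 0)

  # infinite threshold never rejects
  expect_equal(length(reject_epochs(ep, Inf)$rejected_trials), 0)

  expect_error(reject_epochs(epoched_eeg(dat[, , 1:2, drop = FALSE], 128,
                                         c(-100, 400)), 3),
               "at least 3")
})

test_that("spherical-spline interpolation restores smooth dipolar maps", {
  m <- default_model
  mon <- small_sensors(24)
  # time-varying dipolar field: the moment rotates over the epoch so
  # every channel carries a smooth, non-constant time course
  G <- forward_gain(c(15, -25, 30), mon, m)
  ph <- seq(0, 2 * pi, length.out = 48)
  mom <- rbind(10 * cos(ph), -20 * sin(ph), 25 * cos(2 * ph))
  dat <- array(G %*% mom, c(24, 16, 3))
  ep <- epoched_eeg(dat, 128, c(0, 125), montage = mon)

  broken <- ep
  bad <- "C05"
  bi <- match(bad, mon$labels)
  broken$data[bi, , ] <- 0
  fixed <- interpolate_channels(broken, bad)
  expect_equal(fixed$interpolated_channels, bad)
  expect_gt(cor(as.numeric(fixed$data[bi, , ]), as.numeric(ep$data[bi, , ])), 0.95)

  # interpolating an intact channel barely changes it
  refix <- interpolate_channels(ep, "C07")
  ci <- match("C07", mon$labels)
  expect_gt(cor(as.numeric(refix$data[ci, , ]), as.numeric(ep$data[ci, , ])), 0.99)

  expect_identical(interpolate_channels(ep, character()), ep)
  expect_error(interpolate_channels(ep, mon$labels[1:6]), "25%")
  expect_error(interpolate_channels(ep, "nope"), "unknown")
})

test_that("preprocessing is idempotent on its own output", {
  # clean data: every stage's second application is a no-op
  set.seed(21)
  dat <- array(rnorm(6 * 64 * 30), c(6, 64, 30))
  ep <- epoched_eeg(average_reference(dat), 128, c(-100, 400),
                    baseline_window = c(-100, 0))
  ep1 <- reject_epochs(ep, 3.5)
  ep2 <- reject_epochs(ep1, 3.5)
  expect_identical(ep2$data, ep1$data)
  expect_equal(average_reference(ep1$data), ep1$data, tolerance = 1e-12)
})
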