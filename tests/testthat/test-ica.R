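laplacian_mix <- function(k = 3, n = 2e4, seed = 1) {
  set.seed(seed)
  S <- matrix(sample(c(-1, 1), k * n, TRUE) * rexp(k * n), k, n)
  A <- matrix(rnorm(k * k), k, k)
  list(S = S, A = A, X = A %*% S)
}

test_that("sphering yields identity covariance and detects rank", {
  set.seed(3)
  x <- matrix(rnorm(8 * 1e5), 8)
  sph <- sphere_data(x)
  cv <- tcrossprod(sph$data) / (ncol(x) - 1)
  expect_lt(max(abs(cv - diag(8))), 1e-6)
  # white input: symmetric whitening is close to the identity;
  # off-diagonal elements scale as 1/(2 sqrt(n)), so bound at ~5 SD
  expect_lt(max(abs(sph$sphering - diag(diag(sph$sphering)))),
            5 / (2 * sqrt(1e5)))

  # average-referenced data lose one dimension
  xr <- average_reference(matrix(rnorm(12 * 5000), 12))
  expect_message(sphr <- sphere_data(xr), "rank-deficient")
  expect_equal(sphr$rank, 11)

  expect_error(sphere_data(matrix(rnorm(20), 5, 4)), "more samples")
})

test_that("infomax recovers a Laplacian mixture to low Amari index", {
  mx <- laplacian_mix(seed = 1)
  sph <- sphere_data(mx$X)
  im <- infomax(sph, seed = 3)
  expect_true(im$converged)
  W <- im$W %*% sph$sphering
  expect_lt(amari_index(W, mx$A), 0.05)

  # already independent input: a fixed point up to permutation/sign
  sph2 <- sphere_data(mx$S)
  im2 <- infomax(sph2, seed = 4)
  expect_lt(amari_index(im2$W %*% sph2$sphering, diag(3)), 0.05)

  # identical seeds, identical weights
  im3 <- infomax(sph, seed = 3)
  expect_identical(im$W, im3$W)
})

test_that("decomposition reconstructs the input and normalizes maps", {
  co <- quick_cohort(n_channels = 10, n_eog = 0, n_trials = 40)
  sim <- simulate_cohort(co, theta_source())$subjects[[1]]
  ep <- epoch_simulated(sim, co)
  dec <- suppressMessages(ica_decompose(ep, seed = 2))

  dm <- dim(ep$data)
  x <- matrix(ep$data[dec$channels, , ], length(dec$channels), dm[2] * dm[3])
  recon <- dec$mixing %*% dec$activations + dec$center
  expect_lt(max(abs(recon - x)) / max(abs(x)), 1e-6)

  # u = W x on the analyzed channels
  act2 <- dec$unmixing %*% (x - dec$center)
  expect_lt(max(abs(act2 - dec$activations)) / max(abs(dec$activations)), 1e-8)

  norms <- sqrt(colSums(dec$scalp_maps^2))
  expect_equal(unname(norms), rep(1, ncol(dec$scalp_maps)), tolerance = 1e-10)
  peak_sign <- apply(dec$scalp_maps, 2, function(m) sign(m[which.max(abs(m))]))
  expect_true(all(peak_sign > 0))
})

test_that("blink components are flagged and their removal cleans the EOG", {
  hits <- 0L
  for (seed in 1:3) {
    fx <- blink_fixture(seed)
    dec <- suppressMessages(
      ica_decompose(fx$epochs, channels = seq_along(fx$sim$montage$labels),
                    seed = 2))
    flags <- flag_artifact_ics(dec, fx$epochs)
    expect_gt(length(flags), 0)
    cleaned <- remove_ics(dec, flags, fx$epochs)
    eidx <- match(fx$sim$montage$eog_channels, fx$sim$montage$labels)
    v0 <- sum(apply(fx$epochs$data[eidx, , ], 1, var))
    v1 <- sum(apply(cleaned$data[eidx, , ], 1, var))
    if (1 - v1 / v0 >= 0.8) hits <- hits + 1L
  }
  expect_equal(hits, 3L)
})

test_that("flagging stays quiet on artifact-free data", {
  co <- quick_cohort(n_channels = 16, n_trials = 80, blink_rate = 0)
  false_flags <- integer(0)
  for (seed in 1:3) {
    sim <- simulate_subject(theta_source(db = 3, pl = 0.5), co,
                            generate_paradigm(co$n_trials, co$p_target, seed),
                            seed = seed)
    ep <- epoch_simulated(sim, co, "S01")
    dec <- suppressMessages(
      ica_decompose(ep, channels = seq_along(sim$montage$labels), seed = 2))
    false_flags <- c(false_flags, length(flag_artifact_ics(dec, ep)))
  }
  # z = 3 tail across ~15 components: a stray flag or two, not a purge
  expect_lte(mean(false_flags), 2)

  # infinite thresholds flag nothing
  fx <- blink_fixture(1)
  dec <- suppressMessages(
    ica_decompose(fx$epochs, channels = seq_along(fx$sim$montage$labels),
                  seed = 2))
  expect_length(flag_artifact_ics(dec, fx$epochs, z_general = Inf, z_eog = Inf), 0)
})

test_that("component removal is exact at the boundaries", {
  co <- quick_cohort(n_channels = 8, n_eog = 0, n_trials = 30)
  sim <- simulate_cohort(co, theta_source())$subjects[[1]]
  ep <- epoch_simulated(sim, co)
  dec <- suppressMessages(ica_decompose(ep, seed = 2))

  none <- remove_ics(dec, integer(), ep)
  expect_lt(max(abs(none$data[dec$channels, , ] - ep$data[dec$channels, , ])) /
              max(abs(ep$data)), 1e-6)

  k <- nrow(dec$unmixing)
  one <- remove_ics(dec, seq_len(k)[-1], ep)
  flat <- matrix(one$data[dec$channels, , ], length(dec$channels))
  expect_equal(qr(sweep(flat, 1, rowMeans(flat)))$rank, 1)

  expect_error(remove_ics(dec, seq_len(k), ep), "all components")
})

test_that("a missing EOG montage downgrades gracefully", {
  co <- quick_cohort(n_channels = 10, n_eog = 0, n_trials = 30)
  sim <- simulate_cohort(co, theta_source())$subjects[[1]]
  ep <- epoch_simulated(sim, co)
  dec <- suppressMessages(ica_decompose(ep, seed = 2))
  expect_warning(flag_artifact_ics(dec, ep), "no EOG")
})
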