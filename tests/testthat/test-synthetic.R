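test_that("oddball sequences have exact composition and no target runs", {
  ev <- generate_paradigm(205, 0.2, seed = 3)
  expect_length(ev, 205)
  expect_equal(sum(ev == "target"), 41)
  expect_equal(sum(ev == "nontarget"), 164)
  expect_false(any(ev[-1] == "target" & head(ev, -1) == "target"))

  # forced count at tiny n, across seeds
  for (s in 1:10) {
    expect_equal(sum(generate_paradigm(5, 0.2, s) == "target"), 1)
  }

  expect_identical(generate_paradigm(205, 0.2, 9), generate_paradigm(205, 0.2, 9))
  expect_error(generate_paradigm(100, 1.2, 1), "p_target")
  expect_error(generate_paradigm(100, 0, 1), "p_target")
})

test_that("noiseless evoked mixing is exactly rank one", {
  co <- quick_cohort(noise_sd = 0)
  src <- list(p3 = source_spec("p3", dipole(c(0, -42, 40), c(0, -30, 35)),
                               kind = "evoked", latency_window = c(250, 500),
                               condition = "target", amplitude = 2))
  ev <- generate_paradigm(co$n_trials, co$p_target, 4)
  sim <- simulate_subject(src, co, ev, seed = 4)
  ep <- epoch_and_baseline(sim$continuous, co$sampling_rate, sim$events,
                           co$epoch_window, co$baseline_window,
                           montage = sim$montage)
  erp <- apply(ep$data[, , ep$trial_labels == "target"], c(1, 2), mean)
  map <- as.numeric(sim$truth$p3$map)
  ref <- which.max(abs(map))
  recon <- outer(map, erp[ref, ] / map[ref])
  expect_lt(max(abs(erp - recon)) / max(abs(erp)), 1e-10)
})

test_that("planted spectral effects are recovered by the TF module", {
  co <- quick_cohort(n_trials = 500, noise_sd = 0)
  ev <- generate_paradigm(500, 0.2, 3)

  # +3 dB theta ERS within 0.5 dB at 500 trials
  sim <- simulate_subject(theta_source(db = 3, pl = 0), co, ev, seed = 5)
  ep <- epoch_simulated(sim, co)
  ch <- which.max(abs(sim$truth$theta$map[seq_len(co$n_channels)]))
  tf <- time_frequency(ep$data[ch, , ep$trial_labels == "target"],
                       co$sampling_rate, freqs = tf_freqs(30, 3, 45),
                       t0_ms = co$epoch_window[1])
  fi <- which.min(abs(tf$freqs - 6))
  ti <- which(tf$times >= 300 & tf$times <= 400)
  expect_lt(abs(mean(tf$ersp[fi, ti]) - 3), 0.5)

  # full phase locking saturates the ITC at the source frequency
  sim2 <- simulate_subject(theta_source(db = 3, pl = 1), co, ev, seed = 6)
  ep2 <- epoch_simulated(sim2, co)
  tf2 <- time_frequency(ep2$data[ch, , ep2$trial_labels == "target"],
                        co$sampling_rate, freqs = tf_freqs(30, 3, 45),
                        t0_ms = co$epoch_window[1])
  expect_gt(max(tf2$itc[fi, ti]), 0.95)

  # half phase locking gives ITC near 0.5
  sim3 <- simulate_subject(theta_source(db = 3, pl = 0.5), co, ev, seed = 7)
  ep3 <- epoch_simulated(sim3, co)
  tf3 <- time_frequency(ep3$data[ch, , ep3$trial_labels == "target"],
                        co$sampling_rate, freqs = tf_freqs(30, 3, 45),
                        t0_ms = co$epoch_window[1])
  expect_lt(abs(max(tf3$itc[fi, ti]) - 0.5), 0.05)
})

test_that("cohort generation is reproducible and honors group structure", {
  co <- quick_cohort(n_per_group = c(1, 1))
  sim1 <- simulate_cohort(co, theta_source())
  sim2 <- simulate_cohort(co, theta_source())
  expect_length(sim1$subjects, 2)
  expect_identical(sim1$subjects[[1]]$continuous, sim2$subjects[[1]]$continuous)
  expect_identical(sim1$subjects[[2]]$continuous, sim2$subjects[[2]]$continuous)
  expect_equal(vapply(sim1$subjects, `[[`, 0, "group"), c(1, 2))

  # group-2 offsets reach the ground truth; group 1 untouched
  co2 <- quick_cohort(n_per_group = c(1, 1), group_effect = c(theta = -2))
  sim3 <- simulate_cohort(co2, theta_source(db = 3))
  expect_equal(sim3$ground_truth[[1]]$sources$theta$band_power_change, 3)
  expect_equal(sim3$ground_truth[[2]]$sources$theta$band_power_change, 1)

  # dipole jitter differs between subjects but stays inside the brain
  co3 <- quick_cohort(n_per_group = c(2, 2), jitter_sd = 5)
  sim4 <- simulate_cohort(co3, theta_source())
  pos <- t(vapply(sim4$ground_truth, function(g) g$sources$theta$dipole$position,
                  numeric(3)))
  expect_gt(max(dist(pos)), 0)
  expect_true(all(is_inside_brain(pos, default_model)))
})

test_that("invalid source windows are rejected", {
  co <- quick_cohort()
  src <- theta_source(window = c(200, 1200))
  ev <- generate_paradigm(co$n_trials, co$p_target, 1)
  expect_error(simulate_subject(src, co, ev, 1), "latency window")
})

test_that("cohort sidecars are written as events TSV plus truth JSON", {
  co <- quick_cohort(n_per_group = c(1, 1))
  sim <- simulate_cohort(co, theta_source())
  dir <- withr::local_tempdir()
  write_cohort_sidecars(sim, dir)
  ev <- read.table(file.path(dir, "S01_events.tsv"), header = TRUE, sep = "\t")
  expect_equal(nrow(ev), co$n_trials)
  expect_named(ev, c("trial_index", "latency_s", "label"))
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"))
  expect_length(gt, 2)
  expect_equal(gt[[2]]$group, 2)
})
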