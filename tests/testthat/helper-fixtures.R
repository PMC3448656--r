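# Shared fixtures, built in code at test time.

default_model <- head_model()

small_sensors <- function(n = 32, model = default_model) {
  project_to_scalp(make_montage(n, 0), model)
}

# quick-to-simulate cohort: fewer trials/channels than the study
# defaults, used where the test subject only needs to exist
quick_cohort <- function(...) {
  args <- utils::modifyList(
    list(n_per_group = c(2, 2), n_channels = 16, n_eog = 2,
         n_trials = 60, noise_sd = 1, blink_rate = 0, jitter_sd = 0,
         seed = 7L),
    list(...))
  do.call(cohort_spec, args)
}

# one oscillatory source with controllable ERSP/ITC signature
theta_source <- function(db = 3, pl = 0, window = c(200, 500),
                         condition = "target") {
  list(theta = source_spec("theta", dipole(c(0, -42, 40), c(0, -30, 35)),
                           kind = "oscillatory-ers", center_freq = 6,
                           band_power_change = db, phase_locking = pl,
                           latency_window = window, condition = condition))
}

# blink-dominated subject for artifact-flagging tests: frequent, large
# blinks so the ocular component carries most EOG variance
blink_fixture <- function(seed = 1L) {
  co <- quick_cohort(n_channels = 16, n_trials = 80, noise_sd = 1,
                     blink_rate = 25, seed = seed)
  src <- theta_source(db = 3, pl = 0.5)
  src$blink <- source_spec("blink", dipole(c(0, 58, -12), c(0, 35, 60)),
                           kind = "blink", amplitude = 200,
                           latency_window = c(0, 300), condition = "both")
  ev <- generate_paradigm(co$n_trials, co$p_target, seed)
  sim <- simulate_subject(src, co, ev, seed = seed)
  ep <- epoch_simulated(sim, co, "S01")
  list(sim = sim, epochs = ep, cohort = co)
}

# adjusted Rand index against an independent implementation is checked
# in the clustering tests; this plain-count version is the local oracle
rand_index_adjusted <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}
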