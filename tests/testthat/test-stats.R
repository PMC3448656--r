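mk_maps <- function(n, f = 6, t = 8, mean = 0, sd = 1, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) matrix(rnorm(f * t, mean, sd), f, t))
}

test_that("subject-level maps average within subject and split by group", {
  M <- matrix(1:12, 3)
  recs <- list(
    ic_record("S01", 1, 1, rnorm(4), dipole(c(0, 0, 30)), ersp = M),
    ic_record("S01", 1, 2, rnorm(4), dipole(c(0, 0, 30)), ersp = -M),
    ic_record("S02", 1, 1, rnorm(4), dipole(c(0, 0, 30)), ersp = M),
    ic_record("S03", 2, 1, rnorm(4), dipole(c(0, 0, 30)), ersp = 2 * M))
  out <- subject_level_maps(recs, "ersp")
  expect_equal(out$groups[["1"]]$S01, M * 0)          # M and -M cancel
  expect_equal(out$groups[["1"]]$S02, M)              # pass-through
  expect_equal(out$groups[["2"]]$S03, 2 * M)

  solo <- recs[1:2]
  expect_error(subject_level_maps(solo, "ersp"), "group comparison")
  expect_error(subject_level_maps(list(), "ersp"), "empty")
})

test_that("permutation p-values are exact at the degenerate boundary", {
  const <- lapply(1:4, function(i) matrix(3, 4, 5))
  pt <- permutation_test(const[1:2], const[3:4], n_perm = 200, seed = 1)
  expect_true(all(pt$pmap == 1))
  expect_true(all(pt$pmap > 0))

  a <- mk_maps(5, seed = 2); b <- mk_maps(5, mean = 1, seed = 3)
  p1 <- permutation_test(a, b, n_perm = 300, seed = 7)
  p2 <- permutation_test(a, b, n_perm = 300, seed = 7)
  expect_identical(p1$pmap, p2$pmap)

  # common rescaling of both groups leaves t and p unchanged
  p3 <- permutation_test(lapply(a, `*`, 4.2), lapply(b, `*`, 4.2),
                         n_perm = 300, seed = 7)
  expect_equal(p3$tmap, p1$tmap, tolerance = 1e-12)
  expect_identical(p3$pmap, p1$pmap)

  expect_warning(permutation_test(a, b, n_perm = 50, seed = 1), "coarse")
})

test_that("permutation type-I error is calibrated at the nominal level", {
  # both groups drawn from the same null; pixelwise rejection rate at
  # alpha = 0.05 must sit in the calibration band
  reps <- 300
  hits <- 0; total <- 0
  for (r in seq_len(reps)) {
    a <- mk_maps(6, f = 5, t = 6, seed = 1000 + r)
    b <- mk_maps(6, f = 5, t = 6, seed = 5000 + r)
    pt <- permutation_test(a, b, n_perm = 199, seed = r)
    hits <- hits + sum(pt$pmap <= 0.05)
    total <- total + length(pt$pmap)
  }
  rate <- hits / total
  expect_gt(rate, 0.03)
  expect_lt(rate, 0.07)
})

test_that("the BH mask matches an exhaustive step-up oracle", {
  bh_oracle <- function(p, q) {
    m <- length(p)
    ord <- order(p)
    passed <- which(p[ord] <= q * seq_len(m) / m)
    out <- rep(FALSE, m)
    if (length(passed)) out[ord[seq_len(max(passed))]] <- TRUE
    out
  }
  p <- c(0.001, 0.01, 0.02, 0.9)
  expect_equal(fdr_mask(p, 0.05), c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(fdr_mask(p, 0.05), bh_oracle(p, 0.05))

  expect_false(any(fdr_mask(rep(1, 20), 0.05)))

  set.seed(3)
  for (i in 1:50) {
    pv <- runif(40)^sample(c(1, 2, 3), 1)
    expect_equal(as.vector(fdr_mask(pv, 0.1)), bh_oracle(pv, 0.1))
  }

  pm <- matrix(runif(12), 3)
  expect_equal(dim(fdr_mask(pm, 0.05)), dim(pm))
  expect_error(fdr_mask(pm, 1.2))
})

test_that("BH controls the realized false discovery proportion", {
  set.seed(11)
  m <- 100; reps <- 1000; q <- 0.05
  fdp <- replicate(reps, {
    p <- runif(m)                     # global null: every rejection false
    r <- sum(fdr_mask(p, q))
    if (r == 0) 0 else 1              # V/R is 1 whenever R > 0 under the null
  })
  expect_lte(mean(fdp), q + 2 * sqrt(q * (1 - q) / reps))
})

test_that("bonferroni cutoffs reproduce the printed thresholds", {
  expect_equal(bonferroni_cutoff(0.05, 4), 0.0125)
  expect_equal(bonferroni_cutoff(0.05, 5), 0.01)
  expect_equal(bonferroni_cutoff(0.05, 1), 0.05)
  expect_error(bonferroni_cutoff(0.05, 0))
})

test_that("the two-level mask requires both FDR and the cluster cutoff", {
  pm <- matrix(c(0.001, 0.004, 0.02, 0.8), 2)
  perm <- list(tmap = matrix(0, 2, 2), pmap = pm, n_permutations = 999,
               seed = 1)
  m1 <- stat_mask(perm, q = 0.05, cutoff = 0.0125)
  expect_equal(m1$sig, fdr_mask(pm, 0.05) & pm <= 0.0125)
  expect_equal(m1$cutoff_used, 0.0125)

  ss <- significance_summary(m1, freqs = c(5, 10), times = c(250, 350))
  expect_equal(ss$n_significant[ss$band == "theta"], sum(m1$sig[1, ]))
})
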