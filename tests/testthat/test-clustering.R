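fake_record <- function(subject, ic, pos, ori = c(0, 0, 1), seed = 1,
                        profile = 0) {
  set.seed(seed)
  # populations carry distinct activity signatures: the profile offset
  # shifts every non-dipole measure by population
  ic_record(subject_id = subject, group = 1L, ic_index = ic,
            scalp_map = rnorm(16) + 3 * profile,
            dip = dipole(pos, 30 * ori, rv = 0.02),
            spectrum = rnorm(12) + 3 * profile, erp = rnorm(20) + 3 * profile,
            ersp = matrix(rnorm(30), 5) + 3 * profile,
            itc = matrix(runif(30), 5))
}

blob_records <- function(centers, n_each = 8, sd = 2, seed = 3) {
  set.seed(seed)
  out <- list(); truth <- integer(0); i <- 0
  for (b in seq_len(nrow(centers))) {
    for (j in seq_len(n_each)) {
      i <- i + 1
      out[[i]] <- fake_record(sprintf("S%02d", j), i,
                              centers[b, ] + rnorm(3, 0, sd),
                              seed = i, profile = b)
      truth <- c(truth, b)
    }
  }
  list(records = out, truth = truth)
}

test_that("feature weighting makes the dipole block dominant", {
  br <- blob_records(rbind(c(0, -40, 40), c(0, 40, 40), c(-40, 0, 30)))
  f <- build_features(br$records, pca_dims = 5)
  blocks <- attr(f, "blocks")
  bvar <- vapply(blocks, function(ix) sum(apply(unclass(f)[, ix, drop = FALSE],
                                                2, var)), 0)
  expect_true(all(bvar["dipole"] >= bvar[names(bvar) != "dipole"]))

  # weights zero except dipole: distances reduce to weighted z-scored
  # dipole distances
  f0 <- build_features(br$records, pca_dims = 5,
                       weights = c(dipole = 10, scalp_map = 0, spectrum = 0,
                                   erp = 0, ersp = 0, itc = 0))
  dip <- t(vapply(br$records, function(r)
    c(r$dipole$position, p3source:::dipole_orientation(r$dipole)), numeric(6)))
  dz <- apply(dip, 2, function(v) (v - mean(v)) / ifelse(sd(v) > 0, sd(v), 1))
  expect_equal(cor(as.numeric(dist(unclass(f0)[, attr(f0, "blocks")$dipole])),
                   as.numeric(dist(dz * 10)), method = "spearman"), 1)

  # duplicated records map to identical feature rows
  dup <- c(br$records, br$records[1])
  fd <- build_features(dup, pca_dims = 5)
  expect_equal(unclass(fd)[1, ], unclass(fd)[length(dup), ], tolerance = 1e-10)
})

test_that("k-means separates blobs perfectly and deterministically", {
  br <- blob_records(rbind(c(0, -40, 40), c(0, 40, 40), c(-40, 0, 30)))
  f <- build_features(br$records, pca_dims = 5)
  km <- kmeans_cluster(f, 3, seed = 5)
  expect_equal(rand_index_adjusted(km$assignments, br$truth), 1.0)
  # local ARI oracle agrees with an independent implementation
  expect_equal(rand_index_adjusted(km$assignments, br$truth),
               mclust::adjustedRandIndex(km$assignments, br$truth))

  km2 <- kmeans_cluster(f, 3, seed = 5)
  expect_identical(km$assignments, km2$assignments)

  one <- kmeans_cluster(f, 1, seed = 5)
  expect_true(all(one$assignments == 1))

  expect_error(kmeans_cluster(f, nrow(f), 1), "smaller")
})

test_that("cluster membership is invariant to record input order", {
  br <- blob_records(rbind(c(0, -40, 40), c(0, 40, 40)))
  f1 <- build_features(br$records, pca_dims = 5)
  perm <- rev(seq_along(br$records))
  f2 <- build_features(br$records[perm], pca_dims = 5)
  a1 <- kmeans_cluster(f1, 2, seed = 9)$assignments
  a2 <- kmeans_cluster(f2, 2, seed = 9)$assignments
  expect_equal(rand_index_adjusted(a1, a2[order(perm)]), 1.0)
})

test_that("outlier flagging isolates the far point and respects infinity", {
  # tight blob: members sit on a unit shell around the centroid, so
  # their centroid distances are identical; the planted point is far
  set.seed(8)
  dirs <- matrix(rnorm(40 * 4), 40, 4)
  x <- dirs / sqrt(rowSums(dirs^2))
  x[13, ] <- x[13, ] * 30
  assign <- rep(1L, 40)
  ctr <- matrix(0, 1, 4)
  out <- flag_outlier_ics(x, assign, ctr, 2)
  expect_equal(out, 13L)
  expect_length(flag_outlier_ics(x, assign, ctr, Inf), 0)

  # tiny clusters skip the test with a message
  expect_message(flag_outlier_ics(x[1:2, ], rep(1L, 2), ctr, 2), "skipped")
})

test_that("junk components are flagged at roughly their injected rate", {
  centers <- rbind(c(0, -40, 40), c(0, 40, 40), c(-40, 0, 30), c(40, 0, 30))
  br <- blob_records(centers, n_each = 10, sd = 2, seed = 2)
  n_good <- length(br$records)
  n_junk <- round(0.2 * n_good / 0.8)            # 20% junk overall
  set.seed(4)
  junk <- lapply(seq_len(n_junk), function(i) {
    # junk rides on a population's flank -- close enough to join its
    # cluster, far enough (and with a foreign activity signature and
    # orientation) to be an outlier there
    ctr <- centers[sample.int(nrow(centers), 1), ]
    dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
    p <- ctr + runif(1, 14, 20) * dir
    fake_record("SX", 100 + i, p, ori = rnorm(3), seed = 400 + i,
                profile = rnorm(1, 0, 4))
  })
  recs <- c(br$records, junk)
  cl <- cluster_components(recs, k = 4, seed = 6)
  frac_injected <- n_junk / length(recs)
  frac_flagged <- length(cl$outliers) / length(recs)
  expect_lt(abs(frac_flagged - frac_injected), 0.10)
})

test_that("choose_k stops at no-structure and reports monotone diagnostics", {
  set.seed(10)
  recs <- lapply(1:24, function(i)
    fake_record(sprintf("S%02d", i %% 8), i, c(0, -40, 40) + rnorm(3, 0, 3),
                seed = 100 + i))
  f <- build_features(recs, pca_dims = 5)
  sel <- choose_k(f, k_min = 2, k_max = 6, seed = 3)
  expect_equal(sel$k, 2)

  br <- blob_records(rbind(c(0, -40, 40), c(0, 40, 40), c(-40, 0, 30),
                           c(40, 0, 30)), n_each = 8)
  f4 <- build_features(br$records, pca_dims = 5)
  sel4 <- choose_k(f4, k_min = 2, k_max = 8, seed = 3)
  expect_equal(sel4$k, 4)
  expect_true(all(diff(sel4$diagnostics$wss[order(sel4$diagnostics$k)]) <= 1e-9))
})

test_that("cluster reports serialize members and centroids", {
  br <- blob_records(rbind(c(0, -40, 40), c(0, 40, 40)))
  cl <- cluster_components(br$records, k = 2, seed = 2)
  dir <- withr::local_tempdir()
  tab <- write_cluster_report(cl, dir)
  expect_true(file.exists(file.path(dir, "cluster_members.tsv")))
  summ <- jsonlite::read_json(file.path(dir, "cluster_summary.json"))
  expect_length(summ, 2)
  expect_equal(summ[[1]]$n_components + summ[[2]]$n_components,
               length(br$records) - length(cl$outliers))
})
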