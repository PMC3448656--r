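## Cross-subject clustering of accepted independent components.
##
## Each IC contributes a joint feature vector built from its dipole
## location/orientation, scalp map, mean activation spectrum, ERP, ERSP
## and ITC.  Non-dipole measures are z-standardized and PCA-compressed;
## the dipole block is kept at its native 6 dimensions and up-weighted
## (relative weight 10 vs 1), so source geometry dominates the joint
## Euclidean distance that K-means optimizes.

#' Assemble an IC record
#'
#' @param subject_id subject identifier
#' @param group group label (1/2 or string)
#' @param ic_index component index within the subject's decomposition
#' @param scalp_map unit-norm scalp map
#' @param dip fitted `dipole` (with rv)
#' @param spectrum mean activation spectrum, dB
#' @param erp trial-average activation
#' @param ersp,itc `tf_result`-style matrices (or the `tf_result`
#'   itself under `tf`)
#' @param mixing_col projection weights of the component onto the
#'   analyzed channels (column of the mixing matrix)
#' @param activation optional samples x trials activation matrix
#' @return object of class `ic_record`
#' @export
ic_record <- function(subject_id, group, ic_index, scalp_map, dip,
                      spectrum = NULL, erp = NULL, ersp = NULL, itc = NULL,
                      mixing_col = NULL, activation = NULL) {
  structure(list(subject_id = subject_id, group = group,
                 ic_index = ic_index, scalp_map = scalp_map, dipole = dip,
                 spectrum = spectrum, erp = erp, ersp = ersp, itc = itc,
                 mixing_col = mixing_col, activation = activation),
            class = "ic_record")
}

## unit orientation with a stable sign: radially outward where the
## moment has a radial part, positive max-abs element for the rare
## purely tangential case
dipole_orientation <- function(d) {
  m <- d$moment
  n <- sqrt(sum(m^2))
  if (n == 0) return(c(0, 0, 0))
  m <- m / n
  rad <- sum(m * d$position)
  if (abs(rad) > 1e-6 * max(1, sqrt(sum(d$position^2)))) {
    if (rad < 0) m <- -m
  } else if (m[which.max(abs(m))] < 0) m <- -m
  m
}

measure_matrix <- function(records, field) {
  rows <- lapply(records, function(r) {
    v <- r[[field]]
    if (is.null(v)) numeric(0) else as.numeric(v)
  })
  len <- unique(lengths(rows))
  if (length(len) != 1) stop("inconsistent '", field, "' lengths across records")
  if (len == 0) return(NULL)
  do.call(rbind, rows)
}

#' Build joint cluster features
#'
#' Per measure: columns are z-standardized, reduced by PCA to at most
#' `pca_dims` dimensions, rescaled to unit mean per-dimension variance,
#' and multiplied by the measure's weight.  The dipole block (position
#' + sign-fixed orientation, 6 dims) skips PCA.  Blocks are
#' concatenated; the transform (centers, scales, rotations) is stored
#' for reproducibility.
#'
#' @param records list of `ic_record`
#' @param pca_dims PCA dimensions per non-dipole measure; default 10
#' @param weights named weights; defaults: 1 for every measure, 10 for
#'   the dipole block
#' @return feature matrix (ICs x D) with attributes `blocks` (column
#'   index list per measure) and `transform`
#' @export
build_features <- function(records, pca_dims = 10,
                           weights = c(dipole = 10, scalp_map = 1,
                                       spectrum = 1, erp = 1, ersp = 1,
                                       itc = 1)) {
  n <- length(records)
  if (n < 2) stop("need at least 2 records to build features")
  blocks <- list(); transform <- list(); feats <- NULL
  add_block <- function(name, mat) {
    start <- if (is.null(feats)) 1L else ncol(feats) + 1L
    feats <<- if (is.null(feats)) mat else cbind(feats, mat)
    blocks[[name]] <<- start:(start + ncol(mat) - 1L)
  }

  dip <- t(vapply(records, function(r)
    c(r$dipole$position, dipole_orientation(r$dipole)), numeric(6)))
  dipz <- apply(dip, 2, zscore0)
  w_dip <- if ("dipole" %in% names(weights)) weights[["dipole"]] else 10
  add_block("dipole", dipz * w_dip)
  transform$dipole <- list(center = colMeans(dip),
                           scale = apply(dip, 2, stats::sd), weight = w_dip)

  for (nm in c("scalp_map", "spectrum", "erp", "ersp", "itc")) {
    mat <- measure_matrix(records, nm)
    if (is.null(mat)) next
    w <- if (nm %in% names(weights)) weights[[nm]] else 1
    z <- apply(mat, 2, zscore0)
    d <- min(pca_dims, n - 1, ncol(z))
    if (d < pca_dims && pca_dims <= ncol(z))
      warning(sprintf("'%s': PCA dims reduced to %d (only %d records)",
                      nm, d, n))
    pc <- stats::prcomp(z, center = FALSE, rank. = d)
    sc <- pc$x[, seq_len(d), drop = FALSE]
    v <- mean(apply(sc, 2, stats::var))
    if (v > 0) sc <- sc / sqrt(v)          # unit mean per-dim variance
    add_block(nm, sc * w)
    transform[[nm]] <- list(rotation = pc$rotation, mean_var = v, weight = w,
                            center = colMeans(mat),
                            scale = apply(mat, 2, stats::sd))
  }
  structure(feats, blocks = blocks, transform = transform)
}

## Lloyd iterations from fixed starting centers; row-order independent
lloyd <- function(x, centers, iter_max = 100) {
  for (it in seq_len(iter_max)) {
    d2 <- outer(rowSums(x^2), rowSums(centers^2), `+`) - 2 * x %*% t(centers)
    assign <- max.col(-d2, ties.method = "first")
    newc <- centers
    for (k in seq_len(nrow(centers))) {
      idx <- which(assign == k)
      if (length(idx)) newc[k, ] <- colMeans(x[idx, , drop = FALSE])
      else {                                # re-seed empty cluster
        far <- which.max(d2[cbind(seq_len(nrow(x)), assign)])
        newc[k, ] <- x[far, ]
      }
    }
    if (max(abs(newc - centers)) < 1e-12) { centers <- newc; break }
    centers <- newc
  }
  d2 <- outer(rowSums(x^2), rowSums(centers^2), `+`) - 2 * x %*% t(centers)
  assign <- max.col(-d2, ties.method = "first")
  wss <- sum(pmax(d2[cbind(seq_len(nrow(x)), assign)], 0))
  list(assignments = assign, centers = centers, wss = wss)
}

#' K-means clustering of IC features
#'
#' Best of `n_init` seeded restarts by within-cluster sum of squares,
#' with Lloyd iterations from initial centers drawn in a canonical row
#' order, so the partition is deterministic under `seed` and invariant
#' to the input order of records (ties broken toward the earlier
#' restart).
#'
#' @param features ICs x D matrix from [build_features()]
#' @param k number of clusters, < number of ICs
#' @param seed integer
#' @param n_init restarts; default 20
#' @return list with `assignments`, `centers`, `wss`
#' @export
kmeans_cluster <- function(features, k, seed = 1L, n_init = 20) {
  x <- unclass(features)
  attributes(x)[c("blocks", "transform")] <- NULL
  n <- nrow(x)
  if (k >= n) stop("k must be smaller than the number of ICs")
  if (k == 1) {
    ctr <- matrix(colMeans(x), 1)
    return(list(assignments = rep(1L, n), centers = ctr,
                wss = sum(sweep(x, 2, ctr)^2)))
  }
  canon <- do.call(order, as.data.frame(x))   # input-order-free ranking
  picks <- with_seed(seed, replicate(n_init, sample.int(n, k), simplify = FALSE))
  best <- NULL
  for (p in picks) {
    res <- lloyd(x, x[canon[p], , drop = FALSE])
    if (is.null(best) || res$wss < best$wss - 1e-12) best <- res
  }
  best
}

#' Flag outlier components
#'
#' An IC is an outlier when its Euclidean distance to its assigned
#' centroid exceeds `sd_threshold` standard deviations of the member
#' distances in that cluster (z-scored distance, one-sided).  The test
#' is applied iteratively: flagged members are dropped from the
#' mean/SD of distances and the rule re-applied until stable, so a
#' heavy contamination cannot mask itself by inflating the spread.
#' Clusters with fewer than 3 unflagged members are not tested.
#'
#' @param features ICs x D matrix
#' @param assignments cluster index per IC
#' @param centers k x D centroid matrix
#' @param sd_threshold default 2
#' @param max_iter refinement iterations
#' @return integer vector of outlier IC indices
#' @export
flag_outlier_ics <- function(features, assignments, centers, sd_threshold = 2,
                             max_iter = 10) {
  x <- unclass(features)
  out <- integer(0)
  for (it in seq_len(max_iter)) {
    new <- integer(0)
    for (k in seq_len(nrow(centers))) {
      idx <- setdiff(which(assignments == k), out)
      if (length(idx) < 3) {
        if (it == 1 && length(which(assignments == k)) < 3)
          message(sprintf("cluster %d has < 3 members; outlier test skipped", k))
        next
      }
      d <- sqrt(rowSums(sweep(x[idx, , drop = FALSE], 2, centers[k, ])^2))
      s <- stats::sd(d)
      if (!is.finite(s) || s == 0) next
      new <- c(new, idx[(d - mean(d)) / s > sd_threshold])
    }
    if (!length(new)) break
    out <- c(out, new)
  }
  sort(out)
}

## mean non-dipole feature profile of a member set
nondipole_profile <- function(features, idx) {
  blocks <- attr(features, "blocks")
  cols <- unlist(blocks[setdiff(names(blocks), "dipole")], use.names = FALSE)
  colMeans(unclass(features)[idx, cols, drop = FALSE])
}

#' Select the number of clusters
#'
#' Programmatic analogue of the visual stopping rule: increase k while
#' each increment still separates source populations.  Stepping from k
#' to k+1 is rejected when it splits one cluster into two whose
#' activity (non-dipole) profiles are indistinguishable -- the dipole
#' group was divided but the measures stayed the same.  Two
#' indistinguishability criteria are used: centroid profiles
#' correlating above `r_stop`, or a between-children profile distance
#' below `sep_stop` in units of its sampling scale (the pooled
#' within-child spread over the profile dimensions; ~1 when the
#' children are draws from one population).  The last accepted k is
#' returned with a diagnostic trace.
#'
#' @param features ICs x D matrix from [build_features()]
#' @param k_min,k_max candidate range (k_min >= 2)
#' @param seed integer
#' @param r_stop profile-correlation threshold; default 0.95
#' @param sep_stop profile-separation floor; default 3
#' @param sd_threshold outliers flagged at each candidate k before
#'   profiles are computed
#' @return list with `k`, and `diagnostics` (data frame: k, wss,
#'   split_cor, split_sep)
#' @export
choose_k <- function(features, k_min = 2, k_max = 8, seed = 1L,
                     r_stop = 0.95, sep_stop = 3, sd_threshold = 2) {
  stopifnot(k_min >= 2, k_max >= k_min)
  n <- nrow(features)
  k_max <- min(k_max, n - 1)
  fits <- lapply(k_min:k_max, function(k) kmeans_cluster(features, k, seed))
  names(fits) <- k_min:k_max
  diag_rows <- list()
  chosen <- k_max
  for (k in k_min:(k_max - 1)) {
    a1 <- fits[[as.character(k)]]$assignments
    a2 <- fits[[as.character(k + 1)]]$assignments
    out2 <- suppressMessages(
      flag_outlier_ics(features, a2, fits[[as.character(k + 1)]]$centers,
                       sd_threshold))
    ## map each (k+1)-cluster to its majority parent at k
    parent <- vapply(seq_len(k + 1), function(c2) {
      idx <- which(a2 == c2)
      as.integer(names(which.max(table(a1[idx]))))
    }, integer(1))
    split_cor <- NA_real_; split_sep <- NA_real_
    blocks <- attr(features, "blocks")
    nd_cols <- unlist(blocks[setdiff(names(blocks), "dipole")],
                      use.names = FALSE)
    xnd <- unclass(features)[, nd_cols, drop = FALSE]
    for (p in unique(parent[duplicated(parent)])) {
      kids <- which(parent == p)
      for (i in seq_along(kids)) for (j in seq_len(i - 1L)) {
        m1 <- setdiff(which(a2 == kids[i]), out2)
        m2 <- setdiff(which(a2 == kids[j]), out2)
        if (length(m1) < 1 || length(m2) < 1) next
        p1 <- colMeans(xnd[m1, , drop = FALSE])
        p2 <- colMeans(xnd[m2, , drop = FALSE])
        r <- suppressWarnings(stats::cor(p1, p2))
        if (is.finite(r) && (is.na(split_cor) || r > split_cor)) split_cor <- r
        ## pooled within-child variance per dimension -> expected
        ## squared profile distance under a common population
        v1 <- if (length(m1) > 1) apply(xnd[m1, , drop = FALSE], 2, stats::var)
              else rep(NA_real_, ncol(xnd))
        v2 <- if (length(m2) > 1) apply(xnd[m2, , drop = FALSE], 2, stats::var)
              else rep(NA_real_, ncol(xnd))
        vbar <- mean(c(v1, v2), na.rm = TRUE)
        if (is.finite(vbar) && vbar > 0) {
          sep <- sqrt(sum((p1 - p2)^2) /
                        (ncol(xnd) * vbar * (1 / length(m1) + 1 / length(m2))))
          if (is.na(split_sep) || sep < split_sep) split_sep <- sep
        }
      }
    }
    diag_rows[[length(diag_rows) + 1L]] <-
      data.frame(k = k, wss = fits[[as.character(k)]]$wss,
                 split_cor = split_cor, split_sep = split_sep)
    merged <- (is.finite(split_cor) && split_cor > r_stop) ||
      (is.finite(split_sep) && split_sep < sep_stop)
    if (merged) { chosen <- k; break }
  }
  diag_rows[[length(diag_rows) + 1L]] <-
    data.frame(k = chosen, wss = fits[[as.character(chosen)]]$wss,
               split_cor = NA_real_, split_sep = NA_real_)
  list(k = chosen, diagnostics = unique(do.call(rbind, diag_rows)))
}

#' Cluster a set of IC records
#'
#' Features, K-means at a fixed or selected k, and outlier flagging in
#' one call.
#'
#' @param records list of `ic_record`
#' @param k fixed cluster count, or NULL to select via [choose_k()]
#' @param seed integer
#' @param pca_dims,weights passed to [build_features()]
#' @param sd_threshold outlier rule
#' @param k_min,k_max,r_stop,sep_stop passed to [choose_k()] when `k`
#'   is NULL
#' @return object of class `ic_clustering`: `records`, `features`,
#'   `k`, `assignments`, `centers`, `outliers`, `clusters` (list of
#'   member index vectors, outliers excluded), `diagnostics`
#' @export
cluster_components <- function(records, k = NULL, seed = 1L, pca_dims = 10,
                               weights = c(dipole = 10, scalp_map = 1,
                                           spectrum = 1, erp = 1, ersp = 1,
                                           itc = 1),
                               sd_threshold = 2, k_min = 2, k_max = 8,
                               r_stop = 0.95, sep_stop = 3) {
  features <- build_features(records, pca_dims, weights)
  diagnostics <- NULL
  if (is.null(k)) {
    sel <- choose_k(features, k_min, k_max, seed, r_stop, sep_stop,
                    sd_threshold)
    k <- sel$k; diagnostics <- sel$diagnostics
  }
  fit <- kmeans_cluster(features, k, seed)
  outliers <- suppressMessages(
    flag_outlier_ics(features, fit$assignments, fit$centers, sd_threshold))
  clusters <- lapply(seq_len(k), function(c)
    setdiff(which(fit$assignments == c), outliers))
  structure(list(records = records, features = features, k = k,
                 assignments = fit$assignments, centers = fit$centers,
                 outliers = outliers, clusters = clusters,
                 diagnostics = diagnostics, seed = seed),
            class = "ic_clustering")
}

#' @export
print.ic_clustering <- function(x, ...) {
  cat(sprintf("ic_clustering: %d ICs -> %d clusters (%d outliers)\n",
              length(x$records), x$k, length(x$outliers)))
  for (c in seq_len(x$k)) {
    mem <- x$clusters[[c]]
    subj <- unique(vapply(x$records[mem], `[[`, "", "subject_id"))
    cat(sprintf("  cluster %d: %d ICs from %d subjects\n",
                c, length(mem), length(subj)))
  }
  invisible(x)
}

#' Cluster membership and centroid report
#'
#' TSV of members (subject, ic, cluster, distance to centroid, outlier
#' flag) and a JSON summary with centroid dipole positions in model and
#' Talairach-like coordinates, plus subject/component counts per
#' cluster.
#'
#' @param clustering an `ic_clustering`
#' @param dir output directory
#' @export
write_cluster_report <- function(clustering, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  x <- unclass(clustering$features)
  rows <- lapply(seq_along(clustering$records), function(i) {
    r <- clustering$records[[i]]
    cl <- clustering$assignments[i]
    data.frame(subject = r$subject_id, ic = r$ic_index, cluster = cl,
               distance = sqrt(sum((x[i, ] - clustering$centers[cl, ])^2)),
               outlier = i %in% clustering$outliers)
  })
  tab <- do.call(rbind, rows)
  utils::write.table(tab, file.path(dir, "cluster_members.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  summ <- lapply(seq_len(clustering$k), function(c) {
    mem <- clustering$clusters[[c]]
    pos <- t(vapply(clustering$records[mem],
                    function(r) r$dipole$position, numeric(3)))
    ctr <- if (length(mem)) colMeans(pos) else c(NA, NA, NA)
    list(cluster = c, n_components = length(mem),
         n_subjects = length(unique(vapply(clustering$records[mem],
                                           `[[`, "", "subject_id"))),
         centroid_model_mm = ctr, centroid_talairach_mm = to_talairach(ctr))
  })
  jsonlite::write_json(summ, file.path(dir, "cluster_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(tab)
}
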