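## Permutation group statistics on cluster-level ERSP/ITC maps with
## two-level multiple-comparison control: Benjamini-Hochberg FDR within
## each cluster's frequency x latency map, Bonferroni across clusters.

#' Per-subject cluster maps
#'
#' ICs of the same subject within a cluster are averaged first, so each
#' subject contributes one map; maps are split by group.
#'
#' @param records member `ic_record`s of one cluster
#' @param measure "ersp" or "itc"
#' @return list with `groups` (named list of per-subject F x T map
#'   lists), `subjects` (ids per group)
#' @export
subject_level_maps <- function(records, measure = c("ersp", "itc")) {
  measure <- match.arg(measure)
  if (!length(records)) stop("empty cluster")
  subj <- vapply(records, `[[`, "", "subject_id")
  grp <- vapply(records, function(r) as.character(r$group), "")
  out <- list()
  for (g in sort(unique(grp))) {
    ids <- unique(subj[grp == g])
    maps <- lapply(ids, function(id) {
      ms <- lapply(records[subj == id & grp == g], `[[`, measure)
      Reduce(`+`, ms) / length(ms)
    })
    names(maps) <- ids
    out[[g]] <- maps
  }
  if (length(out) < 2)
    stop("cluster contains only group ", names(out),
         "; group comparison impossible")
  list(groups = out, subjects = lapply(out, names))
}

#' Pixelwise permutation test between two groups of maps
#'
#' Statistic: unpaired two-sample t (pooled variance) per pixel.  The
#' null is built by shuffling subject group labels; two-tailed p-values
#' use the add-one rule p = (1 + #{|t*| >= |t|}) / (n_perm + 1), so
#' Monte-Carlo p is never exactly zero.  Deterministic under `seed`.
#'
#' @param maps_a,maps_b lists of equal-dimension matrices (one map per
#'   subject, >= 2 per group)
#' @param n_perm number of permutations; default 2000 (< 100 warns)
#' @param seed integer
#' @return list with `tmap`, `pmap` (same dim as the input maps),
#'   `n_permutations`, `seed`
#' @export
permutation_test <- function(maps_a, maps_b, n_perm = 2000, seed = 1L) {
  na <- length(maps_a); nb <- length(maps_b)
  stopifnot(na >= 2, nb >= 2)
  if (n_perm < 100) warning("fewer than 100 permutations: p-values are coarse")
  dm <- dim(maps_a[[1]])
  X <- rbind(t(vapply(maps_a, as.numeric, numeric(prod(dm)))),
             t(vapply(maps_b, as.numeric, numeric(prod(dm)))))
  n <- na + nb
  sq <- X^2
  sum_all <- colSums(X); sum_sq_all <- colSums(sq)
  ## t statistics for many label assignments at once: P is a
  ## permutations x subjects 0/1 indicator of group-A membership
  tstat_block <- function(P) {
    sa <- P %*% X; sb <- matrix(sum_all, nrow(P), ncol(X), byrow = TRUE) - sa
    qa <- P %*% sq; qb <- matrix(sum_sq_all, nrow(P), ncol(X), byrow = TRUE) - qa
    ma <- sa / na; mb <- sb / nb
    va <- (qa - na * ma^2) / (na - 1)
    vb <- (qb - nb * mb^2) / (nb - 1)
    sp <- ((na - 1) * va + (nb - 1) * vb) / (n - 2)
    (ma - mb) / sqrt(pmax(sp, .Machine$double.eps) * (1 / na + 1 / nb))
  }
  P_obs <- matrix(0, 1, n); P_obs[1, seq_len(na)] <- 1
  t_obs <- drop(tstat_block(P_obs))
  exceed <- numeric(length(t_obs))
  block <- 250L
  with_seed(seed, {
    done <- 0L
    while (done < n_perm) {
      nb_perm <- min(block, n_perm - done)
      P <- matrix(0, nb_perm, n)
      for (p in seq_len(nb_perm)) P[p, sample.int(n, na)] <- 1
      tb <- abs(tstat_block(P))
      ## relative tolerance so exact ties (e.g. the identity relabeling)
      ## count identically under any common rescaling of the maps
      thr <- matrix(abs(t_obs) * (1 - 1e-12), nb_perm, length(t_obs),
                    byrow = TRUE)
      exceed <- exceed + colSums(tb >= thr)
      done <- done + nb_perm
    }
  })
  pmap <- (1 + exceed) / (n_perm + 1)
  list(tmap = matrix(t_obs, dm[1], dm[2]), pmap = matrix(pmap, dm[1], dm[2]),
       n_permutations = n_perm, seed = seed)
}

#' Benjamini-Hochberg mask
#'
#' Step-up FDR over all entries of a p-value matrix.
#'
#' @param pmap numeric matrix (or vector) of p-values
#' @param q FDR level in (0, 1)
#' @return logical mask of the same shape
#' @export
fdr_mask <- function(pmap, q = 0.05) {
  stopifnot(q > 0, q < 1)
  adj <- stats::p.adjust(as.numeric(pmap), method = "BH")
  out <- adj <= q
  if (!is.null(dim(pmap))) dim(out) <- dim(pmap)
  out
}

#' Bonferroni-adjusted significance cutoff
#'
#' Divides the p-value threshold by the number of cluster comparisons:
#' alpha / n_clusters (0.05/4 = 0.0125, 0.05/5 = 0.01).
#'
#' @param alpha nominal level
#' @param n_clusters number of comparisons, >= 1
#' @return adjusted cutoff
#' @export
bonferroni_cutoff <- function(alpha = 0.05, n_clusters) {
  stopifnot(n_clusters >= 1)
  alpha / n_clusters
}

#' Two-level significance mask for one cluster
#'
#' A pixel is significant when it survives Benjamini-Hochberg FDR at
#' `q` within the cluster's map *and* its permutation p-value is at or
#' below the Bonferroni-adjusted cutoff across clusters.
#'
#' @param perm output of [permutation_test()]
#' @param q within-map FDR level
#' @param cutoff across-cluster cutoff from [bonferroni_cutoff()]
#' @return object of class `stat_mask`: `tmap`, `pmap`, `sig`,
#'   `n_permutations`, `seed`, `cutoff_used`, `q`
#' @export
stat_mask <- function(perm, q = 0.05, cutoff = 0.05) {
  sig <- fdr_mask(perm$pmap, q) & perm$pmap <= cutoff
  structure(list(tmap = perm$tmap, pmap = perm$pmap, sig = sig,
                 n_permutations = perm$n_permutations, seed = perm$seed,
                 cutoff_used = cutoff, q = q, statistic = "two-sample t"),
            class = "stat_mask")
}

#' @export
print.stat_mask <- function(x, ...) {
  cat(sprintf("stat_mask: %d x %d pixels, %d significant (q = %g, cutoff = %g, %d perms)\n",
              nrow(x$sig), ncol(x$sig), sum(x$sig), x$q, x$cutoff_used,
              x$n_permutations))
  invisible(x)
}

#' Significance summary per band and latency window
#'
#' Counts significant pixels of a `stat_mask` within conventional
#' frequency bands and a latency window, written as TSV when `path` is
#' given.
#'
#' @param mask a `stat_mask`
#' @param freqs,times axes matching the mask
#' @param window latency window of interest, ms
#' @param bands named list of Hz pairs
#' @param path optional TSV output path
#' @return data frame
#' @export
significance_summary <- function(mask, freqs, times, window = c(200, 400),
                                 bands = list(theta = c(4, 8),
                                              alpha = c(8, 13),
                                              beta = c(14, 30)),
                                 path = NULL) {
  ti <- which(times >= window[1] & times <= window[2])
  rows <- lapply(names(bands), function(b) {
    fi <- which(freqs >= bands[[b]][1] & freqs <= bands[[b]][2])
    n_sig <- if (length(fi) && length(ti)) sum(mask$sig[fi, ti]) else 0L
    data.frame(band = b, window_ms = paste(window, collapse = ".."),
               n_pixels = length(fi) * length(ti), n_significant = n_sig,
               min_p = if (length(fi) && length(ti))
                 min(mask$pmap[fi, ti]) else NA_real_)
  })
  out <- do.call(rbind, rows)
  if (!is.null(path))
    utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  out
}
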