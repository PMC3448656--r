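## Study orchestration: simulate -> preprocess -> ICA -> dipole fit ->
## cluster -> time-frequency -> permutation statistics, with structured
## per-stage bookkeeping (trials rejected, ICs removed, ICs surviving
## the residual-variance filter, outlier ICs) and full determinism
## under the configured seeds.

#' Study configuration
#'
#' Bundles every tunable of the chain.  All seeds are explicit; the
#' configuration round-trips through JSON unchanged.
#'
#' @param cohort a `cohort_spec`
#' @param sources named list of `source_spec`; default
#'   [default_sources()] for the chosen modality
#' @param modality "visual" or "auditory" (controls the default source
#'   layout: 4 vs 5 populations)
#' @param filter list(low, high, notches) or NULL to skip filtering of
#'   the simulated recordings (the simulator is already band-limited)
#' @param reject_z epoch-rejection threshold
#' @param ica list(seed, max_iter, tol)
#' @param artifact list(z_general, z_eog)
#' @param rv_max residual-variance ceiling for component acceptance
#' @param clustering list(k, k_min, k_max, pca_dims, weights,
#'   sd_threshold, r_stop, seed); `k = NULL` selects k by [choose_k()]
#' @param tfr list(freqs, baseline_window, decimate, cycle_rule)
#' @param stats list(alpha, q, n_perm, seed, measure)
#' @param condition epoch condition analyzed ("target" or "nontarget")
#' @return object of class `study_config`
#' @export
study_config <- function(cohort = cohort_spec(),
                         sources = NULL,
                         modality = c("visual", "auditory"),
                         filter = NULL,
                         reject_z = 3,
                         ica = list(seed = 11L, max_iter = 350L, tol = 1e-6),
                         artifact = list(z_general = 3, z_eog = 2),
                         rv_max = 0.15,
                         clustering = list(k = NULL, k_min = 2, k_max = 8,
                                           pca_dims = 10, sd_threshold = 2,
                                           r_stop = 0.95, sep_stop = 3,
                                           seed = 21L),
                         tfr = list(freqs = tf_freqs(n = 30, fmin = 3,
                                                     fmax = 45),
                                    decimate = 4L,
                                    cycle_rule = list(kind = "cap")),
                         stats = list(alpha = 0.05, q = 0.05, n_perm = 1000,
                                      seed = 31L, measure = "ersp"),
                         condition = "target") {
  modality <- match.arg(modality)
  if (is.null(sources)) sources <- default_sources(modality)
  structure(list(cohort = cohort, sources = sources, modality = modality,
                 filter = filter, reject_z = reject_z, ica = ica,
                 artifact = artifact, rv_max = rv_max,
                 clustering = clustering, tfr = tfr, stats = stats,
                 condition = condition),
            class = "study_config")
}

#' Serialize / restore a study configuration
#'
#' @param config a `study_config`
#' @param path JSON file path
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass_deep(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

unclass_deep <- function(x) {
  if (is.list(x)) {
    out <- lapply(x, unclass_deep)
    attr(out, "p3class") <- paste(class(x)[class(x) != "list"], collapse = ",")
    out
  } else x
}

#' Hash of a configuration (provenance stamp)
#' @param config a `study_config`
#' @return md5 string
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  write_config(config, tmp)
  unname(tools::md5sum(tmp))
}

## --- per-subject processing -------------------------------------------------

## epoch, reject, decompose, flag artifacts, fit dipoles, and measure
## every accepted component of one simulated subject
process_subject <- function(sim, config, model = head_model()) {
  cohort <- config$cohort
  dat <- sim$continuous
  if (!is.null(config$filter))
    dat <- bandpass_notch(dat, sim$sampling_rate, config$filter$low,
                          config$filter$high, config$filter$notches)
  sc <- scalp_channels(sim$montage)
  dat <- average_reference(dat, sc)
  ep <- epoch_and_baseline(dat, sim$sampling_rate, sim$events,
                           window = cohort$epoch_window,
                           baseline = cohort$baseline_window,
                           montage = sim$montage,
                           subject_id = sim$subject_id %||% "S00")
  ep <- reject_epochs(ep, config$reject_z)

  dec <- ica_decompose(ep, channels = seq_along(sim$montage$labels),
                       seed = config$ica$seed,
                       max_iter = config$ica$max_iter %||% 350L,
                       tol = config$ica$tol %||% 1e-6)
  arts <- flag_artifact_ics(dec, ep, z_general = config$artifact$z_general,
                            z_eog = config$artifact$z_eog)

  sens_scalp <- sensor_array(sim$montage$labels[sc],
                             sim$montage$positions[sc, , drop = FALSE])
  keep <- setdiff(seq_len(nrow(dec$unmixing)), arts)
  ## residual variance is defined over the scalp electrodes only
  scalp_map_of <- function(k) {
    m <- dec$scalp_maps[sc, k]
    m / max(sqrt(sum(m^2)), .Machine$double.eps)
  }
  tgt <- ep$trial_labels == config$condition
  if (!any(tgt)) stop("no '", config$condition, "' trials after rejection")
  times <- epoch_times(ep)
  records <- list()
  n_inside_rv <- 0L
  for (k in keep) {
    smap <- scalp_map_of(k)
    dip <- fit_single_dipole(smap, sens_scalp, model)
    if (is.null(dip$rv) || dip$rv > config$rv_max ||
        !is_inside_brain(dip$position, model)) next
    n_inside_rv <- n_inside_rv + 1L
    act <- ic_activation(dec, k)
    mixing_col <- dec$mixing[, k]
    ## polarity convention: IC sign is arbitrary, so orient the fitted
    ## moment radially outward; ERP and map polarities then agree
    ## across subjects for radial cortical sources
    if (sum(dip$moment * dip$position) < 0) {
      dip$moment <- -dip$moment
      smap <- -smap
      act <- -act
      mixing_col <- -mixing_col
    }
    tf <- time_frequency(act[, tgt, drop = FALSE], ep$sampling_rate,
                         freqs = config$tfr$freqs,
                         baseline_window = cohort$baseline_window,
                         t0_ms = cohort$epoch_window[1],
                         cycle_rule = config$tfr$cycle_rule %||% list(kind = "cap"),
                         decimate = config$tfr$decimate %||% 1L)
    sp <- activation_spectrum(act, dec$n_samples, ep$sampling_rate)
    records[[length(records) + 1L]] <- ic_record(
      subject_id = ep$subject_id, group = sim$group %||% 1L, ic_index = k,
      scalp_map = smap, dip = dip,
      spectrum = sp$db, erp = rowMeans(act[, tgt, drop = FALSE]),
      ersp = tf$ersp, itc = tf$itc, mixing_col = mixing_col)
  }
  list(records = records, epochs = ep, decomposition = dec,
       log = data.frame(subject = ep$subject_id,
                        trials_in = cohort$n_trials,
                        trials_rejected = length(ep$rejected_trials),
                        ics = nrow(dec$unmixing),
                        ics_artifact = length(arts),
                        ics_accepted = n_inside_rv))
}

## --- full study -------------------------------------------------------------

#' Run the full source-space study chain on a synthetic cohort
#'
#' Simulates the cohort, processes every subject (epoching, rejection,
#' Infomax ICA, artifact flagging, dipole fitting, residual-variance
#' filtering, per-IC ERSP/ITC), clusters accepted ICs across subjects,
#' and tests the group contrast per cluster with permutation statistics
#' under FDR (within map) plus a Bonferroni cutoff computed from the
#' realized cluster count.
#'
#' @param config a `study_config`
#' @param model a `head_model`
#' @return object of class `study_result`: `clustering`, `cluster_stats`
#'   (per cluster: `mask` (`stat_mask`), `group_means`, `n_subjects`),
#'   `tf_axes`, `bonferroni`, `log` (per-subject stage counts),
#'   `config`, `provenance`
#' @export
run_study <- function(config, model = head_model()) {
  stopifnot(inherits(config, "study_config"))
  plan <- cohort_plan(config$cohort, config$sources, config$cohort$seed, model)
  results <- vector("list", length(plan$subjects))
  for (i in seq_along(plan$subjects)) {
    p <- plan$subjects[[i]]
    sim <- simulate_subject(p$sources, config$cohort, p$events, p$sim_seed,
                            plan$montage, model)
    sim$subject_id <- p$subject_id
    sim$group <- p$group
    st <- try(process_subject(sim, config, model), silent = TRUE)
    if (inherits(st, "try-error"))
      stop("stage failure for subject ", p$subject_id, ": ",
           attr(st, "condition")$message)
    st$epochs <- NULL; st$decomposition <- NULL   # keep memory flat
    results[[i]] <- st
  }
  records <- do.call(c, lapply(results, `[[`, "records"))
  if (length(records) < 4) stop("clustering stage: too few accepted ICs")
  logs <- do.call(rbind, lapply(results, `[[`, "log"))

  cl <- cluster_components(
    records, k = config$clustering$k, seed = config$clustering$seed %||% 21L,
    pca_dims = config$clustering$pca_dims %||% 10,
    sd_threshold = config$clustering$sd_threshold %||% 2,
    k_min = config$clustering$k_min %||% 2,
    k_max = config$clustering$k_max %||% 8,
    r_stop = config$clustering$r_stop %||% 0.95,
    sep_stop = config$clustering$sep_stop %||% 3)

  cutoff <- bonferroni_cutoff(config$stats$alpha %||% 0.05, cl$k)
  measure <- config$stats$measure %||% "ersp"
  cluster_stats <- vector("list", cl$k)
  for (c in seq_len(cl$k)) {
    mem <- records[cl$clusters[[c]]]
    maps <- try(subject_level_maps(mem, measure), silent = TRUE)
    if (inherits(maps, "try-error")) {
      cluster_stats[[c]] <- list(skipped = TRUE,
                                 reason = attr(maps, "condition")$message)
      next
    }
    gnames <- names(maps$groups)
    if (any(lengths(maps$groups) < 2)) {
      cluster_stats[[c]] <- list(skipped = TRUE,
                                 reason = "fewer than 2 subjects in a group")
      next
    }
    perm <- permutation_test(maps$groups[[gnames[1]]],
                             maps$groups[[gnames[2]]],
                             n_perm = config$stats$n_perm %||% 1000,
                             seed = (config$stats$seed %||% 31L) + c)
    mask <- stat_mask(perm, q = config$stats$q %||% 0.05, cutoff = cutoff)
    cluster_stats[[c]] <- list(
      skipped = FALSE, mask = mask,
      group_means = lapply(maps$groups, function(g) Reduce(`+`, g) / length(g)),
      n_subjects = lengths(maps$groups))
  }
  ## time axis of the (decimated) maps, reconstructed from one record
  ex <- records[[1]]
  structure(list(clustering = cl, cluster_stats = cluster_stats,
                 bonferroni = cutoff,
                 tf_axes = list(freqs = attr_or_null(ex$ersp, "freqs"),
                                times = attr_or_null(ex$ersp, "times")),
                 log = logs, config = config,
                 provenance = list(config_hash = config_hash(config),
                                   package_version =
                                     as.character(utils::packageVersion("p3source")))),
            class = "study_result")
}

attr_or_null <- function(x, a) attr(x, a, exact = TRUE)

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("study_result: %d clusters (Bonferroni cutoff %.4g)\n",
              x$clustering$k, x$bonferroni))
  for (c in seq_along(x$cluster_stats)) {
    cs <- x$cluster_stats[[c]]
    if (isTRUE(cs$skipped)) {
      cat(sprintf("  cluster %d: skipped (%s)\n", c, cs$reason))
    } else {
      cat(sprintf("  cluster %d: %s subjects, %d significant pixels\n",
                  c, paste(cs$n_subjects, collapse = "+"), sum(cs$mask$sig)))
    }
  }
  invisible(x)
}

#' Channel-level comparison baseline
#'
#' The scalp analogue of the cluster statistics: grand-average ERP plus
#' ERSP/ITC and the permutation group test at a single channel (no
#' ICA), FDR-corrected at `q` with no Bonferroni division.
#'
#' @param config a `study_config`
#' @param channel_label montage channel to analyze (e.g. "Pz")
#' @param model a `head_model`
#' @return list with `erp` (per-group grand averages), `mask`
#'   (`stat_mask`), `tf_axes`, per-group mean maps
#' @export
scalp_baseline <- function(config, channel_label = "Pz", model = head_model()) {
  plan <- cohort_plan(config$cohort, config$sources, config$cohort$seed, model)
  ch <- match(channel_label, plan$montage$labels)
  if (is.na(ch))
    stop("channel '", channel_label, "' not in montage: ",
         paste(plan$montage$labels, collapse = ", "))
  cohort <- config$cohort
  maps <- list(`1` = list(), `2` = list())
  erps <- list(`1` = list(), `2` = list())
  for (p in plan$subjects) {
    sim <- simulate_subject(p$sources, cohort, p$events, p$sim_seed,
                            plan$montage, model)
    dat <- average_reference(sim$continuous, scalp_channels(sim$montage))
    ep <- epoch_and_baseline(dat, sim$sampling_rate, sim$events,
                             window = cohort$epoch_window,
                             baseline = cohort$baseline_window,
                             montage = sim$montage, subject_id = p$subject_id)
    ep <- reject_epochs(ep, config$reject_z)
    tgt <- ep$trial_labels == config$condition
    x <- ep$data[ch, , tgt]
    tf <- time_frequency(x, ep$sampling_rate, freqs = config$tfr$freqs,
                         baseline_window = cohort$baseline_window,
                         t0_ms = cohort$epoch_window[1],
                         cycle_rule = config$tfr$cycle_rule %||% list(kind = "cap"),
                         decimate = config$tfr$decimate %||% 1L)
    g <- as.character(p$group)
    measure <- config$stats$measure %||% "ersp"
    maps[[g]][[p$subject_id]] <- tf[[measure]]
    erps[[g]][[p$subject_id]] <- rowMeans(x)
    if (p$subject_id == plan$subjects[[1]]$subject_id)
      axes <- list(freqs = tf$freqs, times = tf$times)
  }
  perm <- permutation_test(maps[["1"]], maps[["2"]],
                           n_perm = config$stats$n_perm %||% 1000,
                           seed = config$stats$seed %||% 31L)
  mask <- stat_mask(perm, q = config$stats$q %||% 0.05, cutoff = 1)
  list(channel = channel_label,
       erp = lapply(erps, function(g) Reduce(`+`, g) / length(g)),
       group_means = lapply(maps, function(g) Reduce(`+`, g) / length(g)),
       mask = mask, tf_axes = axes)
}

#' Back-project a cluster to one channel
#'
#' Sums the member ICs' contributions at the channel (mixing weight
#' times activation) per subject, then computes the ERP and, with
#' enough trials, ERSP/ITC of the recomposed signal.
#'
#' @param records member `ic_record`s (need `mixing_col` and
#'   `activation`)
#' @param channel_index index of the channel within the analyzed set
#' @param sampling_rate Hz
#' @param epoch_window,baseline_window ms pairs
#' @param freqs analysis frequencies (NULL skips the TF step)
#' @return list with per-subject recomposed `erp` and optional `tf`
#' @export
backproject_cluster <- function(records, channel_index, sampling_rate,
                                epoch_window = c(-500, 1000),
                                baseline_window = c(-200, 0), freqs = NULL) {
  if (!length(records))
    return(list(erp = NULL, tf = NULL, n_subjects = 0L))
  subj <- vapply(records, `[[`, "", "subject_id")
  out <- list()
  for (id in unique(subj)) {
    recs <- records[subj == id]
    contrib <- NULL
    for (r in recs) {
      if (is.null(r$activation) || is.null(r$mixing_col))
        stop("records must carry mixing_col and activation for back-projection")
      x <- r$mixing_col[channel_index] * r$activation
      contrib <- if (is.null(contrib)) x else contrib + x
    }
    tf <- if (!is.null(freqs) && ncol(contrib) >= 2)
      time_frequency(contrib, sampling_rate, freqs = freqs,
                     baseline_window = baseline_window,
                     t0_ms = epoch_window[1])
    else NULL
    out[[id]] <- list(erp = rowMeans(contrib), signal = contrib, tf = tf)
  }
  list(subjects = out, n_subjects = length(out))
}

#' Write a study report
#'
#' Per-cluster panels (group-mean ERSP/ITC images with the significance
#' frame) as PNG plus a machine-readable JSON summary, stamped with the
#' configuration hash.
#'
#' @param result a `study_result`
#' @param dir output directory
#' @export
write_report <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  freqs <- result$tf_axes$freqs; times <- result$tf_axes$times
  summ <- list(config_hash = result$provenance$config_hash,
               n_clusters = result$clustering$k,
               bonferroni_cutoff = result$bonferroni, clusters = list())
  for (c in seq_along(result$cluster_stats)) {
    cs <- result$cluster_stats[[c]]
    if (isTRUE(cs$skipped)) {
      summ$clusters[[c]] <- list(cluster = c, skipped = TRUE)
      next
    }
    grDevices::png(file.path(dir, sprintf("cluster%02d.png", c)), 1200, 400,
                   res = 110)
    op <- graphics::par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
    for (g in names(cs$group_means)) {
      graphics::image(times %||% seq_len(ncol(cs$group_means[[g]])),
                      freqs %||% seq_len(nrow(cs$group_means[[g]])),
                      t(cs$group_means[[g]]), xlab = "latency (ms)",
                      ylab = "frequency (Hz)",
                      main = sprintf("cluster %d group %s", c, g),
                      col = grDevices::hcl.colors(64, "RdBu", rev = TRUE))
    }
    graphics::image(times %||% seq_len(ncol(cs$mask$sig)),
                    freqs %||% seq_len(nrow(cs$mask$sig)),
                    t(cs$mask$sig * 1), xlab = "latency (ms)",
                    ylab = "frequency (Hz)", main = "significant",
                    col = c("grey90", "red3"))
    graphics::par(op)
    grDevices::dev.off()
    summ$clusters[[c]] <- list(cluster = c,
                               n_subjects = as.list(cs$n_subjects),
                               n_significant = sum(cs$mask$sig))
  }
  jsonlite::write_json(summ, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Save / load epoched EEG containers
#'
#' Single-file container holding the data array, montage, windows and
#' provenance; written with R serialization.
#'
#' @param epochs an `epoched_eeg`
#' @param path file path
#' @export
write_epochs <- function(epochs, path) {
  stopifnot(inherits(epochs, "epoched_eeg"))
  saveRDS(epochs, path)
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  x <- readRDS(path)
  stopifnot(inherits(x, "epoched_eeg"))
  x
}
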