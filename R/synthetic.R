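## Synthetic oddball-EEG cohorts with known dipolar ground truth.
##
## Sources are amplitude-modulated sinusoids (oscillatory kinds) or
## stereotyped transients (evoked, blink) attached to dipoles in the
## four-shell model; channel data are the forward-projected sum plus
## white sensor noise.  Oscillatory amplitude varies log-normally from
## trial to trial, emulating the bursty, heavy-tailed amplitude
## dynamics of ongoing rhythms; the ERSP is unaffected because a
## common per-trial amplitude factor cancels between the response
## window and the baseline.

#' Specification of one simulated source
#'
#' @param name identifier used to address group effects and ground truth
#' @param dip a `dipole` (moment sets the scalp projection strength in
#'   nA*m)
#' @param kind one of "evoked", "oscillatory-ers", "oscillatory-erd",
#'   "blink"
#' @param center_freq oscillation frequency, Hz
#' @param band_power_change dB change of single-trial band power within
#'   the latency window relative to baseline (positive = ERS,
#'   negative = ERD)
#' @param phase_locking fraction of trials whose oscillation is
#'   stimulus phase-locked, in [0, 1]
#' @param latency_window `(start, end)` ms relative to stimulus onset;
#'   must lie inside the epoch
#' @param condition "target", "nontarget" or "both"
#' @param amplitude waveform amplitude for the evoked/blink kinds
#'   (arbitrary units; the scalp scale is set by the dipole moment)
#' @return object of class `source_spec`
#' @export
source_spec <- function(name, dip, kind = c("oscillatory-ers", "oscillatory-erd",
                                            "evoked", "blink"),
                        center_freq = 6, band_power_change = 3,
                        phase_locking = 0, latency_window = c(200, 500),
                        condition = c("target", "nontarget", "both"),
                        amplitude = 1) {
  kind <- match.arg(kind)
  condition <- match.arg(condition)
  stopifnot(inherits(dip, "dipole"), center_freq > 0,
            phase_locking >= 0, phase_locking <= 1,
            latency_window[1] < latency_window[2])
  structure(list(name = name, dipole = dip, kind = kind,
                 center_freq = center_freq,
                 band_power_change = band_power_change,
                 phase_locking = phase_locking,
                 latency_window = as.numeric(latency_window),
                 condition = condition, amplitude = amplitude),
            class = "source_spec")
}

#' Cohort specification
#'
#' Defaults are the desk-scale study conditions: 32 scalp channels at
#' 128 Hz, 15 subjects per group, 205-trial oddball runs with 20%
#' targets and a 2 s inter-stimulus interval.  The 128-channel / 512 Hz
#' recording convention of high-density studies is available as a
#' preset, not the default.
#'
#' @param n_per_group two positive integers (group 1, group 2)
#' @param group_effect named numeric vector: per-source dB offsets
#'   added to `band_power_change` (evoked amplitude is scaled by the
#'   equivalent amplitude ratio) for group 2 subjects
#' @param n_channels scalp channel count
#' @param n_eog number of EOG channels appended to the montage
#' @param sampling_rate Hz
#' @param n_trials stimuli per run
#' @param p_target target probability, in (0, 1); realized counts are
#'   exact, not Bernoulli draws
#' @param isi inter-stimulus interval, s
#' @param noise_sd white sensor noise SD, uV
#' @param blink_rate eye blinks per minute (default 10, the order of
#'   spontaneous blink rates; 0 disables the blink source)
#' @param jitter_sd per-subject dipole position jitter SD, mm
#' @param amp_variability log-SD of per-trial oscillatory amplitude
#' @param epoch_window,baseline_window ms pairs used downstream
#' @param seed master seed
#' @return object of class `cohort_spec`
#' @export
cohort_spec <- function(n_per_group = c(15, 15), group_effect = numeric(),
                        n_channels = 32, n_eog = 2, sampling_rate = 128,
                        n_trials = 205, p_target = 0.2, isi = 2,
                        noise_sd = 1.5, blink_rate = 10, jitter_sd = 5,
                        amp_variability = 0.75,
                        epoch_window = c(-500, 1000),
                        baseline_window = c(-200, 0), seed = 1L) {
  stopifnot(length(n_per_group) == 2, all(n_per_group >= 1), n_trials > 0)
  if (p_target <= 0 || p_target >= 1) stop("p_target must lie in (0, 1)")
  structure(list(n_per_group = as.integer(n_per_group),
                 group_effect = group_effect, n_channels = n_channels,
                 n_eog = n_eog, sampling_rate = sampling_rate,
                 n_trials = as.integer(n_trials), p_target = p_target,
                 isi = isi, noise_sd = noise_sd, blink_rate = blink_rate,
                 jitter_sd = jitter_sd, amp_variability = amp_variability,
                 epoch_window = as.numeric(epoch_window),
                 baseline_window = as.numeric(baseline_window),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' High-density recording preset
#'
#' The 128-scalp-channel, 512 Hz configuration of high-density oddball
#' studies, on top of [cohort_spec()] defaults.
#'
#' @param ... overrides passed on to [cohort_spec()]
#' @export
cohort_spec_highdensity <- function(...) {
  args <- utils::modifyList(list(n_channels = 128, sampling_rate = 512), list(...))
  do.call(cohort_spec, args)
}

#' Generate an oddball stimulus sequence
#'
#' Exactly `round(n_trials * p_target)` targets, pseudorandomly placed
#' with no two consecutive targets; reproducible under `seed`.
#'
#' @param n_trials number of stimuli
#' @param p_target target probability in (0, 1)
#' @param seed integer
#' @return character vector of "target"/"nontarget" labels
#' @export
generate_paradigm <- function(n_trials, p_target, seed = 1L) {
  if (p_target <= 0 || p_target >= 1) stop("p_target must lie in (0, 1)")
  n_t <- round(n_trials * p_target)
  if (n_t < 1) stop("round(n_trials * p_target) must be at least 1")
  if (n_t > ceiling(n_trials / 2))
    stop("cannot place targets without adjacency at this rate")
  ## choose target slots among the n - n_t + 1 gap positions, then
  ## shift so no two land adjacent
  slots <- with_seed(seed, sort(sample.int(n_trials - n_t + 1L, n_t)))
  slots <- slots + seq_len(n_t) - 1L
  labels <- rep("nontarget", n_trials)
  labels[slots] <- "target"
  labels
}

#' Default planted source layouts
#'
#' Four source populations for the visual-style preset (midline
#' parietal theta ERS with partial phase locking, frontal-midline theta
#' ERS, occipital alpha ERD, lateral central beta ERD) and a fifth
#' temporal theta population in the auditory-style preset, plus an eye
#' blink artifact source near the eyes.
#'
#' @param modality "visual" (4 populations) or "auditory" (5)
#' @param blink include the blink artifact source
#' @return named list of `source_spec`
#' @export
default_sources <- function(modality = c("visual", "auditory"), blink = TRUE) {
  modality <- match.arg(modality)
  rad_moment <- function(pos, mag = 45, tang = c(0, 0, 0)) {
    pos <- as.numeric(pos)
    mag * pos / sqrt(sum(pos^2)) + tang
  }
  src <- list(
    parietal_theta = source_spec("parietal_theta",
      dipole(c(0, -42, 40), rad_moment(c(0, -42, 40), 50)),
      kind = "oscillatory-ers", center_freq = 6, band_power_change = 3,
      phase_locking = 0.7, latency_window = c(200, 500), condition = "target"),
    frontal_theta = source_spec("frontal_theta",
      dipole(c(0, 38, 42), rad_moment(c(0, 38, 42), 45)),
      kind = "oscillatory-ers", center_freq = 5, band_power_change = 2.5,
      phase_locking = 0.4, latency_window = c(150, 450), condition = "target"),
    occipital_alpha = source_spec("occipital_alpha",
      dipole(c(0, -55, 5), rad_moment(c(0, -55, 5), 50)),
      kind = "oscillatory-erd", center_freq = 10, band_power_change = -4,
      phase_locking = 0, latency_window = c(300, 800), condition = "both"),
    central_beta = source_spec("central_beta",
      dipole(c(-38, -12, 42), rad_moment(c(-38, -12, 42), 45)),
      kind = "oscillatory-erd", center_freq = 20, band_power_change = -3,
      phase_locking = 0, latency_window = c(300, 700), condition = "both"))
  if (modality == "auditory") {
    src$temporal_theta <- source_spec("temporal_theta",
      dipole(c(52, 8, 18), rad_moment(c(52, 8, 18), 45)),
      kind = "oscillatory-ers", center_freq = 6.5, band_power_change = 2.5,
      phase_locking = 0.5, latency_window = c(150, 400), condition = "target")
  }
  if (blink) {
    src$blink <- source_spec("blink",
      dipole(c(0, 58, -12), c(0, 35, 60)),
      kind = "blink", center_freq = 3, amplitude = 40,
      latency_window = c(0, 300), condition = "both")
  }
  src
}

## raised-cosine gain envelope over a latency window: 1 outside, level
## inside, cosine ramps over `ramp` fraction of the window at each edge
window_envelope <- function(t_ms, window, level, ramp = 0.2) {
  w <- rep(1, length(t_ms))
  len <- window[2] - window[1]
  rlen <- ramp * len
  up <- t_ms >= window[1] & t_ms < window[1] + rlen
  plateau <- t_ms >= window[1] + rlen & t_ms <= window[2] - rlen
  down <- t_ms > window[2] - rlen & t_ms <= window[2]
  w[up] <- 1 + (level - 1) * 0.5 * (1 - cos(pi * (t_ms[up] - window[1]) / rlen))
  w[plateau] <- level
  w[down] <- 1 + (level - 1) * 0.5 * (1 - cos(pi * (window[2] - t_ms[down]) / rlen))
  w
}

## stereotyped 300 ms biphasic blink waveform sampled at `srate`
blink_waveform <- function(srate) {
  t <- seq(0, 0.3, by = 1 / srate)
  exp(-(t - 0.12)^2 / (2 * 0.04^2)) - 0.35 * exp(-(t - 0.22)^2 / (2 * 0.06^2))
}

#' Simulate one subject's continuous oddball recording
#'
#' Channel data are the sum over sources of the forward-projected
#' activation plus white sensor noise.  Oscillatory sources are
#' regenerated per trial segment: phase is stimulus-locked (zero at
#' onset) for the phase-locked fraction of trials and uniform
#' otherwise; amplitude gains `band_power_change` dB inside the latency
#' window for the stated condition via a raised-cosine envelope.
#'
#' @param sources list of `source_spec`
#' @param cohort a `cohort_spec`
#' @param events character label vector from [generate_paradigm()]
#' @param seed integer
#' @param montage a `sensor_array`; default built from the cohort spec
#' @param model a `head_model`
#' @return list with `continuous` (channels x samples, uV),
#'   `sampling_rate`, `events` (data frame: trial, latency_s, label),
#'   `montage`, and `truth` (per-source dipoles, scalp maps, and
#'   parameters)
#' @export
simulate_subject <- function(sources, cohort, events, seed = 1L,
                             montage = NULL, model = head_model()) {
  if (is.null(montage))
    montage <- project_to_scalp(make_montage(cohort$n_channels, cohort$n_eog),
                                model)
  srate <- cohort$sampling_rate
  isi_n <- round(cohort$isi * srate)
  pre_s <- abs(cohort$epoch_window[1]) / 1000
  post_s <- cohort$epoch_window[2] / 1000
  n_ev <- length(events)
  pad <- ceiling((pre_s + 0.5) * srate)
  n_total <- 2L * pad + (n_ev - 1L) * isi_n + round(post_s * srate) + isi_n
  onsets <- pad + (seq_len(n_ev) - 1L) * isi_n + 1L
  t_all <- (seq_len(n_total) - 1) / srate

  for (s in sources) {
    win <- s$latency_window
    if (win[1] < cohort$epoch_window[1] || win[2] > cohort$epoch_window[2])
      stop(sprintf("source '%s': latency window outside the epoch", s$name))
  }

  nch <- length(montage$labels)
  data <- matrix(0, nch, n_total)
  truth <- list()
  seg_len <- isi_n
  seg_pre <- round(pre_s * srate)

  with_seed(seed, {
    for (s in sources) {
      map <- forward_potentials(s$dipole, montage, model)
      act <- numeric(n_total)
      applies <- switch(s$condition, both = rep(TRUE, n_ev),
                        target = events == "target",
                        nontarget = events == "nontarget")
      if (s$kind %in% c("oscillatory-ers", "oscillatory-erd")) {
        level <- 10^(s$band_power_change / 20)
        n_lock <- round(s$phase_locking * sum(applies))
        locked <- rep(FALSE, n_ev)
        locked[sample(which(applies), n_lock)] <- TRUE
        for (i in seq_len(n_ev)) {
          idx <- (onsets[i] - seg_pre):(onsets[i] - seg_pre + seg_len - 1L)
          idx <- idx[idx >= 1 & idx <= n_total]
          tt <- (idx - onsets[i]) / srate * 1000        # ms from onset
          amp <- exp(stats::rnorm(1, 0, cohort$amp_variability))
          phi <- if (locked[i]) 0 else stats::runif(1, 0, 2 * pi)
          env <- if (applies[i]) window_envelope(tt, s$latency_window, level)
                 else rep(1, length(tt))
          act[idx] <- amp * env *
            sin(2 * pi * s$center_freq * tt / 1000 + phi)
        }
      } else if (s$kind == "evoked") {
        w <- s$latency_window
        for (i in which(applies)) {
          idx0 <- onsets[i] + round(w[1] / 1000 * srate)
          tt <- seq(idx0, onsets[i] + round(w[2] / 1000 * srate))
          tt <- tt[tt >= 1 & tt <= n_total]
          ph <- (tt - idx0) / (length(tt) - 1)
          act[tt] <- act[tt] + s$amplitude * sin(pi * ph)^2
        }
      } else if (s$kind == "blink") {
        if (cohort$blink_rate > 0) {
          nblink <- stats::rpois(1, cohort$blink_rate * n_total / srate / 60)
          bw <- s$amplitude * blink_waveform(srate)
          if (nblink > 0) {
            at <- sort(sample.int(n_total - length(bw), nblink))
            for (b in at) act[b:(b + length(bw) - 1)] <- act[b:(b + length(bw) - 1)] + bw
          }
        }
      }
      data <- data + outer(as.numeric(map), act)
      truth[[s$name]] <- list(name = s$name, dipole = s$dipole, map = map,
                              kind = s$kind, center_freq = s$center_freq,
                              band_power_change = s$band_power_change,
                              phase_locking = s$phase_locking,
                              latency_window = s$latency_window,
                              condition = s$condition)
    }
    if (cohort$noise_sd > 0)
      data <- data + matrix(stats::rnorm(length(data), 0, cohort$noise_sd),
                            nrow(data), ncol(data))
  })
  list(continuous = data, sampling_rate = srate,
       events = data.frame(trial = seq_len(n_ev),
                           latency_s = (onsets - 1) / srate,
                           label = events),
       montage = montage, truth = truth)
}

## per-subject plan: group labels, jittered sources, seeds, events
cohort_plan <- function(cohort, sources = default_sources(), seed = cohort$seed,
                        model = head_model()) {
  n <- sum(cohort$n_per_group)
  groups <- rep(1:2, cohort$n_per_group)
  seeds <- child_seeds(seed, 3L * n)
  montage <- project_to_scalp(make_montage(cohort$n_channels, cohort$n_eog),
                              model)
  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    subj_sources <- sources
    ## group-2 effect offsets
    if (groups[i] == 2 && length(cohort$group_effect)) {
      for (nm in names(cohort$group_effect)) {
        if (!nm %in% names(subj_sources)) next
        s <- subj_sources[[nm]]
        if (s$kind == "evoked") {
          s$amplitude <- s$amplitude * 10^(cohort$group_effect[[nm]] / 20)
        } else {
          s$band_power_change <- s$band_power_change + cohort$group_effect[[nm]]
        }
        subj_sources[[nm]] <- s
      }
    }
    ## anatomical variability: jitter dipole positions, stay inside brain
    subj_sources <- with_seed(seeds[n + i], {
      lapply(subj_sources, function(s) {
        if (cohort$jitter_sd > 0) {
          p <- s$dipole$position + stats::rnorm(3, 0, cohort$jitter_sd)
          r <- sqrt(sum(p^2))
          if (r >= 0.95 * model$radii[1]) p <- p * (0.95 * model$radii[1] / r)
          s$dipole$position <- p
        }
        s
      })
    })
    subjects[[i]] <- list(
      subject_id = sprintf("S%02d", i), group = groups[i],
      sources = subj_sources,
      events = generate_paradigm(cohort$n_trials, cohort$p_target,
                                 seeds[2L * n + i]),
      sim_seed = seeds[i])
  }
  list(subjects = subjects, montage = montage, cohort = cohort, model = model)
}

#' Simulate a multi-subject cohort
#'
#' Group 2 subjects receive the `group_effect` dB offsets of the cohort
#' spec; per-subject dipole positions are jittered (SD `jitter_sd` mm)
#' to emulate anatomical variability.  Fully reproducible under the
#' cohort seed.
#'
#' @param cohort a `cohort_spec`
#' @param sources named list of `source_spec`; default
#'   [default_sources()]
#' @param seed master seed; defaults to the cohort's
#' @param model a `head_model`
#' @return list with `subjects` (each: the [simulate_subject()] output
#'   plus `subject_id` and `group`), `ground_truth` (per-subject source
#'   dipoles, maps and parameters with group assignment), `montage`,
#'   `cohort`
#' @export
simulate_cohort <- function(cohort, sources = default_sources(),
                            seed = cohort$seed, model = head_model()) {
  plan <- cohort_plan(cohort, sources, seed, model)
  subjects <- lapply(plan$subjects, function(p) {
    sim <- simulate_subject(p$sources, cohort, p$events, p$sim_seed,
                            plan$montage, model)
    sim$subject_id <- p$subject_id
    sim$group <- p$group
    sim
  })
  gt <- lapply(seq_along(subjects), function(i) {
    list(subject_id = plan$subjects[[i]]$subject_id,
         group = plan$subjects[[i]]$group,
         sources = subjects[[i]]$truth)
  })
  list(subjects = subjects, ground_truth = gt, montage = plan$montage,
       cohort = cohort)
}

#' Epoch a simulated subject
#'
#' Convenience: average-reference the scalp channels and cut epochs at
#' the cohort's window/baseline.
#'
#' @param sim output of [simulate_subject()]
#' @param cohort the `cohort_spec` used
#' @param subject_id stored in the result
#' @return an `epoched_eeg`
#' @export
epoch_simulated <- function(sim, cohort, subject_id = sim$subject_id %||% "S00") {
  dat <- average_reference(sim$continuous, scalp_channels(sim$montage))
  epoch_and_baseline(dat, sim$sampling_rate, sim$events,
                     window = cohort$epoch_window,
                     baseline = cohort$baseline_window,
                     montage = sim$montage, subject_id = subject_id)
}

#' Write cohort sidecar files
#'
#' Events as TSV (trial_index, latency_s, label) per subject and the
#' ground truth as one JSON sidecar.
#'
#' @param cohort_sim output of [simulate_cohort()]
#' @param dir output directory (created if needed)
#' @export
write_cohort_sidecars <- function(cohort_sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in cohort_sim$subjects) {
    utils::write.table(
      data.frame(trial_index = s$events$trial, latency_s = s$events$latency_s,
                 label = s$events$label),
      file.path(dir, paste0(s$subject_id, "_events.tsv")),
      sep = "\t", row.names = FALSE, quote = FALSE)
  }
  gt <- lapply(cohort_sim$ground_truth, function(g) {
    list(subject_id = g$subject_id, group = g$group,
         sources = lapply(g$sources, function(src) {
           list(name = src$name, kind = src$kind,
                position = src$dipole$position, moment = src$dipole$moment,
                center_freq = src$center_freq,
                band_power_change = src$band_power_change,
                phase_locking = src$phase_locking,
                latency_window = src$latency_window,
                condition = src$condition)
         }))
  })
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
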