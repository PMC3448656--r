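## Continuous-to-epoched conversion and statistical artifact rejection.
##
## Pipeline order is fixed: filter -> reference -> epoch/baseline ->
## reject -> interpolate.  Rejection thresholds follow the FASTER
## family of statistical criteria (z over trials, default z = 3).

#' Epoched EEG container
#'
#' @param data channels x samples x trials array, uV
#' @param sampling_rate Hz
#' @param epoch_window `(pre, post)` ms relative to stimulus onset
#' @param baseline_window `(from, to)` ms, inside the epoch window
#' @param montage a `sensor_array` with one entry per data row
#' @param trial_labels character vector, "target"/"nontarget", one per trial
#' @param subject_id identifier string
#' @param interpolated_channels labels replaced by interpolation
#' @param rejected_trials original indices of trials removed by rejection
#' @param dropped_events original indices of events too close to the
#'   recording edge to epoch
#' @return object of class `epoched_eeg`
#' @export
epoched_eeg <- function(data, sampling_rate, epoch_window,
                        baseline_window = c(-200, 0), montage = NULL,
                        trial_labels = NULL, subject_id = "S00",
                        interpolated_channels = character(),
                        rejected_trials = integer(),
                        dropped_events = integer()) {
  stopifnot(length(dim(data)) == 3)
  nsamp <- round((epoch_window[2] - epoch_window[1]) / 1000 * sampling_rate)
  if (dim(data)[2] != nsamp)
    stop(sprintf("data has %d samples; window (%g, %g) ms at %g Hz implies %d",
                 dim(data)[2], epoch_window[1], epoch_window[2],
                 sampling_rate, nsamp))
  if (is.null(trial_labels)) trial_labels <- rep("target", dim(data)[3])
  if (length(trial_labels) != dim(data)[3])
    stop("trial_labels length must equal the number of trials")
  if (!is.null(montage) && length(montage$labels) != dim(data)[1])
    stop("montage size must match the number of channels")
  structure(list(data = data, sampling_rate = sampling_rate,
                 epoch_window = as.numeric(epoch_window),
                 baseline_window = as.numeric(baseline_window),
                 montage = montage,
                 trial_labels = as.character(trial_labels),
                 subject_id = subject_id,
                 interpolated_channels = interpolated_channels,
                 rejected_trials = rejected_trials,
                 dropped_events = dropped_events),
            class = "epoched_eeg")
}

#' @export
print.epoched_eeg <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("epoched_eeg %s: %d ch x %d samples x %d trials @ %g Hz\n",
              x$subject_id, d[1], d[2], d[3], x$sampling_rate))
  cat(sprintf("  window (%g, %g) ms, baseline (%g, %g) ms; %d target trials\n",
              x$epoch_window[1], x$epoch_window[2], x$baseline_window[1],
              x$baseline_window[2], sum(x$trial_labels == "target")))
  if (length(x$rejected_trials))
    cat(sprintf("  %d trials rejected\n", length(x$rejected_trials)))
  invisible(x)
}

#' Time axis of an epoch in ms
#' @param x an `epoched_eeg`
#' @return numeric vector, one value per sample
#' @export
epoch_times <- function(x) {
  n <- dim(x$data)[2]
  x$epoch_window[1] + (seq_len(n) - 1) / x$sampling_rate * 1000
}

#' Zero-phase bandpass plus notch filtering
#'
#' Forward-backward (zero-phase) Butterworth filtering: a 4th-order
#' bandpass between `low` and `high`, then a 2nd-order band-stop of
#' +/- 2 Hz around each notch frequency.  Notches at or above ~Nyquist
#' are dropped with a warning.
#'
#' @param data channels x samples matrix (a single channel may be a
#'   plain vector)
#' @param sampling_rate Hz
#' @param low,high band edges, Hz; `high` must be below Nyquist
#' @param notches numeric vector of line/monitor frequencies, Hz
#' @return filtered data, same shape
#' @export
bandpass_notch <- function(data, sampling_rate, low = 1, high = 95,
                           notches = c(50, 60)) {
  vec <- is.null(dim(data))
  if (vec) data <- matrix(data, nrow = 1)
  nyq <- sampling_rate / 2
  if (low <= 0 || low >= high) stop("need 0 < low < high")
  if (high >= nyq) stop("high edge must be below the Nyquist frequency")
  bp <- signal::butter(4, c(low, high) / nyq, type = "pass")
  out <- t(apply(data, 1, function(ch) signal::filtfilt(bp, ch)))
  for (f in notches) {
    if (f + 2 >= nyq * 0.999) {
      warning(sprintf("notch at %g Hz at/above Nyquist; skipped", f))
      next
    }
    bs <- signal::butter(2, c(f - 2, f + 2) / nyq, type = "stop")
    out <- t(apply(out, 1, function(ch) signal::filtfilt(bs, ch)))
  }
  if (vec) drop(out) else out
}

#' Average reference
#'
#' Subtracts the per-sample mean over the referenced channels (all by
#' default) from those channels.  With a montage that includes EOG
#' channels, pass the scalp subset so only scalp electrodes define and
#' receive the reference.
#'
#' @param data channels x samples matrix or channels x samples x trials
#'   array
#' @param channels integer indices of channels forming the reference
#'   (and being re-referenced); default all
#' @return re-referenced data, same shape
#' @export
average_reference <- function(data, channels = NULL) {
  dm <- dim(data)
  if (length(dm) == 3) {
    flat <- matrix(data, dm[1], dm[2] * dm[3])
    out <- average_reference(flat, channels)
    return(array(out, dm))
  }
  if (is.null(channels)) channels <- seq_len(nrow(data))
  if (length(channels) < 2) stop("need at least 2 channels to re-reference")
  mu <- colMeans(data[channels, , drop = FALSE])
  data[channels, ] <- sweep(data[channels, , drop = FALSE], 2, mu)
  data
}

#' Cut a continuous recording into baseline-corrected epochs
#'
#' Events whose epoch would extend beyond the recording are dropped and
#' reported in the `dropped_events` field.
#'
#' @param continuous channels x samples matrix, uV
#' @param sampling_rate Hz
#' @param events data frame with columns `latency_s` (stimulus onset in
#'   seconds from recording start) and `label`
#' @param window `(pre, post)` ms; default the conventional P3b epoch
#' @param baseline `(from, to)` ms for per-trial mean subtraction
#' @param montage,subject_id stored in the result
#' @return an `epoched_eeg`
#' @export
epoch_and_baseline <- function(continuous, sampling_rate, events,
                               window = c(-500, 1000), baseline = c(-200, 0),
                               montage = NULL, subject_id = "S00") {
  stopifnot(is.matrix(continuous), all(c("latency_s", "label") %in% names(events)))
  nsamp <- round((window[2] - window[1]) / 1000 * sampling_rate)
  pre_off <- round(window[1] / 1000 * sampling_rate)
  ntot <- ncol(continuous)
  onset <- round(events$latency_s * sampling_rate) + 1L
  first <- onset + pre_off
  last <- first + nsamp - 1L
  ok <- first >= 1L & last <= ntot
  dropped <- which(!ok)
  if (length(dropped))
    message(sprintf("epoch_and_baseline: dropped %d event(s) too close to the recording edge (%s)",
                    length(dropped), paste(dropped, collapse = ", ")))
  keep <- which(ok)
  if (!length(keep)) stop("no event leaves a complete epoch")
  dat <- array(0, c(nrow(continuous), nsamp, length(keep)))
  for (i in seq_along(keep)) {
    dat[, , i] <- continuous[, first[keep[i]]:last[keep[i]]]
  }
  times <- window[1] + (seq_len(nsamp) - 1) / sampling_rate * 1000
  bidx <- which(times >= baseline[1] & times < baseline[2])
  if (!length(bidx)) stop("baseline window contains no samples")
  bmean <- apply(dat[, bidx, , drop = FALSE], c(1, 3), mean)
  dat <- dat - aperm(array(bmean, c(dim(dat)[1], dim(dat)[3], nsamp)), c(1, 3, 2))
  epoched_eeg(dat, sampling_rate, window, baseline, montage = montage,
              trial_labels = events$label[keep], subject_id = subject_id,
              dropped_events = dropped)
}

## per-(channel, trial) artifact metrics, z-scored over trials
epoch_metrics_z <- function(data) {
  rng <- apply(data, c(1, 3), function(v) diff(range(v)))
  vr <- apply(data, c(1, 3), stats::var)
  chmean <- apply(data, c(1, 3), mean)
  dev <- abs(chmean - rowMeans(chmean))
  zrow <- function(m) t(apply(m, 1, zscore0))
  list(range = zrow(rng), variance = zrow(vr), mean_dev = zrow(dev))
}

#' Statistical epoch rejection
#'
#' A trial is rejected when, for any of three per-channel metrics
#' (amplitude range, variance, deviation of the trial's channel mean
#' from the channel's grand mean), its absolute z-score across trials
#' exceeds `z_threshold` on at least one channel.  Degenerate metrics
#' with zero spread map to z = 0, so identical trials are never
#' rejected.
#'
#' @param epochs an `epoched_eeg` with at least 3 trials
#' @param z_threshold rejection threshold; default 3
#' @return `epoched_eeg` with rejected trials removed and their original
#'   indices recorded in `rejected_trials`
#' @export
reject_epochs <- function(epochs, z_threshold = 3) {
  ntr <- dim(epochs$data)[3]
  if (ntr < 3) stop("need at least 3 trials for statistical rejection")
  zs <- epoch_metrics_z(epochs$data)
  worst <- sapply(zs, function(z) apply(abs(z), 2, max))  # trials x metrics
  bad <- which(apply(worst, 1, max) > z_threshold)
  if (length(bad) == ntr) stop("all trials rejected; lower z_threshold")
  if (length(bad)) {
    epochs$data <- epochs$data[, , -bad, drop = FALSE]
    epochs$trial_labels <- epochs$trial_labels[-bad]
  }
  epochs$rejected_trials <- c(epochs$rejected_trials, bad)
  epochs
}

#' Spherical-spline interpolation of bad channels
#'
#' Replaces the listed channels by a spherical-spline estimate (order
#' `m`, Tikhonov-regularized) computed from the remaining channels,
#' following the standard scalp-spline construction.  Requires a
#' montage and refuses to interpolate 25% or more of it.
#'
#' @param epochs an `epoched_eeg` with a montage
#' @param bad_labels channel labels to replace
#' @param m spline order (stiffness); default 4
#' @param lambda regularization added to the spline system; default 1e-5
#' @param n_terms Legendre series length of the spline kernel
#' @return `epoched_eeg` with channels replaced and recorded in
#'   `interpolated_channels`
#' @export
interpolate_channels <- function(epochs, bad_labels, m = 4, lambda = 1e-5,
                                 n_terms = 50) {
  if (!length(bad_labels)) return(epochs)
  mon <- epochs$montage
  if (is.null(mon)) stop("interpolation requires a montage")
  bad <- match(bad_labels, mon$labels)
  if (anyNA(bad)) stop("unknown channel label(s): ",
                       paste(bad_labels[is.na(bad)], collapse = ", "))
  nch <- length(mon$labels)
  if (length(bad) >= 0.25 * nch)
    stop("refusing to interpolate >= 25% of the montage")
  good <- setdiff(seq_len(nch), bad)

  u <- mon$positions / sqrt(rowSums(mon$positions^2))
  gkern <- function(cosang) {
    n <- seq_len(n_terms)
    leg <- legendre_table(pmin(1, pmax(-1, cosang)), n_terms)
    w <- (2 * n + 1) / (n * (n + 1))^m / (4 * pi)
    drop(leg$p %*% w)
  }
  Ggg <- matrix(gkern(as.vector(u[good, ] %*% t(u[good, ]))),
                length(good), length(good))
  Gbg <- matrix(gkern(as.vector(u[bad, , drop = FALSE] %*% t(u[good, ]))),
                length(bad), length(good))
  ng <- length(good)
  A <- rbind(cbind(Ggg + lambda * diag(ng), rep(1, ng)), c(rep(1, ng), 0))
  dm <- dim(epochs$data)
  flat <- matrix(epochs$data, dm[1], dm[2] * dm[3])
  sol <- solve(A, rbind(flat[good, , drop = FALSE], 0))
  est <- Gbg %*% sol[seq_len(ng), , drop = FALSE] +
    matrix(sol[ng + 1, ], length(bad), ncol(flat), byrow = TRUE)
  flat[bad, ] <- est
  epochs$data <- array(flat, dm)
  epochs$interpolated_channels <- union(epochs$interpolated_channels,
                                        mon$labels[bad])
  epochs
}
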