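## Infomax ICA: sphering, decomposition, artifact-component flagging,
## and back-projection.
##
## Average-referenced scalp data are rank-deficient by one; sphering
## detects the rank and reduces the dimension, so the decomposition has
## rank-many components.  Scale/sign indeterminacy is fixed by unit-norm
## scalp maps with a positive maximum-absolute element.

#' Sphere (whiten) multichannel data
#'
#' Whitening to identity covariance: symmetric (ZCA) whitening at full
#' rank, so white input maps close to itself; when the input covariance
#' is rank deficient (e.g., after average referencing) the dimension is
#' reduced to the numerical rank via PCA whitening, which is reported
#' in the result.
#'
#' @param x channels x samples matrix, or an `epoched_eeg` (trials are
#'   concatenated)
#' @param rank_tol relative eigenvalue tolerance for rank detection
#' @return list with `data` (rank x samples, sphered), `sphering`
#'   (rank x channels), `unsphering` (channels x rank), `center`,
#'   `rank`
#' @export
sphere_data <- function(x, rank_tol = 1e-7) {
  if (inherits(x, "epoched_eeg")) {
    dm <- dim(x$data)
    x <- matrix(x$data, dm[1], dm[2] * dm[3])
  }
  stopifnot(is.matrix(x))
  if (ncol(x) <= nrow(x)) stop("need more samples than channels")
  ctr <- rowMeans(x)
  xc <- x - ctr
  cv <- tcrossprod(xc) / (ncol(x) - 1)
  eg <- eigen(cv, symmetric = TRUE)
  keep <- eg$values > max(eg$values) * rank_tol
  r <- sum(keep)
  if (r < nrow(x))
    message(sprintf("sphere_data: rank-deficient input, reducing %d -> %d dimensions",
                    nrow(x), r))
  V <- eg$vectors[, seq_len(r), drop = FALSE]
  d <- eg$values[seq_len(r)]
  if (r == nrow(x)) {                     # symmetric (ZCA) whitening
    S <- V %*% ((1 / sqrt(d)) * t(V))
    Sinv <- V %*% (sqrt(d) * t(V))
  } else {                                # reduced-rank PCA whitening
    S <- (1 / sqrt(d)) * t(V)
    Sinv <- V %*% diag(sqrt(d), r)
  }
  list(data = S %*% xc, sphering = S, unsphering = Sinv,
       center = ctr, rank = r)
}

#' Infomax ICA on sphered data
#'
#' Bell-Sejnowski information maximization with the logistic
#' nonlinearity and block-wise natural-gradient updates; the learning
#' rate anneals when successive weight changes turn by more than
#' `annealdeg` degrees.  Deterministic for a given `seed`.
#'
#' @param sphered output of [sphere_data()], or a rank x samples matrix
#'   of already-sphered data
#' @param seed integer seed for the per-pass sample permutation
#' @param lrate initial learning rate; default scales with 1/log(k)
#' @param block samples per natural-gradient update block
#' @param annealdeg,annealstep annealing schedule
#' @param tol convergence tolerance on the squared weight change per pass
#' @param max_iter maximum number of passes
#' @return list with the rotation `W` (rank x rank), `iterations`,
#'   `converged`
#' @export
infomax <- function(sphered, seed = 1L, lrate = 0, block = 0,
                    annealdeg = 60, annealstep = 0.9,
                    tol = 1e-6, max_iter = 512L) {
  x <- if (is.list(sphered)) sphered$data else sphered
  stopifnot(is.matrix(x))
  res <- .infomax_core(x, as.integer(seed), as.integer(block), lrate,
                       annealdeg, annealstep, tol, as.integer(max_iter))
  if (!res$converged)
    warning(sprintf("infomax did not converge in %d passes (change %.2e)",
                    res$iterations, res$final_change))
  res
}

#' Full ICA decomposition of epoched EEG
#'
#' Sphering followed by Infomax; returns scalp maps (columns of the
#' mixing matrix), activations, and the matrices needed for
#' back-projection.  Maps are unit-norm with positive max-abs element.
#'
#' @param epochs an `epoched_eeg`
#' @param channels channel indices to decompose (default: scalp
#'   channels of the montage, or all channels without a montage)
#' @param seed integer seed
#' @param ... passed to [infomax()]
#' @return object of class `ic_decomposition`: `unmixing` (comps x
#'   channels, includes sphering), `mixing` (channels x comps),
#'   `scalp_maps`, `activations` (comps x samples*trials), `channels`,
#'   `center`, `n_samples`, `n_trials`, `converged`
#' @export
ica_decompose <- function(epochs, channels = NULL, seed = 1L, ...) {
  stopifnot(inherits(epochs, "epoched_eeg"))
  if (is.null(channels)) {
    channels <- if (!is.null(epochs$montage)) scalp_channels(epochs$montage)
                else seq_len(dim(epochs$data)[1])
  }
  dm <- dim(epochs$data)
  x <- matrix(epochs$data[channels, , , drop = FALSE],
              length(channels), dm[2] * dm[3])
  sph <- sphere_data(x)
  im <- infomax(sph, seed = seed, ...)
  unmix <- im$W %*% sph$sphering          # comps x channels
  mix <- pinv(unmix)                      # channels x comps
  ## fix scale and sign: unit-norm maps, positive max-abs element
  for (k in seq_len(ncol(mix))) {
    nrm <- sqrt(sum(mix[, k]^2))
    if (nrm > 0) {
      sgn <- sign(mix[which.max(abs(mix[, k])), k])
      if (sgn == 0) sgn <- 1
      mix[, k] <- mix[, k] / (nrm * sgn)
      unmix[k, ] <- unmix[k, ] * nrm * sgn
    }
  }
  act <- unmix %*% (x - sph$center)
  structure(list(unmixing = unmix, mixing = mix, scalp_maps = mix,
                 activations = act, channels = channels,
                 center = sph$center, sphering = sph$sphering,
                 n_samples = dm[2], n_trials = dm[3],
                 rank = sph$rank, converged = im$converged,
                 iterations = im$iterations, seed = seed),
            class = "ic_decomposition")
}

#' @export
print.ic_decomposition <- function(x, ...) {
  cat(sprintf("ic_decomposition: %d components from %d channels (%s, %d passes)\n",
              nrow(x$unmixing), length(x$channels),
              if (x$converged) "converged" else "not converged", x$iterations))
  invisible(x)
}

#' Activations of one component as a samples x trials matrix
#' @param decomp an `ic_decomposition`
#' @param k component index
#' @return samples x trials matrix
#' @export
ic_activation <- function(decomp, k) {
  matrix(decomp$activations[k, ], decomp$n_samples, decomp$n_trials)
}

## power spectrum (dB) of each component's activation, for the spectral
## slope metric and for cluster features
activation_spectrum <- function(act, n_samples, sampling_rate) {
  n_trials <- ncol(act) %/% 1
  nf <- n_samples %/% 2
  p <- abs(stats::mvfft(act))^2
  p <- rowMeans(p[2:(nf + 1), , drop = FALSE])
  freqs <- (1:nf) / n_samples * sampling_rate
  list(freqs = freqs, db = 10 * log10(p))
}

#' Flag artifact components
#'
#' FASTER-style statistical flagging: three per-component metrics --
#' maximum absolute correlation of the activation with the EOG channel
#' time courses, activation kurtosis, and the slope of the log-log
#' power spectrum -- are z-scored across components.  A component is
#' flagged when its EOG metric exceeds `z_eog` or a general metric
#' exceeds `z_general` in absolute value.
#'
#' @param decomp an `ic_decomposition`
#' @param epochs the `epoched_eeg` it was computed on
#' @param eog_labels EOG channel labels; default taken from the montage.
#'   With no EOG channels the EOG metric is skipped with a warning.
#' @param z_general threshold for kurtosis and spectral slope; default 3
#' @param z_eog threshold for the EOG correlation metric; default 2
#' @param eog_min_corr absolute-correlation floor for the EOG
#'   criterion: a component is only called ocular when, besides the
#'   z-score, its raw correlation with an EOG trace is substantive.
#'   EOG electrodes record genuine brain activity, so the z-score
#'   alone would mislabel strong frontal/parietal sources.
#' @return integer vector of flagged component indices, with a
#'   `metrics` attribute containing the z-scores
#' @export
flag_artifact_ics <- function(decomp, epochs, eog_labels = NULL,
                              z_general = 3, z_eog = 2,
                              eog_min_corr = 0.65) {
  k <- nrow(decomp$unmixing)
  if (is.null(eog_labels) && !is.null(epochs$montage))
    eog_labels <- epochs$montage$eog_channels
  zs <- list()
  if (length(eog_labels)) {
    eidx <- match(eog_labels, epochs$montage$labels)
    dm <- dim(epochs$data)
    eog <- matrix(epochs$data[eidx, , , drop = FALSE],
                  length(eidx), dm[2] * dm[3])
    cc <- abs(stats::cor(t(decomp$activations), t(eog)))
    raw_eog <- apply(cc, 1, max)
    zs$eog_corr <- zscore0(raw_eog)
  } else {
    warning("no EOG channels; EOG correlation metric skipped")
  }
  zs$kurtosis <- zscore0(apply(decomp$activations, 1, kurtosis))
  slope <- sapply(seq_len(k), function(i) {
    sp <- activation_spectrum(ic_activation(decomp, i), decomp$n_samples,
                              epochs$sampling_rate)
    stats::coef(stats::lm(sp$db ~ log10(sp$freqs)))[2]
  })
  zs$spec_slope <- zscore0(slope)
  ## EOG correlation and kurtosis are one-sided (artifacts are *more*
  ## ocular-correlated and *more* spiky than neural components); the
  ## spectral slope is two-sided (drift-like and muscle-like tails)
  flags <- rep(FALSE, k)
  if (!is.null(zs$eog_corr))
    flags <- flags | (zs$eog_corr > z_eog & raw_eog >= eog_min_corr)
  flags <- flags | zs$kurtosis > z_general | abs(zs$spec_slope) > z_general
  structure(which(flags), metrics = as.data.frame(zs))
}

#' Remove components and back-project
#'
#' Reconstructs the analyzed channels from all components except the
#' listed ones.  Removing the empty set reproduces the input (up to
#' numerical precision on full-rank data).
#'
#' @param decomp an `ic_decomposition`
#' @param indices components to remove
#' @param epochs the `epoched_eeg` the decomposition came from
#' @return `epoched_eeg` with cleaned data in the decomposed channels
#' @export
remove_ics <- function(decomp, indices, epochs) {
  k <- nrow(decomp$unmixing)
  indices <- as.integer(indices)
  if (length(indices)) stopifnot(all(indices >= 1), all(indices <= k))
  if (length(unique(indices)) >= k) stop("cannot remove all components")
  keep <- setdiff(seq_len(k), indices)
  recon <- decomp$mixing[, keep, drop = FALSE] %*%
    decomp$activations[keep, , drop = FALSE] + decomp$center
  dm <- dim(epochs$data)
  epochs$data[decomp$channels, , ] <-
    array(recon, c(length(decomp$channels), dm[2], dm[3]))
  epochs
}
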