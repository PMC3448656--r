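## Morlet-wavelet time-frequency decomposition, ERSP and ITC.
##
## ERSP(f,t) = 10*log10( mean_trials |c(f,t)|^2 / baseline(f) ), with
## baseline(f) the pre-stimulus mean of the trial-mean power.
## ITC(f,t)  = | mean_trials c(f,t)/|c(f,t)| |, in [0, 1].

#' Default time-frequency grid
#'
#' 100 log-spaced frequencies spanning 3-256 Hz, optionally truncated
#' (analyses of theta/alpha/beta effects live below ~45 Hz, so pipeline
#' presets truncate to keep desk-scale runs light).
#'
#' @param n number of frequencies of the full grid
#' @param fmin,fmax full-grid range, Hz
#' @param truncate upper cutoff; frequencies above it are removed after
#'   constructing the full grid (NULL keeps the whole grid)
#' @return numeric vector of frequencies, strictly increasing
#' @export
tf_freqs <- function(n = 100, fmin = 3, fmax = 256, truncate = NULL) {
  f <- exp(seq(log(fmin), log(fmax), length.out = n))
  if (!is.null(truncate)) f <- f[f <= truncate]
  f
}

## per-frequency wavelet window length in seconds under a cycle rule
wavelet_window <- function(freqs, cycle_rule) {
  kind <- cycle_rule$kind %||% "cap"
  if (kind == "cap") {
    ## window capped at max_s; never longer than c_max cycles
    pmin((cycle_rule$c_max %||% 12) / freqs, cycle_rule$max_s %||% 0.185)
  } else if (kind == "ncycles") {
    (cycle_rule$cycles %||% 3) / freqs
  } else stop("unknown cycle_rule kind: ", kind)
}

#' Morlet wavelet coefficients
#'
#' Complex analytic amplitude per frequency, latency, and trial, from
#' convolution with Gaussian-enveloped complex exponentials.  Under the
#' default cycle rule the wavelet window is capped at 185 ms (and at
#' `c_max` cycles at high frequencies), so the longest realized window
#' is 185 ms.  The kernel is amplitude-normalized: a pure sinusoid of
#' amplitude A at a grid frequency yields |coefficient| ~ A.
#'
#' The common time axis is restricted to latencies with full wavelet
#' support at every retained frequency.  Frequencies whose window does
#' not fit in the epoch, or at/above Nyquist, are dropped with a
#' warning.
#'
#' @param x samples x trials matrix (one channel's or component's
#'   epoched activity), or a vector for a single trial
#' @param sampling_rate Hz
#' @param freqs analysis frequencies, Hz
#' @param cycle_rule list: `kind = "cap"` (default) with `max_s`
#'   (0.185) and `c_max` (12), or `kind = "ncycles"` with `cycles`
#' @param t0_ms latency of the first sample, ms (epoch start)
#' @return complex array freqs x times x trials with attributes
#'   `freqs`, `times` (ms)
#' @export
morlet_coeffs <- function(x, sampling_rate, freqs = tf_freqs(),
                          cycle_rule = list(kind = "cap"), t0_ms = 0) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  ns <- nrow(x); ntr <- ncol(x)
  win_s <- wavelet_window(freqs, cycle_rule)
  half <- floor(win_s * sampling_rate / 2)      # half-kernel in samples
  ok <- freqs < sampling_rate / 2 & (2 * half + 1) <= ns & half >= 1
  if (!all(ok)) {
    warning(sprintf("dropping %d frequencies (window does not fit or >= Nyquist)",
                    sum(!ok)))
    freqs <- freqs[ok]; half <- half[ok]
  }
  if (!length(freqs)) stop("no usable frequency")
  hmax <- max(half)
  tidx <- (hmax + 1):(ns - hmax)                # full support everywhere
  nt <- length(tidx)
  nfft <- stats::nextn(ns + 2 * hmax + 1, 2)
  Xf <- stats::mvfft(rbind(x, matrix(0, nfft - ns, ntr)))
  out <- array(0i, c(length(freqs), nt, ntr))
  for (i in seq_along(freqs)) {
    h <- half[i]
    tt <- (-h:h) / sampling_rate
    L <- (2 * h + 1) / sampling_rate
    env <- exp(-tt^2 / (2 * (L / 7)^2))         # truncated at +/- 3.5 sd
    kern <- env * exp(2i * pi * freqs[i] * tt)
    kern <- kern / (sum(env) / 2)               # amplitude normalization
    Kf <- stats::fft(c(kern, rep(0, nfft - length(kern))))
    conv <- stats::mvfft(Xf * Kf, inverse = TRUE) / nfft
    ## kernel center sits at lag h: the coefficient aligned with input
    ## sample t is linear-convolution row t + h
    out[i, , ] <- conv[tidx + h, , drop = FALSE]
  }
  times <- t0_ms + (tidx - 1) / sampling_rate * 1000
  structure(out, freqs = freqs, times = times, class = "tf_coeffs")
}

#' Event-related spectral perturbation (dB)
#'
#' @param coeffs a `tf_coeffs` array from [morlet_coeffs()]
#' @param baseline_window `(from, to)` ms; must intersect the
#'   coefficient time axis
#' @return freqs x times matrix of dB changes from the baseline mean
#' @export
ersp <- function(coeffs, baseline_window = c(-200, 0)) {
  times <- attr(coeffs, "times")
  bidx <- which(times >= baseline_window[1] & times < baseline_window[2])
  if (!length(bidx)) stop("baseline window outside the coefficient time axis")
  p <- apply(abs(unclass(coeffs))^2, c(1, 2), mean)       # F x T mean power
  base <- rowMeans(p[, bidx, drop = FALSE])
  if (any(base <= 0)) stop("zero baseline power")
  out <- 10 * log10(p / base)
  dimnames(out) <- NULL
  structure(out, freqs = attr(coeffs, "freqs"), times = times)
}

#' Inter-trial coherence
#'
#' Magnitude of the mean unit-phase vector across trials; zero-magnitude
#' coefficients are omitted from the mean at their pixel.
#'
#' @param coeffs a `tf_coeffs` array (needs >= 2 trials)
#' @return freqs x times matrix in [0, 1]
#' @export
itc <- function(coeffs) {
  a <- unclass(coeffs)
  if (dim(a)[3] < 2) stop("ITC needs at least 2 trials")
  mag <- abs(a)
  unit <- ifelse(mag > 0, a / mag, 0i)
  nz <- apply(mag > 0, c(1, 2), sum)
  if (any(nz < dim(a)[3]))
    message("itc: zero-magnitude coefficients omitted at some pixels")
  s <- apply(unit, c(1, 2), sum)
  out <- abs(s) / pmax(nz, 1)
  out[nz == 0] <- 0
  structure(out, freqs = attr(coeffs, "freqs"), times = attr(coeffs, "times"))
}

#' Time-frequency result for one signal
#'
#' Convenience wrapper: wavelet transform, ERSP, and ITC in one call,
#' optionally decimating the time axis of the output maps.
#'
#' @param x samples x trials matrix
#' @param sampling_rate Hz
#' @param freqs analysis frequencies
#' @param baseline_window ms pair for the ERSP baseline
#' @param t0_ms latency of the first sample
#' @param cycle_rule see [morlet_coeffs()]
#' @param decimate keep every `decimate`-th latency of the output maps
#' @return object of class `tf_result` with fields `freqs`, `times`,
#'   `ersp` (dB), `itc`, `n_trials`, `baseline_window`
#' @export
time_frequency <- function(x, sampling_rate, freqs = tf_freqs(truncate = 45),
                           baseline_window = c(-200, 0), t0_ms = -500,
                           cycle_rule = list(kind = "cap"), decimate = 1L) {
  co <- morlet_coeffs(x, sampling_rate, freqs, cycle_rule, t0_ms)
  e <- ersp(co, baseline_window)
  z <- itc(co)
  times <- attr(co, "times")
  keep <- seq(1, length(times), by = decimate)
  e <- e[, keep, drop = FALSE]; z <- z[, keep, drop = FALSE]
  attr(e, "freqs") <- attr(z, "freqs") <- attr(co, "freqs")
  attr(e, "times") <- attr(z, "times") <- times[keep]
  structure(list(freqs = attr(co, "freqs"), times = times[keep],
                 ersp = e, itc = z,
                 n_trials = dim(unclass(co))[3],
                 baseline_window = baseline_window),
            class = "tf_result")
}

#' @export
print.tf_result <- function(x, ...) {
  cat(sprintf("tf_result: %d freqs (%.1f-%.1f Hz) x %d latencies (%d trials)\n",
              length(x$freqs), min(x$freqs), max(x$freqs), length(x$times),
              x$n_trials))
  invisible(x)
}

#' Band summaries of a time-frequency result
#'
#' Mean ERSP and ITC in the conventional theta (4-8), alpha (8-13) and
#' beta (14-30 Hz) bands per latency.
#'
#' @param tf a `tf_result`
#' @param bands named list of `(lo, hi)` Hz pairs
#' @return data frame with band, time, ersp, itc
#' @export
band_summary <- function(tf, bands = list(theta = c(4, 8), alpha = c(8, 13),
                                          beta = c(14, 30))) {
  rows <- lapply(names(bands), function(b) {
    fi <- which(tf$freqs >= bands[[b]][1] & tf$freqs <= bands[[b]][2])
    if (!length(fi)) return(NULL)
    data.frame(band = b, time_ms = tf$times,
               ersp = colMeans(tf$ersp[fi, , drop = FALSE]),
               itc = colMeans(tf$itc[fi, , drop = FALSE]))
  })
  do.call(rbind, rows)
}
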