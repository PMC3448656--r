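## Four-shell concentric-sphere volume conductor.
##
## The potential generated on the scalp by a current dipole inside the
## innermost sphere is expanded in Legendre series.  Within each shell j
## the potential for harmonic order n is
##   phi_j(r) = A_j (r / r_j)^n + B_j (r_{j-1} / r)^(n+1)
## (scaled bases keep the boundary system well conditioned at high n).
## The dipole contributes the known singular term of a current dipole in
## an infinite medium; continuity of potential and of radial current
## density at the three interfaces plus the insulating outer boundary
## determine the coefficients.  Radial and tangential dipole components
## share the same radial transfer factor, so one small linear solve per
## order serves both.

#' Four-shell spherical head model
#'
#' Concentric-sphere volume conductor with four compartments (brain,
#' CSF, skull, scalp).  Default geometry and conductivities are the
#' de facto spherical-model conventions of the EEG literature; all
#' values are configurable.
#'
#' @param radii outer radii of the four shells in mm, strictly
#'   increasing (brain, CSF, skull, scalp)
#' @param conductivities compartment conductivities in S/m
#' @param series_order truncation order of the Legendre expansion
#'   (default 80: series tail below 1e-6 for eccentricities up to ~0.84
#'   of the brain radius; a convergence check warns beyond)
#' @return object of class `head_model`
#' @examples
#' m <- head_model()
#' m$radii
#' @export
head_model <- function(radii = c(71, 72, 79, 85),
                       conductivities = c(0.33, 1.0, 0.0042, 0.33),
                       series_order = 80L) {
  stopifnot(length(radii) == 4, length(conductivities) == 4)
  if (any(diff(radii) <= 0)) stop("shell radii must be strictly increasing")
  if (any(conductivities <= 0)) stop("conductivities must be positive")
  series_order <- as.integer(series_order)
  if (series_order < 1L) stop("series_order must be >= 1")
  structure(list(radii = as.numeric(radii),
                 conductivities = as.numeric(conductivities),
                 series_order = series_order),
            class = "head_model")
}

#' @export
print.head_model <- function(x, ...) {
  cat("Four-shell spherical head model\n")
  cat(sprintf("  radii (mm):          %s\n", paste(x$radii, collapse = " / ")))
  cat(sprintf("  conductivity (S/m):  %s\n",
              paste(format(x$conductivities), collapse = " / ")))
  cat(sprintf("  series order:        %d\n", x$series_order))
  invisible(x)
}

#' Current dipole
#'
#' @param position 3-vector, mm, head-center origin (+x right,
#'   +y anterior, +z superior)
#' @param moment 3-vector, nA*m
#' @param rv residual variance in [0, 1], or NULL when not fitted
#' @return object of class `dipole`
#' @export
dipole <- function(position, moment = c(0, 0, 0), rv = NULL) {
  position <- as.numeric(position); moment <- as.numeric(moment)
  stopifnot(length(position) == 3, length(moment) == 3)
  if (!is.null(rv)) {
    stopifnot(length(rv) == 1, rv >= 0, rv <= 1)
  }
  structure(list(position = position, moment = moment, rv = rv),
            class = "dipole")
}

#' @export
print.dipole <- function(x, ...) {
  cat(sprintf("dipole at (%.1f, %.1f, %.1f) mm, moment (%.2f, %.2f, %.2f) nA*m",
              x$position[1], x$position[2], x$position[3],
              x$moment[1], x$moment[2], x$moment[3]))
  if (!is.null(x$rv)) cat(sprintf(", rv = %.4f", x$rv))
  cat("\n")
  invisible(x)
}

#' Electrode montage
#'
#' @param labels unique channel names
#' @param positions n x 3 matrix, mm, same coordinate frame as the model
#' @param eog_channels subset of labels flagged as peri-ocular channels
#' @return object of class `sensor_array`
#' @export
sensor_array <- function(labels, positions, eog_channels = character()) {
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 3, nrow(positions) == length(labels))
  if (anyDuplicated(labels)) stop("channel labels must be unique")
  if (!all(eog_channels %in% labels)) stop("unknown EOG channel label")
  structure(list(labels = as.character(labels), positions = positions,
                 eog_channels = as.character(eog_channels)),
            class = "sensor_array")
}

#' @export
print.sensor_array <- function(x, ...) {
  cat(sprintf("sensor_array: %d channels (%d EOG)\n",
              length(x$labels), length(x$eog_channels)))
  invisible(x)
}

#' Indices of scalp (non-EOG) channels
#' @param sensors a `sensor_array`
#' @return integer vector
#' @export
scalp_channels <- function(sensors) {
  which(!(sensors$labels %in% sensors$eog_channels))
}

#' Project electrode positions radially onto the scalp sphere
#'
#' Digitized montages are never exactly spherical; positions are scaled
#' along their radius to the model's outer shell.
#'
#' @param sensors a `sensor_array`
#' @param model a `head_model`
#' @return `sensor_array` with positions on the outer shell
#' @export
project_to_scalp <- function(sensors, model) {
  r <- sqrt(rowSums(sensors$positions^2))
  if (any(r == 0)) stop("electrode at head center cannot be projected")
  sensors$positions <- sensors$positions * (model$radii[4] / r)
  sensors
}

#' Is a point strictly inside the model brain volume?
#'
#' Strict inequality: a point exactly on the innermost shell counts as
#' outside, matching the exclusion convention for fitted dipoles.
#'
#' @param position 3-vector (or n x 3 matrix), mm
#' @param model a `head_model`
#' @return logical
#' @export
is_inside_brain <- function(position, model) {
  if (is.matrix(position)) {
    sqrt(rowSums(position^2)) < model$radii[1]
  } else {
    sqrt(sum(position^2)) < model$radii[1]
  }
}

## Radial transfer factors T_n: scalp-surface potential coefficient per
## unit source coefficient, one boundary-value solve per order.  Depends
## only on the model, so cached.
shell_transfer <- function(model, nmax) {
  key <- paste0("st|", paste(signif(c(model$radii, model$conductivities), 12),
                             collapse = ","), "|", nmax)
  cache_get(key, function() {
    x <- model$radii / model$radii[4]     # scaled radii, x4 = 1
    s <- model$conductivities
    x1 <- x[1]; x2 <- x[2]; x3 <- x[3]
    tn <- numeric(nmax)
    for (n in seq_len(nmax)) {
      S1 <- x1^(-(n + 1))                  # source basis value at r1 (unit coeff)
      r12 <- (x1 / x2)^n; r23 <- (x2 / x3)^n; r34 <- x3^n
      q12 <- (x1 / x2)^(n + 1); q23 <- (x2 / x3)^(n + 1); q34 <- x3^(n + 1)
      ## unknowns: a1, a2, b2, a3, b3, a4, b4
      M <- matrix(0, 7, 7)
      b <- numeric(7)
      ## interface 1: potential, then sigma * d(phi)/dx * x1
      M[1, ] <- c(1, -r12, -1, 0, 0, 0, 0);               b[1] <- -S1
      M[2, ] <- c(s[1] * n, -s[2] * n * r12, s[2] * (n + 1), 0, 0, 0, 0)
      b[2] <- s[1] * (n + 1) * S1
      ## interface 2
      M[3, ] <- c(0, 1, q12, -r23, -1, 0, 0)
      M[4, ] <- c(0, s[2] * n, -s[2] * (n + 1) * q12,
                  -s[3] * n * r23, s[3] * (n + 1), 0, 0)
      ## interface 3
      M[5, ] <- c(0, 0, 0, 1, q23, -r34, -1)
      M[6, ] <- c(0, 0, 0, s[3] * n, -s[3] * (n + 1) * q23,
                  -s[4] * n * r34, s[4] * (n + 1))
      ## insulating outer boundary at x = 1
      M[7, ] <- c(0, 0, 0, 0, 0, n, -(n + 1) * q34)
      u <- solve(M, b)
      tn[n] <- u[6] + u[7] * q34          # phi_4(1) = a4 + b4 * x3^(n+1)
    }
    tn
  })
}

#' Lead-field (gain) matrix of a dipole position
#'
#' Potential at each sensor per unit moment along x, y, z, in uV per
#' nA*m, average-referenced across the given sensors.
#'
#' @param position dipole position, mm, strictly inside the brain shell
#' @param sensors a `sensor_array`; positions are used as directions and
#'   evaluated on the outer shell surface
#' @param model a `head_model`
#' @param series_order override the model's truncation order
#' @param check_convergence warn when the series tail has not decayed;
#'   disable for deliberately coarse scans
#' @return channels x 3 matrix with zero column means; attribute
#'   `converged` reports the series convergence check
#' @export
forward_gain <- function(position, sensors, model,
                         series_order = model$series_order,
                         check_convergence = TRUE) {
  b_mm <- as.numeric(position)
  bnorm <- sqrt(sum(b_mm^2))
  if (bnorm >= model$radii[1])
    stop("dipole position at or outside the model brain volume")
  nmax <- as.integer(series_order)
  tn <- shell_transfer(model, nmax)

  r4 <- model$radii[4] * 1e-3             # m
  sig1 <- model$conductivities[1]
  bx <- bnorm / model$radii[4]            # scaled eccentricity (vs scalp)

  ## sensor unit directions
  sp <- sensors$positions
  sr <- sqrt(rowSums(sp^2))
  if (any(sr == 0)) stop("sensor at origin")
  shat <- sp / sr
  m <- nrow(shat)

  if (bnorm < 1e-9) {
    bhat <- c(0, 0, 1)                    # direction irrelevant at center
  } else {
    bhat <- b_mm / bnorm
  }
  cosg <- pmin(1, pmax(-1, drop(shat %*% bhat)))
  leg <- legendre_table(cosg, nmax)

  ## s_perp = shat - cosg * bhat, the tangent-plane projection at bhat
  sperp <- shat - outer(cosg, bhat)
  proj_t <- diag(3) - outer(bhat, bhat)

  ## G = sum_n k_n [ n P_n bhat^T + P'_n sperp^T (I - bhat bhat^T) ]
  ## accumulated in closed matrix form: radial part is rank one in bhat,
  ## tangential part row-scales the fixed tangent projection
  nn <- seq_len(nmax)
  kn <- tn * bx^(nn - 1)                  # bx^(n-1); 0^0 = 1 handles center
  Sperp <- sperp %*% proj_t
  gpart <- function(idx) {
    a <- drop(leg$p[, idx, drop = FALSE] %*% (kn[idx] * nn[idx]))
    b <- drop(leg$dp[, idx, drop = FALSE] %*% kn[idx])
    outer(a, bhat) + b * Sperp
  }
  G <- gpart(nn)
  tail_norm <- sum(gpart(tail(nn, 5))^2)
  tot_norm <- sum(G^2)
  G <- G / (4 * pi * sig1 * r4^2)         # volts per A*m
  G <- G * 1e-9 * 1e6                     # uV per nA*m
  G <- sweep(G, 2, colMeans(G))           # average reference
  converged <- tot_norm == 0 || sqrt(tail_norm / tot_norm) < 1e-6
  if (!converged && check_convergence)
    warning("Legendre series not converged at order ", nmax)
  attr(G, "converged") <- converged
  G
}

#' Scalp potentials of a current dipole
#'
#' @param dip a `dipole` (position mm, moment nA*m)
#' @param sensors a `sensor_array`
#' @param model a `head_model`
#' @param series_order override the model's truncation order
#' @return per-channel potential vector in uV, average-referenced;
#'   attribute `converged` as in [forward_gain()]
#' @export
forward_potentials <- function(dip, sensors, model,
                               series_order = model$series_order) {
  G <- forward_gain(dip$position, sensors, model, series_order)
  v <- drop(G %*% dip$moment)
  names(v) <- sensors$labels
  attr(v, "converged") <- attr(G, "converged")
  v
}
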