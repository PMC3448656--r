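## Equivalent-dipole inverse fitting of IC scalp maps.
##
## Position is found by nonlinear least squares (coarse multi-start
## grid followed by Nelder-Mead refinement); for any candidate position
## the optimal moment is a linear least-squares solve against the
## lead-field, so the objective is the residual variance of the map.

#' Residual variance of a modeled scalp map
#'
#' Both maps are average-referenced first; RV is the fraction of
#' observed map power left unexplained,
#' `||obs - model||^2 / ||obs||^2`.
#'
#' @param observed,model numeric vectors of equal length
#' @return fraction in [0, ...]; 0 means a perfect model
#' @export
residual_variance <- function(observed, model) {
  stopifnot(length(observed) == length(model))
  o <- observed - mean(observed)
  m <- model - mean(model)
  denom <- sum(o^2)
  if (denom == 0) stop("observed map is zero after average referencing")
  sum((o - m)^2) / denom
}

## rv of the best linear moment at a fixed position; returns moment too
rv_at_position <- function(position, map, sensors, model, series_order = NULL) {
  G <- forward_gain(position, sensors, model,
                    series_order %||% model$series_order,
                    check_convergence = FALSE)
  mom <- qr.solve(G, map)
  fit <- drop(G %*% mom)
  list(rv = residual_variance(map, fit), moment = mom, fitted = fit)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## coarse search grid (cached per model geometry): eccentricity shells
## times near-uniform directions
dipfit_grid <- function(model, ecc = c(0.3, 0.55, 0.8), n_dir = 162) {
  dirs <- fibonacci_sphere(n_dir)
  do.call(rbind, lapply(ecc * model$radii[1], function(r) r * dirs))
}

## grid lead-fields are sensor-layout dependent but dipole independent;
## cache them keyed by montage + model
grid_gains <- function(sensors, model, grid, series_order) {
  key <- paste0("gg|", paste(signif(sensors$positions, 8), collapse = ","),
                "|", paste(signif(c(model$radii, model$conductivities), 10),
                           collapse = ","),
                "|", series_order, "|", nrow(grid))
  cache_get(key, function() {
    gains <- lapply(seq_len(nrow(grid)), function(i)
      forward_gain(grid[i, ], sensors, model, series_order,
                   check_convergence = FALSE))
    ## orthonormal basis of each gain's column space, stacked so one
    ## matrix product scores every grid position against a map
    qs <- lapply(gains, function(G) qr.Q(qr(G)))
    list(gains = gains, qstack = t(do.call(cbind, qs)),
         qdims = vapply(qs, ncol, integer(1)))
  })
}

## residual variance of a map at every grid position at once
grid_rv_scan <- function(gg, map) {
  proj <- (gg$qstack %*% map)^2
  idx <- rep.int(seq_along(gg$qdims), gg$qdims)
  expl <- rowsum(proj, idx)
  1 - drop(expl) / sum(map^2)
}

#' Fit a single equivalent current dipole to a scalp map
#'
#' Multi-start search: residual variance is evaluated on a coarse grid
#' of positions (3 eccentricity shells x 162 directions); the best
#' `n_restarts` grid points seed Nelder-Mead refinements of the
#' position, with the moment solved linearly at every step.  If the
#' optimizer leaves the brain volume the position is projected back
#' inside and the result flagged.
#'
#' @param map average-referenced scalp map, one value per sensor
#' @param sensors a `sensor_array` (same order as `map`)
#' @param model a `head_model`
#' @param n_restarts number of grid seeds refined; default 3
#' @param seed unused randomness guard (the search is deterministic);
#'   kept for interface stability
#' @param grid_order series order used during the coarse grid scan
#' @param refine_order series order during local refinement (the final
#'   rv is evaluated at the model's full order)
#' @param rv_hopeless grid-rv ceiling above which the map is treated
#'   as non-dipolar and refined only briefly
#' @return a `dipole` with `rv` set; attributes `projected` (logical)
#'   and `grid_rv` (best coarse-grid rv)
#' @export
fit_single_dipole <- function(map, sensors, model, n_restarts = 3,
                              seed = 1L, grid_order = 20L,
                              refine_order = 40L, rv_hopeless = 0.5) {
  stopifnot(length(map) == length(sensors$labels))
  map <- map - mean(map)
  if (all(map == 0)) stop("cannot fit a zero scalp map")
  grid <- dipfit_grid(model)
  gg <- grid_gains(sensors, model, grid, grid_order)
  grv <- grid_rv_scan(gg, map)
  ## maps no dipole can plausibly explain (noise components) get a
  ## single short refinement; dipolar maps the full multi-start search
  hopeless <- min(grv) > rv_hopeless
  n_starts <- if (hopeless) 1L else min(n_restarts, nrow(grid))
  maxit <- if (hopeless) 25L else 250L
  seeds <- order(grv)[seq_len(n_starts)]

  rmax <- model$radii[1]
  obj <- function(p) {
    r <- sqrt(sum(p^2))
    pen <- 0
    if (r >= 0.995 * rmax) {            # keep the search inside the brain
      p <- p * (0.995 * rmax / r)
      pen <- (r - 0.995 * rmax)^2 * 1e-2
    }
    rv_at_position(p, map, sensors, model, refine_order)$rv + pen
  }
  best <- NULL
  for (s in seeds) {
    fit <- stats::optim(grid[s, ], obj, method = "Nelder-Mead",
                        control = list(reltol = 1e-9, maxit = maxit))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  pos <- best$par
  projected <- FALSE
  r <- sqrt(sum(pos^2))
  if (r >= 0.995 * rmax) {
    pos <- pos * (0.995 * rmax / r)
    projected <- TRUE
  }
  final <- rv_at_position(pos, map, sensors, model)
  out <- dipole(pos, final$moment, rv = min(1, final$rv))
  attr(out, "projected") <- projected
  attr(out, "grid_rv") <- min(grv)
  out
}

#' Component-quality filter
#'
#' Keeps IC records whose fitted dipole explains the scalp map with at
#' most `rv_max` residual variance *and* lies strictly inside the model
#' brain volume.  The boundary is kept: exclusion applies to RV
#' strictly greater than `rv_max`.  Input order is preserved.
#'
#' @param ic_records list of records, each with a `dipole` field
#'   carrying `rv`
#' @param rv_max residual-variance ceiling; default 0.15
#' @param model a `head_model`
#' @return the kept sublist, with attribute `kept` (logical vector)
#' @export
select_components <- function(ic_records, rv_max = 0.15, model = head_model()) {
  if (!length(ic_records)) return(ic_records[0])
  keep <- vapply(ic_records, function(rec) {
    d <- rec$dipole
    !is.null(d$rv) && d$rv <= rv_max && is_inside_brain(d$position, model)
  }, logical(1))
  structure(ic_records[keep], kept = keep)
}

#' Nominal affine into a Talairach-like space
#'
#' A fixed scaling/translation from model coordinates (mm, head-center
#' origin) to a Talairach-like frame for reporting cluster centroids.
#' Nominal plumbing only -- not a subject-specific registration.
#'
#' @param position 3-vector or n x 3 matrix, model mm
#' @return same shape, Talairach-like mm
#' @export
to_talairach <- function(position) {
  scale <- c(0.92, 0.97, 0.92)
  shift <- c(0, -18, -15)
  if (is.matrix(position)) {
    sweep(sweep(position, 2, scale, `*`), 2, shift, `+`)
  } else {
    position * scale + shift
  }
}

#' Write a dipole table
#'
#' TSV with one row per fitted component: subject, IC index, position,
#' moment, residual variance and the inside-brain flag.
#'
#' @param records list of IC records (fields `subject_id`, `ic_index`,
#'   `dipole`)
#' @param path output path
#' @param model head model for the inside-brain flag
#' @export
write_dipole_table <- function(records, path, model = head_model()) {
  rows <- lapply(records, function(r) {
    d <- r$dipole
    data.frame(subject = r$subject_id, ic_index = r$ic_index,
               x = d$position[1], y = d$position[2], z = d$position[3],
               mx = d$moment[1], my = d$moment[2], mz = d$moment[3],
               rv = d$rv %||% NA_real_,
               inside = is_inside_brain(d$position, model))
  })
  tab <- do.call(rbind, rows)
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(tab)
}
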