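## Electrode file IO and synthetic montage construction.

#' Read an electrode position file
#'
#' Whitespace-delimited text, one row per channel: `label x y z` with
#' coordinates in mm (sfp-style).  Channels whose label starts with
#' "EOG" are flagged as peri-ocular unless `eog_channels` is given.
#'
#' @param path file path
#' @param eog_channels labels to flag as EOG; default auto-detects by
#'   the "EOG" prefix
#' @return a `sensor_array`
#' @export
read_electrodes <- function(path, eog_channels = NULL) {
  tab <- utils::read.table(path, header = FALSE, col.names = c("label", "x", "y", "z"),
                           colClasses = c("character", rep("numeric", 3)))
  if (is.null(eog_channels)) eog_channels <- tab$label[grepl("^EOG", tab$label)]
  sensor_array(tab$label, as.matrix(tab[, c("x", "y", "z")]), eog_channels)
}

#' Write an electrode position file
#'
#' Inverse of [read_electrodes()]; coordinates are written with six
#' decimals so a read/write round trip is exact to 1e-6 mm.
#'
#' @param sensors a `sensor_array`
#' @param path file path
#' @export
write_electrodes <- function(sensors, path) {
  lines <- sprintf("%s\t%.6f\t%.6f\t%.6f", sensors$labels,
                   sensors$positions[, 1], sensors$positions[, 2],
                   sensors$positions[, 3])
  writeLines(lines, path)
  invisible(path)
}

#' Build a synthetic spherical montage
#'
#' Scalp electrodes are placed on a Fibonacci lattice over the upper
#' part of the scalp sphere (down to ~30 degrees below the equator at
#' the sides, as in extended 10-5 layouts); two EOG channels sit at
#' low-anterior positions near the eyes.  The scalp channel closest to
#' the standard Pz direction is labelled "Pz" so channel-level analyses
#' have a canonical parietal site.
#'
#' @param n_scalp number of scalp channels
#' @param n_eog number of EOG channels (0, 1 or 2)
#' @param radius scalp sphere radius, mm
#' @return a `sensor_array`
#' @export
make_montage <- function(n_scalp = 32, n_eog = 2, radius = 85) {
  i <- seq_len(n_scalp) - 0.5
  z <- 1 - 1.4 * i / n_scalp              # cap from vertex down past the ears
  phi <- pi * (1 + sqrt(5)) * i
  r <- sqrt(pmax(0, 1 - z^2))
  pos <- radius * cbind(r * cos(phi), r * sin(phi), z)
  labels <- sprintf("C%02d", seq_len(n_scalp))
  ## canonical parietal site
  pz_dir <- c(0, -sin(50 * pi / 180), cos(50 * pi / 180))
  d <- drop(pos %*% pz_dir)
  labels[which.max(d)] <- "Pz"
  eogpos <- matrix(numeric(0), 0, 3)
  eoglab <- character(0)
  if (n_eog > 0) {
    eyes <- rbind(c(-28, 75, -25), c(28, 75, -25))
    eyes <- eyes / sqrt(rowSums(eyes^2)) * radius
    eogpos <- eyes[seq_len(min(n_eog, 2)), , drop = FALSE]
    eoglab <- paste0("EOG", seq_len(nrow(eogpos)))
  }
  sensor_array(c(labels, eoglab), rbind(pos, eogpos), eoglab)
}
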