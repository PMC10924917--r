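# First processing stage of raw projections: flat-field normalisation to
# transmittance and suppression of the sinogram column structure that
# reconstructs as ring artifacts.

#' Flat-field correction
#'
#' Normalises raw counts to transmittance
#' `T = (I - mean(darks)) / (mean(flats) - mean(darks))`, clipping to a small
#' positive floor so downstream logarithms stay finite.
#'
#' @param stack a `projection_stack` with at least one flat and one dark.
#' @param floor transmittance floor applied after normalisation.
#' @return array `[n_proj, n_rows, n_cols]` of transmittance values.
#' @export
flat_field_correct <- function(stack, floor = 1e-6) {
  stopifnot(inherits(stack, "projection_stack"), floor > 0)
  if (dim(stack$flats)[1] < 1 || dim(stack$darks)[1] < 1) {
    stop_vh("need at least one flat and one dark frame")
  }
  fbar <- apply(stack$flats, c(2, 3), mean)
  dbar <- apply(stack$darks, c(2, 3), mean)
  bad <- sum(fbar <= dbar)
  if (bad > 0) {
    stop_vh("flat field does not exceed dark field on %d pixel(s); cannot normalise", bad)
  }
  d <- dim(stack$projections)
  out <- array(0, d)
  denom <- fbar - dbar
  for (a in seq_len(d[1])) {
    out[a, , ] <- (matrix(stack$projections[a, , ], d[2], d[3]) - dbar) / denom
  }
  pmax(out, floor)
}

#' Sinogram of one detector row
#'
#' @param trans transmittance array from [flat_field_correct()] (or any
#'   `[n_proj, n_rows, n_cols]` array).
#' @param geom the `scan_geometry` of the acquisition.
#' @param row detector row to extract (1-based).
#' @return object of class `sinogram`: matrix `values` `[n_proj x n_cols]`,
#'   `angles_deg`, `pixel_um`.
#' @export
as_sinogram <- function(trans, geom, row = 1) {
  stopifnot(length(dim(trans)) == 3, row >= 1, row <= dim(trans)[2])
  v <- matrix(trans[, row, ], dim(trans)[1], dim(trans)[3])
  if (!all(is.finite(v))) stop_vh("sinogram contains non-finite values")
  structure(list(values = v, angles_deg = geom$angles_deg,
                 pixel_um = geom$pixel_um),
            class = "sinogram")
}

#' Construct a sinogram from a plain matrix
#' @param values matrix `[n_angles x n_cols]`.
#' @param angles_deg projection angles (defaults to even spacing over 180).
#' @param pixel_um pixel size.
#' @export
sinogram <- function(values, angles_deg = NULL, pixel_um = 1) {
  stopifnot(is.matrix(values))
  if (!all(is.finite(values))) stop_vh("sinogram contains non-finite values")
  n <- nrow(values)
  angles_deg <- angles_deg %||% (180 * (seq_len(n) - 1) / n)
  stopifnot(length(angles_deg) == n)
  structure(list(values = values, angles_deg = angles_deg, pixel_um = pixel_um),
            class = "sinogram")
}

#' Ring-artifact suppression
#'
#' Removes the angle-constant column structure of a sinogram: the column
#' mean profile is smoothed with a moving median and the residual (high
#' frequency, angle-invariant part) is subtracted from every projection.
#' The residual is re-centred so the overall sinogram mean is preserved
#' exactly. A second application changes little (near idempotence).
#'
#' @param sino a `sinogram` with at least 8 angles and 2 columns.
#' @param window moving-median window (odd, in columns).
#' @return corrected `sinogram`.
#' @export
remove_rings <- function(sino, window = 9) {
  stopifnot(inherits(sino, "sinogram"))
  v <- sino$values
  if (nrow(v) < 8) stop_vh("ring removal needs at least 8 angles (got %d)", nrow(v))
  if (ncol(v) < 2) stop_vh("degenerate single-column sinogram")
  window <- min(as.integer(window), ncol(v) - (1 - ncol(v) %% 2))
  if (window %% 2 == 0) window <- window - 1L
  m <- colMeans(v)
  smooth <- stats::runmed(m, max(window, 3), endrule = "median")
  resid <- m - smooth
  resid <- resid - mean(resid)
  sino$values <- sweep(v, 2, resid, "-")
  sino
}
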