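# On-disk interchange: numbered 32-bit TIFF stacks with a JSON metadata
# sidecar. TIFF samples are stored rescaled to [0, 1]; the original value
# range lives in meta.json so readers restore physical units. The numbered
# layout (tomo_0000.tif / flat_0000.tif / dark_0000.tif) matches common
# synchrotron beamline conventions and serves as the real-data entry point.

.write_scaled_tiff <- function(m, path, rng) {
  s <- if (diff(rng) > 0) (m - rng[1]) / diff(rng) else m * 0
  tiff::writeTIFF(s, path, bits.per.sample = 32L)
}

.read_scaled_tiff <- function(path, rng) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  if (diff(rng) > 0) m * diff(rng) + rng[1] else m
}

#' Write a projection stack as numbered TIFFs + metadata
#'
#' Layout: `tomo_%04d.tif`, `flat_%04d.tif`, `dark_%04d.tif` and
#' `meta.json` holding the scan geometry, detector model and the count
#' range used for intensity scaling.
#'
#' @param stack a `projection_stack`.
#' @param dir output directory (created if needed).
#' @export
write_projection_stack <- function(stack, dir) {
  stopifnot(inherits(stack, "projection_stack"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rng <- range(stack$projections, stack$flats, stack$darks)
  d <- dim(stack$projections)
  for (a in seq_len(d[1])) {
    .write_scaled_tiff(matrix(stack$projections[a, , ], d[2], d[3]),
                       file.path(dir, sprintf("tomo_%04d.tif", a - 1)), rng)
  }
  for (f in seq_len(dim(stack$flats)[1])) {
    .write_scaled_tiff(matrix(stack$flats[f, , ], d[2], d[3]),
                       file.path(dir, sprintf("flat_%04d.tif", f - 1)), rng)
  }
  for (f in seq_len(dim(stack$darks)[1])) {
    .write_scaled_tiff(matrix(stack$darks[f, , ], d[2], d[3]),
                       file.path(dir, sprintf("dark_%04d.tif", f - 1)), rng)
  }
  meta <- list(kind = "projection_stack", value_range = rng,
               n_proj = d[1], n_rows = d[2], n_cols = d[3],
               geometry = stack$geom[setdiff(names(stack$geom), "angles_deg")],
               detector = unclass(stack$det))
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a projection stack written by [write_projection_stack()]
#' @param dir directory containing the TIFFs and `meta.json`.
#' @return a `projection_stack`.
#' @export
read_projection_stack <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  stopifnot(identical(meta$kind, "projection_stack"))
  rng <- as.numeric(meta$value_range)
  g <- meta$geometry
  geom <- suppressWarnings(scan_geometry(
    pixel_um = g$pixel_um, distance_mm = g$distance_mm,
    energy_keV = g$energy_keV, n_proj = g$n_proj, range_deg = g$range_deg,
    det_width = g$det_width, det_height = g$det_height,
    local_offset_px = g$local_offset_px, source_m = g$source_m))
  dt <- meta$detector
  det <- detector_model(n0 = dt$n0, dark_level = dt$dark_level,
                        dark_sigma = dt$dark_sigma, gain_sigma = dt$gain_sigma,
                        gain_drift_sigma = dt$gain_drift_sigma,
                        psf_sigma_px = dt$psf_sigma_px, n_flat = dt$n_flat,
                        n_dark = dt$n_dark, noise = dt$noise,
                        beam_hardening = dt$beam_hardening, seed = dt$seed)
  read_group <- function(prefix, n) {
    out <- array(0, c(n, meta$n_rows, meta$n_cols))
    for (i in seq_len(n)) {
      out[i, , ] <- .read_scaled_tiff(
        file.path(dir, sprintf("%s_%04d.tif", prefix, i - 1)), rng)
    }
    out
  }
  structure(list(projections = read_group("tomo", meta$n_proj),
                 flats = read_group("flat", det$n_flat),
                 darks = read_group("dark", det$n_dark),
                 geom = geom, det = det),
            class = "projection_stack")
}

#' Write a reconstructed volume as per-slice TIFFs + metadata
#' @param vol a `recon_volume`.
#' @param dir output directory.
#' @export
write_volume_tiff <- function(vol, dir) {
  stopifnot(inherits(vol, "recon_volume"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rng <- range(vol$volume)
  d <- dim(vol$volume)
  for (k in seq_len(d[3])) {
    .write_scaled_tiff(vol$volume[, , k],
                       file.path(dir, sprintf("slice_%04d.tif", k - 1)), rng)
  }
  meta <- list(kind = "recon_volume", value_range = rng, shape = d,
               voxel_size_um = vol$voxel_um, provenance = vol$provenance)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a volume written by [write_volume_tiff()]
#' @param dir directory containing slice TIFFs and `meta.json`.
#' @return a `recon_volume`.
#' @export
read_volume_tiff <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  stopifnot(identical(meta$kind, "recon_volume"))
  d <- as.integer(meta$shape)
  rng <- as.numeric(meta$value_range)
  vol <- array(0, d)
  for (k in seq_len(d[3])) {
    vol[, , k] <- .read_scaled_tiff(
      file.path(dir, sprintf("slice_%04d.tif", k - 1)), rng)
  }
  structure(list(volume = vol, voxel_um = meta$voxel_size_um,
                 provenance = meta$provenance),
            class = "recon_volume")
}
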