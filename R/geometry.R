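# Acquisition geometry and detector model for the synchrotron protocol:
# parallel monochromatic beam, sample rotated over 180 degrees, free-space
# propagation to an sCMOS detector. The supported (pixel, distance) presets
# mirror the beamline protocol: 4 um / 500 mm, 2.5 um / 250 mm, 1 um / 150 mm.

.geom_presets <- list(c(4, 500), c(2.5, 250), c(1, 150))

#' Scan geometry
#'
#' Describes one propagation-based CT acquisition: energy, effective pixel
#' size, propagation (sample-to-detector) distance, projection angles and
#' detector window. The default protocol acquires 1800 evenly spaced
#' projections over 180 degrees on a 2048-pixel-wide detector.
#'
#' @param pixel_um effective detector pixel size, micrometres.
#' @param distance_mm propagation distance, millimetres.
#' @param energy_keV monochromatic (effective) energy.
#' @param n_proj number of projections (>= 1).
#' @param range_deg angular range; angles are evenly spaced in `[0, range)`.
#' @param det_width,det_height detector size in pixels.
#' @param local_offset_px lateral offset of the detector window for
#'   local-area (interior) scans; 0 means centred.
#' @param source_m source-to-sample distance (informational; the forward
#'   model is parallel-beam, magnification 1).
#' @return object of class `scan_geometry`.
#' @export
scan_geometry <- function(pixel_um = 4, distance_mm = 500, energy_keV = 20,
                          n_proj = 1800, range_deg = 180,
                          det_width = 2048, det_height = 2048,
                          local_offset_px = 0, source_m = 22.3) {
  stopifnot(pixel_um > 0, distance_mm >= 0, n_proj >= 1,
            range_deg > 0, range_deg <= 360, det_width >= 1, det_height >= 1)
  preset_ok <- any(vapply(.geom_presets, function(p)
    isTRUE(all.equal(p, c(pixel_um, distance_mm))), logical(1)))
  if (!preset_ok) {
    warning(sprintf(
      "pixel/distance pair (%g um, %g mm) is not a protocol preset (4/500, 2.5/250, 1/150)",
      pixel_um, distance_mm), call. = FALSE)
  }
  angles <- range_deg * (seq_len(n_proj) - 1) / n_proj
  structure(list(
    energy_keV = energy_keV,
    lambda_m = xray_wavelength(energy_keV),
    pixel_um = pixel_um,
    distance_mm = distance_mm,
    n_proj = as.integer(n_proj),
    range_deg = range_deg,
    angles_deg = angles,
    det_width = as.integer(det_width),
    det_height = as.integer(det_height),
    local_offset_px = as.integer(local_offset_px),
    source_m = source_m
  ), class = "scan_geometry")
}

#' Lateral field of view of a geometry, in millimetres
#'
#' `det_width * pixel_um / 1000`; about 8 mm at 4 um pixels and 5 mm at
#' 2.5 um pixels on a 2048-pixel detector.
#' @param geom a `scan_geometry`.
#' @export
fov_mm <- function(geom) {
  stopifnot(inherits(geom, "scan_geometry"))
  geom$det_width * geom$pixel_um / 1000
}

#' Histology-section to block-thickness ratio
#'
#' Ratio of a microtome section thickness to the imaged sample height: a
#' standard ~5 um section of a ~5 mm tall block is about one-thousandth of
#' the tissue the CT volume covers.
#' @param section_um section thickness in micrometres.
#' @param block_mm imaged block height in millimetres.
#' @export
section_block_ratio <- function(section_um = 5, block_mm = 5) {
  stopifnot(section_um > 0, block_mm > 0)
  section_um / (block_mm * 1000)
}

#' @export
print.scan_geometry <- function(x, ...) {
  cat(sprintf(
    "scan_geometry: %.3g keV, %g um px, z = %g mm, %d proj over %g deg, det %dx%d%s\n",
    x$energy_keV, x$pixel_um, x$distance_mm, x$n_proj, x$range_deg,
    x$det_width, x$det_height,
    if (x$local_offset_px != 0) sprintf(", local offset %d px", x$local_offset_px) else ""))
  invisible(x)
}

#' Detector model
#'
#' Photon statistics and systematic structure of the detector: incident
#' photons per pixel, dark level/noise, a static per-column gain map (the
#' source of ring artifacts), Gaussian point-spread blur standing in for
#' scintillator/optics blur, and an optional quadratic attenuation-bias
#' coefficient emulating beam hardening of a polychromatic beam.
#'
#' @param n0 incident photons per pixel per projection (>= 0).
#' @param dark_level mean dark counts.
#' @param dark_sigma Gaussian dark-noise standard deviation.
#' @param gain_sigma standard deviation of the per-column multiplicative gain
#'   (mean-1 normalised); 0 gives unit gains. Static gain applies to flats
#'   and projections alike and cancels in flat-fielding.
#' @param gain_drift_sigma standard deviation of a per-column gain drift
#'   applied to the sample projections only (the gain state having drifted
#'   since the flats were taken); this survives flat-fielding and is the
#'   controllable ring-artifact source.
#' @param psf_sigma_px detector blur sigma in pixels (0 = none).
#' @param n_flat,n_dark number of flat and dark frames acquired.
#' @param noise logical; Poisson/Gaussian noise on or off.
#' @param beam_hardening quadratic bias coefficient c: absorbance B becomes
#'   `B * (1 - c * B)`, making thick paths attenuate sub-linearly (cupping).
#' @param seed integer seed driving gains and noise.
#' @return object of class `detector_model`.
#' @export
detector_model <- function(n0 = 5000, dark_level = 20, dark_sigma = 0,
                           gain_sigma = 0, gain_drift_sigma = 0,
                           psf_sigma_px = 0,
                           n_flat = 20, n_dark = 20, noise = TRUE,
                           beam_hardening = 0, seed = 1) {
  stopifnot(n0 >= 0, dark_sigma >= 0, gain_sigma >= 0, gain_drift_sigma >= 0,
            psf_sigma_px >= 0,
            n_flat >= 1, n_dark >= 1, beam_hardening >= 0)
  structure(list(n0 = n0, dark_level = dark_level, dark_sigma = dark_sigma,
                 gain_sigma = gain_sigma, gain_drift_sigma = gain_drift_sigma,
                 psf_sigma_px = psf_sigma_px,
                 n_flat = as.integer(n_flat), n_dark = as.integer(n_dark),
                 noise = isTRUE(noise), beam_hardening = beam_hardening,
                 seed = as.integer(seed)),
            class = "detector_model")
}

# Mean-1 multiplicative column gains, deterministic in the detector seed.
column_gains <- function(det, n_col) {
  if (det$gain_sigma <= 0) return(rep(1, n_col))
  g <- with_seed(det$seed + 101L, 1 + stats::rnorm(n_col, 0, det$gain_sigma))
  g <- pmax(g, 0.2)
  g / mean(g)
}

# Per-column drift factor between flat acquisition and the scan.
column_gain_drift <- function(det, n_col) {
  if (det$gain_drift_sigma <= 0) return(rep(1, n_col))
  with_seed(det$seed + 211L,
            pmax(1 + stats::rnorm(n_col, 0, det$gain_drift_sigma), 0.2))
}
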