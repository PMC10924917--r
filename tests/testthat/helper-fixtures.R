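# Shared fixtures: all synthetic, generated in code at test time.

# a small phantom spec that fits comfortably in a 128- or 256-pixel grid
small_spec <- function(n = 128, seed = 42, ...) {
  args <- list(shape = c(n, n), voxel_um = 4,
               n_adipocytes = 3, adipocyte_r_um = c(20, 40),
               n_ducts = 1, duct_r_um = c(25, 35),
               n_calcifications = 2, calc_r_um = c(8, 14),
               n_bubbles = 1, bubble_r_um = c(10, 16),
               stroma_fraction = 0, tissue_radius_frac = 0.68,
               seed = seed)
  args[names(list(...))] <- list(...)
  do.call(phantom_spec, args)
}

# centred uniform disk image
disk_image <- function(n, R, value = 1) {
  r2 <- outer((seq_len(n) - (n + 1) / 2)^2, (seq_len(n) - (n + 1) / 2)^2, "+")
  m <- matrix(0, n, n)
  m[r2 <= R^2] <- value
  m
}

# analytic sinogram of a centred uniform disk (chord length in pixels)
disk_sinogram <- function(n, R, n_angles) {
  s <- seq_len(n) - (n + 1) / 2
  chord <- 2 * sqrt(pmax(R^2 - s^2, 0))
  angles <- 180 * (seq_len(n_angles) - 1) / n_angles
  sinogram(matrix(chord, n_angles, n, byrow = TRUE), angles, pixel_um = 1)
}

# a structured, smooth test image for registration (deterministic)
blob_image <- function(n = 160, seed = 3, sigma = 4) {
  vhisto:::with_seed(seed, vhisto:::gaussian_blur(matrix(stats::rnorm(n * n), n), sigma))
}

# refractive map of a uniform disk of given delta/beta on an air background
disk_refractive <- function(n, R, delta, beta, voxel_um = 4, energy_keV = 20) {
  d <- disk_image(n, R, delta)
  b <- disk_image(n, R, beta)
  structure(list(delta = array(d, c(n, n, 1)), beta = array(b, c(n, n, 1)),
                 voxel_um = voxel_um, energy_keV = energy_keV,
                 labels = array(1L, c(n, n, 1)), legend = c(paraffin = 1L)),
            class = "refractive_map")
}

quiet_geom <- function(...) suppressWarnings(scan_geometry(...))
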