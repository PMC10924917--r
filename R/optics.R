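# Parallel-beam forward model of the acquisition. Per projection angle the
# refractive-index volume is line-integrated (radon transform with bilinear
# sampling), the complex wavefield exp(i*phi - B) is propagated to the
# detector plane with the paraxial Fresnel transfer function, and the
# detector applies gain, blur, photon noise and dark counts. A 2D (single
# slice) phantom produces a one-row projection stack; thin 3D blocks are
# simulated slice per detector row with 1D propagation along the row, which
# is exact for objects invariant along the rotation axis at this scale.

# Radon transform of one image: matrix [n_angles x n_columns] of line
# integrals in units of `step` (the sampling step along the ray).
radon_transform <- function(img, angles_deg, step = 1) {
  ny <- nrow(img); nx <- ncol(img)
  cy <- (ny + 1) / 2; cx <- (nx + 1) / 2
  nt <- ceiling(sqrt(ny^2 + nx^2)) + 2L
  s <- seq_len(nx) - cx
  tt <- seq(-nt / 2, nt / 2, length.out = nt)
  S <- matrix(rep(s, times = nt), nx)
  T <- matrix(rep(tt, each = nx), nx)
  out <- matrix(0, length(angles_deg), nx)
  for (a in seq_along(angles_deg)) {
    th <- angles_deg[a] * pi / 180
    ct <- cos(th); st <- sin(th)
    X <- cx + S * ct - T * st
    Y <- cy + S * st + T * ct
    v <- bilinear_sample(img, as.numeric(X), as.numeric(Y), outside = 0)
    out[a, ] <- rowSums(matrix(v, nx)) * step
  }
  out
}

#' Project a refractive-index map to phase and absorbance
#'
#' Computes, for every projection angle of the geometry, the line integrals
#' of delta and beta through the object (rotation about the central vertical
#' axis, linear interpolation along rays) and the corresponding per-pixel
#' phase `phi = -(2*pi/lambda) * integral(delta)` and absorbance
#' `B = (2*pi/lambda) * integral(beta)` at the object exit plane.
#'
#' @param rmap a `refractive_map`; its voxel size must equal the geometry's
#'   pixel size (resampling is the caller's job).
#' @param geom a `scan_geometry`.
#' @return object of class `projected_fields`: arrays `delta_l` and `beta_l`
#'   (line integrals, metres) and `phase`, `absorb`, each of shape
#'   `[n_proj, n_rows, n_cols]`, plus the angle list and geometry.
#' @export
project_refractive <- function(rmap, geom) {
  stopifnot(inherits(rmap, "refractive_map"), inherits(geom, "scan_geometry"))
  if (abs(rmap$voxel_um - geom$pixel_um) > 1e-9) {
    stop_vh("voxel size (%g um) must equal detector pixel size (%g um)",
            rmap$voxel_um, geom$pixel_um)
  }
  d <- dim(rmap$delta); nz <- d[3]; nx <- d[2]
  vox_m <- rmap$voxel_um * 1e-6
  n <- geom$n_proj
  delta_l <- array(0, c(n, nz, nx))
  beta_l <- array(0, c(n, nz, nx))
  for (z in seq_len(nz)) {
    delta_l[, z, ] <- radon_transform(rmap$delta[, , z], geom$angles_deg, vox_m)
    beta_l[, z, ] <- radon_transform(rmap$beta[, , z], geom$angles_deg, vox_m)
  }
  k <- 2 * pi / geom$lambda_m
  structure(list(delta_l = delta_l, beta_l = beta_l,
                 phase = -k * delta_l, absorb = k * beta_l,
                 angles_deg = geom$angles_deg, geom = geom),
            class = "projected_fields")
}

#' Fresnel free-space propagation
#'
#' Propagates the exit wavefield `exp(i*phase - absorb)` over distance `z_mm`
#' with the paraxial transfer function
#' `exp(-i * pi * lambda * z * (fx^2 + fy^2))` (frequencies in cycles per
#' metre) and returns the intensity normalised to unit incident flux. Inputs
#' are replicate-padded to twice the lateral size to suppress wrap-around.
#' At `z = 0` the intensity is exactly `exp(-2 * absorb)`.
#'
#' @param phase per-pixel phase in radians (vector for a 1D row, matrix for
#'   a full projection).
#' @param absorb per-pixel absorbance B (same shape as `phase`).
#' @param lambda_m wavelength in metres.
#' @param z_mm propagation distance in millimetres (>= 0).
#' @param pixel_um detector pixel size in micrometres.
#' @return intensity, same shape as the input.
#' @export
fresnel_propagate <- function(phase, absorb, lambda_m, z_mm, pixel_um) {
  if (z_mm < 0) stop_vh("propagation distance must be >= 0 (got %g mm)", z_mm)
  stopifnot(lambda_m > 0, pixel_um > 0, all(dim(phase) == dim(absorb)),
            length(phase) == length(absorb))
  if (z_mm == 0) return(exp(-2 * absorb))
  p_m <- pixel_um * 1e-6
  z_m <- z_mm * 1e-3
  if (is.matrix(phase)) {
    pr <- floor(nrow(phase) / 2); pc <- floor(ncol(phase) / 2)
    u <- exp(1i * pad_replicate(phase, c(pr, pc)) - pad_replicate(absorb, c(pr, pc)))
    fy <- fftfreq(nrow(u), p_m); fx <- fftfreq(ncol(u), p_m)
    H <- exp(-1i * pi * lambda_m * z_m * outer(fy^2, fx^2, "+"))
    U <- stats::fft(u)
    uz <- stats::fft(U * H, inverse = TRUE) / length(u)
    unpad(Mod(uz)^2, c(pr, pc))
  } else {
    pad <- floor(length(phase) / 2)
    u <- exp(1i * pad_replicate(phase, pad) - pad_replicate(absorb, pad))
    f <- fftfreq(length(u), p_m)
    H <- exp(-1i * pi * lambda_m * z_m * f^2)
    uz <- stats::fft(stats::fft(u) * H, inverse = TRUE) / length(u)
    unpad(Mod(uz)^2, pad)
  }
}

#' Detector sampling of an ideal intensity
#'
#' Applies the detector model to ideal (unit-incident) intensities:
#' `counts = blur(ideal * n0 * gain) + dark`, Poisson-sampled when noise is
#' on, with Gaussian dark noise. Also synthesises the flat (ideal = 1) and
#' dark (ideal = 0) reference frames. Deterministic in the detector seed.
#'
#' @param ideal array `[n_proj, n_rows, n_cols]` (or matrix/vector for a
#'   single projection) of non-negative intensities.
#' @param det a `detector_model`.
#' @param geom a `scan_geometry` (stored with the stack).
#' @return object of class `projection_stack`: arrays `projections`
#'   `[n_proj, n_rows, n_cols]`, `flats` and `darks`
#'   `[n_frames, n_rows, n_cols]`, plus `geom` and `det`.
#' @export
detect <- function(ideal, det, geom) {
  stopifnot(inherits(det, "detector_model"), inherits(geom, "scan_geometry"))
  if (min(ideal) < 0) stop_vh("ideal intensity must be non-negative")
  if (is.null(dim(ideal))) ideal <- array(ideal, c(1, 1, length(ideal)))
  if (length(dim(ideal)) == 2) ideal <- array(ideal, c(1, dim(ideal)))
  d <- dim(ideal); n_proj <- d[1]; n_row <- d[2]; n_col <- d[3]
  gains <- column_gains(det, n_col)
  drift <- column_gain_drift(det, n_col)

  frame_counts <- function(int_frame, noisy, drifted = FALSE) {
    # int_frame: [n_row x n_col] expected photon counts before dark
    g <- if (drifted) gains * drift else gains
    m <- sweep(int_frame, 2, g, "*") * det$n0
    if (det$psf_sigma_px > 0) {
      m <- if (n_row == 1) matrix(gaussian_blur(m[1, ], det$psf_sigma_px), 1)
           else gaussian_blur(m, det$psf_sigma_px)
    }
    if (noisy) m <- matrix(stats::rpois(length(m), pmax(m, 0)), n_row, n_col)
    dk <- det$dark_level
    if (noisy && det$dark_sigma > 0) {
      dk <- dk + matrix(stats::rnorm(length(m), 0, det$dark_sigma), n_row, n_col)
    }
    m + dk
  }

  with_seed(det$seed, {
    projections <- array(0, c(n_proj, n_row, n_col))
    for (a in seq_len(n_proj)) {
      projections[a, , ] <- frame_counts(matrix(ideal[a, , ], n_row, n_col),
                                         det$noise, drifted = TRUE)
    }
    flats <- array(0, c(det$n_flat, n_row, n_col))
    ones <- matrix(1, n_row, n_col)
    for (f in seq_len(det$n_flat)) flats[f, , ] <- frame_counts(ones, det$noise)
    darks <- array(0, c(det$n_dark, n_row, n_col))
    zero <- matrix(0, n_row, n_col)
    for (f in seq_len(det$n_dark)) darks[f, , ] <- frame_counts(zero, det$noise)
    structure(list(projections = projections, flats = flats, darks = darks,
                   geom = geom, det = det),
              class = "projection_stack")
  })
}

#' Simulate a complete scan
#'
#' Composes [project_refractive()], [fresnel_propagate()] (1D per detector
#' row) and [detect()] for every projection angle. If the geometry's
#' detector is narrower than the object grid, the detector window (shifted
#' by `local_offset_px` for local-area scans) is cropped from the full
#' projection, producing laterally truncated data.
#'
#' @param rmap a `refractive_map`.
#' @param geom a `scan_geometry`.
#' @param det a `detector_model`.
#' @return a `projection_stack`.
#' @export
simulate_scan <- function(rmap, geom, det) {
  pf <- project_refractive(rmap, geom)
  d <- dim(pf$phase); n_proj <- d[1]; n_row <- d[2]; n_col <- d[3]
  ideal <- array(0, d)
  for (a in seq_len(n_proj)) {
    for (z in seq_len(n_row)) {
      B <- pf$absorb[a, z, ]
      if (det$beam_hardening > 0) B <- B * (1 - det$beam_hardening * B)
      ideal[a, z, ] <- fresnel_propagate(pf$phase[a, z, ], B,
                                         geom$lambda_m, geom$distance_mm,
                                         geom$pixel_um)
    }
  }
  if (geom$det_width < n_col) {
    c0 <- floor((n_col - geom$det_width) / 2) + geom$local_offset_px
    if (c0 < 0 || c0 + geom$det_width > n_col) {
      stop_vh("detector window (offset %d) falls outside the projected field",
              geom$local_offset_px)
    }
    ideal <- ideal[, , (c0 + 1):(c0 + geom$det_width), drop = FALSE]
  } else if (geom$local_offset_px != 0) {
    warning("local_offset_px ignored: detector is at least as wide as the object",
            call. = FALSE)
  }
  detect(ideal, det, geom)
}

#' @export
print.projection_stack <- function(x, ...) {
  d <- dim(x$projections)
  cat(sprintf("projection_stack: %d projections of %d row(s) x %d columns, %d flats, %d darks\n",
              d[1], d[2], d[3], dim(x$flats)[1], dim(x$darks)[1]))
  invisible(x)
}
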