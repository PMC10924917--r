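# Forward model: line integrals, Fresnel propagation, detector sampling.

test_that("projections of an empty map are zero and line integrals are linear", {
  n <- 64
  geom <- quiet_geom(4, 500, n_proj = 8, det_width = n, det_height = 1)
  zero <- disk_refractive(n, 0, 0, 0)
  pf <- project_refractive(zero, geom)
  expect_true(all(pf$delta_l == 0) && all(pf$phase == 0))

  a <- disk_refractive(n, 12, 2e-7, 1e-10)
  b <- disk_refractive(n, 20, 1e-7, 2e-10)
  ab <- a; ab$delta <- a$delta + b$delta; ab$beta <- a$beta + b$beta
  pa <- project_refractive(a, geom); pb <- project_refractive(b, geom)
  pab <- project_refractive(ab, geom)
  expect_equal(pab$delta_l, pa$delta_l + pb$delta_l, tolerance = 1e-10)
})

test_that("disk line integrals match the analytic chord length within 1%", {
  n <- 128; R <- 40; delta <- 3e-7
  rmap <- disk_refractive(n, R, delta, 0)
  geom <- quiet_geom(4, 500, n_proj = 3, range_deg = 120, det_width = n, det_height = 1)
  pf <- project_refractive(rmap, geom)
  s <- seq_len(n) - (n + 1) / 2
  sel <- abs(s) <= 0.8 * R
  expected <- 2 * delta * sqrt(R^2 - s[sel]^2) * 4e-6
  for (a in 1:3) {
    expect_equal(pf$delta_l[a, 1, sel], expected, tolerance = 0.01)
  }
})

test_that("voxel/pixel size mismatch is an error", {
  rmap <- disk_refractive(32, 8, 1e-7, 1e-10, voxel_um = 2)
  geom <- quiet_geom(4, 500, n_proj = 2, det_width = 32, det_height = 1)
  expect_error(project_refractive(rmap, geom), "voxel")
})

test_that("Fresnel propagation honours its limits and conserves energy", {
  n <- 256
  lam <- xray_wavelength(20)
  B <- 0.05 * exp(-((seq_len(n)) - n / 2)^2 / (2 * 12^2))
  phi <- -350 * B
  # z = 0 is the identity propagator
  expect_equal(fresnel_propagate(phi, B, lam, 0, 4), exp(-2 * B), tolerance = 1e-14)
  # uniform phase, no absorption: plane wave stays a plane wave
  expect_equal(fresnel_propagate(rep(1.3, n), rep(0, n), lam, 500, 4),
               rep(1, n), tolerance = 1e-10)
  # pure-phase object: flux conserved under propagation
  phic <- 0.5 * exp(-((seq_len(n)) - n / 2)^2 / (2 * 10^2))
  I <- fresnel_propagate(phic, rep(0, n), lam, 500, 4)
  expect_lt(abs(mean(I) - 1), 1e-6)
  expect_error(fresnel_propagate(phi, B, lam, -5, 4), ">= 0")
})

test_that("a phase step develops edge fringes only after propagation", {
  n <- 256
  lam <- xray_wavelength(20)
  phi <- c(rep(0, n / 2), rep(0.8, n / 2))
  I0 <- fresnel_propagate(phi, rep(0, n), lam, 0, 4)
  Iz <- fresnel_propagate(phi, rep(0, n), lam, 500, 4)
  expect_equal(max(I0) - min(I0), 0)
  expect_gt(max(Iz) - min(Iz), 0.05)
})

test_that("detector counts follow the model exactly when noise is off", {
  geom <- quiet_geom(4, 500, n_proj = 2, det_width = 32, det_height = 1)
  ideal <- array(runif(2 * 1 * 32), c(2, 1, 32))
  det <- detector_model(n0 = 1000, dark_level = 30, noise = FALSE,
                        n_flat = 2, n_dark = 2)
  st <- detect(ideal, det, geom)
  expect_equal(st$projections, ideal * 1000 + 30, tolerance = 1e-12)
  expect_true(all(st$flats == 1030))
  expect_true(all(st$darks == 30))
  # n0 = 0: dark level everywhere
  st0 <- detect(ideal, detector_model(n0 = 0, dark_level = 30, noise = FALSE,
                                      n_flat = 1, n_dark = 1), geom)
  expect_true(all(st0$projections == 30))
})

test_that("detected counts are Poisson (variance ~ mean) when noise is on", {
  geom <- quiet_geom(4, 500, n_proj = 1, det_width = 256, det_height = 1)
  det <- detector_model(n0 = 1000, dark_level = 50, noise = TRUE,
                        n_flat = 400, n_dark = 1, seed = 3)
  st <- detect(array(1, c(1, 1, 256)), det, geom)
  x <- as.numeric(st$flats) - 50
  expect_lt(abs(var(x) / mean(x) - 1), 0.05)
})

test_that("simulated scans are deterministic and follow the 1800-angle protocol", {
  rmap <- disk_refractive(16, 5, 1e-7, 1e-10)
  geom <- quiet_geom(4, 500, n_proj = 1800, det_width = 16, det_height = 1)
  det <- detector_model(n0 = 100, dark_level = 5, noise = TRUE,
                        n_flat = 1, n_dark = 1, seed = 11)
  st <- simulate_scan(rmap, geom, det)
  expect_equal(dim(st$projections)[1], 1800)
  st2 <- simulate_scan(rmap, geom, det)
  expect_identical(st$projections, st2$projections)
})

test_that("a narrow detector window on a wide block gives truncated sinograms", {
  spec <- small_spec(96, seed = 4, tissue_radius_frac = 0.6,
                     block_radius_frac = 0.8, n_adipocytes = 1, n_ducts = 0,
                     n_calcifications = 1, n_bubbles = 0)
  rmap <- labels_to_refractive(generate_phantom(spec), build_material_table(20))
  det <- detector_model(n0 = 1000, dark_level = 5, noise = FALSE,
                        n_flat = 1, n_dark = 1)
  full <- simulate_scan(rmap, quiet_geom(4, 500, n_proj = 4, det_width = 96,
                                         det_height = 1), det)
  loc <- simulate_scan(rmap, quiet_geom(4, 500, n_proj = 4, det_width = 48,
                                        det_height = 1, local_offset_px = 8), det)
  att_full <- abs(log(flat_field_correct(full)))
  att_loc <- abs(log(flat_field_correct(loc)))
  # full-field edge columns see air; the local window's edges cut tissue
  edge_full <- mean(att_full[, 1, c(1, 96)])
  edge_loc <- mean(att_loc[, 1, c(1, 48)])
  expect_gt(edge_loc, 5 * edge_full)
  expect_gt(edge_loc, 0.005)
})
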