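# Shepp-Logan FBP, kernel contract, local-area padding, volume assembly.

test_that("the Shepp-Logan kernel matches its closed form", {
  n <- 256
  H <- shepp_logan_kernel(n, 1)
  expect_equal(H[1], 0)                                    # ramp zero at DC
  f <- vhisto:::fftfreq(n, 1)
  # even symmetry over sampled frequencies
  expect_equal(H[2:(n / 2)], rev(H[(n / 2 + 2):n]), tolerance = 1e-14)
  # closed form at the Nyquist frequency: f_N * sinc(1/2) = f_N * 2/pi
  fn <- 0.5
  expect_equal(H[n / 2 + 1], fn * 2 / pi, tolerance = 1e-12)
  # general sample against direct evaluation
  k <- 10
  expect_equal(H[k], abs(f[k]) * sin(pi * f[k]) / (pi * f[k]), tolerance = 1e-12)
})

test_that("FBP reconstructs a centred analytic disk accurately", {
  n <- 128; R <- 40
  rec <- fbp(disk_sinogram(n, R, 720))
  r2 <- outer((seq_len(n) - (n + 1) / 2)^2, (seq_len(n) - (n + 1) / 2)^2, "+")
  inner <- r2 <= (0.7 * R)^2
  bgm <- r2 >= (R + 8)^2
  expect_lt(abs(mean(rec[inner]) - 1), 0.03)
  expect_lt(abs(mean(rec[bgm])), 0.02)
})

test_that("FBP error decreases monotonically with angle count", {
  n <- 128; R <- 40
  truth <- disk_image(n, R)
  rmse <- sapply(c(90, 180, 360, 720), function(na) {
    sqrt(mean((fbp(disk_sinogram(n, R, na)) - truth)^2))
  })
  expect_true(all(diff(rmse) < 0))
})

test_that("FBP is linear and rejects degenerate input", {
  s1 <- disk_sinogram(64, 20, 48)
  s2 <- disk_sinogram(64, 10, 48)
  lin <- s1; lin$values <- 2 * s1$values + 0.5 * s2$values
  expect_equal(fbp(lin), 2 * fbp(s1) + 0.5 * fbp(s2), tolerance = 1e-8)
  expect_true(all(fbp(sinogram(matrix(0, 16, 32))) == 0))
  expect_error(fbp(sinogram(matrix(1, 1, 32))), "2 angles")
  bad <- sinogram(matrix(1, 16, 32)); bad$values[3, 3] <- NaN
  expect_error(fbp(bad), "finite")
})

test_that("local-area padding has the stated construction", {
  sn <- disk_sinogram(128, 30, 16)
  expect_identical(pad_local_sinogram(sn, 0), sn)
  p <- pad_local_sinogram(sn, 64)
  expect_equal(ncol(p$values), 256)
  # boundary continuity with the original edges
  expect_equal(p$values[, 65], sn$values[, 1], tolerance = 1e-9)
  expect_equal(p$values[, 64], sn$values[, 1], tolerance = 0.01 * max(sn$values))
  # taper reaches the target level at the far end
  expect_equal(p$values[, 1], rep(0, 16), tolerance = 1e-12)
  pm <- pad_local_sinogram(sn, 64, target = "mean")
  expect_equal(pm$values[, 1], rowMeans(sn$values), tolerance = 1e-9)
})

test_that("volume reconstruction equals per-slice FBP and records provenance", {
  v <- array(0, c(24, 3, 64))
  for (z in 1:3) v[, z, ] <- disk_sinogram(64, 10 + 3 * z, 24)$values
  geom <- quiet_geom(4, 500, n_proj = 24, det_width = 64, det_height = 3)
  vol <- reconstruct_volume(v, geom, provenance = c("flat_field", "tie_hom"))
  for (z in 1:3) {
    s <- sinogram(matrix(v[, z, ], 24, 64), geom$angles_deg, 4)
    expect_equal(vol$volume[, , z], fbp(s), tolerance = 1e-12)
  }
  expect_equal(vol$provenance[1:2], c("flat_field", "tie_hom"))
  expect_match(vol$provenance[3], "fbp")
  # identical rows reconstruct to identical slices
  v2 <- array(rep(disk_sinogram(64, 12, 24)$values, 3), c(24, 64, 3))
  v2 <- aperm(v2, c(1, 3, 2))
  vol2 <- reconstruct_volume(v2, geom)
  expect_identical(vol2$volume[, , 1], vol2$volume[, , 3])
})
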