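# Single-distance TIE-Hom retrieval: filter contract, limits, end-to-end
# fidelity, and the sensitivity/resolution trade-off.

test_that("the TIE-Hom filter passes DC, is bounded and matches the formula", {
  pr <- tie_hom_params(350, 20, 500, 4)
  H <- tie_hom_filter(256, pr)
  expect_equal(H[1], 1)                      # f = 0
  expect_true(all(H > 0 & H <= 1))
  expect_true(all(diff(H[1:128]) <= 0))      # radially non-increasing
  # independent scalar evaluation at f = 25000 cycles/m
  f <- 25000
  expect_equal(1 / (1 + pi * (1.23984193e-9 / 20) * 0.5 * 350 * f^2),
               1 / (1 + pi * pr$lambda_m * 0.5 * pr$delta_beta * f^2),
               tolerance = 1e-12)
  fgrid <- vhisto:::fftfreq(256, 4e-6)
  k <- which.min(abs(fgrid - f))
  expect_equal(H[k], 1 / (1 + pi * pr$lambda_m * 0.5 * 350 * fgrid[k]^2),
               tolerance = 1e-12)
  # no propagation, no retrieval
  expect_true(all(tie_hom_filter(64, tie_hom_params(350, 20, 0, 4)) == 1))
})

test_that("retrieval limits: empty beam and the attenuation (Paganin) limit", {
  pr <- tie_hom_params(350, 20, 500, 4)
  expect_equal(retrieve(rep(1, 128), pr), rep(0, 128), tolerance = 1e-12)
  T <- 0.5 + 0.3 * sin(seq_len(128) / 9)
  out <- retrieve(T, tie_hom_params(1e-12, 20, 500, 4))
  expect_equal(out, -log(T), tolerance = 1e-6)
  expect_error(retrieve(c(0.5, -0.1, 0.5), pr), "positive")
})

test_that("matched retrieval recovers the projected attenuation of a slab", {
  n <- 256
  lam <- xray_wavelength(20)
  B <- 0.1 / (1 + exp(-((seq_len(n)) - 80) / 3)) -
       0.1 / (1 + exp(-((seq_len(n)) - 180) / 3))
  db <- 350
  I <- fresnel_propagate(-db * B, B, lam, 500, 4)
  ret <- retrieve(I, tie_hom_params(db, 20, 500, 4))
  interior <- 100:160
  expect_equal(ret[interior], 2 * B[interior], tolerance = 0.02)
})

test_that("the filtering step before the logarithm is linear", {
  pr <- tie_hom_params(350, 20, 500, 4)
  t1 <- 0.6 + 0.2 * sin(seq_len(128) / 5)
  t2 <- 0.8 + 0.1 * cos(seq_len(128) / 7)
  f1 <- exp(-retrieve(t1, pr)); f2 <- exp(-retrieve(t2, pr))
  f12 <- exp(-retrieve(0.3 * t1 + 0.7 * t2, pr))
  expect_equal(f12, 0.3 * f1 + 0.7 * f2, tolerance = 1e-10)
})

test_that("raising delta/beta trades noise suppression against resolution", {
  n <- 256
  lam <- xray_wavelength(20)
  noisy <- vhisto:::with_seed(8, 0.8 + rnorm(n, 0, 0.02))
  ratios <- c(10, 100, 350, 1000)
  vars <- sapply(ratios, function(db) {
    var(retrieve(noisy, tie_hom_params(db, 20, 500, 4)))
  })
  expect_true(all(diff(vars) < 0))
  # edge response width grows with delta/beta
  step <- c(rep(0.9, n / 2), rep(0.5, n / 2))
  widths <- sapply(ratios, function(db) {
    r <- retrieve(step, tie_hom_params(db, 20, 500, 4))
    prof <- (r - min(r)) / diff(range(r))
    sum(prof > 0.1 & prof < 0.9)
  })
  expect_true(all(diff(widths) >= 0) && widths[4] > widths[1])
})

test_that("sinogram retrieval filters each angle independently (1D)", {
  v <- matrix(0.7 + 0.1 * sin(outer(1:12, 1:64, "+") / 5), 12, 64)
  sn <- sinogram(v, pixel_um = 4)
  pr <- tie_hom_params(350, 20, 500, 4)
  out <- retrieve(sn, pr)
  expect_s3_class(out, "sinogram")
  expect_equal(out$values[3, ], retrieve(v[3, ], pr), tolerance = 1e-12)
})
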