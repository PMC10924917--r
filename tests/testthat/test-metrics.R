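# Image-quality metrics and enhancement operators.

test_that("detrend removes a quadratic bowl and preserves the background", {
  n <- 160
  r2n <- ((row(diag(n)) - (n + 1) / 2)^2 + (col(diag(n)) - (n + 1) / 2)^2) / (n / 2)^2
  # tissue-like slice: unit-contrast disk on a noisy paraffin background
  slice <- vhisto:::with_seed(2, matrix(rnorm(n * n, 0, 0.003), n)) +
    disk_image(n, 45)
  mask <- r2n > (60 / (n / 2))^2              # background outside the disk
  # nothing to remove on an already-flat background
  out0 <- detrend(slice, mask)
  expect_lt(max(abs(out0 - slice)) / diff(range(slice)), 0.005)
  # strong cupping removed, background median restored, tissue level kept
  biased <- slice + 0.5 * r2n
  out <- detrend(biased, mask)
  expect_gt(cupping_score(biased, mask) / cupping_score(out, mask), 5)
  expect_equal(median(out[mask]), median(biased[mask]), tolerance = 1e-6)
  # idempotence
  out2 <- detrend(out, mask)
  expect_lt(max(abs(out2 - out)) / diff(range(out)), 0.005)
  expect_error(detrend(biased, matrix(FALSE, n, n)), "empty")
})

test_that("unsharp masking is identity at amount 0 and sharpens edges", {
  step <- matrix(0, 64, 64); step[, 33:64] <- 1
  expect_identical(unsharp_mask(step, 0, 2), step)
  expect_equal(unsharp_mask(matrix(3, 32, 32), 1.5, 2), matrix(3, 32, 32),
               tolerance = 1e-12)
  us <- unsharp_mask(step, 1, 2)
  expect_gt(max(abs(diff(t(us)))), max(abs(diff(t(step)))))
})

test_that("CNR matches a two-pass oracle and honours its contract", {
  n <- 60
  roi_a <- matrix(FALSE, n, n); roi_a[1:10, 1:10] <- TRUE
  roi_b <- matrix(FALSE, n, n); roi_b[31:40, 31:40] <- TRUE
  x <- vhisto:::with_seed(4, {
    m <- matrix(rnorm(n * n), n)
    m[roi_a] <- rnorm(100, 2, 0.5); m[roi_b] <- rnorm(100, 1, 0.5); m
  })
  a <- x[roi_a]; b <- x[roi_b]
  oracle <- abs(sum(a) / 100 - sum(b) / 100) /
    sqrt((sum((a - mean(a))^2) / 99 + sum((b - mean(b))^2) / 99) / 2)
  expect_equal(cnr(x, roi_a, roi_b), oracle, tolerance = 1e-10)
  # identical content in disjoint ROIs -> 0
  y <- x; y[roi_b] <- y[roi_a]
  expect_equal(cnr(y, roi_a, roi_b), 0)
  expect_error(cnr(x, roi_a, roi_a), "disjoint")
  small <- matrix(FALSE, n, n); small[1:3, 1] <- TRUE
  expect_error(cnr(x, small, roi_b), "25")
  z <- matrix(1, n, n)
  expect_error(cnr(z, roi_a, roi_b), "variance")
})

test_that("edge FWHM recovers known edge widths", {
  n <- 128
  step <- matrix(0, n, n); step[, (n / 2 + 1):n] <- 1
  # ideal step: at most ~1.2 px equivalent
  expect_lte(edge_fwhm(step, c(n / 2, n / 2 - 20), c(n / 2, n / 2 + 20), 4), 4.8)
  # Gaussian-blurred step: FWHM = 2.355 * sigma within 5%
  bl <- vhisto:::gaussian_blur(step, 3)
  fw <- edge_fwhm(bl, c(n / 2, n / 2 - 25), c(n / 2, n / 2 + 25), 4)
  expect_equal(fw, 2.3548 * 3 * 4, tolerance = 0.05)
  expect_error(edge_fwhm(matrix(1, n, n), c(64, 30), c(64, 90), 4), "edge")
})

test_that("ring score flags concentric patterns, not noise, rotation-invariantly", {
  n <- 200
  r <- sqrt((row(diag(n)) - (n + 1) / 2)^2 + (col(diag(n)) - (n + 1) / 2)^2)
  rings <- sin(2 * pi * r / 3)
  noise <- vhisto:::with_seed(7, matrix(rnorm(n * n, 0, sd(rings)), n))
  expect_gt(ring_score(rings) / ring_score(noise), 10)
  rot <- t(rings[n:1, ])
  expect_equal(ring_score(rot), ring_score(rings), tolerance = 0.02)
  expect_equal(ring_score(matrix(5, n, n)), 0)
  expect_error(ring_score(rings, center = c(-5, 10)), "inside")
})

test_that("quality reports serialise with the expected schema", {
  rep <- quality_report(cnr = list(glandular_vs_adipose = 2.5),
                        edge_fwhm_um = 9.1, ring_score = 0.01,
                        cupping_score = 0.001, provenance = "fbp")
  f <- tempfile(fileext = ".json")
  write_quality_report(rep, f)
  j <- jsonlite::read_json(f)
  expect_true(all(c("cnr", "edge_fwhm_um", "ring_score", "cupping_score")
                  %in% names(j)))
  expect_error(quality_report(list(a = NA_real_), 1, 1, 1), "finite")
})
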