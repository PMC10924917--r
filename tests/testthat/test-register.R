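# Rigid NCC registration and best-plane search.

test_that("registering an image to itself is the identity with score 1", {
  img <- blob_image(128, seed = 3)
  fit <- register_2d(img, img, list(theta_range = c(-3, 3), theta_step = 1))
  expect_equal(fit$theta_deg, 0)
  expect_equal(fit$t, c(0, 0), tolerance = 1e-6)
  expect_equal(fit$score, 1, tolerance = 1e-6)
})

test_that("a planted rigid transform is recovered within 0.5 deg / 0.5 px", {
  fixed <- blob_image(160, seed = 3)
  planted <- rigid_transform_2d(7, c(5, -3))
  moving <- apply_transform(fixed, invert_transform(planted))
  fit <- register_2d(moving, fixed, list(theta_range = c(-12, 12), theta_step = 1))
  expect_lt(abs(fit$theta_deg - 7), 0.5)
  expect_lt(max(abs(fit$t - c(5, -3))), 0.5)
  expect_gt(fit$score, 0.8)
})

test_that("NCC registration is invariant to affine intensity remaps", {
  fixed <- blob_image(160, seed = 3)
  moving <- apply_transform(fixed, rigid_transform_2d(-4, c(2, 6)))
  f1 <- register_2d(moving, fixed, list(theta_range = c(-8, 8), theta_step = 1))
  f2 <- register_2d(2.3 * moving + 0.7, fixed,
                    list(theta_range = c(-8, 8), theta_step = 1))
  expect_equal(f1$theta_deg, f2$theta_deg)
  expect_equal(f1$t, f2$t, tolerance = 1e-6)
  expect_equal(f1$score, f2$score, tolerance = 1e-6)
})

test_that("swapping fixed and moving inverts the recovered transform", {
  fixed <- blob_image(160, seed = 4)
  planted <- rigid_transform_2d(5, c(3, -2))
  moving <- apply_transform(fixed, invert_transform(planted))
  fwd <- register_2d(moving, fixed, list(theta_range = c(-9, 9), theta_step = 1))
  bwd <- register_2d(fixed, moving, list(theta_range = c(-9, 9), theta_step = 1))
  inv <- invert_transform(bwd)
  expect_lt(abs(fwd$theta_deg - inv$theta_deg), 0.3)
  expect_lt(max(abs(fwd$t - inv$t)), 0.5)
})

test_that("zero-variance images cannot be registered", {
  expect_error(register_2d(matrix(1, 32, 32), blob_image(32)), "variance")
})

test_that("planted section depth is recovered, also under degradations", {
  n <- 160
  base <- blob_image(n, seed = 3)
  vol <- list(volume = array(0, c(n, n, 9)), voxel_um = 4)
  for (k in 1:9) {
    vol$volume[, , k] <- base + blob_image(n, seed = 100 + k, sigma = 3)
  }
  # exact slice: recovered exactly
  sec <- extract_slice(vol, axial_plane(vol, 5))
  hit <- find_best_plane(vol, sec, list(theta_range = c(-4, 4), theta_step = 2))
  expect_equal(hit$depth, 5)
  # degraded section: within +-1 slice
  sec2 <- simulate_section(vol, 5, thickness_um = 4,
                           transform = rigid_transform_2d(4, c(2, -6)),
                           intensity = c(1.5, 0.2), dropout_frac = 0.10, seed = 9)
  hit2 <- find_best_plane(vol, sec2, list(theta_range = c(-8, 8), theta_step = 2))
  expect_lte(abs(hit2$depth - 5), 1)
  # single-candidate search returns that plane; empty search errors
  one <- find_best_plane(vol, sec, list(depths = 3, theta_range = c(-2, 2),
                                        theta_step = 2))
  expect_equal(one$depth, 3)
  expect_error(find_best_plane(vol, sec, list(depths = integer(0))), "empty")
})
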