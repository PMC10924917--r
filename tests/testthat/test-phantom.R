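# Procedural phantom generation: determinism, counts, fractions, morphology
# and the label -> refractive-index conversion.

test_that("phantom generation is a pure function of its spec", {
  spec <- small_spec(128, seed = 42)
  v1 <- generate_phantom(spec)
  v2 <- generate_phantom(spec)
  expect_identical(v1$labels, v2$labels)
  # a different seed gives a different phantom
  v3 <- generate_phantom(small_spec(128, seed = 43))
  expect_false(identical(v1$labels, v3$labels))
})

test_that("placed calcification count equals the request (connected components)", {
  skip_if_not_installed("EBImage")
  spec <- small_spec(192, seed = 42, n_calcifications = 5, calc_r_um = c(8, 16))
  vol <- generate_phantom(spec)
  calc <- vol$labels[, , 1] == vol$legend[["calcification"]]
  lab <- EBImage::bwlabel(matrix(as.numeric(calc), nrow(calc)))
  expect_equal(max(lab), 5)
  # adipocytes are placed without overlap, so components match the count too
  adip <- vol$labels[, , 1] == vol$legend[["adipose"]]
  expect_equal(max(EBImage::bwlabel(matrix(as.numeric(adip), nrow(adip)))), 3)
})

test_that("adipose-fraction mode hits the target within 0.05", {
  spec <- phantom_spec(shape = c(512, 512), voxel_um = 4,
                       adipose_fraction = 0.30, n_ducts = 1,
                       n_calcifications = 2, n_bubbles = 1, seed = 7)
  vol <- generate_phantom(spec)
  fr <- label_fractions(vol, within_tissue = TRUE)
  expect_lt(abs(fr[["adipose"]] - 0.30), 0.05)
})

test_that("label fractions sum to one and all requested classes exist", {
  vol <- generate_phantom(small_spec(128, seed = 1))
  fr <- label_fractions(vol)
  expect_equal(sum(fr), 1)
  for (m in c("paraffin", "glandular", "adipose", "calcification", "air")) {
    expect_gt(fr[[m]], 0)
  }
})

test_that("ducts have a lower-attenuation lumen enclosed by a glandular wall", {
  skip_if_not_installed("EBImage")
  vol <- generate_phantom(small_spec(192, seed = 5, n_ducts = 1,
                                     duct_r_um = c(40, 60)))
  lab <- vol$labels[, , 1]
  para <- lab == vol$legend[["paraffin"]]
  comp <- EBImage::bwlabel(matrix(as.numeric(para), nrow(para)))
  # at least two paraffin components: the embedding ring and enclosed lumina
  expect_gte(max(comp), 2)
  # the lumen component (not touching the border) is bordered by glandular
  ids <- setdiff(unique(as.numeric(comp)), 0)
  sizes <- table(comp[comp > 0])
  outer_id <- as.integer(names(which.max(sizes)))     # embedding paraffin ring
  lumen_ids <- setdiff(ids, outer_id)
  expect_gte(length(lumen_ids), 1)
  lum <- comp == lumen_ids[1]
  ring <- vhisto:::erode_mask(!lum, 1) == FALSE & !lum  # pixels adjacent to lumen
  expect_true(mean(lab[ring] == vol$legend[["glandular"]]) > 0.9)
})

test_that("labels_to_refractive matches a per-voxel lookup oracle", {
  vol <- generate_phantom(small_spec(96, seed = 9))
  tab <- build_material_table(20)
  rmap <- labels_to_refractive(vol, tab)
  # brute-force elementwise oracle
  inv <- names(vol$legend)[order(vol$legend)]
  for (i in seq(1, length(vol$labels), by = 997)) {
    nm <- inv[vol$labels[i]]
    e <- material_lookup(tab, nm)
    expect_identical(rmap$delta[i], e[["delta"]])
    expect_identical(rmap$beta[i], e[["beta"]])
  }
  expect_equal(rmap$voxel_um, vol$voxel_um)
  expect_equal(rmap$energy_keV, 20)
})

test_that("an all-paraffin volume maps to spatially constant delta and beta", {
  lv <- structure(list(labels = array(1L, c(8, 8, 1)),
                       legend = c(paraffin = 1L), voxel_um = 4),
                  class = "labeled_volume")
  rmap <- labels_to_refractive(lv, build_material_table(20))
  expect_equal(length(unique(as.numeric(rmap$delta))), 1)
  expect_equal(length(unique(as.numeric(rmap$beta))), 1)
})

test_that("a legend material missing from the table is a named error", {
  lv <- structure(list(labels = array(1L, c(4, 4, 1)),
                       legend = c(unknownium = 1L), voxel_um = 4),
                  class = "labeled_volume")
  expect_error(labels_to_refractive(lv, build_material_table(20)), "unknownium")
})

test_that("invalid specs are rejected", {
  expect_error(phantom_spec(adipose_fraction = 1.5), "adipose_fraction")
  expect_error(phantom_spec(voxel_um = -1))
  expect_error(phantom_spec(n_ducts = -2))
})

test_that("3D thin blocks carry through-depth structure", {
  spec <- small_spec(96, seed = 3)
  spec$shape <- c(96L, 96L, 7L)
  vol <- generate_phantom(spec)
  expect_equal(dim(vol$labels), c(96, 96, 7))
  # adipocytes are spheres, so slices differ
  expect_false(identical(vol$labels[, , 1], vol$labels[, , 4]))
})
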