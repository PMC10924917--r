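# Procedural breast-tissue-block phantoms. A centred cylindrical tissue
# region (loose fibroglandular background with a correlated dense-stroma
# texture) is embedded in paraffin and populated with adipocytes (spheres),
# duct/TDLU-like structures (glandular-walled annuli with paraffin lumina and
# a ring of acini), microcalcifications, blood vessels and air bubbles in the
# surrounding paraffin. Geometry is deterministic in the spec seed, with one
# RNG sub-stream per object class.
#
# Volumes are arrays indexed [row (y), column (x), slice (z)]; a 2D phantom
# is the nz = 1 case. Coordinates are 1-based with pixel centres at integer
# positions, following the usual R convention.

.phantom_legend <- c(paraffin = 1L, adipose = 2L, glandular = 3L,
                     stroma_dense = 4L, blood = 5L, calcification = 6L,
                     air = 7L)

#' Phantom specification
#'
#' Parameters of a procedural tissue-block phantom. Object sizes are radii in
#' micrometres; counts are exact (placement failure after bounded retries is
#' an error). If `adipose_fraction` is given (not `NA`), adipocytes are added
#' until that fraction of the tissue region is adipose and `n_adipocytes` is
#' ignored.
#'
#' @param shape grid shape: `c(ny, nx)` for a 2D slice or `c(ny, nx, nz)`
#'   for a thin 3D block.
#' @param voxel_um voxel size in micrometres.
#' @param n_adipocytes,adipocyte_r_um count and radius range of adipocytes.
#' @param adipose_fraction target adipose area fraction of the tissue region
#'   in `[0, 1]`, or `NA` to use `n_adipocytes`.
#' @param n_ducts,duct_r_um count and outer-radius range of duct/TDLU units.
#' @param n_calcifications,calc_r_um count and radius range of
#'   microcalcifications.
#' @param n_bubbles,bubble_r_um count and radius range of air bubbles in the
#'   paraffin margin.
#' @param n_vessels,vessel_r_um count and radius range of blood vessels.
#' @param stroma_corr_um correlation length of the dense-stroma texture.
#' @param stroma_fraction fraction of the tissue textured as dense stroma.
#' @param tissue_radius_frac tissue cylinder radius as a fraction of the
#'   half-width of the grid.
#' @param block_radius_frac radius of the cylindrical paraffin block as a
#'   fraction of the half-width; air lies outside, so a full-field scan of
#'   the block is laterally complete (truncation only arises when the
#'   detector window is made narrower than the block).
#' @param seed integer random seed; identical specs give identical phantoms.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(512, 512), voxel_um = 4,
                         n_adipocytes = 12, adipocyte_r_um = c(40, 120),
                         adipose_fraction = NA,
                         n_ducts = 2, duct_r_um = c(90, 170),
                         n_calcifications = 3, calc_r_um = c(10, 28),
                         n_bubbles = 2, bubble_r_um = c(12, 35),
                         n_vessels = 0, vessel_r_um = c(15, 40),
                         stroma_corr_um = 60, stroma_fraction = 0.35,
                         tissue_radius_frac = 0.78, block_radius_frac = 0.96,
                         seed = 1) {
  stopifnot(length(shape) %in% c(2, 3), all(shape >= 8), voxel_um > 0,
            n_adipocytes >= 0, n_ducts >= 0, n_calcifications >= 0,
            n_bubbles >= 0, n_vessels >= 0,
            stroma_fraction >= 0, stroma_fraction <= 1,
            tissue_radius_frac > 0, tissue_radius_frac <= 1,
            block_radius_frac > tissue_radius_frac, block_radius_frac <= 1)
  if (!is.na(adipose_fraction) &&
      (adipose_fraction < 0 || adipose_fraction > 1)) {
    stop_vh("adipose_fraction must be in [0, 1] or NA")
  }
  structure(list(shape = as.integer(shape), voxel_um = voxel_um,
                 n_adipocytes = as.integer(n_adipocytes),
                 adipocyte_r_um = adipocyte_r_um,
                 adipose_fraction = adipose_fraction,
                 n_ducts = as.integer(n_ducts), duct_r_um = duct_r_um,
                 n_calcifications = as.integer(n_calcifications),
                 calc_r_um = calc_r_um,
                 n_bubbles = as.integer(n_bubbles), bubble_r_um = bubble_r_um,
                 n_vessels = as.integer(n_vessels), vessel_r_um = vessel_r_um,
                 stroma_corr_um = stroma_corr_um,
                 stroma_fraction = stroma_fraction,
                 tissue_radius_frac = tissue_radius_frac,
                 block_radius_frac = block_radius_frac,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Paint a sphere (or disk when nz = 1) into `labels`; returns the updated
# array and the number of voxels painted.
.paint_sphere <- function(labels, cy, cx, cz, r, value, only_over = NULL) {
  d <- dim(labels); ny <- d[1]; nx <- d[2]; nz <- d[3]
  painted <- 0L
  zs <- max(1L, floor(cz - r)):min(nz, ceiling(cz + r))
  if (nz == 1L) zs <- 1L
  for (z in zs) {
    rz2 <- if (nz == 1L) r^2 else r^2 - (z - cz)^2
    if (rz2 <= 0) next
    rz <- sqrt(rz2)
    ys <- max(1L, floor(cy - rz)):min(ny, ceiling(cy + rz))
    xs <- max(1L, floor(cx - rz)):min(nx, ceiling(cx + rz))
    sub <- labels[ys, xs, z, drop = FALSE]
    m <- outer((ys - cy)^2, (xs - cx)^2, "+") <= rz2
    if (!is.null(only_over)) m <- m & (sub[, , 1] %in% only_over)
    painted <- painted + sum(m)
    sub[, , 1][m] <- value
    labels[ys, xs, z] <- sub
  }
  list(labels = labels, painted = painted)
}

# Rejection-sample non-overlapping object centres. `occupied` is a matrix of
# (cy, cx, cz, r). Objects of a class are placed sequentially with bounded
# retries; in-plane separation is enforced against all previously placed
# objects.
.place_object <- function(occupied, r, centre_fun, max_try = 1500L) {
  for (k in seq_len(max_try)) {
    c0 <- centre_fun(r)
    if (is.null(c0)) next
    if (nrow(occupied) > 0) {
      d2 <- (occupied[, 1] - c0[1])^2 + (occupied[, 2] - c0[2])^2
      if (any(d2 < (occupied[, 4] + r + 1)^2)) next
    }
    return(c(c0, r))
  }
  NULL
}

#' Generate a labeled tissue-block phantom
#'
#' Deterministically realises a [phantom_spec()] into a voxelised label map.
#' Paraffin fills all space not claimed by tissue or objects; every requested
#' object class is guaranteed at least one voxel.
#'
#' @param spec a `phantom_spec`.
#' @return object of class `labeled_volume`: list with integer array
#'   `labels` (`ny x nx x nz`), named integer `legend`, `voxel_um`, the
#'   `spec`, and a `tissue_mask` of the tissue cylinder.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  sh <- spec$shape
  ny <- sh[1]; nx <- sh[2]; nz <- if (length(sh) == 3) sh[3] else 1L
  vx <- spec$voxel_um
  seeds <- sub_seeds(spec$seed, 8)

  labels <- array(.phantom_legend[["air"]], dim = c(ny, nx, nz))
  half <- min(ny, nx) / 2
  r_tissue <- spec$tissue_radius_frac * half
  r_block <- spec$block_radius_frac * half
  # the mounted block and the embedded tissue are never perfectly centred
  # on the rotation axis; small seeded offsets avoid the degenerate
  # angle-invariant (column-locked) edge geometry a perfectly centred
  # cylinder would have
  offs <- with_seed(seeds[7], stats::runif(4, -1, 1))
  bl_cy <- (ny + 1) / 2 + offs[1] * 0.01 * half
  bl_cx <- (nx + 1) / 2 + offs[2] * 0.01 * half
  cy0 <- (ny + 1) / 2 + offs[3] * 0.04 * half
  cx0 <- (nx + 1) / 2 + offs[4] * 0.04 * half
  r_block <- min(r_block, half - max(abs(c(bl_cy - (ny + 1) / 2,
                                           bl_cx - (nx + 1) / 2))) - 1)
  block2d <- outer((seq_len(ny) - bl_cy)^2, (seq_len(nx) - bl_cx)^2, "+") <= r_block^2
  in_plane_r2 <- outer((seq_len(ny) - cy0)^2, (seq_len(nx) - cx0)^2, "+")
  tissue2d <- in_plane_r2 <= r_tissue^2
  for (z in seq_len(nz)) labels[, , z][block2d] <- .phantom_legend[["paraffin"]]
  for (z in seq_len(nz)) labels[, , z][tissue2d] <- .phantom_legend[["glandular"]]
  n_tissue <- sum(tissue2d) * nz

  # dense-stroma texture: thresholded correlated Gaussian field
  if (spec$stroma_fraction > 0) {
    sig <- max(spec$stroma_corr_um / vx, 1)
    field <- with_seed(seeds[1], array(stats::rnorm(ny * nx * nz), c(ny, nx, nz)))
    for (z in seq_len(nz)) field[, , z] <- gaussian_blur(field[, , z], sig)
    if (nz > 1) { # mild through-plane coherence
      for (i in seq_len(2)) {
        f2 <- field
        f2[, , 2:nz] <- (field[, , 2:nz] + field[, , 1:(nz - 1)]) / 2
        field <- f2
      }
    }
    thr <- stats::quantile(field[rep(tissue2d, nz)], 1 - spec$stroma_fraction)
    for (z in seq_len(nz)) {
      m <- tissue2d & field[, , z] >= thr
      labels[, , z][m] <- .phantom_legend[["stroma_dense"]]
    }
  }

  occupied <- matrix(numeric(0), ncol = 4)
  soft <- .phantom_legend[c("glandular", "stroma_dense")]
  centre_tissue <- function(r) {
    a <- stats::runif(1, 0, 2 * pi)
    rr <- sqrt(stats::runif(1)) * max(r_tissue - r - 2, 1)
    c(cy0 + rr * sin(a), cx0 + rr * cos(a), stats::runif(1, 1, nz))
  }

  # ducts / TDLU-like units: glandular wall, paraffin lumen, ring of acini
  if (spec$n_ducts > 0) {
    with_seed(seeds[2], {
      for (i in seq_len(spec$n_ducts)) {
        r <- stats::runif(1, spec$duct_r_um[1], spec$duct_r_um[2]) / vx
        ob <- .place_object(occupied, r * 1.9, centre_tissue)
        if (is.null(ob)) stop_vh("could not place duct %d after bounded retries", i)
        occupied <- rbind(occupied, ob)
        wt <- max(2, 0.22 * r)
        for (z in seq_len(nz)) {
          res <- .paint_sphere(labels[, , z, drop = FALSE], ob[1], ob[2], 1, r,
                               .phantom_legend[["glandular"]])$labels
          res <- .paint_sphere(res, ob[1], ob[2], 1, r - wt,
                               .phantom_legend[["paraffin"]])$labels
          labels[, , z] <- res[, , 1]
        }
        # acini ring
        n_a <- sample(6:12, 1)
        ra <- max(2.5, 0.32 * r)
        for (j in seq_len(n_a)) {
          ang <- 2 * pi * j / n_a + stats::runif(1, -0.15, 0.15)
          ay <- ob[1] + (r + ra + 1) * sin(ang)
          ax <- ob[2] + (r + ra + 1) * cos(ang)
          for (z in seq_len(nz)) {
            res <- .paint_sphere(labels[, , z, drop = FALSE], ay, ax, 1, ra,
                                 .phantom_legend[["glandular"]], only_over = soft)$labels
            res <- .paint_sphere(res, ay, ax, 1, max(ra * 0.45, 1),
                                 .phantom_legend[["paraffin"]],
                                 only_over = .phantom_legend[["glandular"]])$labels
            labels[, , z] <- res[, , 1]
          }
        }
      }
    })
  }

  # adipocytes: non-overlapping spheres; count-driven or fraction-driven
  adip_painted <- 0L
  with_seed(seeds[3], {
    if (!is.na(spec$adipose_fraction)) {
      target <- spec$adipose_fraction * n_tissue
      fails <- 0L
      while (adip_painted < target) {
        r <- stats::runif(1, spec$adipocyte_r_um[1], spec$adipocyte_r_um[2]) / vx
        r <- max(r, 1.5)
        ob <- .place_object(occupied, r, centre_tissue, max_try = 200L)
        if (is.null(ob)) {
          fails <- fails + 1L
          if (fails > 50L) {
            stop_vh("cannot reach adipose fraction %.2f: no room for more adipocytes",
                    spec$adipose_fraction)
          }
          next
        }
        occupied <- rbind(occupied, ob)
        res <- .paint_sphere(labels, ob[1], ob[2], ob[3], r,
                             .phantom_legend[["adipose"]], only_over = soft)
        labels <- res$labels
        adip_painted <- adip_painted + res$painted
      }
    } else if (spec$n_adipocytes > 0) {
      for (i in seq_len(spec$n_adipocytes)) {
        r <- max(stats::runif(1, spec$adipocyte_r_um[1], spec$adipocyte_r_um[2]) / vx, 1.5)
        ob <- .place_object(occupied, r, centre_tissue)
        if (is.null(ob)) stop_vh("could not place adipocyte %d after bounded retries", i)
        occupied <- rbind(occupied, ob)
        res <- .paint_sphere(labels, ob[1], ob[2], ob[3], r,
                             .phantom_legend[["adipose"]], only_over = soft)
        if (res$painted == 0) { # sphere centred between slices; force one voxel
          res <- .paint_sphere(labels, ob[1], ob[2], round(ob[3]), max(r, 1.5),
                               .phantom_legend[["adipose"]], only_over = soft)
        }
        labels <- res$labels
        adip_painted <- adip_painted + res$painted
      }
    }
  })

  # blood vessels
  if (spec$n_vessels > 0) {
    with_seed(seeds[4], {
      for (i in seq_len(spec$n_vessels)) {
        r <- max(stats::runif(1, spec$vessel_r_um[1], spec$vessel_r_um[2]) / vx, 1.5)
        ob <- .place_object(occupied, r, centre_tissue)
        if (is.null(ob)) stop_vh("could not place vessel %d after bounded retries", i)
        occupied <- rbind(occupied, ob)
        for (z in seq_len(nz)) { # vessels run through the thin block
          labels[, , z] <- .paint_sphere(labels[, , z, drop = FALSE],
                                         ob[1], ob[2], 1, r,
                                         .phantom_legend[["blood"]])$labels[, , 1]
        }
      }
    })
  }

  # microcalcifications: strictly disjoint (one connected component each)
  if (spec$n_calcifications > 0) {
    with_seed(seeds[5], {
      for (i in seq_len(spec$n_calcifications)) {
        r <- max(stats::runif(1, spec$calc_r_um[1], spec$calc_r_um[2]) / vx, 1.5)
        ob <- .place_object(occupied, r + 2, centre_tissue)
        if (is.null(ob)) stop_vh("could not place calcification %d after bounded retries", i)
        occupied <- rbind(occupied, ob)
        cz <- if (nz == 1L) 1 else max(1, min(nz, round(ob[3])))
        res <- .paint_sphere(labels, ob[1], ob[2], cz,
                             max(r, if (nz > 1) 1.5 else r),
                             .phantom_legend[["calcification"]])
        labels <- res$labels
      }
    })
  }

  # air bubbles in the paraffin margin
  if (spec$n_bubbles > 0) {
    with_seed(seeds[6], {
      centre_paraffin <- function(r) {
        a <- stats::runif(1, 0, 2 * pi)
        rr <- r_tissue + r + 1 +
          stats::runif(1) * max(r_block - r_tissue - 2 * r - 2, 0.5)
        cy <- cy0 + rr * sin(a); cx <- cx0 + rr * cos(a)
        if (sqrt((cy - bl_cy)^2 + (cx - bl_cx)^2) + r > r_block - 1) return(NULL)
        if (cy - r < 1 || cy + r > ny || cx - r < 1 || cx + r > nx) return(NULL)
        c(cy, cx, stats::runif(1, 1, nz))
      }
      for (i in seq_len(spec$n_bubbles)) {
        r <- max(stats::runif(1, spec$bubble_r_um[1], spec$bubble_r_um[2]) / vx, 1.5)
        ob <- .place_object(occupied, r, centre_paraffin)
        if (is.null(ob)) stop_vh("could not place air bubble %d after bounded retries", i)
        occupied <- rbind(occupied, ob)
        cz <- if (nz == 1L) 1 else max(1, min(nz, round(ob[3])))
        labels <- .paint_sphere(labels, ob[1], ob[2], cz, r,
                                .phantom_legend[["air"]])$labels
      }
    })
  }

  # guarantee: every requested class has at least one voxel
  want <- c(glandular = TRUE,
            adipose = spec$n_adipocytes > 0 ||
              (!is.na(spec$adipose_fraction) && spec$adipose_fraction > 0),
            calcification = spec$n_calcifications > 0,
            air = spec$n_bubbles > 0, blood = spec$n_vessels > 0)
  for (nm in names(want)[unlist(want)]) {
    if (!any(labels == .phantom_legend[[nm]])) {
      stop_vh("requested class '%s' has no voxels in the generated phantom", nm)
    }
  }

  structure(list(labels = labels, legend = .phantom_legend,
                 voxel_um = vx, spec = spec, tissue_mask = tissue2d),
            class = "labeled_volume")
}

#' @export
print.labeled_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("labeled_volume %dx%dx%d @ %g um/voxel\n", d[1], d[2], d[3], x$voxel_um))
  tab <- table(factor(x$labels, levels = x$legend, labels = names(x$legend)))
  frac <- round(as.numeric(tab) / length(x$labels), 4)
  for (i in seq_along(tab)) cat(sprintf("  %-13s %8d (%.2f%%)\n",
                                        names(tab)[i], tab[i], 100 * frac[i]))
  invisible(x)
}

#' Label fractions of a phantom
#'
#' Fraction of voxels carrying each label; sums to 1 over the grid. With
#' `within_tissue = TRUE` fractions are taken over the tissue cylinder only.
#' @param vol a `labeled_volume`.
#' @param within_tissue restrict to the tissue region.
#' @export
label_fractions <- function(vol, within_tissue = FALSE) {
  stopifnot(inherits(vol, "labeled_volume"))
  lab <- vol$labels
  if (within_tissue) lab <- lab[rep(vol$tissue_mask, dim(vol$labels)[3])]
  tab <- table(factor(lab, levels = vol$legend, labels = names(vol$legend)))
  as.numeric(tab) / length(lab) -> fr
  names(fr) <- names(tab)
  fr
}

#' Convert a label map to a refractive-index map
#'
#' Per-voxel lookup of (delta, beta) for each label's material.
#'
#' @param vol a `labeled_volume`.
#' @param table a `material_table` containing every legend material.
#' @param edge_sigma_px optional in-plane Gaussian smoothing (pixels) of the
#'   delta and beta maps, emulating partial-volume softness of biological
#'   interfaces at micrometre pixel sizes; 0 (the default) keeps the exact
#'   per-voxel lookup.
#' @return object of class `refractive_map`: arrays `delta` and `beta`
#'   (same shape as the labels), `voxel_um`, `energy_keV` and the source
#'   `labels`/`legend` kept as ground truth.
#' @export
labels_to_refractive <- function(vol, table, edge_sigma_px = 0) {
  stopifnot(inherits(vol, "labeled_volume"), inherits(table, "material_table"))
  missing <- setdiff(names(vol$legend), material_names(table))
  if (length(missing) > 0) {
    stop_vh("legend material(s) missing from table: %s",
            paste(missing, collapse = ", "))
  }
  ids <- sort(unique(as.integer(vol$legend)))
  dvec <- numeric(max(ids)); bvec <- numeric(max(ids))
  for (nm in names(vol$legend)) {
    e <- material_lookup(table, nm)
    dvec[vol$legend[[nm]]] <- e[["delta"]]
    bvec[vol$legend[[nm]]] <- e[["beta"]]
  }
  delta <- array(dvec[vol$labels], dim = dim(vol$labels))
  beta <- array(bvec[vol$labels], dim = dim(vol$labels))
  if (edge_sigma_px > 0) {
    for (z in seq_len(dim(delta)[3])) {
      delta[, , z] <- gaussian_blur(delta[, , z], edge_sigma_px)
      beta[, , z] <- gaussian_blur(beta[, , z], edge_sigma_px)
    }
  }
  structure(list(delta = delta, beta = beta, voxel_um = vol$voxel_um,
                 energy_keV = table$energy_keV, labels = vol$labels,
                 legend = vol$legend),
            class = "refractive_map")
}

#' Ground-truth linear attenuation map
#'
#' `mu = 4 * pi * beta / lambda` per voxel, in 1/m. This is the quantity a
#' correctly scaled reconstruction is proportional to.
#' @param rmap a `refractive_map`.
#' @export
mu_map <- function(rmap) {
  stopifnot(inherits(rmap, "refractive_map"))
  4 * pi * rmap$beta / xray_wavelength(rmap$energy_keV)
}

#' Region-of-interest mask for one material of a phantom slice
#'
#' Logical mask of the voxels of slice `k` carrying `material`, optionally
#' eroded to stay clear of boundary blur in reconstructed images.
#' @param vol a `labeled_volume` (or `refractive_map` retaining labels).
#' @param material material name.
#' @param k slice index.
#' @param erode_px erosion half-width in pixels.
#' @export
material_mask <- function(vol, material, k = 1, erode_px = 0) {
  legend <- vol$legend
  if (!material %in% names(legend)) stop_vh("unknown material '%s'", material)
  m <- vol$labels[, , k] == legend[[material]]
  if (erode_px > 0) m <- erode_mask(m, erode_px)
  m
}
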