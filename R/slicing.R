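# Virtual slicing of reconstructed volumes and synthesis of degraded
# histology-like sections. Volumes are arrays [row (y), column (x),
# slice (z)], 1-based, with planes defined in voxel units. Rigid 2D
# transforms act about the image centre: T(p) = s * R(theta) * (p - c) +
# c + t, with p = (row, col) and t = (t_row, t_col) in pixels.

#' Oblique slice plane
#'
#' @param origin plane origin `c(row, col, slice)` in voxel coordinates.
#' @param u,v orthonormal in-plane direction vectors (voxel coordinates,
#'   `c(d_row, d_col, d_slice)`), orthogonal to 1e-10.
#' @param extent output size `c(rows, cols)`.
#' @param step_um sampling step along both directions, micrometres.
#' @return object of class `slice_plane`.
#' @export
slice_plane <- function(origin, u, v, extent, step_um) {
  stopifnot(length(origin) == 3, length(u) == 3, length(v) == 3,
            length(extent) == 2, all(extent >= 1), step_um > 0)
  if (abs(sqrt(sum(u^2)) - 1) > 1e-10 || abs(sqrt(sum(v^2)) - 1) > 1e-10 ||
      abs(sum(u * v)) > 1e-10) {
    stop_vh("u and v must be orthonormal unit vectors (tolerance 1e-10)")
  }
  structure(list(origin = origin, u = u, v = v,
                 extent = as.integer(extent), step_um = step_um),
            class = "slice_plane")
}

#' Axis-aligned plane through stored slice k
#' @param vol a `recon_volume` or any object with `volume` and `voxel_um`.
#' @param k slice index.
#' @export
axial_plane <- function(vol, k) {
  d <- dim(vol$volume)
  stopifnot(k >= 1, k <= d[3])
  slice_plane(c(1, 1, k), c(1, 0, 0), c(0, 1, 0), d[1:2], vol$voxel_um)
}

# Trilinear sampling of array `a` at fractional (y, x, z); outside -> NA.
trilinear_sample <- function(a, y, x, z) {
  d <- dim(a)
  ok <- y >= 1 & y <= d[1] & x >= 1 & x <= d[2] & z >= 1 & z <= d[3]
  y0 <- pmin.int(pmax.int(floor(y), 1L), max(d[1] - 1L, 1L))
  x0 <- pmin.int(pmax.int(floor(x), 1L), max(d[2] - 1L, 1L))
  z0 <- pmin.int(pmax.int(floor(z), 1L), max(d[3] - 1L, 1L))
  fy <- y - y0; fx <- x - x0; fz <- z - z0
  if (d[3] == 1L) { z0 <- rep(1L, length(y)); fz <- rep(0, length(y)) }
  idx <- function(dy, dx, dz) a[cbind(y0 + dy, x0 + dx, pmin.int(z0 + dz, d[3]))]
  v <- (((idx(0L, 0L, 0L) * (1 - fx) + idx(0L, 1L, 0L) * fx) * (1 - fy) +
         (idx(1L, 0L, 0L) * (1 - fx) + idx(1L, 1L, 0L) * fx) * fy) * (1 - fz)) +
       (((idx(0L, 0L, 1L) * (1 - fx) + idx(0L, 1L, 1L) * fx) * (1 - fy) +
         (idx(1L, 0L, 1L) * (1 - fx) + idx(1L, 1L, 1L) * fx) * fy) * fz)
  v[!ok] <- NA_real_
  v
}

#' Extract a (possibly oblique) virtual slice
#'
#' Samples the volume over the plane grid with trilinear interpolation.
#' Sample points outside the volume are `NA` and their count is attached as
#' attribute `n_missing`. An axis-aligned plane at an integer slice index
#' reproduces the stored slice exactly.
#'
#' @param vol a `recon_volume` (or any list with `volume`, `voxel_um`).
#' @param plane a `slice_plane`.
#' @return numeric matrix `extent[1] x extent[2]`.
#' @export
extract_slice <- function(vol, plane) {
  stopifnot(inherits(plane, "slice_plane"))
  a <- vol$volume
  step <- plane$step_um / vol$voxel_um
  i <- rep(seq_len(plane$extent[1]) - 1, times = plane$extent[2])
  j <- rep(seq_len(plane$extent[2]) - 1, each = plane$extent[1])
  y <- plane$origin[1] + step * (i * plane$u[1] + j * plane$v[1])
  x <- plane$origin[2] + step * (i * plane$u[2] + j * plane$v[2])
  z <- plane$origin[3] + step * (i * plane$u[3] + j * plane$v[3])
  v <- trilinear_sample(a, y, x, z)
  if (all(is.na(v))) stop_vh("plane lies entirely outside the volume")
  out <- matrix(v, plane$extent[1], plane$extent[2])
  attr(out, "n_missing") <- sum(is.na(v))
  out
}

#' Rigid 2D transform
#'
#' In-plane rotation + translation (+ optional isotropic scale) about the
#' image centre. `theta_deg` is counterclockwise; translation is
#' `c(t_row, t_col)` in pixels.
#'
#' @param theta_deg rotation angle in degrees.
#' @param t translation `c(t_row, t_col)` in pixels.
#' @param scale isotropic scale (> 0).
#' @param score optional similarity score attached after registration.
#' @return object of class `rigid_transform_2d`.
#' @export
rigid_transform_2d <- function(theta_deg = 0, t = c(0, 0), scale = 1,
                               score = NA_real_) {
  stopifnot(length(t) == 2, scale > 0)
  structure(list(theta_deg = theta_deg, t = as.numeric(t), scale = scale,
                 score = score),
            class = "rigid_transform_2d")
}

.rot2 <- function(theta_deg) {
  th <- theta_deg * pi / 180
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)  # acts on (row, col)
}

#' Invert a rigid 2D transform
#' @param tr a `rigid_transform_2d`.
#' @export
invert_transform <- function(tr) {
  stopifnot(inherits(tr, "rigid_transform_2d"))
  rigid_transform_2d(-tr$theta_deg,
                     as.numeric(-(.rot2(-tr$theta_deg) %*% tr$t) / tr$scale),
                     1 / tr$scale, tr$score)
}

#' Compose two rigid 2D transforms (`t2` after `t1`)
#' @param t1,t2 `rigid_transform_2d` objects.
#' @export
compose_transform <- function(t1, t2) {
  rigid_transform_2d(t1$theta_deg + t2$theta_deg,
                     as.numeric(t2$scale * (.rot2(t2$theta_deg) %*% t1$t) + t2$t),
                     t1$scale * t2$scale)
}

#' Apply a rigid 2D transform to an image
#'
#' Resamples with bilinear interpolation: a feature at point `p` of the
#' input appears at `T(p)` in the output. Pixels mapping outside the input
#' are set to `fill` (default: the input median).
#'
#' @param img numeric matrix.
#' @param tr a `rigid_transform_2d`.
#' @param fill fill value for out-of-support pixels.
#' @export
apply_transform <- function(img, tr, fill = NULL) {
  stopifnot(is.matrix(img), inherits(tr, "rigid_transform_2d"))
  fill <- fill %||% stats::median(img)
  if (tr$theta_deg == 0 && all(tr$t == 0) && tr$scale == 1) return(img)
  c0 <- (dim(img) + 1) / 2
  Ri <- .rot2(-tr$theta_deg)
  qy <- rep(seq_len(nrow(img)), times = ncol(img)) - c0[1] - tr$t[1]
  qx <- rep(seq_len(ncol(img)), each = nrow(img)) - c0[2] - tr$t[2]
  py <- (Ri[1, 1] * qy + Ri[1, 2] * qx) / tr$scale + c0[1]
  px <- (Ri[2, 1] * qy + Ri[2, 2] * qx) / tr$scale + c0[2]
  v <- bilinear_sample(img, px, py, outside = NA)
  v[is.na(v)] <- fill
  matrix(v, nrow(img), ncol(img))
}

#' @export
print.rigid_transform_2d <- function(x, ...) {
  cat(sprintf("rigid_transform_2d: theta = %.3f deg, t = (%.2f, %.2f) px, scale = %.4f%s\n",
              x$theta_deg, x$t[1], x$t[2], x$scale,
              if (is.finite(x$score)) sprintf(", score = %.4f", x$score) else ""))
  invisible(x)
}

#' Simulate a histology-like section from a volume
#'
#' Emulates a digitised stained section cut at stored slice `k`: averages
#' the section thickness worth of slices, applies a rigid transform (the
#' unknown mounting pose), an affine intensity remap, and seeded random
#' tissue-dropout holes emulating material lost during sectioning and
#' staining. The realised dropout mask is attached as attribute
#' `dropout_mask`.
#'
#' @param vol a `recon_volume`-like object.
#' @param k stored slice index at which the section is cut.
#' @param thickness_um physical section thickness (> 0); slices within it
#'   are averaged.
#' @param transform a `rigid_transform_2d` (default identity).
#' @param intensity `c(gain, offset)` affine intensity remap.
#' @param dropout_frac target fraction of pixels lost to holes, in [0, 1).
#' @param hole_r_px radius range of dropout holes, pixels.
#' @param seed seed for the dropout holes.
#' @export
simulate_section <- function(vol, k, thickness_um = 5,
                             transform = rigid_transform_2d(),
                             intensity = c(1, 0), dropout_frac = 0,
                             hole_r_px = c(3, 8), seed = 1) {
  d <- dim(vol$volume)
  stopifnot(thickness_um > 0, k >= 1, k <= d[3],
            dropout_frac >= 0, dropout_frac < 1)
  n_avg <- max(1L, ceiling(thickness_um / vol$voxel_um))
  ks <- k:min(d[3], k + n_avg - 1L)
  img <- matrix(0, d[1], d[2])
  for (kk in ks) img <- img + vol$volume[, , kk]
  img <- img / length(ks)
  img <- apply_transform(img, transform)
  img <- intensity[1] * img + intensity[2]
  mask <- matrix(FALSE, d[1], d[2])
  if (dropout_frac > 0) {
    fill <- stats::median(img)
    with_seed(seed, {
      target <- dropout_frac * length(img)
      guard <- 0L
      while (sum(mask) < target && guard < 10000L) {
        guard <- guard + 1L
        r <- stats::runif(1, hole_r_px[1], hole_r_px[2])
        # cap the last holes so the realised fraction lands near the target
        r <- min(r, sqrt((target - sum(mask)) / pi) + 0.5)
        if (r < 0.5) break
        cy <- stats::runif(1, 1 + r, d[1] - r)
        cx <- stats::runif(1, 1 + r, d[2] - r)
        ys <- floor(cy - r):ceiling(cy + r)
        xs <- floor(cx - r):ceiling(cx + r)
        m <- outer((ys - cy)^2, (xs - cx)^2, "+") <= r^2
        mask[ys, xs] <- mask[ys, xs] | m
      }
    })
    img[mask] <- fill
  }
  attr(img, "dropout_mask") <- mask
  img
}
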