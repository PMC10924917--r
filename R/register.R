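# Automated rigid co-registration of a 2D histology-like section to CT
# slices by normalized cross-correlation (NCC): exhaustive coarse search
# over rotation with FFT-based translation search, followed by fine
# rotation refinement and sub-pixel parabolic interpolation of the
# correlation peak. NCC is invariant to affine intensity remaps, which is
# what makes it suitable for sections sharing the CT contrast mechanism.

# normalized (zero-mean, unit population variance) copy of an image
.ncc_normalise <- function(img) {
  m <- mean(img)
  s <- sqrt(mean((img - m)^2))
  if (s < .Machine$double.eps) stop_vh("zero-variance image; cannot register")
  (img - m) / s
}

# Cross-correlation of fixed against shifted moving via FFT; returns the
# best integer shift within max_shift and the score surface around it.
.ncc_best_shift <- function(fz, mz, max_shift) {
  d <- dim(fz)
  np <- c(next_pow2(d[1] + 2 * max_shift), next_pow2(d[2] + 2 * max_shift))
  F <- matrix(0, np[1], np[2]); F[seq_len(d[1]), seq_len(d[2])] <- fz
  M <- matrix(0, np[1], np[2]); M[seq_len(d[1]), seq_len(d[2])] <- mz
  cc <- Re(stats::fft(stats::fft(F) * Conj(stats::fft(M)), inverse = TRUE)) /
    length(F) / length(fz)
  sh <- c(0:max_shift, -(max_shift:1))
  iy <- c(seq_len(max_shift + 1), np[1] - (max_shift:1) + 1)
  ix <- c(seq_len(max_shift + 1), np[2] - (max_shift:1) + 1)
  sub <- cc[iy, ix]
  pk <- arrayInd(which.max(sub), dim(sub))
  # parabolic sub-pixel refinement along each axis
  subpix <- function(i, along) {
    get <- function(di, dj) sub[((pk[1] - 1 + di) %% length(iy)) + 1,
                                ((pk[2] - 1 + dj) %% length(ix)) + 1]
    c0 <- get(0, 0)
    cm <- if (along == 1) get(-1, 0) else get(0, -1)
    cp <- if (along == 1) get(1, 0) else get(0, 1)
    den <- cm - 2 * c0 + cp
    if (abs(den) < .Machine$double.eps) 0 else 0.5 * (cm - cp) / den
  }
  dy <- sh[pk[1]] + subpix(pk[1], 1)
  dx <- sh[pk[2]] + subpix(pk[2], 2)
  list(t = c(dy, dx), score = max(sub))
}

#' Rigid 2D registration by normalized cross-correlation
#'
#' Finds the rigid transform `T` maximising the NCC between
#' `apply_transform(moving, T)` and `fixed`: a coarse grid over rotation
#' angles (translation searched by FFT at each angle) followed by local
#' rotation refinement. Images must share a pixel size (resample first) and
#' have non-zero variance. Deterministic given the search configuration.
#'
#' @param moving,fixed numeric matrices of identical size.
#' @param search list of options: `theta_range` (degrees, default
#'   `c(-15, 15)`), `theta_step` (default 1), `refine_steps` (default 2
#'   rounds of 5x finer grids), `max_shift` (pixels, default a quarter of
#'   the smaller image side).
#' @return a `rigid_transform_2d` with its NCC `score` in `[-1, 1]`.
#' @export
register_2d <- function(moving, fixed, search = list()) {
  stopifnot(is.matrix(moving), is.matrix(fixed), all(dim(moving) == dim(fixed)))
  theta_range <- search$theta_range %||% c(-15, 15)
  theta_step <- search$theta_step %||% 1
  refine_steps <- search$refine_steps %||% 2
  max_shift <- as.integer(search$max_shift %||% floor(min(dim(fixed)) / 4))
  fz <- .ncc_normalise(fixed)
  mz0 <- .ncc_normalise(moving)
  eval_theta <- function(th) {
    mz <- if (th == 0) mz0 else apply_transform(mz0, rigid_transform_2d(th), fill = 0)
    .ncc_best_shift(fz, mz, max_shift)
  }
  thetas <- seq(theta_range[1], theta_range[2], by = theta_step)
  res <- lapply(thetas, eval_theta)
  scores <- vapply(res, `[[`, numeric(1), "score")
  best_i <- which.max(scores)
  best_th <- thetas[best_i]; best <- res[[best_i]]
  step <- theta_step
  for (r in seq_len(refine_steps)) {
    step <- step / 5
    cand <- best_th + step * (-4:4)
    resr <- lapply(cand, eval_theta)
    sc <- vapply(resr, `[[`, numeric(1), "score")
    if (max(sc) > best$score) {
      best_i <- which.max(sc)
      best_th <- cand[best_i]; best <- resr[[best_i]]
    }
  }
  rigid_transform_2d(best_th, best$t, scale = 1, score = best$score)
}

#' Find the CT plane best matching a section
#'
#' Exhaustively registers the section against axis-aligned candidate
#' slices over a depth range and returns the plane and transform with the
#' highest NCC score — the automated counterpart of matching a stained
#' section to its position in the CT stack.
#'
#' @param vol a `recon_volume`-like object.
#' @param section 2D image (same pixel size as the volume).
#' @param search list: `depths` (candidate slice indices, default all),
#'   plus the [register_2d()] options.
#' @return list with `depth`, `plane` (`slice_plane`), `transform`
#'   (`rigid_transform_2d` with score) and `scores` per candidate depth.
#' @export
find_best_plane <- function(vol, section, search = list()) {
  d <- dim(vol$volume)
  depths <- search$depths %||% seq_len(d[3])
  if (length(depths) == 0) stop_vh("empty depth search range")
  stopifnot(all(depths >= 1), all(depths <= d[3]))
  fits <- lapply(depths, function(k) {
    register_2d(section, vol$volume[, , k], search)
  })
  scores <- vapply(fits, function(f) f$score, numeric(1))
  best <- which.max(scores)
  list(depth = depths[best], plane = axial_plane(vol, depths[best]),
       transform = fits[[best]], scores = stats::setNames(scores, depths))
}

#' Export a CT/section overlay as an RGB TIFF
#'
#' CT slice in gray, the (transform-aligned) section in the green channel;
#' both windowed to their 1-99 percentile range.
#'
#' @param ct_slice CT slice matrix.
#' @param section section image matrix.
#' @param transform `rigid_transform_2d` aligning the section to the slice.
#' @param path output TIFF path.
#' @export
write_overlay <- function(ct_slice, section, transform, path) {
  wind <- function(x) {
    q <- stats::quantile(x, c(0.01, 0.99))
    pmin(pmax((x - q[1]) / max(q[2] - q[1], .Machine$double.eps), 0), 1)
  }
  aligned <- apply_transform(section, transform)
  rgb <- array(0, c(dim(ct_slice), 3))
  g <- wind(ct_slice)
  rgb[, , 1] <- g
  rgb[, , 2] <- 0.5 * g + 0.5 * wind(aligned)
  rgb[, , 3] <- g
  tiff::writeTIFF(rgb, path, bits.per.sample = 8L)
  invisible(path)
}
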