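# Internal numeric helpers shared across the pipeline: FFT frequency grids,
# replicate padding, bilinear sampling, separable Gaussian smoothing and a
# seed-scoped RNG guard. All spatial sampling is bilinear with 1-based pixel
# centers at integer coordinates.

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# DFT sample frequencies (cycles per unit of `d`), standard FFT ordering.
fftfreq <- function(n, d = 1) {
  stopifnot(n >= 1, d > 0)
  k <- c(seq_len(ceiling(n / 2)) - 1L, seq.int(-floor(n / 2), -1L))
  k[seq_len(n)] / (n * d)
}

next_pow2 <- function(n) 2^ceiling(log2(max(n, 2)))

# Replicate-edge padding; `pad` columns on each side of a vector, or
# (pad_row, pad_col) around a matrix.
pad_replicate <- function(x, pad) {
  if (is.matrix(x)) {
    pr <- pad[1]; pc <- if (length(pad) > 1) pad[2] else pad[1]
    ri <- c(rep(1L, pr), seq_len(nrow(x)), rep(nrow(x), pr))
    ci <- c(rep(1L, pc), seq_len(ncol(x)), rep(ncol(x), pc))
    x[ri, ci, drop = FALSE]
  } else {
    c(rep(x[1], pad), x, rep(x[length(x)], pad))
  }
}

unpad <- function(x, pad) {
  if (is.matrix(x)) {
    pr <- pad[1]; pc <- if (length(pad) > 1) pad[2] else pad[1]
    x[(pr + 1):(nrow(x) - pr), (pc + 1):(ncol(x) - pc), drop = FALSE]
  } else {
    x[(pad + 1):(length(x) - pad)]
  }
}

# Bilinear sampling of matrix `img` at fractional (row = y, col = x)
# coordinates, 1-based. Points outside the grid return `outside`.
bilinear_sample <- function(img, x, y, outside = 0) {
  nr <- nrow(img); nc <- ncol(img)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  # clamp the sampled corner into range; validity decided separately
  ok <- x >= 1 & x <= nc & y >= 1 & y <= nr
  x0c <- pmin.int(pmax.int(x0, 1L), nc - 1L)
  y0c <- pmin.int(pmax.int(y0, 1L), nr - 1L)
  # treat exact last row/col: shift base cell down, fraction becomes 1
  fx <- x - x0c; fy <- y - y0c
  i00 <- (x0c - 1) * nr + y0c
  v <- (img[i00] * (1 - fx) + img[i00 + nr] * fx) * (1 - fy) +
       (img[i00 + 1] * (1 - fx) + img[i00 + nr + 1] * fx) * fy
  v[!ok] <- outside
  v
}

gaussian_kernel1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable Gaussian smoothing with replicate edges; works on vectors and
# matrices. sigma in pixels; sigma = 0 is the identity.
gaussian_blur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  k <- gaussian_kernel1d(sigma)
  r <- (length(k) - 1L) / 2L
  conv1 <- function(v) {
    vp <- pad_replicate(v, r)
    stats::convolve(vp, rev(k), type = "filter")
  }
  if (is.matrix(x)) {
    x <- apply(x, 2, conv1)
    t(apply(t(x), 2, conv1))
  } else {
    conv1(x)
  }
}

# Evaluate a block seeded deterministically, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# Derive independent sub-stream seeds from one master seed.
sub_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Binary erosion of a logical mask by a square structuring element of
# half-width r, via an integral-image box sum.
erode_mask <- function(mask, r) {
  if (r <= 0) return(mask)
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  cs <- apply(rbind(0, m), 2, cumsum)
  # row-direction box sum
  n <- nrow(m)
  lo <- pmax(seq_len(n) - r, 1L)
  hi <- pmin(seq_len(n) + r, n)
  s1 <- cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]
  # column-direction sum
  cs2 <- t(apply(cbind(0, s1), 1, cumsum))
  nc <- ncol(m)
  lo <- pmax(seq_len(nc) - r, 1L)
  hi <- pmin(seq_len(nc) + r, nc)
  s2 <- cs2[, hi + 1L, drop = FALSE] - cs2[, lo, drop = FALSE]
  full <- outer(pmin(seq_len(n) + r, n) - pmax(seq_len(n) - r, 1L) + 1L,
                pmin(seq_len(nc) + r, nc) - pmax(seq_len(nc) - r, 1L) + 1L)
  s2 >= full - 0.5
}

stop_vh <- function(...) stop(sprintf(...), call. = FALSE)
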