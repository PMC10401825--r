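# Internal grid numerics: array shifts, separable convolution, trilinear
# interpolation, finite-difference gradients, morphology. Everything is
# vectorized over whole 3-D arrays; no compiled code.

# Shift a 3-D array by k voxels along one axis: out[i] = a[i - k] along `axis`,
# vacated entries filled with `fill`.
.shift3 <- function(a, k, axis, fill = 0) {
  if (k == 0L) return(a)
  d <- dim(a)
  n <- d[axis]
  if (abs(k) >= n) return(array(fill, dim = d))
  out <- array(fill, dim = d)
  src <- if (k > 0L) 1L:(n - k) else (1L - k):n
  dst <- if (k > 0L) (1L + k):n else 1L:(n + k)
  ix_src <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  ix_dst <- ix_src
  ix_src[[axis]] <- src
  ix_dst[[axis]] <- dst
  out[ix_dst[[1]], ix_dst[[2]], ix_dst[[3]]] <-
    a[ix_src[[1]], ix_src[[2]], ix_src[[3]]]
  out
}

# Convolve along one axis with a centered odd-length kernel (zero padding).
.conv_axis <- function(a, kernel, axis) {
  m <- (length(kernel) - 1L) %/% 2L
  out <- array(0, dim = dim(a))
  for (j in seq_along(kernel)) {
    w <- kernel[j]
    if (w == 0) next
    out <- out + w * .shift3(a, j - m - 1L, axis)
  }
  out
}

# Separable convolution with per-axis kernels (list of 3, NULL = skip axis).
.conv_sep <- function(a, kernels) {
  for (ax in 1:3) {
    k <- kernels[[ax]]
    if (!is.null(k) && length(k) > 1L) a <- .conv_axis(a, k, ax)
  }
  a
}

# Box (moving-sum) filter of half-width r along all three axes.
.box_sum3 <- function(a, r) {
  k <- rep(1, 2L * r + 1L)
  .conv_sep(a, list(k, k, k))
}

.gauss_kernel <- function(sigma_vox, truncate = 3.5) {
  if (sigma_vox <= 1e-8) return(1)
  m <- max(1L, ceiling(truncate * sigma_vox))
  x <- (-m):m
  k <- exp(-0.5 * (x / sigma_vox)^2)
  k / sum(k)
}

# Cubic B-spline kernel sampled at integer voxel offsets for knot spacing
# h_vox (support |x| < 2h). Used as the smoothing/regularization kernel of
# the free-form deformation updates.
.bspline_kernel <- function(h_vox) {
  if (h_vox <= 0.5) return(1)
  m <- max(1L, ceiling(2 * h_vox) - 1L)
  t <- abs(((-m):m) / h_vox)
  k <- ifelse(t < 1, 2 / 3 - t^2 + t^3 / 2,
              ifelse(t < 2, (2 - t)^3 / 6, 0))
  k / sum(k)
}

# Gaussian smoothing with a mask: normalized convolution so values outside
# the mask do not bleed in. Returns smoothed values inside the mask.
.smooth_masked <- function(a, mask, kernels) {
  a0 <- a
  a0[!mask] <- 0
  num <- .conv_sep(a0, kernels)
  den <- .conv_sep(array(as.numeric(mask), dim = dim(a)), kernels)
  out <- num / pmax(den, 1e-12)
  out[!mask] <- NA_real_
  out
}

# Trilinear interpolation of 3-D array `a` at continuous 1-based voxel
# coordinates (xi, yi, zi), clamped to the grid (nearest-edge extension).
.interp3 <- function(a, xi, yi, zi) {
  d <- dim(a)
  xi <- pmin(pmax(xi, 1), d[1])
  yi <- pmin(pmax(yi, 1), d[2])
  zi <- pmin(pmax(zi, 1), d[3])
  x0 <- pmin(floor(xi), d[1] - 1L); x1 <- x0 + 1
  y0 <- pmin(floor(yi), d[2] - 1L); y1 <- y0 + 1
  z0 <- pmin(floor(zi), d[3] - 1L); z1 <- z0 + 1
  fx <- xi - x0; fy <- yi - y0; fz <- zi - z0
  n12 <- d[1] * d[2]
  idx <- function(x, y, z) x + d[1] * (y - 1) + n12 * (z - 1)
  v000 <- a[idx(x0, y0, z0)]; v100 <- a[idx(x1, y0, z0)]
  v010 <- a[idx(x0, y1, z0)]; v110 <- a[idx(x1, y1, z0)]
  v001 <- a[idx(x0, y0, z1)]; v101 <- a[idx(x1, y0, z1)]
  v011 <- a[idx(x0, y1, z1)]; v111 <- a[idx(x1, y1, z1)]
  (v000 * (1 - fx) + v100 * fx) * (1 - fy) * (1 - fz) +
  (v010 * (1 - fx) + v110 * fx) * fy * (1 - fz) +
  (v001 * (1 - fx) + v101 * fx) * (1 - fy) * fz +
  (v011 * (1 - fx) + v111 * fx) * fy * fz
}

# Nearest-neighbour lookup at continuous 1-based voxel coordinates.
.interp3_nn <- function(a, xi, yi, zi) {
  d <- dim(a)
  xi <- pmin(pmax(round(xi), 1), d[1])
  yi <- pmin(pmax(round(yi), 1), d[2])
  zi <- pmin(pmax(round(zi), 1), d[3])
  a[xi + d[1] * (yi - 1) + d[1] * d[2] * (zi - 1)]
}

# Central-difference partial derivative along `axis` with one-sided
# differences at the two boundary slices; `h` is the voxel spacing (mm).
.deriv_axis <- function(a, h, axis) {
  d <- dim(a)
  n <- d[axis]
  fwd <- .shift3(a, -1L, axis)  # fwd[i] = a[i+1]
  bwd <- .shift3(a, +1L, axis)  # bwd[i] = a[i-1]
  out <- (fwd - bwd) / (2 * h)
  ix <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  i1 <- ix; i1[[axis]] <- 1L
  i2 <- ix; i2[[axis]] <- 2L
  out[i1[[1]], i1[[2]], i1[[3]]] <-
    (a[i2[[1]], i2[[2]], i2[[3]]] - a[i1[[1]], i1[[2]], i1[[3]]]) / h
  iN <- ix; iN[[axis]] <- n
  iN1 <- ix; iN1[[axis]] <- n - 1L
  out[iN[[1]], iN[[2]], iN[[3]]] <-
    (a[iN[[1]], iN[[2]], iN[[3]]] - a[iN1[[1]], iN1[[2]], iN1[[3]]]) / h
  out
}

# Erode a logical mask by one voxel (6-connected neighbourhood).
.erode1 <- function(mask) {
  m <- mask
  for (ax in 1:3) {
    m <- m & .shift3(mask, 1L, ax, fill = FALSE) &
             .shift3(mask, -1L, ax, fill = FALSE)
  }
  m
}

# Block-mean reduction by integer factor along one axis.
.block_mean_axis <- function(a, f, axis) {
  if (f == 1L) return(a)
  d <- dim(a)
  n <- (d[axis] %/% f) * f
  ix <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  ix[[axis]] <- seq_len(n)
  a <- a[ix[[1]], ix[[2]], ix[[3]], drop = FALSE]
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(a, perm)
  da <- dim(a)
  v <- colMeans(matrix(as.vector(a), nrow = f))
  dim(v) <- c(da[1] %/% f, da[2], da[3])
  aperm(v, order(perm))
}

# Block-mean downsampling by an integer factor per axis (trailing voxels
# that do not fill a block are dropped).
.downsample3 <- function(a, f) {
  for (ax in 1:3) a <- .block_mean_axis(a, f[ax], ax)
  a
}

# 1-based voxel-center coordinates (mm, origin at first voxel center) of a
# stage grid produced by block-mean downsampling with factors f.
.stage_centers <- function(n, f, sp) {
  lapply(1:3, function(ax) {
    ((seq_len(n[ax]) - 1) * f[ax] + (f[ax] - 1) / 2) * sp[ax]
  })
}
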