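# Low-level 3D image utilities: separable Gaussian smoothing, finite-
# difference gradients, trilinear / nearest resampling and connected
# components. All vectorized base R; grids up to 64^3 stay fast without
# compiled code.

# take a slice of a 3D array along `axis` with an index vector (allows
# repeated / clamped indices, used for replicate-padded convolution)
slice3 <- function(vol, idx, axis) {
  switch(axis,
         vol[idx, , , drop = FALSE],
         vol[, idx, , drop = FALSE],
         vol[, , idx, drop = FALSE])
}

gauss_kernel <- function(sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  w <- exp(-((-r:r)^2) / (2 * sigma^2))
  w / sum(w)
}

# convolve along one axis with replicate padding
conv_axis3 <- function(vol, w, axis) {
  n <- dim(vol)[axis]
  r <- (length(w) - 1L) %/% 2L
  out <- array(0, dim(vol))
  s <- seq_len(n)
  for (j in seq_along(w)) {
    idx <- pmin(pmax(s + (j - 1L - r), 1L), n)
    out <- out + w[j] * slice3(vol, idx, axis)
  }
  out
}

# separable 3D Gaussian smoothing, sigma in voxels (scalar or per-axis)
gauss_smooth3 <- function(vol, sigma) {
  if (length(sigma) == 1L) sigma <- rep(sigma, 3L)
  for (a in 1:3) {
    if (sigma[a] > 0) vol <- conv_axis3(vol, gauss_kernel(sigma[a]), a)
  }
  vol
}

# central-difference gradient (clamped at borders), spacing in the same
# units the gradient should be expressed in (default: per voxel)
gradient3 <- function(vol, spacing = c(1, 1, 1)) {
  d <- dim(vol)
  g <- vector("list", 3L)
  for (a in 1:3) {
    n <- d[a]
    ip <- pmin(seq_len(n) + 1L, n)
    im <- pmax(seq_len(n) - 1L, 1L)
    # denominator is the actual index span (1 at borders, 2 interior)
    span <- (ip - im) * spacing[a]
    gr <- (slice3(vol, ip, a) - slice3(vol, im, a))
    gr <- sweep(gr, a, span, "/")
    g[[a]] <- gr
  }
  g
}

# trilinear interpolation of a 3D volume at continuous 0-based voxel
# coordinates (n x 3). oob: numeric fill value, or "clamp".
interp_trilinear <- function(vol, pts, oob = 0) {
  d <- dim(vol)
  pts <- matrix(pts, ncol = 3L)
  x <- pts[, 1]; y <- pts[, 2]; z <- pts[, 3]
  clamp <- identical(oob, "clamp")
  if (clamp) {
    x <- pmin(pmax(x, 0), d[1] - 1L)
    y <- pmin(pmax(y, 0), d[2] - 1L)
    z <- pmin(pmax(z, 0), d[3] - 1L)
  }
  i0 <- floor(x); j0 <- floor(y); k0 <- floor(z)
  fx <- x - i0; fy <- y - j0; fz <- z - k0
  ci <- function(v, n) pmin(pmax(v, 0), n - 1L)
  i0c <- ci(i0, d[1]); i1c <- ci(i0 + 1, d[1])
  j0c <- ci(j0, d[2]); j1c <- ci(j0 + 1, d[2])
  k0c <- ci(k0, d[3]); k1c <- ci(k0 + 1, d[3])
  lin <- function(i, j, k) vol[1L + i + d[1] * (j + d[2] * k)]
  v <- (1 - fz) * ((1 - fy) * ((1 - fx) * lin(i0c, j0c, k0c) + fx * lin(i1c, j0c, k0c)) +
                   fy       * ((1 - fx) * lin(i0c, j1c, k0c) + fx * lin(i1c, j1c, k0c))) +
       fz       * ((1 - fy) * ((1 - fx) * lin(i0c, j0c, k1c) + fx * lin(i1c, j0c, k1c)) +
                   fy       * ((1 - fx) * lin(i0c, j1c, k1c) + fx * lin(i1c, j1c, k1c)))
  if (!clamp) {
    # 1e-6-voxel fuzz: numerically-zero displacements must not push
    # border voxels out of bounds
    eps <- 1e-6
    bad <- x < -eps | x > d[1] - 1L + eps | y < -eps | y > d[2] - 1L + eps |
           z < -eps | z > d[3] - 1L + eps
    v[bad] <- oob
  }
  v
}

# nearest-neighbour lookup at continuous 0-based voxel coordinates
interp_nearest <- function(vol, pts, oob = 0) {
  d <- dim(vol)
  pts <- matrix(pts, ncol = 3L)
  i <- round(pts[, 1]); j <- round(pts[, 2]); k <- round(pts[, 3])
  eps <- 1e-6
  bad <- pts[, 1] < -0.5 - eps | pts[, 1] > d[1] - 0.5 + eps |
         pts[, 2] < -0.5 - eps | pts[, 2] > d[2] - 0.5 + eps |
         pts[, 3] < -0.5 - eps | pts[, 3] > d[3] - 0.5 + eps
  i <- pmin(pmax(i, 0), d[1] - 1L)
  j <- pmin(pmax(j, 0), d[2] - 1L)
  k <- pmin(pmax(k, 0), d[3] - 1L)
  v <- vol[1L + i + d[1] * (j + d[2] * k)]
  v[bad] <- oob
  v
}

# smooth + decimate by 2 along each axis (pyramid level)
downsample2 <- function(vol) {
  vol <- gauss_smooth3(vol, 1.0)
  d <- dim(vol)
  vol[seq(1L, d[1], by = 2L), seq(1L, d[2], by = 2L), seq(1L, d[3], by = 2L), drop = FALSE]
}

# 6-connected components of a logical 3D mask; returns integer array with
# components labelled 1..n by decreasing voxel count
label_components <- function(mask) {
  d <- dim(mask)
  lab <- array(0, d)
  lab[mask] <- seq_len(sum(mask))
  big <- sum(mask) + 1
  repeat {
    prev <- lab
    m <- lab
    m[!mask] <- big
    for (a in 1:3) {
      n <- d[a]
      up <- slice3(m, pmin(seq_len(n) + 1L, n), a)
      dn <- slice3(m, pmax(seq_len(n) - 1L, 1L), a)
      m <- pmin(m, pmin(up, dn))
      m[!mask] <- big
    }
    lab[mask] <- m[mask]
    if (identical(lab, prev)) break
  }
  ids <- sort(unique(lab[mask]))
  if (length(ids)) {
    counts <- tabulate(match(lab[mask], ids))
    ord <- order(counts, decreasing = TRUE)
    relab <- integer(max(ids))
    relab[ids[ord]] <- seq_along(ids)
    lab[mask] <- relab[lab[mask]]
  }
  lab
}
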