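# Shared fixtures, all generated in code. Small grids keep the default
# test run fast; the acceptance tests use the full-size phantoms.

# smooth structured test image: two blobs with axial modulation
blob_image <- function(d = c(24L, 24L, 24L)) {
  g <- expand.grid(x = seq_len(d[1]) - 1L, y = seq_len(d[2]) - 1L,
                   z = seq_len(d[3]) - 1L)
  c1 <- (d - 1) / 2
  array(exp(-((g$x - c1[1])^2 + (g$y - c1[2])^2) / 40) * (1 + 0.5 * sin(g$z / 4)) +
        0.3 * exp(-((g$x - d[1] / 4)^2 + (g$y - 2 * d[2] / 3)^2 + (g$z - d[3] / 3)^2) / 30),
        d)
}

# known smooth pull-back displacement (voxel units), 2-voxel peak amplitude
sine_field_vox <- function(d, amplitude = 2) {
  g <- expand.grid(x = seq_len(d[1]) - 1L, y = seq_len(d[2]) - 1L,
                   z = seq_len(d[3]) - 1L)
  list(dx = array(amplitude * sin(2 * pi * g$y / d[2]) * sin(2 * pi * g$z / d[3]), d),
       dy = array(amplitude * sin(2 * pi * g$x / d[1]) * sin(2 * pi * g$z / d[3]), d),
       dz = array(0, d))
}

vox_field <- function(fl, voxel_size = c(1, 1, 1)) {
  d <- dim(fl$dx)
  dmm <- array(0, c(d, 3L))
  dmm[, , , 1] <- fl$dx * voxel_size[1]
  dmm[, , , 2] <- fl$dy * voxel_size[2]
  dmm[, , , 3] <- fl$dz * voxel_size[3]
  displacement_field(dmm, voxel_size = voxel_size)
}

# warp an image by a known voxel-space pull-back field (edge-clamped)
warp_known <- function(img, fl) {
  d <- dim(img)
  g <- as.matrix(expand.grid(seq_len(d[1]) - 1L, seq_len(d[2]) - 1L,
                             seq_len(d[3]) - 1L))
  pts <- g + cbind(as.vector(fl$dx), as.vector(fl$dy), as.vector(fl$dz))
  array(flow4d:::interp_trilinear(img, pts, oob = "clamp"), d)
}

small_meta <- function(dim3 = c(24L, 24L, 24L), n_frames = 6L) {
  acquisition_meta(c(2.7, 2.7, 2.8), 52.8, n_frames, 120, dim = dim3)
}

small_tube_phantom <- function(n_frames = 6L, dim3 = c(24L, 24L, 24L), ...) {
  make_phantom(phantom_spec(meta = small_meta(dim3, n_frames), ...))
}

# tiny flow4d built directly from arrays (uniform magnitude 1)
flow_from_vel <- function(vx, vy, vz, venc = 120, magnitude = NULL) {
  d <- dim(vx)
  if (is.null(magnitude)) magnitude <- array(1, d)
  flow4d(magnitude, vx, vy, vz,
         acquisition_meta(c(1, 1, 1), 50, d[4], venc, dim = d[1:3]))
}
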