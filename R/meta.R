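#' Acquisition metadata for a 4D flow dataset
#'
#' Physical description of the voxel grid and cardiac gating of an
#' acquisition: voxel size in mm, frame duration in ms, number of
#' reconstructed cardiac frames, velocity-encoding limit (VENC) in cm/s and
#' the affine mapping 0-based voxel indices to world coordinates in mm.
#'
#' @param voxel_size numeric length-3, mm per axis; all > 0.
#' @param frame_duration frame duration in ms (> 0).
#' @param n_frames number of cardiac frames (>= 2).
#' @param venc velocity encoding limit in cm/s (> 0).
#' @param dim optional integer length-3 spatial grid size.
#' @param grid_to_world optional 4x4 affine taking 0-based voxel indices to
#'   world mm. Defaults to `diag(voxel_size)` with zero origin.
#' @return An object of class `acquisition_meta`.
#' @export
acquisition_meta <- function(voxel_size, frame_duration, n_frames, venc,
                             dim = NULL, grid_to_world = NULL) {
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    stop("voxel_size must be 3 positive finite numbers (mm)")
  if (!is.finite(frame_duration) || frame_duration <= 0)
    stop("frame_duration must be > 0 (ms)")
  n_frames <- as.integer(n_frames)
  if (is.na(n_frames) || n_frames < 2L)
    stop("n_frames must be >= 2")
  if (!is.finite(venc) || venc <= 0)
    stop("venc must be > 0 (cm/s)")
  if (is.null(grid_to_world)) {
    grid_to_world <- diag(4)
    grid_to_world[1:3, 1:3] <- diag(voxel_size)
  }
  grid_to_world <- matrix(as.numeric(grid_to_world), 4L, 4L)
  if (abs(det(grid_to_world)) < 1e-12)
    stop("grid_to_world must be invertible")
  if (!is.null(dim)) {
    dim <- as.integer(dim)
    if (length(dim) != 3L || any(dim < 1L)) stop("dim must be 3 positive integers")
  }
  structure(list(voxel_size = voxel_size, frame_duration = frame_duration,
                 n_frames = n_frames, venc = venc, dim = dim,
                 grid_to_world = grid_to_world),
            class = "acquisition_meta")
}

#' @export
print.acquisition_meta <- function(x, ...) {
  cat(sprintf("acquisition_meta: voxel %s mm, %d frames x %.1f ms, VENC %g cm/s\n",
              paste(signif(x$voxel_size, 4), collapse = " x "),
              x$n_frames, x$frame_duration, x$venc))
  invisible(x)
}

# 0-based voxel indices (n x 3) -> world mm (n x 3)
voxel_to_world <- function(meta, vox) {
  vox <- matrix(vox, ncol = 3L)
  G <- meta$grid_to_world
  t(G[1:3, 1:3] %*% t(vox) + G[1:3, 4])
}

# world mm (n x 3) -> 0-based continuous voxel indices (n x 3)
world_to_voxel <- function(meta, pts) {
  pts <- matrix(pts, ncol = 3L)
  Gi <- solve(meta$grid_to_world)
  t(Gi[1:3, 1:3] %*% t(pts) + Gi[1:3, 4])
}

# world coordinates of every voxel centre, as an (nvox x 3) matrix in grid order
grid_world_points <- function(meta, dim = meta$dim) {
  stopifnot(!is.null(dim))
  ii <- expand.grid(i = seq_len(dim[1]) - 1L,
                    j = seq_len(dim[2]) - 1L,
                    k = seq_len(dim[3]) - 1L)
  voxel_to_world(meta, as.matrix(ii))
}
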