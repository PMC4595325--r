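# Analysis-plane placement and through-plane flow quantification.
#
# Deformed atlas planes are flattened by PCA, the in-plane vessel mask is
# rounded and slightly enlarged with a circular averaging filter (the
# added rim carries near-zero velocities, so the net volume is
# insensitive to the enlargement), velocities are linearly interpolated
# on the plane lattice masked by the time-resolved segmentation, and the
# net flow volume is the rectangle-rule time integral of the signed
# volumetric flow rate.

#' Fit a flat plane to deformed plane points by PCA
#'
#' Origin = centroid; the first two principal directions span the plane,
#' the third is the normal (sign chosen within 90 degrees of
#' `ref_normal` when given).
#'
#' @param points n x 3 matrix of mm points (n >= 3, non-collinear).
#' @param ref_normal optional pre-deformation normal fixing the sign.
#' @param name,vessel_code carried into the returned plane.
#' @return a [flow_plane()] whose `sample_points` are the input points
#'   projected onto the fitted plane.
#' @export
fit_plane_pca <- function(points, ref_normal = NULL, name = "plane",
                          vessel_code = NA_integer_) {
  pts <- matrix(points, ncol = 3L)
  if (nrow(pts) < 3L) stop("need at least 3 points")
  ctr <- colMeans(pts)
  X <- sweep(pts, 2L, ctr, "-")
  sv <- svd(X)
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1e-300))
    stop("degenerate plane fit: points are collinear")
  a1 <- sv$v[, 1]; a2 <- sv$v[, 2]; nrm <- sv$v[, 3]
  if (!is.null(ref_normal) && sum(nrm * ref_normal) < 0) nrm <- -nrm
  # keep a right-handed (a1, a2, normal) triad
  cr <- c(a1[2] * a2[3] - a1[3] * a2[2],
          a1[3] * a2[1] - a1[1] * a2[3],
          a1[1] * a2[2] - a1[2] * a2[1])
  if (sum(cr * nrm) < 0) a2 <- -a2
  uv <- X %*% cbind(a1, a2)
  extent <- pmax(apply(abs(uv), 2L, max), 1e-6)
  proj <- sweep(uv %*% rbind(a1, a2), 2L, ctr, "+")
  flow_plane(name, ctr, nrm, in_plane_axes = rbind(a1, a2), extent = extent,
             sample_points = proj, vessel_code = vessel_code)
}

disk_kernel <- function(radius_px) {
  r <- as.integer(radius_px)
  off <- -r:r
  k <- outer(off, off, function(i, j) (i^2 + j^2) <= r^2 + 1e-9) * 1
  k / sum(k)
}

#' Smooth an in-plane vessel mask with a circular averaging filter
#'
#' Convolves the 0/1 mask with a normalized disk kernel (default radius 9
#' pixels) and keeps pixels whose response reaches `keep_frac`. With a
#' small `keep_frac` the region becomes rounder, smoother and a bit
#' larger than the input; it never shrinks.
#'
#' @param mask2d logical matrix.
#' @param radius_px disk radius in lattice pixels (default 9).
#' @param keep_frac response threshold in (0, 1]; default 0.1.
#' @return logical matrix.
#' @export
smooth_plane_mask <- function(mask2d, radius_px = 9L, keep_frac = 0.1) {
  stopifnot(radius_px >= 1L)
  m <- mask2d * 1
  k <- disk_kernel(radius_px)
  r <- (nrow(k) - 1L) %/% 2L
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(0, nr + 2L * r, nc + 2L * r)
  pad[(r + 1L):(r + nr), (r + 1L):(r + nc)] <- m
  resp <- matrix(0, nr, nc)
  for (i in seq_len(nrow(k))) for (j in seq_len(ncol(k))) {
    if (k[i, j] == 0) next
    resp <- resp + k[i, j] * pad[(i):(i + nr - 1L), (j):(j + nc - 1L)]
  }
  out <- resp >= keep_frac - 1e-12
  out | mask2d   # contract: never drop an original pixel
}

#' Sample velocities and the vessel mask on an analysis plane
#'
#' Builds a square lattice with the given spacing over the plane patch,
#' linearly interpolates the three velocity components per frame, and
#' masks by the time-resolved segmentation (nearest-label lookup --
#' labels are categorical) followed by [smooth_plane_mask()].
#' Out-of-bounds lattice points are unmasked and zero-velocity.
#'
#' @param flow a [flow4d()].
#' @param seg a [segmentation4d()].
#' @param plane a [flow_plane()].
#' @param vessel_code label code to mask; default `plane$vessel_code`.
#' @param spacing lattice spacing in mm; default `min(voxel_size)/2`.
#' @param radius_px,keep_frac mask-smoothing parameters.
#' @return object of class `plane_sample`: `velocity` (nu x nv x nt x 3,
#'   cm/s), `mask` (nu x nv x nt), `normal`, `pixel_area` (mm^2),
#'   `points` (lattice points, mm), `plane_name`, `vessel_code`.
#' @export
sample_plane <- function(flow, seg, plane, vessel_code = plane$vessel_code,
                         spacing = NULL, radius_px = 9L, keep_frac = 0.1) {
  meta <- flow$meta
  if (is.null(spacing)) spacing <- min(meta$voxel_size) / 2
  stopifnot(spacing > 0)
  ext <- plane$extent
  u <- seq(-ext[1], ext[1], by = spacing)
  v <- seq(-ext[2], ext[2], by = spacing)
  nu <- length(u); nv <- length(v)
  uv <- as.matrix(expand.grid(u = u, v = v))
  pts <- sweep(uv %*% plane$in_plane_axes, 2L, plane$origin, "+")
  vox <- world_to_voxel(meta, pts)
  d <- meta$dim %||% dim(flow$magnitude)[1:3]
  inb <- vox[, 1] >= 0 & vox[, 1] <= d[1] - 1L &
         vox[, 2] >= 0 & vox[, 2] <= d[2] - 1L &
         vox[, 3] >= 0 & vox[, 3] <= d[3] - 1L
  if (!any(inb)) stop("plane lies entirely outside the volume")
  nt <- dim(flow$magnitude)[4]
  vel <- array(0, c(nu, nv, nt, 3L))
  msk <- array(FALSE, c(nu, nv, nt))
  for (t in seq_len(nt)) {
    vel[, , t, 1] <- interp_trilinear(flow$vx[, , , t], vox, oob = 0)
    vel[, , t, 2] <- interp_trilinear(flow$vy[, , , t], vox, oob = 0)
    vel[, , t, 3] <- interp_trilinear(flow$vz[, , , t], vox, oob = 0)
    lab <- interp_nearest(seg$labels_t[, , , t], vox, oob = 0)
    m <- matrix(lab == vessel_code & inb, nu, nv)
    msk[, , t] <- smooth_plane_mask(m, radius_px, keep_frac)
  }
  structure(list(points = pts, u = u, v = v, velocity = vel, mask = msk,
                 normal = plane$normal, pixel_area = spacing^2,
                 spacing = spacing, plane_name = plane$name,
                 vessel_code = vessel_code),
            class = "plane_sample")
}

#' Volumetric flow rate through a plane at one frame
#'
#' `Q = sum_masked (v . normal)[cm/s] * pixel_area[mm^2] * 0.01` in ml/s;
#' signed, retrograde flow negative.
#'
#' @param sample a `plane_sample` from [sample_plane()].
#' @param frame 1-based frame index.
#' @return flow rate in ml/s.
#' @export
flow_rate <- function(sample, frame) {
  nt <- dim(sample$velocity)[3]
  if (frame < 1L || frame > nt) stop("frame out of range")
  m <- sample$mask[, , frame]
  if (!any(m)) {
    warning("empty plane mask at frame ", frame)
    return(0)
  }
  vn <- sample$velocity[, , frame, 1] * sample$normal[1] +
        sample$velocity[, , frame, 2] * sample$normal[2] +
        sample$velocity[, , frame, 3] * sample$normal[3]
  sum(vn[m]) * sample$pixel_area * 1e-2
}

#' Net flow volume over the cardiac cycle
#'
#' Rectangle-rule integral of the per-frame flow rates: with
#' retrospective gating the frames tile the cycle with equal duration, so
#' the rectangle rule equals mean rate x period.
#'
#' @param rates ml/s per frame.
#' @param frame_duration frame duration in ms.
#' @return net volume in ml.
#' @export
net_flow_volume <- function(rates, frame_duration) {
  stopifnot(length(rates) >= 1L, frame_duration > 0)
  sum(rates) * frame_duration / 1000
}

#' Quantify flow through one plane
#'
#' Convenience wrapper: [sample_plane()] on a PCA-fitted plane, per-frame
#' [flow_rate()] and the [net_flow_volume()].
#'
#' @param flow a [flow4d()].
#' @param seg a [segmentation4d()].
#' @param plane a [flow_plane()] (already PCA-fitted if it came from a
#'   deformed point set).
#' @param ... passed to [sample_plane()].
#' @return list: `plane_name`, `vessel_code`, `flow_rate` (ml/s per
#'   frame), `net_volume` (ml).
#' @export
quantify_plane_flow <- function(flow, seg, plane, ...) {
  smp <- sample_plane(flow, seg, plane, ...)
  nt <- dim(smp$velocity)[3]
  q <- vapply(seq_len(nt), function(t) {
    suppressWarnings(flow_rate(smp, t))
  }, 0)
  list(plane_name = plane$name, vessel_code = smp$vessel_code,
       flow_rate = q,
       net_volume = net_flow_volume(q, flow$meta$frame_duration))
}

#' Simple linear regression
#'
#' Ordinary least squares of y on x with the squared Pearson correlation
#' and the two-sided p-value of the slope; `significant` flags p < 0.05.
#'
#' @param x,y numeric vectors, `length >= 3`, x non-constant.
#' @return list: `slope`, `intercept`, `r_squared`, `p_value`,
#'   `significant`.
#' @export
linear_regression <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (stats::sd(x) == 0) stop("x is constant")
  fit <- stats::lm(y ~ x)
  sm <- suppressWarnings(summary(fit))  # exact fits warn harmlessly
  p <- sm$coefficients["x", "Pr(>|t|)"]
  if (is.nan(p)) p <- 0   # exact fit: slope test degenerates
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = sm$r.squared,
       p_value = p,
       significant = p < 0.05)
}

#' Dice overlap coefficient
#'
#' `2|A n B| / (|A| + |B|)`; defined as 1 when both masks are empty.
#'
#' @param a,b logical arrays on the same grid.
#' @return overlap fraction in `[0, 1]`.
#' @export
dice_coefficient <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("grid mismatch")
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}
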