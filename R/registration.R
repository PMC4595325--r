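# Affine and Morphon-style multi-scale non-rigid registration.
#
# The non-rigid stage iteratively estimates a local incremental
# displacement from directional-gradient differences along a fixed set of
# six filter orientations, with per-voxel certainty equal to the local
# gradient energy. Each increment is fluid-regularized (Gaussian smoothing
# of the increment: viscous-fluid behaviour), accumulated by field
# COMPOSITION (diffeomorphic accumulation: compression and deformation
# without tearing or folding), and the accumulated field is
# elastic-regularized (certainty-weighted Gaussian smoothing: elastic
# behaviour). Displacement fields use the pull-back convention: a target
# point x samples the source at x + d(x).

#' Registration parameters
#'
#' @param n_scales number of pyramid scales (coarse to fine). The atlas
#'   fit uses 3, the temporal fit 5.
#' @param iters_per_scale displacement-update iterations per scale
#'   (default 5).
#' @param sigma_fluid Gaussian sigma in voxels for fluid regularization of
#'   each increment (default 2).
#' @param sigma_elastic Gaussian sigma in voxels for elastic regularization
#'   of the accumulated field (default 1.5).
#' @param use_edge_representation register structure-tensor edge maps
#'   instead of raw intensities (used for temporal propagation).
#' @param interpolation only `"linear"` is supported.
#' @param step_cap maximum per-iteration displacement increment in voxels.
#' @return list of class `reg_params`.
#' @export
reg_params <- function(n_scales = 3L, iters_per_scale = 5L,
                       sigma_fluid = 2.0, sigma_elastic = 1.5,
                       use_edge_representation = FALSE,
                       interpolation = "linear", step_cap = 0.8) {
  stopifnot(n_scales >= 1L, iters_per_scale >= 1L,
            sigma_fluid >= 0, sigma_elastic >= 0,
            identical(interpolation, "linear"))
  structure(list(n_scales = as.integer(n_scales),
                 iters_per_scale = as.integer(iters_per_scale),
                 sigma_fluid = sigma_fluid, sigma_elastic = sigma_elastic,
                 use_edge_representation = isTRUE(use_edge_representation),
                 interpolation = interpolation, step_cap = step_cap),
            class = "reg_params")
}

#' Affine transform in world coordinates
#'
#' Maps a point p (mm) to `matrix %*% p + translation`.
#' @param matrix 3x3 invertible matrix.
#' @param translation mm 3-vector.
#' @return object of class `affine_transform`.
#' @export
affine_transform <- function(matrix = diag(3), translation = c(0, 0, 0)) {
  matrix <- base::matrix(as.numeric(matrix), 3L, 3L)
  if (abs(det(matrix)) <= 1e-9) stop("affine matrix must be invertible")
  structure(list(matrix = matrix, translation = as.numeric(translation)),
            class = "affine_transform")
}

#' @export
print.affine_transform <- function(x, ...) {
  cat("affine_transform:\n")
  print(signif(cbind(x$matrix, x$translation), 5))
  invisible(x)
}

#' Apply an affine transform to points
#' @param aff an [affine_transform()].
#' @param pts n x 3 matrix of mm points.
#' @return n x 3 matrix of transformed points.
#' @export
apply_affine <- function(aff, pts) {
  pts <- matrix(pts, ncol = 3L)
  sweep(pts %*% t(aff$matrix), 2L, aff$translation, "+")
}

invert_affine <- function(aff) {
  Mi <- solve(aff$matrix)
  affine_transform(Mi, -as.vector(Mi %*% aff$translation))
}

#' Dense displacement field
#'
#' Pull-back convention: a target-grid point x (world mm) samples the
#' source at `x + d(x)`.
#'
#' @param d array (nx, ny, nz, 3) of mm displacements on the target grid.
#' @param certainty optional non-negative 3D array.
#' @param voxel_size mm per axis of the target grid.
#' @param grid_to_world 4x4 affine of the target grid (default
#'   `diag(voxel_size)`).
#' @return object of class `displacement_field`.
#' @export
displacement_field <- function(d, certainty = NULL, voxel_size = c(1, 1, 1),
                               grid_to_world = NULL) {
  if (length(dim(d)) != 4L || dim(d)[4] != 3L) stop("d must be (nx, ny, nz, 3)")
  if (any(!is.finite(d))) stop("displacement field must be finite")
  if (is.null(grid_to_world)) {
    grid_to_world <- diag(4); grid_to_world[1:3, 1:3] <- diag(as.numeric(voxel_size))
  }
  if (is.null(certainty)) certainty <- array(1, dim(d)[1:3])
  structure(list(d = d, certainty = certainty,
                 voxel_size = as.numeric(voxel_size),
                 grid_to_world = grid_to_world, dim = dim(d)[1:3]),
            class = "displacement_field")
}

#' @export
print.displacement_field <- function(x, ...) {
  mg <- sqrt(x$d[, , , 1]^2 + x$d[, , , 2]^2 + x$d[, , , 3]^2)
  cat(sprintf("displacement_field: %s grid, |d| max %.3f mm, mean %.3f mm\n",
              paste(x$dim, collapse = " x "), max(mg), mean(mg)))
  invisible(x)
}

zero_field <- function(dim3, voxel_size = c(1, 1, 1), grid_to_world = NULL) {
  displacement_field(array(0, c(dim3, 3L)), voxel_size = voxel_size,
                     grid_to_world = grid_to_world)
}

# field displacement in voxel units (nvox x 3 matrix)
field_dvox <- function(field) {
  L <- field$grid_to_world[1:3, 1:3]
  matrix(field$d, ncol = 3L) %*% t(solve(L))
}

dvox_to_field <- function(dvox_mat, dim3, certainty = NULL, voxel_size = c(1, 1, 1),
                          grid_to_world = NULL) {
  if (is.null(grid_to_world)) {
    grid_to_world <- diag(4); grid_to_world[1:3, 1:3] <- diag(voxel_size)
  }
  L <- grid_to_world[1:3, 1:3]
  dmm <- dvox_mat %*% t(L)
  displacement_field(array(dmm, c(dim3, 3L)), certainty = certainty,
                     voxel_size = voxel_size, grid_to_world = grid_to_world)
}

# ---- internal voxel-space machinery ------------------------------------

# 0-based voxel coordinates of every grid point, cached per dim
grid_vox_points <- function(dim3) {
  as.matrix(expand.grid(i = seq_len(dim3[1]) - 1L,
                        j = seq_len(dim3[2]) - 1L,
                        k = seq_len(dim3[3]) - 1L))
}

# warp: out(x) = img(x + dvox(x)); dvox is list of 3 arrays or (nvox x 3).
# Edge clamping keeps border voxels comparable when the field nudges
# sample points just outside the grid (zero-filling would punch dark
# faces into small pyramid levels and wreck the correlation objective).
warp_vox <- function(img, dvox, base = NULL, oob = "clamp") {
  d3 <- dim(img)
  if (is.null(base)) base <- grid_vox_points(d3)
  if (is.list(dvox)) dvox <- cbind(as.vector(dvox[[1]]), as.vector(dvox[[2]]),
                                   as.vector(dvox[[3]]))
  array(interp_trilinear(img, base + dvox, oob = oob), d3)
}

ncc <- function(a, b) {
  sa <- stats::sd(a); sb <- stats::sd(b)
  if (sa == 0 || sb == 0) stop("constant image: correlation undefined")
  stats::cor(as.vector(a), as.vector(b))
}

build_pyramid <- function(vol, n_scales, min_dim = 8L) {
  levels <- list(vol)
  for (s in seq_len(n_scales - 1L)) {
    nxt <- downsample2(levels[[1]])
    if (min(dim(nxt)) < min_dim) break
    levels <- c(list(nxt), levels)
  }
  levels  # coarsest first
}

# voxel-space Jacobian determinant of a displacement given as 3 arrays
jacdet_vox <- function(d1, d2, d3) {
  g1 <- gradient3(d1); g2 <- gradient3(d2); g3 <- gradient3(d3)
  a <- 1 + g1[[1]]; b <- g1[[2]]; c <- g1[[3]]
  d <- g2[[1]]; e <- 1 + g2[[2]]; f <- g2[[3]]
  g <- g3[[1]]; h <- g3[[2]]; i <- 1 + g3[[3]]
  a * (e * i - f * h) - b * (d * i - f * g) + c * (d * h - e * g)
}

interior <- function(arr, m = 1L) {
  d <- dim(arr)
  arr[(1 + m):(d[1] - m), (1 + m):(d[2] - m), (1 + m):(d[3] - m)]
}

# ---- affine registration -----------------------------------------------

#' Affine registration
#'
#' Optimizes a 12-parameter transform (matrix + translation, acting about
#' the grid centre in world mm) over a coarse-to-fine Gaussian pyramid
#' against a normalized intensity-correlation objective. If the optimum is
#' worse than the identity the identity is returned with a warning.
#'
#' @param source,target 3D arrays on grids described by `source_meta` /
#'   `target_meta` (defaults: unit-spacing grids).
#' @param params a [reg_params()]; `n_scales` and `iters_per_scale` govern
#'   the pyramid and per-level optimizer effort.
#' @param source_meta,target_meta optional [acquisition_meta()].
#' @return an [affine_transform()] mapping target world points into source
#'   world points (pull-back), with attributes `objective` (final 1 - NCC)
#'   and `objective_identity`.
#' @export
register_affine <- function(source, target, params = reg_params(),
                            source_meta = NULL, target_meta = NULL) {
  if (length(dim(source)) != 3L || length(dim(target)) != 3L)
    stop("source and target must be 3D")
  if (stats::sd(source) == 0 || stats::sd(target) == 0)
    stop("constant image: correlation undefined")
  if (is.null(source_meta)) source_meta <- unit_spatial_meta(dim(source))
  if (is.null(target_meta)) target_meta <- unit_spatial_meta(dim(target))

  pyr_s <- build_pyramid(source, params$n_scales)
  pyr_t <- build_pyramid(target, params$n_scales)
  nlev <- min(length(pyr_s), length(pyr_t))
  pyr_s <- pyr_s[(length(pyr_s) - nlev + 1L):length(pyr_s)]
  pyr_t <- pyr_t[(length(pyr_t) - nlev + 1L):length(pyr_t)]

  centre <- voxel_to_world(target_meta, matrix((dim(target) - 1) / 2, 1L))
  p <- c(rep(0, 3), rep(0, 9))  # translation mm; vec(M - I)

  obj_level <- function(p, S, Tg, s_meta_lin, t_pts, s_g2w_inv) {
    M <- diag(3) + matrix(p[4:12], 3L, 3L)
    w <- sweep((t_pts - matrix(centre, nrow(t_pts), 3L, byrow = TRUE)) %*% t(M),
               2L, as.vector(centre) + p[1:3], "+")
    vox <- sweep(w %*% t(s_g2w_inv[1:3, 1:3]), 2L, s_g2w_inv[1:3, 4], "+")
    val <- interp_trilinear(S, vox, oob = 0)
    if (stats::sd(val) == 0) return(2)   # moved fully out of view: worst case
    1 - ncc(val, Tg)
  }

  for (lvl in seq_len(nlev)) {
    fac <- 2^(nlev - lvl)
    S <- pyr_s[[lvl]]; Tg <- pyr_t[[lvl]]
    s_g2w <- scale_g2w(source_meta$grid_to_world, fac)
    t_g2w <- scale_g2w(target_meta$grid_to_world, fac)
    s_g2w_inv <- solve(s_g2w)
    ii <- grid_vox_points(dim(Tg))
    t_pts <- t(t_g2w[1:3, 1:3] %*% t(ii) + t_g2w[1:3, 4])
    maxit <- if (lvl == nlev) 2L * params$iters_per_scale else 10L * params$iters_per_scale
    fn <- function(p) obj_level(p, S, Tg, NULL, t_pts, s_g2w_inv)
    res <- stats::optim(p, fn, method = "BFGS",
                        control = list(maxit = maxit, reltol = 1e-10))
    p <- res$par
  }

  # final objective on the full-resolution grid
  ii <- grid_vox_points(dim(target))
  t_pts <- t(target_meta$grid_to_world[1:3, 1:3] %*% t(ii) + target_meta$grid_to_world[1:3, 4])
  s_inv <- solve(source_meta$grid_to_world)
  obj_final <- obj_level(p, source, target, NULL, t_pts, s_inv)
  obj_id <- obj_level(c(rep(0, 12)), source, target, NULL, t_pts, s_inv)
  if (obj_final >= obj_id - 1e-9) {
    # not materially better than the identity: prefer the exact identity
    # (ties) or flag divergence (worse)
    if (obj_final > obj_id + 1e-6) warning("affine registration diverged; returning identity")
    out <- affine_transform()
    attr(out, "objective") <- obj_id
    attr(out, "objective_identity") <- obj_id
    return(out)
  }
  M <- diag(3) + matrix(p[4:12], 3L, 3L)
  tr <- as.vector(centre) + p[1:3] - as.vector(M %*% as.vector(centre))
  out <- affine_transform(M, tr)
  attr(out, "objective") <- obj_final
  attr(out, "objective_identity") <- obj_id
  out
}

unit_spatial_meta <- function(dim3) {
  acquisition_meta(c(1, 1, 1), 1, 2, 1, dim = dim3)
}

# grid_to_world of a pyramid level decimated by `fac` (voxel i -> fine fac*i)
scale_g2w <- function(g2w, fac) {
  S <- diag(c(fac, fac, fac, 1))
  g2w %*% S
}

# ---- Morphon-style non-rigid registration ------------------------------

morphon_orientations <- function() {
  rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
        c(1, 1, 0) / sqrt(2), c(1, 0, 1) / sqrt(2), c(0, 1, 1) / sqrt(2))
}

# certainty-weighted Gaussian smoothing (normalized convolution with a
# small weight floor for stability in flat regions)
nc_smooth <- function(arr, cert, sigma, floor_frac = 0.01) {
  if (sigma <= 0) return(arr)
  cmax <- max(cert)
  w <- if (cmax > 0) cert / cmax + floor_frac else array(1, dim(cert))
  gauss_smooth3(w * arr, sigma) / gauss_smooth3(w, sigma)
}

#' Morphon-style non-rigid registration
#'
#' Multi-scale displacement estimation on a shared grid (apply
#' [register_affine()] and resample first if grids differ). See the file
#' header for the iteration structure. The returned field is
#' diffeomorphic: the interior Jacobian determinant is strictly positive.
#'
#' @param source,target 3D arrays on the same grid.
#' @param params a [reg_params()].
#' @param meta optional [acquisition_meta()] of the shared grid (defaults
#'   to unit spacing).
#' @return a [displacement_field()] (pull-back, world mm) with attributes
#'   `objective` (final 1 - NCC on the full grid) and
#'   `objective_identity`.
#' @export
register_morphon <- function(source, target, params = reg_params(),
                             meta = NULL) {
  if (!identical(dim(source), dim(target))) stop("non-matching grids")
  if (any(!is.finite(source)) || any(!is.finite(target))) stop("NaN in inputs")
  if (is.null(meta)) meta <- unit_spatial_meta(dim(source))

  if (params$use_edge_representation) {
    source <- edge_map(source)
    target <- edge_map(target)
  }

  pyr_s <- build_pyramid(source, params$n_scales)
  pyr_t <- build_pyramid(target, params$n_scales)
  nlev <- min(length(pyr_s), length(pyr_t))
  pyr_s <- pyr_s[(length(pyr_s) - nlev + 1L):length(pyr_s)]
  pyr_t <- pyr_t[(length(pyr_t) - nlev + 1L):length(pyr_t)]

  Nor <- morphon_orientations()
  d1 <- d2 <- d3 <- NULL   # accumulated field, voxel units, arrays
  cert_last <- NULL

  for (lvl in seq_len(nlev)) {
    S <- pyr_s[[lvl]]; Tg <- pyr_t[[lvl]]
    dm <- dim(Tg)
    if (is.null(d1)) {
      d1 <- d2 <- d3 <- array(0, dm)
    } else if (!identical(dim(d1), dm)) {
      up <- function(a) {
        pts <- grid_vox_points(dm) / 2
        array(2 * interp_trilinear(a, pts, oob = "clamp"), dm)
      }
      d1 <- up(d1); d2 <- up(d2); d3 <- up(d3)
    }
    base <- grid_vox_points(dm)
    for (it in seq_len(params$iters_per_scale)) {
      Sw <- warp_vox(S, list(d1, d2, d3), base = base)
      gT <- gradient3(Tg); gS <- gradient3(Sw)
      g1 <- 0.5 * (gT[[1]] + gS[[1]])
      g2 <- 0.5 * (gT[[2]] + gS[[2]])
      g3 <- 0.5 * (gT[[3]] + gS[[3]])
      diffi <- Tg - Sw
      # gradient floor relative to the strongest structure present plus a
      # Thirion-style diff^2 term: both bound the step where the local
      # linearization is unreliable (flat regions, large residuals)
      lam <- 0.01 * max(g1^2 + g2^2 + g3^2) + 1e-30
      A11 <- A12 <- A13 <- A22 <- A23 <- A33 <- array(0, dm)
      b1 <- b2 <- b3 <- array(0, dm)
      for (k in seq_len(nrow(Nor))) {
        n <- Nor[k, ]
        gk <- n[1] * g1 + n[2] * g2 + n[3] * g3
        ck <- gk^2
        dk <- diffi * gk / (ck + diffi^2 + lam)
        A11 <- A11 + ck * n[1] * n[1]; A12 <- A12 + ck * n[1] * n[2]
        A13 <- A13 + ck * n[1] * n[3]; A22 <- A22 + ck * n[2] * n[2]
        A23 <- A23 + ck * n[2] * n[3]; A33 <- A33 + ck * n[3] * n[3]
        b1 <- b1 + ck * dk * n[1]; b2 <- b2 + ck * dk * n[2]; b3 <- b3 + ck * dk * n[3]
      }
      cert <- A11 + A22 + A33
      eps <- 1e-3 * mean(cert) + 1e-12
      A11 <- A11 + eps; A22 <- A22 + eps; A33 <- A33 + eps
      # closed-form symmetric 3x3 inverse times b
      c11 <- A22 * A33 - A23 * A23
      c12 <- A13 * A23 - A12 * A33
      c13 <- A12 * A23 - A13 * A22
      c22 <- A11 * A33 - A13 * A13
      c23 <- A12 * A13 - A11 * A23
      c33 <- A11 * A22 - A12 * A12
      det <- A11 * c11 + A12 * c12 + A13 * c13
      u1 <- (c11 * b1 + c12 * b2 + c13 * b3) / det
      u2 <- (c12 * b1 + c22 * b2 + c23 * b3) / det
      u3 <- (c13 * b1 + c23 * b2 + c33 * b3) / det
      # cap the per-voxel step
      nu <- sqrt(u1^2 + u2^2 + u3^2)
      f <- pmin(1, params$step_cap / pmax(nu, 1e-12))
      u1 <- u1 * f; u2 <- u2 * f; u3 <- u3 * f
      # fluid regularization of the increment
      u1 <- nc_smooth(u1, cert, params$sigma_fluid)
      u2 <- nc_smooth(u2, cert, params$sigma_fluid)
      u3 <- nc_smooth(u3, cert, params$sigma_fluid)
      # diffeomorphic accumulation: compose, never add
      pts <- base + cbind(as.vector(u1), as.vector(u2), as.vector(u3))
      d1 <- u1 + array(interp_trilinear(d1, pts, oob = "clamp"), dm)
      d2 <- u2 + array(interp_trilinear(d2, pts, oob = "clamp"), dm)
      d3 <- u3 + array(interp_trilinear(d3, pts, oob = "clamp"), dm)
      # elastic regularization of the accumulated field
      d1 <- nc_smooth(d1, cert, params$sigma_elastic)
      d2 <- nc_smooth(d2, cert, params$sigma_elastic)
      d3 <- nc_smooth(d3, cert, params$sigma_elastic)
      # enforce the diffeomorphism contract
      tries <- 0L
      while (min(interior(jacdet_vox(d1, d2, d3))) <= 0.02 && tries < 5L) {
        sg <- max(params$sigma_elastic, 1)
        d1 <- gauss_smooth3(d1, sg); d2 <- gauss_smooth3(d2, sg); d3 <- gauss_smooth3(d3, sg)
        tries <- tries + 1L
      }
      cert_last <- cert
    }
  }

  obj_id <- 1 - ncc(source, target)
  obj_fin <- 1 - ncc(warp_vox(source, list(d1, d2, d3)), target)
  dvox <- cbind(as.vector(d1), as.vector(d2), as.vector(d3))
  out <- dvox_to_field(dvox, dim(target),
                       certainty = cert_last / max(max(cert_last), 1e-12),
                       voxel_size = meta$voxel_size,
                       grid_to_world = meta$grid_to_world)
  attr(out, "objective") <- obj_fin
  attr(out, "objective_identity") <- obj_id
  out
}

# ---- warping, inversion, point mapping, diagnostics --------------------

#' Warp an image through an affine and/or displacement field
#'
#' `out(x) = image(affine(x + d(x)))` with linear interpolation;
#' out-of-bounds samples are 0. `mode = "mask"` interpolates a 0/1 image
#' linearly and thresholds at 0.5.
#'
#' @param image 3D array.
#' @param affine optional [affine_transform()] (world mm).
#' @param field optional [displacement_field()]; its grid is the output
#'   grid.
#' @param mode `"linear"` or `"mask"`.
#' @param image_meta [acquisition_meta()] of `image` (default unit grid).
#' @param out_meta output-grid meta when `field` is NULL (default:
#'   `image_meta`).
#' @return 3D array on the output grid.
#' @export
warp_image <- function(image, affine = NULL, field = NULL,
                       mode = c("linear", "mask"), image_meta = NULL,
                       out_meta = NULL) {
  mode <- match.arg(mode)
  if (is.null(image_meta)) image_meta <- unit_spatial_meta(dim(image))
  if (!is.null(field)) {
    out_dim <- field$dim
    g2w <- field$grid_to_world
  } else {
    if (is.null(out_meta)) out_meta <- image_meta
    out_dim <- out_meta$dim %||% dim(image)
    g2w <- out_meta$grid_to_world
  }
  ii <- grid_vox_points(out_dim)
  w <- t(g2w[1:3, 1:3] %*% t(ii) + g2w[1:3, 4])
  if (!is.null(field)) w <- w + matrix(field$d, ncol = 3L)
  if (!is.null(affine)) w <- apply_affine(affine, w)
  vox <- world_to_voxel(image_meta, w)
  val <- interp_trilinear(image, vox, oob = 0)
  out <- array(val, out_dim)
  if (mode == "mask") out <- (out >= 0.5)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Warp an integer label volume
#'
#' Each label code is warped as a 0/1 mask with linear interpolation; a
#' voxel receives the code with the largest interpolated response, if that
#' response reaches 0.5 (mask-mode warping; labels are categorical so
#' interpolating the codes themselves would be meaningless).
#'
#' @param labels integer 3D array (0 = background).
#' @param affine,field,image_meta,out_meta as in [warp_image()].
#' @return integer 3D array on the output grid.
#' @export
warp_labels <- function(labels, affine = NULL, field = NULL,
                        image_meta = NULL, out_meta = NULL) {
  codes <- sort(setdiff(unique(as.vector(labels)), 0L))
  out_dim <- if (!is.null(field)) field$dim else (out_meta$dim %||% dim(labels))
  best <- array(0, out_dim)
  lab <- array(0L, out_dim)
  for (code in codes) {
    r <- warp_image((labels == code) * 1, affine = affine, field = field,
                    mode = "linear", image_meta = image_meta, out_meta = out_meta)
    take <- r >= 0.5 & r > best
    lab[take] <- code
    best[take] <- r[take]
  }
  lab
}

#' Invert a diffeomorphic displacement field
#'
#' Fixed-point iteration `d_inv(x) <- -d(x + d_inv(x))` until the maximum
#' update falls below `tol` (in voxels). The composition residual
#' `max |d_inv(x) + d(x + d_inv(x))|` is attached as attribute
#' `residual` (voxels).
#'
#' @param field a [displacement_field()] with positive Jacobian.
#' @param n_iter maximum iterations (default 50).
#' @param tol convergence tolerance in voxels (default 0.01).
#' @return the inverse [displacement_field()].
#' @export
invert_field <- function(field, n_iter = 50L, tol = 0.01) {
  dm <- field$dim
  base <- grid_vox_points(dm)
  dv <- field_dvox(field)
  dvarr <- lapply(1:3, function(c3) array(dv[, c3], dm))
  inv <- matrix(0, nrow(base), 3L)
  upd <- Inf
  for (it in seq_len(n_iter)) {
    pts <- base + inv
    s <- cbind(interp_trilinear(dvarr[[1]], pts, oob = "clamp"),
               interp_trilinear(dvarr[[2]], pts, oob = "clamp"),
               interp_trilinear(dvarr[[3]], pts, oob = "clamp"))
    new_inv <- -s
    upd <- max(abs(new_inv - inv))
    inv <- new_inv
    if (upd < tol) break
  }
  pts <- base + inv
  res <- cbind(inv[, 1] + interp_trilinear(dvarr[[1]], pts, oob = "clamp"),
               inv[, 2] + interp_trilinear(dvarr[[2]], pts, oob = "clamp"),
               inv[, 3] + interp_trilinear(dvarr[[3]], pts, oob = "clamp"))
  resid <- max(abs(res))
  if (upd >= tol && resid >= tol)
    stop(sprintf("field inversion did not converge: residual %.4f voxels", resid))
  out <- dvox_to_field(inv, dm, voxel_size = field$voxel_size,
                       grid_to_world = field$grid_to_world)
  attr(out, "residual") <- resid
  out
}

#' Map points forward from atlas space to subject space
#'
#' The registration chain is pull-back (a subject point x samples the
#' atlas at `affine(x + d(x))`), so mapping atlas points into the subject
#' requires the inverse: `y = affine^-1(p)`, then `x = y + d_inv(y)`.
#' Points landing outside the subject grid are retained and flagged in the
#' logical attribute `oob`.
#'
#' @param points n x 3 matrix of mm points in atlas space.
#' @param affine optional [affine_transform()] of the chain.
#' @param field optional [displacement_field()] of the chain.
#' @param inverse_field optional precomputed [invert_field()] result.
#' @return n x 3 matrix of mm points in subject space, attribute `oob`.
#' @export
map_points <- function(points, affine = NULL, field = NULL,
                       inverse_field = NULL) {
  pts <- matrix(points, ncol = 3L)
  if (!is.null(affine)) pts <- apply_affine(invert_affine(affine), pts)
  oob <- rep(FALSE, nrow(pts))
  if (!is.null(field) || !is.null(inverse_field)) {
    if (is.null(inverse_field)) inverse_field <- invert_field(field)
    dm <- inverse_field$dim
    Gi <- solve(inverse_field$grid_to_world)
    vox <- sweep(pts %*% t(Gi[1:3, 1:3]), 2L, Gi[1:3, 4], "+")
    dinv <- lapply(1:3, function(c3) array(inverse_field$d[, , , c3], dm))
    shift <- cbind(interp_trilinear(dinv[[1]], vox, oob = "clamp"),
                   interp_trilinear(dinv[[2]], vox, oob = "clamp"),
                   interp_trilinear(dinv[[3]], vox, oob = "clamp"))
    pts <- pts + shift
    vox2 <- sweep(pts %*% t(Gi[1:3, 1:3]), 2L, Gi[1:3, 4], "+")
    oob <- vox2[, 1] < 0 | vox2[, 1] > dm[1] - 1L |
           vox2[, 2] < 0 | vox2[, 2] > dm[2] - 1L |
           vox2[, 3] < 0 | vox2[, 3] > dm[3] - 1L
  }
  attr(pts, "oob") <- oob
  pts
}

#' Jacobian determinant of a displacement field
#'
#' Central-difference determinant of `I + grad(d)` in world coordinates.
#' Values are meaningful at interior voxels; a diffeomorphic field has
#' strictly positive interior values.
#'
#' @param field a [displacement_field()].
#' @return 3D array of determinants.
#' @export
jacobian_determinant <- function(field) {
  dm <- field$dim
  vs <- field$voxel_size
  g <- vector("list", 3L)
  for (c3 in 1:3) g[[c3]] <- gradient3(array(field$d[, , , c3], dm))
  # d is in mm; convert index-derivatives to per-mm using the voxel size
  a <- 1 + g[[1]][[1]] / vs[1]; b <- g[[1]][[2]] / vs[2]; cc <- g[[1]][[3]] / vs[3]
  d <- g[[2]][[1]] / vs[1]; e <- 1 + g[[2]][[2]] / vs[2]; f <- g[[2]][[3]] / vs[3]
  gg <- g[[3]][[1]] / vs[1]; h <- g[[3]][[2]] / vs[2]; i <- 1 + g[[3]][[3]] / vs[3]
  a * (e * i - f * h) - b * (d * i - f * gg) + cc * (d * h - e * gg)
}
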