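# Offline velocity corrections applied before angiography: temporal phase
# unwrapping and removal of residual background phase offsets by a weighted
# 2nd-order polynomial fitted to static tissue. Concomitant-gradient
# correction is assumed done at acquisition time and is out of scope.

#' Detect static tissue
#'
#' Static tissue is identified as voxels with reliable signal (time-mean
#' magnitude at least `mag_frac` times the volume-wide 95th percentile of
#' the time-mean magnitude) whose speed barely varies over the cardiac
#' cycle (temporal standard deviation of speed at most `vel_std_max`).
#' Confidence weights fall linearly from 1 at zero temporal variation to 0
#' at `vel_std_max`.
#'
#' @param flow a [flow4d()].
#' @param mag_frac magnitude threshold as a fraction of the 95th
#'   percentile; default 0.1.
#' @param vel_std_max maximum temporal speed standard deviation in cm/s;
#'   default 2.
#' @return list with `mask` (logical 3D array) and `weights` (numeric 3D
#'   array in `[0, 1]`, zero outside the mask).
#' @export
detect_static_tissue <- function(flow, mag_frac = 0.1, vel_std_max = 2) {
  d <- dim(flow$magnitude)
  nt <- d[4]
  if (nt < 2L) stop("need at least 2 frames")
  magmean <- rowMeans(matrix(flow$magnitude, ncol = nt))
  speed <- matrix(flow_speed(flow), ncol = nt)
  mu <- rowMeans(speed)
  sd_t <- sqrt(pmax(rowSums((speed - mu)^2) / (nt - 1L), 0))
  thr <- mag_frac * stats::quantile(magmean, 0.95, names = FALSE)
  mask <- magmean > 0 & magmean >= thr & sd_t <= vel_std_max
  if (!any(mask)) stop("no static tissue detected; skip background correction")
  w <- pmin(pmax(1 - sd_t / vel_std_max, 0), 1)
  w[!is.finite(w)] <- 1     # vel_std_max = Inf limit
  w[!mask] <- 0
  list(mask = array(mask, d[1:3]), weights = array(w, d[1:3]))
}

#' Temporal phase unwrapping
#'
#' Velocities beyond +/- VENC alias by multiples of 2 VENC. Scanning each
#' voxel's time series in order (the anchor frame is assumed wrap-free),
#' any successive difference larger than VENC in absolute value is
#' corrected by the nearest multiple of 2 VENC and the correction is
#' propagated to later frames. Idempotent; every change is an exact integer
#' multiple of 2 VENC.
#'
#' @param flow a [flow4d()].
#' @param anchor_frame 1-based frame assumed unaliased; default 1 (early
#'   diastole/R-wave, where speeds are lowest).
#' @return corrected [flow4d()].
#' @export
unwrap_temporal <- function(flow, anchor_frame = 1L) {
  venc <- flow$meta$venc
  d <- dim(flow$vx)
  nt <- d[4]
  anchor_frame <- as.integer(anchor_frame)
  if (anchor_frame < 1L || anchor_frame > nt) stop("anchor_frame out of range")
  unwrap_mat <- function(m) {  # nvox x nt, anchor column first conceptually
    fix_dir <- function(cols) { # correct successively along given column order
      corr <- numeric(nrow(m))
      for (i in seq_along(cols)[-1]) {
        dlt <- (m[, cols[i]] + corr) - m2[, cols[i - 1]]
        k <- round(dlt / (2 * venc))
        corr <- corr - 2 * venc * k
        m2[, cols[i]] <<- m[, cols[i]] + corr
      }
      invisible(NULL)
    }
    m2 <- m
    if (anchor_frame < nt) fix_dir(anchor_frame:nt)
    if (anchor_frame > 1L) fix_dir(anchor_frame:1L)
    m2
  }
  out <- flow
  for (nm in c("vx", "vy", "vz")) {
    m <- matrix(flow[[nm]], ncol = nt)
    out[[nm]] <- array(unwrap_mat(m), d)
  }
  out
}

# normalized [-1,1] coordinates and the 10-term quadratic design matrix
poly2_design <- function(dim3) {
  nx <- function(n) if (n > 1L) 2 * (seq_len(n) - 1L) / (n - 1L) - 1 else 0
  g <- expand.grid(x = nx(dim3[1]), y = nx(dim3[2]), z = nx(dim3[3]))
  with(g, cbind(1, x, y, z, x^2, y^2, z^2, x * y, x * z, y * z))
}

#' Fit a background phase-offset model
#'
#' Weighted least-squares fit of a full 2nd-order 3D polynomial (10 terms:
#' 1, x, y, z, x^2, y^2, z^2, xy, xz, yz in per-axis normalized
#' coordinates) to the temporal-mean velocity of each component over static
#' tissue.
#'
#' @param flow a [flow4d()].
#' @param static result of [detect_static_tissue()].
#' @return object of class `background_model`: `coeffs` (10 x 3 matrix, one
#'   column per velocity component, cm/s), `dim`, `residual_rms` (weighted
#'   RMS residual per component, cm/s).
#' @export
fit_background <- function(flow, static) {
  d <- dim(flow$vx)[1:3]
  nt <- dim(flow$vx)[4]
  w <- as.vector(static$weights)
  sel <- w > 0
  if (sum(sel) < 10L) stop("need at least 10 static voxels with positive weight")
  X <- poly2_design(d)[sel, , drop = FALSE]
  sw <- sqrt(w[sel])
  Xw <- X * sw
  qrX <- qr(Xw)
  if (qrX$rank < 10L) stop("rank-deficient background fit: static voxels are degenerate")
  coeffs <- matrix(0, 10L, 3L, dimnames = list(
    c("1", "x", "y", "z", "x2", "y2", "z2", "xy", "xz", "yz"), c("vx", "vy", "vz")))
  rms <- numeric(3L)
  comps <- c("vx", "vy", "vz")
  for (c3 in seq_along(comps)) {
    vmean <- rowMeans(matrix(flow[[comps[c3]]], ncol = nt))[sel]
    beta <- qr.coef(qrX, vmean * sw)
    coeffs[, c3] <- beta
    r <- vmean - as.vector(X %*% beta)
    rms[c3] <- sqrt(sum(w[sel] * r^2) / sum(w[sel]))
  }
  structure(list(coeffs = coeffs, dim = d, residual_rms = rms),
            class = "background_model")
}

# evaluate the polynomial offset field (nvox x 3 matrix, cm/s)
eval_background <- function(model, dim3 = model$dim) {
  poly2_design(dim3) %*% model$coeffs
}

#' Subtract a fitted background offset from every frame
#'
#' @param flow a [flow4d()].
#' @param model a `background_model` from [fit_background()].
#' @return corrected [flow4d()]; magnitude is untouched.
#' @export
correct_background <- function(flow, model) {
  d <- dim(flow$vx)
  if (!identical(as.integer(model$dim), as.integer(d[1:3])))
    stop("background model grid does not match data")
  off <- eval_background(model)
  nt <- d[4]
  comps <- c("vx", "vy", "vz")
  for (c3 in seq_along(comps)) {
    m <- matrix(flow[[comps[c3]]], ncol = nt)
    flow[[comps[c3]]] <- array(m - off[, c3], d)
  }
  flow
}
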