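# Pulsatile flow phantoms with analytic ground truth.
#
# Each phantom is a set of cylindrical vessels carrying laminar Poiseuille
# flow modulated by a cardiac waveform, embedded in a static-tissue shell
# inside a low-signal background -- emulating a 4D flow acquisition
# (default grid 64^3 voxels at 2.7 x 2.7 x 2.8 mm, 20 frames of 52.8 ms,
# VENC 120 cm/s). Velocity is assigned from the analytic profile at the
# voxel centre (no subvoxel averaging) so the ground truth stays analytic;
# what remains is honest discretization error. Optional corruptions: bulk
# or radial motion, Gaussian noise, a quadratic background phase offset
# and velocity aliasing beyond VENC.

#' Cardiac waveform specification
#'
#' @param shape `"half_sine"` (sin(pi t / systole) during systole, 0 in
#'   diastole), `"constant"`, or `"table"` (per-frame multipliers).
#' @param systole_duration systole length in s (default 0.3).
#' @param cycle_duration cycle length in s; default `n_frames *
#'   frame_duration` at sampling time.
#' @param values per-frame multipliers in `[0, 1]` for `shape = "table"`.
#' @return list of class `waveform_spec`.
#' @export
waveform_spec <- function(shape = c("half_sine", "constant", "table"),
                          systole_duration = 0.3, cycle_duration = NULL,
                          values = NULL) {
  shape <- match.arg(shape)
  structure(list(shape = shape, systole_duration = systole_duration,
                 cycle_duration = cycle_duration, values = values),
            class = "waveform_spec")
}

#' Sample a waveform at frame midpoints
#'
#' @param spec a [waveform_spec()].
#' @param n_frames number of cardiac frames.
#' @param frame_duration frame duration in ms (used when no explicit
#'   cycle duration is given).
#' @return list: `multipliers` (length `n_frames`), `integral` (exact
#'   integral of the continuous waveform over the cycle, in s),
#'   `cycle_duration` (s), `fn` (the continuous waveform function).
#' @export
make_waveform <- function(spec, n_frames, frame_duration = NULL) {
  cyc <- spec$cycle_duration
  if (is.null(cyc)) {
    if (is.null(frame_duration)) stop("need cycle_duration or frame_duration")
    cyc <- n_frames * frame_duration / 1000
  }
  if (spec$shape != "table" && spec$systole_duration > cyc)
    stop("systole_duration exceeds cycle_duration")
  dt <- cyc / n_frames
  tm <- (seq_len(n_frames) - 0.5) * dt
  out <- switch(spec$shape,
    constant = {
      list(fn = function(t) rep(1, length(t)), integral = cyc)
    },
    half_sine = {
      Ts <- spec$systole_duration
      list(fn = function(t) ifelse(t >= 0 & t <= Ts, sin(pi * t / Ts), 0),
           integral = 2 * Ts / pi)
    },
    table = {
      vals <- spec$values
      if (is.null(vals)) stop("table waveform needs values")
      if (length(vals) != n_frames) stop("table length must equal n_frames")
      list(fn = local({
             v <- vals
             function(t) v[pmin(pmax(floor(t / dt) + 1L, 1L), length(v))]
           }),
           integral = sum(vals) * dt)
    })
  list(multipliers = out$fn(tm), integral = out$integral,
       cycle_duration = cyc, fn = out$fn)
}

#' Phantom specification
#'
#' @param geometry `"straight_tube"`, `"curved_tube"`, `"y_bifurcation"`
#'   or `"two_vessel"`.
#' @param radius tube radius in mm (trunk radius for the bifurcation).
#' @param v_max peak centreline velocity in cm/s.
#' @param waveform a [waveform_spec()].
#' @param motion_amplitude mm of geometric motion over the cycle.
#' @param motion_mode `"bulk_sinusoidal"` (rigid translation along x) or
#'   `"radial_pulsation"` (radius modulation).
#' @param noise_sigma_vel Gaussian velocity noise sd in cm/s.
#' @param noise_sigma_mag magnitude noise as a fraction of the local
#'   magnitude.
#' @param background_poly optional 10 x 3 coefficient matrix of a
#'   quadratic phase-offset field (cm/s, per component; see
#'   [fit_background()] for the term order).
#' @param wrap_inject alias velocities beyond +/- VENC by 2 VENC, as the
#'   scanner would.
#' @param seed integer fixing all randomness.
#' @param grid `"clinical"` (64^3, acquisition-matched) or `"fast"` (32^3)
#'   preset, ignored when
#'   `meta` is given.
#' @param meta an [acquisition_meta()] with spatial `dim`.
#' @param split flow split fractions for the bifurcation (default 0.6 /
#'   0.4).
#' @param branch_angle bifurcation half-angle in degrees (default 25).
#' @return list of class `phantom_spec`.
#' @export
phantom_spec <- function(geometry = c("straight_tube", "curved_tube",
                                      "y_bifurcation", "two_vessel"),
                         radius = 10, v_max = 100,
                         waveform = waveform_spec(),
                         motion_amplitude = 0,
                         motion_mode = c("bulk_sinusoidal", "radial_pulsation"),
                         noise_sigma_vel = 0, noise_sigma_mag = 0,
                         background_poly = NULL, wrap_inject = FALSE,
                         seed = 1L, grid = c("clinical", "fast"), meta = NULL,
                         split = c(0.6, 0.4), branch_angle = 25) {
  geometry <- match.arg(geometry)
  motion_mode <- match.arg(motion_mode)
  grid <- match.arg(grid)
  if (is.null(meta)) {
    dim3 <- if (grid == "clinical") c(64L, 64L, 64L) else c(32L, 32L, 32L)
    meta <- acquisition_meta(c(2.7, 2.7, 2.8), 52.8, 20L, 120, dim = dim3)
  }
  if (is.null(meta$dim)) stop("meta must carry the spatial dim")
  stopifnot(radius > 0, v_max > 0, noise_sigma_vel >= 0, noise_sigma_mag >= 0,
            motion_amplitude >= 0, abs(sum(split) - 1) < 1e-9)
  structure(list(geometry = geometry, radius = radius, v_max = v_max,
                 waveform = waveform, motion_amplitude = motion_amplitude,
                 motion_mode = motion_mode, noise_sigma_vel = noise_sigma_vel,
                 noise_sigma_mag = noise_sigma_mag,
                 background_poly = background_poly,
                 wrap_inject = wrap_inject, seed = as.integer(seed),
                 meta = meta, split = split, branch_angle = branch_angle),
            class = "phantom_spec")
}

# vessel description list: code, axis (unit), a point on the centreline,
# radius, v_max, axial extent along the axis (range of projections), and
# the flow fraction of the trunk waveform it carries
phantom_vessels <- function(spec) {
  meta <- spec$meta
  fov <- (meta$dim - 1) * meta$voxel_size
  cx <- fov[1] / 2; cy <- fov[2] / 2
  R <- spec$radius
  switch(spec$geometry,
    straight_tube = list(
      list(code = 1L, point = c(cx, cy, 0), axis = c(0, 0, 1), radius = R,
           v_max = spec$v_max, range = c(-Inf, Inf), frac = 1)),
    two_vessel = {
      off <- R + 6
      list(
        list(code = 1L, point = c(cx - off, cy, 0), axis = c(0, 0, 1), radius = R,
             v_max = spec$v_max, range = c(-Inf, Inf), frac = 1),
        list(code = 2L, point = c(cx + off, cy, 0), axis = c(0, 0, 1), radius = R,
             v_max = spec$v_max, range = c(-Inf, Inf), frac = 1))
    },
    y_bifurcation = {
      zs <- 0.45 * fov[3]
      th <- spec$branch_angle * pi / 180
      Rb <- 0.75 * R
      f <- spec$split
      vb <- function(fr) fr * spec$v_max * (R / Rb)^2
      list(
        list(code = 1L, point = c(cx, cy, 0), axis = c(0, 0, 1), radius = R,
             v_max = spec$v_max, range = c(-Inf, zs), frac = 1),
        list(code = 2L, point = c(cx, cy, zs), axis = c(-sin(th), 0, cos(th)),
             radius = Rb, v_max = vb(f[1]), range = c(0, Inf), frac = f[1]),
        list(code = 3L, point = c(cx, cy, zs), axis = c(sin(th), 0, cos(th)),
             radius = Rb, v_max = vb(f[2]), range = c(0, Inf), frac = f[2]))
    },
    curved_tube = {
      # quarter arc in the x-z plane around (cx - Ra, cy, .) -- handled
      # separately in the evaluation below
      Ra <- 0.3 * fov[1]
      list(list(code = 1L, point = c(cx - Ra / 2, cy, fov[3] / 2), axis = NA,
                radius = R, v_max = spec$v_max, range = c(0, pi / 2),
                frac = 1, arc_radius = Ra))
    })
}

# evaluate geometry at points pts (n x 3 world mm), returning per-vessel
# perpendicular radius and axial direction
eval_vessel <- function(v, pts, geometry) {
  if (geometry == "curved_tube") {
    c0 <- v$point; Ra <- v$arc_radius
    dx <- pts[, 1] - c0[1]; dz <- pts[, 3] - c0[3]
    rho <- sqrt(dx^2 + dz^2)
    phi <- atan2(dz, dx)
    r <- sqrt((rho - Ra)^2 + (pts[, 2] - c0[2])^2)
    inside_range <- phi >= v$range[1] & phi <= v$range[2]
    ax <- cbind(-sin(phi), 0, cos(phi))
    list(r = r, axis = ax, in_range = inside_range)
  } else {
    w <- sweep(pts, 2L, v$point, "-")
    proj <- as.vector(w %*% v$axis)
    perp <- w - outer(proj, v$axis)
    r <- sqrt(rowSums(perp^2))
    list(r = r, axis = matrix(v$axis, nrow(pts), 3L, byrow = TRUE),
         in_range = proj >= v$range[1] & proj <= v$range[2])
  }
}

#' Generate a pulsatile flow phantom
#'
#' @param spec a [phantom_spec()].
#' @return list of class `flow_phantom`: `flow` (a [flow4d()]), `truth`
#'   (per-frame `labels_t`, `plane_truth` named net volumes in ml,
#'   `motion_t` per-frame rigid offsets in mm, `peak_frame_true`,
#'   `clean_vel` pre-corruption velocity arrays), `planes` (default
#'   analysis planes, see [phantom_planes()]), `spec`.
#' @export
make_phantom <- function(spec) {
  meta <- spec$meta
  d <- meta$dim
  nt <- meta$n_frames
  wf <- make_waveform(spec$waveform, nt, meta$frame_duration)
  vessels <- phantom_vessels(spec)
  pts0 <- grid_world_points(meta, d)
  fov <- (d - 1) * meta$voxel_size

  amp <- spec$motion_amplitude
  mode <- spec$motion_mode
  offsets <- lapply(seq_len(nt) - 1L, function(k0) {
    if (amp > 0 && mode == "bulk_sinusoidal")
      c(amp * sin(2 * pi * k0 / nt), 0, 0)
    else c(0, 0, 0)
  })
  dR <- vapply(seq_len(nt) - 1L, function(k0) {
    if (amp > 0 && mode == "radial_pulsation") amp * sin(2 * pi * k0 / nt) else 0
  }, 0)

  # off-grid guard: the lumen must stay inside the volume
  margin <- max(meta$voxel_size)
  for (v in vessels) {
    if (spec$geometry == "curved_tube") next
    reach <- v$radius + amp + max(abs(dR)) + margin
    p <- v$point
    for (ax in 1:2) {   # x and y; tubes run roughly along z
      if (abs(v$axis[ax]) < 0.99 &&
          (p[ax] - reach < 0 || p[ax] + reach > fov[ax]))
        stop("motion or geometry pushes the lumen off the grid")
    }
  }

  set.seed(spec$seed)
  mag <- array(0, c(d, nt))
  vx <- array(0, c(d, nt)); vy <- array(0, c(d, nt)); vz <- array(0, c(d, nt))
  labs <- array(0L, c(d, nt))
  shell_th <- 8

  for (t in seq_len(nt)) {
    pts <- sweep(pts0, 2L, offsets[[t]], "-")  # move geometry = shift sample frame
    m <- rep(2, nrow(pts))
    v1 <- v2 <- v3 <- rep(0, nrow(pts))
    lb <- rep(0L, nrow(pts))
    mindist <- rep(Inf, nrow(pts))
    for (v in vessels) {
      ev <- eval_vessel(v, pts, spec$geometry)
      Rt <- v$radius + dR[t]
      inside <- ev$r <= Rt & ev$in_range
      prof <- v$v_max * (1 - (ev$r / Rt)^2) * wf$multipliers[t]
      v1[inside] <- prof[inside] * ev$axis[inside, 1]
      v2[inside] <- prof[inside] * ev$axis[inside, 2]
      v3[inside] <- prof[inside] * ev$axis[inside, 3]
      lb[inside] <- v$code
      mindist <- pmin(mindist, ifelse(ev$in_range, ev$r - Rt, Inf))
    }
    m[mindist <= 0] <- 100
    m[mindist > 0 & mindist <= shell_th] <- 40
    mag[, , , t] <- m
    vx[, , , t] <- v1; vy[, , , t] <- v2; vz[, , , t] <- v3
    labs[, , , t] <- lb
  }

  clean <- list(vx = vx, vy = vy, vz = vz)

  if (spec$noise_sigma_mag > 0)
    mag <- pmax(mag * (1 + stats::rnorm(length(mag)) * spec$noise_sigma_mag), 0)
  if (spec$noise_sigma_vel > 0) {
    vx <- vx + stats::rnorm(length(vx)) * spec$noise_sigma_vel
    vy <- vy + stats::rnorm(length(vy)) * spec$noise_sigma_vel
    vz <- vz + stats::rnorm(length(vz)) * spec$noise_sigma_vel
  }
  if (!is.null(spec$background_poly)) {
    B <- matrix(spec$background_poly, 10L, 3L)
    off <- poly2_design(d) %*% B
    for (t in seq_len(nt)) {
      vx[, , , t] <- vx[, , , t] + array(off[, 1], d)
      vy[, , , t] <- vy[, , , t] + array(off[, 2], d)
      vz[, , , t] <- vz[, , , t] + array(off[, 3], d)
    }
  }
  if (spec$wrap_inject) {
    venc <- meta$venc
    wrap <- function(v) ((v + venc) %% (2 * venc)) - venc
    vx <- wrap(vx); vy <- wrap(vy); vz <- wrap(vz)
  }

  # analytic net volumes: Poiseuille branch, v_max pi R^2 / 2 * integral(w)
  tube_volume <- function(v) {
    if (mode == "radial_pulsation" && amp > 0) {
      dt <- wf$cycle_duration / nt
      sum(v$v_max * pi * (v$radius + dR)^2 / 2 * wf$multipliers * dt) * 1e-2
    } else {
      v$v_max * pi * v$radius^2 / 2 * wf$integral * 1e-2
    }
  }
  planes <- phantom_planes(spec)
  plane_truth <- stats::setNames(vapply(planes, function(p) {
    v <- vessels[[which(vapply(vessels, function(x) x$code, 0L) == p$vessel_code)]]
    tube_volume(v)
  }, 0), vapply(planes, function(p) p$name, ""))

  flow <- flow4d(mag, vx, vy, vz, meta)
  truth <- list(labels_t = labs, plane_truth = plane_truth,
                motion_t = offsets, radius_delta_t = dR,
                peak_frame_true = which.max(wf$multipliers),
                waveform = wf, clean_vel = clean)
  structure(list(flow = flow, truth = truth, planes = planes, spec = spec),
            class = "flow_phantom")
}

#' Default analysis planes for a phantom geometry
#'
#' Planes are perpendicular to each vessel with extent `radius + 10` mm,
#' normals pointing downstream so arterial net volumes are positive.
#'
#' @param spec a [phantom_spec()].
#' @return list of [flow_plane()].
#' @export
phantom_planes <- function(spec) {
  meta <- spec$meta
  fov <- (meta$dim - 1) * meta$voxel_size
  cx <- fov[1] / 2; cy <- fov[2] / 2
  R <- spec$radius
  vessels <- phantom_vessels(spec)
  mk <- function(name, v, along) {
    if (spec$geometry == "curved_tube") {
      phi <- along
      c0 <- v$point; Ra <- v$arc_radius
      org <- c(c0[1] + Ra * cos(phi), cy, c0[3] + Ra * sin(phi))
      nrm <- c(-sin(phi), 0, cos(phi))
    } else {
      lo <- max(v$range[1], 0); hi <- min(v$range[2], fov[3])
      org <- v$point + (lo + along * (hi - lo)) * v$axis
      nrm <- v$axis
    }
    flow_plane(name, org, nrm, extent = rep(v$radius + 10, 2L),
               vessel_code = v$code)
  }
  switch(spec$geometry,
    straight_tube = list(mk("tube_a", vessels[[1]], 0.40),
                         mk("tube_b", vessels[[1]], 0.60)),
    two_vessel = list(mk("vessel_left", vessels[[1]], 0.5),
                      mk("vessel_right", vessels[[2]], 0.5)),
    y_bifurcation = {
      zs <- 0.45 * fov[3]
      trunk <- vessels[[1]]
      lb <- vessels[[2]]; rb <- vessels[[3]]
      blen <- (fov[3] - zs) / max(lb$axis[3], 1e-6) * 0.45
      list(flow_plane("trunk", c(cx, cy, 0.55 * zs), c(0, 0, 1),
                      extent = rep(R + 10, 2L), vessel_code = 1L),
           flow_plane("branch_left", lb$point + blen * lb$axis, lb$axis,
                      extent = rep(lb$radius + 8, 2L), vessel_code = 2L),
           flow_plane("branch_right", rb$point + blen * rb$axis, rb$axis,
                      extent = rep(rb$radius + 8, 2L), vessel_code = 3L))
    },
    curved_tube = list(mk("arc_a", vessels[[1]], 0.3),
                       mk("arc_b", vessels[[1]], 1.2)))
}

#' Re-generate a phantom with motion applied
#'
#' Amplitude 0 returns an identical phantom; otherwise the geometry is
#' displaced per frame and the analytic velocity re-evaluated at the moved
#' positions, with truth motion recorded.
#'
#' @param phantom a `flow_phantom` from [make_phantom()].
#' @param amplitude motion amplitude in mm (>= 0).
#' @param mode `"bulk_sinusoidal"` or `"radial_pulsation"`.
#' @return a new `flow_phantom`.
#' @export
apply_motion <- function(phantom, amplitude,
                         mode = c("bulk_sinusoidal", "radial_pulsation")) {
  mode <- match.arg(mode)
  stopifnot(amplitude >= 0)
  spec <- phantom$spec
  spec$motion_amplitude <- amplitude
  spec$motion_mode <- mode
  make_phantom(spec)
}
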