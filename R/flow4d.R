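#' A 4D flow CMR dataset
#'
#' Container for one time-resolved phase-contrast acquisition: a magnitude
#' volume and three velocity-component volumes per cardiac frame, on one
#' shared spatial grid. Velocities are always held in cm/s; phase-scaled
#' inputs are converted at ingest (see [load_flow4d()]).
#'
#' @param magnitude 4D array (x, y, z, t) of non-negative signal magnitude
#'   (arbitrary units).
#' @param vx,vy,vz 4D arrays of velocity components in cm/s, same dim as
#'   `magnitude`.
#' @param meta an [acquisition_meta()].
#' @return Object of class `flow4d` with elements `magnitude`, `vx`, `vy`,
#'   `vz`, `meta`.
#' @export
flow4d <- function(magnitude, vx, vy, vz, meta) {
  d <- dim(magnitude)
  if (length(d) != 4L) stop("magnitude must be a 4D array (x, y, z, t)")
  for (nm in c("vx", "vy", "vz")) {
    v <- get(nm)
    if (!identical(dim(v), d)) stop("grid mismatch: ", nm, " does not match magnitude")
  }
  if (!inherits(meta, "acquisition_meta")) stop("meta must be an acquisition_meta")
  if (meta$n_frames != d[4]) stop("meta$n_frames does not match 4th array dimension")
  if (is.null(meta$dim)) meta$dim <- d[1:3]
  if (!identical(as.integer(meta$dim), as.integer(d[1:3])))
    stop("meta$dim does not match array grid")
  if (any(magnitude < 0)) stop("magnitude must be non-negative")
  structure(list(magnitude = magnitude, vx = vx, vy = vy, vz = vz, meta = meta),
            class = "flow4d")
}

#' @export
print.flow4d <- function(x, ...) {
  d <- dim(x$magnitude)
  cat(sprintf("flow4d: %d x %d x %d grid, %d frames\n", d[1], d[2], d[3], d[4]))
  print(x$meta)
  invisible(x)
}

# speed (cm/s) for one frame or all frames
flow_speed <- function(flow, frame = NULL) {
  if (is.null(frame))
    sqrt(flow$vx^2 + flow$vy^2 + flow$vz^2)
  else
    sqrt(flow$vx[, , , frame]^2 + flow$vy[, , , frame]^2 + flow$vz[, , , frame]^2)
}

#' Time-resolved vessel segmentation
#'
#' One integer label volume per cardiac frame, produced by propagating a
#' fitted atlas segmentation through per-frame non-rigid registrations.
#'
#' @param labels_t 4D integer array (x, y, z, t) of label codes
#'   (0 = background).
#' @param source_frame 1-based index of the frame the labels were fitted on
#'   (the peak-signal systolic frame); that frame's labels are the unwarped
#'   fitted atlas.
#' @return Object of class `segmentation4d`.
#' @export
segmentation4d <- function(labels_t, source_frame) {
  if (length(dim(labels_t)) != 4L) stop("labels_t must be 4D (x, y, z, t)")
  source_frame <- as.integer(source_frame)
  if (source_frame < 1L || source_frame > dim(labels_t)[4])
    stop("source_frame out of range")
  structure(list(labels_t = labels_t, source_frame = source_frame),
            class = "segmentation4d")
}

#' @export
print.segmentation4d <- function(x, ...) {
  d <- dim(x$labels_t)
  codes <- sort(unique(as.vector(x$labels_t)))
  cat(sprintf("segmentation4d: %d x %d x %d, %d frames, codes {%s}, source frame %d\n",
              d[1], d[2], d[3], d[4],
              paste(setdiff(codes, 0L), collapse = ","), x$source_frame))
  invisible(x)
}
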