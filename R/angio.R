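# Phase-contrast MR angiography (PC-MRA) and cardiac-frame selection.
# The PC-MRA combines the frame-averaged magnitude with the norm of the
# frame-averaged velocity components:
#
#   PC_MRA(x) = Mbar(x) * sqrt(Vxbar^2 + Vybar^2 + Vzbar^2)
#
# where the bars average over the systolic frames. The magnitude factor
# suppresses noise in low-signal regions such as the lungs; averaging the
# components before taking the norm keeps stationary or oscillating spins
# dark.

#' Per-frame angiographic signal curve
#'
#' A scalar summary per cardiac frame, used to find the systolic window
#' and the peak-signal frame. The default is the volume mean of
#' M * speed, the single-frame analogue of the PC-MRA product, so the
#' selected peak frame is the one that best resembles the atlas PC-MRA;
#' `use = "magnitude"` gives the plain magnitude mean.
#'
#' @param flow a [flow4d()].
#' @param use `"product"` (default) or `"magnitude"`.
#' @return numeric vector of length `n_frames`.
#' @export
frame_signal_curve <- function(flow, use = c("product", "magnitude")) {
  use <- match.arg(use)
  nt <- dim(flow$magnitude)[4]
  if (use == "magnitude")
    return(colMeans(matrix(flow$magnitude, ncol = nt)))
  colMeans(matrix(flow$magnitude * flow_speed(flow), ncol = nt))
}

#' Select systolic frames and the peak frame
#'
#' The systolic set is every frame whose signal reaches `systolic_frac`
#' of the curve maximum; a relative threshold adapts to waveform shape.
#' The peak frame is the argmax (ties broken by the earliest frame).
#'
#' @param curve numeric per-frame signal (see [frame_signal_curve()]).
#' @param systolic_frac fraction of the maximum; default 0.7.
#' @return list with `systolic_set` (1-based frame indices) and
#'   `peak_frame`.
#' @export
select_frames <- function(curve, systolic_frac = 0.7) {
  if (!length(curve)) stop("empty signal curve")
  mx <- max(curve)
  if (mx <= 0) stop("no systole detectable: signal curve is all zero")
  set <- which(curve >= systolic_frac * mx)
  list(systolic_set = set, peak_frame = which.max(curve))
}

#' Compute a PC-MRA volume
#'
#' @param flow a [flow4d()].
#' @param frames 1-based frame indices to average over (normally the
#'   systolic set).
#' @return non-negative 3D array.
#' @export
compute_pcmra <- function(flow, frames) {
  if (!length(frames)) stop("empty frame set")
  d <- dim(flow$magnitude)
  if (any(frames < 1L | frames > d[4])) stop("frame index out of range")
  avg <- function(a) {
    m <- matrix(a, ncol = d[4])[, frames, drop = FALSE]
    array(rowMeans(m), d[1:3])
  }
  avg(flow$magnitude) * sqrt(avg(flow$vx)^2 + avg(flow$vy)^2 + avg(flow$vz)^2)
}
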