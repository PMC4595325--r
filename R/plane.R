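#' A 2D analysis plane in world coordinates
#'
#' Planes are defined once in the atlas, perpendicular to a vessel of
#' interest, and carried through registration as point sets. All geometry is
#' in world mm so a plane survives any grid resampling.
#'
#' @param name unique label, e.g. `"ascending_aorta"`.
#' @param origin mm 3-vector, centre of the plane patch.
#' @param normal unit 3-vector; its sign defines positive (downstream) flow.
#' @param in_plane_axes 2 x 3 matrix of orthonormal in-plane direction
#'   vectors.
#' @param extent mm half-widths of the patch along the two in-plane axes.
#' @param sample_points optional n x 3 matrix of mm points on the patch;
#'   defaults to a lattice with spacing `extent/4`.
#' @param vessel_code integer label code of the vessel the plane measures.
#' @return Object of class `flow_plane`.
#' @export
flow_plane <- function(name, origin, normal, in_plane_axes = NULL,
                       extent = c(15, 15), sample_points = NULL,
                       vessel_code = NA_integer_) {
  origin <- as.numeric(origin); normal <- as.numeric(normal)
  if (length(origin) != 3L || length(normal) != 3L) stop("origin/normal must be 3-vectors")
  nn <- sqrt(sum(normal^2))
  if (nn < 1e-12) stop("plane normal has zero length")
  if (abs(nn - 1) > 1e-6) stop("plane normal must be unit length")
  if (is.null(in_plane_axes)) {
    seed <- if (abs(normal[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    a1 <- seed - sum(seed * normal) * normal
    a1 <- a1 / sqrt(sum(a1^2))
    a2 <- c(normal[2] * a1[3] - normal[3] * a1[2],
            normal[3] * a1[1] - normal[1] * a1[3],
            normal[1] * a1[2] - normal[2] * a1[1])
    in_plane_axes <- rbind(a1, a2)
  }
  in_plane_axes <- matrix(as.numeric(in_plane_axes), 2L, 3L)
  for (r in 1:2) {
    if (abs(sqrt(sum(in_plane_axes[r, ]^2)) - 1) > 1e-6)
      stop("in-plane axes must be unit length")
    if (abs(sum(in_plane_axes[r, ] * normal)) > 1e-6)
      stop("in-plane axes must be orthogonal to the normal")
  }
  if (abs(sum(in_plane_axes[1, ] * in_plane_axes[2, ])) > 1e-6)
    stop("in-plane axes must be mutually orthogonal")
  extent <- as.numeric(extent)
  if (length(extent) != 2L || any(extent <= 0)) stop("extent must be 2 positive half-widths (mm)")
  if (is.null(sample_points)) {
    u <- seq(-extent[1], extent[1], length.out = 9L)
    v <- seq(-extent[2], extent[2], length.out = 9L)
    uv <- as.matrix(expand.grid(u = u, v = v))
    sample_points <- sweep(uv %*% in_plane_axes, 2L, origin, "+")
  }
  sample_points <- matrix(as.numeric(sample_points), ncol = 3L)
  rel <- sweep(sample_points, 2L, origin, "-")
  uc <- rel %*% t(in_plane_axes)
  if (any(abs(uc[, 1]) > extent[1] + 1e-6) || any(abs(uc[, 2]) > extent[2] + 1e-6))
    stop("sample_points lie outside the plane extent")
  structure(list(name = as.character(name), origin = origin, normal = normal,
                 in_plane_axes = in_plane_axes, extent = extent,
                 sample_points = sample_points,
                 vessel_code = as.integer(vessel_code)),
            class = "flow_plane")
}

#' @export
print.flow_plane <- function(x, ...) {
  cat(sprintf("flow_plane '%s': origin (%s) mm, normal (%s), extent %s mm, %d sample points\n",
              x$name, paste(signif(x$origin, 4), collapse = ", "),
              paste(signif(x$normal, 3), collapse = ", "),
              paste(signif(x$extent, 3), collapse = " x "),
              nrow(x$sample_points)))
  invisible(x)
}

#' An atlas of the great thoracic vessels
#'
#' Reference PC-MRA, per-vessel integer label masks and named analysis
#' planes. The atlas is built once (see [build_atlas()]) and reused for any
#' number of subjects.
#'
#' @param pcmra non-negative 3D array.
#' @param labels integer 3D array, 0 background, one positive code per
#'   vessel.
#' @param vessel_names named character vector mapping code (as name) to
#'   vessel name.
#' @param planes list of [flow_plane()] objects with unique names.
#' @param meta an [acquisition_meta()] describing the spatial grid.
#' @return Object of class `flow_atlas`.
#' @export
flow_atlas <- function(pcmra, labels, vessel_names, planes, meta) {
  if (!identical(dim(pcmra), dim(labels))) stop("pcmra and labels must share one grid")
  if (any(pcmra < 0)) stop("pcmra must be non-negative")
  codes <- sort(setdiff(unique(as.vector(labels)), 0L))
  if (length(codes) && !all(as.character(codes) %in% names(vessel_names)))
    stop("every nonzero label code needs an entry in vessel_names")
  nms <- vapply(planes, function(p) p$name, "")
  if (anyDuplicated(nms)) stop("plane names must be unique")
  if (is.null(meta$dim)) meta$dim <- dim(pcmra)
  structure(list(pcmra = pcmra, labels = labels,
                 vessel_names = vessel_names, planes = planes, meta = meta),
            class = "flow_atlas")
}

#' @export
print.flow_atlas <- function(x, ...) {
  d <- dim(x$pcmra)
  cat(sprintf("flow_atlas: %d x %d x %d, vessels: %s; planes: %s\n",
              d[1], d[2], d[3],
              paste(x$vessel_names, collapse = ", "),
              paste(vapply(x$planes, function(p) p$name, ""), collapse = ", ")))
  invisible(x)
}
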