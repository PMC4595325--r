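# Readers/writers. Volumes go through NIfTI (one file per component plus a
# JSON sidecar with acquisition metadata); atlases add a label volume and
# plane definitions in the sidecar. The sidecar is authoritative for
# geometry; NIfTI pixdim is written for interoperability.

#' Convert phase values to velocity
#'
#' Standard phase-contrast MRI convention: a phase of +/- pi maps to the
#' velocity-encoding limit +/- VENC.
#'
#' @param phase phase in radians (typically in `[-pi, pi]`).
#' @param venc velocity encoding limit in cm/s (> 0).
#' @return velocity in cm/s, `phase/pi * venc`.
#' @export
phase_to_velocity <- function(phase, venc) {
  if (!is.finite(venc) || venc <= 0) stop("venc must be > 0")
  phase / pi * venc
}

meta_to_list <- function(meta) {
  list(voxel_size = meta$voxel_size,
       frame_duration = meta$frame_duration,
       n_frames = meta$n_frames,
       venc = meta$venc,
       dim = meta$dim,
       grid_to_world = as.vector(meta$grid_to_world))
}

meta_from_list <- function(x) {
  acquisition_meta(x$voxel_size, x$frame_duration, x$n_frames, x$venc,
                   dim = x$dim,
                   grid_to_world = matrix(unlist(x$grid_to_world), 4L, 4L))
}

write_nifti_vol <- function(arr, path, voxel_size) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(voxel_size, rep(1, length(dim(arr)) - 3L))
  RNifti::writeNifti(img, path)
}

#' Save / load a 4D flow dataset
#'
#' On disk a dataset is a directory of four NIfTI volumes (`mag`, `vx`,
#' `vy`, `vz`) plus `meta.json`. [load_flow4d()] also accepts a single 5D
#' NIfTI container whose 5th axis is (magnitude, vx, vy, vz).
#'
#' @param flow a [flow4d()] object.
#' @param dir directory to write into (created if missing).
#' @return `save_flow4d` returns `dir` invisibly; `load_flow4d` returns a
#'   [flow4d()].
#' @export
save_flow4d <- function(flow, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vs <- flow$meta$voxel_size
  write_nifti_vol(flow$magnitude, file.path(dir, "mag.nii.gz"), vs)
  write_nifti_vol(flow$vx, file.path(dir, "vx.nii.gz"), vs)
  write_nifti_vol(flow$vy, file.path(dir, "vy.nii.gz"), vs)
  write_nifti_vol(flow$vz, file.path(dir, "vz.nii.gz"), vs)
  jsonlite::write_json(meta_to_list(flow$meta), file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname save_flow4d
#' @param path directory written by [save_flow4d()], a named list/vector
#'   with entries `magnitude`, `vx`, `vy`, `vz`, `meta`, or a single 5D
#'   NIfTI file (then `meta` must be supplied or a sidecar
#'   `<file>.json` must exist).
#' @param dialect `"cms"` when the component files already hold cm/s;
#'   `"phase"` when they hold phase in radians, converted at ingest via
#'   [phase_to_velocity()] with the sidecar VENC.
#' @param meta optional [acquisition_meta()] overriding the sidecar.
#' @export
load_flow4d <- function(path, dialect = c("cms", "phase"), meta = NULL) {
  dialect <- match.arg(dialect)
  read_arr <- function(f) {
    if (!file.exists(f)) stop("missing file: ", f)
    a <- RNifti::readNifti(f)
    array(as.numeric(a), dim(a))
  }
  if (length(path) == 1L && !is.list(path) && dir.exists(path)) {
    path <- c(magnitude = file.path(path, "mag.nii.gz"),
              vx = file.path(path, "vx.nii.gz"),
              vy = file.path(path, "vy.nii.gz"),
              vz = file.path(path, "vz.nii.gz"),
              meta = file.path(path, "meta.json"))
  }
  if (length(path) == 1L && !is.list(path)) {
    # 5D container: x,y,z,t,component with components (M, vx, vy, vz)
    a <- read_arr(path)
    if (length(dim(a)) != 5L || dim(a)[5] != 4L)
      stop("single-file input must be 5D with 4 components")
    if (is.null(meta)) {
      side <- sub("\\.nii(\\.gz)?$", ".json", path)
      if (!file.exists(side)) stop("missing metadata for 5D container")
      meta <- meta_from_list(jsonlite::read_json(side, simplifyVector = TRUE))
    }
    vols <- lapply(1:4, function(c5) array(a[, , , , c5], dim(a)[1:4]))
  } else {
    path <- as.list(path)
    vols <- lapply(path[c("magnitude", "vx", "vy", "vz")], function(f) read_arr(f))
    if (is.null(meta)) {
      if (is.null(path$meta) || !file.exists(path$meta)) stop("missing file: meta.json")
      meta <- meta_from_list(jsonlite::read_json(path$meta, simplifyVector = TRUE))
    }
    d <- dim(vols[[1]])
    for (i in 2:4)
      if (!identical(dim(vols[[i]]), d)) stop("grid mismatch between component files")
  }
  if (dialect == "phase") {
    if (is.null(meta$venc) || !is.finite(meta$venc)) stop("phase-scaled input requires venc")
    vols[2:4] <- lapply(vols[2:4], phase_to_velocity, venc = meta$venc)
  }
  flow4d(vols[[1]], vols[[2]], vols[[3]], vols[[4]], meta)
}

plane_to_list <- function(p) {
  list(name = p$name, origin = p$origin, normal = p$normal,
       in_plane_axes = as.vector(t(p$in_plane_axes)), extent = p$extent,
       sample_points = as.vector(t(p$sample_points)),
       vessel_code = p$vessel_code)
}

plane_from_list <- function(x) {
  flow_plane(x$name, unlist(x$origin), unlist(x$normal),
             in_plane_axes = matrix(unlist(x$in_plane_axes), ncol = 3L, byrow = TRUE),
             extent = unlist(x$extent),
             sample_points = matrix(unlist(x$sample_points), ncol = 3L, byrow = TRUE),
             vessel_code = if (is.null(x$vessel_code)) NA_integer_ else x$vessel_code)
}

#' Save / load a vessel atlas
#'
#' An atlas directory holds `pcmra.nii.gz`, `labels.nii.gz` and
#' `atlas.json` (grid metadata, vessel names, plane definitions). Loading
#' validates plane geometry; non-unit normals are rejected.
#'
#' @param atlas a [flow_atlas()].
#' @param dir directory to write / read.
#' @return `save_atlas` returns `dir` invisibly; `load_atlas` a
#'   [flow_atlas()].
#' @export
save_atlas <- function(atlas, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vs <- atlas$meta$voxel_size
  write_nifti_vol(atlas$pcmra, file.path(dir, "pcmra.nii.gz"), vs)
  write_nifti_vol(atlas$labels, file.path(dir, "labels.nii.gz"), vs)
  side <- list(meta = meta_to_list(atlas$meta),
               vessel_names = as.list(atlas$vessel_names),
               planes = lapply(atlas$planes, plane_to_list))
  jsonlite::write_json(side, file.path(dir, "atlas.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname save_atlas
#' @export
load_atlas <- function(dir) {
  side <- jsonlite::read_json(file.path(dir, "atlas.json"), simplifyVector = FALSE)
  meta <- meta_from_list(lapply(side$meta, function(x) unlist(x)))
  pc <- RNifti::readNifti(file.path(dir, "pcmra.nii.gz"))
  lb <- RNifti::readNifti(file.path(dir, "labels.nii.gz"))
  pcmra <- array(as.numeric(pc), dim(pc))
  labels <- array(as.integer(round(as.numeric(lb))), dim(lb))
  vn <- unlist(side$vessel_names)
  planes <- lapply(side$planes, plane_from_list)
  flow_atlas(pcmra, labels, vn, planes, meta)
}

#' Write a per-frame flow-rate table to CSV
#'
#' One row per (plane, frame) with the signed volumetric flow rate, plus
#' the per-plane net volume repeated for convenience.
#'
#' @param results list of flow-result lists as returned by
#'   [quantify_plane_flow()].
#' @param path CSV file path.
#' @return the data frame written, invisibly.
#' @export
write_flow_csv <- function(results, path) {
  rows <- do.call(rbind, lapply(results, function(r) {
    data.frame(plane = r$plane_name, vessel_code = r$vessel_code,
               frame = seq_along(r$flow_rate),
               flow_rate_ml_s = r$flow_rate,
               net_volume_ml = r$net_volume)
  }))
  if (is.null(rows)) rows <- data.frame(plane = character(), vessel_code = integer(),
                                        frame = integer(), flow_rate_ml_s = numeric(),
                                        net_volume_ml = numeric())
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(rows)
}
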