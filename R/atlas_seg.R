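# Atlas construction, atlas-to-subject fitting, and temporal propagation
# to a full 4D segmentation.
#
# Fitting registers the atlas PC-MRA onto the subject PC-MRA (affine, then
# Morphon non-rigid at 3 scales x 5 iterations) and transfers the vessel
# labels and analysis planes through the composed transform. Temporal
# propagation then registers the peak-systolic magnitude frame to every
# other frame independently (5 scales x 5 iterations, structure-tensor
# edge representation) -- independent rather than chained, so per-frame
# registration errors do not accumulate around the cycle.

#' Build an atlas by thresholding a PC-MRA
#'
#' A rough vessel segmentation is obtained by thresholding the PC-MRA at a
#' fraction of its maximum; connected components become vessels, labelled
#' by decreasing size (or by seed points). Intended for phantom data,
#' where thresholding is exact; clinical atlases are refined manually.
#'
#' @param flow a [flow4d()].
#' @param threshold_frac foreground threshold as a fraction of the PC-MRA
#'   maximum (default 0.3).
#' @param planes list of [flow_plane()] to attach verbatim.
#' @param vessel_names optional named character vector code -> name;
#'   defaults to `vessel1`, `vessel2`, ...
#' @param seeds optional named list code -> mm 3-vector; the component
#'   containing each seed receives that code.
#' @param labels optional ready-made integer label volume bypassing the
#'   threshold path (e.g. phantom ground truth).
#' @param systolic_frac passed to [select_frames()].
#' @return a [flow_atlas()].
#' @export
build_atlas <- function(flow, threshold_frac = 0.3, planes = list(),
                        vessel_names = NULL, seeds = NULL, labels = NULL,
                        systolic_frac = 0.7) {
  sel <- select_frames(frame_signal_curve(flow), systolic_frac)
  pcmra <- compute_pcmra(flow, sel$systolic_set)
  if (is.null(labels)) {
    fg <- pcmra >= threshold_frac * max(pcmra)
    if (!any(fg)) stop("empty foreground at this threshold")
    comp <- label_components(fg)
    if (!is.null(seeds)) {
      lab <- array(0L, dim(comp))
      for (code in names(seeds)) {
        vox <- round(world_to_voxel(flow$meta, matrix(unlist(seeds[[code]]), 1L)))
        cid <- comp[vox[1] + 1L, vox[2] + 1L, vox[3] + 1L]
        if (cid > 0L) lab[comp == cid] <- as.integer(code)
      }
      labels <- lab
    } else {
      labels <- comp
    }
  }
  codes <- sort(setdiff(unique(as.vector(labels)), 0L))
  if (is.null(vessel_names)) {
    vessel_names <- stats::setNames(paste0("vessel", codes), as.character(codes))
  }
  meta <- flow$meta
  meta$dim <- dim(pcmra)
  flow_atlas(pcmra, labels, vessel_names, planes, meta)
}

#' Structure-tensor edge map
#'
#' Frobenius norm of the local structure tensor (outer product of the
#' smoothed image gradient, Gaussian-averaged per tensor component). The
#' result depends on intensity only through gradients, so it is invariant
#' (up to a global a^2 scale) under affine intensity rescaling a*I + b --
#' the property that makes edge-based registration robust across frames
#' with differing signal levels.
#'
#' @param volume 3D array.
#' @param sigma_grad Gaussian sigma (voxels) before differentiation.
#' @param sigma_tensor Gaussian sigma (voxels) for tensor averaging.
#' @return non-negative 3D array.
#' @export
edge_map <- function(volume, sigma_grad = 1.0, sigma_tensor = 1.5) {
  g <- gradient3(gauss_smooth3(volume, sigma_grad))
  t11 <- gauss_smooth3(g[[1]] * g[[1]], sigma_tensor)
  t22 <- gauss_smooth3(g[[2]] * g[[2]], sigma_tensor)
  t33 <- gauss_smooth3(g[[3]] * g[[3]], sigma_tensor)
  t12 <- gauss_smooth3(g[[1]] * g[[2]], sigma_tensor)
  t13 <- gauss_smooth3(g[[1]] * g[[3]], sigma_tensor)
  t23 <- gauss_smooth3(g[[2]] * g[[3]], sigma_tensor)
  sqrt(t11^2 + t22^2 + t33^2 + 2 * (t12^2 + t13^2 + t23^2))
}

#' Fit an atlas to a subject PC-MRA
#'
#' Affine registration followed by Morphon non-rigid registration of the
#' atlas PC-MRA onto the subject PC-MRA; labels are transferred by
#' mask-mode warping through the composed transform and each plane's
#' sample points are pushed forward with [map_points()]. A fit whose final
#' objective is no better than the identity, or whose residual similarity
#' is below `min_ncc`, raises an "unreliable registration" error (the
#' failure mode seen when cardiovascular morphology differs too much from
#' the atlas).
#'
#' @param atlas a [flow_atlas()].
#' @param subject_pcmra 3D array on the subject grid.
#' @param params a [reg_params()]; default 3 scales, 5 iterations.
#' @param subject_meta [acquisition_meta()] of the subject grid (default:
#'   atlas grid).
#' @param min_ncc minimum acceptable normalized correlation between the
#'   warped atlas and the subject (default 0.25).
#' @return list with `fitted_labels`, `affine`, `field`, `planes`
#'   (deformed sample points per plane, names preserved), `diagnostics`.
#' @export
fit_atlas <- function(atlas, subject_pcmra, params = reg_params(3L, 5L),
                      subject_meta = NULL, min_ncc = 0.25) {
  if (!any(atlas$pcmra > 0) || !any(subject_pcmra > 0))
    stop("empty PC-MRA")
  if (is.null(subject_meta)) subject_meta <- atlas$meta
  subject_meta$dim <- dim(subject_pcmra)

  aff <- register_affine(atlas$pcmra, subject_pcmra, params,
                         source_meta = atlas$meta, target_meta = subject_meta)
  # resample atlas onto the subject grid through the affine, then refine
  atlas_in_subj <- warp_image(atlas$pcmra, affine = aff,
                              image_meta = atlas$meta, out_meta = subject_meta)
  field <- register_morphon(atlas_in_subj, subject_pcmra, params,
                            meta = subject_meta)

  obj_fin <- attr(field, "objective")
  ncc_fin <- 1 - obj_fin
  obj_id_chain <- tryCatch(1 - ncc(warp_image(atlas$pcmra, image_meta = atlas$meta,
                                              out_meta = subject_meta),
                                   subject_pcmra),
                           error = function(e) Inf)
  if ((obj_id_chain > 0.05 && obj_fin >= obj_id_chain) || ncc_fin < min_ncc)
    stop("unreliable registration: subject morphology differs too much from the atlas")

  fitted <- warp_labels(atlas$labels, affine = aff, field = field,
                        image_meta = atlas$meta, out_meta = subject_meta)
  inv <- invert_field(field, tol = 0.05)
  planes <- lapply(atlas$planes, function(p) {
    mp <- map_points(p$sample_points, affine = aff, inverse_field = inv)
    list(name = p$name, points = mp, ref_normal = p$normal,
         vessel_code = p$vessel_code, oob = attr(mp, "oob"))
  })
  names(planes) <- vapply(atlas$planes, function(p) p$name, "")
  list(fitted_labels = fitted, affine = aff, field = field, planes = planes,
       diagnostics = list(objective = obj_fin,
                          objective_identity = obj_id_chain,
                          ncc = ncc_fin,
                          affine_objective = attr(aff, "objective"),
                          inverse_residual = attr(inv, "residual")))
}

#' Propagate a fitted segmentation over the cardiac cycle
#'
#' For every frame t != peak_frame, registers the structure-tensor edge
#' map of the peak-frame magnitude to that of frame t (5 scales, 5
#' iterations by default) and warps the fitted labels through the field.
#' Frames are registered independently from the peak frame, never chained.
#' A frame whose registration diverges is flagged and filled with the
#' nearest successful frame's labels.
#'
#' @param flow a [flow4d()].
#' @param fitted_labels integer 3D label volume on the flow grid.
#' @param peak_frame 1-based systolic peak frame.
#' @param params a [reg_params()]; default 5 scales, 5 iterations with the
#'   edge representation.
#' @return a [segmentation4d()]; attribute `diagnostics` holds a
#'   data.frame (frame, objective, objective_identity, max_d_mm,
#'   min_jacobian, diverged).
#' @export
propagate_temporal <- function(flow, fitted_labels, peak_frame,
                               params = reg_params(5L, 5L,
                                                   use_edge_representation = TRUE)) {
  d <- dim(flow$magnitude)
  nt <- d[4]
  peak_frame <- as.integer(peak_frame)
  if (peak_frame < 1L || peak_frame > nt) stop("peak_frame out of range")
  if (!identical(dim(fitted_labels), d[1:3])) stop("fitted_labels not on the flow grid")

  meta <- flow$meta
  meta$dim <- d[1:3]
  src <- flow$magnitude[, , , peak_frame]
  labs <- array(0L, d)
  labs[, , , peak_frame] <- fitted_labels
  diag_rows <- vector("list", nt)
  ok <- rep(FALSE, nt); ok[peak_frame] <- TRUE

  for (t in seq_len(nt)) {
    if (t == peak_frame) {
      diag_rows[[t]] <- data.frame(frame = t, objective = NA_real_,
                                   objective_identity = NA_real_,
                                   max_d_mm = 0, min_jacobian = 1, diverged = FALSE)
      next
    }
    tgt <- flow$magnitude[, , , t]
    field <- register_morphon(src, tgt, params, meta = meta)
    obj <- attr(field, "objective"); obj_id <- attr(field, "objective_identity")
    jmin <- min(interior(jacobian_determinant(field)))
    dmax <- max(sqrt(field$d[, , , 1]^2 + field$d[, , , 2]^2 + field$d[, , , 3]^2))
    diverged <- obj >= obj_id && obj_id > 1e-6
    if (!diverged) {
      labs[, , , t] <- warp_labels(fitted_labels, field = field,
                                   image_meta = meta)
      ok[t] <- TRUE
    } else {
      warning(sprintf("frame %d: registration diverged; filling from nearest frame", t))
    }
    diag_rows[[t]] <- data.frame(frame = t, objective = obj,
                                 objective_identity = obj_id,
                                 max_d_mm = dmax, min_jacobian = jmin,
                                 diverged = diverged)
  }
  if (!all(ok)) {
    good <- which(ok)
    for (t in which(!ok)) {
      nearest <- good[which.min(abs(good - t))]
      labs[, , , t] <- labs[, , , nearest]
    }
  }
  out <- segmentation4d(labs, peak_frame)
  attr(out, "diagnostics") <- do.call(rbind, diag_rows)
  out
}
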