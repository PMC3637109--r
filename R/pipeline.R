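# in-plane (4-neighbour) erosion by one voxel, slice-wise
#' @keywords internal
#' @noRd
erode_inplane <- function(mask) {
  out <- array(FALSE, dim = dim(mask))
  for (k in seq_len(dim(mask)[3])) {
    sl <- mask[, , k]
    if (any(sl)) out[, , k] <- sl & !boundary2d(sl)
  }
  out
}

#' Run the full BML segmentation pipeline on one scan
#'
#' Executes the three stages for each bone with marked contours:
#' \enumerate{
#'   \item bone segmentation (contour rasterization, edge-based refinement,
#'     articular-surface tagging), followed by exclusion of the central
#'     sagittal slices;
#'   \item two-pass FDR-thresholded region-based BML candidate segmentation
#'     inside the bone (the bone domain is eroded by one in-plane voxel to
#'     guard against boundary halo voxels of bright soft tissue);
#'   \item 3D component formation, false-positive filtering (articular
#'     distance, slice span), medial/lateral region assignment and
#'     volumetry.
#' }
#' The pipeline is deterministic given identical inputs and parameters.
#'
#' @param vol a \code{\link{bml_volume}}.
#' @param contours a named list of \code{\link{bml_contours}} (any subset
#'   of \code{femur}, \code{tibia}), or a single contour set.
#' @param params a \code{\link{bml_params}}.
#' @return Object of class \code{bml_run}: list with \code{report}
#'   (\code{\link{bml_report}}), \code{bones}, \code{candidates},
#'   \code{components} (retained, region-assigned), \code{final_mask}
#'   (component-labelled integer array) and \code{manifest}.
#' @export
run_segmentation <- function(vol, contours, params = bml_params()) {
  stopifnot(inherits(vol, "bml_volume"))
  if (inherits(contours, "bml_contours"))
    contours <- stats::setNames(list(contours), contours$bone)
  if (length(contours) < 1L) stop("contours required for at least one bone")
  t0 <- proc.time()[["elapsed"]]
  timings <- list()
  divider <- params$divider_slice
  bones <- list()
  candidates <- list()
  comp_list <- list()
  for (bn in names(contours)) {
    ct <- contours[[bn]]
    if (is.null(divider)) divider <- ct$divider_slice
    t1 <- proc.time()[["elapsed"]]
    bone <- tryCatch(segment_bone(vol, ct, params), error = function(e)
      stop("bone segmentation (", bn, "): ", conditionMessage(e)))
    bone$mask <- exclude_central_slices(bone$mask, params$n_central_excluded)
    bone$articular <- exclude_central_slices(bone$articular,
                                             params$n_central_excluded)
    bones[[bn]] <- bone
    t2 <- proc.time()[["elapsed"]]
    domain <- erode_inplane(bone$mask)
    cand <- tryCatch(two_pass_segment(vol, structure(
      list(bone = bn, mask = domain, articular = bone$articular,
           spacing = vol$spacing), class = "bml_bone_mask"), params),
      error = function(e)
        stop("BML segmentation (", bn, "): ", conditionMessage(e)))
    candidates[[bn]] <- cand
    t3 <- proc.time()[["elapsed"]]
    comp <- component_table(cand, bone, spacing = vol$spacing,
                            connectivity = params$connectivity)
    comp <- apply_filters(comp, params)
    if (nrow(comp) > 0) {
      comp$bone <- bn
      comp$region <- assign_region(comp$centroid_z, bn,
                                   divider_for(divider, dim(vol$voxels)[3]),
                                   params$medial_is_high)
    }
    comp_list[[bn]] <- comp
    timings[[bn]] <- c(bone_s = t2 - t1, bml_s = t3 - t2,
                       quant_s = proc.time()[["elapsed"]] - t3)
  }
  components <- combine_components(comp_list)
  report <- quantify(components, vol$spacing)
  final_mask <- array(0L, dim = dim(vol$voxels))
  vox <- attr(components, "voxels")
  for (i in seq_along(vox)) final_mask[vox[[i]]] <- i
  manifest <- list(
    params = unclass(params),
    divider_slice = divider_for(divider, dim(vol$voxels)[3]),
    bones = names(contours),
    timings = timings,
    total_s = proc.time()[["elapsed"]] - t0,
    version = as.character(packageVersion("bmlseg")))
  structure(list(report = report, bones = bones, candidates = candidates,
                 components = components, final_mask = final_mask,
                 manifest = manifest),
            class = "bml_run")
}

#' @keywords internal
#' @noRd
divider_for <- function(divider, n_slices) {
  if (is.null(divider)) floor(n_slices / 2) else divider
}

#' @keywords internal
#' @noRd
combine_components <- function(comp_list) {
  comp_list <- comp_list[vapply(comp_list, nrow, integer(1)) > 0]
  if (!length(comp_list)) {
    out <- data.frame(id = integer(0), n_voxels = integer(0),
                      volume_mm3 = numeric(0), slice_span = integer(0),
                      min_articular_dist_mm = numeric(0),
                      centroid_x = numeric(0), centroid_y = numeric(0),
                      centroid_z = numeric(0), pass = integer(0),
                      bone = character(0), region = character(0))
    attr(out, "voxels") <- list()
    return(out)
  }
  vox <- do.call(c, lapply(comp_list, attr, "voxels"))
  out <- do.call(rbind, comp_list)
  out$id <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "voxels") <- vox
  out
}

#' @export
print.bml_run <- function(x, ...) {
  cat(sprintf("<bml_run> bones: %s | %.1f s\n",
              paste(x$manifest$bones, collapse = ", "), x$manifest$total_s))
  print(x$report)
  invisible(x)
}

#' Run the pipeline on a longitudinal scan pair
#'
#' Segments baseline and follow-up independently with the same parameters
#' and reports the per-region volume change (follow-up minus baseline).
#' Both runs are deterministic, so identical inputs give exactly zero
#' change.
#'
#' @param baseline,followup lists with elements \code{volume}
#'   (\code{\link{bml_volume}}) and \code{contours} (as in
#'   \code{\link{run_segmentation}}).
#' @param params a \code{\link{bml_params}}.
#' @return list of class \code{bml_longitudinal}: \code{baseline},
#'   \code{followup} (both \code{bml_run}) and \code{change}
#'   (paired \code{\link{bml_report}}).
#' @export
run_longitudinal <- function(baseline, followup, params = bml_params()) {
  rb <- run_segmentation(baseline$volume, baseline$contours, params)
  rf <- run_segmentation(followup$volume, followup$contours, params)
  structure(list(baseline = rb, followup = rf,
                 change = volume_change(rb$report, rf$report)),
            class = "bml_longitudinal")
}

#' @export
print.bml_longitudinal <- function(x, ...) {
  cat("<bml_longitudinal>\n")
  print(x$change$regions, row.names = FALSE)
  invisible(x)
}
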