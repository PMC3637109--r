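#' Clear the central sagittal slices of a mask
#'
#' The central slices of the knee are excluded from analysis (unreliable
#' bone borders, increased marrow heterogeneity): voxels on the
#' \code{n_central} slices centered at \code{floor(n_slices / 2)} (0-based;
#' left-biased window when parities differ) are cleared.
#'
#' @param mask logical 3D array.
#' @param n_central number of slices to clear (default 9, i.e. 2.7 cm at
#'   3 mm slice thickness).
#' @return the mask with the central window cleared.
#' @export
exclude_central_slices <- function(mask, n_central = 9L) {
  n_central <- as.integer(n_central)
  n_slices <- dim(mask)[3]
  if (n_central > n_slices)
    stop("n_central (", n_central, ") exceeds slice count (", n_slices, ")")
  w <- central_window(n_slices, n_central)
  if (length(w)) mask[, , w + 1L] <- FALSE
  mask
}

# 0-based indices of the excluded central window
#' @keywords internal
#' @noRd
central_window <- function(n_slices, n_central) {
  if (n_central <= 0L) return(integer(0))
  c0 <- floor(n_slices / 2)
  start <- c0 - ceiling((n_central - 1) / 2)
  idx <- seq(start, start + n_central - 1L)
  idx[idx >= 0 & idx < n_slices]
}

#' 3D connected components of a binary mask
#'
#' Maximal connected voxel sets under 6- or 26-connectivity (default 26).
#'
#' @param mask logical 3D array.
#' @param connectivity 6 or 26.
#' @return list with integer \code{labels} array (0 = background),
#'   \code{n}, and \code{voxels}: a list of n matrices of 1-based voxel
#'   indices (i, j, k).
#' @export
connected_components_3d <- function(mask, connectivity = 26L) {
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 26L)) stop("`connectivity` must be 6 or 26")
  lab <- cpp_label3d(as.integer(mask), dim(mask), connectivity)
  lab <- array(lab, dim = dim(mask))
  n <- max(lab)
  vox <- if (n > 0)
    lapply(seq_len(n), function(l) which(lab == l, arr.ind = TRUE))
  else list()
  list(labels = lab, n = n, voxels = vox)
}

#' Minimum distance from a component to the articular surface
#'
#' Minimum over all (component voxel, surface voxel) pairs of the Euclidean
#' distance in world coordinates (anisotropic voxel spacing).
#'
#' @param component matrix of voxel indices (i, j, k), any consistent base.
#' @param surface matrix of articular-surface voxel indices (same base).
#' @param spacing voxel spacing (dx, dy, dz) in mm.
#' @return distance in mm.
#' @export
min_articular_distance <- function(component, surface, spacing) {
  component <- as.matrix(component)
  surface <- as.matrix(surface)
  if (nrow(surface) == 0L) stop("empty articular surface")
  if (nrow(component) == 0L) stop("empty component")
  cpp_min_dist_mm(component * 1.0, surface * 1.0, as.numeric(spacing))
}

#' Build the candidate-lesion component table for one bone
#'
#' Labels the candidate mask into 3D components and measures, per component:
#' voxel count, volume (voxel count x voxel volume), slice span (distinct
#' slice indices), minimum articular distance (mm) and centroid.
#'
#' @param candidates a \code{\link{two_pass_segment}} result or logical mask.
#' @param bone a \code{\link{bml_bone_mask}} providing the articular surface
#'   (or a logical 3D articular array via \code{articular}).
#' @param spacing voxel spacing in mm (taken from \code{bone} if available).
#' @param connectivity 6 or 26.
#' @param articular optional logical 3D articular-surface array overriding
#'   \code{bone$articular}.
#' @return data.frame with one row per component: \code{id},
#'   \code{n_voxels}, \code{volume_mm3}, \code{slice_span},
#'   \code{min_articular_dist_mm}, centroid columns and (when available)
#'   pass provenance; the voxel index matrices are attached as the
#'   \code{"voxels"} attribute.
#' @export
component_table <- function(candidates, bone = NULL, spacing = NULL,
                            connectivity = 26L, articular = NULL) {
  mask <- if (inherits(candidates, "bml_candidates")) candidates$mask
          else candidates
  pass <- if (inherits(candidates, "bml_candidates")) candidates$pass else NULL
  if (is.null(articular) && !is.null(bone)) articular <- bone$articular
  if (is.null(spacing)) {
    if (!is.null(bone) && !is.null(bone$spacing)) spacing <- bone$spacing
    else stop("`spacing` required")
  }
  if (is.null(articular) || !any(articular)) stop("empty articular surface")
  surf <- which(articular, arr.ind = TRUE)
  cc <- connected_components_3d(mask, connectivity)
  vvol <- prod(spacing)
  rows <- lapply(seq_len(cc$n), function(l) {
    v <- cc$voxels[[l]]
    data.frame(
      id = l,
      n_voxels = nrow(v),
      volume_mm3 = nrow(v) * vvol,
      slice_span = length(unique(v[, 3])),
      min_articular_dist_mm = min_articular_distance(v, surf, spacing),
      centroid_x = mean(v[, 1]) - 1,
      centroid_y = mean(v[, 2]) - 1,
      centroid_z = mean(v[, 3]) - 1,
      pass = if (!is.null(pass)) min(pass[v]) else NA_integer_
    )
  })
  out <- if (length(rows)) do.call(rbind, rows)
  else data.frame(id = integer(0), n_voxels = integer(0),
                  volume_mm3 = numeric(0), slice_span = integer(0),
                  min_articular_dist_mm = numeric(0),
                  centroid_x = numeric(0), centroid_y = numeric(0),
                  centroid_z = numeric(0), pass = integer(0))
  attr(out, "voxels") <- cc$voxels
  out
}

#' Remove false-positive candidate lesions
#'
#' Keeps a component iff (1) its minimum distance to the articular surface
#' is at most \code{max_articular_dist_mm} (default 10 mm) and (2) it spans
#' at least \code{min_slice_span} distinct slices (default 2, i.e. more than
#' one MR image). Idempotent and order-independent.
#'
#' @param components a \code{\link{component_table}} data.frame.
#' @param params a \code{\link{bml_params}} (or a list with the two fields).
#' @return the retained rows (with their \code{"voxels"} attribute subset).
#' @export
apply_filters <- function(components, params = bml_params()) {
  keep <- components$min_articular_dist_mm <= params$max_articular_dist_mm &
    components$slice_span >= params$min_slice_span
  out <- components[keep, , drop = FALSE]
  vox <- attr(components, "voxels")
  if (!is.null(vox)) attr(out, "voxels") <- vox[keep]
  out
}

#' Assign a component to a tibiofemoral region
#'
#' Medial versus lateral is decided by the component centroid's slice index
#' relative to a sagittal divider slice; no anatomical compartment boundary
#' is derivable from the image alone, so the divider is configurable,
#' defaulting to the slice through the tibial-spine midpoint when the
#' contour file supplies it. Centroids exactly on the divider are medial.
#'
#' @param centroid_z centroid slice index (0-based, continuous).
#' @param bone \code{"femur"} or \code{"tibia"}.
#' @param divider divider slice index (0-based).
#' @param medial_is_high if TRUE, slices at or above the divider are medial.
#' @return one of \code{"medial femur"}, \code{"lateral femur"},
#'   \code{"medial tibia"}, \code{"lateral tibia"}.
#' @export
assign_region <- function(centroid_z, bone, divider,
                          medial_is_high = TRUE) {
  bone <- match.arg(bone, c("femur", "tibia"))
  medial <- if (medial_is_high) centroid_z >= divider else centroid_z <= divider
  paste(ifelse(medial, "medial", "lateral"), bone)
}

#' Regional BML volume report
#'
#' Assembles filtered, region-assigned components into per-region totals for
#' the four tibiofemoral regions. Component volume is voxel count times
#' voxel volume; region totals are exact sums of member components.
#'
#' @param components data.frame with at least \code{bone}, \code{region} and
#'   \code{volume_mm3} columns (e.g. filtered \code{\link{component_table}}
#'   rows with \code{bone} and \code{region} added).
#' @param spacing voxel spacing in mm (recorded in the report).
#' @return Object of class \code{bml_report}: list with \code{regions}
#'   data.frame (bone, region, n_components, volume_mm3 for all four
#'   regions) and the per-component \code{components} data.frame.
#' @export
quantify <- function(components, spacing) {
  regions <- data.frame(
    bone = c("femur", "femur", "tibia", "tibia"),
    region = c("medial femur", "lateral femur", "medial tibia",
               "lateral tibia"),
    stringsAsFactors = FALSE)
  regions$n_components <- vapply(regions$region, function(r)
    sum(components$region == r), integer(1))
  regions$volume_mm3 <- vapply(regions$region, function(r)
    sum(components$volume_mm3[components$region == r]), numeric(1))
  rownames(regions) <- NULL
  structure(list(regions = regions, components = components,
                 spacing = spacing),
            class = "bml_report")
}

#' @export
print.bml_report <- function(x, ...) {
  cat("<bml_report>\n")
  print(x$regions, row.names = FALSE)
  cat(sprintf("  total BML volume: %.2f mm3 (%d component(s))\n",
              sum(x$regions$volume_mm3), nrow(x$components)))
  invisible(x)
}

#' Paired (longitudinal) volume change
#'
#' Per-region change = follow-up minus baseline.
#'
#' @param baseline,followup \code{\link{bml_report}} objects over the same
#'   region set.
#' @return a \code{bml_report} whose \code{regions} carry both time points'
#'   volumes and a \code{change_mm3} column.
#' @export
volume_change <- function(baseline, followup) {
  b <- baseline$regions
  f <- followup$regions
  if (!identical(b$region, f$region))
    stop("mismatched region sets between baseline and follow-up")
  regions <- data.frame(
    bone = b$bone, region = b$region,
    n_components = f$n_components,
    baseline_mm3 = b$volume_mm3,
    followup_mm3 = f$volume_mm3,
    volume_mm3 = f$volume_mm3,
    change_mm3 = f$volume_mm3 - b$volume_mm3,
    stringsAsFactors = FALSE)
  structure(list(regions = regions, components = followup$components,
                 spacing = followup$spacing),
            class = "bml_report")
}

#' Write a volume report to CSV
#'
#' One row per region: \code{bone}, \code{region}, \code{n_components},
#' \code{volume_mm3}, plus \code{change_mm3} (and both time points) for
#' paired reports.
#'
#' @param report a \code{\link{bml_report}}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_report <- function(report, path) {
  cols <- c("bone", "region", "n_components", "volume_mm3",
            intersect(c("baseline_mm3", "followup_mm3", "change_mm3"),
                      names(report$regions)))
  write.csv(report$regions[, cols, drop = FALSE], path, row.names = FALSE)
  invisible(path)
}
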