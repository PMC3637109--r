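#' Segmentation parameters
#'
#' All tunables of the pipeline, with the defaults used throughout:
#' FDR level \code{q = 0.05} and length penalty \code{mu = 0.28} for BML
#' segmentation, a 10 mm articular-distance cutoff, a minimum lesion span
#' of 2 slices, exclusion of the 9 central slices (2.7 cm at 3 mm slice
#' thickness), and 26-connectivity for 3D components.
#'
#' @param q FDR level in (0, 1). Larger q lowers the intensity threshold and
#'   admits more voxels as BML candidates.
#' @param mu length-penalty weight in [0, 1] for region-based evolution
#'   (intensities are rescaled to [0, 1] inside the bone so mu is
#'   dimensionless). Larger mu smooths boundaries and suppresses isolated
#'   bright specks.
#' @param max_articular_dist_mm retain a lesion only if its minimum 3D
#'   distance to the articular surface is at most this (mm).
#' @param min_slice_span retain a lesion only if it spans at least this many
#'   distinct slices.
#' @param n_central_excluded number of central sagittal slices removed from
#'   the analysis.
#' @param connectivity 6 or 26; 3D neighbourhood for connected components.
#' @param max_iters,convergence_tol,smoothing curve-evolution controls:
#'   iteration cap, fractional mask-change tolerance, and curvature-smoothing
#'   passes per iteration.
#' @param smoothing_sigma edge-map Gaussian scale in mm.
#' @param divider_slice optional 0-based medial/lateral divider slice;
#'   \code{NULL} defers to the contour file or the volume midpoint.
#' @param medial_is_high if \code{TRUE}, slices at or above the divider are
#'   medial (ties are medial by convention).
#' @return An object of class \code{bml_params}.
#' @export
bml_params <- function(q = 0.05, mu = 0.28, max_articular_dist_mm = 10,
                       min_slice_span = 2L, n_central_excluded = 9L,
                       connectivity = 26L, max_iters = 500L,
                       convergence_tol = 0.001, smoothing = 1L,
                       smoothing_sigma = 1.0, divider_slice = NULL,
                       medial_is_high = TRUE) {
  if (!is.numeric(q) || length(q) != 1L || q <= 0 || q >= 1)
    stop("`q` must be a single value in (0, 1)")
  if (!is.numeric(mu) || length(mu) != 1L || mu < 0 || mu > 1)
    stop("`mu` must be in [0, 1]")
  if (max_articular_dist_mm <= 0) stop("`max_articular_dist_mm` must be > 0")
  min_slice_span <- as.integer(min_slice_span)
  if (min_slice_span < 1L) stop("`min_slice_span` must be a positive integer")
  n_central_excluded <- as.integer(n_central_excluded)
  if (n_central_excluded < 0L) stop("`n_central_excluded` must be >= 0")
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 26L)) stop("`connectivity` must be 6 or 26")
  if (max_iters < 1L) stop("`max_iters` must be >= 1")
  if (convergence_tol <= 0) stop("`convergence_tol` must be > 0")
  if (smoothing_sigma <= 0) stop("`smoothing_sigma` must be > 0 (mm)")
  structure(list(
    q = q, mu = mu, max_articular_dist_mm = max_articular_dist_mm,
    min_slice_span = min_slice_span, n_central_excluded = n_central_excluded,
    connectivity = connectivity,
    evolution = list(max_iters = as.integer(max_iters),
                     convergence_tol = convergence_tol,
                     smoothing = as.integer(smoothing),
                     smoothing_sigma = smoothing_sigma),
    divider_slice = divider_slice, medial_is_high = isTRUE(medial_is_high)
  ), class = "bml_params")
}

#' @export
print.bml_params <- function(x, ...) {
  cat(sprintf(paste0(
    "<bml_params> q = %g, mu = %g, max articular dist = %g mm,\n",
    "  min slice span = %d, central slices excluded = %d, ",
    "connectivity = %d\n"),
    x$q, x$mu, x$max_articular_dist_mm, x$min_slice_span,
    x$n_central_excluded, x$connectivity))
  invisible(x)
}

#' Read segmentation parameters from a JSON config
#' @param path JSON file; fields matching \code{\link{bml_params}} arguments
#'   (evolution controls may be nested under \code{evolution}).
#' @return A \code{\link{bml_params}}.
#' @export
read_params <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  obj <- jsonlite::fromJSON(path)
  ev <- obj$evolution
  obj$evolution <- NULL
  args <- c(obj, ev)
  known <- names(formals(bml_params))
  do.call(bml_params, args[names(args) %in% known])
}

#' Write segmentation parameters to a JSON config
#' @param params a \code{\link{bml_params}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_params <- function(params, path) {
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
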