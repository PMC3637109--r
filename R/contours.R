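#' Construct a per-slice contour set for one bone
#'
#' Ordered manually marked boundary points, per sagittal slice, in continuous
#' 0-based voxel coordinates. Each point carries an articular flag marking
#' whether it lies on the joint-facing (articular) surface; flags propagate
#' to the refined bone boundary and anchor the articular-distance filter.
#'
#' @param bone \code{"femur"} or \code{"tibia"}.
#' @param slices named list keyed by 0-based slice index (as character);
#'   each element a data.frame with columns \code{x}, \code{y} (continuous
#'   0-based voxel coordinates, in marked order) and logical
#'   \code{articular}.
#' @param shape optional integer length-3 grid shape used for bounds checks.
#' @param divider_slice optional 0-based slice index of the medial/lateral
#'   divider (e.g. the slice through the tibial-spine midpoint).
#' @return An object of class \code{bml_contours}.
#' @export
bml_contours <- function(bone, slices, shape = NULL, divider_slice = NULL) {
  bone <- match.arg(bone, c("femur", "tibia"))
  if (length(slices) < 1L) stop("at least one marked slice is required")
  idx <- suppressWarnings(as.integer(names(slices)))
  if (anyNA(idx) || any(idx < 0))
    stop("slice keys must be non-negative 0-based integers")
  slices <- slices[order(idx)]
  for (nm in names(slices)) {
    pts <- slices[[nm]]
    if (!all(c("x", "y", "articular") %in% names(pts)))
      stop("slice ", nm, ": points need columns x, y, articular")
    if (nrow(pts) < 3L)
      stop("slice ", nm, ": ", nrow(pts),
           " point(s); at least 3 are required to close a contour")
    if (!any(pts$articular))
      stop("slice ", nm, ": no articular-flagged point")
    if (!is.null(shape)) {
      k <- as.integer(nm)
      if (k >= shape[3])
        stop("slice ", nm, " outside volume (", shape[3], " slices)")
      if (any(pts$x < 0 | pts$x > shape[1] - 1 |
              pts$y < 0 | pts$y > shape[2] - 1))
        stop("slice ", nm, ": point outside volume bounds")
    }
    slices[[nm]]$articular <- as.logical(pts$articular)
  }
  structure(list(bone = bone, slices = slices, shape = shape,
                 divider_slice = divider_slice),
            class = "bml_contours")
}

#' @export
print.bml_contours <- function(x, ...) {
  np <- vapply(x$slices, nrow, integer(1))
  cat(sprintf("<bml_contours> %s: %d marked slice(s), %d points total\n",
              x$bone, length(x$slices), sum(np)))
  invisible(x)
}

#' Slice indices (0-based) carrying marked points
#' @param contours a \code{\link{bml_contours}}.
#' @return integer vector of 0-based slice indices.
#' @export
marked_slices <- function(contours) as.integer(names(contours$slices))

#' Read marked bone-boundary points from JSON
#'
#' The file holds one bone's manual marking: \code{bone}, an optional grid
#' \code{shape}, an optional \code{divider_slice}, and \code{slices} mapping
#' 0-based slice index to a list of \code{[x, y, articular]} triples.
#'
#' @param path JSON file path.
#' @return A validated \code{\link{bml_contours}}.
#' @export
read_contours <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(obj$bone) || is.null(obj$slices))
    stop("contour JSON needs `bone` and `slices` fields: ", path)
  slices <- lapply(obj$slices, function(pl) {
    m <- do.call(rbind, lapply(pl, function(p) as.numeric(unlist(p))))
    if (is.null(m) || ncol(m) != 3L)
      stop("each point must be an [x, y, articular] triple in ", path)
    data.frame(x = m[, 1], y = m[, 2], articular = m[, 3] != 0)
  })
  shape <- if (!is.null(obj$shape)) as.integer(unlist(obj$shape)) else NULL
  div <- if (!is.null(obj$divider_slice)) as.numeric(obj$divider_slice) else NULL
  bml_contours(obj$bone, slices, shape = shape, divider_slice = div)
}

#' Write a contour set to JSON
#' @param contours a \code{\link{bml_contours}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_contours <- function(contours, path) {
  slices <- lapply(contours$slices, function(pts)
    lapply(seq_len(nrow(pts)), function(i)
      c(pts$x[i], pts$y[i], as.numeric(pts$articular[i]))))
  obj <- list(bone = contours$bone, slices = slices)
  if (!is.null(contours$shape)) obj$shape <- contours$shape
  if (!is.null(contours$divider_slice))
    obj$divider_slice <- contours$divider_slice
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
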