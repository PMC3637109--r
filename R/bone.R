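#' @keywords internal
#' @noRd
rescale01 <- function(x) {
  r <- range(x)
  if (r[2] > r[1]) (x - r[1]) / (r[2] - r[1]) else x * 0
}

# closed periodic spline through marked points, sampled densely.
# Returns a matrix (x, y) of n_out vertices (duplicate endpoint dropped).
#' @keywords internal
#' @noRd
sample_closed_spline <- function(x, y, n_out = NULL) {
  n <- length(x)
  if (is.null(n_out)) n_out <- max(120L, 20L * n)
  xs <- c(x, x[1])
  ys <- c(y, y[1])
  t <- c(0, cumsum(sqrt(diff(xs)^2 + diff(ys)^2)))
  if (t[n + 1] <= 0) stop("degenerate contour: all points coincide")
  tt <- seq(0, t[n + 1], length.out = n_out + 1L)[-(n_out + 1L)]
  sx <- spline(t, xs, method = "periodic", xout = tt)$y
  sy <- spline(t, ys, method = "periodic", xout = tt)$y
  cbind(sx, sy)
}

#' Rasterize marked contours into initial per-slice masks
#'
#' Fits a closed periodic spline through each slice's marked points (in
#' marked order), and fills its interior over the voxel grid (even-odd rule
#' on voxel centers). This is the coarse initialization that edge-based
#' refinement sharpens; it need not be adjacent to the true bone boundary.
#'
#' @param contours a \code{\link{bml_contours}}.
#' @param dim integer length-3 grid shape (nx, ny, nz).
#' @return logical 3D array; slices without marked points are all-FALSE.
#' @export
rasterize_initial_contour <- function(contours, dim) {
  stopifnot(length(dim) == 3L)
  out <- array(FALSE, dim = dim)
  for (nm in names(contours$slices)) {
    pts <- contours$slices[[nm]]
    if (nrow(pts) < 3L)
      stop("slice ", nm, ": need at least 3 points to close a contour")
    poly <- sample_closed_spline(pts$x, pts$y)
    if (cpp_self_intersects(poly[, 1], poly[, 2]))
      stop("slice ", nm, ": marked contour is self-intersecting")
    k <- as.integer(nm) + 1L
    out[, , k] <- cpp_polygon_fill(poly[, 1], poly[, 2], dim[1], dim[2])
  }
  out
}

#' Edge-stopping map for one slice
#'
#' Computes \code{g = 1 / (1 + |grad(G_sigma * I)|^2)} after rescaling the
#' slice to [0, 1]. \code{g} is 1 on flat regions and decreases toward 0 as
#' the smoothed gradient grows, so edge-based evolution halts on bone
#' boundaries. The gradient uses central differences (one-sided at borders)
#' divided by the physical in-plane spacing, and the Gaussian scale
#' \code{sigma} is in mm (converted per axis to pixels).
#'
#' @param slice numeric matrix (one sagittal slice).
#' @param sigma Gaussian smoothing scale in mm (> 0).
#' @param spacing in-plane spacing (dx, dy) in mm (a length-3 spacing is
#'   accepted; the slice spacing is ignored).
#' @return An object of class \code{bml_edge_map}: list with matrix \code{g}
#'   in (0, 1] and \code{sigma}.
#' @export
compute_edge_map <- function(slice, sigma = 1.0, spacing = c(1, 1)) {
  if (sigma <= 0) stop("`sigma` must be > 0")
  stopifnot(is.matrix(slice))
  sm <- cpp_gaussian_blur(rescale01(slice), sigma / spacing[1],
                          sigma / spacing[2])
  gx <- grad_axis(sm, 1L) / spacing[1]
  gy <- grad_axis(sm, 2L) / spacing[2]
  structure(list(g = 1 / (1 + gx^2 + gy^2), sigma = sigma),
            class = "bml_edge_map")
}

# central differences, one-sided at the borders, unit grid step
#' @keywords internal
#' @noRd
grad_axis <- function(m, axis) {
  n <- dim(m)[axis]
  g <- m * 0
  if (n < 2L) return(g)
  if (axis == 1L) {
    g[2:(n - 1), ] <- (m[3:n, , drop = FALSE] - m[1:(n - 2), , drop = FALSE]) / 2
    g[1, ] <- m[2, ] - m[1, ]
    g[n, ] <- m[n, ] - m[n - 1, ]
  } else {
    g[, 2:(n - 1)] <- (m[, 3:n, drop = FALSE] - m[, 1:(n - 2), drop = FALSE]) / 2
    g[, 1] <- m[, 2] - m[, 1]
    g[, n] <- m[, n] - m[, n - 1]
  }
  g
}

#' Refine initial bone contours by edge-based curve evolution
#'
#' Geodesic active-contour refinement, discretized with morphological
#' operators (curvature smoothing by alternating sup-inf/inf-sup filters,
#' advection of the contour along the gradient of the edge-stopping map g;
#' balloon force off). Evolution runs slice-wise in 2D; each refined slice
#' is reduced to the single connected region best overlapping its
#' initialization, with interior holes filled.
#'
#' @param init logical 3D array of initial per-slice masks (e.g. from
#'   \code{\link{rasterize_initial_contour}}).
#' @param edges list keyed by 0-based slice index of
#'   \code{\link{compute_edge_map}} results (or bare g matrices).
#' @param evolution list with \code{max_iters}, \code{convergence_tol}
#'   (fractional mask change; convergence requires 5 consecutive iterations
#'   below it) and \code{smoothing} passes per iteration.
#' @return logical 3D array of refined per-slice masks.
#' @export
evolve_bone_contour <- function(init, edges,
                                evolution = bml_params()$evolution) {
  stopifnot(is.array(init), length(dim(init)) == 3L)
  if (!any(init)) stop("initial mask is empty")
  out <- array(FALSE, dim = dim(init))
  for (k in seq_len(dim(init)[3])) {
    sl <- init[, , k]
    if (!any(sl)) next
    key <- as.character(k - 1L)
    em <- edges[[key]]
    if (is.null(em)) stop("no edge map provided for slice ", k - 1L)
    g <- if (inherits(em, "bml_edge_map")) em$g else em
    u0 <- matrix(as.integer(sl), nrow = nrow(sl))
    res <- cpp_morph_gac(u0, g, evolution$max_iters,
                         evolution$convergence_tol,
                         max(1L, evolution$smoothing))
    u <- res$u
    if (!any(u == 1L))
      stop("contour collapsed to empty on slice ", k - 1L)
    out[, , k] <- cpp_clean_slice(u, u0) == 1L
  }
  out
}

# in-plane (4-neighbour) boundary of a 2D mask, matrix-edge voxels included
#' @keywords internal
#' @noRd
boundary2d <- function(m) {
  nx <- nrow(m); ny <- ncol(m)
  pad <- matrix(FALSE, nx + 2L, ny + 2L)
  pad[2:(nx + 1L), 2:(ny + 1L)] <- m
  inner <- pad[2:(nx + 1L), 2:(ny + 1L)] &
    pad[1:nx, 2:(ny + 1L)] & pad[3:(nx + 2L), 2:(ny + 1L)] &
    pad[2:(nx + 1L), 1:ny] & pad[2:(nx + 1L), 3:(ny + 2L)]
  m & !inner
}

# distance from points (px, py) to segment (ax,ay)-(bx,by); all in mm
#' @keywords internal
#' @noRd
point_segment_dist <- function(px, py, ax, ay, bx, by) {
  vx <- bx - ax; vy <- by - ay
  L2 <- vx^2 + vy^2
  t <- if (L2 > 0) pmin(1, pmax(0, ((px - ax) * vx + (py - ay) * vy) / L2)) else 0
  sqrt((px - (ax + t * vx))^2 + (py - (ay + t * vy))^2)
}

#' Assemble a 3D bone mask with a tagged articular surface
#'
#' Stacks refined per-slice masks into a 3D bone mask and tags each in-plane
#' boundary voxel as articular when its nearest segment of the initial marked
#' contour (consecutive marked points, closed) joins two articular-flagged
#' points; distance ties break toward articular. Distances use physical
#' in-plane spacing.
#'
#' @param refined logical 3D array from \code{\link{evolve_bone_contour}}.
#' @param contours the \code{\link{bml_contours}} used for initialization.
#' @param spacing voxel spacing (dx, dy, dz) in mm.
#' @return An object of class \code{bml_bone_mask}: list with \code{bone},
#'   logical arrays \code{mask} and \code{articular}
#'   (articular is a subset of the mask's in-plane boundary), and
#'   \code{spacing}.
#' @export
build_bone_mask <- function(refined, contours, spacing = c(1, 1, 1)) {
  stopifnot(is.array(refined), length(dim(refined)) == 3L)
  if (!any(refined)) stop("empty refined stack")
  articular <- array(FALSE, dim = dim(refined))
  for (nm in names(contours$slices)) {
    k <- as.integer(nm) + 1L
    sl <- refined[, , k]
    if (!any(sl))
      stop("bone mask empty on marked slice ", nm)
    pts <- contours$slices[[nm]]
    n <- nrow(pts)
    nxt <- c(2:n, 1L)
    seg_art <- pts$articular & pts$articular[nxt]
    bd <- which(boundary2d(sl), arr.ind = TRUE)
    px <- (bd[, 1] - 1) * spacing[1]
    py <- (bd[, 2] - 1) * spacing[2]
    dmat <- vapply(seq_len(n), function(s)
      point_segment_dist(px, py,
                         pts$x[s] * spacing[1], pts$y[s] * spacing[2],
                         pts$x[nxt[s]] * spacing[1], pts$y[nxt[s]] * spacing[2]),
      numeric(length(px)))
    dmat <- matrix(dmat, nrow = length(px))
    dmin <- apply(dmat, 1L, min)
    # tie toward articular: voxel is articular if ANY articular segment
    # attains the minimum distance
    is_art <- vapply(seq_along(px), function(i)
      any(seg_art[dmat[i, ] <= dmin[i] + 1e-9]), logical(1))
    art_sl <- array(FALSE, dim = dim(sl))
    art_sl[bd[is_art, , drop = FALSE]] <- TRUE
    articular[, , k] <- art_sl
  }
  structure(list(bone = contours$bone, mask = refined,
                 articular = articular, spacing = spacing),
            class = "bml_bone_mask")
}

#' @export
print.bml_bone_mask <- function(x, ...) {
  cat(sprintf("<bml_bone_mask> %s: %d voxels, %d articular-surface voxels\n",
              x$bone, sum(x$mask), sum(x$articular)))
  invisible(x)
}

#' Segment one bone from a volume and its marked contours
#'
#' Convenience wrapper running rasterization, edge-map computation and
#' edge-based refinement for every marked slice, then assembling the tagged
#' 3D bone mask.
#'
#' @param vol a \code{\link{bml_volume}}.
#' @param contours a \code{\link{bml_contours}} for one bone.
#' @param params a \code{\link{bml_params}}.
#' @return A \code{\link{build_bone_mask}} result.
#' @export
segment_bone <- function(vol, contours, params = bml_params()) {
  d <- dim(vol$voxels)
  init <- rasterize_initial_contour(contours, d)
  edges <- list()
  for (nm in names(contours$slices)) {
    k <- as.integer(nm) + 1L
    edges[[nm]] <- compute_edge_map(vol$voxels[, , k],
                                    sigma = params$evolution$smoothing_sigma,
                                    spacing = vol$spacing)
  }
  refined <- evolve_bone_contour(init, edges, params$evolution)
  build_bone_mask(refined, contours, vol$spacing)
}
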