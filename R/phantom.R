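#' Phantom specification
#'
#' Describes a synthetic sagittal knee-like volume: two convex bone bodies
#' (femur above tibia across a joint gap, super-ellipsoids flattened along
#' z), piecewise-constant tissue intensities, planted ellipsoidal BMLs with
#' stated contrast, planted decoys exercising every false-positive rule
#' (a deep lesion > 10 mm from the articular surface, a single-slice
#' lesion, and an extra-osseous bright blob), plus Gaussian noise. The
#' default grid uses the acquisition geometry of the target MR protocol:
#' 0.357 x 0.511 mm in-plane resolution and 3 mm slice thickness.
#'
#' Blob \code{contrast} is in multiples of \code{intensity_unit}; the
#' default noise sd equals one unit, so contrast 5 means SNR 5.
#'
#' @param dim grid shape (nx, ny, nz).
#' @param spacing voxel spacing in mm.
#' @param soft_tissue,bone_intensity mean intensities of soft tissue and
#'   normal bone marrow (arbitrary units in [0, 1]).
#' @param intensity_unit intensity step corresponding to one contrast unit.
#' @param noise_sd Gaussian noise standard deviation (0 for noiseless).
#' @param rician if TRUE, apply Rician (magnitude) noise instead of
#'   additive Gaussian.
#' @param blobs data.frame of planted blobs (see default for columns:
#'   type, bone, center/radii in voxel units, contrast).
#' @param n_contour_points marked points per slice when simulating manual
#'   bone marking.
#' @param jitter contour-point jitter amplitude in voxels (emulates manual
#'   marking imprecision; the refinement step must tolerate it).
#' @param divider_slice 0-based medial/lateral divider slice.
#' @param seed RNG seed; a fixed seed makes the phantom bit-reproducible.
#' @return list of class \code{bml_phantom_spec}.
#' @export
phantom_spec <- function(dim = c(240L, 120L, 24L),
                         spacing = c(0.357, 0.511, 3.0),
                         soft_tissue = 0.5, bone_intensity = 0.25,
                         intensity_unit = 0.03, noise_sd = 0.03,
                         rician = FALSE,
                         blobs = default_blobs(),
                         n_contour_points = 16L, jitter = 2,
                         divider_slice = floor(dim[3] / 2), seed = 1L) {
  stopifnot(length(dim) == 3L, all(dim >= 8L), all(spacing > 0))
  if (any(blobs$contrast <= 0 & blobs$type != "decoy_extraosseous"))
    stop("blob contrast must be > 0")
  structure(list(
    dim = as.integer(dim), spacing = as.numeric(spacing),
    soft_tissue = soft_tissue, bone_intensity = bone_intensity,
    intensity_unit = intensity_unit, noise_sd = noise_sd, rician = rician,
    bones = list(
      femur = list(center = c(65, 60, (dim[3] - 1) / 2),
                   radii = c(50, 45, dim[3] / 2 - 1)),
      tibia = list(center = c(175, 60, (dim[3] - 1) / 2),
                   radii = c(50, 45, dim[3] / 2 - 1))),
    blobs = blobs, n_contour_points = as.integer(n_contour_points),
    jitter = jitter, divider_slice = divider_slice, seed = as.integer(seed)
  ), class = "bml_phantom_spec")
}

#' Default planted blobs for the knee phantom
#'
#' Two qualifying BMLs (one lateral femur, one medial tibia, both adjacent
#' to the articular surface and spanning several slices) and three decoys:
#' a deep intra-femoral lesion farther than 10 mm from the articular
#' surface, a single-slice tibial lesion, and a bright extra-osseous blob
#' in the joint gap.
#'
#' @param bml_scale multiplicative scale on the in-plane radii of the two
#'   qualifying BMLs (volume scales roughly with its square); length 1 or 2
#'   (femur, tibia). Safe ranges keeping blobs inside bone: about
#'   [0.5, 2.2] for the femoral and [0.5, 2.0] for the tibial lesion.
#' @return data.frame, one row per blob.
#' @export
default_blobs <- function(bml_scale = 1) {
  s <- rep_len(bml_scale, 2)
  data.frame(
    id = 1:5,
    type = c("bml", "bml", "decoy_deep", "decoy_single",
             "decoy_extraosseous"),
    bone = c("femur", "tibia", "femur", "tibia", NA),
    cx = c(82, 152, 30, 165, 120),
    cy = c(60, 60, 60, 60, 60),
    cz = c(4.5, 19, 5, 22, 5),
    rx = c(12 * s[1], 10 * s[2], 4, 6, 3),
    ry = c(14 * s[1], 12 * s[2], 5, 7, 6),
    rz = c(1.6, 1.5, 1.5, 0.45, 1.2),
    contrast = c(5, 5, 5, 5, 10),
    stringsAsFactors = FALSE)
}

# super-ellipsoid occupancy over the 0-based voxel grid
#' @keywords internal
#' @noRd
body_mask <- function(dim, center, radii, zpower = 2) {
  fx <- ((seq_len(dim[1]) - 1 - center[1]) / radii[1])^2
  fy <- ((seq_len(dim[2]) - 1 - center[2]) / radii[2])^2
  fz <- abs((seq_len(dim[3]) - 1 - center[3]) / radii[3])^zpower
  outer(outer(fx, fy, "+"), fz, "+") <= 1
}

# in-plane boundary of a 3D mask, slice by slice
#' @keywords internal
#' @noRd
boundary3d_inplane <- function(mask) {
  out <- array(FALSE, dim = dim(mask))
  for (k in seq_len(dim(mask)[3]))
    if (any(mask[, , k])) out[, , k] <- boundary2d(mask[, , k])
  out
}

#' Generate a synthetic knee phantom
#'
#' Builds the piecewise-constant tissue model from a
#' \code{\link{phantom_spec}}, adds seeded noise, derives ground-truth bone
#' masks with articular surfaces (the joint-facing half of each bone's
#' boundary), simulates manual bone marking by sampling (and optionally
#' jittering) points on the true boundaries, and tabulates each planted
#' blob's true voxel count and volume.
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @return list of class \code{bml_phantom}: \code{volume}
#'   (\code{\link{bml_volume}}), \code{bones} (per-bone
#'   \code{bml_bone_mask} ground truth), \code{bml_truth} (integer label
#'   array of intra-bone blobs), \code{contours} (per-bone
#'   \code{\link{bml_contours}}), \code{truth} (per-blob data.frame) and
#'   \code{spec}.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "bml_phantom_spec"))
  set.seed(spec$seed)
  d <- spec$dim
  img <- array(spec$soft_tissue, dim = d)
  bones <- list()
  for (bn in c("femur", "tibia")) {
    b <- spec$bones[[bn]]
    m <- body_mask(d, b$center, b$radii, zpower = 4)
    img[m] <- spec$bone_intensity
    bd <- boundary3d_inplane(m)
    xcoord <- array(rep(seq_len(d[1]) - 1, times = d[2] * d[3]), dim = d)
    art <- if (bn == "femur") bd & (xcoord > b$center[1])
           else bd & (xcoord < b$center[1])
    bones[[bn]] <- structure(list(bone = bn, mask = m, articular = art,
                                  spacing = spec$spacing),
                             class = "bml_bone_mask")
  }
  # planted blobs
  lab <- array(0L, dim = d)
  truth <- spec$blobs
  truth$n_voxels <- 0L
  truth$volume_mm3 <- 0
  truth$slice_span <- 0L
  for (i in seq_len(nrow(spec$blobs))) {
    bl <- spec$blobs[i, ]
    if (any(c(bl$cx + bl$rx, bl$cy + bl$ry, bl$cz + bl$rz) > d - 1) ||
        any(c(bl$cx - bl$rx, bl$cy - bl$ry, bl$cz - bl$rz) < 0))
      stop("blob ", bl$id, " extends outside the volume bounds")
    m <- body_mask(d, c(bl$cx, bl$cy, bl$cz), c(bl$rx, bl$ry, bl$rz))
    if (bl$type == "decoy_extraosseous") {
      if (any(m & (bones$femur$mask | bones$tibia$mask)))
        stop("extra-osseous blob ", bl$id, " overlaps a bone")
      img[m] <- spec$soft_tissue + bl$contrast * spec$intensity_unit
    } else {
      inside <- bones[[bl$bone]]$mask
      if (any(m & !inside))
        stop("blob ", bl$id, " extends outside its bone")
      img[m] <- spec$bone_intensity + bl$contrast * spec$intensity_unit
      lab[m] <- bl$id
    }
    v <- which(m, arr.ind = TRUE)
    truth$n_voxels[i] <- nrow(v)
    truth$volume_mm3[i] <- nrow(v) * prod(spec$spacing)
    truth$slice_span[i] <- length(unique(v[, 3]))
  }
  truth$qualifies <- truth$type == "bml"
  # noise
  if (spec$noise_sd > 0) {
    if (spec$rician) {
      img <- sqrt((img + array(rnorm(length(img), 0, spec$noise_sd),
                               dim = d))^2 +
                  array(rnorm(length(img), 0, spec$noise_sd), dim = d)^2)
    } else {
      img <- img + array(rnorm(length(img), 0, spec$noise_sd), dim = d)
    }
  }
  vol <- bml_volume(img, spec$spacing)
  # simulated manual marking from the true boundaries
  contours <- list()
  for (bn in c("femur", "tibia")) {
    contours[[bn]] <- trace_contours(bones[[bn]], spec$n_contour_points,
                                     spec$divider_slice)
    if (spec$jitter > 0)
      contours[[bn]] <- jitter_contours(contours[[bn]], spec$jitter,
                                        seed = spec$seed + match(bn, c("femur", "tibia")))
  }
  structure(list(volume = vol, bones = bones, bml_truth = lab,
                 contours = contours, truth = truth, spec = spec),
            class = "bml_phantom")
}

#' @export
print.bml_phantom <- function(x, ...) {
  d <- dim(x$volume$voxels)
  cat(sprintf("<bml_phantom> %d x %d x %d, %d planted blob(s), seed %d\n",
              d[1], d[2], d[3], nrow(x$truth), x$spec$seed))
  print(x$truth[, c("id", "type", "bone", "n_voxels", "volume_mm3",
                    "slice_span", "qualifies")], row.names = FALSE)
  invisible(x)
}

# sample n_points marked points per slice from a truth bone mask, ordered
# by angle around the slice centroid; articular flags from the truth
# articular surface (nearest boundary voxel)
#' @keywords internal
#' @noRd
trace_contours <- function(bone, n_points = 16L, divider_slice = NULL,
                           min_area = 30L) {
  slices <- list()
  d <- dim(bone$mask)
  for (k in seq_len(d[3])) {
    sl <- bone$mask[, , k]
    if (sum(sl) < min_area) next
    bd <- which(boundary2d(sl), arr.ind = TRUE)
    art_sl <- bone$articular[, , k]
    cx <- mean(bd[, 1]); cy <- mean(bd[, 2])
    ang <- atan2(bd[, 2] - cy, bd[, 1] - cx)
    targets <- seq(-pi, pi, length.out = n_points + 1L)[-(n_points + 1L)]
    pick <- vapply(targets, function(a) {
      dd <- abs(((ang - a + pi) %% (2 * pi)) - pi)
      which.min(dd)
    }, integer(1))
    pick <- unique(pick)
    if (length(pick) < 3L) next
    pts <- data.frame(x = bd[pick, 1] - 1, y = bd[pick, 2] - 1,
                      articular = art_sl[bd[pick, , drop = FALSE]])
    if (!any(pts$articular)) next
    slices[[as.character(k - 1L)]] <- pts
  }
  bml_contours(bone$bone, slices, shape = d, divider_slice = divider_slice)
}

#' Jitter marked contour points
#'
#' Displaces every marked point by seeded uniform noise in
#' \code{[-amplitude, amplitude]} voxels per in-plane axis, emulating
#' imprecise manual marking (refinement does not require the initial curve
#' to lie on the bone boundary). Articular flags are preserved; points are
#' clamped to the volume bounds when known.
#'
#' @param contours a \code{\link{bml_contours}}.
#' @param amplitude jitter amplitude in voxels (>= 0).
#' @param seed RNG seed.
#' @return a jittered \code{\link{bml_contours}}.
#' @export
jitter_contours <- function(contours, amplitude, seed = 1L) {
  if (amplitude < 0) stop("`amplitude` must be >= 0")
  if (amplitude == 0) return(contours)
  set.seed(seed)
  for (nm in names(contours$slices)) {
    pts <- contours$slices[[nm]]
    pts$x <- pts$x + runif(nrow(pts), -amplitude, amplitude)
    pts$y <- pts$y + runif(nrow(pts), -amplitude, amplitude)
    if (!is.null(contours$shape)) {
      pts$x <- pmin(pmax(pts$x, 0), contours$shape[1] - 1)
      pts$y <- pmin(pmax(pts$y, 0), contours$shape[2] - 1)
    }
    contours$slices[[nm]] <- pts
  }
  contours
}
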