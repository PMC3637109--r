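#' Construct an image volume
#'
#' A 3D scalar intensity grid with per-axis physical voxel spacing. Axis
#' convention: x = in-plane row, y = in-plane column, z = sagittal slice
#' index. Voxel centers sit at 0-based integer coordinates, matching the
#' coordinates used in contour files.
#'
#' @param voxels 3D numeric array of intensities (finite).
#' @param spacing numeric length-3, voxel spacing (dx, dy, dz) in mm.
#' @return An object of class \code{bml_volume}: list with \code{voxels}
#'   and \code{spacing}.
#' @export
bml_volume <- function(voxels, spacing) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3D array, got ",
         paste(dim(voxels), collapse = "x"))
  if (dim(voxels)[3] < 1L) stop("volume must have at least one slice")
  if (!all(is.finite(voxels))) stop("all intensities must be finite")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || !all(is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive finite values (mm), got: ",
         paste(spacing, collapse = ", "))
  structure(list(voxels = voxels, spacing = spacing), class = "bml_volume")
}

#' @export
print.bml_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<bml_volume> %d x %d x %d voxels, spacing %.3f x %.3f x %.3f mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @export
dim.bml_volume <- function(x) dim(x$voxels)

#' Read a 3D volume from NIfTI
#'
#' Intensities and header voxel spacing are preserved exactly as stored.
#'
#' @param path path to a \code{.nii} or \code{.nii.gz} file with 3D data.
#' @return A \code{\link{bml_volume}}.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected 3D NIfTI data, got ", length(d), "D in ", path)
  sp <- RNifti::pixdim(img)[seq_len(3)]
  if (any(!is.finite(sp)) || any(sp <= 0))
    stop("non-positive voxel spacing in NIfTI header of ", path, ": ",
         paste(sp, collapse = ", "))
  bml_volume(array(as.numeric(img), dim = d), sp)
}

#' Write a volume (or mask) to NIfTI
#'
#' @param vol a \code{\link{bml_volume}}, or a 3D array (logical masks are
#'   written as 0/1 integers) together with \code{spacing}.
#' @param path output path (\code{.nii} or \code{.nii.gz}).
#' @param spacing required when \code{vol} is a bare array.
#' @return \code{path}, invisibly.
#' @export
write_volume <- function(vol, path, spacing = NULL) {
  if (inherits(vol, "bml_volume")) {
    arr <- vol$voxels
    spacing <- vol$spacing
  } else {
    arr <- vol
    if (is.null(spacing)) stop("`spacing` required for a bare array")
  }
  if (is.logical(arr)) arr <- array(as.integer(arr), dim = dim(arr))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- as.numeric(spacing)
  RNifti::writeNifti(img, path)
  invisible(path)
}
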