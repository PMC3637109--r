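#' Fit the Gaussian intensity null over a voxel domain
#'
#' The BML detector models normal bone marrow intensity as Gaussian and only
#' uses its mean and standard deviation: lesions are hyperintense outliers
#' of this null.
#'
#' @param vol a \code{\link{bml_volume}} (or bare 3D array).
#' @param domain logical 3D mask with at least 30 voxels.
#' @return Object of class \code{bml_gaussian_null}: list with \code{mean},
#'   \code{sd} (sample, n-1 denominator) and \code{n}.
#' @export
fit_gaussian_null <- function(vol, domain) {
  voxels <- if (inherits(vol, "bml_volume")) vol$voxels else vol
  x <- voxels[domain]
  if (length(x) < 30L)
    stop("null domain has ", length(x), " voxels; at least 30 required")
  s <- stats::sd(x)
  if (s == 0)
    stop("degenerate null: constant intensity over the domain")
  structure(list(mean = mean(x), sd = s, n = length(x)),
            class = "bml_gaussian_null")
}

#' @export
print.bml_gaussian_null <- function(x, ...) {
  cat(sprintf("<bml_gaussian_null> mean = %.4g, sd = %.4g (n = %d)\n",
              x$mean, x$sd, x$n))
  invisible(x)
}

#' Upper-tail p-values of domain intensities under the Gaussian null
#'
#' BMLs are areas of high signal intensity within bone, so each voxel is
#' scored by \code{p = 1 - Phi((I - mean) / sd)}.
#'
#' @param vol a \code{\link{bml_volume}} (or bare 3D array).
#' @param domain logical 3D mask.
#' @param null a \code{\link{fit_gaussian_null}} result.
#' @return numeric vector of p-values, aligned with \code{which(domain)}.
#' @export
pixel_pvalues <- function(vol, domain, null) {
  voxels <- if (inherits(vol, "bml_volume")) vol$voxels else vol
  pnorm(voxels[domain], mean = null$mean, sd = null$sd, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up threshold
#'
#' Rejects the hypotheses with \code{p <= p_(k)} where \code{k} is the
#' largest index with \code{p_(i) <= i * q / m} over the sorted p-values.
#' A larger q yields a lower implied intensity threshold and therefore more
#' candidate voxels.
#'
#' @param pvalues numeric vector of p-values (at least one).
#' @param q FDR level in (0, 1).
#' @param intensities optional intensities aligned with \code{pvalues}; when
#'   given, the implied intensity threshold (minimum over rejected voxels,
#'   +Inf if none) is reported.
#' @return list with logical \code{reject}, integer \code{n_reject},
#'   \code{p_crit} (largest rejected p-value, NA if none) and
#'   \code{threshold}.
#' @export
bh_threshold <- function(pvalues, q, intensities = NULL) {
  m <- length(pvalues)
  if (m < 1L) stop("at least one p-value required")
  if (q <= 0 || q >= 1) stop("`q` must be in (0, 1)")
  ps <- sort(pvalues)
  ok <- ps <= seq_len(m) * q / m
  if (any(ok)) {
    k <- max(which(ok))
    p_crit <- ps[k]
    reject <- pvalues <= p_crit
  } else {
    p_crit <- NA_real_
    reject <- rep(FALSE, m)
  }
  threshold <- if (is.null(intensities)) NULL
  else if (any(reject)) min(intensities[reject]) else Inf
  list(reject = reject, n_reject = sum(reject), p_crit = p_crit,
       threshold = threshold)
}

#' Region-based curve refinement of a candidate mask
#'
#' Two-phase piecewise-constant segmentation restricted to the bone domain:
#' minimizes the discrete energy
#' \code{sum_in (I - c1)^2 + sum_out (I - c2)^2 + mu * L}, with \code{L} the
#' boundary length (in-plane 4-neighbour discordant pairs within the domain)
#' and \code{c1, c2} the class means. Intensities are rescaled to [0, 1]
#' within the domain so \code{mu} is dimensionless. The curve evolves in a
#' narrow band: each iteration exactly minimizes the energy (graph min-cut)
#' over a shell of half-width \code{band_width} around the current front,
#' with the eroded region interior frozen as foreground and the far exterior
#' frozen as background, then refits the class means; iteration stops when
#' the labelling is stationary. The previous labelling is always feasible in
#' each banded problem, so the energy never increases; every step is
#' deterministic, and the front moves at most \code{band_width} voxels per
#' iteration — the local, initialization-driven behaviour of region-based
#' curve evolution (a distant homogeneous region is never relabelled, and a
#' lesion wider than the band cannot be deleted wholesale, only evolved at
#' its boundary).
#' At \code{mu = 0.28} an isolated single in-plane voxel is always removed
#' (its boundary saving 4*mu exceeds the largest possible data-term gain
#' of 1), which eliminates small discrete bright specks; at \code{mu = 0}
#' bright specks survive.
#'
#' @param init logical 3D mask of initial candidates (subset of domain);
#'   sets the initial class means and the starting front.
#' @param vol a \code{\link{bml_volume}} (or bare 3D array).
#' @param domain logical 3D bone mask.
#' @param mu length-penalty weight in [0, 1].
#' @param max_iters cap on front-evolution iterations.
#' @param band_width in-plane half-width (voxels) of the evolution band: the
#'   front can advance at most this far per iteration.
#' @return logical 3D refined mask, subset of \code{domain}. An empty
#'   \code{init} returns an empty mask unchanged (no-op, with a message).
#' @export
chan_vese_refine <- function(init, vol, domain, mu = 0.28, max_iters = 50L,
                             band_width = 2L) {
  voxels <- if (inherits(vol, "bml_volume")) vol$voxels else vol
  stopifnot(identical(dim(init), dim(voxels)),
            identical(dim(domain), dim(voxels)))
  if (mu < 0 || mu > 1) stop("`mu` must be in [0, 1]")
  if (any(init & !domain)) stop("`init` must be a subset of `domain`")
  if (!any(init)) {
    message("chan_vese_refine: empty initialization, returning empty mask")
    return(init & FALSE)
  }
  d <- dim(voxels)
  I <- array(0, dim = d)
  I[domain] <- rescale01(voxels[domain])
  cbar <- mean(I[domain])
  u <- init
  for (iter in seq_len(max_iters)) {
    if (!any(u)) break
    c1 <- mean(I[u])
    c0 <- if (any(domain & !u)) mean(I[domain & !u]) else cbar
    # free voxels: a shell of half-width band_width around the front; the
    # eroded interior stays foreground and the far exterior background, so
    # only the front moves (by at most band_width voxels per iteration)
    core <- erode_inplane_by(u, band_width)
    band <- dilate_inplane(u, band_width) & domain & !core
    idx <- which(band)
    n <- length(idx)
    if (n == 0L) break
    M <- array(0L, dim = d)
    M[idx] <- seq_len(n)
    Iv <- I[idx]
    # frozen neighbours charge mu per in-plane edge across the freeze line
    nfroz0 <- count_inplane_neighbours(domain & !band & !core)[idx]
    nfroz1 <- count_inplane_neighbours(core)[idx]
    cap_s <- (Iv - c0)^2 + mu * nfroz1  # paid when labelled 0
    cap_t <- (Iv - c1)^2 + mu * nfroz0  # paid when labelled 1
    pa <- c(band_pairs(M, 1L, "a"), band_pairs(M, 2L, "a"))
    pb <- c(band_pairs(M, 1L, "b"), band_pairs(M, 2L, "b"))
    lab <- cpp_mincut(n, cap_s, cap_t, pa, pb, mu)
    u_new <- core
    u_new[idx[lab]] <- TRUE
    if (identical(u_new, u)) break
    u <- u_new
  }
  u
}

# in-plane (4-neighbour) erosion by w voxels, slice-wise
#' @keywords internal
#' @noRd
erode_inplane_by <- function(mask, w) !dilate_inplane(!mask, w)

# in-plane 4-neighbour binary dilation by w voxels, slice-wise
#' @keywords internal
#' @noRd
dilate_inplane <- function(mask, w) {
  d <- dim(mask)
  for (r in seq_len(w)) {
    out <- mask
    out[-1, , ] <- out[-1, , ] | mask[-d[1], , ]
    out[-d[1], , ] <- out[-d[1], , ] | mask[-1, , ]
    out[, -1, ] <- out[, -1, ] | mask[, -d[2], ]
    out[, -d[2], ] <- out[, -d[2], ] | mask[, -1, ]
    mask <- out
  }
  mask
}

# in-plane morphological closing (dilation then erosion) by w voxels
#' @keywords internal
#' @noRd
close_inplane <- function(mask, w) {
  !dilate_inplane(!dilate_inplane(mask, w), w)
}

# per-voxel count of in-plane 4-neighbours that are TRUE in `mask`
#' @keywords internal
#' @noRd
count_inplane_neighbours <- function(mask) {
  d <- dim(mask)
  cnt <- array(0L, dim = d)
  m <- array(as.integer(mask), dim = d)
  cnt[-1, , ] <- cnt[-1, , ] + m[-d[1], , ]
  cnt[-d[1], , ] <- cnt[-d[1], , ] + m[-1, , ]
  cnt[, -1, ] <- cnt[, -1, ] + m[, -d[2], ]
  cnt[, -d[2], ] <- cnt[, -d[2], ] + m[, -1, ]
  cnt
}

# node-id pairs of in-plane neighbours along one axis ("a" = lower side)
#' @keywords internal
#' @noRd
band_pairs <- function(M, axis, side) {
  d <- dim(M)
  if (axis == 1L) {
    A <- M[-d[1], , , drop = FALSE]
    B <- M[-1, , , drop = FALSE]
  } else {
    A <- M[, -d[2], , drop = FALSE]
    B <- M[, -1, , drop = FALSE]
  }
  sel <- A > 0L & B > 0L
  if (side == "a") A[sel] else B[sel]
}

#' Discrete region-based energy of a labelling
#'
#' The energy minimized by \code{\link{chan_vese_refine}}, evaluated at a
#' given mask (class means refit from the mask). Useful for verifying that
#' refinement never increases the energy.
#'
#' @inheritParams chan_vese_refine
#' @param mask logical 3D mask to evaluate.
#' @return scalar energy.
#' @export
cv_energy <- function(mask, vol, domain, mu = 0.28) {
  voxels <- if (inherits(vol, "bml_volume")) vol$voxels else vol
  I <- array(0, dim = dim(voxels))
  I[domain] <- rescale01(voxels[domain])
  cpp_cv_energy(as.numeric(I), as.integer(domain), as.integer(mask),
                dim(voxels), mu)
}

#' Boundary length of a mask within a domain
#'
#' Counts in-plane 4-neighbour label-discordant voxel pairs inside the
#' domain — the discrete perimeter penalized by \code{mu}.
#'
#' @param mask logical 3D mask.
#' @param domain logical 3D domain mask.
#' @return scalar count.
#' @export
boundary_length <- function(mask, domain = NULL) {
  if (is.null(domain)) domain <- array(TRUE, dim = dim(mask))
  cpp_perimeter(as.integer(domain), as.integer(mask), dim(mask))
}

#' Two-pass BML candidate segmentation within a bone
#'
#' Pass 1 fits the Gaussian null on all bone voxels, thresholds upper-tail
#' p-values by Benjamini-Hochberg at level q, builds contiguous initial
#' regions from the thresholded image (in-plane closing), and refines them
#' by region-based evolution. Pass 2 repeats the whole procedure with
#' the null and p-values refit on the bone voxels excluding the pass-1
#' lesions, capturing dimmer lesions whose contrast was masked by bright
#' ones. The final candidate mask is the union, with per-voxel pass
#' provenance. A degenerate null (or an empty threshold set) makes that pass
#' contribute nothing.
#'
#' @param vol a \code{\link{bml_volume}}.
#' @param bone a \code{\link{bml_bone_mask}} (or logical 3D array).
#' @param params a \code{\link{bml_params}}.
#' @return Object of class \code{bml_candidates}: list with logical
#'   \code{mask} (subset of the bone mask), integer array \code{pass}
#'   (0 = background, 1, 2) and \code{bone} label.
#' @export
two_pass_segment <- function(vol, bone, params = bml_params()) {
  bone_mask <- if (inherits(bone, "bml_bone_mask")) bone$mask else bone
  bone_lab <- if (inherits(bone, "bml_bone_mask")) bone$bone else NA_character_
  if (!any(bone_mask)) stop("empty bone mask")
  run_pass <- function(domain) {
    empty <- array(FALSE, dim = dim(domain))
    if (sum(domain) < 30L) return(empty)
    null <- tryCatch(fit_gaussian_null(vol, domain), error = function(e) NULL)
    if (is.null(null)) {
      message("two_pass_segment: degenerate null, pass skipped")
      return(empty)
    }
    p <- pixel_pvalues(vol, domain, null)
    bh <- bh_threshold(p, params$q)
    if (bh$n_reject == 0L) return(empty)
    init <- empty
    init[domain][bh$reject] <- TRUE
    # initial curves from the thresholded image: an in-plane closing bridges
    # the scattered supra-threshold voxels into contiguous seed regions
    # (isolated noise voxels stay isolated and are eliminated by the length
    # penalty during evolution)
    init <- close_inplane(init, 2L) & domain
    chan_vese_refine(init, vol, domain, mu = params$mu,
                     max_iters = params$evolution$max_iters)
  }
  m1 <- run_pass(bone_mask)
  m2 <- run_pass(bone_mask & !m1)
  pass <- array(0L, dim = dim(bone_mask))
  pass[m2] <- 2L
  pass[m1] <- 1L
  structure(list(mask = m1 | m2, pass = pass, bone = bone_lab),
            class = "bml_candidates")
}

#' @export
print.bml_candidates <- function(x, ...) {
  cat(sprintf("<bml_candidates> %s: %d voxels (pass 1: %d, pass 2: %d)\n",
              x$bone, sum(x$mask), sum(x$pass == 1L), sum(x$pass == 2L)))
  invisible(x)
}
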