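test_that("rasterization interpolates marked points and fills the interior", {
  sq <- data.frame(x = c(10, 29, 29, 10), y = c(10, 10, 29, 29),
                   articular = c(TRUE, TRUE, FALSE, FALSE))
  m <- rasterize_initial_contour(bml_contours("femur", list("0" = sq)),
                                 c(40, 40, 1))[, , 1]
  inside <- matrix(FALSE, 40, 40)
  inside[11:30, 11:30] <- TRUE
  # the closed spline passes through the corners and bulges outward between
  # them: the square is covered (up to corner discretization) and the
  # overshoot is bounded
  expect_lte(sum(inside & !m), 8)
  expect_gte(sum(m), 380)
  expect_lte(sum(m), 620)

  circ <- circle_contour(40, 40, 25, 16L)
  m2 <- rasterize_initial_contour(bml_contours("femur", list("0" = circ)),
                                  c(80, 80, 1))[, , 1]
  expect_lt(abs(sum(m2) - pi * 25^2) / (pi * 25^2), 0.02)

  two <- data.frame(x = c(1, 5), y = c(1, 5), articular = c(TRUE, TRUE))
  expect_error(bml_contours("femur", list("0" = two)), "at least 3")

  bow <- data.frame(x = c(5, 25, 25, 5), y = c(5, 25, 5, 25),
                    articular = rep(TRUE, 4))
  expect_error(
    rasterize_initial_contour(bml_contours("femur", list("3" = bow)),
                              c(30, 30, 5)),
    "slice 3.*self-intersecting")
})

test_that("edge map is 1 on flat regions and minimal on step edges", {
  flat <- compute_edge_map(matrix(3.7, 32, 32), sigma = 1, spacing = c(1, 1))
  expect_true(all(flat$g == 1))

  step <- matrix(0.2, 40, 40)
  step[21:40, ] <- 0.8
  em <- compute_edge_map(step, sigma = 1, spacing = c(1, 1))
  inner <- em$g[5:36, 5:36]
  rows_at_min <- 4L + unique(which(inner == min(inner), arr.ind = TRUE)[, 1])
  expect_true(all(rows_at_min %in% 20:21))
})

test_that("edge map on a ramp matches the closed-form gradient", {
  nx <- 41; ny <- 30
  ramp <- matrix(rep(seq(0, 4, length.out = nx), ny), nx, ny)
  sp <- c(0.357, 0.511)
  em <- compute_edge_map(ramp, sigma = 1, spacing = sp)
  # after rescaling to [0,1] a ramp stays a ramp under Gaussian smoothing
  # (away from the replicated borders): |grad| = 1 / ((nx - 1) * dx)
  gexp <- 1 / (1 + (1 / ((nx - 1) * sp[1]))^2)
  interior <- em$g[15:27, 10:20]
  expect_equal(as.vector(interior), rep(gexp, length(interior)),
               tolerance = 1e-10)
})

test_that("edge-based evolution locks onto high-contrast boundaries", {
  for (dil in c(0L, 5L)) {
    ds <- disc_slice(64, r = 14)
    init <- array(ds$truth, dim = c(64, 64, 1))
    if (dil > 0L) init <- bmlseg:::dilate_inplane(init, dil)
    em <- list("0" = compute_edge_map(ds$img, sigma = 1, spacing = c(1, 1)))
    out <- evolve_bone_contour(init, em,
                               evolution = bml_params()$evolution)
    expect_lte(hausdorff2d(out[, , 1], ds$truth), 1)
  }
})

test_that("evolution on a constant image shrinks by curvature only", {
  init <- array(FALSE, dim = c(48, 48, 1))
  init[12:36, 12:36, 1] <- TRUE
  em <- list("0" = compute_edge_map(matrix(1, 48, 48), sigma = 1,
                                    spacing = c(1, 1)))
  out <- evolve_bone_contour(init, em, evolution = bml_params()$evolution)
  expect_lte(sum(out), sum(init))
  expect_gt(sum(out), 0)
})

test_that("a vanishing contour raises an error naming the slice", {
  init <- array(FALSE, dim = c(32, 32, 3))
  init[15:16, 15:16, 2] <- TRUE  # tiny blob, no edges to hold it
  em <- list("1" = compute_edge_map(matrix(1, 32, 32), sigma = 1,
                                    spacing = c(1, 1)))
  expect_error(
    evolve_bone_contour(init, em, evolution = bml_params()$evolution),
    "slice 1")
})

test_that("articular tags follow the nearest marked segment", {
  # circular bone, articular on the +x half of the marked points
  circ <- circle_contour(20, 20, 14, 10L)
  circ$articular <- circ$x >= 20
  ct <- bml_contours("tibia", list("0" = circ))
  refined <- rasterize_initial_contour(ct, c(40, 40, 1))
  bm <- build_bone_mask(refined, ct, spacing = c(0.357, 0.511, 3))
  expect_true(all(bm$articular[bm$articular] %in% TRUE))
  # articular surface is a subset of the in-plane boundary
  bd <- bmlseg:::boundary2d(bm$mask[, , 1])
  expect_true(all(!bm$articular[, , 1] | bd))

  # oracle: exhaustive nearest-segment search over the 10 marked segments
  pts <- ct$slices[["0"]]
  nseg <- nrow(pts)
  nxt <- c(2:nseg, 1L)
  seg_art <- pts$articular & pts$articular[nxt]
  sp <- c(0.357, 0.511)
  pdist <- function(px, py, ax, ay, bx, by) {
    vx <- bx - ax; vy <- by - ay
    tt <- ((px - ax) * vx + (py - ay) * vy) / (vx^2 + vy^2)
    tt <- min(1, max(0, tt))
    sqrt((px - ax - tt * vx)^2 + (py - ay - tt * vy)^2)
  }
  bdv <- which(bd, arr.ind = TRUE)
  for (r in seq_len(nrow(bdv))) {
    px <- (bdv[r, 1] - 1) * sp[1]
    py <- (bdv[r, 2] - 1) * sp[2]
    dists <- vapply(seq_len(nseg), function(s)
      pdist(px, py, pts$x[s] * sp[1], pts$y[s] * sp[2],
            pts$x[nxt[s]] * sp[1], pts$y[nxt[s]] * sp[2]), numeric(1))
    expect_equal(bm$articular[bdv[r, 1], bdv[r, 2], 1],
                 any(seg_art[dists <= min(dists) + 1e-9]))
  }
})

test_that("fully articular marking tags the whole boundary", {
  circ <- circle_contour(16, 16, 10, 8L, articular = TRUE)
  ct <- bml_contours("femur", list("0" = circ))
  refined <- rasterize_initial_contour(ct, c(32, 32, 1))
  bm <- build_bone_mask(refined, ct, spacing = c(1, 1, 1))
  bd <- bmlseg:::boundary2d(bm$mask[, , 1])
  expect_identical(bm$articular[, , 1], bd)
})
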