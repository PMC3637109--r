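test_that("central-slice exclusion clears the documented window", {
  mk <- function(nz) array(TRUE, dim = c(2, 2, nz))
  expect_identical(exclude_central_slices(mk(12), 0L), mk(12))
  # 37 slices, 9 central -> 0-based slices 14..22 cleared
  m <- exclude_central_slices(mk(37), 9L)
  cleared <- which(!apply(m, 3, any)) - 1L
  expect_identical(cleared, 14:22)
  # a mask entirely inside the window vanishes
  m2 <- array(FALSE, dim = c(2, 2, 37))
  m2[, , 16:22] <- TRUE
  expect_false(any(exclude_central_slices(m2, 9L)))
  expect_error(exclude_central_slices(mk(5), 9L), "exceeds")
})

test_that("3D components respect the configured connectivity", {
  m <- array(FALSE, dim = c(4, 4, 4))
  m[1, 1, 1] <- TRUE
  m[2, 2, 2] <- TRUE  # shares only a corner
  expect_equal(connected_components_3d(m, 26L)$n, 1L)
  expect_equal(connected_components_3d(m, 6L)$n, 2L)
  expect_equal(connected_components_3d(array(FALSE, c(3, 3, 3)))$n, 0L)
})

test_that("3D labelling matches a flood-fill oracle on random masks", {
  set.seed(41)
  for (conn in c(6L, 26L)) {
    m <- array(runif(20^3) < 0.2, dim = c(20, 20, 20))
    got <- connected_components_3d(m, conn)$labels
    want <- flood_fill_oracle(m, conn)
    # same partition up to label numbering; both label in first-voxel order
    expect_identical(got > 0, want > 0)
    expect_identical(sort(as.vector(table(got[got > 0]))),
                     sort(as.vector(table(want[want > 0]))))
    # one-to-one label correspondence
    key <- paste(got[m], want[m])
    expect_equal(length(unique(key)), max(got))
    expect_equal(max(got), max(want))
  }
})

test_that("articular distance is exact anisotropic Euclidean", {
  sp <- c(0.357, 0.511, 3.0)
  expect_equal(min_articular_distance(rbind(c(3, 4, 5)), rbind(c(3, 4, 5)),
                                      sp), 0)
  expect_equal(min_articular_distance(rbind(c(3, 4, 7)), rbind(c(3, 4, 5)),
                                      sp), 6.0)
  expect_equal(min_articular_distance(rbind(c(4, 4, 5)), rbind(c(3, 4, 5)),
                                      sp), 0.357)
  expect_error(min_articular_distance(rbind(c(1, 1, 1)),
                                      matrix(0, 0, 3), sp), "empty")
  set.seed(42)
  for (rep in 1:20) {
    A <- cbind(sample(30, 8, TRUE), sample(30, 8, TRUE), sample(10, 8, TRUE))
    B <- cbind(sample(30, 12, TRUE), sample(30, 12, TRUE), sample(10, 12, TRUE))
    expect_equal(min_articular_distance(A, B, sp), min_dist_oracle(A, B, sp),
                 tolerance = 1e-12)
  }
})

test_that("false-positive filters enforce both criteria and are idempotent", {
  comp <- data.frame(
    id = 1:4,
    n_voxels = c(100, 80, 60, 40),
    volume_mm3 = c(100, 80, 60, 40),
    slice_span = c(3L, 3L, 1L, 2L),
    min_articular_dist_mm = c(2, 12, 1, 10))
  attr(comp, "voxels") <- as.list(1:4)
  kept <- apply_filters(comp, bml_params())
  expect_identical(kept$id, c(1L, 4L))          # 12 mm and single-slice removed
  expect_identical(apply_filters(kept, bml_params())$id, kept$id)
  expect_equal(nrow(apply_filters(comp[0, ], bml_params())), 0L)
})

test_that("region assignment splits medial/lateral at the divider", {
  expect_equal(assign_region(20, "tibia", divider = 15), "medial tibia")
  expect_equal(assign_region(10, "femur", divider = 15), "lateral femur")
  expect_equal(assign_region(15, "femur", divider = 15), "medial femur")
  expect_equal(assign_region(10, "tibia", divider = 15,
                             medial_is_high = FALSE), "medial tibia")
})

test_that("volumes are voxel counts times voxel volume and sum exactly", {
  sp <- c(0.357, 0.511, 3.0)
  comp <- data.frame(bone = c("tibia", "tibia", "femur"),
                     region = c("medial tibia", "lateral tibia",
                                "medial femur"),
                     volume_mm3 = c(1 * prod(sp), 1000, 250))
  rep1 <- quantify(comp, sp)
  expect_equal(rep1$regions$volume_mm3[rep1$regions$region == "medial tibia"],
               prod(sp))
  expect_equal(sum(rep1$regions$volume_mm3), sum(comp$volume_mm3))
  expect_equal(prod(sp), 0.357 * 0.511 * 3.0)

  u <- quantify(data.frame(bone = "femur", region = "lateral femur",
                           volume_mm3 = 1000), c(1, 1, 1))
  expect_equal(sum(u$regions$volume_mm3), 1000)
})

test_that("paired change is follow-up minus baseline and anti-symmetric", {
  mk <- function(v) quantify(data.frame(bone = "tibia",
                                        region = "medial tibia",
                                        volume_mm3 = v), c(1, 1, 1))
  a <- mk(100); b <- mk(150)
  expect_equal(volume_change(a, a)$regions$change_mm3, rep(0, 4))
  ab <- volume_change(a, b)$regions$change_mm3
  ba <- volume_change(b, a)$regions$change_mm3
  expect_equal(ab[ab != 0], 50)
  expect_equal(ab, -ba)
  bad <- a
  bad$regions <- bad$regions[c(2, 1, 3, 4), ]
  expect_error(volume_change(a, bad), "mismatch")
})
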