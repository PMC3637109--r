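test_that("volume round-trips through NIfTI with spacing preserved", {
  vox <- array(rnorm(8), dim = c(2, 2, 2))
  vol <- bml_volume(vox, c(0.357, 0.511, 3.0))
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(vol, path)
  back <- read_volume(path)
  expect_equal(back$voxels, vox, tolerance = 1e-7)
  expect_equal(back$spacing, c(0.357, 0.511, 3.0), tolerance = 1e-7)
})

test_that("volume reader rejects bad inputs", {
  expect_error(read_volume(tempfile()), "no such file")
  path <- withr::local_tempfile(fileext = ".nii.gz")
  img4 <- RNifti::asNifti(array(0, dim = c(2, 2, 2, 2)))
  RNifti::writeNifti(img4, path)
  expect_error(read_volume(path), "3D")
  expect_error(bml_volume(array(0, c(2, 2)), c(1, 1, 1)), "3D")
  expect_error(bml_volume(array(0, c(2, 2, 2)), c(1, -1, 1)), "positive")
  expect_error(bml_volume(array(NA_real_, c(2, 2, 2)), c(1, 1, 1)), "finite")
})

test_that("contour sets validate their invariants", {
  sq <- data.frame(x = c(1, 8, 8, 1), y = c(1, 1, 8, 8),
                   articular = c(TRUE, TRUE, FALSE, FALSE))
  ct <- bml_contours("tibia", list("0" = sq), shape = c(10L, 10L, 3L))
  expect_s3_class(ct, "bml_contours")
  expect_identical(marked_slices(ct), 0L)
  expect_error(bml_contours("tibia", list("0" = sq[1:2, ])), "at least 3")
  no_art <- sq
  no_art$articular <- FALSE
  expect_error(bml_contours("tibia", list("0" = no_art)), "articular")
  oob <- sq
  oob$x[1] <- 42
  expect_error(bml_contours("tibia", list("0" = oob), shape = c(10L, 10L, 3L)),
               "bounds")
  expect_error(bml_contours("tibia", list("5" = sq), shape = c(10L, 10L, 3L)),
               "outside")
})

test_that("contours round-trip through JSON", {
  sq <- data.frame(x = c(1.25, 8.5, 8, 1), y = c(1, 1, 8.75, 8),
                   articular = c(TRUE, TRUE, FALSE, TRUE))
  ct <- bml_contours("femur", list("2" = sq, "4" = sq),
                     shape = c(12L, 12L, 6L), divider_slice = 3)
  path <- withr::local_tempfile(fileext = ".json")
  write_contours(ct, path)
  back <- read_contours(path)
  expect_equal(back$bone, "femur")
  expect_equal(back$slices, ct$slices)
  expect_equal(back$divider_slice, 3)
})

test_that("segmentation parameters carry the documented defaults", {
  p <- bml_params()
  expect_equal(p$q, 0.05)
  expect_equal(p$mu, 0.28)
  expect_equal(p$max_articular_dist_mm, 10)
  expect_equal(p$min_slice_span, 2L)
  expect_equal(p$n_central_excluded, 9L)
  expect_equal(p$connectivity, 26L)
  expect_error(bml_params(q = 1.2), "q")
  expect_error(bml_params(mu = -0.1), "mu")
  expect_error(bml_params(connectivity = 8), "connectivity")

  path <- withr::local_tempfile(fileext = ".json")
  write_params(bml_params(q = 0.1, mu = 0.4), path)
  back <- read_params(path)
  expect_equal(back$q, 0.1)
  expect_equal(back$mu, 0.4)
  expect_equal(back$evolution, bml_params()$evolution)
})

test_that("report writer emits one row per region and paired changes", {
  # empty report (no regions assembled) -> header only
  empty <- structure(list(regions = data.frame(
    bone = character(0), region = character(0),
    n_components = integer(0), volume_mm3 = numeric(0))),
    class = "bml_report")
  path <- withr::local_tempfile(fileext = ".csv")
  write_report(empty, path)
  expect_equal(nrow(read.csv(path)), 0L)

  comp <- data.frame(bone = "tibia", region = "medial tibia",
                     volume_mm3 = 100)
  rep1 <- quantify(comp, c(1, 1, 1))
  write_report(rep1, path)
  got <- read.csv(path)
  expect_equal(nrow(got), 4L)
  expect_equal(got$volume_mm3[got$region == "medial tibia"], 100)
  expect_equal(sum(got$volume_mm3), 100)

  rep2 <- quantify(transform(comp, volume_mm3 = 150), c(1, 1, 1))
  write_report(volume_change(rep1, rep2), path)
  got <- read.csv(path)
  expect_equal(got$change_mm3[got$region == "medial tibia"], 50)
  expect_equal(got$change_mm3[got$region != "medial tibia"], rep(0, 3))
})
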