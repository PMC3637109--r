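test_that("Gaussian null recovers sample moments and rejects degenerate fits", {
  vox <- array(rep(c(0, 2), length.out = 30), dim = c(30, 1, 1))
  dom <- array(TRUE, dim = c(30, 1, 1))
  null <- fit_gaussian_null(vox, dom)
  expect_equal(null$mean, 1)
  expect_equal(null$sd, stats::sd(rep(c(0, 2), 15)))

  set.seed(11)
  big <- array(rnorm(1e5, mean = 40, sd = 6), dim = c(100, 100, 10))
  domb <- array(TRUE, dim = dim(big))
  nb <- fit_gaussian_null(big, domb)
  expect_lt(abs(nb$mean - 40) / 40, 0.01)
  expect_lt(abs(nb$sd - 6) / 6, 0.01)

  expect_error(fit_gaussian_null(array(5, c(40, 1, 1)),
                                 array(TRUE, c(40, 1, 1))), "degenerate")
  expect_error(fit_gaussian_null(vox, array(c(TRUE, rep(FALSE, 29)),
                                            c(30, 1, 1))), "30")
})

test_that("upper-tail p-values match the normal CDF", {
  null <- structure(list(mean = 10, sd = 2, n = 100),
                    class = "bml_gaussian_null")
  vox <- array(c(10, 10 + 1.96 * 2, rnorm(18, 10, 2)), dim = c(20, 1, 1))
  dom <- array(TRUE, dim = c(20, 1, 1))
  p <- pixel_pvalues(vox, dom, null)
  expect_equal(p[1], 0.5)
  expect_equal(p[2], 0.025, tolerance = 1e-4)
  expect_equal(p, 1 - pnorm((as.vector(vox) - 10) / 2), tolerance = 1e-12)
})

test_that("BH step-up matches the exhaustive oracle and its examples", {
  bh <- bh_threshold(c(0.001, 0.01, 0.02, 0.2, 0.9), q = 0.05)
  expect_equal(bh$n_reject, 3L)
  expect_equal(bh$reject, c(TRUE, TRUE, TRUE, FALSE, FALSE))

  ones <- bh_threshold(rep(1, 10), q = 0.05, intensities = rnorm(10))
  expect_equal(ones$n_reject, 0L)
  expect_identical(ones$threshold, Inf)

  set.seed(21)
  for (rep in 1:50) {
    m <- sample(1:200, 1)
    p <- runif(m)^sample(1:3, 1)
    q <- runif(1, 0.01, 0.3)
    expect_identical(bh_threshold(p, q)$reject, bh_oracle(p, q))
  }
})

test_that("BH rejections grow monotonically with q", {
  set.seed(22)
  p <- runif(500)^2
  r1 <- bh_threshold(p, 0.02)$reject
  r2 <- bh_threshold(p, 0.05)$reject
  r3 <- bh_threshold(p, 0.2)$reject
  expect_true(all(r2[r1]))
  expect_true(all(r3[r2]))
})

test_that("region-based refinement is a fixed point on noiseless two-level data", {
  d <- c(32, 32, 2)
  img <- array(0.2, dim = d)
  truth <- array(FALSE, dim = d)
  truth[10:22, 8:24, ] <- TRUE
  img[truth] <- 0.8
  dom <- array(TRUE, dim = d)
  out <- chan_vese_refine(truth, img, dom, mu = 0.28)
  expect_identical(out, truth)
})

test_that("region-based refinement recovers a noisy disc from a threshold init", {
  set.seed(5)
  d <- c(64, 64, 3)
  img <- array(rnorm(prod(d), 0.3, 0.04), dim = d)
  disc <- outer(1:64, 1:64, function(i, j) (i - 32)^2 + (j - 30)^2 <= 13^2)
  truth <- array(rep(disc, 3), dim = d)
  img[truth] <- img[truth] + 5 * 0.04
  dom <- array(TRUE, dim = d)
  init <- img > 0.3 + 2.5 * 0.04
  out <- chan_vese_refine(init, img, dom, mu = 0.28)
  expect_gte(dice(out, truth), 0.95)
  # energy never increases from initialization
  expect_lte(cv_energy(out, img, dom, 0.28),
             cv_energy(init, img, dom, 0.28) + 1e-9)
})

test_that("an empty initialization is a logged no-op", {
  d <- c(8, 8, 2)
  img <- array(rnorm(prod(d)), dim = d)
  dom <- array(TRUE, dim = d)
  expect_message(out <- chan_vese_refine(array(FALSE, d), img, dom),
                 "empty")
  expect_false(any(out))
})

test_that("two-pass segmentation unions a bright and a dim lesion", {
  set.seed(31)
  d <- c(40, 40, 6)
  sd0 <- 0.03
  img <- array(rnorm(prod(d), 0.25, sd0), dim = d)
  bright <- array(FALSE, d); bright[6:15, 6:15, 2:4] <- TRUE
  dim_bl <- array(FALSE, d); dim_bl[26:33, 24:31, 3:4] <- TRUE
  img[bright] <- img[bright] + 8 * sd0
  img[dim_bl] <- img[dim_bl] + 4 * sd0
  bone <- array(TRUE, d)
  cand <- two_pass_segment(bml_volume(img, c(1, 1, 1)), bone, bml_params())
  m1 <- cand$pass == 1L
  expect_gte(sum(m1 & bright) / sum(bright), 0.8)
  expect_equal(sum(m1 & dim_bl), 0)
  expect_gte(sum(cand$mask & dim_bl) / sum(dim_bl), 0.8)
  # union contains pass 1 and stays inside the bone
  expect_true(all(cand$mask[m1]))
  expect_true(all(!cand$mask | bone))
})

test_that("homogeneous bone yields an empty candidate mask", {
  set.seed(32)
  d <- c(30, 30, 5)
  img <- array(rnorm(prod(d), 0.25, 0.03), dim = d)
  bone <- array(TRUE, d)
  cand <- two_pass_segment(bml_volume(img, c(1, 1, 1)), bone, bml_params())
  expect_false(any(cand$mask))
})
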