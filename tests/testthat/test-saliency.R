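test_that("to_lab matches the standard sRGB -> CIELAB reference", {
  # white and black hit the reference-white definition
  lab <- to_lab(uniform_image(3, 4, c(255, 255, 255)))
  expect_equal(dim(lab$L), c(3L, 4L))
  expect_true(all(abs(lab$L - 100) < 0.01))
  expect_true(all(abs(lab$a) < 0.05) && all(abs(lab$b) < 0.05))

  lab0 <- to_lab(uniform_image(2, 2, c(0, 0, 0)))
  expect_true(all(abs(lab0$L) < 1e-6))
  expect_true(all(abs(lab0$a) < 1e-6) && all(abs(lab0$b) < 1e-6))

  # sRGB red against an independently computed reference conversion
  labr <- to_lab(uniform_image(1, 1, c(255, 0, 0)))
  expect_equal(labr$L[1, 1], 53.2406, tolerance = 0.01)
  expect_equal(labr$a[1, 1], 80.0923, tolerance = 0.01)
  expect_equal(labr$b[1, 1], 67.2028, tolerance = 0.01)

  expect_error(to_lab(array(0, c(2, 2, 2))), "H x W x 3")
})

test_that("gaussian_smooth preserves constants and mass, matches direct convolution", {
  expect_equal(gaussian_smooth(matrix(3.3, 8, 8), 2), matrix(3.3, 8, 8))

  imp <- matrix(0, 31, 31); imp[16, 16] <- 1
  expect_equal(sum(gaussian_smooth(imp, 1.5)), 1, tolerance = 1e-10)

  set.seed(42)
  p <- matrix(runif(25), 5, 5)
  expect_equal(gaussian_smooth(p, 1), brute_gaussian_blur(p, 1),
               tolerance = 1e-12)

  expect_error(gaussian_smooth(p, 0), "positive")
  expect_error(gaussian_smooth(p, -1), "positive")
})

test_that("compute_saliency is zero on constant images and peaks at a blob", {
  S <- compute_saliency(uniform_image(9, 9, c(230, 200, 40)))
  expect_true(all(abs(S) < 1e-9))

  img <- uniform_image(9, 9, c(230, 200, 40))
  img[4:6, 4:6, ] <- 20          # small dark blob at the center
  S <- compute_saliency(img, sigma = 1)
  peak <- which(S == max(S), arr.ind = TRUE)
  expect_true(all(peak[, 1] %in% 3:7) && all(peak[, 2] %in% 3:7))
})

test_that("compute_saliency equals the elementwise definition on random images", {
  set.seed(101)
  for (rep in 1:3) {
    img <- rgb_image(array(sample(0:255, 16 * 16 * 3, TRUE), c(16, 16, 3)))
    expect_equal(compute_saliency(img, sigma = 2),
                 brute_saliency(img, sigma = 2),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("saliency is transpose-equivariant and contrast-monotone", {
  set.seed(7)
  img <- rgb_image(array(sample(0:255, 12 * 18 * 3, TRUE), c(12, 18, 3)))
  timg <- rgb_image(aperm(img, c(2, 1, 3)))
  expect_equal(compute_saliency(timg, 2), t(compute_saliency(img, 2)),
               tolerance = 1e-9, ignore_attr = TRUE)

  # scaling contrast away from the mean never decreases the peak
  base <- uniform_image(16, 16, c(128, 128, 128))
  base[6:9, 6:9, ] <- 60
  stretch <- base
  stretch[6:9, 6:9, ] <- 20      # same blob, farther from the mean
  expect_gte(max(compute_saliency(stretch, 2)),
             max(compute_saliency(base, 2)))
})

test_that("normalize_saliency rescales to unit max and keeps zeros", {
  Z <- matrix(0, 4, 4)
  expect_equal(normalize_saliency(Z), Z, ignore_attr = TRUE)

  S <- matrix(c(0, 1, 3, 2), 2, 2)
  N <- normalize_saliency(S)
  expect_equal(max(N), 1)
  expect_equal(N[2, 1], 1 / 3)
  expect_true(attr(N, "normalized"))
})

test_that("threshold_mask applies the >= rule", {
  S <- matrix(c(0.04, 0.6, 0.2, 0.09), 2, 2)  # [[0.04,0.2],[0.6,0.09]]
  expect_equal(threshold_mask(S, 0.1), matrix(c(0L, 1L, 1L, 0L), 2, 2))
  expect_equal(threshold_mask(matrix(0, 3, 3), 0.1), matrix(0L, 3, 3))
  expect_equal(threshold_mask(S, 0), matrix(1L, 2, 2))  # rule is >=
  expect_error(threshold_mask(S, 1.2), "alpha")
})

test_that("mask shrinks monotonically as alpha grows", {
  set.seed(33)
  for (rep in 1:5) {
    S <- normalize_saliency(matrix(runif(400), 20, 20))
    alphas <- sort(runif(4))
    prev <- threshold_mask(S, alphas[1])
    for (a in alphas[-1]) {
      cur <- threshold_mask(S, a)
      expect_true(all(cur <= prev))   # 1-pixels are a subset
      prev <- cur
    }
  }
})
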