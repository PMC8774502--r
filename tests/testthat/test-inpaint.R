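test_that("unknown backends give an informative error", {
  img <- flat_image(c(0.5, 0.5, 0.5), 16)
  m <- matrix(FALSE, 16, 16); m[5:8, 5:8] <- TRUE
  expect_error(inpaint(img, m, "no-such-backend"), "harmonic")
  expect_true(all(c("harmonic", "identity") %in% inpaint_backends()))
})

test_that("inpainting with an empty mask is the identity", {
  img <- noisy_image(20, seed = 2)
  for (b in inpaint_backends()) {
    expect_identical(inpaint(img, matrix(FALSE, 20, 20), b), img)
  }
})

test_that("harmonic fill of a constant image reproduces the constant", {
  img <- flat_image(c(0.3, 0.6, 0.9), 24)
  m <- matrix(FALSE, 24, 24); m[5:15, 8:18] <- TRUE
  out <- inpaint(img, m, "harmonic")
  expect_equal(out, img, tolerance = 1e-8)
})

test_that("harmonic fill handles masks touching the image border", {
  img <- noisy_image(24, seed = 4)
  m <- matrix(FALSE, 24, 24); m[1:6, 1:6] <- TRUE
  out <- inpaint(img, m, "harmonic")
  expect_identical(out[, , 1][!m], img[, , 1][!m])
  expect_true(all(out >= 0 & out <= 1))
  expect_error(inpaint(img, matrix(TRUE, 24, 24), "harmonic"), "entire image")
})

test_that("random inpainting of skin-only images keeps SSIM high", {
  set.seed(21)
  skin <- generate_dermo_dataset(dermo_params(
    image_size = 96L, n_benign = 3L, n_malignant = 0L,
    patch_fraction_benign = 0, lesion_contrast_benign = 0.0, seed = 31L
  ))
  for (im in skin) {
    m <- random_elliptical_mask(dim(im$pixels), seed = 7L)
    out <- inpaint(im$pixels, m, "harmonic")
    expect_gte(ssim(im$pixels, out), 0.9)
  }
})

test_that("random elliptical masks are seeded, ring-bound and well-sized", {
  shape <- c(96L, 96L)
  expect_identical(random_elliptical_mask(shape, seed = 5L),
                   random_elliptical_mask(shape, seed = 5L))
  prm <- random_mask_params()
  ring <- prm$boundary_ring * 96
  set.seed(12)
  for (i in 1:50) {
    m <- random_elliptical_mask(shape, prm)
    expect_true(any(m))
    cy <- mean(which(m, arr.ind = TRUE)[, 1])
    cx <- mean(which(m, arr.ind = TRUE)[, 2])
    dist_edge <- min(cx - 0.5, cy - 0.5, 96.5 - cx, 96.5 - cy)
    # centres sit in the border band (up to the fit-inside clamp for the
    # largest ellipses, whose bounding radius can reach the ring width)
    expect_lte(dist_edge, max(ring, prm$axes_range[2] * 96) + 1)
  }
  # fixed semi-axes: pixel area within 2% of the continuous ellipse area,
  # and identical to a brute-force rasterisation
  prm2 <- random_mask_params(axes_range = c(0.1, 0.1))
  m <- random_elliptical_mask(shape, prm2, seed = 9L)
  expect_lt(abs(sum(m) - pi * (0.1 * 96)^2) / (pi * (0.1 * 96)^2), 0.02)
  set.seed(9L)
  ref <- shortcutaudit:::sample_ring_ellipse(96, 96, c(0.1, 0.1), 0.25)
  brute <- matrix(FALSE, 96, 96)
  for (r in 1:96) for (c in 1:96) {
    dx <- c - ref$cx; dy <- r - ref$cy
    u <- (dx * cos(ref$theta) + dy * sin(ref$theta)) / ref$a
    v <- (-dx * sin(ref$theta) + dy * cos(ref$theta)) / ref$b
    brute[r, c] <- u * u + v * v <= 1
  }
  expect_identical(m, brute)
})

test_that("ssim satisfies identity, symmetry and the zero-variance form", {
  a <- noisy_image(32, seed = 1)
  b <- noisy_image(32, seed = 2)
  expect_equal(ssim(a, a), 1.0)
  expect_equal(ssim(a, b), ssim(b, a), tolerance = 1e-12)
  mu_x <- 0.3; mu_y <- 0.7
  c1 <- 0.01^2
  expected <- (2 * mu_x * mu_y + c1) / (mu_x^2 + mu_y^2 + c1)
  expect_equal(ssim(flat_image(rep(mu_x, 3), 24), flat_image(rep(mu_y, 3), 24)),
               expected, tolerance = 1e-9)
  expect_error(ssim(a, noisy_image(16)), "identical shape")
})

test_that("ssim agrees with an independent windowed implementation", {
  for (seed in 1:3) {
    a <- noisy_image(24, seed = seed)
    b <- a + array(rnorm(24 * 24 * 3, 0, 0.1), dim = dim(a))
    b[] <- pmin(1, pmax(0, b))
    expect_equal(ssim(a, b), ssim_oracle(a, b), tolerance = 1e-6)
  }
})

test_that("validity check reports zero shift for pixel-blind classifiers", {
  ds <- Filter(function(im) !im$has_patch, small_confounded())[1:6]
  rep1 <- validity_check(constant_classifier(0.35), ds, seed = 2L)
  expect_equal(rep1$dp$mean, 0)
  expect_equal(rep1$dp$frac_outliers, 0)
  expect_length(rep1$outlier_ids, 0L)

  # identity backend: nothing changes, so dp = 0 and SSIM = 1 regardless of
  # the classifier
  clf <- memo("tiny_clf", {
    fit_reference(small_confounded(),
                  train_config(image_size = 96L, seed = 1L))
  })
  rep2 <- validity_check(clf, ds, backend = "identity", seed = 2L)
  expect_equal(rep2$dp$mean, 0)
  expect_equal(rep2$ssim$median, 1)

  expect_error(validity_check(clf, list(), seed = 1L), "empty")
  expect_error(validity_check(clf, small_confounded(), seed = 1L),
               "without patches")
})

test_that("the backend contract is enforced on every call", {
  img <- noisy_image(20, seed = 6)
  m <- matrix(FALSE, 20, 20); m[3:9, 3:9] <- TRUE
  bad_touch <- function(image, mask) { image[1, 1, 1] <- 0.123; image }
  bad_range <- function(image, mask) {
    for (ch in 1:3) { x <- image[, , ch]; x[mask] <- 1.5; image[, , ch] <- x }
    image
  }
  expect_error(inpaint(img, m, bad_touch), "outside the mask")
  expect_error(inpaint(img, m, bad_range), "out of \\[0, 1\\]")
})
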