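# Triangle thresholding, size-filtered segmentation and partition
# coefficients.

test_that("triangle threshold separates a two-level image", {
  img <- matrix(10, 40, 40)
  img[10:20, 10:20] <- 100
  thr <- triangle_threshold(img)
  expect_gt(thr, 10)
  expect_lt(thr, 100)
  expect_error(triangle_threshold(matrix(5, 10, 10)), "constant")
})

test_that("triangle threshold equals the exhaustive distance search", {
  set.seed(31)
  for (r in 1:8) {
    img <- matrix(stats::rgamma(64 * 64, shape = 2, scale = 30), 64, 64)
    img[sample(length(img), 400)] <- img[sample(length(img), 400)] + 200
    expect_equal(triangle_threshold(img), brute_triangle(img))
  }
})

test_that("inverting intensities mirrors the threshold about the midpoint", {
  set.seed(5)
  img <- matrix(stats::rgamma(64 * 64, 2, 0.02), 64, 64)
  thr <- triangle_threshold(img)
  inv <- max(img) + min(img) - img
  thr_inv <- triangle_threshold(inv)
  binw <- diff(range(img)) / 256
  expect_lt(abs(thr_inv - (max(img) + min(img) - thr)), 1.5 * binw)
})

test_that("the minimum-area filter removes sub-0.5 um^2 components", {
  r_crit <- sqrt(0.5 / pi)  # ~0.399 um
  # one disk below the limit: empty mask after filtering
  small <- gen_condensate_image(image_gen_params(
    shape = c(200, 200), pixel_size = 0.02,
    centres = cbind(2, 2), radii = 0.9 * r_crit,
    intensity_in = 500, intensity_bg = 100))
  m_small <- segment_condensates(small$green, small$pixel_size)
  expect_equal(sum(m_small$mask), 0L)
  expect_length(m_small$areas, 0L)
  # one disk above: retained
  big <- gen_condensate_image(image_gen_params(
    shape = c(200, 200), pixel_size = 0.02,
    centres = cbind(2, 2), radii = 1.1 * r_crit,
    intensity_in = 500, intensity_bg = 100))
  m_big <- segment_condensates(big$green, big$pixel_size)
  expect_length(m_big$areas, 1L)
  expect_gte(m_big$areas, 0.5)
})

test_that("segmentation keeps exactly the disks above the size filter", {
  centres <- rbind(c(2, 2), c(6, 2), c(10, 2), c(2, 6), c(6, 6),
                   c(10, 6), c(2, 10), c(6, 10))
  radii <- c(0.8, 0.9, 1.0, 0.7, 0.75, 0.2, 0.25, 0.3)  # um; 5 above
  img <- gen_condensate_image(image_gen_params(
    shape = c(128, 128), pixel_size = 0.1, centres = centres,
    radii = radii, intensity_in = 400, intensity_bg = 50))
  m <- segment_condensates(img$green, img$pixel_size)
  expect_length(m$areas, 5L)
})

test_that("segmentation is invariant to image orientation", {
  img <- gen_condensate_image(image_gen_params(
    shape = c(96, 96), pixel_size = 0.1,
    centres = rbind(c(3, 2), c(7, 6.5)), radii = c(1, 0.8),
    intensity_in = 300, intensity_bg = 40, noise_sd = 5, seed = 9))
  m <- segment_condensates(img$green, img$pixel_size)
  flipped <- img$green[nrow(img$green):1, ]
  m_fl <- segment_condensates(flipped, img$pixel_size)
  expect_identical(m_fl$mask, m$mask[nrow(m$mask):1, ])
  rotated <- t(img$green)[ncol(img$green):1, ]
  m_rot <- segment_condensates(rotated, img$pixel_size)
  expect_equal(sum(m_rot$mask), sum(m$mask))
  expect_equal(sort(m_rot$areas), sort(m$areas))
})

test_that("partition coefficients follow pixel arithmetic", {
  img <- gen_condensate_image(image_gen_params(
    shape = c(128, 128), pixel_size = 0.1, centres = cbind(6.4, 6.4),
    radii = 2, intensity_in = 500, intensity_bg = 100))
  # uniform image: coefficient 1 for any mask
  uni <- matrix(7, 128, 128)
  expect_equal(partition_coefficient(uni, img$truth$mask)$value, 1)
  # planted 5x ratio, mask from segmentation: coefficient 5
  m <- segment_condensates(img$green, img$pixel_size)
  expect_equal(partition_coefficient(img$green, m)$value, 5,
               tolerance = 1e-12)
  # empty and full masks are flagged undefined
  expect_true(partition_coefficient(uni, matrix(FALSE, 128, 128))$undefined)
  expect_true(partition_coefficient(uni, matrix(TRUE, 128, 128))$undefined)
})

test_that("partition coefficient is scale-invariant and offset-monotone", {
  img <- gen_condensate_image(image_gen_params(
    shape = c(96, 96), pixel_size = 0.1, centres = cbind(5, 5),
    radii = 1.5, intensity_in = 420, intensity_bg = 60))
  m <- segment_condensates(img$green, img$pixel_size)
  pc0 <- partition_coefficient(img$green, m)$value
  expect_equal(partition_coefficient(3.1 * img$green, m)$value, pc0)
  offsets <- c(0, 50, 200, 1000)
  pcs <- vapply(offsets, function(o) {
    partition_coefficient(img$green + o, m)$value
  }, numeric(1L))
  expect_true(all(diff(pcs) < 0))  # moves toward 1 from above
  expect_true(all(pcs > 1))
})

test_that("co-localisation reports no recruitment for a uniform red channel", {
  img <- gen_condensate_image(image_gen_params(
    shape = c(128, 128), pixel_size = 0.1, centres = cbind(6.4, 6.4),
    radii = 2, intensity_in = 500, intensity_bg = 100,
    red_in = 80, red_bg = 80))
  cl <- colocalisation(img)
  expect_equal(cl$green$value, 5, tolerance = 1e-12)
  expect_equal(cl$red$value, 1, tolerance = 1e-12)
  # recruited client: red enriched in the green-derived mask
  img2 <- gen_condensate_image(image_gen_params(
    shape = c(128, 128), pixel_size = 0.1, centres = cbind(6.4, 6.4),
    radii = 2, intensity_in = 500, intensity_bg = 100,
    red_in = 240, red_bg = 80))
  expect_equal(colocalisation(img2)$red$value, 3, tolerance = 1e-12)
})

test_that("replicate aggregation excludes undefined coefficients", {
  imgs <- lapply(1:3, function(s) {
    gen_condensate_image(image_gen_params(
      shape = c(96, 96), pixel_size = 0.1, centres = cbind(5, 5),
      radii = 1.5, intensity_in = 400, intensity_bg = 100,
      noise_sd = 8, seed = s))
  })
  res <- lapply(imgs, function(im) {
    partition_coefficient(im$green,
                          segment_condensates(im$green, im$pixel_size))
  })
  res[[4L]] <- partition_coefficient(matrix(1, 4, 4), matrix(FALSE, 4, 4))
  s <- partition_summary(res)
  expect_equal(s$n, 3L)
  expect_equal(s$n_excluded, 1L)
  expect_lt(abs(s$mean - 4) / 4, 0.1)
})

test_that("pipeline recovers the planted ratio under moderate noise", {
  img <- gen_condensate_image(image_gen_params(
    shape = c(128, 128), pixel_size = 0.1,
    centres = rbind(c(4, 4), c(9, 8)), radii = c(1.6, 1.2),
    intensity_in = 500, intensity_bg = 100, noise_sd = 15, seed = 77))
  m <- segment_condensates(img$green, img$pixel_size)
  pc <- partition_coefficient(img$green, m)
  expect_lt(abs(pc$value - 5) / 5, 0.1)
})
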