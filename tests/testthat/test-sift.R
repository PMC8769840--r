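test_that("scale space preserves constants and rejects tiny images", {
  ss <- build_scale_space(matrix(0.4, 32, 32))
  for (oct in ss$octaves) for (lv in oct) {
    expect_equal(range(lv), c(0.4, 0.4), tolerance = 1e-12)
  }
  expect_error(build_scale_space(matrix(0.5, 10, 10)), "16 x 16")
})

test_that("Gaussian blur preserves mass on an impulse and obeys the
          semigroup property", {
  img <- matrix(0, 33, 33); img[17, 17] <- 1
  for (s in c(1.2, 2.5)) {
    b <- wbcpipe:::gaussian_blur(img, s)
    expect_equal(sum(b), 1, tolerance = 1e-3)
    # compare center value against the closed-form 2-D Gaussian peak
    expect_equal(b[17, 17], 1 / (2 * pi * s^2), tolerance = 2e-2)
  }
  two <- wbcpipe:::gaussian_blur(wbcpipe:::gaussian_blur(img, 1.0), 1.5)
  one <- wbcpipe:::gaussian_blur(img, sqrt(1.0^2 + 1.5^2))
  expect_lt(max(abs(two - one)), 1e-6)
})

test_that("DoG is the levelwise difference and vanishes on ramps", {
  ss <- build_scale_space(matrix(0.5, 24, 24))
  dog <- build_dog(ss)
  for (oct in dog$octaves) for (lv in oct) expect_lt(max(abs(lv)), 1e-12)
  set.seed(5)
  ss2 <- build_scale_space(matrix(runif(24 * 24), 24, 24))
  dog2 <- build_dog(ss2)
  for (o in seq_along(dog2$octaves)) {
    for (i in seq_along(dog2$octaves[[o]])) {
      ref <- ss2$octaves[[o]][[i + 1]] - ss2$octaves[[o]][[i]]
      expect_equal(dog2$octaves[[o]][[i]], ref, tolerance = 1e-14)
    }
  }
  ramp <- matrix(seq(0, 1, length.out = 32), 32, 32)
  dog3 <- build_dog(build_scale_space(ramp))
  interior <- dog3$octaves[[1]][[1]][9:24, 9:24]
  expect_lt(max(abs(interior)), 1e-6)
})

test_that("detect_extrema matches a brute-force 26-neighbour scan", {
  set.seed(11)
  stack <- lapply(1:4, function(i) matrix(rnorm(15 * 15), 15, 15))
  dog <- structure(list(octaves = list(stack), sigmas_rel = 1.6 * 2^((0:4) / 3),
                        s = 3L, sigma0 = 1.6), class = "wbc_dog")
  kp <- detect_extrema(dog, contrast_thr = 0, edge_ratio = Inf, refine = FALSE)
  found <- integer(0)
  for (d in 2:3) for (r in 2:14) for (c in 2:14) {
    nb <- c()
    for (dl in -1:1) for (dr in -1:1) for (dc in -1:1) {
      if (dl | dr | dc) nb <- c(nb, stack[[d + dl]][r + dr, c + dc])
    }
    v <- stack[[d]][r, c]
    if (v > max(nb) || v < min(nb)) found <- c(found, r + 100 * c + 10000 * d)
  }
  expect_setequal(kp$row + 100 * kp$col + 10000 * kp$level, found)
})

test_that("a bright blob yields a keypoint at its center and constant images
          yield none", {
  img <- blob_image(64, cbind(32, 32), 3)
  kp <- sift_extract(img)
  expect_gte(nrow(kp), 1L)
  d <- sqrt((kp$y + 1 - 32)^2 + (kp$x + 1 - 32)^2)
  expect_lte(min(d), 2)
  expect_identical(nrow(sift_extract(matrix(0.5, 64, 64))), 0L)
})

test_that("orientation follows the gradient of a step edge and rotates with
          the image", {
  # vertical edge smoothed enough to survive blurring: gradient along +x
  img <- matrix(rep(stats::pnorm(seq(-8, 8, length.out = 64), 0, 2),
                    each = 64), 64, 64)
  img <- 0.25 + 0.5 * img
  ss <- build_scale_space(img)
  kp <- tibble::tibble(x = 31, y = 31, octave = 1L, level = 2L,
                       row = 32L, col = 32L, sigma = 2, value = 0.1,
                       polarity = 1L)
  ori <- assign_orientation(kp, ss)$orientation
  bin <- 2 * pi / 36
  expect_lt(min(abs(ori - 0), abs(ori - 2 * pi)), bin + 1e-9)
  # rotate image 90 degrees counter-clockwise: gradient turns to -y = +pi/2
  ssr <- build_scale_space(t(img)[64:1, ])
  orir <- assign_orientation(kp, ssr)$orientation
  expect_lt(abs(orir - (ori + 3 * pi / 2) %% (2 * pi)), bin + 1e-9)
  # flat window: orientation zero with a warning
  ssf <- build_scale_space(matrix(0.5, 64, 64))
  expect_warning(kf <- assign_orientation(kp, ssf), "flat")
  expect_identical(kf$orientation, 0)
})

test_that("descriptors are 128-long, non-negative, unit norm; flat windows
          are dropped", {
  img <- blob_image(96, cbind(c(30, 60), c(40, 70)), c(3, 4))
  kp <- sift_extract(img)
  expect_gte(nrow(kp), 2L)
  D <- descriptor_matrix(kp)
  expect_identical(ncol(D), 128L)
  expect_true(all(D >= 0))
  expect_equal(unname(sqrt(rowSums(D^2))), rep(1, nrow(D)), tolerance = 1e-9)
  # flat window drop
  ssf <- build_scale_space(matrix(0.5, 64, 64))
  kpf <- tibble::tibble(x = 31, y = 31, octave = 1L, level = 2L, row = 32L,
                        col = 32L, sigma = 2, value = 0, polarity = 1L,
                        orientation = 0)
  expect_null(compute_descriptor(kpf, ssf))
})

test_that("extraction is deterministic and rotation-invariant", {
  set.seed(21)
  ctr <- cbind(runif(6, 20, 108), runif(6, 20, 108))
  sg <- runif(6, 2.5, 5)
  img <- blob_image(128, ctr, sg)
  k1 <- sift_extract(img)
  k2 <- sift_extract(img)
  expect_identical(k1, k2)
  # 90-degree counter-clockwise rotation
  imgr <- t(img)[ncol(img):1, ]
  kr <- sift_extract(imgr)
  D <- descriptor_matrix(k1); Dr <- descriptor_matrix(kr)
  matched <- 0L; close_desc <- 0L
  for (i in seq_len(nrow(k1))) {
    # (x, y) -> (y, W - 1 - x) under this rotation
    d2 <- (kr$y - (ncol(img) - 1 - k1$x[i]))^2 + (kr$x - k1$y[i])^2
    j <- which.min(d2)
    if (d2[j] <= 9) {
      matched <- matched + 1L
      if (sqrt(sum((D[i, ] - Dr[j, ])^2)) <= 0.3) close_desc <- close_desc + 1L
    }
  }
  expect_gte(matched / nrow(k1), 0.8)
  expect_gte(close_desc / matched, 0.8)
})

test_that("doubling the image scale preserves keypoints and descriptors", {
  ctr <- cbind(c(30, 40, 70, 95, 100, 60), c(35, 90, 60, 30, 100, 110))
  sg <- c(3, 4, 5, 3.5, 4.5, 3)
  k1 <- sift_extract(blob_image(128, ctr, sg))
  k2 <- sift_extract(blob_image(256, 2 * ctr - 0.5, 2 * sg))
  D1 <- descriptor_matrix(k1); D2 <- descriptor_matrix(k2)
  matched <- 0L; close_desc <- 0L
  for (i in seq_len(nrow(k1))) {
    d2 <- (k2$y - (2 * k1$y[i] + 0.5))^2 + (k2$x - (2 * k1$x[i] + 0.5))^2
    j <- which.min(d2)
    if (d2[j] <= 16) {
      matched <- matched + 1L
      if (sqrt(sum((D1[i, ] - D2[j, ])^2)) <= 0.3) close_desc <- close_desc + 1L
    }
  }
  expect_gte(matched / nrow(k1), 0.5)
  expect_gte(close_desc, 1L)
})

test_that("keypoints agree with an independent SIFT implementation", {
  py <- Sys.which("python")
  skip_if(py == "", "python not on PATH")
  has_skimage <- suppressWarnings(system2(
    py, c("-c", shQuote("import skimage.feature")),
    stdout = FALSE, stderr = FALSE)) == 0L
  skip_if_not(has_skimage, "scikit-image not importable")
  set.seed(5)
  ctr <- cbind(runif(8, 20, 108), runif(8, 20, 108))
  sg <- runif(8, 2.5, 5)
  img <- blob_image(128, ctr, sg)
  kp <- sift_extract(img)
  expect_gte(nrow(kp), 3L)
  tmp_png <- tempfile(fileext = ".png")
  tmp_csv <- tempfile(fileext = ".csv")
  tmp_out <- tempfile(fileext = ".txt")
  png::writePNG(img, tmp_png)
  utils::write.csv(data.frame(x = kp$x, y = kp$y), tmp_csv, row.names = FALSE)
  script <- sprintf("
import numpy as np, csv
import imageio.v3 as iio
from skimage.feature import SIFT
img = iio.imread('%s').astype(float) / 255.0
s = SIFT(); s.detect_and_extract(img)
ours = np.loadtxt('%s', delimiter=',', skiprows=1, ndmin=2)
matched = sum(
    np.sqrt((s.keypoints[:, 0] - y) ** 2 +
            (s.keypoints[:, 1] - x) ** 2).min() <= 3
    for x, y in ours)
print(matched, len(ours))
", tmp_png, tmp_csv)
  tmp_py <- tempfile(fileext = ".py")
  writeLines(script, tmp_py)
  status <- system2(py, tmp_py, stdout = tmp_out, stderr = FALSE)
  skip_if(status != 0L, "external SIFT oracle failed to run")
  res <- scan(tmp_out, what = integer(), quiet = TRUE)
  expect_gte(res[1] / res[2], 0.5)
})
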