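test_that("warping by a zero field is the exact identity", {
  set.seed(1)
  img <- matrix(runif(15 * 11), 15, 11)
  z <- constantField(15, 11, 0, 0)
  expect_identical(warpRaster(img, z, "bilinear"), img)
  m <- (img > 0.5) * 1
  expect_identical(warpRaster(m, z, "nearest"), m)
})

test_that("integer-translation fields match the explicit index-shift oracle", {
  set.seed(2)
  img <- matrix(runif(20 * 20), 20, 20)
  for (sh in list(c(3, 0), c(0, -2), c(-4, 5))) {
    f <- constantField(20, 20, sh[1], sh[2])
    w <- warpRaster(img, f, "bilinear")
    expect_equal(w, shiftOracle(img, sh[1], sh[2]), tolerance = 1e-14)
    wn <- warpRaster(img, f, "nearest")
    expect_equal(wn, shiftOracle(img, sh[1], sh[2]), tolerance = 1e-14)
  }
})

test_that("half-pixel sampling of a linear ramp interpolates midpoints", {
  ramp <- matrix(rep(seq(0, 1, length.out = 16), each = 16), 16, 16,
                 byrow = TRUE)   # value varies along columns
  w <- warpRaster(ramp, constantField(16, 16, 0.5, 0), "bilinear")
  expect_equal(w[, 1:15], (ramp[, 1:15] + ramp[, 2:16]) / 2,
               tolerance = 1e-12)
})

test_that("nearest warping keeps masks strictly binary; bilinear on a mask errors", {
  m <- blobMask(24, 24, seed = 3)
  f <- constantField(24, 24, 1.3, -0.7)
  wm <- warpRaster(m, f, "nearest")
  expect_true(all(wm %in% c(0, 1)))
  expect_error(warpRaster(m, f, "bilinear"), "nearest")
})

test_that("padding rules govern out-of-bounds samples", {
  img <- matrix(runif(10 * 10), 10, 10)
  f <- constantField(10, 10, 4, 0)
  wz <- warpRaster(img, f, "bilinear", "zeros")
  expect_true(all(wz[, 7:10] == 0))
  wb <- warpRaster(img, f, "bilinear", "border")
  expect_equal(wb[, 7:10], img[, c(10, 10, 10, 10)], tolerance = 1e-14)
})

test_that("integer translations compose in the interior", {
  set.seed(4)
  img <- matrix(runif(30 * 30), 30, 30)
  w12 <- warpRaster(warpRaster(img, constantField(30, 30, 2, 1)),
                    constantField(30, 30, 1, 2))
  w3 <- warpRaster(img, constantField(30, 30, 3, 3))
  expect_equal(w12[1:25, 1:25], w3[1:25, 1:25], tolerance = 1e-14)
})

test_that("warp gradients with respect to the field match finite differences", {
  set.seed(5)
  img <- matrix(runif(12 * 12), 12, 12)
  dx <- matrix(runif(144, -1.2, 1.2), 12, 12) + 0.31  # off integer kinks
  dy <- matrix(runif(144, -1.2, 1.2), 12, 12) + 0.17
  g <- lungreg:::warpBilinearGrad(img, dx, dy)
  eps <- 1e-6
  for (k in sample(144, 6)) {
    dxp <- dx; dxp[k] <- dxp[k] + eps
    dxm <- dx; dxm[k] <- dxm[k] - eps
    num <- (lungreg:::warpBilinearGrad(img, dxp, dy)$out[k] -
              lungreg:::warpBilinearGrad(img, dxm, dy)$out[k]) / (2 * eps)
    expect_equal(num, g$dcs[k], tolerance = 1e-5)
    dyp <- dy; dyp[k] <- dyp[k] + eps
    dym <- dy; dym[k] <- dym[k] - eps
    num <- (lungreg:::warpBilinearGrad(img, dx, dyp)$out[k] -
              lungreg:::warpBilinearGrad(img, dx, dym)$out[k]) / (2 * eps)
    expect_equal(num, g$drs[k], tolerance = 1e-5)
  }
})

test_that("affine transforms move content as specified", {
  p <- generatePhantom(smallConfig(seed = 8), 0.2)
  id <- identityAffine()
  expect_identical(applyAffine(p$image, id, "bilinear"), p$image)
  ## pure integer translation moves the mask centroid by exactly (tx, ty)
  tr <- new("AffineParams", rotation = 0, scale = 1,
            translationX = 5 / 64, translationY = -3 / 64, shear = 0)
  m2 <- applyAffine(p$mask, tr, "nearest")
  c1 <- which(p$mask == 1, arr.ind = TRUE)
  c2 <- which(m2 == 1, arr.ind = TRUE)
  expect_equal(colMeans(c2) - colMeans(c1), c(row = -3, col = 5),
               tolerance = 1e-9)
})
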