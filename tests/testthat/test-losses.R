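test_that("NCC loss closed forms: self-correlation, constants, affine invariance", {
  set.seed(1)
  I <- matrix(runif(16 * 16), 16)
  expect_lt(abs(nccLoss(I, I) + 1), 1e-3)
  expect_equal(nccLoss(I, matrix(0.5, 16, 16)), 0)
  ## affine intensity invariance: J = 2 I2 + 0.1 stays inside [0,1]; the
  ## invariance is exact as the eps guard vanishes
  I2 <- matrix(runif(256, 0.05, 0.4), 16)
  expect_equal(nccLoss(I2, 2 * I2 + 0.1, eps = 1e-12),
               nccLoss(I2, I2, eps = 1e-12), tolerance = 1e-6)
  expect_gte(nccLoss(I, 1 - I), -1)  # bounded below by -1 regardless
  expect_error(nccLoss(I, matrix(0.5, 8, 8)), "dimensions")
})

test_that("the two printed NCC algebraic forms agree numerically", {
  set.seed(2)
  worst <- 0
  for (r in 1:100) {
    I <- matrix(runif(256), 16); J <- matrix(runif(256), 16)
    worst <- max(worst, nccEquivalenceCheck(I, J))
  }
  expect_lt(worst, 1e-8)
  C <- matrix(0.3, 16, 16)
  expect_equal(nccEquivalenceCheck(C, C), 0)
  I <- matrix(runif(256), 16)
  expect_lt(abs(nccLoss(I, I) + 1), 1e-3)
})

test_that("TV loss matches its printed definition on constructed fields", {
  expect_equal(tvLoss(constantField(8, 8, 3.2, -1.7)), 0)
  ## x-plane t(i,j) = i has unit forward differences along rows
  grid <- matrix(0:(7), 8, 8)
  expect_equal(tvLoss(displacementField(grid, matrix(0, 8, 8))), 0.5)
  gridC <- matrix(0:7, 8, 8, byrow = TRUE)
  expect_equal(tvLoss(displacementField(grid, gridC)), 1.0)
  ## translation invariance: adding constants leaves it unchanged
  f <- displacementField(matrix(rnorm(64), 8), matrix(rnorm(64), 8))
  g <- displacementField(f@dx + 5, f@dy - 2)
  expect_equal(tvLoss(f), tvLoss(g), tolerance = 1e-12)
  expect_gte(tvLoss(f, mode = "full"), 0)
})

test_that("BCE loss closed forms under clamping", {
  ones <- matrix(1, 6, 6)
  expect_lt(bceLoss(ones, ones), 1e-6)
  expect_equal(bceLoss(matrix(0.5, 6, 6), ones), log(2), tolerance = 1e-12)
  expect_equal(bceLoss(1 - ones, ones, clip = 1e-7), -log(1e-7),
               tolerance = 1e-3)
  expect_error(bceLoss(matrix(0.5, 6, 6), matrix(1, 3, 3)), "dimensions")
})

test_that("latent L2 loss is the mean over all code entries", {
  z3 <- new("EncoderCode", values = matrix(0, 3, 3))
  one <- matrix(0, 3, 3); one[2, 2] <- 3
  expect_equal(l2LatentLoss(new("EncoderCode", values = one), z3), 1.0)
  a <- new("EncoderCode", values = matrix(1, 2, 2))
  b <- new("EncoderCode", values = matrix(3, 2, 2))
  expect_equal(l2LatentLoss(a, b), 4.0)
  expect_equal(l2LatentLoss(a, a), 0)
})

test_that("the composite loss decomposes into its independently computed terms", {
  set.seed(3)
  p <- generatePhantom(phantomConfig(imageSize = 32, seed = 5), 0.2)
  q <- generatePhantom(phantomConfig(imageSize = 32, seed = 6), 0.6)
  f <- displacementField(matrix(rnorm(32 * 32, 0, 0.8), 32),
                         matrix(rnorm(32 * 32, 0, 0.8), 32))
  enc <- buildAutoencoder(netConfig(32, baseChannels = 2L, depth = 3L,
                                    seed = 2L))
  w <- lossWeights()
  br <- compositeLoss(p$image, q$image, p$mask, q$mask, f, w, enc)
  wI <- lungreg:::warpCore(p$image, f, "bilinear", "zeros")
  wS <- lungreg:::warpCore(p$mask, f, "bilinear", "zeros")
  expect_equal(br@ncc, -nccLoss(wI, q$image, w@eps), tolerance = 1e-12)
  expect_equal(br@tv, tvLoss(f), tolerance = 1e-12)
  expect_equal(br@bce, bceLoss(wS, q$mask), tolerance = 1e-12)
  expect_equal(br@l2,
               l2LatentLoss(new("EncoderCode",
                                values = lungreg:::aeEncodeForward(enc@params, wS)$code),
                            encodeMask(enc, q$mask)),
               tolerance = 1e-12)
  expect_equal(br@total,
               -w@lambdaNcc * br@ncc + w@lambdaTv * br@tv +
                 w@lambdaBce * br@bce + w@lambdaL2 * br@l2,
               tolerance = 1e-9)
  ## zero field on a self-pair: total is essentially the -NCC term
  z <- constantField(32, 32, 0, 0)
  brz <- compositeLoss(p$image, p$image, p$mask, p$mask, z, w, enc)
  expect_lt(abs(brz@ncc - 1), 5e-3)   # eps guard slightly deflates |NCC|
  expect_equal(brz@tv, 0)
  expect_lt(brz@bce, 1e-6)
  expect_equal(brz@l2, 0, tolerance = 1e-12)
  expect_lt(abs(brz@total + 1), 6e-3)
  ## weight masking reduces the total to the NCC term alone
  w0 <- lossWeights(lambdaTv = 0, lambdaBce = 0, lambdaL2 = 0)
  br0 <- compositeLoss(p$image, q$image, p$mask, q$mask, f, w0)
  expect_equal(br0@total, -br0@ncc, tolerance = 1e-12)
  expect_error(compositeLoss(p$image, q$image, p$mask, q$mask, f,
                             lossWeights()),
               "encoder")
})

test_that("analytic gradients of the training loss match finite differences", {
  set.seed(6)
  s <- 16
  I <- matrix(runif(s * s), s); J <- matrix(runif(s * s), s)
  SI <- blobMask(s, s, 7); SJ <- blobMask(s, s, 8)
  enc <- buildAutoencoder(tinyNetConfig(seed = 9))
  w <- lossWeights()
  model <- buildVectorCNN(tinyNetConfig(seed = 10), fieldStride = 2L)
  params <- model@params
  params$head$b <- c(0.37, -0.23)   # keep the field off bilinear kinks
  lossAt <- function(p)
    lungreg:::registrationPairGrad(p, I, J, SI, SJ, enc@params, w)$loss
  r <- lungreg:::registrationPairGrad(params, I, J, SI, SJ, enc@params, w)
  eps <- 1e-5
  slots <- list(
    list(get = function(p) p$enc[[1]]$W,
         set = function(p, v) { p$enc[[1]]$W <- v; p },
         g = r$grads$enc[[1]]$W),
    list(get = function(p) p$bott$W,
         set = function(p, v) { p$bott$W <- v; p },
         g = r$grads$bott$W),
    list(get = function(p) p$dec[[2]]$W,
         set = function(p, v) { p$dec[[2]]$W <- v; p },
         g = r$grads$dec[[2]]$W),
    list(get = function(p) p$head$W,
         set = function(p, v) { p$head$W <- v; p },
         g = r$grads$head$W))
  for (sl in slots) {
    for (k in sample(length(sl$get(params)), 3)) {
      up <- sl$get(params); up[k] <- up[k] + eps
      dn <- sl$get(params); dn[k] <- dn[k] - eps
      num <- (lossAt(sl$set(params, up)) - lossAt(sl$set(params, dn))) /
        (2 * eps)
      expect_lt(abs(num - sl$g[k]), 1e-6 + 1e-3 * abs(num))
    }
  }
})
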