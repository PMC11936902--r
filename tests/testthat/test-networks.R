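test_that("network configurations enforce the size/depth contract", {
  expect_equal(latentGrid(netConfig(96, depth = 4L)), 6)
  expect_error(netConfig(90, depth = 4L), "divisible")
  expect_error(netConfig(96, depth = 0L), "depth")
})

test_that("the segmenter obeys its shape and determinism contracts", {
  cfg <- netConfig(32, baseChannels = 2L, depth = 2L, seed = 5L)
  m1 <- buildSegmenter(cfg)
  img <- matrix(runif(32 * 32), 32)
  p <- predictSegmenter(m1, img)
  expect_equal(dim(p), c(32, 32))
  expect_true(all(p > 0 & p < 1))
  m2 <- buildSegmenter(cfg)      # same seed: identical weights
  expect_identical(predictSegmenter(m2, img), p)
})

test_that("the deformation predictor starts near the identity transform", {
  cfg <- netConfig(32, baseChannels = 2L, depth = 2L, seed = 6L)
  m <- buildVectorCNN(cfg, fieldStride = 2L)
  a <- matrix(runif(32 * 32), 32); b <- matrix(runif(32 * 32), 32)
  f <- predictField(m, a, b)
  expect_equal(dim(fieldX(f)), c(32, 32))
  expect_lt(mean(abs(c(fieldX(f), fieldY(f)))), 0.5)
  f2 <- predictField(buildVectorCNN(cfg, fieldStride = 2L), a, b)
  expect_identical(fieldX(f2), fieldX(f))
  expect_error(buildVectorCNN(cfg, fieldStride = 3L), "power of two")
  expect_error(buildVectorCNN(cfg, fieldStride = 8L), "depth")
})

test_that("the autoencoder code grid follows n = size / 2^depth and encoding is deterministic", {
  cfg <- netConfig(96, baseChannels = 2L, depth = 4L, seed = 7L)
  ae <- buildAutoencoder(cfg)
  msk <- generatePhantom(phantomConfig(imageSize = 96, seed = 3), 0.2)$mask
  code <- encodeMask(ae, msk)
  expect_equal(dim(code@values), c(6, 6))
  expect_identical(encodeMask(ae, msk)@values, code@values)
  rec <- decodeCode(ae, code)
  expect_equal(dim(rec), c(96, 96))
  expect_true(all(rec > 0 & rec < 1))
})

test_that("denoising training reconstructs held-out lung masks", {
  msks <- lapply(1:14, function(s)
    generatePhantom(phantomConfig(imageSize = 64, seed = 100 + s),
                    (s %% 5) / 5)$mask)
  ae <- trainAutoencoder(msks[1:10], noiseRate = 0.05, epochs = 40L,
                         seed = 2L,
                         config = netConfig(64, baseChannels = 6L,
                                            depth = 3L, seed = 2L))
  expect_true(all(is.finite(ae@lossLog)))
  ## training loss decreased over the run
  nb <- length(ae@lossLog)
  expect_lt(mean(ae@lossLog[(nb - 2):nb]), ae@lossLog[1])
  ## held-out reconstruction: binarized decode(encode(mask)) matches well
  recDsc <- vapply(msks[11:14], function(m) {
    r <- decodeCode(ae, encodeMask(ae, m))
    dsc(binarizeMask(r), m)
  }, numeric(1))
  expect_gt(mean(recDsc), 0.95)
  ## training targets are strictly binary lung masks (single foreground
  ## label; no other structures enter the anatomical prior)
  expect_true(all(vapply(msks, function(m) all(m %in% c(0, 1)), logical(1))))
  expect_error(trainAutoencoder(msks[1]), "at least 2")
})

test_that("autoencoder smoke run with zero corruption logs a finite loss", {
  msks <- lapply(1:4, function(s)
    generatePhantom(phantomConfig(imageSize = 32, seed = s), 0.1)$mask)
  ae <- trainAutoencoder(msks, noiseRate = 0, epochs = 1L, seed = 1L,
                         config = netConfig(32, baseChannels = 2L,
                                            depth = 3L, seed = 1L))
  expect_true(length(ae@lossLog) >= 1 && all(is.finite(ae@lossLog)))
})

test_that("segmenter training reaches high Dice on held-out phantoms", {
  corpus <- simulateTrainingCorpus(46, imageSize = 64, seed = 21)
  seg <- trainSegmenter(corpus$images[1:40], corpus$masks[1:40],
                        epochs = 4L, seed = 3L,
                        config = netConfig(64, baseChannels = 8L,
                                           depth = 3L, seed = 3L))
  heldDsc <- vapply(41:46, function(i) {
    pred <- binarizeMask(predictSegmenter(seg, corpus$images[[i]]))
    dsc(pred, corpus$masks[[i]])
  }, numeric(1))
  expect_gt(mean(heldDsc), 0.9)
})
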