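test_that("phantom generation is deterministic and motion-free at zero amplitude", {
  cfg0 <- smallConfig(seed = 3, breathingAmplitude = 0)
  a <- generatePhantom(cfg0, 0)
  b <- generatePhantom(cfg0, 0.5)
  expect_identical(a$image, b$image)
  expect_identical(a$mask, b$mask)
  cfg <- smallConfig(seed = 3, breathingAmplitude = 0.15)
  p1 <- generatePhantom(cfg, 0.25)
  p2 <- generatePhantom(cfg, 0.25)
  expect_identical(p1$image, p2$image)
  expect_identical(p1$mask, p2$mask)
})

test_that("breathing moves the lung support", {
  cfg <- smallConfig(seed = 7, breathingAmplitude = 0.15)
  p0 <- generatePhantom(cfg, 0)
  p5 <- generatePhantom(cfg, 0.5)
  expect_lt(dsc(p0$mask, p5$mask), 1.0)
  ## diaphragm analogue moves down by amplitude * sin(pi/2) * lung height
  bottom0 <- max(which(rowSums(p0$mask) > 0))
  bottom5 <- max(which(rowSums(p5$mask) > 0))
  expect_gt(bottom5, bottom0)
})

test_that("phantom contracts hold: intensity range, mask support, foreground fraction", {
  for (seed in c(1, 9, 33)) {
    p <- generatePhantom(smallConfig(seed = seed), 0.4)
    expect_true(all(p$image >= 0 & p$image <= 1))
    expect_true(all(p$mask %in% c(0, 1)))
    fg <- mean(p$mask)
    expect_gt(fg, 0.05); expect_lt(fg, 0.6)
    ## lungs are brightened exactly on the mask support: interior of the
    ## support is brighter than the immediately surrounding tissue
    expect_gt(mean(p$image[p$mask == 1]), mean(p$image[p$mask == 0]))
  }
})

test_that("a breathing sequence has consistent lengths and a zero reference field", {
  cfg <- phantomConfig(imageSize = 64, nFrames = 11, seed = 2)
  sq <- generateBreathingSequence(cfg)
  expect_length(frames(sq), 11)
  expect_length(masks(sq), 11)
  expect_length(trueFields(sq), 11)
  expect_true(all(fieldX(trueFields(sq)[[1]]) == 0))
  expect_true(all(fieldY(trueFields(sq)[[1]]) == 0))
  one <- generateBreathingSequence(smallConfig(seed = 2, nFrames = 1))
  expect_length(frames(one), 1)
  expect_true(all(fieldY(trueFields(one)[[1]]) == 0))
  ## bit-identical regeneration
  sq2 <- generateBreathingSequence(cfg)
  expect_identical(frames(sq), frames(sq2))
  expect_identical(trueFields(sq)[[5]]@dy, trueFields(sq2)[[5]]@dy)
})

test_that("warping frames by the ground-truth field recovers frame 1", {
  sq <- generateBreathingSequence(smallConfig(seed = 4, nFrames = 5,
                                              breathingAmplitude = 0.15))
  for (k in 2:4) {
    w <- warpRaster(frames(sq)[[k]], trueFields(sq)[[k]], "bilinear")
    expect_lt(msd(w, frames(sq)[[1]]),
              msd(frames(sq)[[k]], frames(sq)[[1]]))
  }
})

test_that("mean true displacement is monotone in breathing amplitude", {
  mags <- vapply(c(0, 0.05, 0.1, 0.2), function(a) {
    sq <- generateBreathingSequence(smallConfig(seed = 5, nFrames = 3,
                                                breathingAmplitude = a))
    f <- trueFields(sq)[[2]]
    mean(sqrt(fieldX(f)^2 + fieldY(f)^2))
  }, numeric(1))
  expect_true(all(diff(mags) >= 0))
  expect_equal(mags[1], 0)
})

test_that("invalid phantom configurations are rejected", {
  expect_error(phantomConfig(imageSize = 16), "imageSize")
  expect_error(phantomConfig(breathingAmplitude = 0.5), "breathingAmplitude")
  expect_error(phantomConfig(noiseSd = -1), "noiseSd")
  expect_error(generatePhantom(smallConfig(), 1.2), "phase")
})

test_that("affine sampling respects ranges, seeds and degenerate identity", {
  idRanges <- list(rotation = c(0, 0), scale = c(1, 1),
                   translation = c(0, 0), shear = c(0, 0))
  id <- sampleAffine(1, idRanges)
  expect_equal(id@rotation, 0); expect_equal(id@scale, 1)
  expect_equal(id@translationX, 0); expect_equal(id@shear, 0)
  a <- sampleAffine(42); b <- sampleAffine(42)
  expect_identical(a, b)
  rot <- vapply(1:1000, function(s)
    sampleAffine(s, list(rotation = c(-10, 10), scale = c(1, 1),
                         translation = c(0, 0), shear = c(0, 0)))@rotation,
    numeric(1))
  expect_gte(min(rot), -10); expect_lte(max(rot), 10)
  expect_gt(max(rot), 5); expect_lt(min(rot), -5)   # actually explores range
  expect_error(sampleAffine(1, list(rotation = c(2, -2), scale = c(1, 1),
                                    translation = c(0, 0), shear = c(0, 0))),
               "rotation")
})
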