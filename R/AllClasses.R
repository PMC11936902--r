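#' @include generics.R
NULL

## Rasters are plain numeric matrices (row 1 = image top, column 1 = left;
## intensities in [0,1]); binary masks are matrices with values in {0,1}.
## The S4 classes below hold the structured objects built on top of them.

#' Configuration of the breathing phantom generator
#'
#' Describes one synthetic chest-like scene and its breathing motion.
#' The generator draws two vertically elongated super-elliptic "lungs"
#' on a darker elliptic thorax with rib-like sinusoidal texture; the
#' diaphragm analogue (lower lung boundary) moves downward by
#' `breathingAmplitude * sin(pi * phase) * lungHeight` pixels at breathing
#' phase `phase`, with the displacement decaying linearly to zero at the
#' lung apex and a small coupled lateral expansion.
#'
#' @slot imageSize integer, pixels per side (square frames), >= 32.
#' @slot nFrames integer, number of frames in a sequence, >= 1.
#' @slot breathingAmplitude numeric in [0, 0.3]; fraction of the lung height
#'   displaced at full inspiration.
#' @slot textureStrength numeric in [0, 1]; contrast of the rib-like bands.
#' @slot noiseSd numeric >= 0; SD of additive Gaussian intensity noise
#'   (intensity units, images live in [0,1]).
#' @slot seed integer RNG seed; identical configurations are bit-reproducible.
#' @seealso [phantomConfig()], [generatePhantom()], [generateBreathingSequence()]
#' @export
setClass("PhantomConfig",
  representation(imageSize = "integer", nFrames = "integer",
                 breathingAmplitude = "numeric", textureStrength = "numeric",
                 noiseSd = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@imageSize) != 1L || object@imageSize < 32L)
      msg <- c(msg, "imageSize must be a single integer >= 32")
    if (length(object@nFrames) != 1L || object@nFrames < 1L)
      msg <- c(msg, "nFrames must be >= 1")
    if (object@breathingAmplitude < 0 || object@breathingAmplitude > 0.3)
      msg <- c(msg, "breathingAmplitude must lie in [0, 0.3]")
    if (object@textureStrength < 0 || object@textureStrength > 1)
      msg <- c(msg, "textureStrength must lie in [0, 1]")
    if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' Dense 2-D displacement field
#'
#' Two H x W planes of per-pixel displacements in pixel units under the
#' backward-mapping convention: a warped output at pixel p = (row, col)
#' samples the input at p + (dy, dx). `dx` displaces along columns (x),
#' `dy` along rows (y).
#'
#' @slot dx numeric matrix, column displacements.
#' @slot dy numeric matrix, row displacements (same dimensions as `dx`).
#' @seealso [displacementField()], [warpRaster()], [writeField()]
#' @export
setClass("DisplacementField",
  representation(dx = "matrix", dy = "matrix"),
  validity = function(object) {
    if (!all(dim(object@dx) == dim(object@dy)))
      return("dx and dy must have identical dimensions")
    if (any(dim(object@dx) < 2L))
      return("field planes must be at least 2 x 2")
    if (!all(is.finite(object@dx)) || !all(is.finite(object@dy)))
      return("field values must be finite")
    TRUE
  })

#' A simulated breathing sequence with ground truth
#'
#' Ordered phantom frames over one breathing cycle, their binary lung
#' masks, and for every frame the dense displacement field that warps it
#' back onto frame 1 (the ground-truth motion of the generative model).
#'
#' @slot frames list of H x W intensity matrices in [0,1].
#' @slot masks list of H x W binary matrices ({0,1}).
#' @slot trueFields list of [DisplacementField-class]; `trueFields[[k]]`
#'   warps `frames[[k]]` onto `frames[[1]]`.
#' @slot config the generating [PhantomConfig-class].
#' @export
setClass("PhantomSequence",
  representation(frames = "list", masks = "list", trueFields = "list",
                 config = "PhantomConfig"),
  validity = function(object) {
    n <- length(object@frames)
    if (length(object@masks) != n || length(object@trueFields) != n)
      return("frames, masks and trueFields must have equal length")
    area <- object@config@imageSize^2
    for (k in seq_len(n)) {
      m <- object@masks[[k]]
      if (!all(m %in% c(0, 1))) return("masks must be strictly binary")
      fg <- sum(m) / area
      if (fg <= 0.05 || fg >= 0.6)
        return(sprintf("mask %d foreground fraction %.3f outside (0.05, 0.6)", k, fg))
    }
    TRUE
  })

#' Network architecture configuration
#'
#' Shared configuration of the three learnable components (segmenter,
#' deformation predictor, denoising autoencoder). All are small U-Net
#' style encoder-decoders; `depth` pooling levels shrink an
#' `imageSize` square input to an `n x n` bottleneck with
#' `n = imageSize / 2^depth` (the autoencoder code grid).
#'
#' @slot imageSize integer, square input side; must be divisible by `2^depth`.
#' @slot baseChannels integer, channels of the first encoder level
#'   (doubled at each level, capped at 48).
#' @slot depth integer, number of 2x down-sampling levels.
#' @slot seed integer, weight-initialisation seed.
#' @seealso [netConfig()], [buildSegmenter()], [buildVectorCNN()],
#'   [buildAutoencoder()]
#' @export
setClass("NetConfig",
  representation(imageSize = "integer", baseChannels = "integer",
                 depth = "integer", seed = "integer"),
  validity = function(object) {
    if (object@imageSize < 8L) return("imageSize too small")
    if (object@depth < 1L) return("depth must be >= 1")
    if (object@baseChannels < 1L) return("baseChannels must be >= 1")
    if (object@imageSize %% (2L^object@depth) != 0L)
      return(sprintf("imageSize %d is not divisible by 2^depth = %d",
                     object@imageSize, 2L^object@depth))
    TRUE
  })

#' A trained or freshly initialised convolutional model
#'
#' Container for one of the three learnable components. Parameters are a
#' plain list of weight matrices/vectors; `kind` selects the forward pass
#' (`"segmenter"`, `"vectorcnn"`, `"autoencoder"`).
#'
#' @slot kind character, one of `"segmenter"`, `"vectorcnn"`, `"autoencoder"`.
#' @slot config the [NetConfig-class] used to build the model.
#' @slot params named list of parameter arrays.
#' @slot inChannels integer, input channel count.
#' @slot lossLog numeric vector of per-update training losses (empty before
#'   training).
#' @export
setClass("ConvModel",
  representation(kind = "character", config = "NetConfig", params = "list",
                 inChannels = "integer", lossLog = "numeric"),
  validity = function(object) {
    if (!object@kind %in% c("segmenter", "vectorcnn", "autoencoder"))
      return("unknown model kind")
    TRUE
  })

#' Latent code produced by the autoencoder encoder
#'
#' Single-channel n x n grid summarising a lung-field mask; the anatomical
#' constraint of the composite registration loss is the mean squared
#' difference between the codes of the warped source mask and the target
#' mask.
#'
#' @slot values numeric n x n matrix.
#' @export
setClass("EncoderCode",
  representation(values = "matrix"),
  validity = function(object) {
    if (!all(is.finite(object@values))) return("code values must be finite")
    TRUE
  })

#' Weights of the composite registration loss
#'
#' The composite loss is
#' `-lambdaNcc * NCC + lambdaTv * TV + lambdaBce * BCE + lambdaL2 * L2`,
#' with `eps` guarding the NCC denominator against zero variance.
#' Defaults are the published settings: lambdaNcc = 1.0, lambdaTv = 5e-5,
#' lambdaBce = 1.0, lambdaL2 = 0.1, eps = 1e-5.
#'
#' @slot lambdaNcc,lambdaTv,lambdaBce,lambdaL2 numeric >= 0.
#' @slot eps numeric > 0.
#' @seealso [lossWeights()], [compositeLoss()]
#' @export
setClass("LossWeights",
  representation(lambdaNcc = "numeric", lambdaTv = "numeric",
                 lambdaBce = "numeric", lambdaL2 = "numeric", eps = "numeric"),
  validity = function(object) {
    w <- c(object@lambdaNcc, object@lambdaTv, object@lambdaBce, object@lambdaL2)
    if (any(w < 0)) return("loss weights must be >= 0")
    if (object@eps <= 0) return("eps must be > 0")
    TRUE
  })

#' Per-term breakdown of one composite-loss evaluation
#'
#' `ncc` stores the normalized cross-correlation itself (about +1 for a
#' perfect match); the composite total subtracts it with weight
#' `lambdaNcc`, so `total = -lNcc*ncc + lTv*tv + lBce*bce + lL2*l2`.
#'
#' @slot ncc,tv,bce,l2,total numeric scalars.
#' @export
setClass("LossBreakdown",
  representation(ncc = "numeric", tv = "numeric", bce = "numeric",
                 l2 = "numeric", total = "numeric"))

#' Parameters of one 2-D affine transform
#'
#' Used for the consistent image/mask augmentation of the enhanced and
#' final training steps. The forward map rotates by `rotation` degrees,
#' shears by `shear` degrees, scales by `scale` about the image centre,
#' then translates by (`translationX`, `translationY`) expressed as
#' fractions of the image side; content moves by + translation.
#'
#' @slot rotation,shear numeric, degrees.
#' @slot scale numeric, isotropic scale factor.
#' @slot translationX,translationY numeric, fractions of the image side.
#' @seealso [sampleAffine()], [makeAffinePair()]
#' @export
setClass("AffineParams",
  representation(rotation = "numeric", scale = "numeric",
                 translationX = "numeric", translationY = "numeric",
                 shear = "numeric"),
  validity = function(object) {
    v <- c(object@rotation, object@scale, object@translationX,
           object@translationY, object@shear)
    if (!all(is.finite(v))) return("affine parameters must be finite")
    if (object@scale <= 0) return("scale must be > 0")
    TRUE
  })

#' Configuration of one registration training step
#'
#' @slot step integer in 1..3 (initial, enhanced, final training).
#' @slot epochs integer >= 1.
#' @slot batchSize integer >= 1.
#' @slot learningRate numeric > 0 (Adam step size).
#' @slot pairsPerEpoch integer >= 1; ordered pairs subsampled per epoch in
#'   step 1 (steps 2 and 3 always use one pair per image per epoch).
#' @slot affineRanges list of sampling ranges for steps 2/3 (see
#'   [sampleAffine()]); empty for step 1.
#' @slot weights a [LossWeights-class].
#' @slot seed integer.
#' @seealso [trainStepConfig()], [trainStep1()], [trainStep2()], [trainStep3()]
#' @export
setClass("TrainStepConfig",
  representation(step = "integer", epochs = "integer", batchSize = "integer",
                 learningRate = "numeric", pairsPerEpoch = "integer",
                 affineRanges = "list", weights = "LossWeights",
                 seed = "integer"),
  validity = function(object) {
    if (!object@step %in% 1:3) return("step must be 1, 2 or 3")
    if (object@pairsPerEpoch < 1L) return("pairsPerEpoch must be >= 1")
    if (object@epochs < 1L) return("epochs must be >= 1")
    if (object@batchSize < 1L) return("batchSize must be >= 1")
    if (object@learningRate <= 0) return("learningRate must be > 0")
    TRUE
  })

#' Per-pair registration metrics with aggregates
#'
#' One row per evaluated (source, target) pair carrying DSC, HD, ASSD and
#' MSD; aggregate mean, SD, min and max per metric are recomputed from the
#' rows (rows flagged as degenerate, e.g. empty masks, are excluded from
#' aggregation).
#'
#' @slot rows data.frame with columns `source`, `target`, `dsc`, `hd`,
#'   `assd`, `msd`, `flagged`.
#' @slot aggregates data.frame with columns `metric`, `mean`, `sd`,
#'   `min`, `max`.
#' @export
setClass("MetricsReport",
  representation(rows = "data.frame", aggregates = "data.frame"),
  validity = function(object) {
    need <- c("source", "target", "dsc", "hd", "assd", "msd", "flagged")
    if (!all(need %in% names(object@rows)))
      return("rows must have columns source, target, dsc, hd, assd, msd, flagged")
    ok <- !object@rows$flagged
    if (any(object@rows$dsc[ok] < 0 | object@rows$dsc[ok] > 1, na.rm = TRUE))
      return("dsc must lie in [0,1]")
    if (any(c(object@rows$hd[ok], object@rows$assd[ok], object@rows$msd[ok]) < 0,
            na.rm = TRUE))
      return("hd, assd and msd must be >= 0")
    TRUE
  })

## ---- constructors ----

#' Create a phantom configuration
#'
#' @param imageSize pixels per side (default 96, the package's desk scale).
#' @param nFrames frames per breathing cycle (default 11, mirroring an
#'   11-frame dynamic acquisition).
#' @param breathingAmplitude fraction of the lung height displaced at full
#'   inspiration (default 0.15).
#' @param textureStrength contrast of the rib-like bands in [0,1].
#' @param noiseSd SD of additive Gaussian intensity noise.
#' @param seed RNG seed.
#' @return a validated [PhantomConfig-class].
#' @examples
#' cfg <- phantomConfig(imageSize = 64, nFrames = 5, seed = 7)
#' @export
phantomConfig <- function(imageSize = 96L, nFrames = 11L,
                          breathingAmplitude = 0.15, textureStrength = 0.6,
                          noiseSd = 0.01, seed = 1L) {
  obj <- new("PhantomConfig", imageSize = as.integer(imageSize),
             nFrames = as.integer(nFrames),
             breathingAmplitude = as.numeric(breathingAmplitude),
             textureStrength = as.numeric(textureStrength),
             noiseSd = as.numeric(noiseSd), seed = as.integer(seed))
  obj
}

#' Create a displacement field
#'
#' @param dx,dy numeric matrices of identical dimension: column (x) and
#'   row (y) displacements in pixels, backward-mapping convention.
#' @return a [DisplacementField-class].
#' @examples
#' f <- displacementField(matrix(0, 4, 4), matrix(0, 4, 4))
#' @export
displacementField <- function(dx, dy) new("DisplacementField", dx = dx, dy = dy)

#' Create a network configuration
#'
#' @param imageSize square input side, divisible by `2^depth`.
#' @param baseChannels first-level channel count.
#' @param depth number of pooling levels.
#' @param seed weight-initialisation seed.
#' @return a [NetConfig-class].
#' @examples
#' netConfig(96, baseChannels = 8, depth = 4)   # 6 x 6 latent grid
#' @export
netConfig <- function(imageSize, baseChannels = 8L, depth = 3L, seed = 1L) {
  new("NetConfig", imageSize = as.integer(imageSize),
      baseChannels = as.integer(baseChannels), depth = as.integer(depth),
      seed = as.integer(seed))
}

#' Create composite-loss weights
#'
#' Defaults are the published weight factors of the composite registration
#' loss.
#'
#' @param lambdaNcc,lambdaTv,lambdaBce,lambdaL2 nonnegative weights.
#' @param eps positive guard added under the square root of the NCC
#'   denominator.
#' @return a [LossWeights-class].
#' @export
lossWeights <- function(lambdaNcc = 1.0, lambdaTv = 5e-5, lambdaBce = 1.0,
                        lambdaL2 = 0.1, eps = 1e-5) {
  new("LossWeights", lambdaNcc = lambdaNcc, lambdaTv = lambdaTv,
      lambdaBce = lambdaBce, lambdaL2 = lambdaL2, eps = eps)
}

#' Create a training-step configuration
#'
#' @param step 1 (initial), 2 (enhanced) or 3 (final) training.
#' @param epochs passes over the step's pair set.
#' @param batchSize pairs per optimizer update.
#' @param learningRate Adam step size.
#' @param pairsPerEpoch ordered pairs subsampled per epoch (step 1 only).
#' @param affineRanges sampling ranges for the consistent affine
#'   augmentation (steps 2/3); see [defaultAffineRanges()].
#' @param weights a [LossWeights-class].
#' @param seed RNG seed controlling subsampling, affine draws and batching.
#' @return a [TrainStepConfig-class].
#' @export
trainStepConfig <- function(step, epochs = 8L, batchSize = 2L,
                            learningRate = 3e-3, pairsPerEpoch = 40L,
                            affineRanges = list(), weights = lossWeights(),
                            seed = 1L) {
  new("TrainStepConfig", step = as.integer(step), epochs = as.integer(epochs),
      batchSize = as.integer(batchSize), learningRate = learningRate,
      pairsPerEpoch = as.integer(pairsPerEpoch), affineRanges = affineRanges,
      weights = weights, seed = as.integer(seed))
}

## ---- accessors & show ----

#' @rdname sequence-accessors
setMethod("frames", "PhantomSequence", function(x) x@frames)
#' @rdname sequence-accessors
setMethod("masks", "PhantomSequence", function(x) x@masks)
#' @rdname sequence-accessors
setMethod("trueFields", "PhantomSequence", function(x) x@trueFields)

#' @rdname field-accessors
setMethod("fieldX", "DisplacementField", function(x) x@dx)
#' @rdname field-accessors
setMethod("fieldY", "DisplacementField", function(x) x@dy)

#' @rdname report-accessors
setMethod("reportRows", "MetricsReport", function(x) x@rows)
#' @rdname report-accessors
setMethod("reportAggregates", "MetricsReport", function(x) x@aggregates)

#' @rdname latentGrid
setMethod("latentGrid", "NetConfig",
          function(x) x@imageSize %/% (2L^x@depth))

setMethod("show", "PhantomConfig", function(object) {
  cat(sprintf("PhantomConfig: %d x %d, %d frame(s), amplitude %.3f, texture %.2f, noise SD %.3f, seed %d\n",
              object@imageSize, object@imageSize, object@nFrames,
              object@breathingAmplitude, object@textureStrength,
              object@noiseSd, object@seed))
})

setMethod("show", "PhantomSequence", function(object) {
  cat(sprintf("PhantomSequence of %d frame(s) (%d x %d, amplitude %.3f)\n",
              length(object@frames), object@config@imageSize,
              object@config@imageSize, object@config@breathingAmplitude))
})

setMethod("show", "DisplacementField", function(object) {
  mag <- sqrt(object@dx^2 + object@dy^2)
  cat(sprintf("DisplacementField %d x %d; |d| mean %.3f, max %.3f px\n",
              nrow(object@dx), ncol(object@dx), mean(mag), max(mag)))
})

setMethod("show", "ConvModel", function(object) {
  cat(sprintf("ConvModel <%s>: input %d x %d x %d, base %d, depth %d, %s\n",
              object@kind, object@config@imageSize, object@config@imageSize,
              object@inChannels, object@config@baseChannels,
              object@config@depth,
              if (length(object@lossLog)) sprintf("trained (%d updates, final loss %.4f)",
                                                  length(object@lossLog),
                                                  object@lossLog[length(object@lossLog)])
              else "untrained"))
})

setMethod("show", "LossBreakdown", function(object) {
  cat(sprintf("LossBreakdown: total %.5f (ncc %.5f, tv %.5f, bce %.5f, l2 %.5f)\n",
              object@total, object@ncc, object@tv, object@bce, object@l2))
})

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf("MetricsReport: %d pair(s)%s\n", nrow(object@rows),
              if (any(object@rows$flagged)) sprintf(" (%d flagged)",
                                                    sum(object@rows$flagged)) else ""))
  a <- object@aggregates
  for (i in seq_len(nrow(a)))
    cat(sprintf("  %-4s %.3f (%.3f-%.3f) +/- %.3f\n", a$metric[i], a$mean[i],
                a$min[i], a$max[i], a$sd[i]))
})
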