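## The three learnable components: lung-field segmenter (Stage I), the
## deformation predictor feeding the differentiable warper (Stage III),
## and the anatomically constrained denoising autoencoder whose frozen
## encoder provides the latent penalty of the composite loss.

#' Build the lung-field segmenter
#'
#' A U-Net style encoder-decoder with skip connections mapping a grayscale
#' chest frame to a per-pixel lung probability map in (0,1). One
#' configurable backbone; weights are seeded by `config@seed`, so two
#' freshly built models with the same configuration are identical.
#'
#' @param config a [NetConfig-class].
#' @return an untrained [ConvModel-class] of kind `"segmenter"`.
#' @seealso [trainSegmenter()], [predictSegmenter()]
#' @export
buildSegmenter <- function(config) {
  methods::validObject(config)
  new("ConvModel", kind = "segmenter", config = config,
      params = initUNetParams(config, 1L, 1L, headStd = 0.01),
      inChannels = 1L, lossLog = numeric())
}

#' Build the deformation predictor
#'
#' A U-Net style network taking the channel-concatenated (source, target)
#' pair and emitting a two-plane dense displacement field of the input's
#' spatial size. The output head is initialised near zero so a fresh
#' model predicts (almost exactly) the identity transform — the standard
#' stabilisation for unsupervised registration training. The field is
#' predicted on a grid coarsened by `fieldStride` and bilinearly
#' upsampled to full resolution inside the network: breathing-like
#' deformations are smooth, and the coarse parameterisation builds that
#' smoothness in (and makes boundary-only displacement artefacts
#' unrepresentable).
#'
#' @param config a [NetConfig-class]; `depth` must be at least
#'   `log2(fieldStride) + 1`.
#' @param fieldStride power of two (default 4): the displacement field is
#'   predicted every `fieldStride` pixels.
#' @return an untrained [ConvModel-class] of kind `"vectorcnn"`.
#' @seealso [predictField()], [trainStep1()]
#' @export
buildVectorCNN <- function(config, fieldStride = 4L) {
  methods::validObject(config)
  if (fieldStride < 1L || bitwAnd(fieldStride, fieldStride - 1L) != 0L)
    stop("fieldStride must be a power of two", call. = FALSE)
  outLevel <- as.integer(log2(fieldStride)) + 1L
  if (outLevel > config@depth)
    stop("fieldStride too large for the configured depth", call. = FALSE)
  new("ConvModel", kind = "vectorcnn", config = config,
      params = initUNetParams(config, 2L, 2L, headStd = 1e-3,
                              outLevel = outLevel),
      inChannels = 2L, lossLog = numeric())
}

#' Build the anatomically constrained denoising autoencoder
#'
#' Encoder-decoder without skip connections (so the single-channel
#' `n x n` bottleneck code, `n = imageSize / 2^depth`, is informative):
#' `encode` maps a binary lung mask to an [EncoderCode-class], `decode`
#' maps a code back to a probability map.
#'
#' @param config a [NetConfig-class].
#' @return an untrained [ConvModel-class] of kind `"autoencoder"`.
#' @seealso [trainAutoencoder()], [encodeMask()], [decodeCode()]
#' @export
buildAutoencoder <- function(config) {
  methods::validObject(config)
  new("ConvModel", kind = "autoencoder", config = config,
      params = initAEParams(config), inChannels = 1L, lossLog = numeric())
}

#' Segment a frame into a lung probability map
#'
#' @param model a `"segmenter"` [ConvModel-class].
#' @param image numeric matrix in [0,1] of the model's configured size.
#' @return numeric matrix of lung probabilities in (0,1).
#' @export
predictSegmenter <- function(model, image) {
  stopifnot(is(model, "ConvModel"), model@kind == "segmenter")
  assertIntensityRaster(image, "image")
  unetForward(model@params, image, "sigmoid")$out[, , 1L]
}

#' Predict the displacement field registering source onto target
#'
#' @param model a `"vectorcnn"` [ConvModel-class].
#' @param source,target numeric matrices in [0,1] (moving and fixed
#'   image).
#' @return a [DisplacementField-class] (backward mapping, pixels).
#' @export
predictField <- function(model, source, target) {
  stopifnot(is(model, "ConvModel"), model@kind == "vectorcnn")
  assertIntensityRaster(source, "source")
  assertIntensityRaster(target, "target")
  assertSameShape(source, target, "source and target")
  x <- array(0, c(dim(source), 2L))
  x[, , 1L] <- source; x[, , 2L] <- target
  out <- unetForward(model@params, x, "linear")$out
  displacementField(out[, , 1L], out[, , 2L])
}

#' Encode a lung mask into its latent code
#'
#' Deterministic at inference: the same mask always yields the same code.
#'
#' @param model an `"autoencoder"` [ConvModel-class].
#' @param mask binary (or soft, during training) matrix.
#' @return an [EncoderCode-class] with an `n x n` value grid.
#' @export
encodeMask <- function(model, mask) {
  stopifnot(is(model, "ConvModel"), model@kind == "autoencoder")
  assertRaster(mask, "mask")
  new("EncoderCode", values = aeEncodeForward(model@params, mask)$code)
}

#' Decode a latent code into a mask probability map
#'
#' @param model an `"autoencoder"` [ConvModel-class].
#' @param code an [EncoderCode-class].
#' @return numeric matrix of probabilities in (0,1) at the model's
#'   configured image size.
#' @export
decodeCode <- function(model, code) {
  stopifnot(is(model, "ConvModel"), model@kind == "autoencoder")
  stopifnot(is(code, "EncoderCode"))
  aeDecodeForward(model@params, code@values)$out
}

#' Train the denoising autoencoder on lung masks
#'
#' Corrupts each training mask by independent pixel flips at `noiseRate`
#' and minimises the binary cross-entropy between the reconstruction of
#' the noisy mask and the clean mask (Adam). Only lung-field masks enter
#' training — the anatomical constraint is a lung-shape prior.
#'
#' @param masks list of binary matrices (>= 2).
#' @param noiseRate probability of flipping each pixel (default 0.05).
#' @param epochs passes over the mask set.
#' @param seed RNG seed (initialisation, corruption, batching).
#' @param config optional [NetConfig-class]; defaults to a depth-4
#'   autoencoder at the masks' size.
#' @param batchSize,learningRate optimizer settings.
#' @return a trained `"autoencoder"` [ConvModel-class]; `@lossLog` holds
#'   one mean BCE value per optimizer update.
#' @export
trainAutoencoder <- function(masks, noiseRate = 0.05, epochs = 30L,
                             seed = 1L, config = NULL, batchSize = 4L,
                             learningRate = 3e-3) {
  if (!is.list(masks) || length(masks) < 2L)
    stop("need at least 2 masks to train the autoencoder", call. = FALSE)
  for (m in masks) assertMask(m, "mask")
  if (is.null(config))
    config <- netConfig(nrow(masks[[1]]), baseChannels = 6L, depth = 4L,
                        seed = seed)
  model <- buildAutoencoder(config)
  params <- model@params
  opt <- adamInit(params)
  n <- length(masks)
  lossLog <- numeric()
  epochSeeds <- deriveSeeds(seed, epochs)
  for (ep in seq_len(epochs)) {
    ord <- withSeed(epochSeeds[ep], sample.int(n))
    flipSeeds <- deriveSeeds(epochSeeds[ep] %% 1000000L + ep, n)
    for (start in seq(1L, n, by = batchSize)) {
      idx <- ord[start:min(start + batchSize - 1L, n)]
      gradSum <- NULL; lossSum <- 0
      for (i in idx) {
        clean <- masks[[i]]
        noisy <- clean
        if (noiseRate > 0) {
          flips <- withSeed(flipSeeds[i],
                            stats::runif(length(clean)) < noiseRate)
          noisy <- abs(clean - matrix(as.numeric(flips), nrow(clean)))
        }
        ef <- aeEncodeForward(params, noisy)
        df <- aeDecodeForward(params, ef$code)
        p <- pmin(1 - 1e-7, pmax(1e-7, df$out))
        lossSum <- lossSum + mean(-(clean * log(p) + (1 - clean) * log(1 - p)))
        dOut <- (p - clean) / (p * (1 - p)) / length(p)
        dOut[df$out != p] <- 0                      # clamped pixels
        gDec <- aeDecodeBackward(params, df$cache, dOut)
        gEnc <- aeEncodeBackward(params, ef$cache, gDec$dCode)
        gDec$dCode <- NULL
        g <- c(gEnc, gDec)
        gradSum <- if (is.null(gradSum)) g else paramsAdd(gradSum, g)
      }
      gradSum <- paramsScale(gradSum, 1 / length(idx))
      st <- adamStep(params, gradSum, opt, learningRate)
      params <- st$params; opt <- st$state
      lossLog <- c(lossLog, lossSum / length(idx))
    }
  }
  methods::initialize(model, params = params, lossLog = lossLog)
}

#' Train the lung-field segmenter on image/mask pairs
#'
#' Minimises per-pixel binary cross-entropy between the predicted lung
#' probability map and the reference mask (Adam, seeded batching).
#'
#' @param images list of intensity matrices.
#' @param masks list of matching binary masks.
#' @param epochs passes over the training set.
#' @param seed RNG seed.
#' @param config optional [NetConfig-class] (default depth 3 at the
#'   images' size).
#' @param batchSize,learningRate optimizer settings.
#' @return a trained `"segmenter"` [ConvModel-class] with `@lossLog`.
#' @export
trainSegmenter <- function(images, masks, epochs = 6L, seed = 1L,
                           config = NULL, batchSize = 2L,
                           learningRate = 3e-3) {
  if (length(images) != length(masks) || length(images) < 2L)
    stop("need matching image/mask lists of length >= 2", call. = FALSE)
  if (is.null(config))
    config <- netConfig(nrow(images[[1]]), baseChannels = 8L, depth = 3L,
                        seed = seed)
  model <- buildSegmenter(config)
  params <- model@params
  opt <- adamInit(params)
  n <- length(images)
  lossLog <- numeric()
  epochSeeds <- deriveSeeds(seed, epochs)
  for (ep in seq_len(epochs)) {
    ord <- withSeed(epochSeeds[ep], sample.int(n))
    for (start in seq(1L, n, by = batchSize)) {
      idx <- ord[start:min(start + batchSize - 1L, n)]
      gradSum <- NULL; lossSum <- 0
      for (i in idx) {
        fw <- unetForward(params, images[[i]], "sigmoid")
        p <- pmin(1 - 1e-7, pmax(1e-7, fw$out[, , 1L]))
        m <- masks[[i]]
        lossSum <- lossSum + mean(-(m * log(p) + (1 - m) * log(1 - p)))
        dOut <- array((p - m) / (p * (1 - p)) / length(p), dim(fw$out))
        g <- unetBackward(params, fw$cache, dOut)
        gradSum <- if (is.null(gradSum)) g else paramsAdd(gradSum, g)
      }
      gradSum <- paramsScale(gradSum, 1 / length(idx))
      st <- adamStep(params, gradSum, opt, learningRate)
      params <- st$params; opt <- st$state
      lossLog <- c(lossLog, lossSum / length(idx))
    }
  }
  methods::initialize(model, params = params, lossLog = lossLog)
}
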