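## Three-step registration training: initial training on all ordered
## image pairs (subsampled per epoch at desk scale), enhanced training on
## image -> affine-image pairs, final training on extracted lung-field ->
## affine lung-field pairs. The anatomical encoder is frozen throughout;
## only the deformation predictor learns.

#' Enumerate all ordered pairs (i, j), i != j
#'
#' @param nItems number of items (>= 1).
#' @return list with `count` (`nItems^2 - nItems`) and `pairAt(k)`, a
#'   deterministic bijection from `1:count` to the ordered pairs
#'   ((1,2), (1,3), ..., (2,1), (2,3), ...).
#' @examples
#' enumerateOrderedPairs(11)$count   # 110
#' @export
enumerateOrderedPairs <- function(nItems) {
  if (!is.numeric(nItems) || length(nItems) != 1L || nItems < 1)
    stop("nItems must be a single integer >= 1", call. = FALSE)
  n <- as.numeric(nItems)
  count <- n * n - n
  pairAt <- function(k) {
    stopifnot(k >= 1, k <= count)
    i <- (k - 1) %/% (n - 1) + 1
    r <- (k - 1) %% (n - 1) + 1
    j <- r + (r >= i)
    c(i = i, j = j)
  }
  list(count = count, pairAt = pairAt)
}

#' Apply one affine transform consistently to an image and its mask
#'
#' Both outputs are produced by the SAME transform: the image by bilinear
#' interpolation, the mask by nearest-neighbour followed by
#' re-binarization — the augmentation rule of the enhanced and final
#' training steps.
#'
#' @param image intensity matrix in [0,1].
#' @param mask binary matrix of the same shape.
#' @param params an [AffineParams-class].
#' @return list with `image` and `mask`.
#' @export
makeAffinePair <- function(image, mask, params) {
  assertIntensityRaster(image, "image")
  assertMask(mask, "mask")
  assertSameShape(image, mask, "image and mask")
  list(image = applyAffine(image, params, "bilinear"),
       mask = applyAffine(mask, params, "nearest"))
}

## Composite loss + parameter gradients for one (source, target) pair.
## encTargetCode may be precomputed (frozen encoder, fixed target).
## bceClip: clamp of the BCE gradient path during training — softer than
## the evaluation default so a handful of saturated warped-mask pixels
## cannot dominate the update.
registrationPairGrad <- function(params, I, J, SI, SJ, encParams, weights,
                                 encTargetCode = NULL, bceClip = 1e-3) {
  x <- array(0, c(dim(I), 2L)); x[, , 1L] <- I; x[, , 2L] <- J
  fw <- unetForward(params, x, "linear")
  dxp <- fw$out[, , 1L]; dyp <- fw$out[, , 2L]
  wI <- warpBilinearGrad(I, dxp, dyp)
  wS <- warpBilinearGrad(SI, dxp, dyp)
  ng <- nccLossGrad(wI$out, J, weights@eps)
  tg <- tvLossGrad(dxp, dyp)
  bg <- bceLossGrad(wS$out, SJ, clip = bceClip)
  dWarpedS <- weights@lambdaBce * bg$grad
  l2 <- 0
  if (weights@lambdaL2 > 0) {
    ef <- aeEncodeForward(encParams, wS$out)
    if (is.null(encTargetCode))
      encTargetCode <- aeEncodeForward(encParams, SJ)$code
    diff <- ef$code - encTargetCode
    l2 <- mean(diff^2)
    dCode <- 2 * diff / length(diff)
    eb <- aeEncodeBackward(encParams, ef$cache, dCode, wantInputGrad = TRUE)
    dWarpedS <- dWarpedS + weights@lambdaL2 * eb$dInput
  }
  dWarpedI <- weights@lambdaNcc * ng$grad
  ddx <- dWarpedI * wI$dcs + dWarpedS * wS$dcs + weights@lambdaTv * tg$gdx
  ddy <- dWarpedI * wI$drs + dWarpedS * wS$drs + weights@lambdaTv * tg$gdy
  dOut <- array(0, dim(fw$out)); dOut[, , 1L] <- ddx; dOut[, , 2L] <- ddy
  grads <- unetBackward(params, fw$cache, dOut)
  loss <- weights@lambdaNcc * ng$loss + weights@lambdaTv * tg$loss +
    weights@lambdaBce * bg$loss + weights@lambdaL2 * l2
  list(loss = loss, grads = grads,
       breakdown = c(ncc = -ng$loss, tv = tg$loss, bce = bg$loss, l2 = l2))
}

## Shared optimizer loop. pairProvider(epoch) returns a list of pairs,
## each a list(I, J, SI, SJ); order within the epoch is already shuffled.
trainRegistrationLoop <- function(model, pairProvider, encoder, cfg) {
  params <- model@params
  opt <- adamInit(params)
  lossLog <- numeric()
  encParams <- if (cfg@weights@lambdaL2 > 0) encoder@params
  for (ep in seq_len(cfg@epochs)) {
    ## learning rate decays linearly to half of its initial value
    lrEp <- cfg@learningRate *
      (1 - 0.5 * (ep - 1) / max(1, cfg@epochs - 1))
    pairs <- pairProvider(ep)
    for (start in seq(1L, length(pairs), by = cfg@batchSize)) {
      idx <- start:min(start + cfg@batchSize - 1L, length(pairs))
      gradSum <- NULL; lossSum <- 0
      for (q in idx) {
        pr <- pairs[[q]]
        r <- registrationPairGrad(params, pr$I, pr$J, pr$SI, pr$SJ,
                                  encParams, cfg@weights)
        lossSum <- lossSum + r$loss
        gradSum <- if (is.null(gradSum)) r$grads
                   else paramsAdd(gradSum, r$grads)
      }
      gradSum <- paramsScale(gradSum, 1 / length(idx))
      st <- adamStep(params, gradSum, opt, lrEp)
      params <- st$params; opt <- st$state
      lossLog <- c(lossLog, lossSum / length(idx))
    }
  }
  methods::initialize(model, params = params,
                      lossLog = c(model@lossLog, lossLog))
}

checkTrainInputs <- function(images, masks, encoder, cfg) {
  if (length(images) < 2L)
    stop("need at least 2 training images", call. = FALSE)
  if (length(images) != length(masks))
    stop("images and masks must have equal length", call. = FALSE)
  if (cfg@weights@lambdaL2 > 0 &&
      (is.null(encoder) || !is(encoder, "ConvModel") ||
       encoder@kind != "autoencoder"))
    stop("a pretrained autoencoder is required (lambdaL2 > 0)",
         call. = FALSE)
  invisible(TRUE)
}

#' Initial registration training on all ordered image pairs
#'
#' Step 1 of the three-step scheme: a fresh deformation predictor is
#' trained on ordered pairs drawn from the full (n^2 - n)-pair set of the
#' training images — subsampled uniformly to `pairsPerEpoch` pairs per
#' epoch — minimising the composite loss with the frozen anatomical
#' encoder. Returns the model conventionally called V1.
#'
#' @param images list of intensity matrices (full frames).
#' @param masks list of matching binary lung masks.
#' @param encoder trained `"autoencoder"` [ConvModel-class] (frozen).
#' @param cfg a [TrainStepConfig-class] with `step = 1`.
#' @param netCfg optional [NetConfig-class] for the fresh model (default:
#'   depth 4, base 8 at the images' size).
#' @param fieldStride coarse-grid stride of the predicted field (see
#'   [buildVectorCNN()]).
#' @return a trained `"vectorcnn"` [ConvModel-class]; `@lossLog` holds one
#'   value per optimizer update
#'   (`epochs * ceiling(pairsPerEpoch / batchSize)` entries).
#' @export
trainStep1 <- function(images, masks, encoder, cfg, netCfg = NULL,
                       fieldStride = 8L) {
  stopifnot(cfg@step == 1L)
  checkTrainInputs(images, masks, encoder, cfg)
  if (is.null(netCfg))
    netCfg <- netConfig(nrow(images[[1]]), baseChannels = 8L, depth = 4L,
                        seed = cfg@seed)
  model <- buildVectorCNN(netCfg, fieldStride = fieldStride)
  enum <- enumerateOrderedPairs(length(images))
  nPick <- min(cfg@pairsPerEpoch, enum$count)
  epochSeeds <- deriveSeeds(cfg@seed, cfg@epochs)
  provider <- function(ep) {
    ks <- withSeed(epochSeeds[ep], sample.int(enum$count, nPick))
    lapply(ks, function(k) {
      ij <- enum$pairAt(k)
      list(I = images[[ij[1]]], J = images[[ij[2]]],
           SI = masks[[ij[1]]], SJ = masks[[ij[2]]])
    })
  }
  trainRegistrationLoop(model, provider, encoder, cfg)
}

## Common machinery of the affine-augmented steps 2 and 3.
affineStepProvider <- function(images, masks, cfg, fixedDraws,
                               includeReversed) {
  n <- length(images)
  epochSeeds <- deriveSeeds(cfg@seed + 1L, cfg@epochs)
  drawSeedsFixed <- deriveSeeds(cfg@seed + 2L, n)
  function(ep) {
    drawSeeds <- if (fixedDraws) drawSeedsFixed
                 else deriveSeeds(epochSeeds[ep], n)
    pairs <- vector("list", 0L)
    for (i in seq_len(n)) {
      ap <- sampleAffine(drawSeeds[i], cfg@affineRanges)
      aff <- makeAffinePair(images[[i]], masks[[i]], ap)
      pairs[[length(pairs) + 1L]] <-
        list(I = images[[i]], J = aff$image, SI = masks[[i]], SJ = aff$mask)
      if (includeReversed)
        pairs[[length(pairs) + 1L]] <-
          list(I = aff$image, J = images[[i]], SI = aff$mask, SJ = masks[[i]])
    }
    ord <- withSeed(epochSeeds[ep] %% 1000000L + 7L, sample.int(length(pairs)))
    pairs[ord]
  }
}

#' Enhanced registration training on affine-augmented image pairs
#'
#' Step 2: continues training the step-1 model on (original -> affine)
#' pairs — one consistent affine draw per image per epoch by default
#' (`fixedDraws = TRUE` replicates a single-draw protocol where the same
#' affine set is reused every epoch). Masks are transformed with the same
#' parameters as their images. Returns V2.
#'
#' @param model the step-1 `"vectorcnn"` model.
#' @param images,masks training frames and masks.
#' @param affineRanges sampling ranges (see [sampleAffine()]); if missing,
#'   taken from `cfg@affineRanges`.
#' @param encoder frozen `"autoencoder"` model.
#' @param cfg a [TrainStepConfig-class] with `step = 2`.
#' @param fixedDraws reuse one affine draw per image across epochs.
#' @param includeReversed also train the (affine -> original) direction.
#' @return the continued model (V2).
#' @export
trainStep2 <- function(model, images, masks, affineRanges = NULL, encoder,
                       cfg, fixedDraws = FALSE, includeReversed = FALSE) {
  stopifnot(cfg@step == 2L, is(model, "ConvModel"),
            model@kind == "vectorcnn")
  if (!is.null(affineRanges)) cfg@affineRanges <- affineRanges
  if (!length(cfg@affineRanges)) cfg@affineRanges <- defaultAffineRanges()
  checkTrainInputs(images, masks, encoder, cfg)
  provider <- affineStepProvider(images, masks, cfg, fixedDraws,
                                 includeReversed)
  trainRegistrationLoop(model, provider, encoder, cfg)
}

#' Final registration training on extracted lung-field pairs
#'
#' Step 3: the same affine-augmented pairing scheme as step 2, but on
#' lung-field images (zero outside the mask, produced by
#' [extractLungField()]). Inputs with nonzero background raise a warning.
#' Returns V3, the model used by the inference pipeline.
#'
#' @param model the step-2 `"vectorcnn"` model.
#' @param lungFieldImages list of extracted lung-field images.
#' @param masks matching binary masks.
#' @param affineRanges,encoder,cfg,fixedDraws,includeReversed as in
#'   [trainStep2()]; `cfg@step` must be 3.
#' @return the continued model (V3).
#' @export
trainStep3 <- function(model, lungFieldImages, masks, affineRanges = NULL,
                       encoder, cfg, fixedDraws = FALSE,
                       includeReversed = FALSE) {
  stopifnot(cfg@step == 3L, is(model, "ConvModel"),
            model@kind == "vectorcnn")
  for (k in seq_along(lungFieldImages)) {
    bg <- lungFieldImages[[k]] * (1 - masks[[k]])
    if (any(bg != 0)) {
      warning(sprintf("lung-field image %d has nonzero background; expected extractLungField() output", k))
      break
    }
  }
  if (!is.null(affineRanges)) cfg@affineRanges <- affineRanges
  if (!length(cfg@affineRanges)) cfg@affineRanges <- defaultAffineRanges()
  checkTrainInputs(lungFieldImages, masks, encoder, cfg)
  provider <- affineStepProvider(lungFieldImages, masks, cfg, fixedDraws,
                                 includeReversed)
  trainRegistrationLoop(model, provider, encoder, cfg)
}

#' Ablation harness over all ordered frame pairs of a sequence
#'
#' Evaluates the unregistered baseline and the three training stages on
#' every ordered frame pair (n^2 - n pairs): V1 and V2 register full
#' frames; V3 registers extracted lung fields. Masks come from the
#' segmentation model when given (binarized at 0.5), otherwise the
#' sequence's reference masks are used. Warped masks are evaluated with
#' the hard nearest-neighbour path; MSD for the V3 arm is computed on
#' lung-field images (so arms are labelled by what they register).
#'
#' @param sequence a [PhantomSequence-class] (or compatible list with
#'   `frames`/`masks`).
#' @param segModel optional trained `"segmenter"` model.
#' @param models named list with any of `V1`, `V2`, `V3`
#'   (`"vectorcnn"` models).
#' @param msdScale intensity scale for MSD reporting (default 255).
#' @return named list of [MetricsReport-class] objects
#'   (`baseline` plus one per supplied model).
#' @export
runAblation <- function(sequence, segModel = NULL, models = list(),
                        msdScale = 255) {
  frames <- if (is(sequence, "PhantomSequence")) sequence@frames
            else sequence$frames
  refMasks <- if (is(sequence, "PhantomSequence")) sequence@masks
              else sequence$masks
  n <- length(frames)
  if (n < 2L) stop("need a sequence of at least 2 frames", call. = FALSE)
  for (nm in names(models))
    if (!is(models[[nm]], "ConvModel") || models[[nm]]@kind != "vectorcnn")
      stop(sprintf("model %s is not a deformation predictor", nm),
           call. = FALSE)
  msks <- if (is.null(segModel)) refMasks
          else lapply(frames, function(f)
            binarizeMask(predictSegmenter(segModel, f)))
  lungFields <- mapply(extractLungField, frames, msks, SIMPLIFY = FALSE)
  enum <- enumerateOrderedPairs(n)
  arms <- c("baseline", names(models))
  out <- setNames(vector("list", length(arms)), arms)
  for (arm in arms) {
    rows <- vector("list", enum$count)
    for (k in seq_len(enum$count)) {
      ij <- enum$pairAt(k); i <- ij[1]; j <- ij[2]
      if (arm == "baseline") {
        wm <- msks[[i]]; wi <- frames[[i]]; ti <- frames[[j]]
      } else if (arm %in% c("V1", "V2")) {
        fld <- predictField(models[[arm]], frames[[i]], frames[[j]])
        wm <- warpRaster(msks[[i]], fld, "nearest")
        wi <- warpRaster(frames[[i]], fld, "bilinear")
        ti <- frames[[j]]
      } else {  # V3 registers lung fields
        fld <- predictField(models[[arm]], lungFields[[i]], lungFields[[j]])
        wm <- warpRaster(msks[[i]], fld, "nearest")
        wi <- warpRaster(lungFields[[i]], fld, "bilinear")
        ti <- lungFields[[j]]
      }
      rows[[k]] <- metricRow(i, j, msks[[j]], wm, ti, wi, msdScale)
    }
    out[[arm]] <- newMetricsReport(do.call(rbind, rows))
  }
  out
}
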