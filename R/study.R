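## Desk-scale end-to-end study: simulate a static training corpus and a
## dynamic test sequence, train the anatomical autoencoder, the segmenter
## and the three registration steps, then evaluate the ablation arms and
## translation recovery. This is the package's equivalent of the original
## protocol (787 static radiographs + one 11-frame dynamic sequence) at
## CPU-trainable size; the vignette discusses the scaling choices.

#' Simulate a static training corpus of phantom subjects
#'
#' Each "subject" is one phantom anatomy (its own seed) rendered at a
#' random breathing phase — the stand-in for a corpus of static
#' radiographs from different individuals.
#'
#' @param n number of subjects.
#' @param imageSize pixels per side.
#' @param seed master seed.
#' @param amplitude breathing amplitude of the rendering.
#' @return list with `images` and `masks`.
#' @export
simulateTrainingCorpus <- function(n, imageSize = 96L, seed = 1L,
                                   amplitude = 0.15) {
  subjSeeds <- deriveSeeds(seed, n)
  phases <- withSeed(seed + 1L, stats::runif(n))
  images <- vector("list", n); msks <- vector("list", n)
  for (i in seq_len(n)) {
    cfg <- phantomConfig(imageSize = imageSize, nFrames = 1L,
                         breathingAmplitude = amplitude, seed = subjSeeds[i])
    p <- generatePhantom(cfg, phases[i])
    images[[i]] <- p$image; msks[[i]] <- p$mask
  }
  list(images = images, masks = msks)
}

#' Run the full desk-scale study
#'
#' Simulates `nTrain` static phantom subjects and an `nFrames`-frame
#' dynamic test sequence, trains the denoising autoencoder and the
#' segmenter, runs the three-step registration training (V1, V2, V3), and
#' evaluates (i) the ablation arms over all ordered test-frame pairs and
#' (ii) recovery of known pure translations of at most `maxShift` pixels.
#'
#' @param seed master seed for every stochastic choice.
#' @param nTrain training subjects (default 60).
#' @param imageSize frame side (default 96).
#' @param nFrames test-sequence length (default 11; 110 ordered pairs).
#' @param amplitude breathing amplitude of the test sequence (default
#'   0.15).
#' @param epochsAE,epochsSeg autoencoder / segmenter training lengths.
#' @param epochsStep1,epochsStep2,epochsStep3 epochs of the three
#'   registration steps (step 3, the final specialisation actually used at
#'   inference, trains longest).
#' @param pairsPerEpoch step-1 subsample size per epoch.
#' @param maxShift largest translation magnitude (pixels) in the recovery
#'   probe.
#' @param verbose print stage progress.
#' @return list with `models` (ae, seg, V1, V2, V3), `ablation` (named
#'   list of [MetricsReport-class]), `translation` (data.frame of probe
#'   results plus `meanError`), and `sequence` (the test
#'   [PhantomSequence-class]).
#' @export
runStudy <- function(seed = 1L, nTrain = 60L, imageSize = 96L,
                     nFrames = 11L, amplitude = 0.15,
                     epochsAE = 10L, epochsSeg = 6L, epochsStep1 = 8L,
                     epochsStep2 = 8L, epochsStep3 = 20L,
                     pairsPerEpoch = 40L, maxShift = 4L, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  seeds <- deriveSeeds(seed, 8L)

  say("simulating %d training subjects (%dpx)", nTrain, imageSize)
  corpus <- simulateTrainingCorpus(nTrain, imageSize, seed = seeds[1],
                                   amplitude = amplitude)
  testCfg <- phantomConfig(imageSize = imageSize, nFrames = nFrames,
                           breathingAmplitude = amplitude, seed = seeds[2])
  testSeq <- generateBreathingSequence(testCfg)

  say("training anatomical autoencoder")
  ae <- trainAutoencoder(corpus$masks, epochs = epochsAE, seed = seeds[3],
                         config = netConfig(imageSize, baseChannels = 6L,
                                            depth = 4L, seed = seeds[3]))
  say("training segmenter")
  seg <- trainSegmenter(corpus$images, corpus$masks, epochs = epochsSeg,
                        seed = seeds[4])

  netCfg <- netConfig(imageSize, baseChannels = 8L, depth = 4L,
                      seed = seeds[5])
  say("step 1: initial training (all ordered pairs, subsampled)")
  v1 <- trainStep1(corpus$images, corpus$masks, ae,
                   trainStepConfig(1L, epochs = epochsStep1,
                                   pairsPerEpoch = pairsPerEpoch,
                                   seed = seeds[5]),
                   netCfg = netCfg)
  say("step 2: enhanced training (affine pairs)")
  v2 <- trainStep2(v1, corpus$images, corpus$masks,
                   defaultAffineRanges(), ae,
                   trainStepConfig(2L, epochs = epochsStep2, seed = seeds[6],
                                   affineRanges = defaultAffineRanges()))
  say("step 3: final training (lung-field pairs)")
  lungFields <- mapply(extractLungField, corpus$images, corpus$masks,
                       SIMPLIFY = FALSE)
  v3 <- trainStep3(v2, lungFields, corpus$masks, defaultAffineRanges(), ae,
                   trainStepConfig(3L, epochs = epochsStep3, seed = seeds[7],
                                   affineRanges = defaultAffineRanges()))

  say("ablation over %d ordered test pairs", nFrames^2 - nFrames)
  ablation <- runAblation(testSeq, segModel = seg,
                          models = list(V1 = v1, V2 = v2, V3 = v3))

  say("translation-recovery probe")
  translation <- translationRecovery(testSeq, v3, maxShift = maxShift,
                                     seed = seeds[8])

  list(models = list(ae = ae, seg = seg, V1 = v1, V2 = v2, V3 = v3),
       ablation = ablation, translation = translation, sequence = testSeq)
}

#' Probe recovery of known pure translations
#'
#' Shifts extracted lung fields by known integer translations of at most
#' `maxShift` pixels and asks the trained deformation predictor to
#' register the original onto the shifted copy. The ground-truth backward
#' field is uniformly minus the shift; recovery is summarised by the
#' Euclidean distance between the truth and the mean predicted
#' displacement inside the target lung mask.
#'
#' @param sequence a [PhantomSequence-class].
#' @param model trained `"vectorcnn"` model (step 3).
#' @param maxShift largest per-axis shift magnitude in pixels.
#' @param nProbes number of (frame, shift) probes.
#' @param seed RNG seed for probe selection.
#' @return data.frame with one row per probe (`frame`, `tx`, `ty`,
#'   `predDx`, `predDy`, `error`) and attribute `meanError`.
#' @export
translationRecovery <- function(sequence, model, maxShift = 4L,
                                nProbes = 8L, seed = 1L) {
  stopifnot(is(sequence, "PhantomSequence"))
  n <- length(sequence@frames)
  s <- sequence@config@imageSize
  probes <- withSeed(seed, {
    fr <- sample.int(n, nProbes, replace = TRUE)
    tx <- integer(nProbes); ty <- integer(nProbes)
    for (k in seq_len(nProbes)) {
      repeat {   # nonzero integer shifts of magnitude at most maxShift
        a <- sample(seq(-maxShift, maxShift), 1L)
        b <- sample(seq(-maxShift, maxShift), 1L)
        if (a^2 + b^2 > 0 && a^2 + b^2 <= maxShift^2) break
      }
      tx[k] <- a; ty[k] <- b
    }
    data.frame(frame = fr, tx = tx, ty = ty)
  })
  rows <- lapply(seq_len(nProbes), function(k) {
    i <- probes$frame[k]; tx <- probes$tx[k]; ty <- probes$ty[k]
    lf <- extractLungField(sequence@frames[[i]], sequence@masks[[i]])
    par <- new("AffineParams", rotation = 0, scale = 1,
               translationX = tx / s, translationY = ty / s, shear = 0)
    target <- applyAffine(lf, par, "bilinear")
    tMask <- applyAffine(sequence@masks[[i]], par, "nearest")
    fld <- predictField(model, lf, target)
    inside <- tMask == 1
    predDx <- mean(fld@dx[inside]); predDy <- mean(fld@dy[inside])
    ## truth: output(p) samples source at p - t
    err <- sqrt((predDx + tx)^2 + (predDy + ty)^2)
    data.frame(frame = i, tx = tx, ty = ty, predDx = predDx,
               predDy = predDy, error = err)
  })
  out <- do.call(rbind, rows)
  attr(out, "meanError") <- mean(out$error)
  out
}
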