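## Seeded breathing-phantom generator.
##
## The scene is defined analytically in "base" (end-expiration, phase 0)
## coordinates: two vertically elongated super-elliptic lungs brightened on
## a darker elliptic thorax carrying sinusoidal rib-like texture. Breathing
## is a diaphragm-dominant analytic coordinate map: at phase p the content
## at base row r moves down by d(p) * max(0, r - apex) / L pixels
## (d(p) = amplitude * sin(pi * p) * L, L = lung height), i.e. zero at the
## lung apex and the full amplitude at the lower lung boundary, plus a small
## lateral expansion about the midline coupled to the same depth ramp. The
## map is triangular (rows move independently of columns) and piecewise
## linear in the row, so it has an analytic inverse; frames are rendered by
## evaluating the continuous base scene at inverse-mapped coordinates, and
## the ground-truth field warping frame k back onto frame 0 is simply
## phi_k(p) - p on the output grid.

LATERAL_COUPLING <- 0.25  # lateral expansion as a fraction of d(p)/L

## Anatomy parameters, drawn once per config seed (jittered so different
## seeds give different "subjects").
phantomAnatomy <- function(config) {
  s <- config@imageSize
  withSeed(config@seed, {
    jit <- function(lo, hi) stats::runif(1, lo, hi)
    list(
      s = s,
      cxL = s * jit(0.30, 0.34), cxR = s * jit(0.66, 0.70),
      cy = s * jit(0.455, 0.485),
      aL = s * jit(0.125, 0.145), aR = s * jit(0.125, 0.145),
      bL = s * jit(0.255, 0.285), bR = s * jit(0.255, 0.285),
      pow = jit(2.3, 2.7),
      ribPeriod = s * jit(0.10, 0.12), ribPhase = jit(0, 2 * pi),
      colPeriod = s * jit(0.21, 0.25), colPhase = jit(0, 2 * pi),
      thoraxA = s * 0.47, thoraxB = s * 0.45,
      thoraxCx = s / 2, thoraxCy = s * 0.52)
  })
}

## d(p): peak diaphragm displacement in pixels at phase p.
phantomMotionScale <- function(config, anat, phase) {
  L <- 2 * max(anat$bL, anat$bR)
  list(d = config@breathingAmplitude * sin(pi * phase) * L,
       L = L, apex = anat$cy - max(anat$bL, anat$bR),
       cm = anat$s / 2)
}

## Forward map phi (base -> phase coords), components evaluated on 0-based
## coordinate matrices R (rows) and C (cols).
phantomForwardMap <- function(mot, R, C) {
  u <- pmax(R - mot$apex, 0) / mot$L
  dy <- mot$d * u
  g <- LATERAL_COUPLING * (mot$d / mot$L) * u
  dx <- (C - mot$cm) * g
  list(dy = dy, dx = dx)
}

## Inverse map (phase -> base): rows first (piecewise linear, monotone),
## then columns given the base row.
phantomInverseMap <- function(mot, Rp, Cp) {
  k <- mot$d / mot$L
  R0 <- ifelse(Rp > mot$apex, (Rp + k * mot$apex) / (1 + k), Rp)
  u <- pmax(R0 - mot$apex, 0) / mot$L
  g <- LATERAL_COUPLING * k * u
  C0 <- mot$cm + (Cp - mot$cm) / (1 + g)
  list(R0 = R0, C0 = C0)
}

## Continuous base scene: intensity and lung membership at base coords.
phantomScene <- function(anat, ts, R0, C0) {
  se <- function(cx, a, b, p)
    (abs((C0 - cx) / a))^p + (abs((R0 - anat$cy) / b))^p <= 1
  lung <- se(anat$cxL, anat$aL, anat$bL, anat$pow) |
          se(anat$cxR, anat$aR, anat$bR, anat$pow)
  thorax <- ((C0 - anat$thoraxCx) / anat$thoraxA)^2 +
            ((R0 - anat$thoraxCy) / anat$thoraxB)^2 <= 1
  ribs <- ts * (0.10 * sin(2 * pi * R0 / anat$ribPeriod + anat$ribPhase) +
                0.05 * sin(2 * pi * C0 / anat$colPeriod + anat$colPhase))
  img <- 0.08 + 0.22 * thorax + 0.5 * ribs * thorax
  img[lung] <- 0.70 + ribs[lung]
  list(image = clip01(img), mask = lung * 1)
}

#' Generate one phantom frame and its lung mask
#'
#' Renders the chest-like phantom of `config` at a given breathing phase.
#' The binary mask is the exact analytic lung support used to brighten the
#' lung regions; at phase `p` the lower lung boundary sits
#' `breathingAmplitude * sin(pi * p) * lungHeight` pixels below its
#' end-expiration position. Identical `(config, phase)` give bit-identical
#' output; additive noise is seeded from `config@seed` (override with
#' `noiseSeed`, used by [generateBreathingSequence()] to give each frame an
#' independent noise realisation).
#'
#' @param config a [PhantomConfig-class].
#' @param phase breathing phase in [0, 1].
#' @param noiseSeed optional integer seed for the additive noise stream.
#' @return list with elements `image` (matrix in [0,1]) and `mask`
#'   (binary matrix).
#' @examples
#' p <- generatePhantom(phantomConfig(imageSize = 64, seed = 3), phase = 0.5)
#' range(p$image); mean(p$mask)
#' @export
generatePhantom <- function(config, phase, noiseSeed = NULL) {
  stopifnot(is(config, "PhantomConfig"))
  methods::validObject(config)
  if (!is.numeric(phase) || length(phase) != 1L || phase < 0 || phase > 1)
    stop("phase must be a single value in [0, 1]", call. = FALSE)
  s <- config@imageSize
  anat <- phantomAnatomy(config)
  mot <- phantomMotionScale(config, anat, phase)
  R <- matrix(0:(s - 1), s, s)            # 0-based row coords
  C <- matrix(0:(s - 1), s, s, byrow = TRUE)
  inv <- phantomInverseMap(mot, R, C)
  sc <- phantomScene(anat, config@textureStrength, inv$R0, inv$C0)
  img <- sc$image
  if (config@noiseSd > 0) {
    seed <- if (is.null(noiseSeed)) config@seed else noiseSeed
    noise <- withSeed(seed, stats::rnorm(s * s, 0, config@noiseSd))
    img <- clip01(img + matrix(noise, s, s))
  }
  list(image = img, mask = sc$mask)
}

## Ground-truth field warping the frame at `phase` back onto phase 0:
## V(p) = phi(p) - p on the output (= base) grid.
phantomTrueField <- function(config, phase) {
  s <- config@imageSize
  anat <- phantomAnatomy(config)
  mot <- phantomMotionScale(config, anat, phase)
  R <- matrix(0:(s - 1), s, s)
  C <- matrix(0:(s - 1), s, s, byrow = TRUE)
  fw <- phantomForwardMap(mot, R, C)
  displacementField(fw$dx, fw$dy)
}

#' Generate a full breathing sequence with ground-truth motion
#'
#' Samples `nFrames` frames at phases `k / (nFrames - 1)` (a single frame
#' sits at phase 0) and attaches, for every frame, the dense displacement
#' field of the generative motion model that warps it back onto frame 1.
#' Each frame receives an independent, seed-derived noise realisation.
#'
#' @param config a [PhantomConfig-class].
#' @return a [PhantomSequence-class].
#' @examples
#' seq <- generateBreathingSequence(phantomConfig(imageSize = 64, nFrames = 3))
#' length(frames(seq))
#' @export
generateBreathingSequence <- function(config) {
  stopifnot(is(config, "PhantomConfig"))
  methods::validObject(config)
  n <- config@nFrames
  phases <- if (n == 1L) 0 else (0:(n - 1)) / (n - 1)
  noiseSeeds <- deriveSeeds(config@seed, n)
  frames <- vector("list", n); msk <- vector("list", n); flds <- vector("list", n)
  for (k in seq_len(n)) {
    fr <- generatePhantom(config, phases[k], noiseSeed = noiseSeeds[k])
    frames[[k]] <- fr$image
    msk[[k]] <- fr$mask
    flds[[k]] <- phantomTrueField(config, phases[k])
  }
  new("PhantomSequence", frames = frames, masks = msk, trueFields = flds,
      config = config)
}

#' Default affine-augmentation sampling ranges
#'
#' Ranges used by the enhanced and final training steps to simulate
#' breathing-like pose changes: translation ±8% of the image side per
#' axis (the dominant component — a diaphragm excursion of roughly 8
#' pixels at the default desk scale), rotation ±4°, scale 0.96–1.04,
#' shear ±2°.
#'
#' @return named list of length-2 numeric ranges.
#' @export
defaultAffineRanges <- function() {
  list(rotation = c(-4, 4), scale = c(0.96, 1.04),
       translation = c(-0.08, 0.08), shear = c(-2, 2))
}

#' Sample affine-augmentation parameters
#'
#' Draws rotation, scale, per-axis translation and shear uniformly within
#' the given ranges; reproducible under `seed`.
#'
#' @param seed integer RNG seed.
#' @param ranges named list with entries `rotation` (degrees), `scale`,
#'   `translation` (fraction of image side, drawn independently for x and
#'   y) and `shear` (degrees); each a `c(lo, hi)` range with `lo <= hi`.
#' @return an [AffineParams-class].
#' @examples
#' sampleAffine(1, defaultAffineRanges())
#' @export
sampleAffine <- function(seed, ranges = defaultAffineRanges()) {
  need <- c("rotation", "scale", "translation", "shear")
  if (!all(need %in% names(ranges)))
    stop("ranges must name rotation, scale, translation and shear",
         call. = FALSE)
  for (nm in need) {
    r <- ranges[[nm]]
    if (length(r) != 2L || !all(is.finite(r)) || r[1] > r[2])
      stop(sprintf("invalid range for %s", nm), call. = FALSE)
  }
  withSeed(seed, {
    new("AffineParams",
        rotation = stats::runif(1, ranges$rotation[1], ranges$rotation[2]),
        scale = stats::runif(1, ranges$scale[1], ranges$scale[2]),
        translationX = stats::runif(1, ranges$translation[1], ranges$translation[2]),
        translationY = stats::runif(1, ranges$translation[1], ranges$translation[2]),
        shear = stats::runif(1, ranges$shear[1], ranges$shear[2]))
  })
}

#' Identity affine parameters
#' @return an [AffineParams-class] representing the identity transform.
#' @export
identityAffine <- function() {
  new("AffineParams", rotation = 0, scale = 1, translationX = 0,
      translationY = 0, shear = 0)
}
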