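## The four components of the composite registration loss and the
## weighted combination, exactly as the method defines them:
## total = -lNcc * NCC(I o T, J) + lTv * TV(T) + lBce * BCE(S_I o T, S_J)
##         + lL2 * mean((enc(S_I o T) - enc(S_J))^2).
## NCC uses population moments over all pixels with a single eps guard
## added under the square root of the denominator so it stays strictly
## positive even at zero variance.

nccParts <- function(a, b, eps) {
  ma <- mean(a); mb <- mean(b)
  da <- a - ma; db <- b - mb
  cov <- mean(da * db)
  va <- mean(da^2); vb <- mean(db^2)
  den <- sqrt(va * vb + eps)
  list(cov = cov, va = va, vb = vb, den = den, da = da, db = db,
       ncc = cov / den)
}

#' Negative normalized cross-correlation loss
#'
#' Returns `-cov(warped, target) / sqrt(Var(warped) * Var(target) + eps)`
#' computed with population moments over all pixels. Close to -1 for a
#' perfect (or affinely related) match, 0 when either input is constant;
#' always >= -1.
#'
#' @param warped,target numeric matrices of identical shape.
#' @param eps positive denominator guard (default 1e-5).
#' @return scalar loss in [-1, 1].
#' @examples
#' img <- matrix(runif(64), 8)
#' nccLoss(img, img)       # ~ -1
#' @export
nccLoss <- function(warped, target, eps = 1e-5) {
  assertRaster(warped, "warped"); assertRaster(target, "target")
  assertSameShape(warped, target, "warped and target")
  if (eps <= 0) stop("eps must be > 0", call. = FALSE)
  -nccParts(warped, target, eps)$ncc
}

## Gradient of nccLoss w.r.t. the warped image (used in training).
nccLossGrad <- function(warped, target, eps = 1e-5) {
  p <- nccParts(warped, target, eps)
  N <- length(warped)
  ## d(-cov/den)/da = -(db/N)/den + cov * vb * (da/N) / den^3
  grad <- -(p$db / N) / p$den + p$cov * p$vb * (p$da / N) / p$den^3
  list(loss = -p$ncc, grad = grad)
}

#' Numerical check of the two printed NCC algebraic forms
#'
#' The NCC denominator can be written with centred second moments
#' (`E[(X - EX)^2]`) or, after expanding by linearity of expectation,
#' with raw moments (`E[X^2] - (EX)^2`). Both forms are evaluated
#' independently and the absolute difference returned; algebraically the
#' difference is zero.
#'
#' @param I,J numeric matrices of identical shape.
#' @param eps denominator guard used by both forms.
#' @return absolute difference between the two evaluations.
#' @export
nccEquivalenceCheck <- function(I, J, eps = 1e-5) {
  assertRaster(I, "I"); assertRaster(J, "J")
  assertSameShape(I, J, "I and J")
  mi <- mean(I); mj <- mean(J)
  num <- mean((I - mi) * (J - mj))
  formA <- -num / sqrt(mean((I - mi)^2) * mean((J - mj)^2) + eps)
  formB <- -num / sqrt((mean(I^2) - mi^2) * (mean(J^2) - mj^2) + eps)
  abs(formA - formB)
}

#' Total-variation smoothness loss of a displacement field
#'
#' As printed in the method: the x-plane is differenced along its first
#' index and the y-plane along its second index; the two mean absolute
#' forward differences are averaged. `mode = "full"` instead differences
#' both planes along both axes (common practice) before averaging.
#'
#' @param field a [DisplacementField-class].
#' @param mode `"printed"` (default) or `"full"`.
#' @return nonnegative scalar; 0 for a constant field.
#' @examples
#' tvLoss(displacementField(matrix(0, 4, 4), matrix(0, 4, 4)))  # 0
#' @export
tvLoss <- function(field, mode = c("printed", "full")) {
  mode <- match.arg(mode)
  stopifnot(is(field, "DisplacementField"))
  dRow <- function(m) abs(m[-1, , drop = FALSE] - m[-nrow(m), , drop = FALSE])
  dCol <- function(m) abs(m[, -1, drop = FALSE] - m[, -ncol(m), drop = FALSE])
  if (mode == "printed")
    (mean(dRow(field@dx)) + mean(dCol(field@dy))) / 2
  else
    (mean(dRow(field@dx)) + mean(dCol(field@dx)) +
       mean(dRow(field@dy)) + mean(dCol(field@dy))) / 4
}

## Gradient of the printed-form TV loss w.r.t. both planes.
tvLossGrad <- function(dx, dy) {
  H <- nrow(dx); W <- ncol(dx)
  gdx <- matrix(0, H, W); gdy <- matrix(0, H, W)
  sR <- sign(dx[-1, , drop = FALSE] - dx[-H, , drop = FALSE])
  nR <- (H - 1) * W
  gdx[-1, ] <- gdx[-1, ] + sR / nR / 2
  gdx[-H, ] <- gdx[-H, ] - sR / nR / 2
  sC <- sign(dy[, -1, drop = FALSE] - dy[, -W, drop = FALSE])
  nC <- H * (W - 1)
  gdy[, -1] <- gdy[, -1] + sC / nC / 2
  gdy[, -W] <- gdy[, -W] - sC / nC / 2
  loss <- (sum(abs(dx[-1, ] - dx[-H, ])) / nR +
             sum(abs(dy[, -1] - dy[, -W])) / nC) / 2
  list(loss = loss, gdx = gdx, gdy = gdy)
}

#' Binary cross-entropy between a warped (soft) mask and a target mask
#'
#' Mean over pixels of `-(s log p + (1 - s) log(1 - p))` with the
#' prediction clamped to `[clip, 1 - clip]` to avoid `log(0)`.
#'
#' @param warpedMask numeric matrix in [0,1] (soft warped mask).
#' @param targetMask binary matrix of the same shape.
#' @param clip clamp bound (default 1e-7).
#' @return nonnegative scalar.
#' @examples
#' bceLoss(matrix(0.5, 4, 4), matrix(1, 4, 4))   # log(2)
#' @export
bceLoss <- function(warpedMask, targetMask, clip = 1e-7) {
  assertRaster(warpedMask, "warpedMask")
  assertMask(targetMask, "targetMask")
  assertSameShape(warpedMask, targetMask, "warpedMask and targetMask")
  p <- pmin(1 - clip, pmax(clip, warpedMask))
  mean(-(targetMask * log(p) + (1 - targetMask) * log(1 - p)))
}

## Loss + gradient w.r.t. the (unclamped) soft mask.
bceLossGrad <- function(warpedMask, targetMask, clip = 1e-7) {
  p <- pmin(1 - clip, pmax(clip, warpedMask))
  loss <- mean(-(targetMask * log(p) + (1 - targetMask) * log(1 - p)))
  grad <- (p - targetMask) / (p * (1 - p)) / length(p)
  grad[warpedMask != p] <- 0
  list(loss = loss, grad = grad)
}

#' Latent-space anatomical constraint
#'
#' Mean squared difference between the encoder codes of the warped source
#' mask and the target mask, averaged over all n^2 grid entries.
#'
#' @param codeWarped,codeTarget [EncoderCode-class] objects of identical
#'   grid size.
#' @return nonnegative scalar.
#' @export
l2LatentLoss <- function(codeWarped, codeTarget) {
  stopifnot(is(codeWarped, "EncoderCode"), is(codeTarget, "EncoderCode"))
  assertSameShape(codeWarped@values, codeTarget@values, "codes")
  mean((codeWarped@values - codeTarget@values)^2)
}

#' Evaluate the composite registration loss
#'
#' Warps the source image and source mask by `field` through the
#' differentiable warper (bilinear, zeros padding; the mask is warped
#' softly), computes the four loss terms and combines them with the given
#' weights:
#' `total = -lNcc * NCC + lTv * TV + lBce * BCE + lL2 * L2`.
#'
#' @param source,target intensity matrices in [0,1].
#' @param sourceMask,targetMask binary matrices.
#' @param field a [DisplacementField-class].
#' @param weights a [LossWeights-class].
#' @param encoder an `"autoencoder"` [ConvModel-class]; required when
#'   `lambdaL2 > 0` (its frozen encoder provides the anatomical term).
#' @return a [LossBreakdown-class].
#' @examples
#' cfg <- phantomConfig(imageSize = 64, seed = 2)
#' p <- generatePhantom(cfg, 0)
#' z <- displacementField(matrix(0, 64, 64), matrix(0, 64, 64))
#' compositeLoss(p$image, p$image, p$mask, p$mask, z,
#'               weights = lossWeights(lambdaL2 = 0))
#' @export
compositeLoss <- function(source, target, sourceMask, targetMask, field,
                          weights = lossWeights(), encoder = NULL) {
  assertIntensityRaster(source, "source")
  assertIntensityRaster(target, "target")
  assertMask(sourceMask, "sourceMask")
  assertMask(targetMask, "targetMask")
  stopifnot(is(field, "DisplacementField"))
  assertSameShape(source, field@dx, "source and field")
  if (weights@lambdaL2 > 0 && is.null(encoder))
    stop("an encoder model is required when lambdaL2 > 0", call. = FALSE)
  warped <- warpCore(source, field, "bilinear", "zeros")
  warpedMask <- warpCore(sourceMask, field, "bilinear", "zeros")
  ncc <- -nccLoss(warped, target, weights@eps)
  tv <- tvLoss(field)
  bce <- bceLoss(warpedMask, targetMask)
  l2 <- if (weights@lambdaL2 > 0)
    l2LatentLoss(new("EncoderCode",
                     values = aeEncodeForward(encoder@params, warpedMask)$code),
                 encodeMask(encoder, targetMask))
  else 0
  new("LossBreakdown", ncc = ncc, tv = tv, bce = bce, l2 = l2,
      total = -weights@lambdaNcc * ncc + weights@lambdaTv * tv +
        weights@lambdaBce * bce + weights@lambdaL2 * l2)
}
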