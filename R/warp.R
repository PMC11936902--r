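## The differentiable warper: backward resampling of rasters by a dense
## displacement field. Output pixel p = (r, c) (0-based) samples the input
## at (r + dy[p], c + dx[p]); bilinear interpolation for intensity images,
## nearest-neighbour for binary masks; out-of-bounds samples follow the
## padding rule ("zeros" reads 0, "border" clamps to the edge).

## Gather with zero padding at 0-based (r, c); r, c numeric matrices.
gatherZeros <- function(I, r, c) {
  H <- nrow(I); W <- ncol(I)
  ok <- r >= 0 & r <= H - 1 & c >= 0 & c <= W - 1
  v <- numeric(length(r))
  idx <- (r[ok] + 1) + c[ok] * H
  v[ok] <- I[idx]
  matrix(v, nrow(r), ncol(r))
}

warpCore <- function(input, field, interpolation, padding) {
  H <- nrow(input); W <- ncol(input)
  R <- matrix(0:(H - 1), H, W)
  C <- matrix(0:(W - 1), H, W, byrow = TRUE)
  rs <- R + field@dy
  cs <- C + field@dx
  if (padding == "border") {
    rs <- pmin(pmax(rs, 0), H - 1)
    cs <- pmin(pmax(cs, 0), W - 1)
  }
  if (interpolation == "nearest") {
    out <- gatherZeros(input, round(rs), round(cs))
    return(out)
  }
  r0 <- floor(rs); c0 <- floor(cs)
  fr <- rs - r0; fc <- cs - c0
  g00 <- gatherZeros(input, r0, c0)
  g01 <- gatherZeros(input, r0, c0 + 1)
  g10 <- gatherZeros(input, r0 + 1, c0)
  g11 <- gatherZeros(input, r0 + 1, c0 + 1)
  (1 - fr) * (1 - fc) * g00 + (1 - fr) * fc * g01 +
    fr * (1 - fc) * g10 + fr * fc * g11
}

#' Warp a raster by a displacement field
#'
#' Applies a [DisplacementField-class] by backward sampling: the output at
#' pixel p equals the input at p + (dx, dy). Intensity images use bilinear
#' interpolation; binary masks must use nearest-neighbour (which preserves
#' strict binarity). The soft differentiable path used in training warps
#' masks bilinearly internally; this user-facing function enforces the
#' hard evaluation convention.
#'
#' @param input numeric matrix (image in [0,1] or binary mask).
#' @param field a [DisplacementField-class] of the same shape.
#' @param interpolation `"bilinear"` (images) or `"nearest"` (masks).
#' @param padding `"zeros"` (default) or `"border"` for out-of-bounds
#'   samples.
#' @return matrix of the input's shape (strictly binary when a binary
#'   input is warped with nearest interpolation).
#' @examples
#' img <- matrix(runif(16), 4)
#' identical(warpRaster(img, displacementField(matrix(0, 4, 4),
#'                                             matrix(0, 4, 4))), img)
#' @export
warpRaster <- function(input, field,
                       interpolation = c("bilinear", "nearest"),
                       padding = c("zeros", "border")) {
  interpolation <- match.arg(interpolation)
  padding <- match.arg(padding)
  assertRaster(input, "input")
  stopifnot(is(field, "DisplacementField"))
  assertSameShape(input, field@dx, "input and field")
  isMask <- all(input %in% c(0, 1)) && length(unique(as.vector(input))) <= 2
  if (interpolation == "bilinear" && isMask && !all(input == input[1]))
    stop("bilinear interpolation on a binary mask; use interpolation = \"nearest\"",
         call. = FALSE)
  if (all(field@dx == 0) && all(field@dy == 0)) return(input)  # exact identity
  out <- warpCore(input, field, interpolation, padding)
  if (interpolation == "nearest" && isMask) out <- (out > 0.5) * 1
  out
}

## Differentiable warp used in training: bilinear, zeros padding.
## Returns the warped raster plus everything needed to backpropagate a
## gradient on the output to a gradient on the field planes.
warpBilinearGrad <- function(input, dxp, dyp) {
  H <- nrow(input); W <- ncol(input)
  R <- matrix(0:(H - 1), H, W)
  C <- matrix(0:(W - 1), H, W, byrow = TRUE)
  rs <- R + dyp; cs <- C + dxp
  r0 <- floor(rs); c0 <- floor(cs)
  fr <- rs - r0; fc <- cs - c0
  g00 <- gatherZeros(input, r0, c0)
  g01 <- gatherZeros(input, r0, c0 + 1)
  g10 <- gatherZeros(input, r0 + 1, c0)
  g11 <- gatherZeros(input, r0 + 1, c0 + 1)
  out <- (1 - fr) * (1 - fc) * g00 + (1 - fr) * fc * g01 +
    fr * (1 - fc) * g10 + fr * fc * g11
  ## d out / d cs and d out / d rs (piecewise-linear bilinear derivatives)
  dcs <- (1 - fr) * (g01 - g00) + fr * (g11 - g10)
  drs <- (1 - fc) * (g10 - g00) + fc * (g11 - g01)
  list(out = out, dcs = dcs, drs = drs)
}

## Build the backward-mapping displacement field realising an affine
## transform: content rotates/shears/scales about the image centre and
## moves by + (translationX, translationY) * image side.
affineField <- function(params, H, W) {
  stopifnot(is(params, "AffineParams"))
  th <- params@rotation * pi / 180
  sh <- tan(params@shear * pi / 180)
  Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)  # col-major
  Sh <- matrix(c(1, 0, sh, 1), 2, 2)
  M <- Rm %*% Sh * params@scale
  Minv <- solve(M)
  cx <- (W - 1) / 2; cy <- (H - 1) / 2
  tx <- params@translationX * W; ty <- params@translationY * H
  R <- matrix(0:(H - 1), H, W)
  C <- matrix(0:(W - 1), H, W, byrow = TRUE)
  ## forward: q = M (p - c) + c + t  =>  sample input at M^-1 (q - c - t) + c
  qx <- C - cx - tx; qy <- R - cy - ty
  px <- Minv[1, 1] * qx + Minv[1, 2] * qy + cx
  py <- Minv[2, 1] * qx + Minv[2, 2] * qy + cy
  displacementField(px - C, py - R)
}

#' Apply an affine transform to a raster
#'
#' Realises the transform as a backward-mapping displacement field and
#' warps through the same resampling machinery as [warpRaster()]
#' (bilinear for images, nearest + re-binarization for masks, zeros
#' padding).
#'
#' @param input numeric matrix.
#' @param params an [AffineParams-class].
#' @param interpolation `"bilinear"` or `"nearest"`.
#' @return transformed matrix of the same shape.
#' @export
applyAffine <- function(input, params,
                        interpolation = c("bilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  assertRaster(input, "input")
  fld <- affineField(params, nrow(input), ncol(input))
  warpRaster(input, fld, interpolation = interpolation, padding = "zeros")
}
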