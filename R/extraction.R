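## Stage II: binarize segmentation outputs and extract lung-field images.

#' Binarize a probabilistic or label raster into a lung mask
#'
#' Pixels strictly greater than `threshold` become 1, all others 0 (ties
#' at the threshold go to 0 — documented strict inequality).
#'
#' @param raw numeric matrix in [0,1] (segmenter probabilities or labels).
#' @param threshold scalar strictly inside (0, 1); default 0.5.
#' @param cleanup if `TRUE`, keep only the two largest 4-connected
#'   foreground components (for noisy segmenters; off by default).
#' @return a binary matrix.
#' @examples
#' binarizeMask(matrix(c(0.2, 0.7, 0.5, 0.9), 2), threshold = 0.5)
#' @export
binarizeMask <- function(raw, threshold = 0.5, cleanup = FALSE) {
  assertIntensityRaster(raw, "raw")
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1)
    stop("threshold must lie strictly inside (0, 1)", call. = FALSE)
  m <- (raw > threshold) * 1
  if (cleanup && any(m > 0)) m <- keepLargestComponents(m, 2L)
  m
}

## Keep the k largest 4-connected foreground components.
keepLargestComponents <- function(mask, k = 2L) {
  lab <- EBImage::bwlabel(mask)
  sizes <- tabulate(lab[lab > 0])
  if (length(sizes) <= k) return(mask)
  keep <- order(sizes, decreasing = TRUE)[seq_len(k)]
  matrix(as.numeric(lab %in% keep), nrow(mask), ncol(mask))
}

#' Extract the lung-field image by pixel-wise multiplication
#'
#' Multiplies a chest image by its binary lung mask: pixels outside the
#' lung field become exactly 0, pixels inside retain the original
#' grayscale.
#'
#' @param image numeric matrix in [0,1].
#' @param mask binary matrix of the same shape.
#' @return numeric matrix, `image * mask`.
#' @examples
#' extractLungField(matrix(c(0.2, 0.4, 0.6, 0.8), 2),
#'                  matrix(c(1, 0, 0, 1), 2))
#' @export
extractLungField <- function(image, mask) {
  assertIntensityRaster(image, "image")
  assertMask(mask, "mask")
  assertSameShape(image, mask, "image and mask")
  image * mask
}
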