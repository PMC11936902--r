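## Registration evaluation metrics: Dice similarity coefficient, Hausdorff
## distance, average symmetric surface distance and mean squared intensity
## distance, plus per-pair reports with aggregates and paired significance
## testing.
##
## HD and ASSD operate on boundary pixel sets: foreground pixels with at
## least one background 4-neighbour (pixels on the image border count as
## boundary). The set form of the printed ASSD sums each boundary point's
## distance to its own surface, which is identically zero; the standard
## symmetric surface distance is implemented instead and this reading is
## documented here and in the vignette.

#' Dice similarity coefficient of two binary masks
#'
#' `2 |A intersect B| / (|A| + |B|)` over foreground pixels; defined as 1
#' when both masks are empty.
#'
#' @param a,b binary matrices of identical shape.
#' @return scalar in [0, 1].
#' @examples
#' dsc(matrix(c(1, 1, 0, 0), 2), matrix(c(1, 1, 0, 0), 2))   # 1
#' @export
dsc <- function(a, b) {
  assertMask(a, "a"); assertMask(b, "b")
  assertSameShape(a, b, "masks")
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1.0)
  2 * sum(a * b) / (sa + sb)
}

## 0-based (r, c) coordinates of boundary pixels (foreground with a
## background 4-neighbour; image border counts as background).
boundaryCoords <- function(m) {
  H <- nrow(m); W <- ncol(m)
  p <- matrix(0, H + 2L, W + 2L)
  p[2:(H + 1), 2:(W + 1)] <- m
  core <- p[2:(H + 1), 2:(W + 1)]
  nb <- p[1:H, 2:(W + 1)] * p[3:(H + 2), 2:(W + 1)] *
    p[2:(H + 1), 1:W] * p[2:(H + 1), 3:(W + 2)]
  bnd <- core == 1 & nb == 0
  which(bnd, arr.ind = TRUE) - 1L
}

## Full-region coordinate set.
regionCoords <- function(m) which(m == 1, arr.ind = TRUE) - 1L

## For every point of A, the Euclidean distance to the nearest point of B
## (vectorized |a|^2 + |b|^2 - 2 a.b distance matrix).
nearestDistances <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  sqrt(pmax(apply(d2, 1L, min), 0))
}

#' Hausdorff distance between two masks
#'
#' The larger of the two directed maxima of pointwise Euclidean
#' nearest-neighbour distances between the masks' point sets —
#' boundary pixels by default, full foreground regions with
#' `mode = "region"`.
#'
#' @param a,b nonempty binary matrices of identical shape.
#' @param mode `"surface"` (default) or `"region"`.
#' @return nonnegative scalar (pixels).
#' @examples
#' m1 <- matrix(0, 8, 8); m1[1, 1] <- 1
#' m2 <- matrix(0, 8, 8); m2[4, 5] <- 1
#' hausdorff(m1, m2)   # 5 (3-4-5 triangle)
#' @export
hausdorff <- function(a, b, mode = c("surface", "region")) {
  mode <- match.arg(mode)
  assertMask(a, "a"); assertMask(b, "b")
  assertSameShape(a, b, "masks")
  if (sum(a) == 0 || sum(b) == 0)
    stop("Hausdorff distance is undefined for an empty mask", call. = FALSE)
  getC <- if (mode == "surface") boundaryCoords else regionCoords
  A <- getC(a); B <- getC(b)
  max(max(nearestDistances(A, B)), max(nearestDistances(B, A)))
}

#' Average symmetric surface distance between two masks
#'
#' `(sum_{x in bd(A)} d(x, bd(B)) + sum_{y in bd(B)} d(y, bd(A))) /
#' (|bd(A)| + |bd(B)|)` over boundary pixel sets.
#'
#' @param a,b nonempty binary matrices of identical shape.
#' @return nonnegative scalar (pixels).
#' @export
assd <- function(a, b) {
  assertMask(a, "a"); assertMask(b, "b")
  assertSameShape(a, b, "masks")
  if (sum(a) == 0 || sum(b) == 0)
    stop("ASSD is undefined for an empty mask", call. = FALSE)
  A <- boundaryCoords(a); B <- boundaryCoords(b)
  (sum(nearestDistances(A, B)) + sum(nearestDistances(B, A))) /
    (nrow(A) + nrow(B))
}

#' Mean squared intensity distance between two images
#'
#' `mean((a - b)^2)` computed on intensities multiplied by `scale`.
#' Intensities live in [0,1] internally; the default `scale = 255`
#' reports on the 8-bit scale conventional for this metric.
#'
#' @param a,b numeric matrices of identical shape.
#' @param scale intensity reporting scale (default 255).
#' @return nonnegative scalar.
#' @examples
#' msd(matrix(0.5, 4, 4), matrix(0.5, 4, 4))   # 0
#' @export
msd <- function(a, b, scale = 255) {
  assertRaster(a, "a"); assertRaster(b, "b")
  assertSameShape(a, b, "images")
  mean(((a - b) * scale)^2)
}

## One report row; empty masks make the distance metrics undefined and
## flag the row (excluded from aggregates with a warning at report time).
metricRow <- function(i, j, fixedMask, movingMask, fixedImage, movingImage,
                      msdScale = 255) {
  empty <- sum(fixedMask) == 0 || sum(movingMask) == 0
  data.frame(
    source = i, target = j,
    dsc = dsc(movingMask, fixedMask),
    hd = if (empty) NA_real_ else hausdorff(movingMask, fixedMask),
    assd = if (empty) NA_real_ else assd(movingMask, fixedMask),
    msd = msd(movingImage, fixedImage, msdScale),
    flagged = empty)
}

aggregateMetricRows <- function(rows) {
  ok <- rows[!rows$flagged, , drop = FALSE]
  agg <- do.call(rbind, lapply(c("dsc", "hd", "assd", "msd"), function(m) {
    v <- ok[[m]]
    data.frame(metric = m, mean = mean(v), sd = stats::sd(v),
               min = min(v), max = max(v))
  }))
  rownames(agg) <- NULL
  agg
}

newMetricsReport <- function(rows) {
  rownames(rows) <- NULL
  if (any(rows$flagged))
    warning(sprintf("%d pair(s) with an empty mask flagged and excluded from aggregates",
                    sum(rows$flagged)))
  new("MetricsReport", rows = rows, aggregates = aggregateMetricRows(rows))
}

#' Evaluate registration metrics over a list of pairs
#'
#' Computes DSC, HD, ASSD and MSD per pair and aggregates mean, SD, min
#' and max per metric (formatted as "mean (min-max) ± SD" when shown).
#' Pairs with an empty mask are flagged: DSC is still defined (1 for two
#' empty masks), the distance metrics are recorded as `NA` and the row is
#' excluded from aggregation with a warning.
#'
#' @param pairs list; each element a list with `fixedMask`, `movingMask`
#'   (binary matrices), `fixedImage`, `movingImage` (intensity matrices),
#'   and optionally `source`/`target` ids.
#' @param msdScale intensity scale for MSD (default 255).
#' @return a [MetricsReport-class].
#' @export
evaluatePairs <- function(pairs, msdScale = 255) {
  if (!is.list(pairs) || length(pairs) == 0L)
    stop("pairs must be a nonempty list", call. = FALSE)
  rows <- do.call(rbind, lapply(seq_along(pairs), function(k) {
    p <- pairs[[k]]
    metricRow(if (is.null(p$source)) k else p$source,
              if (is.null(p$target)) k else p$target,
              p$fixedMask, p$movingMask, p$fixedImage, p$movingImage,
              msdScale)
  }))
  newMetricsReport(rows)
}

#' Paired two-sided significance test between two metric columns
#'
#' Wilcoxon signed-rank by default (no normality assumption on the paired
#' differences), paired t-test as an option. Identical columns return
#' p = 1 by convention (the signed-rank statistic is undefined when all
#' differences are zero).
#'
#' @param armA,armB numeric vectors of equal length >= 2 (the same metric
#'   under two registration arms, pairs aligned).
#' @param method `"wilcoxon"` (default) or `"ttest"`.
#' @return two-sided p-value.
#' @export
pairedSignificance <- function(armA, armB, method = c("wilcoxon", "ttest")) {
  method <- match.arg(method)
  if (length(armA) != length(armB))
    stop("arms must have equal length", call. = FALSE)
  if (length(armA) < 2L)
    stop("need at least 2 paired observations", call. = FALSE)
  d <- armA - armB
  if (all(d == 0)) return(1.0)
  if (method == "wilcoxon")
    suppressWarnings(stats::wilcox.test(armA, armB, paired = TRUE,
                                        exact = FALSE))$p.value
  else
    stats::t.test(armA, armB, paired = TRUE)$p.value
}
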