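## Stage-complete inference: segmentation -> lung-field extraction ->
## deformable registration over frames or whole sequences.

#' Register one source frame onto a target frame
#'
#' Runs the full three-stage pipeline on a frame pair: segments both
#' frames (Stage I), extracts both lung fields (Stage II), predicts the
#' dense displacement field on the lung-field pair and warps the source
#' lung field (bilinear) and source mask (nearest) by it (Stage III).
#'
#' @param source,target intensity matrices in [0,1] of the models'
#'   configured size.
#' @param segModel trained `"segmenter"` [ConvModel-class].
#' @param regModel trained `"vectorcnn"` [ConvModel-class]
#'   (conventionally the step-3 model V3).
#' @param threshold mask binarization threshold (default 0.5).
#' @return list with `registered` (warped lung field), `field`
#'   (the [DisplacementField-class]), `mask` (warped binary mask),
#'   `sourceMask`, `targetMask`, `sourceLungField`, `targetLungField`.
#' @export
registerPair <- function(source, target, segModel, regModel,
                         threshold = 0.5) {
  assertIntensityRaster(source, "source")
  assertIntensityRaster(target, "target")
  assertSameShape(source, target, "source and target")
  stopifnot(is(segModel, "ConvModel"), is(regModel, "ConvModel"))
  if (segModel@kind != "segmenter")
    stop("segmentation stage: segModel is not a segmenter", call. = FALSE)
  if (regModel@kind != "vectorcnn")
    stop("registration stage: regModel is not a deformation predictor",
         call. = FALSE)
  sMask <- binarizeMask(predictSegmenter(segModel, source), threshold)
  tMask <- binarizeMask(predictSegmenter(segModel, target), threshold)
  if (sum(sMask) == 0 || sum(tMask) == 0)
    stop("segmentation stage produced an empty lung mask", call. = FALSE)
  sLF <- extractLungField(source, sMask)
  tLF <- extractLungField(target, tMask)
  fld <- predictField(regModel, sLF, tLF)
  list(registered = warpRaster(sLF, fld, "bilinear"),
       field = fld,
       mask = warpRaster(sMask, fld, "nearest"),
       sourceMask = sMask, targetMask = tMask,
       sourceLungField = sLF, targetLungField = tLF)
}

#' Register a dynamic sequence
#'
#' `mode = "all_pairs"` registers every ordered frame pair (n^2 - n
#' registrations, the quantitative-evaluation protocol);
#' `mode = "to_reference"` registers the reference frame onto every other
#' frame (n - 1 registrations, the figure-style protocol). Per-pair
#' artifacts are written under `out` when given.
#'
#' @param frames list of intensity matrices (>= 2).
#' @param segModel,regModel trained models as in [registerPair()].
#' @param mode `"all_pairs"` or `"to_reference"`.
#' @param refIndex reference frame for `to_reference` (default 1).
#' @param out optional output directory for registered rasters, fields and
#'   the report.
#' @param msdScale MSD reporting scale.
#' @return list with `report` (a [MetricsReport-class] comparing warped
#'   masks/lung fields against the targets') and `results` (per-pair
#'   registration outputs).
#' @export
registerSequence <- function(frames, segModel, regModel,
                             mode = c("all_pairs", "to_reference"),
                             refIndex = 1L, out = NULL, msdScale = 255) {
  mode <- match.arg(mode)
  n <- length(frames)
  if (n < 2L) stop("need at least 2 frames", call. = FALSE)
  pairsIdx <- if (mode == "all_pairs") {
    enum <- enumerateOrderedPairs(n)
    lapply(seq_len(enum$count), enum$pairAt)
  } else {
    if (refIndex < 1L || refIndex > n)
      stop(sprintf("bad reference index %d (1..%d)", refIndex, n),
           call. = FALSE)
    lapply(setdiff(seq_len(n), refIndex), function(j) c(i = refIndex, j = j))
  }
  results <- vector("list", length(pairsIdx))
  rows <- vector("list", length(pairsIdx))
  if (!is.null(out)) dir.create(out, recursive = TRUE, showWarnings = FALSE)
  for (k in seq_along(pairsIdx)) {
    ij <- pairsIdx[[k]]
    r <- registerPair(frames[[ij[1]]], frames[[ij[2]]], segModel, regModel)
    results[[k]] <- r
    rows[[k]] <- metricRow(ij[1], ij[2], r$targetMask, r$mask,
                           r$targetLungField, r$registered, msdScale)
    if (!is.null(out)) {
      tag <- sprintf("%03d_%03d", ij[1], ij[2])
      writeRaster(file.path(out, sprintf("registered_%s.png", tag)),
                  clip01(r$registered))
      writeRaster(file.path(out, sprintf("mask_%s.png", tag)), r$mask)
      writeField(file.path(out, sprintf("field_%s.fld", tag)), r$field)
    }
  }
  report <- newMetricsReport(do.call(rbind, rows))
  if (!is.null(out)) writeReport(file.path(out, "report.csv"), report)
  list(report = report, results = results)
}
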