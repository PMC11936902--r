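#' @include generics.R
NULL

#' Frames of a phantom sequence
#'
#' Accessors for the ordered components of a [PhantomSequence-class]:
#' the grayscale frames, their binary lung masks, and the ground-truth
#' displacement fields mapping each frame back onto frame 1.
#'
#' @param x a `PhantomSequence`.
#' @return `frames` and `masks` return lists of matrices; `trueFields`
#'   returns a list of [DisplacementField-class] objects.
#' @aliases frames masks trueFields
#' @rdname sequence-accessors
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))

#' @rdname sequence-accessors
#' @export
setGeneric("masks", function(x) standardGeneric("masks"))

#' @rdname sequence-accessors
#' @export
setGeneric("trueFields", function(x) standardGeneric("trueFields"))

#' Displacement-field plane accessors
#'
#' `fieldX` returns the column-displacement plane (pixels), `fieldY` the
#' row-displacement plane. The field follows the backward-mapping
#' convention: the warped output at pixel p samples the input at
#' p + (dx, dy).
#'
#' @param x a [DisplacementField-class].
#' @return a numeric matrix.
#' @aliases fieldX fieldY
#' @rdname field-accessors
#' @export
setGeneric("fieldX", function(x) standardGeneric("fieldX"))

#' @rdname field-accessors
#' @export
setGeneric("fieldY", function(x) standardGeneric("fieldY"))

#' Metrics-report accessors
#'
#' `reportRows` returns the per-pair metric rows (one row per registered
#' source/target pair); `reportAggregates` returns the mean/SD/min/max
#' summary per metric, recomputed from the unflagged rows.
#'
#' @param x a [MetricsReport-class].
#' @return a `data.frame`.
#' @aliases reportRows reportAggregates
#' @rdname report-accessors
#' @export
setGeneric("reportRows", function(x) standardGeneric("reportRows"))

#' @rdname report-accessors
#' @export
setGeneric("reportAggregates", function(x) standardGeneric("reportAggregates"))

#' Latent grid side length of a network configuration
#'
#' The autoencoder encoder maps an `imageSize` x `imageSize` mask to an
#' `n` x `n` single-channel code with `n = imageSize / 2^depth`.
#'
#' @param x a [NetConfig-class].
#' @return integer scalar.
#' @export
setGeneric("latentGrid", function(x) standardGeneric("latentGrid"))
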