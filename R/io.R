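## Raster, field, manifest and report IO.
##
## Conventions (asserted here, imported everywhere): rasters are numeric
## matrices with row 1 at the image top and column 1 at the left; pixel
## coordinates used for fields are 0-based (r, c); displacement fields are
## backward-mapping in pixel units. Intensities are rescaled to [0,1] by
## the maximum representable value of the file's bit depth.

FIELD_MAGIC <- charToRaw("LFD1")

#' Read a grayscale raster or binary mask
#'
#' Reads a single-channel 8- or 16-bit PNG or TIFF file. Intensities are
#' rescaled by the maximum representable value to [0,1]; for
#' `kind = "mask"` the result is binarized at > 0.5 after rescaling.
#'
#' @param path file path (extension selects the decoder).
#' @param kind `"image"` (default) or `"mask"`.
#' @return a numeric matrix in [0,1] (`"image"`) or {0,1} (`"mask"`).
#' @seealso [writeRaster()]
#' @export
readRaster <- function(path, kind = c("image", "mask")) {
  kind <- match.arg(kind)
  if (!file.exists(path))
    stop(sprintf("raster file does not exist: %s", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  x <- tryCatch({
    if (ext %in% c("png")) png::readPNG(path)
    else if (ext %in% c("tif", "tiff")) tiff::readTIFF(path)
    else stop("unsupported extension (need png/tif/tiff)")
  }, error = function(e)
    stop(sprintf("cannot read raster %s: %s", path, conditionMessage(e)),
         call. = FALSE))
  if (length(dim(x)) == 3L) {
    if (dim(x)[3] != 1L)
      stop(sprintf("multi-channel raster not supported: %s (%d channels)",
                   path, dim(x)[3]), call. = FALSE)
    x <- x[, , 1L]
  }
  if (!is.matrix(x))
    stop(sprintf("unreadable raster: %s", path), call. = FALSE)
  if (kind == "mask") (x > 0.5) * 1 else x
}

#' Write a grayscale raster or binary mask
#'
#' Writes an 8-bit single-channel PNG or TIFF (values quantised to 1/255
#' steps; binary masks round-trip exactly).
#'
#' @param path output path (`.png`, `.tif`/`.tiff`).
#' @param x numeric matrix in [0,1].
#' @return `path`, invisibly.
#' @export
writeRaster <- function(path, x) {
  assertIntensityRaster(x, "x")
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") png::writePNG(x, target = path)
  else if (ext %in% c("tif", "tiff")) tiff::writeTIFF(x, where = path,
                                                      bits.per.sample = 8L)
  else stop("unsupported extension (need png/tif/tiff)", call. = FALSE)
  invisible(path)
}

#' Write a displacement field to its binary container
#'
#' The container is a little-endian binary file: 4-byte magic `"LFD1"`,
#' two int32 values (height, width), then the dx plane and the dy plane
#' as column-major float32. Values are therefore stored at 32-bit float
#' precision; [readField()] inverts the writer bit-exactly at that
#' precision.
#'
#' @param path output path.
#' @param field a [DisplacementField-class].
#' @return `path`, invisibly.
#' @export
writeField <- function(path, field) {
  stopifnot(is(field, "DisplacementField"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(FIELD_MAGIC, con)
  writeBin(as.integer(dim(field@dx)), con, size = 4L, endian = "little")
  writeBin(as.vector(field@dx), con, size = 4L, endian = "little")
  writeBin(as.vector(field@dy), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read a displacement field written by [writeField()]
#'
#' @param path file path.
#' @return a [DisplacementField-class].
#' @export
readField <- function(path) {
  if (!file.exists(path))
    stop(sprintf("field file does not exist: %s", path), call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 4L)
  if (length(magic) < 4L || !identical(magic, FIELD_MAGIC))
    stop(sprintf("not a displacement-field file (bad magic): %s", path),
         call. = FALSE)
  hw <- readBin(con, "integer", 2L, size = 4L, endian = "little")
  if (length(hw) < 2L || any(hw < 2L))
    stop(sprintf("corrupt field header: %s", path), call. = FALSE)
  n <- hw[1] * hw[2]
  dx <- readBin(con, "double", n, size = 4L, endian = "little")
  dy <- readBin(con, "double", n, size = 4L, endian = "little")
  if (length(dx) != n || length(dy) != n)
    stop(sprintf("truncated field file: %s", path), call. = FALSE)
  displacementField(matrix(dx, hw[1], hw[2]), matrix(dy, hw[1], hw[2]))
}

#' Write a sequence manifest
#'
#' JSON manifest listing the per-frame artifact files of a simulated or
#' registered sequence, plus the generating configuration when known.
#'
#' @param dir directory holding the frame/mask/field files.
#' @param frameFiles,maskFiles,fieldFiles character vectors of file names
#'   relative to `dir` (`fieldFiles` may be `NULL`).
#' @param config optional [PhantomConfig-class] recorded in the manifest.
#' @return the manifest path, invisibly.
#' @export
writeSequenceManifest <- function(dir, frameFiles, maskFiles,
                                  fieldFiles = NULL, config = NULL) {
  m <- list(nFrames = length(frameFiles), frames = frameFiles,
            masks = maskFiles)
  if (!is.null(fieldFiles)) m$fields <- fieldFiles
  if (!is.null(config))
    m$config <- list(imageSize = config@imageSize, nFrames = config@nFrames,
                     breathingAmplitude = config@breathingAmplitude,
                     textureStrength = config@textureStrength,
                     noiseSd = config@noiseSd, seed = config@seed)
  path <- file.path(dir, "sequence.json")
  jsonlite::write_json(m, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a sequence manifest and its rasters
#'
#' @param dir directory containing `sequence.json`.
#' @return list with `frames`, `masks` (lists of matrices), `fields`
#'   (list of [DisplacementField-class] or `NULL`), and `manifest`.
#' @export
readSequenceManifest <- function(dir) {
  path <- file.path(dir, "sequence.json")
  if (!file.exists(path))
    stop(sprintf("no sequence.json in %s", dir), call. = FALSE)
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  frames <- lapply(file.path(dir, m$frames), readRaster, kind = "image")
  msk <- lapply(file.path(dir, m$masks), readRaster, kind = "mask")
  fields <- if (!is.null(m$fields)) lapply(file.path(dir, m$fields), readField)
  list(frames = frames, masks = msk, fields = fields, manifest = m)
}

#' Write a metrics report
#'
#' Writes the per-pair rows as a CSV table (fixed column order: source,
#' target, dsc, hd, assd, msd, flagged) and the aggregates — recomputed
#' from the rows — as a JSON file alongside
#' (`<path without extension>.aggregates.json`).
#'
#' @param path CSV output path.
#' @param report a [MetricsReport-class] with at least one row.
#' @return `path`, invisibly.
#' @seealso [readReport()]
#' @export
writeReport <- function(path, report) {
  stopifnot(is(report, "MetricsReport"))
  if (nrow(report@rows) == 0L)
    stop("cannot write an empty metrics report", call. = FALSE)
  rows <- report@rows[, c("source", "target", "dsc", "hd", "assd", "msd",
                          "flagged")]
  utils::write.csv(rows, path, row.names = FALSE)
  agg <- aggregateMetricRows(rows)
  aggPath <- paste0(tools::file_path_sans_ext(path), ".aggregates.json")
  jsonlite::write_json(agg, aggPath, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Read a metrics report written by [writeReport()]
#'
#' @param path CSV path.
#' @return a [MetricsReport-class] (aggregates recomputed from the rows).
#' @export
readReport <- function(path) {
  rows <- utils::read.csv(path)
  rows$flagged <- as.logical(rows$flagged)
  new("MetricsReport", rows = rows, aggregates = aggregateMetricRows(rows))
}
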