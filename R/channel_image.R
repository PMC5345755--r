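#' Single-channel intensity image
#'
#' `channel_image()` wraps a 2-D intensity raster together with its
#' bit-depth metadata and a channel label.  It is the atom of the
#' pipeline: every operation consumes and produces these objects.
#' Pixel intensities are stored as doubles in `[0, 1]` regardless of the
#' source bit depth, so that downstream arithmetic is uniform across
#' 8-bit and 16-bit captures; `bit_depth` records the original scale.
#'
#' @param pixels Numeric matrix of intensities.  Either already in
#'   `[0, 1]`, or raw integer gray values in `[0, 2^bit_depth - 1]` with
#'   `rescale = TRUE`.
#' @param channel_label One of `"DAPI"`, `"BIOMARKER"`, `"CONTROL"`,
#'   `"MERGED"`.
#' @param bit_depth Bits per sample of the source data, 8 or 16.
#' @param rescale If `TRUE`, divide `pixels` by `2^bit_depth - 1`.
#'
#' @return An object of class `channel_image` with fields `pixels`
#'   (matrix in `[0, 1]`), `height`, `width`, `bit_depth` and
#'   `channel_label`.
#'
#' @details Images smaller than 16 x 16 pixels are rejected: they cannot
#'   carry a meaningful nucleus at the magnifications this pipeline
#'   targets and usually indicate a truncated read.
#'
#' @examples
#' img <- channel_image(matrix(0.5, 32, 32), "DAPI")
#' img$height
#' @export
channel_image <- function(pixels, channel_label, bit_depth = 16L,
                          rescale = FALSE) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix")
  }
  channel_label <- match.arg(channel_label, CHANNEL_LABELS)
  if (!bit_depth %in% c(8L, 16L)) {
    stop("`bit_depth` must be 8 or 16")
  }
  if (nrow(pixels) < 16L || ncol(pixels) < 16L) {
    stop("image must be at least 16 x 16 pixels (got ",
         nrow(pixels), " x ", ncol(pixels), ")")
  }
  pixels <- pixels * 1.0
  if (rescale) pixels <- pixels / (2^bit_depth - 1)
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 1) {
    stop("intensities must lie in [0, 1] after rescaling (channel ",
         channel_label, ")")
  }
  structure(
    list(pixels = pixels,
         height = nrow(pixels),
         width = ncol(pixels),
         bit_depth = as.integer(bit_depth),
         channel_label = channel_label),
    class = "channel_image"
  )
}

#' @export
print.channel_image <- function(x, ...) {
  cat(sprintf("<channel_image %s %dx%d %d-bit, range [%.4f, %.4f]>\n",
              x$channel_label, x$height, x$width, x$bit_depth,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

is_channel_image <- function(x) inherits(x, "channel_image")

stopifnot_channel <- function(x, arg = deparse(substitute(x))) {
  if (!is_channel_image(x)) stop("`", arg, "` must be a channel_image")
  invisible(x)
}

#' Paired two-channel field
#'
#' A field is one microscope capture of a specimen: a DAPI channel and a
#' biomarker channel of identical size, with the identifiers needed to
#' pool fields by specimen and diagnostic group downstream.
#'
#' @param specimen_id Character scalar.
#' @param group_label One of `"REACTIVE"`, `"RECURRENT_GB"`,
#'   `"DE_NOVO_GB"`, `"PILOCYTIC"`.
#' @param field_index Integer >= 1, unique within a specimen.
#' @param dapi,biomarker [channel_image] objects of identical size.
#'
#' @return An object of class `field_record`.
#' @export
field_record <- function(specimen_id, group_label, field_index,
                         dapi, biomarker) {
  stopifnot_channel(dapi)
  stopifnot_channel(biomarker)
  group_label <- match.arg(group_label, GROUP_LABELS)
  field_index <- as.integer(field_index)
  if (is.na(field_index) || field_index < 1L) {
    stop("`field_index` must be an integer >= 1")
  }
  if (dapi$height != biomarker$height || dapi$width != biomarker$width) {
    stop("DAPI and biomarker channels must have identical dimensions")
  }
  structure(
    list(specimen_id = as.character(specimen_id),
         group_label = group_label,
         field_index = field_index,
         dapi = dapi,
         biomarker = biomarker),
    class = "field_record"
  )
}

#' @export
print.field_record <- function(x, ...) {
  cat(sprintf("<field_record %s/%s field %d, %dx%d>\n",
              x$specimen_id, x$group_label, x$field_index,
              x$dapi$height, x$dapi$width))
  invisible(x)
}
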