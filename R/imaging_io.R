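#' Read a single channel from a TIFF file
#'
#' Reads an 8- or 16-bit grayscale TIFF directly as the named channel,
#' or extracts one plane from an RGB TIFF using the standard staining
#' color convention: the blue plane carries DAPI, the red plane carries
#' the biomarker (and the no-primary-antibody control, which is imaged
#' in the biomarker emission channel).  The green plane is never used.
#'
#' @param path Path to an existing TIFF file.
#' @param channel_label `"DAPI"`, `"BIOMARKER"` or `"CONTROL"`.
#' @return A [channel_image].
#' @examples
#' f <- tempfile(fileext = ".tif")
#' tiff::writeTIFF(matrix(0.25, 32, 32), f, bits.per.sample = 8L)
#' img <- load_channel(f, "DAPI")
#' @export
load_channel <- function(path, channel_label) {
  channel_label <- match.arg(channel_label, CHANNEL_LABELS[1:3])
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- tiff::readTIFF(path, info = TRUE)
  bits <- attr(raw, "bits.per.sample")
  if (is.null(bits)) bits <- 16L
  if (!bits %in% c(8L, 16L)) {
    stop("unsupported sample format (", bits, " bits per sample): ", path)
  }
  if (length(dim(raw)) == 3L) {
    if (dim(raw)[3] < 3L) {
      stop("multi-plane TIFF with fewer than 3 planes is not supported: ",
           path)
    }
    plane <- if (channel_label == "DAPI") 3L else 1L
    px <- raw[, , plane]
  } else {
    px <- raw
  }
  px <- matrix(as.numeric(px), nrow(px), ncol(px))  # drop TIFF attributes
  if (all(px == 0)) {
    warning("image is entirely zero: ", path)
  }
  channel_image(px, channel_label, bit_depth = as.integer(bits))
}

#' Write a channel image to TIFF
#'
#' Intensities are stored at the image's own bit depth.  Values on the
#' `k / (2^bit_depth - 1)` grid (as produced by [generate_scene()] or
#' by [load_channel()]) round-trip with every gray level preserved
#' exactly.
#'
#' @param image A [channel_image].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_channel <- function(image, path) {
  stopifnot_channel(image)
  tiff::writeTIFF(image$pixels, path,
                  bits.per.sample = image$bit_depth)
  invisible(path)
}

#' Split an RGB raster into DAPI and biomarker channels
#'
#' @param rgb A height x width x 3 numeric array with values in `[0, 1]`.
#' @param bit_depth Bit depth to record on the resulting channels.
#' @return A named list with elements `DAPI` (blue plane) and
#'   `BIOMARKER` (red plane); the green plane is discarded.
#' @export
split_channels <- function(rgb, bit_depth = 16L) {
  if (!is.array(rgb) || length(dim(rgb)) != 3L || dim(rgb)[3] != 3L) {
    stop("`rgb` must be a height x width x 3 array")
  }
  list(
    DAPI = channel_image(rgb[, , 3L], "DAPI", bit_depth = bit_depth),
    BIOMARKER = channel_image(rgb[, , 1L], "BIOMARKER",
                              bit_depth = bit_depth)
  )
}

#' HSV rendering of an intensity image for visual QC
#'
#' Maps intensity to a hue ramp running from blue (dark) to red
#' (bright) at full saturation, a rendering that makes residual images
#' and faint background structure far easier to judge by eye than a
#' gray ramp.  The output is for human inspection only and is never
#' consumed by any quantification step.
#'
#' @param image A [channel_image].
#' @return A height x width x 3 RGB array in `[0, 1]`.
#' @export
hsv_visualization <- function(image) {
  stopifnot_channel(image)
  x <- image$pixels
  hue <- (1 - as.vector(x)) * 0.7  # 0.7 = blue, 0 = red
  cols <- grDevices::hsv(h = hue, s = 1, v = 1)
  rgb <- grDevices::col2rgb(cols) / 255
  out <- array(0, dim = c(image$height, image$width, 3L))
  out[, , 1L] <- matrix(rgb[1L, ], image$height)
  out[, , 2L] <- matrix(rgb[2L, ], image$height)
  out[, , 3L] <- matrix(rgb[3L, ], image$height)
  out
}

# Hue assigned to each pixel by hsv_visualization(); exposed for tests
# of the monotone intensity -> hue mapping.
viz_hue <- function(intensity) (1 - intensity) * 0.7

#' Write per-field metrics to CSV
#'
#' @param metrics A data frame as returned by [metrics_table()] /
#'   [compute_field_metrics()], one row per field.
#' @param path Output CSV path.
#' @return `path`, invisibly.  Rows are written in deterministic
#'   (specimen_id, field_index) order.
#' @export
write_metrics_table <- function(metrics, path) {
  if (!is.data.frame(metrics) || nrow(metrics) == 0L) {
    stop("`metrics` must be a non-empty data frame")
  }
  required <- c("specimen_id", "group_label", "field_index",
                "n_nuclei", "n_merged_positive", "n_biomarker_positive",
                "mean_intensity")
  missing <- setdiff(required, names(metrics))
  if (length(missing)) {
    stop("metrics table is missing columns: ",
         paste(missing, collapse = ", "))
  }
  metrics <- metrics[order(metrics$specimen_id, metrics$field_index),
                     required]
  utils::write.csv(metrics, path, row.names = FALSE)
  invisible(path)
}

#' Read a per-field metrics CSV written by [write_metrics_table()]
#'
#' @param path CSV path.
#' @return A data frame with one row per field.
#' @export
read_metrics_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
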