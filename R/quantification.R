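#' Pipeline parameters
#'
#' Collects every tunable of [compute_field_metrics()] with its default.
#'
#' @param k_clusters Number of intensity clusters for the biomarker and
#'   merged images (default 6; positivity is the brightest cluster).
#' @param dapi_k Number of clusters used to segment the DAPI channel
#'   (default 2: the DAPI channel is background-clean, so
#'   foreground/background is a two-class problem).
#' @param nuclear_clusters_from First DAPI cluster counted as nuclear
#'   (default 2, everything above the dimmest cluster).
#' @param min_area Minimum nucleus area in pixels (default 50).
#' @param denoise_radius Median filter radius (default 1).
#' @param low_pct,high_pct Normalization percentiles (defaults 1, 99).
#' @param shared_threshold If `TRUE` (default) the positivity threshold
#'   derived from the biomarker-image clustering is applied to both the
#'   biomarker and the merged image, which makes the count ordering
#'   `n_biomarker_positive <= n_merged_positive` a theorem (the merged
#'   image dominates the biomarker image pixelwise).  If `FALSE`, the
#'   merged image is clustered independently and classified against its
#'   own sixth-cluster threshold.
#' @param intensity_over `"positive"` (default) averages the
#'   mean-intensity metric over biomarker-positive nuclei only;
#'   `"all"` averages over every detected nucleus.
#' @return A list of class `field_params`.
#' @export
field_params <- function(k_clusters = 6L, dapi_k = 2L,
                         nuclear_clusters_from = 2L, min_area = 50L,
                         denoise_radius = 1L, low_pct = 1,
                         high_pct = 99, shared_threshold = TRUE,
                         intensity_over = c("positive", "all")) {
  intensity_over <- match.arg(intensity_over)
  structure(
    list(k_clusters = as.integer(k_clusters),
         dapi_k = as.integer(dapi_k),
         nuclear_clusters_from = as.integer(nuclear_clusters_from),
         min_area = as.integer(min_area),
         denoise_radius = as.integer(denoise_radius),
         low_pct = low_pct, high_pct = high_pct,
         shared_threshold = isTRUE(shared_threshold),
         intensity_over = intensity_over),
    class = "field_params"
  )
}

#' Mean biomarker intensity inside each nucleus
#'
#' Averages the biomarker intensity over exactly the pixel set of each
#' DAPI-defined nucleus.  Biomarker signal outside every nucleus is
#' never read — this is the autofluorescence rejection step: an
#' erythrocyte, however bright, cannot contribute to any measurement
#' because no DAPI nucleus overlaps it.
#'
#' @param biomarker A [channel_image] from the matching field.
#' @param nuclei A list of `nucleus_region`s from [label_nuclei()].
#' @return A numeric vector of per-region means, named by `region_id`.
#' @export
gate_by_dapi <- function(biomarker, nuclei) {
  stopifnot_channel(biomarker)
  h <- biomarker$height
  means <- vapply(nuclei, function(r) {
    px <- r$pixels
    if (any(px[, 1L] < 0L | px[, 1L] >= h |
            px[, 2L] < 0L | px[, 2L] >= biomarker$width)) {
      stop("region ", r$region_id, " has pixels outside the image")
    }
    idx <- px[, 1L] + 1L + px[, 2L] * h
    mean(biomarker$pixels[idx])
  }, numeric(1), USE.NAMES = FALSE)
  names(means) <- vapply(nuclei, function(r) as.character(r$region_id),
                         character(1))
  means
}

#' Classify nuclei as positive or negative
#'
#' A nucleus is positive iff its mean intensity is at least the
#' positivity threshold (the lower boundary of the brightest intensity
#' cluster).  The boundary itself counts as positive.
#'
#' @param mean_intensity Numeric vector of per-nucleus means.
#' @param positive_threshold Threshold from the corresponding image's
#'   [cluster_intensities()] result.
#' @return Character vector of `"POSITIVE"` / `"NEGATIVE"`.
#' @export
classify_nucleus <- function(mean_intensity, positive_threshold) {
  if (!is.numeric(positive_threshold) || length(positive_threshold) != 1L) {
    stop("`positive_threshold` must be a single number")
  }
  ifelse(mean_intensity >= positive_threshold, "POSITIVE", "NEGATIVE")
}

#' Biomarker-to-DAPI density ratio
#'
#' Ratio of mean nuclear biomarker intensity to mean nuclear DAPI
#' intensity, per nucleus or per field.  Normalizing by DAPI density
#' compensates for differences in nuclear size and chromatin content
#' when comparing expression between treatment arms.
#'
#' @param mean_biomarker,mean_dapi Numeric vectors of equal length;
#'   `mean_dapi` must be strictly positive.
#' @return Numeric vector of ratios.
#' @export
density_ratio <- function(mean_biomarker, mean_dapi) {
  if (length(mean_biomarker) != length(mean_dapi)) {
    stop("inputs must have equal length")
  }
  if (any(mean_dapi <= 0)) {
    stop("`mean_dapi` must be strictly positive")
  }
  mean_biomarker / mean_dapi
}

zero_metrics <- function(field, reason) {
  warning("field ", field$specimen_id, "/", field$field_index, ": ",
          reason, "; metrics set to zero")
  metrics_row(field, 0L, 0L, 0L, 0)
}

metrics_row <- function(field, n_nuclei, n_merged, n_bio, mean_int) {
  data.frame(specimen_id = field$specimen_id,
             group_label = field$group_label,
             field_index = field$field_index,
             n_nuclei = as.integer(n_nuclei),
             n_merged_positive = as.integer(n_merged),
             n_biomarker_positive = as.integer(n_bio),
             mean_intensity = as.numeric(mean_int),
             stringsAsFactors = FALSE)
}

#' Compute the three per-field metrics
#'
#' Runs the full single-field workflow and returns the three outputs
#' the method is built around: the number of nuclei positive in the
#' merged DAPI/biomarker image, the number of nuclei positive in the
#' biomarker image alone, and the mean biomarker intensity over
#' positive nuclei.
#'
#' The stages are:
#' \enumerate{
#'   \item DAPI: percentile normalization, median denoising,
#'     `dapi_k`-cluster segmentation, mask, 8-connected labelling with
#'     a minimum-area filter.
#'   \item Biomarker: percentile normalization with the percentiles
#'     computed over nuclear pixels only, then median denoising.
#'   \item Merged image: pixelwise maximum of the two processed
#'     channels.
#'   \item Clustering of the nuclear-gated biomarker image
#'     (extranuclear pixels zeroed) into `k_clusters`; the brightest
#'     cluster's lower boundary is the positivity threshold.
#'   \item Per-nucleus mean intensities and positive/negative calls on
#'     both the biomarker and the merged image.
#' }
#' Every intensity statistic that feeds a decision is computed from
#' nuclear pixels only, so extranuclear autofluorescence has exactly
#' zero influence on all three metrics.
#'
#' Fields without detectable nuclei (or without biomarker dynamic
#' range) yield zero counts and `mean_intensity = 0` with a warning.
#'
#' @param field A [field_record].
#' @param params A [field_params()] list.
#' @return A one-row data frame with columns `specimen_id`,
#'   `group_label`, `field_index`, `n_nuclei`, `n_merged_positive`,
#'   `n_biomarker_positive`, `mean_intensity`.  Per-nucleus detail
#'   (means, calls, thresholds) is attached as attribute `"detail"`.
#' @export
compute_field_metrics <- function(field, params = field_params()) {
  if (!inherits(field, "field_record")) {
    stop("`field` must be a field_record")
  }
  if (!inherits(params, "field_params")) {
    stop("`params` must come from field_params()")
  }
  if (diff(range(field$dapi$pixels)) == 0) {
    return(zero_metrics(field, "DAPI channel is constant (no nuclei)"))
  }

  # --- DAPI branch: segment nuclei ---------------------------------
  dapi_n <- normalize_channel(field$dapi, params$low_pct, params$high_pct)
  dapi_d <- denoise(dapi_n, params$denoise_radius)$denoised
  cl_dapi <- cluster_intensities(dapi_d, k = params$dapi_k)
  mask <- dapi_mask(dapi_d, cl_dapi, params$nuclear_clusters_from)
  nuclei <- label_nuclei(mask, params$min_area)
  if (length(nuclei) == 0L) {
    return(zero_metrics(field, "no nuclei detected"))
  }
  nuclear <- matrix(FALSE, field$dapi$height, field$dapi$width)
  for (r in nuclei) {
    nuclear[r$pixels[, 1L] + 1L + r$pixels[, 2L] * field$dapi$height] <- TRUE
  }

  # --- biomarker branch: nuclear-referenced normalization ----------
  bio_range <- diff(range(field$biomarker$pixels[nuclear]))
  if (bio_range == 0) {
    n <- length(nuclei)
    res <- metrics_row(field, n, 0L, 0L, 0)
    warning("field ", field$specimen_id, "/", field$field_index,
            ": biomarker channel has no dynamic range inside nuclei")
    return(res)
  }
  bio_n <- normalize_channel(field$biomarker, params$low_pct,
                             params$high_pct, reference_mask = nuclear)
  bio_d <- denoise(bio_n, params$denoise_radius)$denoised
  merged <- merge_dapi_biomarker(dapi_d, bio_d)

  # --- positivity thresholds from the gated biomarker image --------
  gated_bio <- bio_d$pixels
  gated_bio[!nuclear] <- 0
  cl_bio <- cluster_intensities(gated_bio, k = params$k_clusters)
  thr_bio <- cl_bio$positive_threshold
  if (params$shared_threshold) {
    thr_merged <- thr_bio
  } else {
    gated_merged <- merged$pixels
    gated_merged[!nuclear] <- 0
    thr_merged <- cluster_intensities(gated_merged,
                                      k = params$k_clusters)$positive_threshold
  }

  # --- per-nucleus measurement and calls ---------------------------
  mean_bio <- gate_by_dapi(bio_d, nuclei)
  mean_merged <- gate_by_dapi(merged, nuclei)
  mean_dapi <- gate_by_dapi(dapi_d, nuclei)
  call_bio <- classify_nucleus(mean_bio, thr_bio)
  call_merged <- classify_nucleus(mean_merged, thr_merged)
  pos <- call_bio == "POSITIVE"
  mean_int <- if (params$intensity_over == "positive") {
    if (any(pos)) mean(mean_bio[pos]) else 0
  } else {
    mean(mean_bio)
  }
  res <- metrics_row(field, length(nuclei), sum(call_merged == "POSITIVE"),
                     sum(pos), mean_int)
  attr(res, "detail") <- list(
    nuclei = nuclei,
    mean_biomarker = mean_bio,
    mean_merged = mean_merged,
    mean_dapi = mean_dapi,
    call_biomarker = call_bio,
    call_merged = call_merged,
    threshold_biomarker = thr_bio,
    threshold_merged = thr_merged,
    centroids_biomarker = cl_bio$centroids
  )
  res
}

#' Compute metrics for a list of fields
#'
#' @param fields List of [field_record]s.
#' @param params A [field_params()] list.
#' @return A data frame with one row per field, ordered by
#'   (specimen_id, field_index).
#' @export
metrics_table <- function(fields, params = field_params()) {
  if (length(fields) == 0L) stop("`fields` must be non-empty")
  rows <- lapply(fields, compute_field_metrics, params = params)
  out <- do.call(rbind, rows)
  out[order(out$specimen_id, out$field_index), , drop = FALSE]
}
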