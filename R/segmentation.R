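#' Cluster pixel intensities into K ordered classes
#'
#' One-dimensional k-means over the pixel intensities of an image.
#' The solver is exact: the globally WCSS-optimal partition is found
#' by dynamic programming over the sorted distinct intensity values
#' (the standard approach for 1-D data, where k-means is solvable in
#' polynomial time), and Lloyd iterations are then run from the
#' optimal centroids — a fixed point, so they serve as verification
#' and to materialize the nearest-centroid label map.  The procedure
#' is fully deterministic: a diagnostic tool must give the same answer
#' on the same image every time, so no random initialization is used.
#' Heuristic seeding (e.g. evenly spaced quantiles) was rejected
#' because fluorescence intensity histograms are strongly gapped —
#' background, nucleoplasm and speckle brightness form separated
#' modes — and Lloyd's algorithm cannot move centroids across an empty
#' gap, which strands it in local optima precisely on the images this
#' pipeline targets.
#'
#' Clusters are reported in ascending centroid order, making "the
#' sixth cluster" (for the default `k = 6`) the brightest — its lower
#' boundary, the midpoint of the two top centroids, is the positivity
#' threshold used by [classify_nucleus()].
#'
#' Ties in pixel assignment (a pixel exactly midway between two
#' centroids) go to the lower-indexed cluster.
#'
#' @param image A [channel_image] or a numeric matrix/vector of
#'   intensities in `[0, 1]`.
#' @param k Number of clusters (default 6).
#' @param max_iter Maximum Lloyd iterations (default 300).
#' @param tol Convergence tolerance on the largest centroid shift
#'   (default 1e-7).
#' @return An object of class `intensity_clustering` with fields `k`,
#'   `centroids` (strictly increasing), `label_map` (integer raster of
#'   cluster indices 1..k, when the input was a matrix or image),
#'   `positive_threshold`, `iterations` and `converged`.
#' @examples
#' img <- channel_image(matrix(rep(c(0.1, 0.9), each = 512), 32),
#'                      "BIOMARKER")
#' cl <- cluster_intensities(img, k = 2)
#' cl$positive_threshold  # 0.5
#' @export
cluster_intensities <- function(image, k = 6L, max_iter = 300L,
                                tol = 1e-7) {
  k <- as.integer(k)
  if (is.na(k) || k < 2L) stop("`k` must be an integer >= 2")
  if (is_channel_image(image)) {
    px <- image$pixels
  } else if (is.numeric(image)) {
    px <- image
  } else {
    stop("`image` must be a channel_image or numeric")
  }
  x <- as.vector(px)
  ux <- unique(x)
  if (length(ux) < k) {
    stop("image has only ", length(ux), " distinct intensity values; ",
         "use k <= ", length(ux))
  }
  xs <- sort(x, method = "radix")
  runs <- rle(xs)
  centers <- kmeans1d_dp_cpp(runs$values, runs$lengths, k)
  iter <- 0L
  converged <- FALSE
  assign_idx <- NULL
  while (iter < max_iter) {
    iter <- iter + 1L
    mids <- (centers[-1L] + centers[-k]) / 2
    assign_idx <- findInterval(x, mids, left.open = TRUE) + 1L
    new_centers <- centers
    cnt <- tabulate(assign_idx, nbins = k)
    sums <- numeric(k)
    got <- sort(unique(assign_idx))
    sums[got] <- rowsum(x, assign_idx, reorder = TRUE)
    nonempty <- cnt > 0L
    new_centers[nonempty] <- sums[nonempty] / cnt[nonempty]
    shift <- max(abs(new_centers - centers))
    centers <- new_centers
    if (shift < tol) {
      converged <- TRUE
      break
    }
  }
  # Final assignment against the final centroids (nearest centroid,
  # ties to the lower index).
  mids <- (centers[-1L] + centers[-k]) / 2
  assign_idx <- findInterval(x, mids, left.open = TRUE) + 1L
  if (any(diff(centers) <= 0)) {
    stop("degenerate clustering: centroids are not strictly increasing")
  }
  label_map <- NULL
  if (is.matrix(px)) {
    label_map <- matrix(assign_idx, nrow(px), ncol(px))
  }
  structure(
    list(k = k,
         centroids = as.numeric(centers),
         label_map = label_map,
         labels = assign_idx,
         positive_threshold = (centers[k - 1L] + centers[k]) / 2,
         iterations = iter,
         converged = converged),
    class = "intensity_clustering"
  )
}

#' @export
print.intensity_clustering <- function(x, ...) {
  cat(sprintf("<intensity_clustering k=%d, threshold=%.4f, %s in %d it>\n",
              x$k, x$positive_threshold,
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  cat("centroids:", format(round(x$centroids, 4)), "\n")
  invisible(x)
}

#' Nuclear mask from a DAPI-channel clustering
#'
#' In FFPE tissue the DAPI excitation range shows essentially no
#' autofluorescent background, so everything above the dimmest
#' intensity cluster of the DAPI channel can be taken as nuclear
#' material.  A pixel is nuclear iff its cluster index is at least
#' `nuclear_clusters_from` (default 2).
#'
#' A guard protects empty fields: on a field with no nuclei the
#' clustering merely splits the background noise, and "above the
#' dimmest cluster" would select a random half of the image.  The mask
#' is therefore returned empty unless the two clusters flanking the
#' nuclear boundary separate by at least `min_separation` times their
#' largest within-cluster spread — trivially true for any field with
#' real nuclei (chromatin is far brighter than background), and false
#' for pure noise, whose 2-means split separates by only about 1.6
#' standard deviations.
#'
#' @param dapi The [channel_image] the clustering was computed on.
#' @param clustering An [cluster_intensities()] result for `dapi`.
#' @param nuclear_clusters_from First cluster index counted as nuclear;
#'   must lie in `2..k`.
#' @param min_separation Minimum ratio of boundary cluster separation
#'   to within-cluster spread (default 4).
#' @return A logical matrix, `TRUE` at nuclear pixels.
#' @export
dapi_mask <- function(dapi, clustering, nuclear_clusters_from = 2L,
                      min_separation = 4) {
  stopifnot_channel(dapi)
  if (!inherits(clustering, "intensity_clustering") ||
      is.null(clustering$label_map)) {
    stop("`clustering` must be an intensity_clustering with a label map")
  }
  if (!identical(dim(clustering$label_map), dim(dapi$pixels))) {
    stop("clustering was not computed on this image")
  }
  from <- as.integer(nuclear_clusters_from)
  if (is.na(from) || from < 2L || from > clustering$k) {
    stop("`nuclear_clusters_from` must lie in 2..k")
  }
  lab <- clustering$label_map
  below <- dapi$pixels[lab == from - 1L]
  above <- dapi$pixels[lab == from]
  spread <- suppressWarnings(
    max(stats::sd(below), stats::sd(above), na.rm = TRUE))
  sep <- clustering$centroids[from] - clustering$centroids[from - 1L]
  if (is.finite(spread) && spread > 0 && sep < min_separation * spread) {
    return(matrix(FALSE, nrow(lab), ncol(lab)))
  }
  lab >= from
}

#' Label nuclei as 8-connected components of a binary mask
#'
#' Connected components of the nuclear mask are extracted with
#' 8-connectivity and components smaller than `min_area` pixels are
#' discarded as debris.  Region ids are assigned in raster-scan order
#' (rows scanned first) of each component's first pixel, so labelling
#' is deterministic.
#'
#' @param mask Logical matrix (e.g. from [dapi_mask()]).
#' @param min_area Minimum component area in pixels (default 50, about
#'   the smallest credible nucleus cross-section at 20x).
#' @return A list of `nucleus_region` objects, each with `region_id`,
#'   `pixels` (an n x 2 matrix of 0-based `(row, col)` coordinates),
#'   `area` and `centroid` (0-based `(row, col)` floats).  The full
#'   label matrix is attached as attribute `"label_map"`.
#' @export
label_nuclei <- function(mask, min_area = 50L) {
  if (!is.matrix(mask)) stop("`mask` must be a matrix")
  storage.mode(mask) <- "logical"
  min_area <- as.integer(min_area)
  lab <- label_components_cpp(mask)
  n_raw <- max(lab)
  regions <- list()
  next_id <- 0L
  if (n_raw > 0L) {
    idx <- which(lab > 0L)
    comp <- lab[idx]
    rows <- (idx - 1L) %% nrow(mask)       # 0-based
    cols <- (idx - 1L) %/% nrow(mask)      # 0-based
    ord <- order(comp)
    comp <- comp[ord]; rows <- rows[ord]; cols <- cols[ord]
    bounds <- c(0L, cumsum(tabulate(comp, nbins = n_raw)))
    for (i in seq_len(n_raw)) {
      sel <- (bounds[i] + 1L):bounds[i + 1L]
      area <- length(sel)
      if (area < min_area) next
      next_id <- next_id + 1L
      regions[[next_id]] <- structure(
        list(region_id = next_id,
             pixels = cbind(row = rows[sel], col = cols[sel]),
             area = area,
             centroid = c(row = mean(rows[sel]), col = mean(cols[sel]))),
        class = "nucleus_region"
      )
    }
  }
  attr(regions, "label_map") <- lab
  regions
}

#' Merge DAPI and biomarker channels pixelwise
#'
#' The merged ("double-stain") image is the element-wise maximum of the
#' two channels.  The maximum preserves the `[0, 1]` range without
#' rescaling and dominates the biomarker channel everywhere, which is
#' the mechanism behind the merged positive count always reaching at
#' least the biomarker-only positive count.
#'
#' @param dapi,biomarker [channel_image]s of identical size with
#'   intensities in `[0, 1]`.
#' @return A [channel_image] with label `"MERGED"`.
#' @export
merge_dapi_biomarker <- function(dapi, biomarker) {
  stopifnot_channel(dapi)
  stopifnot_channel(biomarker)
  if (dapi$height != biomarker$height || dapi$width != biomarker$width) {
    stop("channel dimensions do not match")
  }
  out <- dapi
  out$pixels <- pmax(dapi$pixels, biomarker$pixels)
  out$channel_label <- "MERGED"
  out$bit_depth <- max(dapi$bit_depth, biomarker$bit_depth)
  out
}
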