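#' Specification of a synthetic two-channel scene
#'
#' Describes one simulated microscope field emulating the imaging
#' physics of DAPI-counterstained FFPE tissue stained for a nuclear
#' biomarker:
#' \itemize{
#'   \item elliptical nuclei on a clean (artifact-free) DAPI channel,
#'     with chromatin texture;
#'   \item biomarker signal that is strictly nuclear and speckled:
#'     inside positive nuclei a fraction `speckle_density` of pixels
#'     carry speckle grains at `biomarker_pos_level`, over a faint
#'     nucleoplasmic base at `biomarker_neg_level`; negative nuclei
#'     show only the base; optionally one perinucleolar punctum per
#'     positive nucleus;
#'   \item extranuclear erythrocyte-like artifact blobs, present only
#'     in the biomarker channel, at `artifact_level` which must exceed
#'     `biomarker_pos_level` — true signal is dimmer than
#'     autofluorescence;
#'   \item global multiplicative illumination decay of the biomarker
#'     channel (`illumination_factor`) and additive Gaussian sensor
#'     noise on both channels.
#' }
#'
#' @param height,width Image size in pixels (default 256 x 256,
#'   representative of a cropped 20x confocal field).
#' @param n_nuclei Number of nuclei to place (default 20).
#' @param fraction_positive Fraction of nuclei that are
#'   biomarker-positive (default 0.4); the positive count is
#'   `round(fraction_positive * n_nuclei)`.
#' @param nucleus_axes Range `c(min, max)` of ellipse semi-axes in
#'   pixels (default `c(5, 9)`, glial-scale nuclei at 20x).
#' @param dapi_level Mean nuclear DAPI intensity (default 0.7).
#' @param biomarker_pos_level Speckle intensity (default 0.55).
#' @param biomarker_neg_level Nucleoplasmic base intensity
#'   (default 0.08).
#' @param speckle_density Fraction of nuclear pixels carrying 1-px
#'   speckle grains in positive nuclei (default 0.7: dense speckling
#'   throughout the nucleoplasm).
#' @param perinucleolar_punctum Add one 3-px-radius punctum adjacent
#'   to the centroid of each positive nucleus (default `TRUE`).
#' @param n_artifacts Number of extranuclear artifact blobs in the
#'   biomarker channel (default 4).
#' @param artifact_level Artifact intensity (default 0.9); must exceed
#'   `biomarker_pos_level`.
#' @param illumination_factor Multiplicative factor in `(0, 1]` applied
#'   to the biomarker signal before noise (default 1).
#' @param noise_sd Additive Gaussian noise sd on both channels
#'   (default 0.01, typical of averaged confocal captures).
#' @param texture_sd Within-nucleus intensity texture sd (default
#'   0.06); chromatin and nucleoplasm are never flat in real tissue,
#'   and this spread is what gives the intensity histogram its
#'   continuous shape.
#' @param seed Integer RNG seed; scenes are bit-reproducible given the
#'   seed.
#' @param bit_depth Output quantization depth (default 16).
#' @return A list of class `scene_spec`.
#' @export
scene_spec <- function(height = 256L, width = 256L, n_nuclei = 20L,
                       fraction_positive = 0.4,
                       nucleus_axes = c(5, 9), dapi_level = 0.7,
                       biomarker_pos_level = 0.55,
                       biomarker_neg_level = 0.08,
                       speckle_density = 0.7,
                       perinucleolar_punctum = TRUE,
                       n_artifacts = 4L, artifact_level = 0.9,
                       illumination_factor = 1, noise_sd = 0.01,
                       texture_sd = 0.06, seed = 1L,
                       bit_depth = 16L) {
  spec <- list(height = as.integer(height), width = as.integer(width),
               n_nuclei = as.integer(n_nuclei),
               fraction_positive = fraction_positive,
               nucleus_axes = as.numeric(nucleus_axes),
               dapi_level = dapi_level,
               biomarker_pos_level = biomarker_pos_level,
               biomarker_neg_level = biomarker_neg_level,
               speckle_density = speckle_density,
               perinucleolar_punctum = isTRUE(perinucleolar_punctum),
               n_artifacts = as.integer(n_artifacts),
               artifact_level = artifact_level,
               illumination_factor = illumination_factor,
               noise_sd = noise_sd, texture_sd = texture_sd,
               seed = as.integer(seed),
               bit_depth = as.integer(bit_depth))
  if (spec$height < 16L || spec$width < 16L) {
    stop("scene must be at least 16 x 16")
  }
  if (spec$n_nuclei < 0L || spec$n_artifacts < 0L) {
    stop("counts must be non-negative")
  }
  if (spec$fraction_positive < 0 || spec$fraction_positive > 1) {
    stop("`fraction_positive` must lie in [0, 1]")
  }
  if (length(spec$nucleus_axes) != 2L ||
      spec$nucleus_axes[1L] > spec$nucleus_axes[2L] ||
      spec$nucleus_axes[1L] < 2) {
    stop("`nucleus_axes` must be c(min, max) with min >= 2")
  }
  if (!(spec$artifact_level > spec$biomarker_pos_level &&
        spec$biomarker_pos_level > spec$biomarker_neg_level)) {
    stop("require artifact_level > biomarker_pos_level > ",
         "biomarker_neg_level: artifacts outshine true signal")
  }
  if (spec$illumination_factor <= 0 || spec$illumination_factor > 1) {
    stop("`illumination_factor` must lie in (0, 1]")
  }
  if (spec$noise_sd < 0 || spec$texture_sd < 0) {
    stop("noise/texture sd must be non-negative")
  }
  class(spec) <- "scene_spec"
  spec
}

# Rasterize a rotated ellipse; returns linear pixel indices (1-based).
ellipse_pixels <- function(cr, cc, a, b, theta, h, w) {
  half <- ceiling(max(a, b))
  rr <- max(1L, floor(cr - half)):min(h, ceiling(cr + half))
  cc_ <- max(1L, floor(cc - half)):min(w, ceiling(cc + half))
  grid_r <- rep(rr, times = length(cc_))
  grid_c <- rep(cc_, each = length(rr))
  dr <- grid_r - cr
  dc <- grid_c - cc
  u <- dr * cos(theta) + dc * sin(theta)
  v <- -dr * sin(theta) + dc * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  grid_r[inside] + (grid_c[inside] - 1L) * h
}

# Dilate a logical mask by one pixel (8-neighbourhood), `times` times.
dilate1 <- function(mask, times = 1L) {
  h <- nrow(mask); w <- ncol(mask)
  for (t in seq_len(times)) {
    out <- mask
    out[-1, ] <- out[-1, ] | mask[-h, ]
    out[-h, ] <- out[-h, ] | mask[-1, ]
    out[, -1] <- out[, -1] | mask[, -w]
    out[, -w] <- out[, -w] | mask[, -1]
    out[-1, -1] <- out[-1, -1] | mask[-h, -w]
    out[-1, -w] <- out[-1, -w] | mask[-h, -1]
    out[-h, -1] <- out[-h, -1] | mask[-1, -w]
    out[-h, -w] <- out[-h, -w] | mask[-1, -1]
    mask <- out
  }
  mask
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

#' Generate a synthetic two-channel field with ground truth
#'
#' Renders the scene described by a [scene_spec()] and returns both the
#' [field_record] (quantized to the spec's bit depth, so TIFF writes
#' preserve every gray level exactly) and the ground truth needed to
#' score
#' the pipeline: the nucleus label map, per-nucleus positivity flags,
#' and the artifact mask.
#'
#' Determinism and placement guarantees:
#' \itemize{
#'   \item identical spec and seed give bit-identical images;
#'   \item all random draws for nuclei, speckles and noise happen
#'     before artifact placement, so two specs differing only in
#'     `n_artifacts` produce images identical outside the artifact
#'     blobs ("twin scenes");
#'   \item nuclei are separated by at least 2 px from each other and
#'     artifact blobs by at least 3 px from every nucleus, so median
#'     windows of nuclear pixels never touch an artifact.
#' }
#'
#' @param spec A [scene_spec()].
#' @param specimen_id,group_label,field_index Identifiers for the
#'   resulting [field_record].
#' @return A list with elements `field` (a [field_record]) and `truth`
#'   (list: `label_map`, `positive` logical vector per nucleus,
#'   `artifact_mask`, `nucleus_area`, `spec`).
#' @export
generate_scene <- function(spec, specimen_id = "SYN1",
                           group_label = "REACTIVE", field_index = 1L) {
  if (!inherits(spec, "scene_spec")) stop("`spec` must be a scene_spec")
  h <- spec$height; w <- spec$width
  with_seed(spec$seed, {
    label_map <- matrix(0L, h, w)
    occupied <- matrix(FALSE, h, w)   # nuclei dilated by the 2 px gap
    nuc_pixels <- vector("list", spec$n_nuclei)
    nuc_axes <- matrix(NA_real_, spec$n_nuclei, 2L,
                       dimnames = list(NULL, c("a", "b")))
    attempts <- 0L
    for (i in seq_len(spec$n_nuclei)) {
      placed <- FALSE
      while (!placed) {
        attempts <- attempts + 1L
        if (attempts > 1000L * max(1L, spec$n_nuclei)) {
          stop("could not place ", spec$n_nuclei, " nuclei without ",
               "overlap; reduce n_nuclei or enlarge the scene")
        }
        a <- stats::runif(1, spec$nucleus_axes[1L], spec$nucleus_axes[2L])
        b <- stats::runif(1, spec$nucleus_axes[1L], spec$nucleus_axes[2L])
        m <- max(a, b) + 2
        cr <- stats::runif(1, 1 + m, h - m)
        cc <- stats::runif(1, 1 + m, w - m)
        theta <- stats::runif(1, 0, pi)
        # test a gap-enlarged ellipse so nuclei keep a >= 3 px
        # separation (8-connected components never touch)
        test <- ellipse_pixels(cr, cc, a + 3.5, b + 3.5, theta, h, w)
        if (length(test) == 0L || any(occupied[test])) next
        idx <- ellipse_pixels(cr, cc, a, b, theta, h, w)
        if (length(idx) == 0L) next
        label_map[idx] <- i
        occupied[idx] <- TRUE
        nuc_pixels[[i]] <- idx
        nuc_axes[i, ] <- c(a, b)
        placed <- TRUE
      }
    }
    nuclear_mask <- label_map > 0L

    # positivity assignment: exact count, random identity
    n_pos <- round(spec$fraction_positive * spec$n_nuclei)
    positive <- rep(FALSE, spec$n_nuclei)
    if (n_pos > 0L) positive[sample(spec$n_nuclei, n_pos)] <- TRUE

    dapi <- matrix(0, h, w)
    bio <- matrix(0, h, w)
    for (i in seq_len(spec$n_nuclei)) {
      idx <- nuc_pixels[[i]]
      dapi[idx] <- spec$dapi_level +
        stats::rnorm(length(idx), 0, spec$texture_sd)
      bio[idx] <- spec$biomarker_neg_level +
        stats::rnorm(length(idx), 0, spec$texture_sd)
      if (positive[i]) {
        grains <- stats::runif(length(idx)) < spec$speckle_density
        bio[idx[grains]] <- spec$biomarker_pos_level
        if (spec$perinucleolar_punctum) {
          ctr_r <- mean((idx - 1L) %% h) + 1
          ctr_c <- mean((idx - 1L) %/% h) + 1
          ang <- stats::runif(1, 0, 2 * pi)
          off <- spec$nucleus_axes[1L] / 2
          pidx <- ellipse_pixels(ctr_r + off * cos(ang),
                                 ctr_c + off * sin(ang),
                                 3, 3, 0, h, w)
          pidx <- pidx[label_map[pidx] == i]
          bio[pidx] <- spec$biomarker_pos_level
        }
      }
    }
    bio <- bio * spec$illumination_factor
    if (spec$noise_sd > 0) {
      dapi <- dapi + stats::rnorm(h * w, 0, spec$noise_sd)
      bio <- bio + stats::rnorm(h * w, 0, spec$noise_sd)
    }

    # artifacts last: every draw above is unchanged when n_artifacts
    # differs, which is what makes twin-scene comparisons exact
    artifact_mask <- matrix(FALSE, h, w)
    if (spec$n_artifacts > 0L) {
      keepout <- dilate1(nuclear_mask, 3L)
      attempts <- 0L
      for (j in seq_len(spec$n_artifacts)) {
        placed <- FALSE
        while (!placed) {
          attempts <- attempts + 1L
          if (attempts > 1000L * spec$n_artifacts) {
            stop("could not place ", spec$n_artifacts,
                 " artifact blobs clear of all nuclei")
          }
          a <- stats::runif(1, 4, 8)
          b <- stats::runif(1, 4, 8)
          m <- max(a, b) + 1
          cr <- stats::runif(1, 1 + m, h - m)
          cc <- stats::runif(1, 1 + m, w - m)
          theta <- stats::runif(1, 0, pi)
          idx <- ellipse_pixels(cr, cc, a, b, theta, h, w)
          if (length(idx) == 0L || any(keepout[idx]) ||
              any(artifact_mask[idx])) next
          # biconcave profile: dimmer centre, erythrocyte-like
          core <- ellipse_pixels(cr, cc, a / 2, b / 2, theta, h, w)
          lvl <- rep(spec$artifact_level, length(idx))
          lvl[idx %in% core] <- spec$artifact_level * 0.7
          bio[idx] <- bio[idx] + lvl * spec$illumination_factor
          artifact_mask[idx] <- TRUE
          placed <- TRUE
        }
      }
    }

    qmax <- 2^spec$bit_depth - 1
    dapi <- round(pmin(pmax(dapi, 0), 1) * qmax) / qmax
    bio <- round(pmin(pmax(bio, 0), 1) * qmax) / qmax

    field <- field_record(
      specimen_id, group_label, field_index,
      dapi = channel_image(dapi, "DAPI", bit_depth = spec$bit_depth),
      biomarker = channel_image(bio, "BIOMARKER",
                                bit_depth = spec$bit_depth)
    )
    list(field = field,
         truth = list(label_map = label_map,
                      positive = positive,
                      artifact_mask = artifact_mask,
                      nucleus_area = lengths(nuc_pixels),
                      nucleus_axes = nuc_axes,
                      spec = spec))
  })
}

#' Default cohort group profiles
#'
#' Specimen counts follow the archival series the pipeline was designed
#' around (4 reactive gliosis, 4 recurrent glioblastoma, 5 de novo
#' glioblastoma, 16 pilocytic astrocytoma).  Recurrent and de novo
#' glioblastoma carry elevated cellularity and positive fraction
#' relative to reactive tissue, with identical staining intensity
#' levels across all groups — group separation is driven by counts,
#' not by per-cell brightness.
#'
#' @return A named list of per-group profiles (`n_specimens`,
#'   `n_nuclei_mean`, `fraction_positive`).
#' @export
cohort_groups <- function() {
  list(
    REACTIVE     = list(n_specimens = 4L, n_nuclei_mean = 18,
                        fraction_positive = 0.15),
    RECURRENT_GB = list(n_specimens = 4L, n_nuclei_mean = 32,
                        fraction_positive = 0.45),
    DE_NOVO_GB   = list(n_specimens = 5L, n_nuclei_mean = 32,
                        fraction_positive = 0.45),
    PILOCYTIC    = list(n_specimens = 16L, n_nuclei_mean = 20,
                        fraction_positive = 0.30)
  )
}

#' Generate a multi-group synthetic cohort
#'
#' Generates `fields_per_specimen` fields for every specimen of every
#' group.  Per-field cellularity is drawn from a Poisson distribution
#' around the group mean (fields of the same specimen vary, as real
#' randomized captures do).  Each field's scene seed is derived
#' deterministically from `seed`, so the whole cohort is reproducible.
#'
#' @param groups Named list of group profiles as in [cohort_groups()];
#'   names must be valid group labels.
#' @param fields_per_specimen Fields captured per specimen (default 7).
#' @param seed Base RNG seed.
#' @param out_dir Optional directory; when given, per-field TIFF pairs,
#'   a `manifest.csv` and a `truth.csv` are written there.
#' @param base_spec A [scene_spec()] providing every parameter other
#'   than `n_nuclei`, `fraction_positive` and `seed`.
#' @return A list with `fields` (list of [field_record]s), `truth`
#'   (data frame: one row per field with planted counts) and, when
#'   `out_dir` was given, `manifest` (the manifest data frame).
#' @export
generate_cohort <- function(groups = cohort_groups(),
                            fields_per_specimen = 7L, seed = 1L,
                            out_dir = NULL,
                            base_spec = scene_spec()) {
  if (is.null(names(groups)) ||
      !all(names(groups) %in% GROUP_LABELS)) {
    stop("`groups` must be a named list with valid group labels")
  }
  fields <- list()
  truth <- list()
  manifest <- list()
  counter <- 0L
  for (g in names(groups)) {
    prof <- groups[[g]]
    for (s in seq_len(prof$n_specimens)) {
      sid <- sprintf("%s_%02d", g, s)
      for (f in seq_len(fields_per_specimen)) {
        counter <- counter + 1L
        field_seed <- as.integer(
          (as.double(seed) * 100003 + counter * 7919) %% 2147483647)
        n_nuc <- with_seed(field_seed,
                           max(3L, stats::rpois(1L, prof$n_nuclei_mean)))
        spec <- base_spec
        spec$n_nuclei <- n_nuc
        spec$fraction_positive <- prof$fraction_positive
        spec$seed <- field_seed
        scn <- generate_scene(spec, specimen_id = sid, group_label = g,
                              field_index = f)
        fields[[counter]] <- scn$field
        truth[[counter]] <- data.frame(
          specimen_id = sid, group_label = g, field_index = f,
          seed = field_seed, n_nuclei_true = n_nuc,
          n_positive_true = sum(scn$truth$positive),
          stringsAsFactors = FALSE)
        if (!is.null(out_dir)) {
          spec_dir <- file.path(out_dir, sid)
          dir.create(spec_dir, recursive = TRUE, showWarnings = FALSE)
          dp <- file.path(spec_dir, sprintf("field%02d_dapi.tif", f))
          bp <- file.path(spec_dir, sprintf("field%02d_biomarker.tif", f))
          write_channel(scn$field$dapi, dp)
          write_channel(scn$field$biomarker, bp)
          manifest[[counter]] <- data.frame(
            specimen_id = sid, group_label = g, field_index = f,
            dapi_path = file.path(sid, basename(dp)),
            biomarker_path = file.path(sid, basename(bp)),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  truth <- do.call(rbind, truth)
  out <- list(fields = fields, truth = truth)
  if (!is.null(out_dir)) {
    out$manifest <- do.call(rbind, manifest)
    utils::write.csv(out$manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
    utils::write.csv(truth, file.path(out_dir, "truth.csv"),
                     row.names = FALSE)
  }
  out
}
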