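#' Run configuration for an end-to-end analysis
#'
#' @param input_dir Directory containing channel TIFFs and a
#'   `manifest.csv` (columns `specimen_id`, `group_label`,
#'   `field_index`, `dapi_path`, `biomarker_path`; paths relative to
#'   the manifest).
#' @param output_dir Directory for results (created if absent).
#' @param params A [field_params()] list.
#' @param ratings_path Optional CSV of rater scores (columns
#'   `case_id`, `group_label`, `scale`, `rater_a`, `rater_b`); when
#'   supplied a weighted-kappa report is written.
#' @param write_qc Write an HSV QC rendering of each biomarker channel
#'   under `output_dir/qc/` (default `FALSE`).
#' @param seed Seed recorded in the run log (the quantification itself
#'   is deterministic; the seed matters only when the run also
#'   simulates data).
#' @return A list of class `run_config`.
#' @export
run_config <- function(input_dir, output_dir,
                       params = field_params(), ratings_path = NULL,
                       write_qc = FALSE, seed = 1L) {
  if (!inherits(params, "field_params")) {
    stop("`params` must come from field_params()")
  }
  structure(
    list(input_dir = input_dir, output_dir = output_dir,
         params = params, ratings_path = ratings_path,
         write_qc = isTRUE(write_qc), seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Validate a manifest CSV
#'
#' Checks that the manifest has the required columns, that every
#' referenced image exists, and that no (specimen_id, field_index)
#' pair occurs twice.  The parse is order-insensitive: rows are
#' returned sorted by (specimen_id, field_index).
#'
#' @param path Path to `manifest.csv`.
#' @return A data frame of field stubs with absolute image paths.
#' @export
validate_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("specimen_id", "group_label", "field_index",
                "dapi_path", "biomarker_path")
  missing <- setdiff(required, names(man))
  if (length(missing)) {
    stop("manifest is missing columns: ",
         paste(missing, collapse = ", "))
  }
  if (nrow(man) == 0L) stop("manifest has no rows")
  base <- dirname(normalizePath(path))
  for (col in c("dapi_path", "biomarker_path")) {
    p <- man[[col]]
    abs <- ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
    bad <- which(!file.exists(abs))
    if (length(bad)) {
      stop("manifest row ", bad[1L], ": file not found: ",
           man[[col]][bad[1L]])
    }
    man[[col]] <- abs
  }
  key <- paste(man$specimen_id, man$field_index, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup)) {
    stop("manifest row ", dup[1L], ": duplicate (specimen_id, ",
         "field_index) = (", man$specimen_id[dup[1L]], ", ",
         man$field_index[dup[1L]], ")")
  }
  man[order(man$specimen_id, man$field_index), required]
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config[c("input_dir", "output_dir",
                                       "params", "seed")],
                              auto_unbox = TRUE, force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full pipeline over an image directory
#'
#' Quantifies every manifest field, writes `field_metrics.csv`, runs
#' ANOVA/Tukey HSD on each metric across diagnostic groups
#' (`pairwise_comparisons.csv`), optionally computes weighted-kappa
#' rater agreement (`kappa_report.csv`), and writes a structured
#' `run_log.json` with the full parameter echo, a config hash, and
#' per-field status.  Unreadable or degenerate fields are skipped with
#' a warning and counted in the log — never silently dropped.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `metrics`, `comparisons`, `kappa`
#'   (or `NULL`) and `log`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) {
    stop("`config` must come from run_config()")
  }
  man <- validate_manifest(file.path(config$input_dir, "manifest.csv"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  log <- list(parameters = unclass(config$params),
              seed = config$seed,
              config_hash = config_hash(config),
              n_fields = nrow(man), fields = list())
  rows <- list()
  n_skipped <- 0L
  for (i in seq_len(nrow(man))) {
    rec <- man[i, ]
    status <- "ok"
    row <- tryCatch({
      field <- field_record(
        rec$specimen_id, rec$group_label, rec$field_index,
        dapi = load_channel(rec$dapi_path, "DAPI"),
        biomarker = load_channel(rec$biomarker_path, "BIOMARKER"))
      withCallingHandlers(
        compute_field_metrics(field, config$params),
        warning = function(w) {
          status <<- paste("warning:", conditionMessage(w))
          invokeRestart("muffleWarning")
        })
    }, error = function(e) {
      warning("skipping field ", rec$specimen_id, "/", rec$field_index,
              ": ", conditionMessage(e))
      status <<- paste("skipped:", conditionMessage(e))
      NULL
    })
    if (is.null(row)) {
      n_skipped <- n_skipped + 1L
    } else {
      rows[[length(rows) + 1L]] <- row
      if (config$write_qc) {
        qc_dir <- file.path(config$output_dir, "qc")
        dir.create(qc_dir, showWarnings = FALSE)
        viz <- hsv_visualization(
          load_channel(rec$biomarker_path, "BIOMARKER"))
        tiff::writeTIFF(viz, file.path(
          qc_dir, sprintf("%s_f%02d_biomarker_hsv.tif",
                          rec$specimen_id, rec$field_index)))
      }
    }
    log$fields[[i]] <- list(specimen_id = rec$specimen_id,
                            field_index = rec$field_index,
                            status = status)
  }
  log$n_skipped <- n_skipped
  if (length(rows) == 0L) stop("no field could be quantified")
  metrics <- do.call(rbind, rows)
  metrics <- metrics[order(metrics$specimen_id, metrics$field_index), ]
  write_metrics_table(metrics, file.path(config$output_dir,
                                         "field_metrics.csv"))

  comparisons <- NULL
  if (length(unique(metrics$group_label)) >= 2L) {
    cmp <- lapply(c("n_merged_positive", "n_biomarker_positive",
                    "mean_intensity"),
                  function(m) {
                    tryCatch(
                      anova_tukey(metrics[[m]], metrics$group_label,
                                  metric_name = m),
                      error = function(e) NULL)
                  })
    comparisons <- do.call(rbind, cmp)
    if (!is.null(comparisons)) {
      utils::write.csv(comparisons,
                       file.path(config$output_dir,
                                 "pairwise_comparisons.csv"),
                       row.names = FALSE)
    }
  }

  kappa <- NULL
  if (!is.null(config$ratings_path)) {
    rt <- utils::read.csv(config$ratings_path, stringsAsFactors = FALSE)
    rt <- rating_table(rt$case_id, rt$group_label, rt$scale,
                       rt$rater_a, rt$rater_b)
    res <- lapply(unique(rt$scale), function(s) {
      kr <- weighted_kappa(rt, scale = s)
      data.frame(scale = s, kappa = kr$kappa, z = kr$z, p = kr$p,
                 n_items = kr$n_items,
                 interpretation = kr$interpretation,
                 stringsAsFactors = FALSE)
    })
    kappa <- do.call(rbind, res)
    utils::write.csv(kappa, file.path(config$output_dir,
                                      "kappa_report.csv"),
                     row.names = FALSE)
  }

  jsonlite::write_json(log, file.path(config$output_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  invisible(list(metrics = metrics, comparisons = comparisons,
                 kappa = kappa, log = log))
}
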