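.default_config <- function() list(
  imzml = NULL,           # path to the .imzML input (ibd alongside)
  library = NULL,         # compound library CSV; NULL = bundled mini-library
  adducts = NULL,         # adduct CSV; NULL = bundled standard set
  roi_labels = NULL,      # ROI label matrix CSV (palette JSON alongside)
  cluster_mapping = NULL, # named list cluster id -> label, alternative to roi_labels
  out_dir = "lotusmsi_out",
  bin_ppm = 5, snr_min = 3, window_ppm = 10, n_top = 1020,
  tol_ppm = 5, tau = 0.5, r2_min = 0.8,
  k = 10, n_restarts = 10, beta = 0.10, gamma = 3.0,
  seed = 1
)

.config_ranges <- list(
  bin_ppm = c(0, Inf), snr_min = c(0, Inf), window_ppm = c(0, Inf),
  n_top = c(1, Inf), tol_ppm = c(0, Inf), tau = c(0, Inf),
  r2_min = c(0, 1), k = c(2, Inf), n_restarts = c(1, Inf),
  beta = c(0, Inf), gamma = c(0, Inf)
)

#' Validate and normalize a run configuration
#'
#' Accepts a JSON file path or a named list; injects defaults for missing
#' keys and collects every problem rather than failing at the first.
#'
#' @param config Path to a JSON config, a named list, or NULL (all defaults).
#' @return List with `config` (normalized), `errors` (character vector,
#'   empty when valid) and `warnings`.
#' @export
validate_config <- function(config = NULL) {
  errors <- character(0); warns <- character(0)
  if (is.character(config)) {
    if (!file.exists(config))
      return(list(config = .default_config(),
                  errors = paste("config file not found:", config),
                  warnings = warns))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (is.null(config)) config <- list()
  if (!is.list(config)) {
    errors <- c(errors, "config must be a named list or JSON object")
    config <- list()
  }
  def <- .default_config()
  unknown <- setdiff(names(config), names(def))
  if (length(unknown))
    warns <- c(warns, paste("unknown config keys preserved:",
                            paste(unknown, collapse = ", ")))
  cfg <- utils::modifyList(def, config)
  for (key in names(.config_ranges)) {
    v <- cfg[[key]]
    rg <- .config_ranges[[key]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < rg[1] || v > rg[2])
      errors <- c(errors, sprintf("%s must be a number in [%g, %g] (got %s)",
                                  key, rg[1], rg[2], paste(v, collapse = ",")))
  }
  for (key in c("imzml", "library", "adducts", "roi_labels")) {
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]]))
      errors <- c(errors, sprintf("%s file not found: %s", key, cfg[[key]]))
  }
  list(config = cfg, errors = errors, warnings = warns)
}

.stage <- function(name, log, expr) {
  log(sprintf("stage %s: start", name))
  res <- tryCatch(expr, error = function(e)
    stop("stage ", name, ": ", conditionMessage(e), call. = FALSE))
  log(sprintf("stage %s: done", name))
  res
}

#' Run the full analysis pipeline
#'
#' normalize -> mean spectrum -> pick peaks -> top-N -> annotate ->
#' blank/shape filter -> k-means segmentation -> per-tissue
#' semi-quantification, writing every stage output and a provenance log into
#' `config$out_dir`.
#'
#' @param config A config list or JSON path (see [validate_config()]).
#' @param dataset Optional in-memory `msi_dataset`; otherwise read from
#'   `config$imzml`.
#' @param stages Subset of `c("annotate", "segment", "semiquant")` to run
#'   after preprocessing (default all).
#' @return Invisibly, a list with the intermediate objects (`dataset`,
#'   `peaks`, `annotation`, `summary`, `segmentation`, `roi`,
#'   `tissue_table`, `counts`, `config`).
#' @export
run_pipeline <- function(config = NULL, dataset = NULL,
                         stages = c("annotate", "segment", "semiquant")) {
  val <- validate_config(config)
  if (length(val$errors))
    stop("invalid configuration:\n  ", paste(val$errors, collapse = "\n  "))
  for (w in val$warnings) warning(w)
  cfg <- val$config
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$out_dir, "run_log.txt")
  log_con <- file(log_path, "w")
  on.exit(close(log_con), add = TRUE)
  log <- function(msg)
    writeLines(sprintf("%s %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), msg),
               log_con)
  log(paste("lotusmsi", as.character(utils::packageVersion("lotusmsi"))))
  prov <- cfg[vapply(cfg, function(v) is.numeric(v) || is.character(v), logical(1))]
  log(paste("parameters:", jsonlite::toJSON(prov, auto_unbox = TRUE)))

  if (is.null(dataset)) {
    if (is.null(cfg$imzml)) stop("stage input: no dataset and no imzml path")
    dataset <- .stage("input", log, read_imzml(cfg$imzml))
  }
  log(sprintf("dataset: %d pixels, polarity %s", n_pixels(dataset),
              dataset$polarity))

  norm <- .stage("normalize", log, rms_normalize(dataset))
  ms <- .stage("mean_spectrum", log, mean_spectrum(norm, bin_ppm = cfg$bin_ppm))
  peaks <- .stage("pick_peaks", log,
                  pick_peaks(ms, snr_min = cfg$snr_min,
                             window_ppm = cfg$window_ppm))
  peaks <- .stage("select_top_n", log, select_top_n(peaks, n = cfg$n_top))
  # per-pixel stats only for the retained peaks (cheap after top-N)
  peaks$max_intensity <- apply(.ion_matrix(norm, peaks$centroid_mz,
                                           cfg$window_ppm), 2, max)
  write_peak_table(peaks, file.path(cfg$out_dir, "peaks.csv"))
  log(sprintf("peaks: %d retained", nrow(peaks)))

  roi <- NULL
  if (!is.null(cfg$roi_labels))
    roi <- .stage("roi", log,
                  load_roi_labels(cfg$roi_labels, dataset = dataset))

  annotation <- NULL; summary <- NULL
  if ("annotate" %in% stages) {
    library <- .stage("library", log, if (is.null(cfg$library)) minilib()
                      else read_compound_library(cfg$library))
    adducts <- .stage("adducts", log, {
      ad <- if (is.null(cfg$adducts)) read_adducts() else read_adducts(cfg$adducts)
      Filter(function(a) a$polarity == dataset$polarity, ad)
    })
    index <- .stage("ion_index", log,
                    build_ion_index(library, adducts, dataset$mz_range))
    annotation <- .stage("match", log,
                         match_peaks(peaks, index, tol_ppm = cfg$tol_ppm))
    if (!is.null(roi))
      annotation <- .stage("blank_filter", log,
                           blank_filter(annotation, norm, roi, tau = cfg$tau))
    else log("stage blank_filter: skipped (no ROI labels)")
    annotation <- .stage("shape_filter", log,
                         shape_filter(annotation, r2_min = cfg$r2_min))
    write_annotation_csv(annotation, file.path(cfg$out_dir, "annotation.csv"))
    summary <- summarize_annotations(annotation, library)
    jsonlite::write_json(
      list(n_compounds = summary$n_compounds,
           class_counts = as.list(summary$class_counts),
           n_peaks = summary$n_peaks,
           n_unidentified_peaks = summary$n_unidentified_peaks,
           undetected = summary$undetected),
      file.path(cfg$out_dir, "summary.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    log(sprintf("annotation: %d compounds retained", summary$n_compounds))
  }

  segmentation <- NULL
  if ("segment" %in% stages) {
    segmentation <- .stage("segment", log,
                           kmeans_segment(norm, peaks, k = cfg$k,
                                          seed = cfg$seed,
                                          n_restarts = cfg$n_restarts))
    utils::write.csv(data.frame(x = dataset$coords$x, y = dataset$coords$y,
                                cluster = segmentation$cluster),
                     file.path(cfg$out_dir, "segmentation.csv"),
                     row.names = FALSE)
    log(sprintf("segmentation: k=%d inertia=%.6g", segmentation$k,
                segmentation$inertia))
    if (is.null(roi) && !is.null(cfg$cluster_mapping)) {
      mapping <- unlist(cfg$cluster_mapping)
      roi <- .stage("clusters_to_roi", log,
                    clusters_to_roi(segmentation, mapping))
    }
  }

  tissue_table <- NULL; counts <- NULL
  if ("semiquant" %in% stages && !is.null(annotation)) {
    if (is.null(roi)) {
      log("stage semiquant: skipped (no ROI available)")
    } else {
      tissue_table <- .stage("semiquant", log, {
        tt <- roi_intensity_table(norm, annotation, roi,
                                  tol_ppm = cfg$tol_ppm)
        presence_calls(tt, beta = cfg$beta, gamma = cfg$gamma)
      })
      write_tissue_tables(tissue_table, cfg$out_dir)
      counts <- tissue_counts(tissue_table)
      utils::write.csv(
        data.frame(tissue = names(counts$per_tissue),
                   n_metabolites = as.integer(counts$per_tissue)),
        file.path(cfg$out_dir, "tissue_counts.csv"), row.names = FALSE)
      utils::write.csv(
        data.frame(class = rownames(counts$class_by_tissue),
                   counts$class_by_tissue, check.names = FALSE),
        file.path(cfg$out_dir, "class_composition.csv"), row.names = FALSE)
      log(sprintf("semiquant: %d distinct metabolites across tissues",
                  counts$n_distinct))
    }
  }
  log("run complete")
  invisible(list(dataset = dataset, normalized = norm, peaks = peaks,
                 annotation = annotation, summary = summary,
                 segmentation = segmentation, roi = roi,
                 tissue_table = tissue_table, counts = counts, config = cfg))
}
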