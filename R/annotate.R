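#' Match picked peaks against an ion index
#'
#' For every peak, all library ion candidates with
#' `|obs - theo| / theo * 1e6 <= tol_ppm` are reported; a peak matching
#' several compounds (isomers at the instrument's accuracy) keeps them all as
#' a group. Matching is a binary search (via `findInterval`) over the
#' m/z-sorted index. Peaks with no candidate are retained as unidentified
#' rows, never dropped.
#'
#' @param peaks A `peak_table`.
#' @param index An `ion_index` from [build_ion_index()].
#' @param tol_ppm Matching tolerance in ppm (default 5).
#' @return An `annotation_table` data.frame: one row per (peak, compound,
#'   adduct) hit plus one row per unidentified peak; columns `centroid_mz`,
#'   `compound_id`, `name`, `class`, `adduct_label`, `theoretical_mz`,
#'   `ppm_error`, `shape_r2`, `blank_ratio`, `is_isomer_group`, `excluded`.
#'   Hits within a peak are ranked by |ppm| then compound_id.
#' @export
match_peaks <- function(peaks, index, tol_ppm = 5) {
  stopifnot(inherits(peaks, "peak_table"), inherits(index, "ion_index"))
  if (tol_ppm <= 0) stop("tol_ppm must be > 0")
  if (is.unsorted(index$theoretical_mz)) stop("ion index must be sorted by m/z")
  rows <- vector("list", nrow(peaks))
  theo <- index$theoretical_mz
  for (i in seq_len(nrow(peaks))) {
    obs <- peaks$centroid_mz[i]
    lo <- obs / (1 + tol_ppm * 1e-6)
    hi <- obs / (1 - tol_ppm * 1e-6)
    i1 <- findInterval(lo, theo, left.open = TRUE) + 1L
    i2 <- findInterval(hi, theo)
    if (i2 >= i1) {
      cand <- index[i1:i2, , drop = FALSE]
      ppm <- (obs - cand$theoretical_mz) / cand$theoretical_mz * 1e6
      keep <- abs(ppm) <= tol_ppm
      cand <- cand[keep, , drop = FALSE]; ppm <- ppm[keep]
    } else {
      cand <- index[0, , drop = FALSE]; ppm <- numeric(0)
    }
    if (nrow(cand)) {
      ord <- order(abs(ppm), cand$compound_id)
      rows[[i]] <- data.frame(
        centroid_mz = obs, compound_id = cand$compound_id[ord],
        name = cand$name[ord], class = cand$class[ord],
        adduct_label = cand$adduct_label[ord],
        theoretical_mz = cand$theoretical_mz[ord], ppm_error = ppm[ord],
        shape_r2 = peaks$shape_r2[i], blank_ratio = NA_real_,
        is_isomer_group = length(unique(cand$compound_id)) > 1L,
        excluded = "none", stringsAsFactors = FALSE)
    } else {
      rows[[i]] <- data.frame(
        centroid_mz = obs, compound_id = NA_character_, name = NA_character_,
        class = NA_character_, adduct_label = NA_character_,
        theoretical_mz = NA_real_, ppm_error = NA_real_,
        shape_r2 = peaks$shape_r2[i], blank_ratio = NA_real_,
        is_isomer_group = FALSE, excluded = "none", stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "tol_ppm") <- tol_ppm
  class(out) <- c("annotation_table", "data.frame")
  out
}

.tissue_labels <- function() c("pericarp", "seed_coat", "cotyledon", "plumule")

# blank_mask may be a logical matrix (TRUE = blank pixel) or an roi_mask label
# matrix, in which case "background" pixels are the blank control and all
# other labels count as on-tissue.
.blank_logical <- function(blank_mask) {
  if (is.logical(blank_mask)) return(blank_mask)
  if (inherits(blank_mask, "roi_mask") || is.character(blank_mask))
    return(unclass(blank_mask) == "background")
  stop("blank_mask must be a logical matrix or an roi_mask")
}

#' Flag hits with evident distribution in the blank control
#'
#' For each annotated peak the ion image is averaged over blank (off-tissue
#' matrix) pixels and over on-tissue pixels; the hit is excluded when
#' `blank_ratio = mean(blank) / mean(tissue) >= tau`, and always when the
#' on-tissue mean is 0 (0/0 or x/0). With `tau = Inf` nothing is excluded.
#'
#' @param table An `annotation_table`.
#' @param dataset The (normalized) `msi_dataset` the peaks came from.
#' @param blank_mask Logical matrix of blank pixels, or an `roi_mask` whose
#'   `"background"` label marks the blank control.
#' @param tau Exclusion threshold (> 0, default 0.5).
#' @param tol_ppm Ion-image window; defaults to the matching tolerance.
#' @return The table with `blank_ratio` filled and `excluded` set to
#'   `"blank"` where the filter fires.
#' @export
blank_filter <- function(table, dataset, blank_mask, tau = 0.5,
                         tol_ppm = attr(table, "tol_ppm")) {
  stopifnot(inherits(table, "annotation_table"), tau > 0)
  blank <- .blank_logical(blank_mask)
  bl_pix <- blank[cbind(dataset$coords$y, dataset$coords$x)]
  if (!any(bl_pix)) {
    warning("blank mask contains no acquired pixels; blank filter skipped")
    return(table)
  }
  mzs <- unique(table$centroid_mz)
  vals <- .ion_matrix(dataset, mzs, tol_ppm)
  mean_blank <- colMeans(vals[bl_pix, , drop = FALSE])
  mean_tiss <- colMeans(vals[!bl_pix, , drop = FALSE])
  ratio <- ifelse(mean_tiss > 0, mean_blank / mean_tiss,
                  ifelse(mean_blank > 0, Inf, NaN))
  idx <- match(table$centroid_mz, mzs)
  table$blank_ratio <- ratio[idx]
  fire <- is.finite(tau) &
    (mean_tiss[idx] == 0 | (!is.nan(ratio[idx]) & ratio[idx] >= tau))
  hit <- fire & table$excluded == "none"   # unidentified peaks are flagged too
  table$excluded[hit] <- "blank"
  attr(table, "tau") <- tau
  table
}

#' Flag hits whose peak has poor shape
#'
#' Excludes hits whose mean-spectrum peak deviates from a symmetric Gaussian
#' (`shape_r2 < r2_min`); merged/bimodal artifacts fail this test.
#'
#' @param table An `annotation_table` (carries `shape_r2` per peak).
#' @param r2_min Minimum goodness of fit in `[0, 1]` (default 0.8).
#' @return The table with `excluded` set to `"shape"` where the filter fires.
#' @export
shape_filter <- function(table, r2_min = 0.8) {
  stopifnot(inherits(table, "annotation_table"))
  fire <- !is.na(table$shape_r2) & table$shape_r2 < r2_min &
    table$excluded == "none" & !is.na(table$compound_id)
  table$excluded[fire] <- "shape"
  attr(table, "r2_min") <- r2_min
  table
}

#' Retained (non-excluded, identified) hits
#' @param table An `annotation_table`.
#' @export
retained_hits <- function(table) {
  table[table$excluded == "none" & !is.na(table$compound_id), , drop = FALSE]
}

#' Summarize an annotation table
#'
#' Counts distinct retained compounds overall and per metabolite class; a
#' compound matched by several adducts (or in both polarities, if tables are
#' concatenated) counts once. Isomer groups count each listed compound.
#'
#' @param table An `annotation_table` (filters applied).
#' @param library Optional `compound_library`; when given, library compounds
#'   with no retained hit are listed as `undetected`.
#' @return A list: `n_compounds`, `class_counts`, `compounds` (one row per
#'   retained compound), `n_peaks`, `n_unidentified_peaks`, `undetected`.
#' @export
summarize_annotations <- function(table, library = NULL) {
  stopifnot(inherits(table, "annotation_table"))
  kept <- retained_hits(table)
  comp <- unique(kept[, c("compound_id", "name", "class")])
  comp <- comp[order(comp$compound_id), , drop = FALSE]
  rownames(comp) <- NULL
  cls <- if (nrow(comp)) sort(table(comp$class), decreasing = TRUE) else table(character(0))
  undetected <- NULL
  if (!is.null(library))
    undetected <- setdiff(library$compound_id, comp$compound_id)
  list(n_compounds = nrow(comp),
       class_counts = cls,
       compounds = comp,
       n_peaks = length(unique(table$centroid_mz)),
       n_unidentified_peaks = length(unique(
         table$centroid_mz[is.na(table$compound_id)])),
       undetected = undetected)
}

#' Write the annotation report CSV
#' @param table An `annotation_table`.
#' @param path CSV path.
#' @export
write_annotation_csv <- function(table, path) {
  cols <- c("centroid_mz", "compound_id", "name", "class", "adduct_label",
            "ppm_error", "blank_ratio", "shape_r2", "excluded")
  utils::write.csv(as.data.frame(table)[, cols], path, row.names = FALSE)
  invisible(path)
}
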