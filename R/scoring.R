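#' Score annotation recovery against a phantom manifest
#'
#' A planted (non-matrix) ion counts as recovered when some retained hit
#' names its (compound, adduct) pair. Precision is computed over the distinct
#' retained (compound, adduct) pairs; an empty annotation reports precision 0
#' with `undefined_precision = TRUE`.
#'
#' @param table An `annotation_table` with filters applied.
#' @param manifest A `phantom_manifest`.
#' @details A retained hit that is not a planted (compound, adduct) pair but
#'   whose theoretical m/z coincides (within 0.1 ppm) with a planted ion's is
#'   an isobaric equivalent -- an equal-mass isomer or an identical ion
#'   formula reached through another adduct. Accurate-mass annotation cannot
#'   distinguish these by construction (they are listed alongside each other,
#'   as isomer groups), so `precision` counts them as correct;
#'   `precision_strict` does not.
#' @return List: `recall`, `precision` (isobar-aware), `precision_strict`,
#'   `n_planted`, `n_recovered`, `n_spurious`, `spurious`, `ppm_errors`
#'   (named, per recovered ion), `undefined_precision`.
#' @export
score_recovery <- function(table, manifest) {
  stopifnot(inherits(table, "annotation_table"),
            inherits(manifest, "phantom_manifest"))
  planted <- manifest$ions[!manifest$ions$is_matrix, , drop = FALSE]
  kept <- retained_hits(table)
  key <- function(c, a) paste(c, a, sep = "|")
  hits <- unique(kept[, c("compound_id", "adduct_label", "theoretical_mz")])
  hit_keys <- key(hits$compound_id, hits$adduct_label)
  plant_keys <- key(planted$compound_id, planted$adduct_label)
  recovered <- plant_keys %in% hit_keys
  exact_pair <- hit_keys %in% plant_keys
  isobaric <- vapply(hits$theoretical_mz, function(mz)
    any(abs(planted$true_mz - mz) / mz * 1e6 < 0.1), logical(1))
  correct <- exact_pair | isobaric
  ppm <- stats::setNames(rep(NA_real_, nrow(planted)), plant_keys)
  for (i in which(recovered)) {
    sub <- kept[key(kept$compound_id, kept$adduct_label) == plant_keys[i], ]
    ppm[i] <- sub$ppm_error[which.min(abs(sub$ppm_error))]
  }
  undefined <- length(hit_keys) == 0L
  list(recall = mean(recovered),
       precision = if (undefined) 0 else mean(correct),
       precision_strict = if (undefined) 0 else mean(exact_pair),
       n_planted = nrow(planted),
       n_recovered = sum(recovered),
       n_spurious = sum(!correct),
       spurious = hit_keys[!correct],
       ppm_errors = ppm,
       undefined_precision = undefined)
}

#' Fraction of matrix-only ions removed by the blank filter
#'
#' A matrix ion counts as excluded when every peak within `tol_ppm` of its
#' observed m/z is flagged by the blank filter (or when no such peak survives
#' into the table at all).
#'
#' @param table An `annotation_table` after [blank_filter()].
#' @param manifest A `phantom_manifest`.
#' @param tol_ppm Peak-to-ion matching tolerance (default 5).
#' @return List: `fraction_excluded`, `n_matrix`, `unexcluded` (observed m/z
#'   of matrix ions that survive).
#' @export
score_blank_exclusion <- function(table, manifest, tol_ppm = 5) {
  mat <- manifest$ions[manifest$ions$is_matrix, , drop = FALSE]
  if (nrow(mat) == 0L)
    return(list(fraction_excluded = NA_real_, n_matrix = 0L,
                unexcluded = numeric(0)))
  bad <- numeric(0)
  for (i in seq_len(nrow(mat))) {
    d <- abs(table$centroid_mz - mat$observed_mz[i]) / mat$observed_mz[i] * 1e6
    rows <- which(d <= tol_ppm)
    if (length(rows) && any(table$excluded[rows] != "blank"))
      bad <- c(bad, mat$observed_mz[i])
  }
  list(fraction_excluded = 1 - length(bad) / nrow(mat),
       n_matrix = nrow(mat), unexcluded = bad)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items;
#' 1 for identical partitions (up to relabeling), ~0 for independent ones.
#'
#' @param a,b Vectors of equal length (any label type).
#' @return Numeric ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

#' Score a segmentation against phantom ground truth
#'
#' Maps clusters to anatomical labels by majority vote against the manifest
#' geometry and reports the adjusted Rand index of the mapped labels versus
#' the true region labels, plus the ARI of the raw cluster assignment.
#'
#' @param segmentation A `segmentation_result`.
#' @param manifest A `phantom_manifest` (same grid).
#' @return List: `ari` (mapped labels vs truth), `ari_raw` (clusters vs
#'   truth), `mapping`.
#' @export
score_segmentation <- function(segmentation, manifest) {
  stopifnot(inherits(segmentation, "segmentation_result"),
            inherits(manifest, "phantom_manifest"))
  truth <- unclass(manifest$geometry)[cbind(segmentation$coords$y,
                                            segmentation$coords$x)]
  if (anyNA(truth)) stop("segmentation grid does not match the manifest")
  mapping <- majority_vote_mapping(segmentation, manifest$geometry)
  mapped <- mapping[as.character(segmentation$cluster)]
  list(ari = adjusted_rand_index(mapped, truth),
       ari_raw = adjusted_rand_index(segmentation$cluster, truth),
       mapping = mapping)
}
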