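#' Per-tissue mean ion intensities of annotated metabolites
#'
#' One row per distinct retained compound; the cell value is the mean of the
#' compound's ion image over the tissue's pixels (summed across the
#' compound's retained adduct peaks). Cavity and background means are
#' tracked in extra columns but excluded from the four-tissue statistics.
#'
#' @param dataset A normalized `msi_dataset`.
#' @param table An `annotation_table` with filters applied.
#' @param roi An `roi_mask` covering the pixel grid.
#' @param tol_ppm Ion-image window (defaults to the matching tolerance).
#' @return A `tissue_table`: list with `intensity` (compound x region
#'   matrix over pericarp, seed_coat, cotyledon, plumule, cavity,
#'   background), `classes`, `mz` (representative m/z per compound),
#'   `presence` (NULL until [presence_calls()]).
#' @export
roi_intensity_table <- function(dataset, table, roi,
                                tol_ppm = attr(table, "tol_ppm")) {
  stopifnot(inherits(dataset, "msi_dataset"),
            inherits(table, "annotation_table"), inherits(roi, "roi_mask"))
  if (is.null(tol_ppm)) tol_ppm <- 5
  kept <- retained_hits(table)
  regions <- roi_labels()
  lab_pix <- unclass(roi)[cbind(dataset$coords$y, dataset$coords$x)]
  compounds <- sort(unique(kept$compound_id))
  mat <- matrix(0, nrow = length(compounds), ncol = length(regions),
                dimnames = list(compounds, regions))
  classes <- character(length(compounds)); names(classes) <- compounds
  mzrep <- numeric(length(compounds)); names(mzrep) <- compounds
  region_idx <- lapply(regions, function(r) which(lab_pix == r))
  names(region_idx) <- regions
  empty <- intersect(regions[vapply(region_idx, length, integer(1)) == 0L],
                     .tissue_labels())
  if (length(empty))
    warning("regions with zero pixels: ", paste(empty, collapse = ", "))
  if (length(compounds)) {
    mzs <- unique(kept$centroid_mz)
    vals <- .ion_matrix(dataset, mzs, tol_ppm)
    for (ci in seq_along(compounds)) {
      sub <- kept[kept$compound_id == compounds[ci], , drop = FALSE]
      # one image per distinct peak, summed over the compound's adducts
      pk <- unique(sub$centroid_mz)
      v <- rowSums(vals[, match(pk, mzs), drop = FALSE])
      for (r in regions) {
        idx <- region_idx[[r]]
        mat[ci, r] <- if (length(idx)) mean(v[idx]) else NA_real_
      }
      classes[ci] <- sub$class[1]
      mzrep[ci] <- min(sub$theoretical_mz)
    }
  }
  structure(list(intensity = mat, classes = classes, mz = mzrep,
                 presence = NULL, tissues = .tissue_labels()),
            class = "tissue_table")
}

#' @export
print.tissue_table <- function(x, ...) {
  cat(sprintf("<tissue_table> %d compounds x %d regions%s\n",
              nrow(x$intensity), ncol(x$intensity),
              if (is.null(x$presence)) "" else " (presence called)"))
  invisible(x)
}

#' Call per-tissue presence of each metabolite
#'
#' A metabolite is present in tissue T iff its mean intensity there is
#' positive, at least `beta` times the maximum tissue mean, and at least
#' `gamma` times the background mean. Cavity and background columns are
#' carried but not called.
#'
#' @param table A `tissue_table`.
#' @param beta Fraction of the max tissue mean (default 0.10).
#' @param gamma Multiple of the background mean (default 3.0).
#' @return The `tissue_table` with a logical `presence` matrix
#'   (compound x four tissues).
#' @export
presence_calls <- function(table, beta = 0.10, gamma = 3.0) {
  stopifnot(inherits(table, "tissue_table"), beta >= 0, gamma >= 0)
  tis <- table$tissues
  m <- table$intensity[, tis, drop = FALSE]
  bg <- table$intensity[, "background"]
  bg[is.na(bg)] <- 0
  rowmax <- apply(m, 1, function(v) max(v, 0, na.rm = TRUE))
  pres <- m > 0 & m >= beta * rowmax & m >= gamma * bg
  pres[is.na(pres)] <- FALSE
  table$presence <- pres
  attr(table, "beta") <- beta
  attr(table, "gamma") <- gamma
  table
}

#' Per-tissue metabolite counts and class composition
#'
#' @param table A `tissue_table` after [presence_calls()] (or a logical
#'   presence matrix plus a `classes` vector).
#' @param classes Class label per compound (defaults to the table's).
#' @return List: `per_tissue` (named counts), `n_distinct` (compounds present
#'   in at least one tissue), `class_by_tissue` (class x tissue counts),
#'   `class_overall` (named counts among present compounds).
#' @export
tissue_counts <- function(table, classes = NULL) {
  if (inherits(table, "tissue_table")) {
    if (is.null(table$presence)) stop("run presence_calls() first")
    pres <- table$presence
    if (is.null(classes)) classes <- table$classes
  } else {
    pres <- table
  }
  stopifnot(is.matrix(pres), !is.null(classes), length(classes) == nrow(pres))
  per_tissue <- colSums(pres)
  any_pres <- rowSums(pres) > 0
  cls <- factor(classes)
  class_by_tissue <- t(vapply(levels(cls), function(cl)
    colSums(pres[cls == cl, , drop = FALSE]), numeric(ncol(pres))))
  list(per_tissue = per_tissue,
       n_distinct = sum(any_pres),
       class_by_tissue = class_by_tissue,
       class_overall = table(cls[any_pres]))
}

#' Row-scaled heatmap matrix
#'
#' Each compound's tissue intensities are divided by the row maximum, giving
#' values in `[0, 1]` (all-zero rows stay 0). Rows are ordered by metabolite
#' class, then by m/z, the conventional layout of MSI semi-quantification
#' heatmaps; scaling is idempotent.
#'
#' @param table A `tissue_table`.
#' @param include_cavity Include the cavity column (default FALSE: four
#'   tissues only).
#' @return A `heatmap_matrix`: numeric matrix with `classes` attribute.
#' @export
heatmap_matrix <- function(table, include_cavity = FALSE) {
  stopifnot(inherits(table, "tissue_table"))
  cols <- c(table$tissues, if (include_cavity) "cavity")
  m <- table$intensity[, cols, drop = FALSE]
  m[is.na(m)] <- 0
  ord <- order(table$classes, table$mz)
  m <- m[ord, , drop = FALSE]
  rmax <- apply(m, 1, max)
  scl <- ifelse(rmax > 0, rmax, 1)
  out <- m / scl
  structure(out, classes = table$classes[ord],
            class = c("heatmap_matrix", "matrix", "array"))
}

#' Render a heatmap matrix to a PNG file
#'
#' Thin optional layer over [heatmap_matrix()]: rows = metabolites (ordered
#' by class then m/z), columns = tissues, blue-yellow-red gradient from low
#' to high row-scaled intensity.
#'
#' @param hm A `heatmap_matrix`.
#' @param path PNG output path.
#' @param width,height Device size in pixels.
#' @export
plot_heatmap <- function(hm, path, width = 800, height = 1200) {
  stopifnot(inherits(hm, "heatmap_matrix"))
  pal <- grDevices::colorRampPalette(c("#08306B", "#F7E35D", "#A50F15"))(256)
  grDevices::png(path, width = width, height = height)
  on.exit(grDevices::dev.off())
  op <- graphics::par(mar = c(6, 10, 2, 2))
  on.exit(graphics::par(op), add = TRUE)
  m <- unclass(hm)[rev(seq_len(nrow(hm))), , drop = FALSE]
  graphics::image(t(m), col = pal, axes = FALSE, zlim = c(0, 1))
  graphics::axis(1, at = seq(0, 1, length.out = ncol(m)), labels = colnames(m),
                 las = 2, cex.axis = 0.9)
  graphics::axis(2, at = seq(0, 1, length.out = nrow(m)), labels = rownames(m),
                 las = 2, cex.axis = 0.6)
  invisible(path)
}

#' Write tissue-table exports as CSV
#'
#' Writes the intensity matrix, the presence matrix (if called) and the
#' heatmap matrix into `dir`.
#'
#' @param table A `tissue_table`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written paths.
#' @export
write_tissue_tables <- function(table, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  p <- file.path(dir, "tissue_intensity.csv")
  utils::write.csv(data.frame(compound_id = rownames(table$intensity),
                              class = unname(table$classes),
                              table$intensity, check.names = FALSE),
                   p, row.names = FALSE)
  paths <- c(paths, p)
  if (!is.null(table$presence)) {
    p <- file.path(dir, "tissue_presence.csv")
    utils::write.csv(data.frame(compound_id = rownames(table$presence),
                                table$presence * 1L, check.names = FALSE),
                     p, row.names = FALSE)
    paths <- c(paths, p)
  }
  hm <- heatmap_matrix(table)
  p <- file.path(dir, "heatmap_matrix.csv")
  utils::write.csv(data.frame(compound_id = rownames(hm),
                              class = attr(hm, "classes"),
                              unclass(hm), check.names = FALSE),
                   p, row.names = FALSE)
  paths <- c(paths, p)
  invisible(paths)
}
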