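#' Anatomical region labels
#'
#' Fixed vocabulary: the four tissues (pericarp, seed coat, cotyledon,
#' plumule), the internal cavity separating plumule from cotyledons, and
#' off-tissue background (matrix only).
#' @return Character vector of the six labels.
#' @export
roi_labels <- function() c(.tissue_labels(), "cavity", "background")

#' Construct an ROI mask
#'
#' @param m Character matrix (rows = y, cols = x) of labels from
#'   [roi_labels()].
#' @return An `roi_mask`.
#' @export
roi_mask <- function(m) {
  stopifnot(is.matrix(m), is.character(m))
  bad <- setdiff(unique(as.vector(m)), c(roi_labels(), NA))
  if (length(bad)) stop("unknown ROI labels: ", paste(bad, collapse = ", "))
  structure(m, class = c("roi_mask", "matrix", "array"))
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> %dx%d\n", ncol(x), nrow(x)))
  print(table(factor(as.vector(x), levels = roi_labels())))
  invisible(x)
}

#' Write / read ROI label matrices as delimited text with a palette
#'
#' The matrix is stored as comma-separated integer codes; the palette (a JSON
#' object mapping code to label) travels alongside, so externally drawn ROIs
#' can be exchanged with other tools.
#'
#' @param mask An `roi_mask`.
#' @param path Label-matrix CSV path.
#' @param palette_path JSON palette path (default: `path` + `.palette.json`).
#' @export
write_roi_labels <- function(mask, path,
                             palette_path = paste0(path, ".palette.json")) {
  labs <- roi_labels()
  codes <- matrix(match(as.vector(mask), labs), nrow = nrow(mask))
  utils::write.table(codes, path, sep = ",", row.names = FALSE,
                     col.names = FALSE, na = "0")
  pal <- as.list(labs)
  names(pal) <- as.character(seq_along(labs))
  jsonlite::write_json(pal, palette_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(labels = path, palette = palette_path))
}

#' @rdname write_roi_labels
#' @param dataset Optional `msi_dataset`; when given, the label image
#'   dimensions must cover the dataset's pixel grid.
#' @return For `load_roi_labels`, an `roi_mask`.
#' @export
load_roi_labels <- function(path, palette_path = paste0(path, ".palette.json"),
                            dataset = NULL) {
  codes <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  pal <- jsonlite::read_json(palette_path, simplifyVector = TRUE)
  miss <- setdiff(roi_labels(), unlist(pal))
  if (length(miss))
    warning("palette lacks labels: ", paste(miss, collapse = ", "))
  bad <- setdiff(setdiff(unique(as.vector(codes)), 0L), as.integer(names(pal)))
  if (length(bad)) stop("unknown label codes in ", path, ": ",
                        paste(bad, collapse = ", "))
  m <- matrix(NA_character_, nrow = nrow(codes), ncol = ncol(codes))
  for (code in names(pal)) m[codes == as.integer(code)] <- pal[[code]]
  if (!is.null(dataset)) {
    if (nrow(m) < max(dataset$coords$y) || ncol(m) < max(dataset$coords$x))
      stop("ROI label image dimensions do not cover the pixel grid")
  }
  roi_mask(m)
}

# squared Euclidean distances between rows of X and rows of C;
# xs2 = rowSums(X^2), precomputed once per clustering run
.dist2 <- function(X, C, xs2) {
  d2 <- outer(xs2, rowSums(C^2), `+`) - 2 * tcrossprod(X, C)
  pmax(d2, 0)
}

.kmeanspp_init <- function(X, k, xs2) {
  n <- nrow(X)
  centers <- matrix(0, nrow = k, ncol = ncol(X))
  idx <- sample.int(n, 1L)
  centers[1, ] <- X[idx, ]
  d2 <- .dist2(X, centers[1, , drop = FALSE], xs2)[, 1]
  for (j in 2:k) {
    if (all(d2 == 0)) idx <- sample.int(n, 1L)
    else idx <- sample.int(n, 1L, prob = d2)
    centers[j, ] <- X[idx, ]
    d2 <- pmin(d2, .dist2(X, centers[j, , drop = FALSE], xs2)[, 1])
  }
  centers
}

.lloyd <- function(X, centers, xs2, max_iter = 100L) {
  k <- nrow(centers)
  assign_prev <- integer(nrow(X))
  for (it in seq_len(max_iter)) {
    d2 <- .dist2(X, centers, xs2)
    assign_cur <- max.col(-d2, ties.method = "first")
    # empty-cluster repair: seed each empty cluster with the point currently
    # farthest from its own center
    repeat {
      sizes <- tabulate(assign_cur, nbins = k)
      empty <- which(sizes == 0L)
      if (length(empty) == 0L) break
      far <- which.max(d2[cbind(seq_len(nrow(X)), assign_cur)])
      assign_cur[far] <- empty[1]
      centers[empty[1], ] <- X[far, ]
      d2[, empty[1]] <- .dist2(X, centers[empty[1], , drop = FALSE], xs2)[, 1]
    }
    for (j in seq_len(k))
      centers[j, ] <- colMeans(X[assign_cur == j, , drop = FALSE])
    if (identical(assign_cur, assign_prev)) break
    assign_prev <- assign_cur
  }
  d2 <- .dist2(X, centers, xs2)
  assign_cur <- max.col(-d2, ties.method = "first")
  inertia <- sum(d2[cbind(seq_len(nrow(X)), assign_cur)])
  list(assignment = assign_cur, centers = centers, inertia = inertia)
}

#' K-means segmentation of an MSI dataset
#'
#' Features are the per-pixel intensities at the picked peak channels of a
#' normalized dataset (no further scaling). Lloyd iterations from k-means++
#' starts, best of `n_restarts` by inertia; empty clusters are repaired by
#' reassigning the farthest point. Pixels are processed in canonical (y, x)
#' order, so the result is invariant to pixel enumeration order, and the
#' whole procedure is deterministic given `seed`.
#'
#' @param dataset A normalized `msi_dataset`.
#' @param peaks A `peak_table` defining the feature channels.
#' @param k Number of clusters (>= 2; default 10).
#' @param seed RNG seed recorded in the result.
#' @param n_restarts Number of k-means++ restarts (default 10).
#' @param tol_ppm Ion-image window for the feature channels (defaults to the
#'   peak table's centroiding window).
#' @return A `segmentation_result`: `cluster` (1..k per pixel, dataset
#'   order), `k`, `inertia`, `seed`, `centers`, `coords`.
#' @export
kmeans_segment <- function(dataset, peaks, k = 10, seed = 1, n_restarts = 10,
                           tol_ppm = NULL) {
  stopifnot(inherits(dataset, "msi_dataset"), inherits(peaks, "peak_table"))
  if (k < 2) stop("k must be >= 2")
  if (n_pixels(dataset) < k) stop("fewer pixels than clusters")
  if (nrow(peaks) == 0L) stop("no peaks to use as features")
  if (is.null(tol_ppm)) {
    tol_ppm <- attr(peaks, "params")$window_ppm
    if (is.null(tol_ppm) || is.na(tol_ppm)) tol_ppm <- 10
  }
  X <- .ion_matrix(dataset, peaks$centroid_mz, tol_ppm)
  ord <- order(dataset$coords$y, dataset$coords$x)
  Xc <- X[ord, , drop = FALSE]
  xs2 <- rowSums(Xc^2)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- with_local_seed(seed + r - 1L, {
      centers <- .kmeanspp_init(Xc, k, xs2)
      .lloyd(Xc, centers, xs2)
    })
    if (is.null(best) || fit$inertia < best$inertia) best <- fit
  }
  cluster <- integer(n_pixels(dataset))
  cluster[ord] <- best$assignment
  structure(list(cluster = cluster, k = as.integer(k),
                 inertia = best$inertia, seed = seed,
                 centers = best$centers, coords = dataset$coords),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result> k=%d, %d pixels, inertia %.4g, seed %d\n",
              x$k, length(x$cluster), x$inertia, x$seed))
  invisible(x)
}

#' Relabel clusters as anatomical ROIs
#'
#' @param segmentation A `segmentation_result`.
#' @param mapping Named character vector: names = cluster ids, values =
#'   labels from [roi_labels()]. Clusters absent from `mapping` become
#'   `"background"`; names not matching any cluster id are an error.
#' @return An `roi_mask` on the segmentation's pixel grid.
#' @export
clusters_to_roi <- function(segmentation, mapping) {
  stopifnot(inherits(segmentation, "segmentation_result"))
  ids <- as.integer(names(mapping))
  if (any(is.na(ids)) || any(!ids %in% seq_len(segmentation$k)))
    stop("mapping references unknown cluster ids")
  bad <- setdiff(unique(mapping), roi_labels())
  if (length(bad)) stop("mapping uses unknown labels: ", paste(bad, collapse = ", "))
  full <- rep("background", segmentation$k)
  full[ids] <- unname(mapping)
  labels <- full[segmentation$cluster]
  m <- matrix(NA_character_,
              nrow = max(segmentation$coords$y),
              ncol = max(segmentation$coords$x))
  m[cbind(segmentation$coords$y, segmentation$coords$x)] <- labels
  roi_mask(m)
}

#' Majority-vote cluster-to-tissue mapping
#'
#' Assigns each cluster the most frequent true label among its pixels
#' (ties broken by label order of [roi_labels()]). This automates the manual
#' step of collapsing k clusters onto anatomical regions when a reference
#' mask is available.
#'
#' @param segmentation A `segmentation_result`.
#' @param reference An `roi_mask` with the reference labels.
#' @return Named character vector usable as `mapping` in [clusters_to_roi()].
#' @export
majority_vote_mapping <- function(segmentation, reference) {
  ref <- unclass(reference)[cbind(segmentation$coords$y, segmentation$coords$x)]
  out <- character(0)
  for (cl in sort(unique(segmentation$cluster))) {
    tab <- table(factor(ref[segmentation$cluster == cl], levels = roi_labels()))
    out[as.character(cl)] <- names(tab)[which.max(tab)]
  }
  out
}
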