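#' Construct an MSI dataset
#'
#' The canonical in-memory form is "processed-like": one m/z vector and one
#' intensity vector per pixel. Continuous-mode data (a shared axis) are stored
#' the same way with `shared_axis = TRUE`. Pixels absent from a
#' non-rectangular acquisition are simply not listed; they are rendered as
#' `NA` in ion images and excluded from statistics, never zero-filled.
#'
#' @param coords data.frame with integer columns `x`, `y` (1-based grid).
#' @param mz_list List of strictly ascending numeric m/z vectors, one per pixel.
#' @param int_list List of non-negative intensity vectors, same lengths.
#' @param polarity `"positive"` or `"negative"` (uniform per dataset).
#' @param pixel_size_um Pixel edge length in micrometres.
#' @param mz_range Numeric `c(lo, hi)` acquisition range.
#' @param shared_axis TRUE if all pixels share one m/z axis (continuous mode).
#' @return An object of class `msi_dataset`.
#' @export
msi_dataset <- function(coords, mz_list, int_list, polarity,
                        pixel_size_um = 50, mz_range = c(50, 1200),
                        shared_axis = FALSE) {
  polarity <- match.arg(polarity, c("positive", "negative"))
  stopifnot(is.data.frame(coords), all(c("x", "y") %in% names(coords)),
            length(mz_list) == nrow(coords), length(int_list) == nrow(coords))
  if (nrow(coords) == 0L) stop("empty dataset: no pixels")
  key <- paste(coords$x, coords$y)
  if (anyDuplicated(key)) stop("duplicate pixel coordinates")
  for (i in seq_along(mz_list)) {
    mzv <- mz_list[[i]]
    if (length(mzv) != length(int_list[[i]]))
      stop("pixel ", i, ": m/z and intensity lengths differ")
    if (is.unsorted(mzv, strictly = TRUE))
      stop("pixel ", i, ": m/z values not strictly ascending")
    if (length(int_list[[i]]) && any(int_list[[i]] < 0))
      stop("pixel ", i, ": negative intensities")
  }
  structure(list(
    coords = data.frame(x = as.integer(coords$x), y = as.integer(coords$y)),
    mz_list = mz_list, int_list = int_list,
    polarity = polarity, pixel_size_um = pixel_size_um,
    mz_range = as.numeric(mz_range), shared_axis = isTRUE(shared_axis),
    flags = list(), cache = new.env(parent = emptyenv())),
    class = "msi_dataset")
}

#' @export
print.msi_dataset <- function(x, ...) {
  cat(sprintf("<msi_dataset> %d pixels, %s mode axis, polarity %s, m/z %g-%g, %g um\n",
              n_pixels(x), if (x$shared_axis) "continuous" else "processed",
              x$polarity, x$mz_range[1], x$mz_range[2], x$pixel_size_um))
  invisible(x)
}

#' Number of pixels in a dataset
#' @param dataset An `msi_dataset`.
#' @export
n_pixels <- function(dataset) nrow(dataset$coords)

# Flattened channel view: all channels of all pixels, sorted by m/z.
# Built lazily, cached per dataset object.
.flatten <- function(dataset) {
  if (!is.null(dataset$cache$flat)) return(dataset$cache$flat)
  n <- lengths(dataset$mz_list)
  flat <- list(mz = unlist(dataset$mz_list, use.names = FALSE),
               intensity = unlist(dataset$int_list, use.names = FALSE),
               pixel = rep.int(seq_along(n), n))
  ord <- order(flat$mz)
  flat <- lapply(flat, `[`, ord)
  dataset$cache$flat <- flat
  flat
}

# Per-pixel windowed intensity sums for one or more target m/z values.
# Returns an n_pixels x length(targets) matrix.
.ion_matrix <- function(dataset, targets, tol_ppm) {
  if (tol_ppm <= 0) stop("tol_ppm must be > 0")
  flat <- .flatten(dataset)
  np <- n_pixels(dataset)
  out <- matrix(0, nrow = np, ncol = length(targets))
  for (j in seq_along(targets)) {
    t <- targets[j]
    lo <- t * (1 - tol_ppm * 1e-6)
    hi <- t * (1 + tol_ppm * 1e-6)
    i1 <- findInterval(lo, flat$mz, left.open = TRUE) + 1L
    i2 <- findInterval(hi, flat$mz)
    if (i2 >= i1) {
      idx <- i1:i2
      sums <- rowsum(flat$intensity[idx], flat$pixel[idx])
      out[as.integer(rownames(sums)), j] <- sums[, 1]
    }
  }
  out
}

#' Extract an ion image
#'
#' Per pixel, the summed intensity of all channels within `tol_ppm` of
#' `target_mz`. Pixels absent from the acquisition grid are `NA`.
#'
#' @param dataset An `msi_dataset`.
#' @param target_mz Target m/z, inside the dataset's `mz_range`.
#' @param tol_ppm Window half-width in ppm (> 0).
#' @return An `ion_image`: numeric matrix (rows = y, cols = x) with
#'   attributes `target_mz` and `tol_ppm`.
#' @export
ion_image <- function(dataset, target_mz, tol_ppm = 5) {
  stopifnot(inherits(dataset, "msi_dataset"))
  if (target_mz < dataset$mz_range[1] || target_mz > dataset$mz_range[2])
    stop("target_mz outside the dataset m/z range")
  vals <- .ion_matrix(dataset, target_mz, tol_ppm)[, 1]
  pixel_values_to_image(dataset, vals, target_mz = target_mz, tol_ppm = tol_ppm)
}

#' Arrange a per-pixel vector on the acquisition grid
#'
#' @param dataset An `msi_dataset`.
#' @param values Numeric vector, one value per pixel (dataset order).
#' @param target_mz,tol_ppm Optional provenance attributes.
#' @return Matrix (rows = y, cols = x); unacquired pixels are `NA`.
#' @export
pixel_values_to_image <- function(dataset, values, target_mz = NA_real_,
                                  tol_ppm = NA_real_) {
  stopifnot(length(values) == n_pixels(dataset))
  nx <- max(dataset$coords$x)
  ny <- max(dataset$coords$y)
  img <- matrix(NA_real_, nrow = ny, ncol = nx)
  img[cbind(dataset$coords$y, dataset$coords$x)] <- values
  structure(img, target_mz = target_mz, tol_ppm = tol_ppm,
            class = c("ion_image", "matrix", "array"))
}

#' @export
print.ion_image <- function(x, ...) {
  cat(sprintf("<ion_image> %dx%d at m/z %.4f (+/- %g ppm), max %.4g\n",
              ncol(x), nrow(x), attr(x, "target_mz"), attr(x, "tol_ppm"),
              suppressWarnings(max(x, na.rm = TRUE))))
  invisible(x)
}

#' Write an ion image (or any pixel matrix) as delimited text
#'
#' @param image Matrix, e.g. from [ion_image()].
#' @param path Output file.
#' @export
write_image_csv <- function(image, path) {
  utils::write.table(unclass(image), path, sep = ",", row.names = FALSE,
                     col.names = FALSE, na = "NA")
  invisible(path)
}
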