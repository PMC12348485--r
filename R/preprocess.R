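#' Root-mean-square normalization
#'
#' Divides each pixel's intensities by that spectrum's RMS
#' (sqrt(mean(intensity^2)) over its stored channels), the convention used by
#' imaging workstations to correct pixel-to-pixel ionization variability.
#' All-zero spectra are left unchanged and flagged.
#'
#' @param dataset An `msi_dataset`.
#' @return A normalized copy; `$flags$zero_spectra` lists untouched pixels,
#'   `$flags$normalized` is set to TRUE.
#' @export
rms_normalize <- function(dataset) {
  stopifnot(inherits(dataset, "msi_dataset"))
  rms <- vapply(dataset$int_list, function(v)
    if (length(v) == 0L) 0 else sqrt(mean(v^2)), numeric(1))
  zero <- which(rms == 0)
  out <- dataset
  out$int_list <- lapply(seq_along(rms), function(i)
    if (rms[i] > 0) dataset$int_list[[i]] / rms[i] else dataset$int_list[[i]])
  out$flags$normalized <- TRUE
  out$flags$zero_spectra <- zero
  out$cache <- new.env(parent = emptyenv())
  out
}

# Log-spaced common axis: consecutive bin edges differ by bin_ppm parts per
# million, so a fixed-ppm peak width occupies the same number of bins at any
# m/z (resolving-power-limited instruments behave this way).
.make_axis <- function(lo, hi, bin_ppm) {
  step <- log1p(bin_ppm * 1e-6)
  nbin <- ceiling(log(hi / lo) / step)
  lo * exp((seq_len(nbin) - 0.5) * step)
}

#' Dataset mean spectrum on a common axis
#'
#' Channels of every pixel are accumulated into log-spaced bins of width
#' `bin_ppm`; each bin holds the pixel-wise mean of its summed intensity.
#'
#' @param dataset An `msi_dataset` (normally RMS-normalized first).
#' @param bin_ppm Bin width in ppm (default 5).
#' @return A `mean_spectrum`: list with `mz` (bin centers), `intensity`,
#'   `bin_ppm`, `n_pixels`.
#' @export
mean_spectrum <- function(dataset, bin_ppm = 5) {
  stopifnot(inherits(dataset, "msi_dataset"))
  lo <- dataset$mz_range[1]; hi <- dataset$mz_range[2]
  centers <- .make_axis(lo, hi, bin_ppm)
  step <- log1p(bin_ppm * 1e-6)
  flat <- .flatten(dataset)
  y <- numeric(length(centers))
  if (length(flat$mz)) {
    bin <- pmin(pmax(floor(log(flat$mz / lo) / step) + 1L, 1L), length(centers))
    s <- rowsum(flat$intensity, bin)
    y[as.integer(rownames(s))] <- s[, 1] / n_pixels(dataset)
  }
  structure(list(mz = centers, intensity = y, bin_ppm = bin_ppm,
                 n_pixels = n_pixels(dataset)),
            class = "mean_spectrum")
}

#' @export
print.mean_spectrum <- function(x, ...) {
  cat(sprintf("<mean_spectrum> %d bins (%g ppm), %d pixels, %d non-empty\n",
              length(x$mz), x$bin_ppm, x$n_pixels, sum(x$intensity > 0)))
  invisible(x)
}

# Symmetric Gaussian goodness-of-fit of the mean-spectrum profile around an
# apex bin, as an R^2 in [0,1]. Fewer than 4 positive points carries no shape
# evidence and scores 1. A weighted log-quadratic fit (solved directly, no
# lm() overhead) stands in for nonlinear least squares; a non-negative
# curvature (no peak) scores 0.
.shape_r2 <- function(ms, apex_bin, extent_bins) {
  idx0 <- max(1L, apex_bin - extent_bins):min(length(ms$mz), apex_bin + extent_bins)
  # the peak region proper: points above 5% of the apex, so that a flat
  # noise floor far from the apex cannot dominate the quadratic's leverage
  idx <- idx0[ms$intensity[idx0] > 0.05 * ms$intensity[apex_bin]]
  y <- ms$intensity[idx]
  if (length(idx) < 4L) return(1)
  mz0 <- ms$mz[apex_bin]
  u <- (ms$mz[idx] / mz0 - 1) * 1e6
  X <- cbind(1, u, u^2)
  XtW <- t(X * y)
  beta <- tryCatch(solve(XtW %*% X, XtW %*% log(y)), error = function(e) NULL)
  if (is.null(beta) || !is.finite(beta[3]) || beta[3] >= 0) return(0)
  yhat <- exp(X %*% beta)
  ss_res <- sum((y - yhat)^2)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot <= 0) return(1)
  max(0, min(1, 1 - ss_res / ss_tot))
}

#' Pick peaks on a mean spectrum
#'
#' Local maxima with signal-to-noise >= `snr_min`, where noise is
#' 1.4826 x MAD of the mean spectrum (falling back to the MAD of strictly
#' positive bins when the spectrum is sparse enough that the plain MAD is 0).
#' The centroid is the intensity-weighted mean m/z within `+/- window_ppm` of
#' the apex; maxima closer than `window_ppm` to an already accepted (taller)
#' peak are merged into it. A symmetric-Gaussian goodness of fit (`shape_r2`)
#' is computed per peak over `4 x window_ppm` around the apex.
#'
#' @param ms A `mean_spectrum`.
#' @param snr_min Minimum signal-to-noise (default 3).
#' @param window_ppm Centroiding/merge half-window in ppm (default 10).
#' @param dataset Optional `msi_dataset`; when given, per-pixel windowed sums
#'   supply `mean_intensity` and `max_intensity` (otherwise the mean-spectrum
#'   window sum is used and `max_intensity` is `NA`).
#' @return A `peak_table` data.frame: `centroid_mz`, `mean_intensity`,
#'   `max_intensity`, `shape_r2`, sorted by `centroid_mz`.
#' @export
pick_peaks <- function(ms, snr_min = 3, window_ppm = 10, dataset = NULL) {
  stopifnot(inherits(ms, "mean_spectrum"))
  y <- ms$intensity
  n <- length(y)
  if (n == 0L) stop("empty mean spectrum")
  # noise floor: 1.4826 x MAD of the mean spectrum; on sparse axes (majority
  # of bins empty) this is 0, and the MAD of the occupied bins is used
  # instead -- but only when occupied bins are frequent enough (> 25% of the
  # axis) to constitute a noise floor rather than isolated signal. An almost
  # empty axis has no measurable noise and SNR filtering is vacuous.
  noise <- stats::mad(y)
  if (noise == 0) {
    pos <- y[y > 0]
    noise <- if (length(pos) > 0.25 * n) stats::mad(pos) else 0
  }
  if (!is.finite(noise)) noise <- 0
  is_max <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n], FALSE)
  cand <- if (noise > 0) which(is_max & y >= snr_min * noise) else which(is_max & y > 0)
  if (length(cand) == 0L)
    return(.empty_peak_table(snr_min, window_ppm, ms$bin_ppm))
  # non-maximum suppression on the log-spaced axis: k bins apart means
  # k * bin_ppm ppm apart, so the ppm merge radius is exact in bin units
  rad <- max(1L, floor(window_ppm / ms$bin_ppm))
  cand <- cand[order(-y[cand], ms$mz[cand])]
  blocked <- logical(n)
  accepted <- integer(0)
  for (b in cand) {
    if (blocked[b]) next
    accepted <- c(accepted, b)
    blocked[max(1L, b - rad):min(n, b + rad)] <- TRUE
  }
  centroid <- numeric(length(accepted))
  win_sum <- numeric(length(accepted))
  r2 <- numeric(length(accepted))
  for (k in seq_along(accepted)) {
    b <- accepted[k]
    idx <- max(1L, b - rad):min(n, b + rad)
    w <- ms$intensity[idx]
    centroid[k] <- sum(ms$mz[idx] * w) / sum(w)
    win_sum[k] <- sum(w)
    r2[k] <- .shape_r2(ms, b, 4L * rad)
  }
  mean_int <- win_sum
  max_int <- rep(NA_real_, length(accepted))
  if (!is.null(dataset)) {
    pix <- .ion_matrix(dataset, centroid, window_ppm)
    mean_int <- colMeans(pix)
    max_int <- apply(pix, 2, max)
  }
  tb <- data.frame(centroid_mz = centroid, mean_intensity = mean_int,
                   max_intensity = max_int, shape_r2 = r2)
  tb <- tb[order(tb$centroid_mz), , drop = FALSE]
  rownames(tb) <- NULL
  attr(tb, "params") <- list(snr_min = snr_min, window_ppm = window_ppm,
                             bin_ppm = ms$bin_ppm)
  class(tb) <- c("peak_table", "data.frame")
  tb
}

.empty_peak_table <- function(snr_min = NA, window_ppm = NA, bin_ppm = NA) {
  tb <- data.frame(centroid_mz = numeric(0), mean_intensity = numeric(0),
                   max_intensity = numeric(0), shape_r2 = numeric(0))
  attr(tb, "params") <- list(snr_min = snr_min, window_ppm = window_ppm,
                             bin_ppm = bin_ppm)
  class(tb) <- c("peak_table", "data.frame")
  tb
}

#' Keep the N most intense peaks
#'
#' Selects the `min(n, nrow)` entries with the largest `mean_intensity`
#' (ties broken toward lower m/z) and re-sorts the result by m/z.
#'
#' @param peaks A `peak_table`.
#' @param n Number of peaks to keep (default 1020, applied once per
#'   polarity dataset).
#' @return A `peak_table`.
#' @export
select_top_n <- function(peaks, n = 1020) {
  stopifnot(inherits(peaks, "peak_table"), n >= 1)
  if (nrow(peaks) <= n) return(peaks)
  ord <- order(-peaks$mean_intensity, peaks$centroid_mz)
  keep <- sort(ord[seq_len(n)])
  out <- peaks[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "params") <- c(attr(peaks, "params"), list(top_n = n))
  class(out) <- c("peak_table", "data.frame")
  out
}

#' Export / import a peak table as CSV
#' @param peaks A `peak_table`.
#' @param path CSV file path.
#' @export
write_peak_table <- function(peaks, path) {
  utils::write.csv(as.data.frame(peaks)[, c("centroid_mz", "mean_intensity",
                                            "max_intensity", "shape_r2")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_peak_table
#' @export
read_peak_table <- function(path) {
  tb <- utils::read.csv(path)
  class(tb) <- c("peak_table", "data.frame")
  tb
}
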