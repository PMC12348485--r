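# Shared fixtures. Phantom renders and pipeline runs are expensive, so they
# are built once per test session and memoised here.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

phantom_cfg <- function(polarity = "positive", noiseless = FALSE, seed = 42, ...) {
  if (noiseless)
    phantom_config(polarity = polarity, seed = seed, sigma_ppm = 0,
                   sigma_int = 0, baseline_mean = 0, baseline_channels = 0, ...)
  else phantom_config(polarity = polarity, seed = seed, ...)
}

get_phantom <- function(polarity = "positive", noiseless = FALSE, seed = 42, ...) {
  key <- paste("phantom", polarity, noiseless, seed)
  memo(key, function() render_phantom(phantom_cfg(polarity, noiseless, seed, ...)))
}

# full annotation pipeline on a cached phantom, default parameters
get_annotated <- function(polarity = "positive", noiseless = FALSE, seed = 42) {
  key <- paste("annotated", polarity, noiseless, seed)
  memo(key, function() {
    ph <- get_phantom(polarity, noiseless, seed)
    norm <- rms_normalize(ph$dataset)
    ms <- mean_spectrum(norm)
    peaks <- select_top_n(pick_peaks(ms))
    index <- build_ion_index(minilib(), default_adducts(polarity),
                             ph$dataset$mz_range)
    ann <- match_peaks(peaks, index, tol_ppm = 5)
    ann <- blank_filter(ann, norm, ph$manifest$geometry, tau = 0.5)
    ann <- shape_filter(ann, r2_min = 0.8)
    list(phantom = ph, norm = norm, ms = ms, peaks = peaks, index = index,
         annotation = ann)
  })
}

# tiny processed-mode dataset on an ngrid x ngrid grid with the given channel
# lists (defaults to two channels everywhere)
toy_dataset <- function(nx = 3, ny = 2, polarity = "positive",
                        mz = c(100, 200), int = c(1, 2)) {
  coords <- expand.grid(x = seq_len(nx), y = seq_len(ny))
  msi_dataset(coords,
              mz_list = rep(list(mz), nrow(coords)),
              int_list = rep(list(int), nrow(coords)),
              polarity = polarity, mz_range = c(50, 1200))
}

# random compound library for property tests
random_library <- function(n, seed) {
  with_seed(seed, {
    f <- sprintf("C%dH%dN%dO%d", sample(5:40, n, TRUE), sample(5:60, n, TRUE),
                 sample(1:4, n, TRUE), sample(1:15, n, TRUE))
    df <- data.frame(compound_id = sprintf("cmpd%03d", seq_len(n)),
                     name = sprintf("Compound %d", seq_len(n)),
                     formula = f, class = sample(c("alkaloid", "flavonoid",
                                                   "other"), n, TRUE),
                     stringsAsFactors = FALSE)
    path <- tempfile(fileext = ".csv")
    utils::write.csv(df, path, row.names = FALSE)
    read_compound_library(path)
  })
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# IUPAC monoisotopic masses, duplicated here so mass tests have a reference
# independent of the package internals
REF_MASS <- c(C = 12, H = 1.00782503, N = 14.00307401, O = 15.99491462,
              S = 31.97207069, P = 30.97376151, Na = 22.98976928,
              K = 38.96370649, Cl = 34.96885268)
REF_ELECTRON <- 0.00054858
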