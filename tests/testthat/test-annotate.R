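make_peak_table <- function(mz, r2 = 1) {
  structure(data.frame(centroid_mz = mz, mean_intensity = 1,
                       max_intensity = NA_real_, shape_r2 = r2),
            class = c("peak_table", "data.frame"))
}

neg_index <- build_ion_index(minilib(), default_adducts("negative"), c(50, 1200))

test_that("match_peaks finds rutin within 1 ppm and respects the tolerance", {
  ann <- match_peaks(make_peak_table(609.1461), neg_index, tol_ppm = 5)
  hit <- ann[!is.na(ann$compound_id), ]
  expect_true("rutin" %in% hit$compound_id)
  expect_lt(min(abs(hit$ppm_error[hit$compound_id == "rutin"])), 1)

  # 10 ppm away with a 5 ppm tolerance: unidentified but retained
  far <- match_peaks(make_peak_table(609.1461 * (1 + 10e-6)), neg_index, 5)
  expect_true(all(is.na(far$compound_id[far$centroid_mz > 600])))
  expect_equal(nrow(far), 1L)
})

test_that("match_peaks equals the brute-force all-pairs oracle", {
  adducts <- default_adducts("both")
  n_instances <- 100
  with_seed(31, {
    for (i in seq_len(n_instances)) {
      lib <- random_library(sample(5:25, 1), seed = 1000 + i)
      idx <- build_ion_index(lib, adducts, c(50, 1200))
      tol <- runif(1, 1, 20)
      # peaks partly near real candidates, partly random
      near <- sample(idx$theoretical_mz, min(5, nrow(idx))) *
        (1 + runif(5, -2, 2) * tol * 1e-6)
      peaks <- make_peak_table(sort(c(near, runif(5, 50, 1200))))
      got <- match_peaks(peaks, idx, tol)
      got_hits <- got[!is.na(got$compound_id), ]
      # oracle: scan every (peak, candidate) pair
      exp_keys <- character(0)
      for (p in peaks$centroid_mz) for (j in seq_len(nrow(idx))) {
        ppm <- (p - idx$theoretical_mz[j]) / idx$theoretical_mz[j] * 1e6
        if (abs(ppm) <= tol)
          exp_keys <- c(exp_keys, paste(p, idx$compound_id[j],
                                        idx$adduct_label[j]))
      }
      got_keys <- paste(got_hits$centroid_mz, got_hits$compound_id,
                        got_hits$adduct_label)
      expect_setequal(got_keys, exp_keys)
    }
  })
})

test_that("hits are ranked by |ppm| then compound id, isomers grouped", {
  # the three C18H21NO3 isomers share one theoretical m/z
  pos_index <- build_ion_index(minilib(), default_adducts("positive"), c(50, 1200))
  mz <- adduct_mz(monoisotopic_mass("C18H21NO3"), default_adducts("positive")[[1]])
  ann <- match_peaks(make_peak_table(mz), pos_index, 5)
  hits <- ann[!is.na(ann$compound_id), ]
  expect_setequal(hits$compound_id,
                  c("n_norarmepavine", "n_methylisococlaurine", "n_methylcoclaurine"))
  expect_true(all(hits$is_isomer_group))
  expect_equal(hits$compound_id, sort(hits$compound_id))  # tie -> id order
})

test_that("enlarging tol_ppm never removes a hit", {
  peaks <- make_peak_table(c(151.0405, 289.0710, 609.1480))
  prev <- 0
  for (tol in c(1, 3, 5, 10, 30)) {
    ann <- match_peaks(peaks, neg_index, tol)
    n <- sum(!is.na(ann$compound_id))
    expect_gte(n, prev)
    prev <- n
  }
})

# toy two-zone dataset: left half "tissue", right half blank; ion A on tissue
# only, ion B uniform everywhere
blank_fixture <- function() {
  coords <- expand.grid(x = 1:4, y = 1:2)
  tissue <- coords$x <= 2
  mkpix <- function(i) {
    if (tissue[i]) list(mz = c(100, 200), int = c(10, 5))
    else list(mz = c(200), int = c(5))
  }
  px <- lapply(seq_len(nrow(coords)), mkpix)
  d <- msi_dataset(coords, lapply(px, `[[`, "mz"), lapply(px, `[[`, "int"),
                   "positive", mz_range = c(50, 1200))
  mask <- matrix("background", 2, 4)
  mask[, 1:2] <- "cotyledon"
  list(dataset = d, mask = roi_mask(mask))
}

fake_annotation <- function(mz, compound = "c1") {
  structure(data.frame(centroid_mz = mz, compound_id = compound,
                       name = compound, class = "other", adduct_label = "[M+H]+",
                       theoretical_mz = mz, ppm_error = 0, shape_r2 = 1,
                       blank_ratio = NA_real_, is_isomer_group = FALSE,
                       excluded = "none", stringsAsFactors = FALSE),
            tol_ppm = 5, class = c("annotation_table", "data.frame"))
}

test_that("blank_filter excludes by blank/tissue intensity ratio", {
  fx <- blank_fixture()
  ann <- fake_annotation(c(100, 200), c("tissue_ion", "matrix_ion"))
  out <- blank_filter(ann, fx$dataset, fx$mask, tau = 0.5)
  expect_equal(out$excluded[out$compound_id == "tissue_ion"], "none")
  expect_equal(out$blank_ratio[out$compound_id == "tissue_ion"], 0)
  expect_equal(out$excluded[out$compound_id == "matrix_ion"], "blank")
  expect_gte(out$blank_ratio[out$compound_id == "matrix_ion"], 0.5)

  # tau = Inf excludes nothing
  out2 <- blank_filter(ann, fx$dataset, fx$mask, tau = Inf)
  expect_true(all(out2$excluded == "none"))

  # raising tau excludes a subset of what a lower tau excludes
  for (tau_pair in list(c(0.2, 0.5), c(0.5, 2))) {
    lo <- blank_filter(ann, fx$dataset, fx$mask, tau = tau_pair[1])
    hi <- blank_filter(ann, fx$dataset, fx$mask, tau = tau_pair[2])
    expect_true(all(which(hi$excluded == "blank") %in%
                      which(lo$excluded == "blank")))
  }

  # empty blank mask: skipped with a warning
  allt <- roi_mask(matrix("cotyledon", 2, 4))
  expect_warning(out3 <- blank_filter(ann, fx$dataset, allt, 0.5), "skipped")
  expect_true(all(out3$excluded == "none"))
})

test_that("blank_filter excludes ions absent from tissue (x/0 and 0/0)", {
  fx <- blank_fixture()
  # ion at 300 exists nowhere -> 0/0 -> excluded
  ann <- fake_annotation(300, "ghost")
  out <- blank_filter(ann, fx$dataset, fx$mask, tau = 0.5)
  expect_equal(out$excluded, "blank")
})

test_that("shape_filter excludes low-r2 peaks", {
  ann <- fake_annotation(c(100, 200), c("good", "bad"))
  ann$shape_r2 <- c(0.95, 0.42)
  out <- shape_filter(ann, r2_min = 0.8)
  expect_equal(out$excluded, c("none", "shape"))
  out0 <- shape_filter(ann, r2_min = 0)
  expect_true(all(out0$excluded == "none"))
})

test_that("summarize_annotations dedups adducts and reports undetected", {
  ann <- fake_annotation(c(100, 150), c("c1", "c1"))   # two adducts, one compound
  ann$adduct_label <- c("[M+H]+", "[M+Na]+")
  s <- summarize_annotations(ann)
  expect_equal(s$n_compounds, 1L)
  expect_equal(unname(s$class_counts["other"]), 1L)

  empty <- ann[0, ]
  class(empty) <- c("annotation_table", "data.frame")
  s0 <- summarize_annotations(empty)
  expect_equal(s0$n_compounds, 0L)
  expect_equal(s0$n_peaks, 0L)

  lib <- minilib()
  s2 <- summarize_annotations(ann, lib)
  expect_true(all(c("liensinine", "neferine") %in% s2$undetected))
})

test_that("annotation report CSV has the documented columns", {
  ann <- fake_annotation(100)
  path <- tempfile(fileext = ".csv")
  write_annotation_csv(ann, path)
  got <- utils::read.csv(path)
  expect_named(got, c("centroid_mz", "compound_id", "name", "class",
                      "adduct_label", "ppm_error", "blank_ratio", "shape_r2",
                      "excluded"))
})
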