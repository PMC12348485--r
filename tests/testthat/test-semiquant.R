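# 4x2 grid split into four single-column "tissues" plus background row
quad_fixture <- function(int_by_col = list(c(10, 0), c(10, 0), c(10, 0),
                                           c(10, 0))) {
  coords <- expand.grid(x = 1:4, y = 1:2)
  mz <- c(100, 200)
  int_list <- lapply(seq_len(nrow(coords)), function(i) {
    if (coords$y[i] == 2) c(0.0, 0.0) else int_by_col[[coords$x[i]]]
  })
  d <- msi_dataset(coords, rep(list(mz), nrow(coords)), int_list, "positive",
                   mz_range = c(50, 1200))
  m <- matrix("background", 2, 4)
  m[1, ] <- c("pericarp", "seed_coat", "cotyledon", "plumule")
  list(dataset = d, roi = roi_mask(m))
}

ann_for <- function(mz, compounds, classes = "other") {
  structure(data.frame(centroid_mz = mz, compound_id = compounds,
                       name = compounds, class = classes,
                       adduct_label = "[M+H]+", theoretical_mz = mz,
                       ppm_error = 0, shape_r2 = 1, blank_ratio = NA_real_,
                       is_isomer_group = FALSE, excluded = "none",
                       stringsAsFactors = FALSE),
            tol_ppm = 5, class = c("annotation_table", "data.frame"))
}

test_that("roi_intensity_table: uniform ion has identical tissue means", {
  fx <- quad_fixture()
  tt <- roi_intensity_table(fx$dataset, ann_for(100, "u"), fx$roi)
  expect_equal(unname(tt$intensity["u", .tissue <- c("pericarp", "seed_coat",
                                                     "cotyledon", "plumule")]),
               rep(10, 4))
  expect_equal(unname(tt$intensity["u", "background"]), 0)
})

test_that("roi_intensity_table: 1-pixel tissue mean is that pixel's value", {
  fx <- quad_fixture(list(c(10, 0), c(4, 0), c(0, 0), c(0, 0)))
  tt <- roi_intensity_table(fx$dataset, ann_for(100, "a"), fx$roi)
  expect_equal(unname(tt$intensity["a", "seed_coat"]), 4)
  expect_equal(unname(tt$intensity["a", "cotyledon"]), 0)
})

test_that("empty tissue yields an NA column with a warning", {
  fx <- quad_fixture()
  m <- unclass(fx$roi)
  m[m == "plumule"] <- "cotyledon"
  expect_warning(tt <- roi_intensity_table(fx$dataset, ann_for(100, "a"),
                                           roi_mask(m)), "plumule")
  expect_true(is.na(tt$intensity["a", "plumule"]))
})

test_that("presence_calls implements the beta/gamma rule", {
  fx <- quad_fixture(list(c(10, 0), c(10, 0), c(0, 0), c(0.5, 0)))
  tt <- roi_intensity_table(fx$dataset, ann_for(100, "a"), fx$roi)
  p <- presence_calls(tt, beta = 0.10, gamma = 3)$presence
  expect_equal(unname(p["a", ]), c(TRUE, TRUE, FALSE, FALSE))  # 0.5 < 0.1*10
  # beta = 0, gamma = 0: present wherever > 0
  p0 <- presence_calls(tt, 0, 0)$presence
  expect_equal(unname(p0["a", ]), c(TRUE, TRUE, FALSE, TRUE))
  # all-zero row is absent everywhere even at zero thresholds
  tt0 <- roi_intensity_table(fx$dataset, ann_for(200, "z"), fx$roi)
  expect_false(any(presence_calls(tt0, 0, 0)$presence["z", ]))
})

test_that("per-tissue counts are monotone non-increasing in beta and gamma", {
  ph <- get_annotated("positive")
  tt <- roi_intensity_table(ph$norm, ph$annotation,
                            ph$phantom$manifest$geometry)
  prev <- NULL
  for (beta in c(0, 0.05, 0.1, 0.3, 0.9)) {
    counts <- tissue_counts(presence_calls(tt, beta = beta, gamma = 3))
    if (!is.null(prev)) expect_true(all(counts$per_tissue <= prev))
    prev <- counts$per_tissue
  }
  prev <- NULL
  for (gamma in c(0, 1, 3, 10, 1000)) {
    counts <- tissue_counts(presence_calls(tt, beta = 0.1, gamma = gamma))
    if (!is.null(prev)) expect_true(all(counts$per_tissue <= prev))
    prev <- counts$per_tissue
  }
})

test_that("tissue_counts tallies presence and class composition", {
  pres <- matrix(c(TRUE, TRUE, FALSE, FALSE,
                   TRUE, FALSE, FALSE, FALSE,
                   FALSE, FALSE, FALSE, FALSE), nrow = 3, byrow = TRUE,
                 dimnames = list(c("a", "b", "c"),
                                 c("pericarp", "seed_coat", "cotyledon",
                                   "plumule")))
  tc <- tissue_counts(pres, classes = c("alkaloid", "flavonoid", "alkaloid"))
  expect_equal(unname(tc$per_tissue), c(2, 1, 0, 0))
  expect_equal(tc$n_distinct, 2L)
  expect_equal(unname(tc$class_by_tissue["alkaloid", "pericarp"]), 1)
  # a compound present in all four tissues adds 1 to each and 1 to distinct
  pres["c", ] <- TRUE
  tc2 <- tissue_counts(pres, classes = c("alkaloid", "flavonoid", "alkaloid"))
  expect_equal(unname(tc2$per_tissue), c(3, 2, 1, 1))
  expect_equal(tc2$n_distinct, 3L)
  # empty presence
  tc0 <- tissue_counts(pres[0, , drop = FALSE], classes = character(0))
  expect_equal(unname(tc0$per_tissue), rep(0, 4))
  expect_equal(tc0$n_distinct, 0L)
})

test_that("heatmap_matrix row-scales to [0,1], idempotently, ordered by class then m/z", {
  fx <- quad_fixture(list(c(8, 2), c(8, 2), c(8, 2), c(8, 2)))
  ann <- ann_for(c(100, 200), c("b_cmpd", "a_cmpd"), c("zclass", "aclass"))
  tt <- roi_intensity_table(fx$dataset, ann, fx$roi)
  hm <- heatmap_matrix(tt)
  expect_equal(rownames(hm), c("a_cmpd", "b_cmpd"))   # class order
  expect_true(all(hm >= 0 & hm <= 1))
  expect_equal(unname(apply(hm, 1, max)), c(1, 1))    # constant rows -> 1
  # zero row stays zero
  tt$intensity["a_cmpd", ] <- 0
  hm0 <- heatmap_matrix(tt)
  expect_true(all(hm0["a_cmpd", ] == 0))
  # scaling twice = scaling once
  tt2 <- tt; tt2$intensity[, colnames(hm)] <- 0
  tt2$intensity[rownames(hm), colnames(hm)] <- unclass(hm)
  expect_equal(unclass(heatmap_matrix(tt2)), unclass(hm))
})

test_that("permuting tissue labels permutes table columns equivariantly", {
  fx <- quad_fixture(list(c(10, 1), c(7, 2), c(5, 3), c(2, 4)))
  ann <- ann_for(c(100, 200), c("a", "b"))
  tt <- roi_intensity_table(fx$dataset, ann, fx$roi)
  # swap pericarp and plumule masks
  m <- unclass(fx$roi)
  m[m == "pericarp"] <- "tmp"; m[m == "plumule"] <- "pericarp"
  m[m == "tmp"] <- "plumule"
  tt2 <- roi_intensity_table(fx$dataset, ann, roi_mask(m))
  expect_equal(tt2$intensity[, "pericarp"], tt$intensity[, "plumule"])
  expect_equal(tt2$intensity[, "plumule"], tt$intensity[, "pericarp"])
  expect_equal(tt2$intensity[, "seed_coat"], tt$intensity[, "seed_coat"])
})

test_that("tissue table exports are written", {
  fx <- quad_fixture()
  tt <- presence_calls(roi_intensity_table(fx$dataset, ann_for(100, "a"),
                                           fx$roi))
  dir <- tempfile()
  paths <- write_tissue_tables(tt, dir)
  expect_true(all(file.exists(file.path(dir, c("tissue_intensity.csv",
                                               "tissue_presence.csv",
                                               "heatmap_matrix.csv")))))
})
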