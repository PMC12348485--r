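test_that("parse_formula reads element tokens with implicit counts", {
  expect_equal(unclass(parse_formula("C27H30O16"))[c("C", "H", "O")],
               c(C = 27L, H = 30L, O = 16L))
  expect_equal(unclass(parse_formula("H2O"))[c("H", "O")], c(H = 2L, O = 1L))
  expect_equal(unclass(parse_formula("C6H14N4O2"))[c("C", "H", "N", "O")],
               c(C = 6L, H = 14L, N = 4L, O = 2L))
  # element order is free; repeated elements accumulate
  expect_equal(monoisotopic_mass("O2C3"), monoisotopic_mass("C3O2"))
  expect_equal(unclass(parse_formula("CHC"))[["C"]], 2L)
})

test_that("parse_formula rejects malformed input by naming the token", {
  expect_error(parse_formula("C2X5"), "unsupported element 'X'")
  expect_error(parse_formula("C0H2"), "zero count for element 'C'")
  expect_error(parse_formula("12CH4"), "malformed")
  expect_error(parse_formula(""), "non-empty")
  expect_error(parse_formula("C2 H4"), "malformed")
})

test_that("monoisotopic_mass sums the fixed atomic mass table", {
  # frozen from an independent per-atom summation with the IUPAC table
  expect_equal(round(monoisotopic_mass("C27H30O16"), 4), 610.1534)
  expect_equal(round(monoisotopic_mass("H2O"), 4), 18.0106)
  expect_equal(monoisotopic_mass(null_formula()), 0)
  # cross-check against the independent reference table on random formulas
  with_seed(7, for (i in 1:25) {
    cnt <- c(C = sample(1:50, 1), H = sample(1:80, 1), N = sample(1:6, 1),
             O = sample(1:20, 1), S = sample(1:3, 1))
    f <- paste0(names(cnt), cnt, collapse = "")
    expect_equal(monoisotopic_mass(f), sum(REF_MASS[names(cnt)] * cnt),
                 tolerance = 1e-12)
  })
})

test_that("mass is additive over formula concatenation", {
  with_seed(11, for (i in 1:20) {
    f1 <- sprintf("C%dH%dO%d", sample(1:30, 1), sample(1:40, 1), sample(1:10, 1))
    f2 <- sprintf("N%dS%dP%d", sample(1:5, 1), sample(1:3, 1), sample(1:3, 1))
    expect_equal(monoisotopic_mass(paste0(f1, f2)),
                 monoisotopic_mass(f1) + monoisotopic_mass(f2),
                 tolerance = 1e-9)
  })
})

adducts <- default_adducts("both")
names(adducts) <- vapply(adducts, `[[`, character(1), "label")

test_that("adduct_mz reproduces printed reference masses at 4 decimals", {
  cases <- list(  # compound, formula, adduct, printed m/z
    list("armepavine", "C19H23NO3", "[M+H]+", 314.1751),
    list("rutin", "C27H30O16", "[M-H]-", 609.1461),
    list("oleic acid", "C18H34O2", "[M-H]-", 281.2486),
    list("linolenic acid", "C18H30O2", "[M-H]-", 277.2173),
    list("anisic acid", "C8H8O3", "[M-H]-", 151.0401),
    list("myricetin 3-O-glucoside", "C21H20O13", "[M-H]-", 479.0831),
    list("pronuciferine", "C19H21NO3", "[M+HCOO]-", 356.1503),
    list("luteolin 7-O-rutinoside", "C27H30O15", "[M-H]-", 593.1512),
    list("schaftoside", "C26H28O14", "[M-H]-", 563.1406),
    list("syringetin 3-O-glucoside", "C23H24O13", "[M-H]-", 507.1144)
  )
  for (cs in cases) {
    mz <- adduct_mz(monoisotopic_mass(cs[[2]]), adducts[[cs[[3]]]])
    expect_equal(round(mz, 4), cs[[4]], info = cs[[1]])
  }
})

test_that("observed reference masses with experimental offsets stay within 4 ppm", {
  # these printed values are observed (not theoretical) masses; the library
  # formula + default adduct set must still land within instrument accuracy
  cases <- list(
    list("C15H14O6", "[M+K]+", 329.0428),    # catechin, positive mode
    list("C21H20O10", "[M+HCOO]-", 477.1039), # vitexin
    list("C6H14N4O2", "[M+H]+", 175.1195),   # arginine
    list("C10H17N3O6S", "[M+Na]+", 330.0736), # glutathione
    list("C55H74N4O5", "[M+H]+", 871.5737)   # pheophytin A
  )
  for (cs in cases) {
    mz <- adduct_mz(monoisotopic_mass(cs[[1]]), adducts[[cs[[2]]]])
    expect_lt(abs(cs[[3]] - mz) / mz * 1e6, 4)
  }
})

test_that("adduct_mz handles the zero-mass and error edge cases", {
  expect_equal(round(adduct_mz(0, adducts[["[M+H]+"]]), 4), 1.0073)
  expect_error(adduct_spec("[M+H]+", "negative", atoms_added = "H", charge = 1),
               "inconsistent")
  expect_error(adduct_spec("[M+2H]2+", "positive", atoms_added = "H2", charge = 2),
               "singly charged")
})

test_that("neutral_mass_from_mz inverts adduct_mz", {
  expect_equal(round(neutral_mass_from_mz(609.1461, adducts[["[M-H]-"]]), 4),
               610.1534)
  for (M in c(50, 174.1117, 610.1534, 1199)) {
    for (a in adducts) {
      expect_equal(neutral_mass_from_mz(adduct_mz(M, a), a), M,
                   tolerance = 1e-9 / M)
    }
  }
  expect_error(neutral_mass_from_mz(0.9, adducts[["[M+H]+"]]), "negative")
  expect_error(neutral_mass_from_mz(-1, adducts[["[M-H]-"]]), "> 0")
})

test_that("build_ion_index enumerates the cross product, sorted and filtered", {
  lib <- random_library(3, seed = 21)
  idx <- build_ion_index(lib, adducts[1:3], c(50, 5000))
  expect_s3_class(idx, "ion_index")
  expect_equal(nrow(idx), 9L)
  expect_false(is.unsorted(idx$theoretical_mz))

  # brute-force cross-product oracle on a larger random library
  lib <- random_library(120, seed = 22)
  rng <- c(50, 1200)
  idx <- build_ion_index(lib, adducts, rng)
  brute <- expand.grid(ci = seq_len(nrow(lib)), ai = seq_along(adducts))
  brute$mz <- mapply(function(ci, ai)
    adduct_mz(lib$neutral_mass[ci], adducts[[ai]]), brute$ci, brute$ai)
  brute <- brute[brute$mz >= rng[1] & brute$mz <= rng[2], ]
  expect_equal(nrow(idx), nrow(brute))
  expect_equal(sort(idx$theoretical_mz), sort(brute$mz))

  # boundary: candidate just above the upper limit is excluded
  path <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(compound_id = "big", name = "big",
                              formula = "C80H120O12", class = "other"),
                   path, row.names = FALSE)
  big <- read_compound_library(path)  # M = 1288.9, all ions > 1200
  expect_warning(idx2 <- build_ion_index(big, adducts, c(50, 1200)), "empty")
  expect_equal(nrow(idx2), 0L)
})

test_that("the bundled mini-library loads and excludes nothing it promises", {
  lib <- minilib()
  expect_gt(nrow(lib), 25)
  expect_true(all(c("liensinine", "isoliensinine", "neferine") %in%
                    lib$compound_id))
  expect_error(read_compound_library(textConnection("x,y\n1,2")))
  # duplicate ids rejected
  path <- tempfile(fileext = ".csv")
  writeLines("compound_id,name,formula,class\na,A,H2O,other\na,B,CO2,other", path)
  expect_error(read_compound_library(path), "duplicate")
})
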