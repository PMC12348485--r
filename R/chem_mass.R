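# Monoisotopic atomic masses (Da), IUPAC/CODATA. Fixed table: annotation
# accuracy is defined against these constants, not against a mutable source.
.MONO_MASS <- c(
  C  = 12.000000,
  H  = 1.00782503,
  N  = 14.00307401,
  O  = 15.99491462,
  S  = 31.97207069,
  P  = 30.97376151,
  Na = 22.98976928,
  K  = 38.96370649,
  Cl = 34.96885268
)
.ELECTRON_MASS <- 0.00054858
.PROTON_MASS   <- 1.00727646

#' Supported chemical elements
#'
#' @return Character vector of element symbols the formula parser accepts.
#' @export
supported_elements <- function() names(.MONO_MASS)

.as_formula <- function(counts) {
  if (length(counts)) counts <- counts[order(names(counts))]
  else names(counts) <- character(0)
  storage.mode(counts) <- "integer"
  structure(counts, class = "chem_formula")
}

#' The empty ("null") molecular formula
#'
#' Used for adduct specifications that add or remove nothing.
#' @return A `chem_formula` with no atoms; its mass is 0.
#' @export
null_formula <- function() .as_formula(integer(0))

#' Parse a molecular formula string
#'
#' Accepts plain element-count notation (e.g. `"C27H30O16"`, `"H2O"`) in any
#' element order. Only C, H, N, O, S, P, Na, K, Cl are supported; parentheses,
#' hydrates and isotope labels are not.
#'
#' @param text Non-empty ASCII formula string.
#' @return A named integer vector of class `chem_formula` (element -> count).
#' @examples
#' parse_formula("C6H14N4O2")
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(text))
    stop("formula must be a single non-empty string")
  m <- gregexpr("[A-Z][a-z]?[0-9]*", text)[[1]]
  tokens <- regmatches(text, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(text) || m[1] != 1L)
    stop("malformed formula: ", sQuote(text))
  counts <- integer(0)
  for (tok in tokens) {
    el <- sub("[0-9]*$", "", tok)
    n_str <- sub("^[A-Za-z]+", "", tok)
    if (!el %in% names(.MONO_MASS))
      stop("unsupported element ", sQuote(el), " in formula ", sQuote(text))
    n <- if (nzchar(n_str)) as.integer(n_str) else 1L
    if (n == 0L)
      stop("zero count for element ", sQuote(el), " in formula ", sQuote(text))
    counts[el] <- if (el %in% names(counts)) counts[[el]] + n else n
  }
  .as_formula(counts)
}

#' @export
format.chem_formula <- function(x, ...) {
  if (length(x) == 0L) return("(null)")
  # Hill order on output: C, H, then alphabetical
  ord <- c(intersect(c("C", "H"), names(x)), setdiff(sort(names(x)), c("C", "H")))
  paste0(ord, ifelse(x[ord] == 1L, "", x[ord]), collapse = "")
}

#' @export
print.chem_formula <- function(x, ...) {
  cat("<chem_formula> ", format(x), "\n", sep = "")
  invisible(x)
}

#' Monoisotopic mass of a formula
#'
#' @param formula A `chem_formula` (or string, parsed on the fly).
#' @return Mass in Da; 0 for the null formula.
#' @examples
#' monoisotopic_mass("H2O") # 18.0106
#' @export
monoisotopic_mass <- function(formula) {
  if (is.character(formula)) formula <- parse_formula(formula)
  if (length(formula) == 0L) return(0)
  sum(.MONO_MASS[names(formula)] * as.numeric(formula))
}

#' Construct an adduct specification
#'
#' Only singly charged species are modeled (|charge| = 1), matching the
#' molecular-ion annotation convention for small-molecule MALDI imaging.
#'
#' @param label Canonical label, e.g. `"[M+H]+"`.
#' @param polarity `"positive"` or `"negative"`; must match the charge sign.
#' @param atoms_added,atoms_removed Formulas (string or `chem_formula`).
#' @param charge `+1` or `-1`.
#' @return A list of class `adduct_spec`.
#' @export
adduct_spec <- function(label, polarity, atoms_added = null_formula(),
                        atoms_removed = null_formula(), charge) {
  polarity <- match.arg(polarity, c("positive", "negative"))
  if (is.character(atoms_added))
    atoms_added <- if (nzchar(atoms_added)) parse_formula(atoms_added) else null_formula()
  if (is.character(atoms_removed))
    atoms_removed <- if (nzchar(atoms_removed)) parse_formula(atoms_removed) else null_formula()
  if (!charge %in% c(1L, -1L, 1, -1)) stop("only singly charged adducts are supported")
  charge <- as.integer(charge)
  if ((charge > 0L) != (polarity == "positive"))
    stop("polarity ", sQuote(polarity), " inconsistent with charge ", charge)
  structure(list(label = label, polarity = polarity, atoms_added = atoms_added,
                 atoms_removed = atoms_removed, charge = charge),
            class = "adduct_spec")
}

#' Default adduct sets
#'
#' Positive: \[M+H\]+, \[M+Na\]+, \[M+K\]+. Negative: \[M-H\]-, \[M+Cl\]-,
#' \[M+HCOO\]-. The potassium and formate adducts are required to reproduce
#' printed reference masses of seed flavonoids and alkaloids; the set is
#' configurable wherever it is consumed.
#'
#' @param polarity `"positive"`, `"negative"`, or `"both"` (default).
#' @return List of `adduct_spec`.
#' @export
default_adducts <- function(polarity = c("both", "positive", "negative")) {
  polarity <- match.arg(polarity)
  all <- list(
    adduct_spec("[M+H]+",    "positive", atoms_added = "H",    charge = +1L),
    adduct_spec("[M+Na]+",   "positive", atoms_added = "Na",   charge = +1L),
    adduct_spec("[M+K]+",    "positive", atoms_added = "K",    charge = +1L),
    adduct_spec("[M-H]-",    "negative", atoms_removed = "H",  charge = -1L),
    adduct_spec("[M+Cl]-",   "negative", atoms_added = "Cl",   charge = -1L),
    adduct_spec("[M+HCOO]-", "negative", atoms_added = "CHO2", charge = -1L)
  )
  if (polarity == "both") return(all)
  Filter(function(a) a$polarity == polarity, all)
}

.adduct_delta <- function(adduct) {
  monoisotopic_mass(adduct$atoms_added) - monoisotopic_mass(adduct$atoms_removed) -
    adduct$charge * .ELECTRON_MASS
}

#' Theoretical m/z of an adduct ion
#'
#' m/z = M + mass(added) - mass(removed) - charge * m_e. Singly charged, so
#' no division by |z|. The electron mass is included: it is needed for
#' 4-decimal agreement with reference values.
#'
#' @param neutral_mass Neutral monoisotopic mass M in Da (>= 0).
#' @param adduct An `adduct_spec`.
#' @return m/z in Da.
#' @examples
#' adduct_mz(monoisotopic_mass("C27H30O16"), default_adducts("negative")[[1]])
#' @export
adduct_mz <- function(neutral_mass, adduct) {
  stopifnot(inherits(adduct, "adduct_spec"))
  if (any(neutral_mass < 0)) stop("neutral_mass must be >= 0")
  mz <- neutral_mass + .adduct_delta(adduct)
  if (any(mz <= 0))
    stop("adduct ", adduct$label, " yields non-positive m/z for this mass")
  mz
}

#' Neutral mass implied by an observed m/z
#'
#' Exact inverse of [adduct_mz()].
#'
#' @param mz Observed m/z (> 0).
#' @param adduct An `adduct_spec`.
#' @return Neutral mass in Da.
#' @export
neutral_mass_from_mz <- function(mz, adduct) {
  stopifnot(inherits(adduct, "adduct_spec"))
  if (any(mz <= 0)) stop("mz must be > 0")
  m <- mz - .adduct_delta(adduct)
  if (any(m < 0))
    stop("implied neutral mass is negative for adduct ", adduct$label)
  m
}

#' Read adduct definitions from CSV
#'
#' Header: `label,polarity,atoms_added,atoms_removed,charge`; empty formula
#' cells mean "nothing added/removed".
#'
#' @param path CSV file path; defaults to the bundled standard set.
#' @return List of `adduct_spec`.
#' @export
read_adducts <- function(path = system.file("extdata", "adducts.csv",
                                            package = "lotusmsi", mustWork = TRUE)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(atoms_added = "character",
                                       atoms_removed = "character"))
  df$atoms_added[is.na(df$atoms_added)] <- ""
  df$atoms_removed[is.na(df$atoms_removed)] <- ""
  lapply(seq_len(nrow(df)), function(i)
    adduct_spec(df$label[i], df$polarity[i], df$atoms_added[i],
                df$atoms_removed[i], df$charge[i]))
}

#' Read a compound library from CSV
#'
#' Expected header: `compound_id,name,formula,class,smiles,source` (the last
#' two optional). Formulas are parsed eagerly so errors surface at load time.
#'
#' @param path CSV file path.
#' @return data.frame of class `compound_library` with a `formula` list column
#'   and a `neutral_mass` column.
#' @export
read_compound_library <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("compound_id", "name", "formula", "class")
  if (!all(req %in% names(df)))
    stop("library is missing columns: ", paste(setdiff(req, names(df)), collapse = ", "))
  if (anyDuplicated(df$compound_id))
    stop("duplicate compound_id in library")
  if (!"smiles" %in% names(df)) df$smiles <- NA_character_
  if (!"source" %in% names(df)) df$source <- NA_character_
  df$formula <- lapply(df$formula, parse_formula)
  df$neutral_mass <- vapply(df$formula, monoisotopic_mass, numeric(1))
  class(df) <- c("compound_library", "data.frame")
  df
}

#' Bundled mini-library of named lotus-seed metabolites
#'
#' Roughly thirty compounds with literature-standard molecular formulas,
#' spanning alkaloids, flavonoids, fatty acids, phenolic acids, a
#' phenylpropanoid amide, an apocarotenoid glucoside and primary metabolites.
#' Includes the bisbenzylisoquinoline alkaloids (liensinine, isoliensinine,
#' neferine) that dominate mature seed plumules, so that their absence from a
#' young-seed dataset can be asserted.
#'
#' @return A `compound_library` data.frame.
#' @export
minilib <- function() {
  read_compound_library(system.file("extdata", "minilib.csv",
                                    package = "lotusmsi", mustWork = TRUE))
}

#' Build a searchable ion index over a compound library
#'
#' Materializes the library x adduct cross product, keeps ions inside the
#' instrument m/z range, and sorts by theoretical m/z (ties in compound_id
#' order) so annotation can binary-search it.
#'
#' @param library A `compound_library`.
#' @param adducts List of `adduct_spec`.
#' @param mz_range Numeric `c(lo, hi)`, lo < hi.
#' @return data.frame `ion_index` with columns `compound_id`, `adduct_label`,
#'   `theoretical_mz`, plus `name`, `class` carried through for reporting.
#' @export
build_ion_index <- function(library, adducts, mz_range = c(50, 1200)) {
  stopifnot(inherits(library, "compound_library"), length(mz_range) == 2L,
            mz_range[1] < mz_range[2])
  if (nrow(library) == 0L) stop("library is empty")
  rows <- list()
  for (a in adducts) {
    mz <- library$neutral_mass + .adduct_delta(a)
    keep <- mz >= mz_range[1] & mz <= mz_range[2] & mz > 0
    if (any(keep)) {
      rows[[length(rows) + 1L]] <- data.frame(
        compound_id = library$compound_id[keep],
        name = library$name[keep],
        class = library$class[keep],
        adduct_label = a$label,
        polarity = a$polarity,
        theoretical_mz = mz[keep],
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    warning("ion index is empty for the given m/z range")
    idx <- data.frame(compound_id = character(0), name = character(0),
                      class = character(0), adduct_label = character(0),
                      polarity = character(0), theoretical_mz = numeric(0),
                      stringsAsFactors = FALSE)
  } else {
    idx <- do.call(rbind, rows)
    idx <- idx[order(idx$theoretical_mz, idx$compound_id), , drop = FALSE]
    rownames(idx) <- NULL
  }
  class(idx) <- c("ion_index", "data.frame")
  idx
}
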