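#' Configuration for the synthetic seed phantom
#'
#' The phantom emulates a MALDI-MSI acquisition of a longitudinal seed
#' section: a 50 um pixel grid, m/z 50-1200, concentric anatomy (pericarp
#' ring, seed-coat ring, cotyledon body, central plumule, cavity annulus
#' between plumule and cotyledon, off-tissue matrix background), planted
#' singly charged ions with region-specific abundances, ppm-scale systematic
#' mass error, multiplicative lognormal intensity noise, additive baseline
#' channels, and matrix-only background ions.
#'
#' @param nx,ny Grid size in pixels (default 120 x 100).
#' @param pixel_size_um Pixel size (default 50).
#' @param mz_range Acquisition range (default c(50, 1200)).
#' @param polarity `"positive"` or `"negative"`.
#' @param outer_rx,outer_ry Outer ellipse semi-axes as fractions of nx/2,
#'   ny/2.
#' @param pericarp_frac,seedcoat_frac Ring widths as fractions of the
#'   normalized radius.
#' @param body_frac Normalized radius of the cotyledon body.
#' @param plumule_rx,plumule_ry Plumule semi-axes as fractions of the outer
#'   semi-axes.
#' @param cavity_frac Cavity annulus width relative to the plumule ellipse.
#' @param apex_halfangle_deg Half-angle of the apex sector of the pericarp.
#' @param sigma_ppm Systematic per-ion mass error SD in ppm (default 2).
#' @param sigma_ppm_pixel Optional per-pixel mass jitter SD in ppm (default 0).
#' @param sigma_int Lognormal intensity noise SD (default 0.3).
#' @param baseline_mean,baseline_channels Additive baseline: mean intensity
#'   and number of random channels per pixel.
#' @param resolving_power Peak FWHM = m/z / resolving_power (default 30000).
#' @param profile_spacing_ppm Sampling spacing of the rendered peak profile.
#' @param base_intensity Reference planted abundance (arbitrary counts).
#' @param matrix_intensity Abundance of matrix background ions.
#' @param seed RNG seed; every stochastic element derives from it.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(nx = 120, ny = 100, pixel_size_um = 50,
                           mz_range = c(50, 1200),
                           polarity = c("positive", "negative"),
                           outer_rx = 0.90, outer_ry = 0.84,
                           pericarp_frac = 0.12, seedcoat_frac = 0.08,
                           body_frac = 0.80,
                           plumule_rx = 0.18, plumule_ry = 0.28,
                           cavity_frac = 0.35, apex_halfangle_deg = 55,
                           sigma_ppm = 2, sigma_ppm_pixel = 0,
                           sigma_int = 0.3,
                           baseline_mean = 1, baseline_channels = 30,
                           resolving_power = 30000,
                           profile_spacing_ppm = 5,
                           base_intensity = 100, matrix_intensity = 50,
                           seed = 42) {
  polarity <- match.arg(polarity)
  cfg <- list(nx = as.integer(nx), ny = as.integer(ny),
              pixel_size_um = pixel_size_um, mz_range = as.numeric(mz_range),
              polarity = polarity, outer_rx = outer_rx, outer_ry = outer_ry,
              pericarp_frac = pericarp_frac, seedcoat_frac = seedcoat_frac,
              body_frac = body_frac, plumule_rx = plumule_rx,
              plumule_ry = plumule_ry, cavity_frac = cavity_frac,
              apex_halfangle_deg = apex_halfangle_deg,
              sigma_ppm = sigma_ppm, sigma_ppm_pixel = sigma_ppm_pixel,
              sigma_int = sigma_int, baseline_mean = baseline_mean,
              baseline_channels = as.integer(baseline_channels),
              resolving_power = resolving_power,
              profile_spacing_ppm = profile_spacing_ppm,
              base_intensity = base_intensity,
              matrix_intensity = matrix_intensity, seed = as.integer(seed))
  if (any(c(cfg$sigma_ppm, cfg$sigma_ppm_pixel, cfg$sigma_int) < 0))
    stop("noise SDs must be >= 0")
  if (cfg$pericarp_frac <= 0 || cfg$seedcoat_frac <= 0 ||
      cfg$pericarp_frac + cfg$seedcoat_frac >= 1)
    stop("degenerate geometry: ring widths")
  class(cfg) <- "phantom_config"
  cfg
}

# normalized elliptic radius and polar angle (y axis points down; the apex of
# the seed points up, toward negative y)
.phantom_frame <- function(config) {
  cx <- (config$nx + 1) / 2; cy <- (config$ny + 1) / 2
  rx <- config$outer_rx * config$nx / 2
  ry <- config$outer_ry * config$ny / 2
  g <- expand.grid(x = seq_len(config$nx), y = seq_len(config$ny))
  list(coords = g,
       r = sqrt(((g$x - cx) / rx)^2 + ((g$y - cy) / ry)^2),
       theta = atan2(cy - g$y, g$x - cx),
       cx = cx, cy = cy, rx = rx, ry = ry)
}

#' Generate the phantom's anatomical geometry
#'
#' @param config A `phantom_config`.
#' @return An `roi_mask` (ny x nx) with all six labels non-empty.
#' @export
make_geometry <- function(config) {
  fr <- .phantom_frame(config)
  r <- fr$r
  lab <- rep("background", length(r))
  lab[r <= 1] <- "pericarp"
  r2 <- 1 - config$pericarp_frac
  lab[r <= r2] <- "seed_coat"
  r3 <- r2 - config$seedcoat_frac
  lab[r <= r3] <- "background"      # gap between seed coat and body, if any
  lab[r <= config$body_frac] <- "cotyledon"
  # plumule ellipse, slightly below center (anatropous attachment)
  prx <- config$plumule_rx * fr$rx
  pry <- config$plumule_ry * fr$ry
  pcx <- fr$cx; pcy <- fr$cy + 0.10 * fr$ry
  rp <- sqrt(((fr$coords$x - pcx) / prx)^2 + ((fr$coords$y - pcy) / pry)^2)
  lab[rp <= 1 + config$cavity_frac & lab == "cotyledon"] <- "cavity"
  lab[rp <= 1 & lab %in% c("cavity", "cotyledon")] <- "plumule"
  m <- matrix(NA_character_, nrow = config$ny, ncol = config$nx)
  m[cbind(fr$coords$y, fr$coords$x)] <- lab
  mask <- roi_mask(m)
  missing <- roi_labels()[!roi_labels() %in% unique(lab)]
  if (length(missing))
    stop("degenerate geometry: empty regions ", paste(missing, collapse = ", "))
  mask
}

# apex sector of the pericarp: angular wedge around +90 degrees (top)
.apex_mask <- function(config, geometry) {
  fr <- .phantom_frame(config)
  half <- config$apex_halfangle_deg * pi / 180
  in_sector <- abs(fr$theta - pi / 2) <= half
  lab <- unclass(geometry)[cbind(fr$coords$y, fr$coords$x)]
  m <- matrix(FALSE, nrow = config$ny, ncol = config$nx)
  m[cbind(fr$coords$y, fr$coords$x)] <- in_sector & lab == "pericarp"
  m
}

.plan_regions <- function() c("pericarp", "pericarp_apex", "seed_coat",
                              "cotyledon", "plumule", "cavity", "background")

.plan_row <- function(compound_id, adduct_label, regions, rel_intensity = 1,
                      is_matrix = FALSE, matrix_mz = NA_real_) {
  prof <- stats::setNames(as.numeric(.plan_regions() %in% regions),
                          .plan_regions())
  c(list(compound_id = compound_id, adduct_label = adduct_label,
         rel_intensity = rel_intensity, is_matrix = is_matrix,
         matrix_mz = matrix_mz), as.list(prof))
}

# Matrix-cluster background m/z values (synthetic, not in any compound
# library; placement verified against the library ion index at plan build).
.MATRIX_MZ <- list(
  positive = c(146.0600, 172.0393, 190.0498, 212.1031, 335.1400, 379.0930),
  negative = c(145.0320, 193.0766, 218.0813, 290.5500, 385.1290, 421.0777)
)

#' Default planting plan for the phantom
#'
#' Reproduces the qualitative tissue localizations reported for the named
#' seed metabolites: apex-restricted chlorophyll degradation (pheophytin A)
#' and benzylisoquinoline monomers in the pericarp apex, a ubiquitous
#' tripeptide (glutathione), flavonoid glycosides of the plumule and its
#' cavity (rutin, vitexin, schaftoside, ...), fatty acids of the storage
#' cotyledons, and matrix-only background ions for blank-filter testing.
#' Every planted compound resolves in the bundled mini-library. The
#' bisbenzylisoquinoline alkaloids of mature plumules (liensinine,
#' isoliensinine, neferine) are deliberately present in the library but never
#' planted. Each compound is planted under a primary adduct and, where it
#' does not collide within 40 ppm of an already planted ion, a secondary
#' adduct at 30% relative abundance with the same spatial profile.
#'
#' @param polarity `"positive"` or `"negative"`.
#' @param library Compound library (default the bundled mini-library).
#' @return A `planting_plan` data.frame: compound_id, adduct_label,
#'   `true_mz`, `rel_intensity`, `is_matrix`, and one 0/1 column per region
#'   profile (`pericarp`, `pericarp_apex`, `seed_coat`, `cotyledon`,
#'   `plumule`, `cavity`, `background`).
#' @export
default_planting_plan <- function(polarity = c("positive", "negative"),
                                  library = minilib()) {
  polarity <- match.arg(polarity)
  P <- list()
  add <- function(...) P[[length(P) + 1L]] <<- .plan_row(...)
  if (polarity == "positive") {
    add("arginine", "[M+H]+", c("pericarp", "cotyledon", "plumule"), 1.2)
    add("glutathione", "[M+Na]+",
        c("pericarp", "seed_coat", "cotyledon", "plumule", "cavity"), 1.5)
    add("coclaurine", "[M+H]+", "pericarp_apex", 1.0)
    add("armepavine", "[M+H]+", c("pericarp_apex", "plumule"), 1.3)
    add("norcoclaurine", "[M+H]+", c("pericarp", "plumule"), 0.8)
    add("n_norarmepavine", "[M+H]+", c("pericarp", "plumule"), 0.8)
    add("n_methylisococlaurine", "[M+H]+", c("pericarp", "plumule"), 0.8)
    add("n_methylcoclaurine", "[M+H]+", c("pericarp", "plumule"), 0.8)
    add("n_feruloyltyramine", "[M+H]+",
        c("pericarp_apex", "seed_coat", "plumule"), 1.1)
    add("xylopine", "[M+H]+", c("cotyledon", "plumule"), 0.9)
    add("pheophytin_a", "[M+H]+", "pericarp_apex", 1.6)
    add("kaempferol", "[M+H]+", c("pericarp", "seed_coat"), 1.4)
    add("catechin", "[M+K]+", c("pericarp", "seed_coat"), 1.2)
    add("taxifolin", "[M+H]+", c("pericarp", "seed_coat"), 0.7)
    add("methyladenosine_5", "[M+K]+", c("pericarp", "seed_coat", "cavity"), 1.0)
    add("dihydrophaseic_glc", "[M+H]+", "cotyledon", 1.1)
    secondary <- c("[M+H]+" = "[M+Na]+", "[M+Na]+" = "[M+H]+",
                   "[M+K]+" = "[M+H]+")
  } else {
    add("palmitic_acid", "[M-H]-", c("pericarp", "cotyledon", "plumule"), 1.6)
    add("oleic_acid", "[M-H]-", c("cotyledon", "plumule"), 1.5)
    add("linolenic_acid", "[M-H]-", c("pericarp", "seed_coat"), 1.3)
    add("anisic_acid", "[M-H]-", c("pericarp", "seed_coat"), 0.9)
    add("protocatechuic_acid", "[M-H]-", c("pericarp", "seed_coat"), 0.8)
    add("myricetin_3_glc", "[M-H]-", c("pericarp", "seed_coat"), 1.1)
    add("catechin", "[M-H]-", c("pericarp", "seed_coat"), 1.4)
    add("astragalin", "[M-H]-",
        c("pericarp", "seed_coat", "plumule", "cavity"), 1.2)
    add("rutin", "[M-H]-", c("pericarp", "plumule", "cavity"), 1.3)
    add("syringetin_3_glc", "[M-H]-", c("plumule", "cavity"), 0.9)
    add("vitexin", "[M-H]-", c("plumule", "cavity"), 1.0)
    add("luteolin_7_rut", "[M-H]-", c("plumule", "cavity"), 0.8)
    add("schaftoside", "[M-H]-", c("plumule", "cavity"), 0.9)
    add("epitaxifolin", "[M-H]-", "cotyledon", 0.8)
    add("lanuginosine", "[M-H]-",
        c("pericarp", "seed_coat", "cotyledon", "plumule"), 1.0)
    add("pronuciferine", "[M+HCOO]-", "cotyledon", 1.1)
    secondary <- c("[M-H]-" = "[M+HCOO]-", "[M+HCOO]-" = "[M-H]-")
  }
  forbidden <- c("liensinine", "isoliensinine", "neferine")
  prim <- do.call(rbind, lapply(P, as.data.frame))
  stopifnot(!any(prim$compound_id %in% forbidden),
            all(prim$compound_id %in% library$compound_id))
  sec <- prim
  sec$adduct_label <- unname(secondary[prim$adduct_label])
  sec$rel_intensity <- 0.3 * prim$rel_intensity
  plan <- rbind(prim, sec)
  # theoretical m/z from the library
  adducts <- default_adducts(polarity)
  names(adducts) <- vapply(adducts, `[[`, character(1), "label")
  mass <- library$neutral_mass[match(plan$compound_id, library$compound_id)]
  plan$true_mz <- vapply(seq_len(nrow(plan)), function(i)
    adduct_mz(mass[i], adducts[[plan$adduct_label[i]]]), numeric(1))
  # matrix-only ions: uniform over the whole slide, background included
  mats <- .MATRIX_MZ[[polarity]]
  matrows <- do.call(rbind, lapply(seq_along(mats), function(i) {
    r <- as.data.frame(.plan_row(sprintf("matrix_%s_%d", substr(polarity, 1, 3), i),
                                 NA_character_, .plan_regions(), 1,
                                 is_matrix = TRUE, matrix_mz = mats[i]))
    r$true_mz <- mats[i]
    r
  }))
  plan <- rbind(plan, matrows)
  # drop ions colliding within 40 ppm of an earlier entry; ions sharing an
  # identical m/z AND identical profile (true isomers) are kept as a group
  keep <- rep(TRUE, nrow(plan))
  profcols <- .plan_regions()
  for (i in seq_len(nrow(plan))) {
    if (!keep[i]) next
    prev <- which(keep & seq_len(nrow(plan)) < i)
    if (!length(prev)) next
    dppm <- abs(plan$true_mz[prev] - plan$true_mz[i]) / plan$true_mz[i] * 1e6
    near <- prev[dppm <= 40]
    if (length(near)) {
      twin <- plan$true_mz[near] == plan$true_mz[i] &
        apply(plan[near, profcols, drop = FALSE], 1, function(v)
          all(v == as.numeric(plan[i, profcols]))) &
        plan$rel_intensity[near] == plan$rel_intensity[i]
      if (!all(twin)) keep[i] <- FALSE
    }
  }
  plan <- plan[keep, , drop = FALSE]
  # matrix ions must sit > 20 ppm from every library ion candidate
  idx <- build_ion_index(library, default_adducts(polarity), c(0.1, 1e5))
  for (mzv in plan$true_mz[plan$is_matrix]) {
    if (any(abs(idx$theoretical_mz - mzv) / mzv * 1e6 <= 20))
      stop("matrix ion at m/z ", mzv, " is within 20 ppm of a library ion")
  }
  if (!any(!plan$is_matrix)) stop("no planted ions for polarity ", polarity)
  rownames(plan) <- NULL
  class(plan) <- c("planting_plan", "data.frame")
  plan
}

#' Render a phantom dataset with its ground-truth manifest
#'
#' Per pixel, each planted ion contributes a Gaussian peak profile (FWHM =
#' m/z / resolving power, sampled every `profile_spacing_ppm`) centered at
#' `true_mz * (1 + eps)` with a per-ion systematic mass error `eps ~
#' N(0, sigma_ppm)` shared across the dataset (ions with identical true m/z
#' share one error, as a common calibration offset would), an optional
#' per-pixel jitter, intensity `region_mean * exp(N(0, sigma_int))`, plus
#' `baseline_channels` additive baseline channels at uniform random m/z.
#' Fully deterministic given `config$seed`.
#'
#' @param config A `phantom_config`.
#' @param plan A `planting_plan` (default [default_planting_plan()]).
#' @param dir Optional directory: writes `phantom.imzML`/`.ibd`, the ROI
#'   label matrix + palette, and `manifest.json`.
#' @return List with `dataset` (an `msi_dataset`), `manifest` (a
#'   `phantom_manifest`: `ions` data.frame with true/observed m/z and
#'   per-region mean planted intensity, `geometry`, `config`).
#' @export
render_phantom <- function(config, plan = default_planting_plan(config$polarity),
                           dir = NULL) {
  stopifnot(inherits(config, "phantom_config"))
  if (any(plan$true_mz < config$mz_range[1] | plan$true_mz > config$mz_range[2]))
    stop("planting plan contains ions outside the m/z range")
  geometry <- make_geometry(config)
  apex <- .apex_mask(config, geometry)
  fr <- .phantom_frame(config)
  coords <- fr$coords
  np <- nrow(coords)
  lab <- unclass(geometry)[cbind(coords$y, coords$x)]
  apx <- apex[cbind(coords$y, coords$x)]
  # extended region of each pixel: pericarp splits into apex / rest
  ext <- ifelse(lab == "pericarp" & apx, "pericarp_apex", lab)

  sig_prof <- 1e6 / (config$resolving_power * 2 * sqrt(2 * log(2)))
  n_half <- max(1L, ceiling(3 * sig_prof / config$profile_spacing_ppm))
  offs <- seq(-n_half, n_half) * config$profile_spacing_ppm
  w <- exp(-offs^2 / (2 * sig_prof^2))
  w <- w / sum(w)

  out <- with_local_seed(config$seed, {
    eps_by_mz <- stats::setNames(
      stats::rnorm(length(unique(plan$true_mz)), 0, config$sigma_ppm * 1e-6),
      format(unique(plan$true_mz), digits = 15))
    eps <- unname(eps_by_mz[format(plan$true_mz, digits = 15)])
    obs_mz <- plan$true_mz * (1 + eps)

    pix_mz <- vector("list", np); pix_int <- vector("list", np)
    region_levels <- .plan_regions()
    ext_f <- factor(ext, levels = region_levels)
    region_mean <- matrix(0, nrow = nrow(plan), ncol = length(roi_labels()),
                          dimnames = list(NULL, roi_labels()))
    # accumulate channels ion group by ion group
    chan_pixel <- list(); chan_mz <- list(); chan_int <- list()
    groups <- split(seq_len(nrow(plan)), format(obs_mz, digits = 15))
    for (g in groups) {
      tot <- numeric(np)
      for (i in g) {
        I <- (if (plan$is_matrix[i]) config$matrix_intensity
              else config$base_intensity) * plan$rel_intensity[i]
        prof <- as.numeric(plan[i, region_levels]) * I
        base_int <- prof[as.integer(ext_f)]
        on <- base_int > 0
        amp <- numeric(np)
        if (config$sigma_int > 0) {
          amp[on] <- base_int[on] * exp(stats::rnorm(sum(on), 0, config$sigma_int))
        } else amp[on] <- base_int[on]
        tot <- tot + amp
        # manifest truth: mean planted (pre-noise) intensity per standard region
        for (r in roi_labels()) region_mean[i, r] <- mean(base_int[lab == r])
      }
      on <- which(tot > 0)
      if (!length(on)) next
      m0 <- plan$true_mz[g[1]] * (1 + eps[g[1]])
      if (config$sigma_ppm_pixel > 0) {
        jit <- stats::rnorm(length(on), 0, config$sigma_ppm_pixel * 1e-6)
        centers <- m0 * (1 + jit)
      } else centers <- rep(m0, length(on))
      # each on-pixel gets the sampled profile around its center
      mzs <- as.vector(outer(offs * 1e-6, centers)) +
        rep(centers, each = length(offs))                    # npts x on-pixels
      ints <- as.vector(outer(w, tot[on]))
      chan_pixel[[length(chan_pixel) + 1L]] <- rep(on, each = length(offs))
      chan_mz[[length(chan_mz) + 1L]] <- mzs
      chan_int[[length(chan_int) + 1L]] <- ints
    }
    if (config$baseline_channels > 0L && config$baseline_mean > 0) {
      nb <- config$baseline_channels
      lo <- config$mz_range[1]; hi <- config$mz_range[2]
      bmz <- lo * exp(stats::runif(np * nb) * log(hi / lo))
      bint <- stats::rexp(np * nb, rate = 1 / config$baseline_mean)
      chan_pixel[[length(chan_pixel) + 1L]] <- rep(seq_len(np), each = nb)
      chan_mz[[length(chan_mz) + 1L]] <- bmz
      chan_int[[length(chan_int) + 1L]] <- bint
    }
    list(pixel = unlist(chan_pixel), mz = unlist(chan_mz),
         int = unlist(chan_int), eps = eps, obs_mz = obs_mz,
         region_mean = region_mean)
  })

  ord <- order(out$pixel, out$mz)
  pix <- out$pixel[ord]; mzv <- out$mz[ord]; intv <- out$int[ord]
  # clamp baseline channels to the acquisition range and drop exact dupes
  okr <- mzv >= config$mz_range[1] & mzv <= config$mz_range[2]
  pix <- pix[okr]; mzv <- mzv[okr]; intv <- intv[okr]
  dup <- c(FALSE, diff(pix) == 0 & diff(mzv) == 0)
  if (any(dup)) {
    grp <- cumsum(!dup)
    intv <- as.numeric(rowsum(intv, grp))
    pix <- pix[!dup]; mzv <- mzv[!dup]
  }
  pf <- factor(pix, levels = seq_len(np))
  mz_list <- split(mzv, pf)
  int_list <- split(intv, pf)
  names(mz_list) <- names(int_list) <- NULL
  mz_list <- lapply(mz_list, as.numeric)
  int_list <- lapply(int_list, as.numeric)
  dataset <- msi_dataset(coords, mz_list, int_list,
                         polarity = config$polarity,
                         pixel_size_um = config$pixel_size_um,
                         mz_range = config$mz_range)
  ions <- data.frame(compound_id = plan$compound_id,
                     adduct_label = plan$adduct_label,
                     true_mz = plan$true_mz, observed_mz = out$obs_mz,
                     epsilon_ppm = out$eps * 1e6,
                     is_matrix = plan$is_matrix,
                     stringsAsFactors = FALSE)
  ions <- cbind(ions, as.data.frame(out$region_mean))
  manifest <- structure(list(ions = ions, geometry = geometry,
                             config = config, seed = config$seed),
                        class = "phantom_manifest")
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_imzml(dataset, file.path(dir, "phantom.imzML"), mode = "processed",
                uuid_seed = config$seed)
    write_roi_labels(geometry, file.path(dir, "roi_labels.csv"))
    mj <- list(ions = ions, seed = config$seed,
               config = config[setdiff(names(config), "polarity")],
               polarity = config$polarity)
    jsonlite::write_json(mj, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(dataset = dataset, manifest = manifest)
}

#' @export
print.phantom_manifest <- function(x, ...) {
  cat(sprintf("<phantom_manifest> %d planted ions (%d matrix-only), %s mode, seed %d\n",
              nrow(x$ions), sum(x$ions$is_matrix), x$config$polarity, x$seed))
  invisible(x)
}
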