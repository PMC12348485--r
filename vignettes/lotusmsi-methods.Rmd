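---
title: "Methods: accurate-mass annotation and semi-quantification of seed MALDI-MSI data"
author: "lotusmsi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: accurate-mass annotation and semi-quantification of seed MALDI-MSI data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and model

`lotusmsi` implements the standard analysis chain for small-molecule MALDI
mass spectrometry imaging of plant seed sections: per-pixel spectra on a
50 µm grid over m/z 50–1200 are RMS-normalized, a mean spectrum is built and
peak-picked, the most intense peaks are matched against a curated compound
library as singly charged molecular ions, hits are filtered against the
off-tissue blank and for peak shape, the section is segmented by k-means into
anatomical regions (pericarp, seed coat, cotyledon, plumule, plus the cavity
separating plumule from cotyledons), and per-tissue mean ion intensities,
presence calls, counts and a row-scaled heatmap matrix are exported.

The central quantity is the theoretical ion m/z of a neutral molecule M under
an adduct A:

$$ m/z = M + m(\text{added}) - m(\text{removed}) - z\, m_e, \qquad |z| = 1 $$

with monoisotopic atomic masses fixed to IUPAC/CODATA values
(C 12, H 1.00782503, N 14.00307401, O 15.99491462, S 31.97207069,
P 30.97376151, Na 22.98976928, K 38.96370649, Cl 34.96885268;
electron 0.00054858 Da). The electron mass matters: omitting it shifts every
ion by ≈ 0.0005 Da, visible at the 4-decimal precision at which reference
values are printed. Matching error is expressed in ppm relative to the
theoretical mass.

**Adduct sets.** Positive mode uses [M+H]+, [M+Na]+, [M+K]+; negative mode
[M−H]−, [M+Cl]−, [M+HCOO]−. Potassium and formate adducts are required to
reconcile several published seed-metabolite ion masses (e.g. catechin
observed at m/z 329.04 in positive mode is the potassium adduct; vitexin at
477.10 the formate adduct). Both sets are configurable via a CSV of adduct
definitions (`label,polarity,atoms_added,atoms_removed,charge`). Multiply
charged ions, isotopologue envelopes and in-source fragments are out of
scope.

## Tunable parameters

| Parameter | Default | Unit | Role |
|---|---|---|---|
| `bin_ppm` | 5 | ppm | common-axis bin width for the mean spectrum (log-spaced, so a fixed-ppm peak occupies the same number of bins at any m/z) |
| `snr_min` | 3 | – | minimum peak signal-to-noise |
| `window_ppm` | 10 | ppm | centroiding half-window and peak merge radius |
| `n_top` | 1020 | peaks | most intense peaks kept, applied once per polarity dataset |
| `tol_ppm` | 5 | ppm | annotation tolerance; published vs theoretical masses differ by ≲3 ppm for this instrument class |
| `tau` | 0.5 | – | blank exclusion: hit removed when mean blank intensity ≥ τ × mean on-tissue intensity |
| `r2_min` | 0.8 | – | minimum symmetric-Gaussian goodness of fit of the mean-spectrum peak |
| `k`, `n_restarts` | 10, 10 | – | k-means clusters and k-means++ restarts |
| `beta` | 0.10 | – | presence: tissue mean ≥ β × max tissue mean |
| `gamma` | 3.0 | – | presence: tissue mean ≥ γ × background mean |

The `n_top = 1020` convention mirrors vendor-software practice of processing
a fixed number of most intense peaks. Whether such a budget covers one or
both polarities is ambiguous in common workflows; here it is applied **per
polarity dataset**, since each polarity is acquired and processed as a
separate file.

The blank-ratio threshold τ, the shape threshold `r2_min`, and the presence
rule (β, γ) are declared operational definitions of criteria that are usually
stated only qualitatively ("evident distribution in the blank control",
"poor peak shape"); they are not reconstructions of any specific vendor
implementation, and all are exposed in the run configuration.

## Numerical choices

* **RMS normalization** divides each pixel's intensities by
  $\sqrt{\operatorname{mean}(I^2)}$ over that spectrum's stored channels.
  All-zero spectra are left unchanged and flagged. The operation is
  idempotent; it changes relative pixel weights in the mean spectrum, so the
  SNR-thresholded peak list may legitimately differ between raw and
  normalized data even though the positions of local maxima do not.
* **Noise floor** for peak picking is 1.4826 × MAD of the binned mean
  spectrum. On sparse axes the plain MAD is 0; the MAD of occupied bins is
  then used, but only when occupied bins exceed 25 % of the axis — an almost
  empty axis (e.g. noise-free simulated data) has no measurable noise floor,
  and SNR filtering is vacuous rather than mistaking signal for noise.
* **Peak merging** is non-maximum suppression with radius `window_ppm`,
  exact in bin units on the log-spaced axis; the taller peak wins, and ties
  in intensity resolve toward lower m/z.
* **Peak shape** is scored by a weighted log-quadratic (i.e. Gaussian) fit
  over the peak region (bins above 5 % of the apex, within 4 merge radii),
  reported as R² in linear intensity space. Fewer than 4 positive points
  carry no shape evidence and score 1; non-negative curvature scores 0. The
  5 % floor keeps distant baseline bins from dominating the quadratic's
  leverage.
* **Blank filter** excludes a peak when mean(blank)/mean(tissue) ≥ τ, and
  always when the on-tissue mean is 0 (x/0 and 0/0 conventions); τ = ∞
  disables the filter. Unidentified peaks are flagged too, so matrix-derived
  signals are visibly marked even when no library candidate exists.
* **k-means** is Lloyd's algorithm with k-means++ initialization, best of
  `n_restarts` by inertia, empty clusters repaired by reassigning the point
  farthest from its center. Pixels are processed in canonical (y, x) order,
  making the result invariant to pixel enumeration order and bitwise
  reproducible given the seed. Features are the per-pixel intensities at the
  retained peak channels of the normalized dataset, unscaled.
* **Tissue tables** use the mean (not median) ion intensity per region,
  matching common export conventions; a compound observed under several
  adducts contributes the sum of its retained peak images. Cavity and
  background means are tracked but excluded from the four-tissue counts.

## The synthetic phantom: what it emulates, and what it does not

Because no raw imaging data are publicly deposited for this kind of study,
every stage is exercised on a generated phantom with known ground truth. The
default phantom is a 120 × 100 pixel grid (50 µm pixels, m/z 50–1200) with
concentric elliptical anatomy — pericarp ring, seed-coat ring, cotyledon
body, central plumule ellipse, cavity annulus between plumule and cotyledon,
and off-tissue background — plus an angular "apex" sector of the pericarp
for apex-restricted compounds (chlorophyll degradation products and
benzylisoquinoline monomers concentrate there in real sections).

The planting plan reproduces the qualitative localizations reported for
~30 named seed metabolites (e.g. rutin in pericarp, plumule and cavity;
oleic acid in the cotyledons; a ubiquitous glutathione; an apex-restricted
pheophytin A), each under a primary adduct and — where it does not collide
within 40 ppm of an already planted ion — a secondary adduct at 30 %
abundance with the same spatial profile. Matrix-only background ions
(synthetic m/z values kept > 20 ppm from every library candidate, so
blank-filter tests are not confounded with tolerance tests) are planted
uniformly across the slide. The bisbenzylisoquinoline alkaloids that
dominate *mature* seed plumules (liensinine, isoliensinine, neferine) are
present in the bundled library but never planted, emulating their absence
from young seeds; the pipeline must report them as undetected.

Signal model per pixel and ion: intensity = region mean ×
exp(N(0, σ_int)) with σ_int = 0.3; observed m/z = true m/z × (1 + ε) with a
systematic per-ion ε ~ N(0, σ_ppm), σ_ppm = 2 ppm, shared across the dataset
(ions of identical true m/z share one ε, as a calibration offset would);
peaks are rendered as Gaussian profiles with FWHM = m/z / 30 000 sampled
every 5 ppm; 30 additive baseline channels per pixel at uniform random m/z
with exponential intensities (mean 1 vs planted means ~60–160). Everything
derives from a single seed; identical configuration and seed give
byte-identical imzML/ibd/manifest files (the embedded UUID is seeded too).

The phantom does **not** emulate isotope envelopes, detector saturation,
in-source fragmentation, real MALDI matrix cluster chemistry, profile-mode
peak tailing, or spatial intensity gradients within a region. A green test
therefore establishes that the pipeline's arithmetic, matching, filtering
and bookkeeping are correct under a realistic noise model — not that the
declared thresholds are optimal for any particular instrument.

## Isobars and the meaning of "precision"

The library deliberately contains equal-mass isomers
(taxifolin/epitaxifolin, both C15H12O7; three C18H21NO3 benzylisoquinoline
monomers) and one exact ion-formula isobar across adducts: schaftoside
[M+HCOO]− and rutin [M−H]− are both C27H29O16⁻, 0.007 ppm apart. An
accurate-mass method cannot distinguish these by construction, and the
matcher is required to report all candidates within tolerance (isomer
groups). Recovery scoring therefore counts a retained hit as correct when
its theoretical m/z coincides (< 0.1 ppm) with a planted ion's — isobaric
equivalents inherit their partner's localization, which is exactly what the
measurement measures — and additionally reports a strict (compound, adduct)
precision. With zero noise the pipeline achieves recall = precision = 1
under the isobar-aware definition; under the strict definition the isobars
are inherent, irreducible "false" positives.

Similarly, the per-tissue presence of an isobar-matched compound equals the
union of the planted profiles of all ions at that m/z; the noiseless
acceptance check uses that closure as its oracle.

## Design decisions taken where the procedure was open

* Peaks are picked on the **mean spectrum** (not per pixel with subsequent
  consolidation); per-pixel picking is noisier and the downstream statistics
  only need dataset-level channels.
* Formate ([M+HCOO]−) and potassium ([M+K]+) complete the published adduct
  sets; the exact "other specific adducts" used by vendor software is not
  disclosed, and the default set is an inference from published ion masses.
* Config files, ROI palettes and manifests are JSON; adduct definitions and
  all tabular exchange are CSV. (No YAML parser is part of the declared
  dependency environment, and JSON round-trips R structures losslessly.)
* Cluster-to-tissue mapping supports both an explicit mapping file and
  automated majority vote against a reference mask; the latter stands in
  for the manual step of collapsing k = 10 clusters onto 4 tissues.
* `validate_config()` returns all problems at once rather than failing at
  the first, and unknown keys are preserved with a warning so configs can
  carry user metadata.

## Known limitations

* No MS/MS, isotope-pattern or retention-time evidence: structure-level
  isomer discrimination is explicitly out of scope.
* The imzML writer targets the common subset of imzML 1.1 (64-bit m/z,
  32-bit intensities, no compression, MD5 checksum) and does not aim at
  vendor-specific extensions or ion mobility.
* Absolute quantification, calibration curves and between-tissue statistical
  testing are out of scope; tissue tables are semi-quantitative.
* Peak centroids inherit up to ±½ bin (±2.5 ppm at defaults) quantization
  from the binned mean spectrum; with the 2 ppm systematic mass error this
  occasionally pushes an ion beyond the 5 ppm matching tolerance, which is
  the dominant cause of sub-unity recall on the noisy phantom.
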