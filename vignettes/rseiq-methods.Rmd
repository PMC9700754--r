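---
title: "Ecological-quality indexing and spatial attribution: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ecological-quality indexing and spatial attribution: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rseiq)
```

This vignette is the package's own account of the science it implements:
the composite ecological-quality index, the four spatial-attribution
detectors, the numerical choices made where the methods leave room, and
what the synthetic-landscape validation does and does not establish.

## The RSEI model

Ecological quality is treated as a latent per-pixel property expressed
through four observable indicators: greenness (NDVI), surface moisture
(tasseled-cap wetness), heat (land surface temperature) and dryness (the
building–soil index NDBSI). Rather than fixing weights a priori, the index
is the first principal component of the standardized indicators — the
single axis that preserves the most joint variance. The workflow is:

1. **Water masking.** Open water is detected by MNDWI
   $(G - SWIR1)/(G + SWIR1) > \tau$ (default $\tau = 0$, the standard
   cut-off; configurable) and removed from every indicator, because water
   dominates the wetness axis and would distort the composite. Masking
   happens after any temporal compositing and before standardization.
2. **Standardization.** Each indicator is centred and scaled,
   $y = (x - \bar x)/s$, with $s$ the *sample* standard deviation. (Some
   presentations print the variance in this step; using it would not give
   unit-variance inputs, so the standard deviation is used.) After this
   step PCA on the covariance and on the correlation matrix coincide, a
   property the test suite asserts.
3. **Suitability diagnostics.** KMO (ratio of squared correlations to
   squared correlations plus squared partial correlations; > 0.5 read as
   adequate) and Bartlett's sphericity test
   $\chi^2 = -(n - 1 - (2p+5)/6)\ln\det R$ are attached to every fit.
4. **PC1 orientation and rescaling.** The eigenvector sign returned by an
   eigen-solver is arbitrary, so the package pins it deterministically:
   PC1 is flipped, if necessary, so the NDVI loading is positive (ties
   broken by requiring a non-positive NDBSI loading). This reproduces the
   conventional (+greenness, +wetness, −heat, −dryness) pattern whenever
   the data carry it. Scores are then min–max rescaled to $[0,1]$ over the
   valid pixels of the epoch being processed. Per-epoch rescaling (rather
   than pooling epochs) matches the practice of producing an independent
   index map per year; it is a documented choice, and cross-epoch
   comparisons therefore happen on the *grade* scale, not raw RSEI.

One orientation caveat is worth stating precisely: no data-driven sign
rule can make the index invariant to negating all four input layers.
Negation leaves the correlation matrix — hence the eigenvectors — intact
while negating the scores, so the rescaled index maps exactly to its
complement $1 - \mathrm{RSEI}$. The tests assert this complement identity;
it is the correct invariant, and it guarantees no *arbitrary* solver sign
ever reaches the user.

The eigenvalue-weighted composite $Y = \sum_{i \le m} \lambda_i /
(\sum_{j \le m} \lambda_j)\, \mathrm{PC}_i$ is provided
(`composite_index()`) as an explicit alternative, but the default index is
rescaled PC1, which is the dominant usage.

### Grading and change

RSEI is cut into five fixed 0.2-wide grades (poor, fair, moderate, good,
excellent). Printed grade tables often show overlapping endpoints
("0.0–0.2 / 0.2–0.4"); here bins are left-closed/right-open with the final
bin closed, so every value in $[0,1]$ gets exactly one grade and 1.0 is
"excellent". Cut membership is decided by `findInterval`, which is robust
to floating-point representation of the cuts. Change between epochs is the
per-pixel *sign* of the grade difference (improved / unchanged /
declined) — a deliberately coarse, monotone summary that matches how
change proportions are conventionally reported; the 9-level signed
difference is not used.

## The Geodetector statistics

All four detectors consume a sample table: a response $Y$ (RSEI) and
stratified covariates. The factor detector is

$$ q = 1 - \frac{\sum_{h=1}^{L} N_h \sigma_h^2}{N \sigma^2}, $$

where the variance convention matters and is rarely stated. This package
uses **population variances** ($\div N_h$) inside $q$ and the ecological
detector's SSW, which makes $N_h\sigma_h^2$ the exact within-stratum sum
of squares and $q = \mathrm{SSB}/\mathrm{SST}$ an identity (asserted in
tests, along with affine invariance in $Y$ and monotonicity under stratum
refinement). The risk detector, by contrast, uses conventional Welch
two-sample t statistics with *sample* variances and Welch–Satterthwaite
degrees of freedom — the printed form of that statistic sometimes shows
the variance of a stratum mean divided by $n_h$ again, which would divide
twice; that is read as a typo. Risk results report raw two-sided decisions
at 95% confidence (the conventional output) alongside Holm-adjusted
p-values for readers who want family-wise control.

Interaction typing compares $q(X_1 \cap X_2)$ (computed on the overlay
stratification, strata = observed label pairs) with $q(X_1)$, $q(X_2)$ and
their sum; the five categories (non-linear reduction, single-factor
non-linear reduction, two-factor enhancement, independent, non-linear
enhancement) are implemented as a total, mutually exclusive rule with the
equality case "independent" decided at tolerance $10^{-12}$. A 50³ lattice
sweep in the tests verifies totality and exclusivity.

The ecological detector's F ratio compares two factors' SSW. Its decision
is implemented **two-sided** so that exchanging the factors maps
$F \mapsto 1/F$ without changing the conclusion; a one-sided version would
break that reciprocity.

Because the significance recipe behind reported factor-detector p-values
is generally not disclosed by the desktop tools, the package defaults to a
transparent, assumption-free seeded permutation test (shuffle labels,
recompute q, upper-tail proportion with add-one smoothing) and offers the
noncentral-F approximation from the spatial-stratified-heterogeneity
literature as an explicitly labelled alternative. The permutation test's
null calibration (rejection rate at $\alpha = 0.05$ within the 3σ binomial
band over 200 seeded runs of $N = 300$, $L = 5$, 199 permutations) is part
of the acceptance suite.

### Sampling and discretization

`grid_sample()` lays a square lattice (default spacing 1200 map units,
anchored at origin + spacing/2, cell-centre style — the anchor is
configurable since conventions differ) and drops "abnormal" rows, defined
as any-nodata or response outside $[0,1]$; no other outlier trimming is
applied. Continuous covariates are discretized by **exact** Fisher–Jenks
natural breaks (default $k = 11$): a weighted dynamic program over the
sorted unique values minimizing within-class sum of squares, implemented
in C++ and verified against exhaustive search over all contiguous
partitions for 500 random instances. Land use passes through as IGBP
codes.

## The synthetic landscape generator

`simulate_landscape()` emulates a 500 m resolution scene:

* **Latent field**: seeded white noise convolved circularly (FFT) with an
  isotropic Gaussian kernel (default length scale 8 cells),
  restandardized. The scene default is 120×120 cells (60 km × 60 km).
* **Indicators**: linear in the latent with independent Gaussian noise
  (default sd 0.05 per indicator against a unit-variance latent) and signs
  (+, +, −, −); each mapped to a plausible physical range by a positive
  affine transform, which standardization removes.
* **Reflectance bands**: seven bands linear in the latent with small noise
  (sd 0.01), with slopes chosen so the tasseled-cap wetness of the bands
  rises with the latent and SI/IBI fall with it. Exact inversion of the
  index formulas (especially IBI) is over-determined, so the contract is
  consistency — band-derived wet/NDBSI correlate with the direct layers at
  $|r| > 0.9$ — not equality.
* **Water**: the top 2% (default) of an independent smooth field receives
  a water spectral signature (high green, very low SWIR), so the MNDWI
  mask removes almost exactly the injected fraction.
* **Covariates**: stratifications are contiguous quantile bands of
  auxiliary fields $a = \rho z + \sqrt{1-\rho^2}\, e$ with independent
  smooth $e$ — spatially contiguous bands survive coarse lattice sampling,
  as real covariates do. For Gaussian fields and quantile bands the q of
  the stratification against the latent has the closed form
  $q = \rho^2 (1 - \sum_h p_h v_h)$ with $v_h$ truncated-normal band
  variances (`quantile_band_q()`). Default $\rho$: fvc 0.85, rainfall
  0.55, nightlight 0.45, temperature 0.30, popdensity 0.25, land use 0.35
  — vegetation cover is deliberately the strongest driver and rainfall
  second, the qualitative structure such analyses typically report.
  `gen_covariate_with_q()` additionally builds responses
  `effects[stratum] + noise` whose $q_{true} =
  \mathrm{SSB}/(\mathrm{SSB} + N\sigma_w^2)$ is exact; that path drives
  the parameter-recovery validation ($|\hat q - q_{true}| \le 0.02$ at
  $N = 10{,}000$ over 100 seeds for $q_{true} \in \{0, .25, .5, .75\}$).
* **Land use**: IGBP codes restricted to {5, 7, 9, 10, 11, 12, 13, 14,
  17}, croplands-dominated by default, assigned to rank bands of a smooth
  auxiliary field (exact frequencies, clumped spatial structure).

All randomness flows from one root seed through fixed documented offsets,
so any component regenerates independently and full outputs are
byte-identical under a seed.

**What passing on synthetic data does not show.** The generator is linear
and Gaussian with stationary smoothness; real landscapes have seasonality,
sensor noise structure, mixed pixels, nonstationary covariance and
registration error, none of which are emulated. Validation here
establishes the *statistics* are computed correctly and recover known
structure — not that the RSEI is ecologically exhaustive (it omits, e.g.,
air quality and salinity extensions) nor that four indicators suffice in
every biome.

## Numerical choices and degenerate inputs

* Nodata is `NA` internally, a finite sentinel (default −9999) on disk;
  nodata propagates through every per-pixel operation and never enters a
  statistic. Zero denominators in normalized-difference indices yield
  nodata rather than infinities.
* Even-count temporal medians use the midpoint of the two central values.
* Constant indicators, zero-spread responses (SST = 0), single-stratum
  overlays and degenerate NDVI distributions are hard errors naming the
  offending input, not silent results.
* Equal eigenvalues (within 1e−12) are disambiguated by the
  first-nonzero-component sign convention; RSEI orientation is pinned by
  the NDVI-loading rule above.
* The pipeline records every such default (mask threshold, bin closure,
  variance conventions, lattice anchor, seeds) in its JSON run record so a
  result can be audited.

## Problem sizes used in validation

The shipped test and acceptance runs use scenes of 40×40 to 120×120 cells,
detector samples of a few hundred to 10,000 points, 199–999 permutations,
100–200 seed replicates for calibration/recovery studies, and 500 random
Jenks instances at $n \le 12$, $k \le 4$ against exhaustive search — sizes
chosen so the full suite gives tight statistical checks while completing
in well under the time a desk analysis would tolerate.
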