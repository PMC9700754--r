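# rseiq

Ecological-quality monitoring from multispectral imagery, in R: build the
**remote sensing ecological index (RSEI)**, grade it, track its change over
time, and attribute its spatial pattern to environmental and social
covariates with the four **Geodetector** statistics. The package is aimed at
spatial ecologists and remote-sensing analysts who want the full RSEI +
Geodetector workflow as tested, scriptable functions rather than a chain of
GIS point-and-click steps, and at methodologists who want the statistics
validated against landscapes with known ground truth.

## The methods

**RSEI.** Four per-pixel indicators — greenness (NDVI), wetness
(tasseled-cap Wet), heat (LST) and dryness (NDBSI, the mean of the soil
index SI and the built-up index IBI) — are water-masked (MNDWI > 0),
standardized to zero mean and unit variance, and combined by principal
component analysis. The first component typically absorbs most of the
variance with a stable sign pattern (+greenness, +wetness, −heat,
−dryness); it is oriented so that greenness loads positively and min–max
rescaled to [0, 1]:

    y_i = (x_i − x̄) / s,   RSEI = rescale( PC1(y_NDVI, y_Wet, y_LST, y_NDBSI) )

Wetness uses the fixed MODIS tasseled-cap coefficients
(0.1147, 0.2489, 0.2408, 0.3132, −0.3122, −0.6416, −0.5087 on bands 1–7).
KMO and Bartlett-sphericity diagnostics are attached to every PCA. The RSEI
is cut into five 0.2-wide grades (poor → excellent), and per-pixel grade
differences between epochs give improved / unchanged / declined maps.

**Geodetector.** Given point samples of the RSEI and stratified covariates
(continuous ones discretized by exact Fisher–Jenks natural breaks, land use
by its IGBP codes), the factor detector measures explanatory power as

    q = 1 − Σ_h N_h σ_h² / (N σ²)   ∈ [0, 1]

with population variances, so q = SSB/SST exactly. The interaction detector
types q(X1∩X2) against q(X1), q(X2) (enhancement / reduction /
independence), the risk detector compares stratum means by Welch t-tests,
and the ecological detector compares two factors' within-stratum sums of
squares by an F ratio. q significance comes from a seeded permutation test
(a noncentral-F approximation is available as a labelled alternative).

**Synthetic landscapes.** `simulate_landscape()` generates a smooth latent
ecological-quality field, indicator layers and seven reflectance bands
driven by it, open water, and covariates whose stratifications have
*analytically known* q against the latent field — so the entire pipeline is
testable end to end without any satellite download.

## Worked example

```r
library(rseiq)

scene <- simulate_landscape(sim_config(nrow = 120, ncol = 120, seed = 42))
bands <- scene$indicators$bands
mndwi <- compute_mndwi(bands)
wet   <- water_mask(compute_wet(bands), mndwi)
ndbsi <- water_mask(compute_ndbsi(compute_si(bands), compute_ibi(bands)), mndwi)
ndvi  <- water_mask(scene$indicators$ndvi, mndwi)
lst   <- water_mask(scene$indicators$lst, mndwi)

res <- build_rsei(ndvi, wet, lst, ndbsi)
print(res$pca)
#> <eco_pca>
#>  eigenvalues: 3.9208 0.0554 0.0212 0.0025
#>  contribution rates: 98.0% 1.4% 0.5% 0.1%
#>   KMO 0.816, Bartlett chi2 160543.7 (df 6, p 0), n = 14112
#>          PC1    PC2    PC3    PC4
#> ndvi   0.502  0.457  0.194  0.709
#> wet    0.496 -0.737  0.458 -0.002
#> lst   -0.502 -0.461 -0.196  0.705
#> ndbsi -0.501  0.188  0.845  0.002
```

PC1 carries 98% of the indicator variance with the expected (+, +, −, −)
sign pattern, and KMO = 0.816 > 0.5 licenses the PCA. Grading the RSEI and
attributing its spatial pattern:

```r
grade_area_table(grade_rsei(res$rsei))[, c("label", "count", "percent")]
#>       label count   percent
#>        poor   401  2.841553
#>        fair  2277 16.135204
#>    moderate  4434 31.420068
#>        good  5760 40.816327
#>   excellent  1240  8.786848

samples <- grid_sample(res$rsei,
                       c(scene$covariates, list(landuse = scene$landuse)),
                       spacing = 1200)   # 2448 sample points
det <- detect_all(samples,
                  c(rainfall = "continuous", temperature = "continuous",
                    fvc = "continuous", nightlight = "continuous",
                    popdensity = "continuous", landuse = "categorical"),
                  reps = 199, seed = 42)
det$factor
#>       factor          q     p  L    N
#>          fvc 0.75026233 0.005 11 2448
#>     rainfall 0.45445332 0.005 11 2448
#>   popdensity 0.21125177 0.005 11 2448
#>   nightlight 0.20347456 0.005 11 2448
#>  temperature 0.15380412 0.005 11 2448
#>      landuse 0.05269921 0.005  9 2448
```

Vegetation cover was generated as the strongest driver (analytic
q_true = 0.696 against the latent field) and the factor detector ranks it
first; the top interaction (fvc ∩ rainfall, q12 = 0.839 >
max(q1, q2)) is typed "two-factor enhancement".

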