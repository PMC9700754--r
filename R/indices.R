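#' Seven-band surface reflectance container
#'
#' Holds the seven co-registered surface reflectance bands in MOD09A1 order:
#' band 1 Red, 2 NIR1, 3 Blue, 4 Green, 5 NIR2, 6 SWIR1, 7 SWIR2.
#' Reflectances are dimensionless (nominally within \[-0.1, 1.6\]) and are not
#' clipped before index computation; physically invalid values only surface
#' as nodata through zero denominators.
#'
#' @param red,nir1,blue,green,nir2,swir1,swir2 co-registered [eco_grid()]s.
#' @return object of class `reflectance_bands`.
#' @export
reflectance_bands <- function(red, nir1, blue, green, nir2, swir1, swir2) {
  stop_unless_coregistered(red, nir1, blue, green, nir2, swir1, swir2,
                           what = "reflectance bands")
  structure(list(red = red, nir1 = nir1, blue = blue, green = green,
                 nir2 = nir2, swir1 = swir1, swir2 = swir2),
            class = "reflectance_bands")
}

band_mats <- function(bands) lapply(bands, function(g) g$values)

#' Tasseled-cap wetness from MODIS reflectance
#'
#' The wetness component of the tasseled-cap transformation for MODIS:
#' `Wet = 0.1147 Red + 0.2489 NIR1 + 0.2408 Blue + 0.3132 Green
#'  - 0.3122 NIR2 - 0.6416 SWIR1 - 0.5087 SWIR2`.
#' Nodata in any band propagates to the output.
#'
#' @param bands a [reflectance_bands()].
#' @return an `eco_grid` of wetness values.
#' @export
compute_wet <- function(bands) {
  b <- band_mats(bands)
  w <- 0.1147 * b$red + 0.2489 * b$nir1 + 0.2408 * b$blue +
    0.3132 * b$green - 0.3122 * b$nir2 - 0.6416 * b$swir1 -
    0.5087 * b$swir2
  grid_like(bands$red, w)
}

safe_ratio <- function(num, den) {
  out <- num / den
  out[!is.na(den) & den == 0] <- NA_real_
  out
}

#' Bare-soil index SI
#'
#' `SI = ((SWIR1 + Red) - (NIR + Blue)) / ((SWIR1 + Red) + (NIR + Blue))`,
#' with NIR taken as NIR1 (MODIS band 2) by default. A zero denominator
#' yields nodata.
#'
#' @param bands a [reflectance_bands()].
#' @param nir which band plays the unsubscripted NIR role.
#' @return an `eco_grid`.
#' @export
compute_si <- function(bands, nir = c("nir1", "nir2")) {
  nir <- match.arg(nir)
  b <- band_mats(bands)
  a <- b$swir1 + b$red
  c <- b[[nir]] + b$blue
  grid_like(bands$red, safe_ratio(a - c, a + c))
}

#' Index-based built-up index IBI
#'
#' `IBI = (A - B) / (A + B)` with `A = 2 SWIR1 / (SWIR1 + NIR)` and
#' `B = NIR / (NIR + Red) + Green / (Green + SWIR1)`. Any zero
#' sub-denominator yields nodata.
#'
#' @inheritParams compute_si
#' @return an `eco_grid`.
#' @export
compute_ibi <- function(bands, nir = c("nir1", "nir2")) {
  nir <- match.arg(nir)
  b <- band_mats(bands)
  A <- safe_ratio(2 * b$swir1, b$swir1 + b[[nir]])
  B <- safe_ratio(b[[nir]], b[[nir]] + b$red) +
    safe_ratio(b$green, b$green + b$swir1)
  grid_like(bands$red, safe_ratio(A - B, A + B))
}

#' Dryness indicator NDBSI = (SI + IBI) / 2
#' @param si,ibi co-registered [eco_grid()]s from [compute_si()] and
#'   [compute_ibi()].
#' @return an `eco_grid`.
#' @export
compute_ndbsi <- function(si, ibi) {
  stop_unless_coregistered(si, ibi, what = "SI/IBI")
  grid_like(si, (si$values + ibi$values) / 2)
}

#' Modified normalized difference water index
#'
#' `MNDWI = (Green - SWIR1) / (Green + SWIR1)`; zero denominator -> nodata.
#' @param bands a [reflectance_bands()].
#' @return an `eco_grid`.
#' @export
compute_mndwi <- function(bands) {
  b <- band_mats(bands)
  grid_like(bands$red, safe_ratio(b$green - b$swir1, b$green + b$swir1))
}

#' Mask open water out of an indicator layer
#'
#' Pixels whose MNDWI exceeds `threshold` (default 0, the standard water
#' cut-off) are set to nodata so that open water does not distort the
#' wetness-driven composite index; all other pixels pass through unchanged.
#'
#' @param indicator [eco_grid()] to mask.
#' @param mndwi co-registered MNDWI [eco_grid()].
#' @param threshold water cut-off; `mndwi > threshold` is masked.
#' @return an `eco_grid`.
#' @export
water_mask <- function(indicator, mndwi, threshold = 0) {
  stop_unless_coregistered(indicator, mndwi, what = "indicator/MNDWI")
  v <- indicator$values
  v[!is.na(mndwi$values) & mndwi$values > threshold] <- NA_real_
  grid_like(indicator, v)
}

#' Fractional vegetation cover by the dimidiate pixel model
#'
#' `FVC = (NDVI - NDVI_soil) / (NDVI_veg - NDVI_soil)` clipped to \[0, 1\],
#' where the bare-soil and full-vegetation endmembers are the `low_pct` and
#' `high_pct` percentiles of the valid NDVI distribution (defaults 5 and 95,
#' the common convention).
#'
#' @param ndvi [eco_grid()] of NDVI.
#' @param low_pct,high_pct endmember percentiles in \[0, 100\].
#' @return an `eco_grid` of cover fractions in \[0, 1\].
#' @export
compute_fvc <- function(ndvi, low_pct = 5, high_pct = 95) {
  v <- ndvi$values
  valid <- v[!is.na(v)]
  if (length(unique(valid)) < 2L)
    stop("compute_fvc: NDVI is degenerate (fewer than 2 distinct valid values)")
  qq <- stats::quantile(valid, c(low_pct, high_pct) / 100, names = FALSE)
  if (qq[2] <= qq[1])
    stop("compute_fvc: endmember percentiles collapse (soil >= vegetation)")
  fvc <- (v - qq[1]) / (qq[2] - qq[1])
  fvc[!is.na(fvc) & fvc < 0] <- 0
  fvc[!is.na(fvc) & fvc > 1] <- 1
  grid_like(ndvi, fvc)
}
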