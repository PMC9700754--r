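# All simulator randomness flows from one root seed through derive_seed():
# each component draws with seed root + a fixed documented offset, so any
# component can be regenerated independently and the full output is
# byte-identical under a fixed root seed.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 37 + offset) %% 2147483647)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
          else rm(".Random.seed", envir = .GlobalEnv))
  force(expr)
}

#' Smooth Gaussian random field (latent ecological quality)
#'
#' Seeded white noise convolved (circularly, via FFT) with an isotropic
#' Gaussian kernel of the given length scale (in cells), then restandardized
#' to zero mean and unit variance over the grid. Larger length scales give
#' smoother fields with higher spatial autocorrelation.
#'
#' @param nrow,ncol field dimensions in cells.
#' @param length_scale Gaussian kernel standard deviation in cells (> 0).
#' @param seed RNG seed; the same seed reproduces the field exactly.
#' @param cell_size,origin_x,origin_y,crs georeferencing of the output grid.
#' @return an [eco_grid()] with mean 0 and standard deviation 1.
#' @export
gen_latent_field <- function(nrow, ncol, length_scale = 8, seed = 1L,
                             cell_size = 500, origin_x = 0,
                             origin_y = nrow * cell_size, crs = "local") {
  if (length_scale <= 0) stop("gen_latent_field: length_scale must be > 0")
  z <- with_seed(seed, matrix(stats::rnorm(nrow * ncol), nrow, ncol))
  dr <- pmin(0:(nrow - 1), nrow - 0:(nrow - 1))
  dc <- pmin(0:(ncol - 1), ncol - 0:(ncol - 1))
  kern <- exp(-outer(dr^2, dc^2, `+`) / (2 * length_scale^2))
  sm <- Re(stats::fft(stats::fft(z) * stats::fft(kern / sum(kern)),
                      inverse = TRUE)) / length(z)
  sm <- (sm - mean(sm)) / stats::sd(sm)
  eco_grid(sm, origin_x, origin_y, cell_size, crs)
}

#' Default synthetic-landscape configuration
#'
#' The generator emulates a 500 m MODIS-like scene over a smooth latent
#' ecological-quality field: four indicator layers loading (+, +, -, -) on
#' the latent with independent Gaussian noise, seven reflectance bands that
#' approximately invert the index formulas, a small fraction of open water,
#' and six covariates (five continuous, one IGBP-coded land use) built as
#' quantile bands of auxiliary fields with known correlation to the latent,
#' which makes their q values analytically available.
#'
#' @param nrow,ncol scene size in cells.
#' @param cell_size cell edge in map units (default 500 m).
#' @param seed root seed; all randomness derives from it.
#' @param length_scale latent-field smoothness in cells.
#' @param noise_sd indicator noise standard deviation (latent is unit sd).
#' @param loadings positive loading magnitudes for ndvi, wet, lst, ndbsi
#'   (signs are fixed +, +, -, -).
#' @param band_noise_sd reflectance band noise sd.
#' @param water_fraction fraction of cells converted to open water.
#' @param covariates data frame with columns `name`, `rho` (correlation of
#'   the stratifying auxiliary field with the latent), `L` (strata count).
#' @param landuse_proportions named proportions over the IGBP codes
#'   5, 7, 9, 10, 11, 12, 13, 14, 17 (croplands-dominated by default).
#' @param landuse_rho correlation of the land-use auxiliary field with the
#'   latent.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(nrow = 120, ncol = 120, cell_size = 500, seed = 1L,
                       length_scale = 8, noise_sd = 0.05,
                       loadings = c(ndvi = 1, wet = 1, lst = 1, ndbsi = 1),
                       band_noise_sd = 0.01, water_fraction = 0.02,
                       covariates = data.frame(
                         name = c("rainfall", "temperature", "fvc",
                                  "nightlight", "popdensity"),
                         rho = c(0.55, 0.30, 0.85, 0.45, 0.25),
                         L = 11L),
                       landuse_proportions = c(
                         "5" = 0.04, "7" = 0.02, "9" = 0.03, "10" = 0.08,
                         "11" = 0.05, "12" = 0.55, "13" = 0.10, "14" = 0.08,
                         "17" = 0.05),
                       landuse_rho = 0.35) {
  if (abs(sum(landuse_proportions) - 1) > 1e-8)
    stop("sim_config: land-use proportions must sum to 1")
  if (any(noise_sd < 0) || band_noise_sd < 0)
    stop("sim_config: noise sds must be >= 0")
  structure(as.list(environment()), class = "sim_config")
}

#' Indicator layers and reflectance bands from a latent field
#'
#' Builds `ndvi = +a1 z + e1`, `wet = +a2 z + e2`, `lst = -(a3 z + e3)`,
#' `ndbsi = -(a4 z + e4)` (each mapped to a plausible physical range by a
#' positive affine transform, which PCA standardization later removes), plus
#' seven reflectance bands constructed as linear functions of the latent so
#' that [compute_wet()] and [compute_ndbsi()] applied to the bands correlate
#' strongly with the direct wet/ndbsi layers. The inversion is approximate
#' by design (exact inversion of IBI is over-determined); the contract is
#' |r| > 0.9 consistency, not equality.
#'
#' @param latent [eco_grid()] from [gen_latent_field()].
#' @param config a [sim_config()].
#' @return list with `ndvi`, `wet`, `lst`, `ndbsi` (eco_grids) and `bands`
#'   (a [reflectance_bands()]).
#' @export
gen_indicators <- function(latent, config = sim_config()) {
  z <- latent$values
  a <- config$loadings
  ns <- config$noise_sd
  eps <- with_seed(derive_seed(config$seed, 101), replicate(4, {
    matrix(stats::rnorm(length(z), sd = ns), nrow(z), ncol(z))
  }, simplify = FALSE))
  ndvi <- grid_like(latent, 0.45 + 0.12 * (a["ndvi"] * z + eps[[1]]))
  wet <- grid_like(latent, 0.00 + 0.115 * (a["wet"] * z + eps[[2]]))
  lst <- grid_like(latent, 28 - 4 * (a["lst"] * z + eps[[3]]))
  ndbsi <- grid_like(latent, 0.05 - 0.15 * (a["ndbsi"] * z + eps[[4]]))
  bn <- config$band_noise_sd
  be <- with_seed(derive_seed(config$seed, 102), replicate(7, {
    matrix(stats::rnorm(length(z), sd = bn), nrow(z), ncol(z))
  }, simplify = FALSE))
  mk <- function(base, slope, e) grid_like(latent, base + slope * z + e)
  bands <- reflectance_bands(
    red   = mk(0.25, -0.030, be[[1]]),
    nir1  = mk(0.30, +0.030, be[[2]]),
    blue  = mk(0.10, -0.010, be[[3]]),
    green = mk(0.15, +0.006, be[[4]]),
    nir2  = mk(0.28, +0.024, be[[5]]),
    swir1 = mk(0.30, -0.036, be[[6]]),
    swir2 = mk(0.25, -0.030, be[[7]]))
  list(ndvi = ndvi, wet = wet, lst = lst, ndbsi = ndbsi, bands = bands)
}

# variance of a standard normal truncated to (a, b)
truncnorm_var <- function(a, b) {
  p <- stats::pnorm(b) - stats::pnorm(a)
  da <- stats::dnorm(a); db <- stats::dnorm(b)
  ada <- ifelse(is.finite(a), a * da, 0)
  bdb <- ifelse(is.finite(b), b * db, 0)
  mu <- (da - db) / p
  1 + (ada - bdb) / p - mu^2
}

#' Analytic q of quantile-band strata of a correlated Gaussian field
#'
#' If strata are the bands of an auxiliary standard-normal field cut at the
#' quantiles of cumulative weights `p` (equal bands by default), and the
#' response is standard normal with correlation `rho` to the auxiliary
#' field, then `q = rho^2 * (1 - sum_h p_h Var_h)` with `Var_h` the
#' truncated-normal variance of band `h` -- the closed form behind the
#' simulator's `q_true` values.
#'
#' @param L number of equal-probability bands (ignored when `p` is given).
#' @param rho correlation between the stratifying field and the response.
#' @param p optional vector of band probabilities summing to 1.
#' @return scalar q in \[0, 1\].
#' @export
quantile_band_q <- function(L, rho = 1, p = NULL) {
  if (is.null(p)) p <- rep(1 / L, L)
  if (abs(sum(p) - 1) > 1e-9) stop("band probabilities must sum to 1")
  cuts <- stats::qnorm(cumsum(c(0, p)))
  vars <- truncnorm_var(cuts[-length(cuts)], cuts[-1])
  rho^2 * (1 - sum(p * vars))
}

# contiguous rank bands of a field with given cumulative proportions
rank_bands <- function(field_values, p) {
  n <- length(field_values)
  sizes <- diff(round(cumsum(c(0, p)) * n))
  labels <- rep(seq_along(p), times = sizes)
  out <- integer(n)
  out[order(field_values)] <- labels
  out
}

#' Categorical covariate with analytically known q
#'
#' Strata are `L` contiguous equal-quantile bands of the supplied field
#' (spatially contiguous when the field is smooth, so coarse lattice
#' sampling still sees every stratum). The returned response is
#' `effects[stratum] + N(0, within_sd^2)` and the analytic
#' `q_true = SSB / (SSB + N within_sd^2)` is computed from the effect sizes
#' with population stratum weights.
#'
#' @param field an [eco_grid()] whose values stratify the scene.
#' @param L number of strata (>= 2).
#' @param effects per-stratum response means, length `L`.
#' @param within_sd within-stratum response noise sd (>= 0).
#' @param seed RNG seed for the noise.
#' @return list with `strata` ([eco_catgrid()]), `response` ([eco_grid()]),
#'   `q_true`.
#' @export
gen_covariate_with_q <- function(field, L, effects, within_sd, seed = 1L) {
  if (L < 2L) stop("gen_covariate_with_q: L must be >= 2")
  if (within_sd < 0) stop("gen_covariate_with_q: within_sd must be >= 0")
  if (length(effects) != L) stop("gen_covariate_with_q: need one effect per stratum")
  v <- as.vector(field$values)
  lab <- rank_bands(v, rep(1 / L, L))
  n_h <- tabulate(lab, L)
  ew <- sum(n_h * effects) / sum(n_h)
  ssb <- sum(n_h * (effects - ew)^2)
  q_true <- if (ssb == 0 && within_sd == 0) 1
  else ssb / (ssb + sum(n_h) * within_sd^2)
  resp <- effects[lab] +
    with_seed(seed, stats::rnorm(length(lab), sd = within_sd))
  d <- dim(field$values)
  list(strata = eco_catgrid(matrix(lab, d[1], d[2]),
                            origin_x = field$origin_x,
                            origin_y = field$origin_y,
                            cell_size = field$cell_size, crs = field$crs),
       response = grid_like(field, matrix(resp, d[1], d[2])),
       q_true = q_true)
}

#' Spatially clumped IGBP land-use map
#'
#' Assigns IGBP codes to contiguous rank bands of a smooth auxiliary field
#' (band widths given by the target proportions, band-to-code assignment
#' shuffled by the seed), so class frequencies match the targets to rounding
#' while the map stays spatially clumped.
#'
#' @param nrow,ncol map size in cells.
#' @param proportions named proportions over IGBP codes (must sum to 1).
#' @param seed RNG seed.
#' @param length_scale smoothness of the auxiliary field in cells.
#' @param aux optional precomputed auxiliary [eco_grid()] (overrides
#'   `nrow`/`ncol`/`seed` field generation).
#' @return an [eco_catgrid()] with the IGBP legend.
#' @export
gen_landuse <- function(nrow, ncol, proportions, seed = 1L, length_scale = 8,
                        aux = NULL) {
  if (length(proportions) == 0L) stop("gen_landuse: empty proportions")
  if (abs(sum(proportions) - 1) > 1e-8)
    stop("gen_landuse: proportions must sum to 1")
  if (is.null(aux))
    aux <- gen_latent_field(nrow, ncol, length_scale, seed = derive_seed(seed, 7))
  codes <- as.integer(names(proportions))
  ord <- with_seed(derive_seed(seed, 8), sample(length(codes)))
  lab <- rank_bands(as.vector(aux$values), unname(proportions[ord]))
  code_map <- codes[ord]
  igbp_legend <- c("5" = "mixed forests", "7" = "open shrublands",
                   "9" = "savannas", "10" = "grasslands",
                   "11" = "permanent wetlands", "12" = "croplands",
                   "13" = "urban areas",
                   "14" = "cropland-natural vegetation mosaic",
                   "17" = "water bodies")
  d <- dim(aux$values)
  out <- eco_catgrid(matrix(code_map[lab], d[1], d[2]),
                     legend = igbp_legend[as.character(sort(codes))],
                     origin_x = aux$origin_x, origin_y = aux$origin_y,
                     cell_size = aux$cell_size, crs = aux$crs)
  # band widths in the spatial band order actually used (needed for the
  # analytic q of the stratification, which depends on band placement)
  attr(out, "band_p") <- unname(proportions[ord])
  out
}

mix_field <- function(latent, rho, seed, length_scale) {
  indep <- gen_latent_field(nrow(latent$values), ncol(latent$values),
                            length_scale, seed = seed,
                            cell_size = latent$cell_size,
                            origin_x = latent$origin_x,
                            origin_y = latent$origin_y, crs = latent$crs)
  v <- rho * latent$values + sqrt(1 - rho^2) * indep$values
  grid_like(latent, (v - mean(v)) / stats::sd(v))
}

#' Generate a full synthetic landscape
#'
#' Produces every input the analysis pipeline consumes -- reflectance bands
#' (with injected open water), NDVI and LST layers, five continuous
#' covariates, an IGBP land-use map -- together with the latent
#' ecological-quality field and the analytic `q_true` of each covariate's
#' 11-band (or IGBP-class) stratification with respect to the latent field.
#' Fully deterministic under the config's root seed.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_landscape`: `latent`, `indicators` (list from
#'   [gen_indicators()], water-injected bands), `covariates` (named list of
#'   continuous eco_grids), `landuse` ([eco_catgrid()]), `water` (logical
#'   matrix of injected water cells), `q_true` (named vector), `config`.
#' @export
simulate_landscape <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  latent <- gen_latent_field(config$nrow, config$ncol, config$length_scale,
                             seed = derive_seed(config$seed, 1),
                             cell_size = config$cell_size)
  ind <- gen_indicators(latent, config)

  # open water: top water_fraction of an independent smooth field
  water <- matrix(FALSE, config$nrow, config$ncol)
  if (config$water_fraction > 0) {
    wf <- gen_latent_field(config$nrow, config$ncol, config$length_scale,
                           seed = derive_seed(config$seed, 2),
                           cell_size = config$cell_size)
    n_w <- round(config$water_fraction * length(wf$values))
    thr <- sort(as.vector(wf$values), decreasing = TRUE)[n_w]
    water <- wf$values >= thr
    sig <- c(red = 0.04, nir1 = 0.03, blue = 0.06, green = 0.12,
             nir2 = 0.03, swir1 = 0.02, swir2 = 0.01)
    for (nm in names(sig)) {
      b <- ind$bands[[nm]]
      b$values[water] <- sig[[nm]]
      ind$bands[[nm]] <- b
    }
    ind$ndvi$values[water] <- 0.05
  }

  covs <- list()
  q_true <- numeric(0)
  spec <- config$covariates
  scales <- list(rainfall = c(850, 120), temperature = c(15.5, 1.2),
                 fvc = c(0.5, 0.18), nightlight = c(12, 8),
                 popdensity = c(400, 250))
  for (i in seq_len(nrow(spec))) {
    nm <- spec$name[i]
    aux <- mix_field(latent, spec$rho[i], derive_seed(config$seed, 10 + i),
                     config$length_scale)
    sc <- if (nm %in% names(scales)) scales[[nm]] else c(0, 1)
    covs[[nm]] <- grid_like(latent, sc[1] + sc[2] * aux$values)
    q_true[nm] <- quantile_band_q(spec$L[i], rho = spec$rho[i])
  }
  lu_aux <- mix_field(latent, config$landuse_rho,
                      derive_seed(config$seed, 30), config$length_scale)
  landuse <- gen_landuse(config$nrow, config$ncol,
                         config$landuse_proportions,
                         seed = derive_seed(config$seed, 31), aux = lu_aux)
  q_true["landuse"] <- quantile_band_q(
    length(config$landuse_proportions), rho = config$landuse_rho,
    p = attr(landuse, "band_p"))

  structure(list(latent = latent, indicators = ind, covariates = covs,
                 landuse = landuse, water = water, q_true = q_true,
                 config = config),
            class = "sim_landscape")
}
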