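test_that("latent field is deterministic, standardized, and tunably smooth", {
  f1 <- gen_latent_field(60, 60, length_scale = 6, seed = 99)
  f2 <- gen_latent_field(60, 60, length_scale = 6, seed = 99)
  expect_identical(f1$values, f2$values)
  expect_lt(abs(mean(f1$values)), 1e-10)
  expect_equal(sd(f1$values), 1)

  lag1 <- function(m) cor(as.vector(m[, -1]), as.vector(m[, -ncol(m)]))
  rough <- gen_latent_field(200, 200, length_scale = 0.01, seed = 5)
  smooth <- gen_latent_field(200, 200, length_scale = 12, seed = 5)
  expect_lt(abs(lag1(rough$values)), 0.05)
  expect_gt(lag1(smooth$values), 0.9)
  expect_error(gen_latent_field(10, 10, length_scale = 0), "length_scale")
})

test_that("indicators carry the (+, +, -, -) structure on the latent", {
  latent <- gen_latent_field(50, 50, 5, seed = 2)
  cfg <- sim_config(nrow = 50, ncol = 50, seed = 2, noise_sd = 0)
  ind <- gen_indicators(latent, cfg)
  z <- as.vector(latent$values)
  expect_equal(cor(as.vector(ind$ndvi$values), z), 1)
  expect_equal(cor(as.vector(ind$wet$values), z), 1)
  expect_equal(cor(as.vector(ind$lst$values), z), -1)
  expect_equal(cor(as.vector(ind$ndbsi$values), z), -1)

  # with default noise the PC1 loading signs come out (+, +, -, -)
  cfg2 <- sim_config(nrow = 50, ncol = 50, seed = 2)
  ind2 <- gen_indicators(latent, cfg2)
  std <- standardize(indicator_stack(ind2$ndvi, ind2$wet, ind2$lst,
                                     ind2$ndbsi))
  pca <- principal_components(std$stack)
  w <- pca$vectors[, 1] * sign(pca$vectors["ndvi", 1])
  expect_true(w["ndvi"] > 0 && w["wet"] > 0)
  expect_true(w["lst"] < 0 && w["ndbsi"] < 0)
})

test_that("band-derived wetness and dryness agree with the direct layers", {
  latent <- gen_latent_field(60, 60, 6, seed = 3)
  cfg <- sim_config(nrow = 60, ncol = 60, seed = 3)
  ind <- gen_indicators(latent, cfg)
  wet_b <- compute_wet(ind$bands)
  ndbsi_b <- compute_ndbsi(compute_si(ind$bands), compute_ibi(ind$bands))
  expect_gt(abs(cor(as.vector(wet_b$values), as.vector(ind$wet$values))), 0.9)
  expect_gt(abs(cor(as.vector(ndbsi_b$values),
                    as.vector(ind$ndbsi$values))), 0.9)
})

test_that("gen_covariate_with_q returns the analytic q_true", {
  f <- gen_latent_field(40, 40, 4, seed = 6)
  # equal effects -> no between-stratum variance
  expect_equal(gen_covariate_with_q(f, 3, c(2, 2, 2), 0.5, seed = 1)$q_true, 0)
  # L = 2, effects +-1, sd 1 -> q = 0.5
  expect_equal(gen_covariate_with_q(f, 2, c(-1, 1), 1, seed = 1)$q_true, 0.5)
  # zero within-stratum noise -> q = 1
  cv <- gen_covariate_with_q(f, 2, c(-1, 1), 0, seed = 1)
  expect_equal(cv$q_true, 1)
  expect_equal(factor_q(as.vector(cv$response$values),
                        as.vector(cv$strata$codes))$q, 1)
  expect_error(gen_covariate_with_q(f, 1, 0, 1), "L must be")
})

test_that("q-hat estimates q_true closely at moderate size", {
  f <- gen_latent_field(70, 70, 6, seed = 8)
  cv <- gen_covariate_with_q(f, 4, c(-1.5, -0.5, 0.5, 1.5), 1, seed = 9)
  qhat <- factor_q(as.vector(cv$response$values),
                   as.vector(cv$strata$codes))$q
  expect_lt(abs(qhat - cv$q_true), 0.03)
})

test_that("land use is clumped, uses only IGBP codes and recovers proportions", {
  props <- c("5" = 0.04, "7" = 0.02, "9" = 0.03, "10" = 0.08, "11" = 0.05,
             "12" = 0.55, "13" = 0.10, "14" = 0.08, "17" = 0.05)
  lu <- gen_landuse(200, 200, props, seed = 12)
  codes <- as.vector(lu$codes)
  expect_true(all(codes %in% c(5, 7, 9, 10, 11, 12, 13, 14, 17)))
  freq <- table(codes) / length(codes)
  for (cd in names(props))
    expect_lt(abs(freq[[cd]] - props[[cd]]), 0.02)
  expect_equal(unname(lu$legend["11"]), "permanent wetlands")
  # single class -> uniform map
  lu1 <- gen_landuse(20, 20, c("12" = 1), seed = 1)
  expect_true(all(lu1$codes == 12L))
  expect_error(gen_landuse(10, 10, numeric(0)), "empty")
  expect_error(gen_landuse(10, 10, c("12" = 0.5)), "sum to 1")
})

test_that("the full simulated landscape is byte-identical under one seed", {
  cfg <- sim_config(nrow = 40, ncol = 40, seed = 77)
  s1 <- simulate_landscape(cfg)
  s2 <- simulate_landscape(cfg)
  expect_identical(s1$latent$values, s2$latent$values)
  expect_identical(s1$indicators$bands$swir1$values,
                   s2$indicators$bands$swir1$values)
  expect_identical(s1$covariates$rainfall$values,
                   s2$covariates$rainfall$values)
  expect_identical(s1$landuse$codes, s2$landuse$codes)
  expect_identical(s1$q_true, s2$q_true)
  expect_true(all(s1$q_true >= 0 & s1$q_true <= 1))
})

test_that("injected water is removed by the MNDWI mask at the stated fraction", {
  cfg <- sim_config(nrow = 100, ncol = 100, seed = 13, water_fraction = 0.05)
  s <- simulate_landscape(cfg)
  mndwi <- compute_mndwi(s$indicators$bands)
  masked <- water_mask(s$indicators$ndvi, mndwi, threshold = 0)
  frac <- mean(is.na(masked$values))
  expect_lt(abs(frac - 0.05), 0.01)
  # masked cells are (essentially) the injected ones
  expect_gt(mean(is.na(masked$values[s$water])), 0.95)
})

test_that("end-to-end: RSEI tracks the latent and the strongest factor ranks first", {
  cfg <- sim_config(nrow = 100, ncol = 100, seed = 20)
  s <- simulate_landscape(cfg)
  res <- build_rsei(s$indicators$ndvi, s$indicators$wet, s$indicators$lst,
                    s$indicators$ndbsi)
  ok <- !is.na(res$rsei$values)
  expect_gt(cor(res$rsei$values[ok], s$latent$values[ok],
                method = "spearman"), 0.95)

  covlayers <- c(s$covariates, list(landuse = s$landuse))
  samples <- grid_sample(res$rsei, covlayers, spacing = 1200)
  types <- c(rainfall = "continuous", temperature = "continuous",
             fvc = "continuous", nightlight = "continuous",
             popdensity = "continuous", landuse = "categorical")
  det <- detect_all(samples, types, reps = 49, seed = 20)
  # fvc is constructed with the largest q_true and must rank first
  expect_equal(det$factor$factor[1], names(which.max(s$q_true)))
  expect_equal(det$factor$factor[1], "fvc")
})
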