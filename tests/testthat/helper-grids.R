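# small fixture builders shared across test files

mkgrid <- function(v, nrow = NULL, cell = 1, crs = "local") {
  if (is.null(dim(v))) {
    if (is.null(nrow)) nrow <- 1L
    v <- matrix(v, nrow = nrow)
  }
  eco_grid(v, origin_x = 0, origin_y = nrow(v) * cell, cell_size = cell,
           crs = crs)
}

# constant-per-band reflectance fixture
const_bands <- function(red = 0, nir1 = 0, blue = 0, green = 0, nir2 = 0,
                        swir1 = 0, swir2 = 0, n = 1) {
  g <- function(x) mkgrid(matrix(x, n, n))
  reflectance_bands(g(red), g(nir1), g(blue), g(green), g(nir2), g(swir1),
                    g(swir2))
}

# brute-force optimal within-class SS over all contiguous partitions of
# sorted values into k classes (independent oracle for the Jenks DP)
jenks_exhaustive_ssw <- function(values, k) {
  v <- sort(values)
  n <- length(v)
  sse <- function(x) sum((x - mean(x))^2)
  best <- Inf
  recurse <- function(start, classes_left, acc) {
    if (classes_left == 1L) {
      best <<- min(best, acc + sse(v[start:n]))
      return(invisible())
    }
    for (end in start:(n - classes_left + 1L)) {
      a <- acc + sse(v[start:end])
      if (a < best) recurse(end + 1L, classes_left - 1L, a)
    }
  }
  recurse(1L, as.integer(k), 0)
  best
}

# tiny standard 4-indicator stack built from a shared latent ramp
toy_indicator_stack <- function(n = 20, noise = 0, seed = 1) {
  set.seed(seed)
  z <- matrix(seq(-1, 1, length.out = n * n), n, n)
  eps <- function() matrix(rnorm(n * n, sd = noise), n, n)
  indicator_stack(
    ndvi = mkgrid(z + eps()), wet = mkgrid(0.5 * z + eps()),
    lst = mkgrid(-2 * z + eps()), ndbsi = mkgrid(-0.7 * z + eps()))
}

rsei_grade_legend_for_tests <- function() {
  c("1" = "poor", "2" = "fair", "3" = "moderate", "4" = "good",
    "5" = "excellent")
}
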