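#' Bundle the four RSEI indicator layers
#'
#' Co-registers the greenness (NDVI), wetness (tasseled-cap Wet), heat (LST)
#' and dryness (NDBSI) layers and intersects their valid-pixel masks so that
#' every layer carries the identical nodata pattern. Layers are expected to
#' be water-masked already.
#'
#' @param ndvi,wet,lst,ndbsi co-registered [eco_grid()]s.
#' @return object of class `indicator_stack` (named list of 4 grids).
#' @export
indicator_stack <- function(ndvi, wet, lst, ndbsi) {
  stop_unless_coregistered(ndvi, wet, lst, ndbsi, what = "indicators")
  layers <- list(ndvi = ndvi, wet = wet, lst = lst, ndbsi = ndbsi)
  valid <- Reduce(`&`, lapply(layers, function(g) !is.na(g$values)))
  layers <- lapply(layers, function(g) {
    v <- g$values
    v[!valid] <- NA_real_
    grid_like(g, v)
  })
  structure(layers, class = "indicator_stack")
}

indicator_matrix <- function(stack) {
  stopifnot(inherits(stack, "indicator_stack"))
  x <- vapply(stack, function(g) as.vector(g$values), numeric(length(stack$ndvi$values)))
  colnames(x) <- names(stack)
  x[stats::complete.cases(x), , drop = FALSE]
}

#' Standardize the four indicators to zero mean and unit variance
#'
#' Per indicator, `y = (x - mean) / s` over valid pixels with `s` the sample
#' standard deviation (n - 1 denominator). This is the normalization step
#' that puts the four indicators on a common dimensionless scale before PCA,
#' and it makes the PCA covariance and correlation routes coincide.
#'
#' @param stack an [indicator_stack()].
#' @return list with elements `stack` (standardized `indicator_stack`),
#'   `means` and `sds` (named numeric vectors).
#' @export
standardize <- function(stack) {
  stopifnot(inherits(stack, "indicator_stack"))
  means <- sds <- stats::setNames(numeric(4), names(stack))
  out <- stack
  for (nm in names(stack)) {
    v <- stack[[nm]]$values
    valid <- v[!is.na(v)]
    if (length(valid) < 2L)
      stop("standardize: indicator '", nm, "' has fewer than 2 valid pixels")
    m <- mean(valid); s <- stats::sd(valid)
    if (!is.finite(s) || s == 0)
      stop("standardize: indicator '", nm, "' has zero spread")
    means[nm] <- m; sds[nm] <- s
    out[[nm]] <- grid_like(stack[[nm]], (v - m) / s)
  }
  list(stack = out, means = means, sds = sds)
}

#' Kaiser-Meyer-Olkin measure of sampling adequacy
#'
#' `KMO = sum r_ij^2 / (sum r_ij^2 + sum a_ij^2)` over off-diagonal entries,
#' where `a_ij` are the partial correlations obtained from the inverse of the
#' correlation matrix. Values above 0.5 are conventionally read as "suitable
#' for PCA".
#'
#' @param correlation symmetric positive-definite correlation matrix, p >= 3.
#' @return scalar in (0, 1\].
#' @export
kmo_statistic <- function(correlation) {
  p <- nrow(correlation)
  if (is.null(p) || p < 3L || p != ncol(correlation))
    stop("kmo_statistic: need a square correlation matrix with p >= 3")
  inv <- tryCatch(solve(correlation), error = function(e)
    stop("kmo_statistic: correlation matrix is singular"))
  d <- 1 / sqrt(diag(inv))
  partial <- -inv * outer(d, d)
  off <- upper.tri(correlation)
  r2 <- sum(correlation[off]^2)
  a2 <- sum(partial[off]^2)
  r2 / (r2 + a2)
}

#' Bartlett's test of sphericity
#'
#' Tests whether the correlation matrix is the identity:
#' `chi2 = -(n - 1 - (2p + 5)/6) * ln det(R)` with `p (p - 1) / 2` degrees of
#' freedom; a tiny p-value licenses PCA.
#'
#' @param correlation correlation matrix.
#' @param n number of observations behind it (`n > p`).
#' @return list with `statistic`, `df`, `p_value`.
#' @export
bartlett_sphericity <- function(correlation, n) {
  p <- nrow(correlation)
  if (n <= p) stop("bartlett_sphericity: need n > p")
  dt <- det(correlation)
  if (!is.finite(dt) || dt <= 0)
    stop("bartlett_sphericity: non-positive determinant")
  stat <- -(n - 1 - (2 * p + 5) / 6) * log(dt)
  df <- p * (p - 1) / 2
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Principal components of the standardized indicators
#'
#' Eigen-decomposition of the correlation matrix of the standardized
#' indicator values over valid pixels. Components are ordered by descending
#' eigenvalue; each eigenvector's sign is fixed deterministically (first
#' nonzero component positive) and contribution rates are
#' `lambda_i / sum(lambda)`. KMO and Bartlett diagnostics are attached.
#'
#' @param x an [indicator_stack()] of standardized layers (the usual route),
#'   or a plain numeric matrix of observations by variables (>= 2 columns;
#'   useful for testing the decomposition in isolation).
#' @return object of class `eco_pca`: `eigenvalues`, `vectors` (unit
#'   eigenvectors by column), `loadings` (vectors scaled by sqrt(lambda)),
#'   `contribution`, `correlation`, `n`, `kmo`, `bartlett`.
#' @export
principal_components <- function(x) {
  if (inherits(x, "indicator_stack")) {
    X <- indicator_matrix(x)
    if (ncol(X) < 4L) stop("principal_components: need the 4 indicators")
  } else if (is.matrix(x) && is.numeric(x)) {
    X <- x[stats::complete.cases(x), , drop = FALSE]
    if (ncol(X) < 2L) stop("principal_components: need >= 2 variables")
  } else stop("principal_components: unsupported input")
  if (is.null(colnames(X))) colnames(X) <- paste0("v", seq_len(ncol(X)))
  R <- stats::cor(X)
  eg <- eigen(R, symmetric = TRUE)
  vec <- eg$vectors
  for (j in seq_len(ncol(vec))) {
    nz <- which(abs(vec[, j]) > 1e-12)
    if (length(nz) && vec[nz[1], j] < 0) vec[, j] <- -vec[, j]
  }
  dimnames(vec) <- list(colnames(X), paste0("PC", seq_len(ncol(vec))))
  lam <- eg$values
  kmo <- if (ncol(X) >= 3L && abs(det(R)) > 1e-14)
    kmo_statistic(R) else NA_real_
  bart <- if (det(R) > 0 && nrow(X) > ncol(X))
    bartlett_sphericity(R, nrow(X)) else list(statistic = NA, df = NA, p_value = NA)
  structure(list(
    eigenvalues = lam,
    vectors = vec,
    loadings = sweep(vec, 2, sqrt(pmax(lam, 0)), `*`),
    contribution = lam / sum(lam),
    correlation = R,
    n = nrow(X),
    kmo = kmo,
    bartlett = bart), class = "eco_pca")
}

#' @export
print.eco_pca <- function(x, ...) {
  cat("<eco_pca>\n eigenvalues:", sprintf("%.4f", x$eigenvalues), "\n",
      "contribution rates:", sprintf("%.1f%%", 100 * x$contribution), "\n",
      sprintf(" KMO %.3f, Bartlett chi2 %.1f (df %d, p %.3g), n = %d\n",
              x$kmo, x$bartlett$statistic, as.integer(x$bartlett$df),
              x$bartlett$p_value, x$n))
  print(round(x$vectors, 3))
  invisible(x)
}

project_scores <- function(std_stack, weights) {
  mats <- lapply(names(weights), function(nm) std_stack[[nm]]$values * weights[nm])
  Reduce(`+`, mats)
}

#' RSEI from the first principal component
#'
#' Projects the standardized indicators onto PC1, orients the axis so that
#' greenness loads positively (ties broken by requiring a non-positive
#' dryness loading) -- reproducing the expected sign pattern (+ greenness,
#' + wetness, - heat, - dryness) -- and min-max rescales valid pixels to
#' \[0, 1\], higher = better ecological quality.
#'
#' @param pca an `eco_pca` from [principal_components()] on the stack.
#' @param std_stack the standardized [indicator_stack()].
#' @return an `eco_grid` with valid values spanning exactly \[0, 1\].
#' @export
rsei_from_pc1 <- function(pca, std_stack) {
  stopifnot(inherits(pca, "eco_pca"), inherits(std_stack, "indicator_stack"))
  w <- pca$vectors[, 1]
  if (is.na(w["ndvi"])) stop("rsei_from_pc1: PC1 lacks an ndvi loading")
  if (w["ndvi"] < 0 || (w["ndvi"] == 0 && w["ndbsi"] > 0)) w <- -w
  sc <- project_scores(std_stack, w)
  rng <- range(sc, na.rm = TRUE)
  if (!is.finite(diff(rng)) || diff(rng) == 0)
    stop("rsei_from_pc1: PC1 scores are constant")
  grid_like(std_stack$ndvi, (sc - rng[1]) / diff(rng))
}

#' Eigenvalue-weighted composite of the first m components
#'
#' The alternative composite estimator `Y = sum_{i<=m} w_i PC_i` with weights
#' `w_i = lambda_i / sum_{j<=m} lambda_j` (weights sum to 1). The default
#' RSEI pipeline uses [rsei_from_pc1()]; this weighted composite is provided
#' as an explicit option.
#'
#' @param pca an `eco_pca`.
#' @param std_stack the standardized [indicator_stack()].
#' @param m number of leading components, `1 <= m <= p`.
#' @return an `eco_grid` of unscaled composite scores.
#' @export
composite_index <- function(pca, std_stack, m = 1L) {
  p <- length(pca$eigenvalues)
  if (m < 1L || m > p) stop("composite_index: m must be in 1..", p)
  wts <- pca$eigenvalues[seq_len(m)] / sum(pca$eigenvalues[seq_len(m)])
  total <- 0
  for (i in seq_len(m))
    total <- total + wts[i] * project_scores(std_stack, pca$vectors[, i])
  grid_like(std_stack$ndvi, total)
}

#' One-call RSEI construction from raw indicator layers
#'
#' Convenience wrapper: intersect masks, standardize, run diagnostics and
#' PCA, orient and rescale PC1.
#'
#' @param ndvi,wet,lst,ndbsi co-registered, water-masked [eco_grid()]s.
#' @return list with `rsei` (eco_grid), `pca` (eco_pca), `standardized`.
#' @export
build_rsei <- function(ndvi, wet, lst, ndbsi) {
  stk <- indicator_stack(ndvi, wet, lst, ndbsi)
  std <- standardize(stk)
  pca <- principal_components(std$stack)
  list(rsei = rsei_from_pc1(pca, std$stack), pca = pca,
       standardized = std)
}
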