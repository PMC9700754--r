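#' Regular-lattice point sampling of a response and covariate rasters
#'
#' Lays a square lattice at the given spacing over the co-registered layers
#' (first point at `origin + offset`, cell-centre style by default) and
#' extracts, at each lattice point, the value of the cell containing it from
#' the response and every covariate. Rows containing any nodata value -- or a
#' response outside `y_range` -- are treated as abnormal and dropped.
#'
#' @param response [eco_grid()] of the dependent variable (e.g. RSEI).
#' @param covariates an [eco_stack()] of covariate layers (categorical layers
#'   as their integer codes), or a named list of `eco_grid`/`eco_catgrid`.
#' @param spacing lattice spacing in map units, `>= cell_size`.
#' @param offset lattice anchor offset from the grid origin; default
#'   `spacing / 2`.
#' @param y_range admissible closed range for the response, or `NULL` to
#'   disable the range filter.
#' @return data frame with columns `id`, `x`, `y`, `Y`, then one column per
#'   covariate.
#' @export
grid_sample <- function(response, covariates, spacing, offset = spacing / 2,
                        y_range = c(0, 1)) {
  if (inherits(covariates, "eco_stack")) covariates <- covariates$layers
  for (g in covariates)
    stop_unless_coregistered(response, g, what = "response/covariate layers")
  if (spacing < response$cell_size)
    stop("grid_sample: spacing must be >= cell size")
  d <- dim(response$values)
  width <- d[2] * response$cell_size
  height <- d[1] * response$cell_size
  xs <- seq(response$origin_x + offset, response$origin_x + width - 1e-9,
            by = spacing)
  ys <- seq(response$origin_y - offset, response$origin_y - height + 1e-9,
            by = -spacing)
  px <- rep(xs, times = length(ys))
  py <- rep(ys, each = length(xs))
  col <- floor((px - response$origin_x) / response$cell_size) + 1L
  row <- floor((response$origin_y - py) / response$cell_size) + 1L
  idx <- (col - 1L) * d[1] + row
  out <- data.frame(id = seq_along(px), x = px, y = py,
                    Y = as.vector(response$values)[idx])
  for (nm in names(covariates))
    out[[nm]] <- as.vector(grid_values(covariates[[nm]]))[idx]
  keep <- stats::complete.cases(out)
  if (!is.null(y_range))
    keep <- keep & !is.na(out$Y) & out$Y >= y_range[1] & out$Y <= y_range[2]
  out <- out[keep, , drop = FALSE]
  if (nrow(out) == 0L) stop("grid_sample: no sampling point survived filtering")
  rownames(out) <- NULL
  out
}

#' Jenks natural breaks (exact Fisher optimization)
#'
#' Partitions a 1-D variable into `k` classes, contiguous in sorted order,
#' minimizing the total within-class sum of squared deviations (the exact
#' Fisher dynamic program, not the heuristic). Tied values always land in
#' the same class.
#'
#' @param values numeric vector (NA dropped), with at least `k` distinct
#'   values.
#' @param k number of classes, `>= 1`.
#' @return list with `breaks` (the `k - 1` interior class boundaries, upper
#'   edge value of each class but the last), `classes` (per-class value
#'   ranges), and `ssw` (the optimal within-class sum of squares).
#' @export
jenks_breaks <- function(values, k) {
  v <- values[!is.na(values)]
  if (k < 1L) stop("jenks_breaks: k must be >= 1")
  u <- sort(unique(v))
  if (length(u) < k)
    stop("jenks_breaks: k exceeds the number of distinct values")
  w <- as.numeric(table(factor(v, levels = u)))
  ends <- .jenks_fisher(u, w, as.integer(k))
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  ssw <- sum(vapply(seq_len(k), function(i) {
    cls <- v[v >= u[starts[i]] & v <= u[ends[i]]]
    sum((cls - mean(cls))^2)
  }, numeric(1)))
  list(breaks = u[utils::head(ends, -1L)],
       classes = cbind(lower = u[starts], upper = u[ends]),
       ssw = ssw)
}

#' Discretize a covariate column into strata
#'
#' Continuous covariates are cut into `k` classes by exact Jenks natural
#' breaks (default `k = 11`, the conventional setting for these detectors);
#' categorical covariates pass their codes through unchanged. Stratum labels
#' are `1..L`, ordered by class interval (continuous) or by sorted code
#' (categorical).
#'
#' @param column numeric vector.
#' @param k class count for continuous columns.
#' @param type `"continuous"` or `"categorical"`.
#' @return integer vector of stratum labels `1..L` with attribute `"breaks"`
#'   (continuous) or `"codes"` (categorical).
#' @export
discretize <- function(column, k = 11L, type = c("continuous", "categorical")) {
  type <- match.arg(type)
  if (anyNA(column)) stop("discretize: column contains NA")
  if (type == "categorical") {
    codes <- sort(unique(column))
    out <- match(column, codes)
    attr(out, "codes") <- codes
    return(out)
  }
  jb <- jenks_breaks(column, k)
  out <- findInterval(column, jb$breaks, left.open = TRUE) + 1L
  attr(out, "breaks") <- jb$breaks
  out
}

check_strata <- function(y, strata) {
  if (length(y) != length(strata))
    stop("response and strata must have equal length")
  if (anyNA(y) || anyNA(strata)) stop("NA in response or strata")
  f <- if (is.factor(strata)) strata else factor(strata)
  if (nlevels(f) < 1L) stop("empty stratification")
  if (any(tabulate(f, nlevels(f)) == 0L))
    stop("empty stratum in stratification")
  f
}

#' Factor detector: the q statistic of stratified heterogeneity
#'
#' `q = 1 - SSW / SST` where `SSW = sum_h N_h sigma_h^2` uses population
#' (divide-by-N_h) variances so that it is exactly the within-stratum sum of
#' squares and `q = SSB / SST` holds as an identity. `q` lies in \[0, 1\]:
#' 0 means the stratification carries no information about the response,
#' 1 means it explains the response completely.
#'
#' @param y numeric response (no NA).
#' @param strata stratum label per observation (`L >= 1`, each non-empty).
#' @param p_method `"none"` (default), `"permutation"` or `"noncentral-F"`;
#'   see [q_significance()].
#' @param reps,seed forwarded to [q_significance()].
#' @return object of class `factor_result`: `q`, `ssw`, `sst`, `L`, `N`,
#'   `p_value`, `method`.
#' @export
factor_q <- function(y, strata, p_method = c("none", "permutation",
                                             "noncentral-F"),
                     reps = 999L, seed = 1L) {
  p_method <- match.arg(p_method)
  f <- check_strata(y, strata)
  if (length(y) < 2L) stop("factor_q: need N >= 2")
  sst <- sum((y - mean(y))^2)
  if (sst == 0) stop("factor_q: response has zero total variance (SST = 0)")
  ssw <- q_ssw(y, f)
  q <- 1 - ssw / sst
  p <- switch(p_method,
              none = NA_real_,
              permutation = q_significance(y, f, method = "permutation",
                                           reps = reps, seed = seed),
              `noncentral-F` = q_significance(y, f, method = "noncentral-F"))
  structure(list(q = q, ssw = ssw, sst = sst, L = nlevels(f),
                 N = length(y), p_value = p, method = p_method),
            class = "factor_result")
}

#' @export
print.factor_result <- function(x, ...) {
  cat(sprintf("<factor_result> q = %.4f (L = %d, N = %d)", x$q, x$L, x$N))
  if (!is.na(x$p_value)) cat(sprintf(", p = %.4g [%s]", x$p_value, x$method))
  cat("\n")
  invisible(x)
}

# within-stratum sum of squares via group sums (population variances);
# group sums and sizes both come from rowsum so their orders always match
q_ssw <- function(y, f) {
  s_h <- rowsum(y, f)
  n_h <- rowsum(rep(1, length(y)), f)
  sum(y^2) - sum(s_h^2 / n_h)
}

#' Significance of the q statistic
#'
#' Default: a seeded permutation test -- stratum labels are shuffled, q is
#' recomputed, and the p-value is the upper-tail proportion with add-one
#' smoothing, `(1 + #{q* >= q}) / (reps + 1)`. Alternative: the noncentral-F
#' approximation from the spatial-stratified-heterogeneity literature
#' (`F = (N - L) / (L - 1) * q / (1 - q)` against a noncentral F with
#' `L - 1, N - L` degrees of freedom), labelled as such.
#'
#' @param y numeric response.
#' @param strata stratum labels.
#' @param method `"permutation"` or `"noncentral-F"`.
#' @param reps number of permutations, `>= 1`.
#' @param seed RNG seed for the permutation draw.
#' @return p-value in (0, 1\].
#' @export
q_significance <- function(y, strata, method = c("permutation",
                                                 "noncentral-F"),
                           reps = 999L, seed = 1L) {
  method <- match.arg(method)
  f <- check_strata(y, strata)
  sst <- sum((y - mean(y))^2)
  if (sst == 0) stop("q_significance: SST = 0")
  q_obs <- 1 - q_ssw(y, f) / sst
  N <- length(y); L <- nlevels(f)
  if (method == "permutation") {
    if (reps < 1L) stop("q_significance: reps must be >= 1")
    hits <- 0L
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    set.seed(seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    fi <- as.integer(f)
    for (r in seq_len(reps)) {
      qp <- 1 - q_ssw(y, sample(fi)) / sst
      if (qp >= q_obs - 1e-12) hits <- hits + 1L
    }
    (1 + hits) / (reps + 1)
  } else {
    if (L < 2L || N <= L) stop("q_significance: need L >= 2 and N > L")
    Fv <- (N - L) / (L - 1) * q_obs / (1 - q_obs)
    m_h <- tapply(y, f, mean)
    n_h <- tabulate(f)
    sigma2 <- sst / N
    lambda <- (sum(m_h^2) - sum(sqrt(n_h) * m_h)^2 / N) / sigma2
    stats::pf(Fv, L - 1, N - L, ncp = lambda, lower.tail = FALSE)
  }
}

#' Classify an interaction triple (q1, q2, q12)
#'
#' The standard five-way typing of how the overlay of two stratifications
#' compares with the single factors: below both -> non-linear reduction;
#' between them -> single-factor non-linear reduction; above both but below
#' their sum -> two-factor enhancement; equal to the sum (within `tol`) ->
#' independent; above the sum -> non-linear enhancement. The rules are total
#' and mutually exclusive. Vectorized over triples.
#'
#' @param q1,q2 single-factor q values.
#' @param q12 q of the overlay stratification.
#' @param tol equality tolerance for the "independent" case.
#' @return character vector of interaction types.
#' @export
interaction_type <- function(q1, q2, q12, tol = 1e-12) {
  lo <- pmin(q1, q2); hi <- pmax(q1, q2); s <- q1 + q2
  ifelse(abs(q12 - s) <= tol, "independent",
  ifelse(q12 > s, "non-linear enhancement",
  ifelse(q12 > hi, "two-factor enhancement",
  ifelse(q12 >= lo, "single-factor non-linear reduction",
         "non-linear reduction"))))
}

#' Interaction detector for two stratifications
#'
#' Computes q for each factor and for their overlay (strata defined by the
#' observed pairs of labels) and assigns the interaction type via
#' [interaction_type()].
#'
#' @param y numeric response.
#' @param strata_a,strata_b stratum labels on the same rows.
#' @return object of class `interaction_result`: `q1`, `q2`, `q12`, `type`.
#' @export
interaction_detect <- function(y, strata_a, strata_b) {
  fa <- check_strata(y, strata_a)
  fb <- check_strata(y, strata_b)
  overlay <- interaction(fa, fb, drop = TRUE)
  if (nlevels(overlay) < 2L)
    stop("interaction_detect: overlay collapses to a single stratum")
  q1 <- factor_q(y, fa)$q
  q2 <- factor_q(y, fb)$q
  q12 <- factor_q(y, overlay)$q
  structure(list(q1 = q1, q2 = q2, q12 = q12,
                 type = interaction_type(q1, q2, q12)),
            class = "interaction_result")
}

#' @export
print.interaction_result <- function(x, ...) {
  cat(sprintf("<interaction_result> q1 = %.4f, q2 = %.4f, q12 = %.4f: %s\n",
              x$q1, x$q2, x$q12, x$type))
  invisible(x)
}

#' Risk detector: stratum means and pairwise Welch t-tests
#'
#' Reports the mean response per stratum and, for each stratum pair with at
#' least two observations on both sides, the Welch two-sample t statistic
#' `t = (m1 - m2) / sqrt(s1^2/n1 + s2^2/n2)` (sample variances,
#' Welch-Satterthwaite degrees of freedom) with a two-sided decision at the
#' given confidence level. Pairs involving a stratum with fewer than two
#' observations are flagged untested. Raw p-values are the default decision
#' column; Holm-adjusted p-values are reported alongside.
#'
#' @param y numeric response.
#' @param strata stratum labels.
#' @param alpha significance level (default 0.05, i.e. 95% confidence).
#' @return object of class `risk_result`: `means` (named vector), `n`
#'   (stratum sizes), `t`, `p`, `p_holm`, `significant` (matrices),
#'   `tested` (logical matrix), `alpha`.
#' @export
risk_detect <- function(y, strata, alpha = 0.05) {
  f <- check_strata(y, strata)
  lev <- levels(f)
  L <- length(lev)
  means <- c(tapply(y, f, mean))
  n_h <- c(tapply(y, f, length))
  tmat <- pmat <- matrix(NA_real_, L, L, dimnames = list(lev, lev))
  tested <- matrix(FALSE, L, L, dimnames = list(lev, lev))
  for (i in seq_len(L - 1)) for (j in seq(i + 1, L)) {
    yi <- y[f == lev[i]]; yj <- y[f == lev[j]]
    if (length(yi) >= 2L && length(yj) >= 2L &&
        (stats::sd(yi) > 0 || stats::sd(yj) > 0)) {
      tt <- stats::t.test(yi, yj)
      tmat[i, j] <- tmat[j, i] <- unname(tt$statistic)
      pmat[i, j] <- pmat[j, i] <- tt$p.value
      tested[i, j] <- tested[j, i] <- TRUE
    } else if (length(yi) >= 2L && length(yj) >= 2L) {
      # both strata constant: difference is exact
      tmat[i, j] <- tmat[j, i] <- if (means[i] == means[j]) 0 else Inf
      pmat[i, j] <- pmat[j, i] <- if (means[i] == means[j]) 1 else 0
      tested[i, j] <- tested[j, i] <- TRUE
    }
  }
  holm <- matrix(NA_real_, L, L, dimnames = list(lev, lev))
  up <- upper.tri(pmat) & !is.na(pmat)
  holm[up] <- stats::p.adjust(pmat[up], method = "holm")
  holm[lower.tri(holm)] <- t(holm)[lower.tri(holm)]
  structure(list(means = means, n = n_h, t = tmat, p = pmat, p_holm = holm,
                 significant = pmat < alpha, tested = tested, alpha = alpha),
            class = "risk_result")
}

#' @export
print.risk_result <- function(x, ...) {
  cat("<risk_result> stratum means:\n")
  print(round(x$means, 4))
  cat(sprintf("highest-mean stratum: %s\n", names(which.max(x$means))))
  invisible(x)
}

#' Ecological detector: F comparison of two factors' explanatory power
#'
#' `F = (N_1 (N_2 - 1) SSW_1) / (N_2 (N_1 - 1) SSW_2)` where `SSW` is the
#' within-stratum sum of squares (population variances) of each
#' stratification. The decision is a two-sided F test with
#' `(N_1 - 1, N_2 - 1)` degrees of freedom, so it is invariant under
#' exchanging the factors (F maps to 1/F).
#'
#' @param y numeric response.
#' @param strata_a,strata_b the two stratifications.
#' @param alpha significance level.
#' @return object of class `eco_result`: `F`, `df`, `significant`, `ssw_a`,
#'   `ssw_b`.
#' @export
ecological_detect <- function(y, strata_a, strata_b, alpha = 0.05) {
  fa <- check_strata(y, strata_a)
  fb <- check_strata(y, strata_b)
  ssw_a <- q_ssw(y, fa)
  ssw_b <- q_ssw(y, fb)
  if (ssw_b == 0) stop("ecological_detect: SSW of the second factor is zero")
  N <- length(y)
  Fv <- (N * (N - 1) * ssw_a) / (N * (N - 1) * ssw_b)
  df <- c(N - 1, N - 1)
  crit_hi <- stats::qf(1 - alpha / 2, df[1], df[2])
  crit_lo <- stats::qf(alpha / 2, df[1], df[2])
  structure(list(F = Fv, df = df, significant = (Fv > crit_hi | Fv < crit_lo),
                 ssw_a = ssw_a, ssw_b = ssw_b, alpha = alpha),
            class = "eco_result")
}

#' @export
print.eco_result <- function(x, ...) {
  cat(sprintf("<eco_result> F = %.4f (df %d, %d): %s\n", x$F, x$df[1],
              x$df[2], if (x$significant) "significant difference (Y)"
              else "no significant difference (N)"))
  invisible(x)
}

#' Run all four detectors over a sample table
#'
#' Discretizes each covariate ([discretize()]; continuous columns by Jenks
#' into `k` classes, categorical pass-through), then produces the factor-q
#' table, the pairwise interaction table, the pairwise ecological table and
#' per-covariate risk summaries.
#'
#' @param samples data frame from [grid_sample()] (columns `Y` plus
#'   covariates).
#' @param covariate_types named character vector, `"continuous"` or
#'   `"categorical"` per covariate column.
#' @param k Jenks class count for continuous covariates.
#' @param reps,seed permutation-test settings for factor p-values.
#' @param alpha significance level for risk/ecological decisions.
#' @return list of data frames `factor`, `interaction`, `ecological`, and a
#'   list `risk` of [risk_detect()] results per covariate.
#' @export
detect_all <- function(samples, covariate_types, k = 11L, reps = 999L,
                       seed = 1L, alpha = 0.05) {
  y <- samples$Y
  covs <- names(covariate_types)
  strata <- lapply(covs, function(nm)
    discretize(samples[[nm]], k = k, type = covariate_types[[nm]]))
  names(strata) <- covs
  fac <- do.call(rbind, lapply(seq_along(covs), function(i) {
    fr <- factor_q(y, strata[[i]], p_method = "permutation", reps = reps,
                   seed = seed + i)
    data.frame(factor = covs[i], q = fr$q, p = fr$p_value, L = fr$L,
               N = fr$N, stringsAsFactors = FALSE)
  }))
  pairs <- utils::combn(covs, 2, simplify = FALSE)
  inter <- do.call(rbind, lapply(pairs, function(pr) {
    ir <- interaction_detect(y, strata[[pr[1]]], strata[[pr[2]]])
    data.frame(factor1 = pr[1], factor2 = pr[2], q1 = ir$q1, q2 = ir$q2,
               q12 = ir$q12, type = ir$type, stringsAsFactors = FALSE)
  }))
  eco <- do.call(rbind, lapply(pairs, function(pr) {
    er <- ecological_detect(y, strata[[pr[1]]], strata[[pr[2]]],
                            alpha = alpha)
    data.frame(factor1 = pr[1], factor2 = pr[2], F = er$F,
               significant = er$significant, stringsAsFactors = FALSE)
  }))
  risk <- lapply(strata, function(s) risk_detect(y, s, alpha = alpha))
  list(factor = fac[order(-fac$q), ], interaction = inter, ecological = eco,
       risk = risk)
}
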