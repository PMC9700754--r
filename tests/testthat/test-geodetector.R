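test_that("q hits its analytic endpoints and the hand oracle", {
  # internally constant strata explain everything
  expect_equal(factor_q(c(2, 2, 2, 7, 7, 7), rep(1:2, each = 3))$q, 1)
  # stratum means equal to the grand mean explain nothing
  expect_equal(factor_q(c(1, 3, 1, 3), c(1, 1, 2, 2))$q, 0)
  # hand computation with population variances: 1 - 4/17.5
  fr <- factor_q(1:6, rep(1:2, each = 3))
  expect_equal(fr$q, 1 - 4 / 17.5)
  expect_equal(round(fr$q, 4), 0.7714)
  expect_equal(fr$ssw, 4)
  expect_equal(fr$sst, 17.5)
  # identity q = SSB/SST holds exactly
  expect_equal(fr$q, (fr$sst - fr$ssw) / fr$sst)
  # error contracts
  expect_error(factor_q(rep(1, 4), c(1, 1, 2, 2)), "SST = 0")
  expect_error(factor_q(1:4, factor(c("a", "a", "b", "b"),
                                    levels = c("a", "b", "c"))),
               "empty stratum")
})

test_that("q is affine-invariant and monotone under stratum refinement", {
  set.seed(21)
  for (i in 1:10) {
    y <- rnorm(60)
    s <- sample(1:4, 60, replace = TRUE)
    q0 <- factor_q(y, s)$q
    expect_true(q0 >= 0 && q0 <= 1)
    expect_equal(factor_q(-2.5 * y + 7, s)$q, q0)
    # split stratum 1 into two arbitrary halves: q cannot decrease
    s2 <- s
    idx <- which(s == 1)
    s2[idx[seq_len(floor(length(idx) / 2))]] <- 5L
    expect_gte(factor_q(y, s2)$q + 1e-12, q0)
  }
})

test_that("permutation p-value: maximal q gives the smallest p, SST = 0 errors", {
  y <- c(2, 2, 2, 7, 7, 7)
  s <- rep(1:2, each = 3)
  p <- q_significance(y, s, reps = 99, seed = 4)
  # observed q = 1 can at best be tied by a permutation (ties happen with
  # probability 2 * 3!3!/6! = 0.1 per draw), so p stays small
  expect_lte(p, 0.25)
  expect_gte(p, 1 / 100)
  expect_error(q_significance(rep(3, 6), s), "SST = 0")
  expect_error(q_significance(y, s, reps = 0), "reps")
  # determinism under the seed
  yr <- rnorm(40); sr <- sample(1:4, 40, replace = TRUE)
  expect_identical(q_significance(yr, sr, reps = 199, seed = 7),
                   q_significance(yr, sr, reps = 199, seed = 7))
})

test_that("noncentral-F p-value broadly agrees with permutation on strong effects", {
  set.seed(31)
  y <- c(rnorm(50, 0), rnorm(50, 1.5))
  s <- rep(1:2, each = 50)
  p_perm <- q_significance(y, s, reps = 999, seed = 1)
  p_ncf <- q_significance(y, s, method = "noncentral-F")
  expect_lt(p_perm, 0.01)
  expect_lt(p_ncf, 0.05)
})

test_that("Jenks natural breaks equal the exhaustive optimum", {
  jb <- jenks_breaks(c(1, 2, 3, 10, 11, 12), 2)
  expect_equal(jb$classes, cbind(lower = c(1, 10), upper = c(3, 12)))
  expect_equal(jb$ssw, jenks_exhaustive_ssw(c(1, 2, 3, 10, 11, 12), 2))
  # k = 1: single class, SSW = total SS
  v <- c(4, 8, 15, 16, 23, 42)
  expect_equal(jenks_breaks(v, 1)$ssw, sum((v - mean(v))^2))
  # k = number of distinct values: SSW = 0
  expect_equal(jenks_breaks(v, 6)$ssw, 0)
  expect_error(jenks_breaks(v, 7), "distinct")

  set.seed(17)
  for (i in 1:40) {
    n <- sample(4:12, 1)
    k <- sample(2:min(4, n), 1)
    vals <- round(runif(n, 0, 100), 1)
    if (length(unique(vals)) < k) next
    expect_equal(jenks_breaks(vals, k)$ssw, jenks_exhaustive_ssw(vals, k),
                 tolerance = 1e-9)
  }
})

test_that("discretize: Jenks labels for continuous, passthrough for categorical", {
  # ramp 1..110 into 11 equal classes of 10
  lab <- discretize(1:110, k = 11)
  expect_equal(tabulate(lab, 11), rep(10L, 11))
  expect_true(all(diff(lab[order(1:110)]) >= 0))
  # categorical IGBP codes pass through as ordered labels
  codes <- c(12, 12, 5, 17, 13, 5)
  labc <- discretize(codes, type = "categorical")
  expect_equal(max(labc), length(unique(codes)))
  expect_equal(attr(labc, "codes"), sort(unique(codes)))
  expect_equal(labc[3], labc[6])
  expect_error(discretize(rep(3, 10), k = 2), "distinct")
})

test_that("interaction typing follows the five-way rules, totally and exclusively", {
  expect_equal(interaction_type(0.2, 0.3, 0.6), "non-linear enhancement")
  expect_equal(interaction_type(0.2, 0.3, 0.45), "two-factor enhancement")
  expect_equal(interaction_type(0.2, 0.3, 0.25),
               "single-factor non-linear reduction")
  expect_equal(interaction_type(0.2, 0.3, 0.1), "non-linear reduction")
  expect_equal(interaction_type(0.2, 0.3, 0.5), "independent")
  # sweep: every triple gets exactly one of the five labels
  qs <- seq(0, 1, length.out = 21)
  grid <- expand.grid(q1 = qs, q2 = qs, q12 = qs)
  types <- interaction_type(grid$q1, grid$q2, grid$q12)
  expect_false(anyNA(types))
  expect_true(all(types %in% c("non-linear reduction",
                               "single-factor non-linear reduction",
                               "two-factor enhancement", "independent",
                               "non-linear enhancement")))
})

test_that("interaction detector overlays stratifications correctly", {
  set.seed(41)
  y <- rnorm(80)
  sa <- sample(1:3, 80, replace = TRUE)
  sb <- sample(1:4, 80, replace = TRUE)
  ir <- interaction_detect(y, sa, sb)
  # overlay of identical stratifications equals the single factor
  same <- interaction_detect(y, sa, sa)
  expect_equal(same$q12, same$q1)
  expect_equal(same$type, "single-factor non-linear reduction")
  # overlay refines both factors -> q12 >= max(q1, q2)
  expect_gte(ir$q12 + 1e-12, max(ir$q1, ir$q2))
  expect_error(interaction_detect(y, rep(1, 80), rep(2, 80)), "single stratum")
})

test_that("risk detector reproduces the hand Welch example and flags maxima", {
  rr <- risk_detect(c(0.5, 0.7, 0.2, 0.4), c(1, 1, 2, 2))
  expect_equal(rr$t["1", "2"], 0.3 / sqrt(0.02), tolerance = 1e-9)
  expect_equal(round(rr$t["1", "2"], 4), 2.1213)
  expect_equal(unname(rr$means), c(0.6, 0.3))
  expect_equal(names(which.max(rr$means)), "1")
  expect_equal(rr$t["1", "2"], rr$t["2", "1"])

  # identical groups: t = 0, not significant
  r0 <- risk_detect(c(1, 2, 1, 2), c(1, 1, 2, 2))
  expect_equal(unname(r0$t["1", "2"]), 0)
  expect_false(r0$significant["1", "2"])

  # a singleton stratum is reported but untested
  r1 <- risk_detect(c(1, 2, 3, 9), c(1, 1, 1, 2))
  expect_equal(unname(r1$means["2"]), 9)
  expect_false(r1$tested["1", "2"])
})

test_that("ecological detector: identity, hand ratio, reciprocity", {
  y <- c(1, 2, 3, 4)
  sa <- c(1, 1, 2, 2)
  sb <- c(1, 2, 1, 2)
  same <- ecological_detect(y, sa, sa)
  expect_equal(same$F, 1)
  expect_false(same$significant)
  er <- ecological_detect(y, sa, sb)
  # SSW_A = 1, SSW_B = 4; N factors cancel
  expect_equal(er$F, 0.25)
  rev <- ecological_detect(y, sb, sa)
  expect_equal(rev$F, 1 / er$F)
  expect_equal(rev$significant, er$significant)
  expect_error(ecological_detect(y, sa, c(1, 2, 3, 4)), "zero")
})

test_that("grid_sample lays the documented lattice and drops abnormal rows", {
  set.seed(51)
  resp <- eco_grid(matrix(runif(100), 10, 10), origin_x = 0, origin_y = 5000,
                   cell_size = 500)
  cov1 <- grid_like(resp, matrix(rnorm(100), 10, 10))
  # spacing = cell size: one row per pixel
  s1 <- grid_sample(resp, list(c1 = cov1), spacing = 500)
  expect_equal(nrow(s1), 100)
  # 10x10 at 500 m, spacing 1000 m -> 5 x 5 lattice
  s2 <- grid_sample(resp, list(c1 = cov1), spacing = 1000)
  expect_equal(nrow(s2), 25)
  expect_equal(sort(unique(s2$x)), c(500, 1500, 2500, 3500, 4500))
  # nodata in a covariate at 3 lattice points drops 3 rows
  cov2 <- cov1
  drop_pts <- s2[1:3, c("x", "y")]
  for (i in 1:3) {
    col <- floor(drop_pts$x[i] / 500) + 1
    row <- floor((5000 - drop_pts$y[i]) / 500) + 1
    cov2$values[row, col] <- NA
  }
  s3 <- grid_sample(resp, list(c1 = cov2), spacing = 1000)
  expect_equal(nrow(s3), 22)
  # response outside [0,1] is abnormal
  resp2 <- resp; resp2$values[] <- 5
  expect_error(grid_sample(resp2, list(c1 = cov1), spacing = 1000),
               "no sampling point")
})
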