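test_that("directed GCC hits the exact bounds on monotone pairs", {
  set.seed(1)
  for (i in 1:20) {
    x <- sort(rnorm(sample(5:30, 1)))
    expect_identical(gcc_directed(x, exp(x)), 1)       # monotone map
    expect_identical(gcc_directed(x, rank(x)), 1)
    expect_identical(gcc_directed(x, -x), -1)
    expect_identical(gcc_directed(x, x), 1)            # self-correlation
  }
})

test_that("directed GCC matches direct evaluation of the definition", {
  x <- c(1, 2, 4, 8)
  y <- c(2, 1, 3, 4)
  # hand evaluation: rank(y) = (2,1,3,4), weights (2r-n-1) = (-1,-3,1,3),
  # numerator -1*1 - 3*2 + 1*4 + 3*8 = 21; denominator over sorted x:
  # -3*1 - 1*2 + 1*4 + 3*8 = 23
  expect_equal(gcc_directed(x, y), 21 / 23)
  set.seed(7)
  for (i in 1:50) {
    a <- rnorm(12); b <- rnorm(12)
    expect_equal(gcc_directed(a, b), oracle_gcc(a, b))
    expect_equal(gcc_directed_cpp(a, b), oracle_gcc(a, b))
  }
})

test_that("GCC is invariant to monotone y-transforms and affine x-maps", {
  set.seed(2)
  for (i in 1:200) {
    x <- rnorm(9); y <- rnorm(9)
    g <- gcc_directed(x, y)
    expect_equal(gcc_directed(x, exp(y)), g)
    expect_equal(gcc_directed(x, y^3), g)
    expect_equal(gcc_directed(3.7 * x + 11, y), g)
    expect_true(abs(g) <= 1 + 1e-12)
  }
})

test_that("GCC errors on degenerate input instead of returning NaN", {
  expect_error(gcc_directed(rep(1, 5), 1:5), "constant")
  expect_error(gcc_directed(1:2, 2:1), "insufficient")
  expect_error(gcc_directed(c(1, NA, 3, NA), c(1, 2, 3, 4)), "insufficient")
})

test_that("symmetrization picks the direction of larger magnitude", {
  set.seed(3)
  for (i in 1:50) {
    x <- rnorm(10); y <- rnorm(10)
    s <- gcc_symmetric(x, y)
    expect_equal(abs(s$gcc), max(abs(s$gcc_xy), abs(s$gcc_yx)))
    expect_equal(s$gcc, if (s$direction == "xy") s$gcc_xy else s$gcc_yx)
    # swapping the arguments changes only the direction label
    s2 <- gcc_symmetric(y, x)
    expect_equal(s2$gcc, s$gcc)
  }
  # on near-symmetric bivariate normal data the directions agree closely
  set.seed(4)
  z <- matrix(rnorm(2000), ncol = 2) %*% chol(matrix(c(1, .6, .6, 1), 2))
  s <- gcc_symmetric(z[, 1], z[, 2])
  expect_lt(abs(s$gcc_xy - s$gcc_yx), 0.05)
})

test_that("exhaustive permutation p equals brute-force enumeration", {
  set.seed(5)
  for (i in 1:5) {
    x <- rnorm(5); y <- rnorm(5)
    res <- permutation_pvalue(x, y, exhaustive_threshold = 6)
    expect_true(res$exhaustive)
    expect_equal(res$p, oracle_perm_p(x, y))
  }
  # a perfectly dependent pair: p is the exact null mass at |gcc| = 1
  x <- c(0.3, 1.1, 2.2, 2.9, 4.1)
  res <- permutation_pvalue(x, x, exhaustive_threshold = 6)
  expect_equal(res$p, oracle_perm_p(x, x))
  expect_equal(res$p, 2 / 120)  # identity and full reversal only
})

test_that("Monte-Carlo p respects the add-one floor and determinism", {
  x <- 1:12
  res1 <- permutation_pvalue(x, x, B = 500, exhaustive_threshold = 0,
                             seed = 9)
  res2 <- permutation_pvalue(x, x, B = 500, exhaustive_threshold = 0,
                             seed = 9)
  expect_identical(res1$p, res2$p)
  expect_gte(res1$p, 1 / 501)
  set.seed(6)
  for (i in 1:20) {
    r <- permutation_pvalue(rnorm(8), rnorm(8), B = 99,
                            exhaustive_threshold = 0)
    expect_gte(r$p, 1 / 100)
    expect_lte(r$p, 1)
  }
})

test_that("correlate_all returns one record per pair with coherent q", {
  ds <- noiseless_dataset()
  rec <- correlate_all(ds$traits$values, B = 200, seed = 31)
  expect_equal(nrow(rec), choose(6, 2))
  expect_true(all(rec$status == "ok"))
  expect_true(all(abs(rec$gcc) <= 1 + 1e-12))
  # noiseless construction: lignin and digestibility anti-correlate exactly
  row <- rec[rec$x_name == "lignin" & rec$y_name == "ED24", ]
  expect_equal(row$gcc, -1)
  # Pearson and Spearman agree in sign with the GCC on monotone pairs
  mono <- abs(rec$gcc) > 0.99
  expect_true(all(sign(rec$pcc[mono]) == sign(rec$gcc[mono])))
  expect_true(all(sign(rec$scc[mono]) == sign(rec$gcc[mono])))
  # records are independent of pair evaluation order (seed fan-out)
  rec2 <- correlate_all(ds$traits$values,
                        pairs = cbind("lignin", "ED24"), B = 200, seed = 31)
  expect_equal(rec2$p, row$p)
})

test_that("failed pairs are flagged, not dropped", {
  m <- cbind(a = c(1, 1, 1, 1), b = 1:4, c = c(2, 1, 4, 3))
  rec <- correlate_all(m, B = 50, seed = 1)
  expect_equal(nrow(rec), 3)
  expect_true(any(grepl("constant", rec$status)))
  expect_true(all(!is.na(rec$p[rec$status == "ok"])))
})
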