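test_that("one-way ANOVA matches the two-sample t equivalence", {
  set.seed(51)
  v <- c(rnorm(6, 0), rnorm(6, 1))
  g <- rep(c("a", "b"), each = 6)
  fit <- anova_oneway(v, g)
  tt <- t.test(v ~ g, var.equal = TRUE)
  expect_equal(fit$F, unname(tt$statistic)^2)
  expect_equal(fit$p, tt$p.value)
  expect_error(anova_oneway(rep(c(1, 2), each = 5),
                            rep(c("a", "b"), each = 5)),
               "zero residual variance")
  expect_error(anova_oneway(1:3, c("a", "a", "a")), "insufficient")
})

test_that("ANOVA F matches a hand computation on a small fixture", {
  v <- c(2, 4, 6, 5, 7, 9, 10, 12, 14)
  g <- rep(c("g1", "g2", "g3"), each = 3)
  # group means 4, 7, 12; grand 23/3; SSB = 3*((4-23/3)^2 + ...) ; SSW = 8*3
  ssb <- 3 * sum((c(4, 7, 12) - mean(v))^2)
  ssw <- sum((v - rep(c(4, 7, 12), each = 3))^2)
  f_hand <- (ssb / 2) / (ssw / 6)
  fit <- anova_oneway(v, g)
  expect_equal(fit$F, f_hand)
  expect_equal(fit$df_between, 2)
  expect_equal(fit$df_within, 6)
})

test_that("Tukey-Kramer p-values match the reference implementation", {
  set.seed(52)
  for (i in 1:5) {
    sizes <- sample(3:6, 3, replace = TRUE)  # unbalanced on purpose
    g <- rep(c("g1", "g2", "g3"), times = sizes)
    v <- rnorm(length(g), mean = rep(c(0, 0.8, 2.5), times = sizes))
    pm <- tukey_hsd(v, g)
    ref <- TukeyHSD(aov(v ~ factor(g)))[[1]]
    for (row in rownames(ref)) {
      pair <- strsplit(row, "-")[[1]]
      expect_equal(pm[pair[1], pair[2]], ref[row, "p adj"],
                   tolerance = 1e-6)
    }
  }
  # two groups: Tukey p equals the ANOVA p
  v <- rnorm(10); g <- rep(c("a", "b"), each = 5)
  expect_equal(tukey_hsd(v, g)["a", "b"], anova_oneway(v, g)$p,
               tolerance = 1e-10)
  # widely separated, tight groups: all p effectively zero
  v <- c(rnorm(5, 0, 0.01), rnorm(5, 50, 0.01), rnorm(5, 100, 0.01))
  g <- rep(c("a", "b", "c"), each = 5)
  expect_true(all(tukey_hsd(v, g) < 1e-8, na.rm = TRUE))
})

test_that("compact letters encode exactly the pairwise verdicts", {
  sig_all <- matrix(0.001, 3, 3, dimnames = list(c("a", "b", "c"),
                                                 c("a", "b", "c")))
  diag(sig_all) <- NA
  expect_equal(sort(unname(compact_letters(sig_all))),
               c("a", "b", "c"))

  none <- matrix(0.9, 3, 3, dimnames = list(c("a", "b", "c"),
                                            c("a", "b", "c")))
  diag(none) <- NA
  expect_equal(unname(compact_letters(none)), c("a", "a", "a"))

  # chain pattern: only the extremes differ
  chain <- none
  chain["a", "c"] <- chain["c", "a"] <- 0.01
  expect_equal(unname(compact_letters(chain)), c("a", "ab", "b"))
})

test_that("letter displays never contradict the p matrix", {
  set.seed(53)
  share <- function(a, b) {
    length(intersect(strsplit(a, "")[[1]], strsplit(b, "")[[1]])) > 0
  }
  for (i in 1:50) {
    k <- sample(3:6, 1)
    pm <- matrix(NA_real_, k, k, dimnames = list(letters[1:k],
                                                 letters[1:k]))
    for (a in seq_len(k - 1)) for (b in seq(a + 1, k)) {
      pm[a, b] <- pm[b, a] <- sample(c(0.001, 0.2), 1)
    }
    cld <- tryCatch(compact_letters(pm), error = function(e) NULL)
    # insert-absorb can always represent a transitive-free pattern;
    # when it returns, the invariant must hold exactly
    if (!is.null(cld)) {
      for (a in seq_len(k - 1)) for (b in seq(a + 1, k)) {
        expect_equal(!share(cld[a], cld[b]), pm[a, b] < 0.05)
      }
    }
  }
})

test_that("group summaries carry means, SEs, and letters", {
  set.seed(54)
  v <- c(rnorm(5, 0, 0.1), rnorm(5, 10, 0.1))
  g <- rep(c("young", "old"), each = 5)
  gs <- group_summary(v, g)
  expect_equal(gs$group, c("old", "young"))
  expect_false(gs$letters[1] == gs$letters[2])
  expect_equal(gs$mean[gs$group == "old"], mean(v[g == "old"]))
  expect_equal(gs$se[gs$group == "old"],
               sd(v[g == "old"]) / sqrt(5))
})

test_that("PCA satisfies the decomposition identities", {
  set.seed(55)
  x <- matrix(rnorm(20 * 6), 20, 6,
              dimnames = list(NULL, paste0("t", 1:6)))
  fit <- pca_traits(x, scale = TRUE)
  expect_equal(sum(fit$variance), 1)
  # reconstruction of the standardized data used by the decomposition
  z <- sweep(sweep(x, 2, fit$center), 2, fit$scale, "/")
  expect_lt(max(abs(fit$scores %*% t(fit$loadings) - z)), 1e-8)
  # loadings are orthonormal up to sign
  expect_equal(t(fit$loadings) %*% fit$loadings, diag(6),
               tolerance = 1e-8, ignore_attr = TRUE)
  # deterministic sign convention: top loading of each component positive
  for (c in seq_len(ncol(fit$loadings))) {
    expect_gt(fit$loadings[which.max(abs(fit$loadings[, c])), c], 0)
  }
  # sample order invariance
  fit2 <- pca_traits(x[sample(20), ], scale = TRUE)
  expect_equal(abs(fit2$loadings), abs(fit$loadings), tolerance = 1e-8)

  # two perfectly correlated variables: PC1 carries everything
  y <- cbind(a = 1:10, b = 2 * (1:10) + 3)
  expect_equal(pca_traits(y, scale = TRUE)$variance[[1]], 1)

  expect_error(pca_traits(cbind(a = rep(1, 5), b = 1:5), scale = TRUE),
               "domain error")
  expect_error(pca_traits(matrix(c(1, NA, 2, 3), 2, 2)), "missing")
})
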