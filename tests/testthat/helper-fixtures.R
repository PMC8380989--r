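# Shared fixtures and independent oracles for the test suite.

# All permutations of 1..n (independent of the C++ enumeration order).
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  out <- NULL
  for (i in seq_len(n)) {
    rest <- seq_len(n)[-i]
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

# Direct evaluation of the directed Gini correlation definition on
# tie-free data: order x by ascending y in the numerator, by itself in
# the denominator. Independent of the package's implementation.
oracle_gcc <- function(x, y) {
  n <- length(x)
  w <- 2 * seq_len(n) - n - 1
  sum(w * x[order(y)]) / sum(w * x[order(x)])
}

# Brute-force exhaustive permutation p-value of the symmetrized |GCC|.
oracle_perm_p <- function(x, y) {
  n <- length(x)
  sym <- function(a, b) {
    g1 <- oracle_gcc(a, b); g2 <- oracle_gcc(b, a)
    if (abs(g2) > abs(g1)) g2 else g1
  }
  obs <- abs(sym(x, y))
  pm <- all_perms(n)
  hits <- sum(apply(pm, 1, function(p) abs(sym(x, y[p])) >= obs - 1e-9))
  hits / nrow(pm)
}

# Small noiseless dataset used across modules.
noiseless_dataset <- function(...) {
  generate_dataset(sim_config(noise_cv = 0, ...))
}

# Stage + segment series combined into one pair of matrices, for the
# cross-series cumulative models.
two_series_dataset <- function(noise_cv = 0, seed = 1) {
  st <- generate_dataset(sim_config(noise_cv = noise_cv, seed = seed))
  sg <- generate_dataset(sim_config(noise_cv = noise_cv, seed = seed + 1,
                                    positions = c("S3", "S2", "S1"),
                                    series = "segment"))
  expr <- expression_matrix(rbind(st$expression$keys, sg$expression$keys),
                            rbind(st$expression$values,
                                  sg$expression$values))
  traits <- trait_matrix(rbind(st$traits$keys, sg$traits$keys),
                         rbind(st$traits$values, sg$traits$values),
                         st$traits$traits)
  list(expression = expr, traits = traits, truth = st$truth)
}
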