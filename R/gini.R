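#' Directed Gini correlation coefficient
#'
#' The Gini correlation of `x` conditioned on the ranks of `y`:
#' \deqn{GCC(x|y) = \frac{\sum_i (2 r_i(y) - n - 1)\, x_i}
#'                      {\sum_i (2 i - n - 1)\, x_{(i)}}}
#' where \eqn{r_i(y)} is the (tie-averaged) rank of \eqn{y_i} and the
#' denominator orders `x` by itself. The statistic mixes the value
#' information of `x` with the rank information of `y`, is asymmetric in
#' its arguments, lies in \eqn{[-1, 1]}, equals +1 whenever `y` is a
#' strictly increasing function of `x`, and is invariant to strictly
#' increasing transforms of `y` and positive affine transforms of `x`.
#' Missing pairs are removed before computation.
#'
#' @param x numeric vector supplying values.
#' @param y numeric vector supplying ranks; same length as `x`.
#' @return A single numeric value in `[-1, 1]`.
#' @seealso [gcc_symmetric()], [permutation_pvalue()]
#' @export
gcc_directed <- function(x, y) {
  xy <- drop_incomplete(x, y)
  x <- xy$x; y <- xy$y
  n <- length(x)
  w <- 2 * rank(y, ties.method = "average") - n - 1
  # iterate both sums in x-ascending order so that perfectly co- and
  # anti-monotone pairs return exactly +1 / -1
  ox <- order(x)
  den <- sum((2 * seq_len(n) - n - 1) * x[ox])
  if (den == 0) {
    stop("constant input: Gini correlation undefined", call. = FALSE)
  }
  sum(w[ox] * x[ox]) / den
}

drop_incomplete <- function(x, y) {
  if (length(x) != length(y)) {
    stop("x and y must have the same length", call. = FALSE)
  }
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) {
    stop("insufficient data: fewer than 3 complete pairs", call. = FALSE)
  }
  list(x = x, y = y)
}

#' Symmetrized Gini correlation
#'
#' Both directed values are computed and the one with larger absolute
#' magnitude is reported, ties broken toward `GCC(x|y)`. The reporting
#' rule is a package convention (a single coefficient per pair is needed
#' for tables and networks); both directed values are returned alongside.
#'
#' @inheritParams gcc_directed
#' @return A list with `gcc` (reported value), `direction` (`"xy"` or
#'   `"yx"`), `gcc_xy`, and `gcc_yx`.
#' @export
gcc_symmetric <- function(x, y) {
  gxy <- gcc_directed(x, y)
  gyx <- gcc_directed(y, x)
  if (abs(gyx) > abs(gxy)) {
    list(gcc = gyx, direction = "yx", gcc_xy = gxy, gcc_yx = gyx)
  } else {
    list(gcc = gxy, direction = "xy", gcc_xy = gxy, gcc_yx = gyx)
  }
}

#' Permutation p-value for the symmetrized Gini correlation
#'
#' Tests the null of no association by permuting `y`. With `n` at or
#' below `exhaustive_threshold` all `n!` permutations are enumerated and
#' the p-value is the exact null fraction with \eqn{|GCC^*| \ge |GCC|}
#' (the identity permutation guarantees p >= 1/n!). Otherwise `B` Monte
#' Carlo permutations are drawn and the add-one estimate
#' \eqn{p = (1 + \#\{|GCC^*_b| \ge |GCC|\})/(B+1)} is returned, which is
#' never zero and never below `1/(B+1)`. Draws use R's RNG, so results
#' are deterministic under `set.seed()` (or the `seed` argument).
#'
#' @inheritParams gcc_directed
#' @param B number of Monte Carlo permutations (default 2000).
#' @param exhaustive_threshold enumerate all permutations when the paired
#'   sample count is at or below this (default 6; 6! = 720).
#' @param seed optional integer seed applied before sampling.
#' @return A list with `gcc`, `gcc_xy`, `gcc_yx`, `direction`, `p`, `n`,
#'   `exhaustive`, and `n_perm`.
#' @export
permutation_pvalue <- function(x, y, B = 2000, exhaustive_threshold = 6,
                               seed = NULL) {
  stopifnot(B >= 1)
  xy <- drop_incomplete(x, y)
  if (!is.null(seed)) set.seed(seed)
  res <- gcc_perm_cpp(xy$x, xy$y, as.integer(B),
                      as.integer(exhaustive_threshold))
  sym <- if (abs(res$gcc_yx) > abs(res$gcc_xy)) {
    list(gcc = res$gcc_yx, direction = "yx")
  } else {
    list(gcc = res$gcc_xy, direction = "xy")
  }
  list(gcc = sym$gcc, gcc_xy = res$gcc_xy, gcc_yx = res$gcc_yx,
       direction = sym$direction, p = res$p, n = length(xy$x),
       exhaustive = res$exhaustive, n_perm = res$n_perm)
}

#' False discovery rate q-values
#'
#' Storey-style q-values \eqn{q_i = \pi_0 \cdot \min_{j: p_j \ge p_i}
#' m\,p_j / \mathrm{rank}(p_j)}. \eqn{\pi_0} is estimated over a lambda
#' grid with a smoothing spline evaluated at the largest lambda; for
#' small test families (fewer than `storey_min_tests` tests, where the
#' estimate is unstable) the conservative \eqn{\pi_0 = 1} is used, which
#' makes the q-values exactly the Benjamini-Hochberg step-up values.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @param pi0 optional fixed null proportion overriding estimation.
#' @param storey_min_tests minimum family size for spline estimation of
#'   `pi0` (default 50).
#' @param lambda grid for the `pi0` estimate.
#' @return Numeric vector of q-values, same order as `p`; monotone
#'   non-decreasing in ranked `p` and never exceeding 1.
#' @export
fdr_qvalues <- function(p, pi0 = NULL, storey_min_tests = 50,
                        lambda = seq(0.05, 0.95, by = 0.05)) {
  m <- length(p)
  if (m == 0) return(numeric(0))
  if (any(is.na(p)) || any(p <= 0) || any(p > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  if (is.null(pi0)) {
    if (m < storey_min_tests) {
      pi0 <- 1
    } else {
      pi0_lambda <- vapply(lambda, function(l) mean(p > l) / (1 - l), 0)
      fit <- smooth.spline(lambda, pi0_lambda, df = 3)
      pi0 <- predict(fit, x = max(lambda))$y
      pi0 <- min(max(pi0, 1 / m), 1)
    }
  }
  pmin(1, pi0 * p.adjust(p, method = "BH"))
}

#' Gini correlations for a list of variable pairs
#'
#' Computes one correlation record per pair: directed and symmetrized
#' GCC, Pearson and Spearman cross-checks, permutation p-value, and an
#' FDR q-value computed within the family of all pairs tested here.
#' Pairs that fail (constant variable, fewer than 3 complete pairs) are
#' flagged via the `status` column, not dropped.
#'
#' @param data numeric matrix with named columns (samples x variables).
#' @param pairs two-column character matrix or data.frame of variable
#'   names; defaults to all unordered pairs of columns.
#' @param B,exhaustive_threshold,seed see [permutation_pvalue()]. Each
#'   pair receives a sub-seed derived from `seed` so records do not
#'   depend on evaluation order.
#' @return A `data.frame` with columns `x_name`, `y_name`, `n`, `gcc_xy`,
#'   `gcc_yx`, `gcc`, `direction`, `pcc`, `scc`, `p`, `q`, `status`.
#' @export
correlate_all <- function(data, pairs = NULL, B = 2000,
                          exhaustive_threshold = 6, seed = NULL) {
  data <- as.matrix(data)
  if (is.null(pairs)) {
    pairs <- t(combn(colnames(data), 2))
  }
  pairs <- as.matrix(pairs)
  npair <- nrow(pairs)
  rec <- data.frame(
    x_name = pairs[, 1], y_name = pairs[, 2],
    n = NA_integer_, gcc_xy = NA_real_, gcc_yx = NA_real_, gcc = NA_real_,
    direction = NA_character_, pcc = NA_real_, scc = NA_real_,
    p = NA_real_, q = NA_real_, status = "ok",
    stringsAsFactors = FALSE
  )
  for (i in seq_len(npair)) {
    x <- data[, pairs[i, 1]]
    y <- data[, pairs[i, 2]]
    sub_seed <- if (is.null(seed)) NULL else
      derive_seed(seed, paste(pairs[i, 1], pairs[i, 2], sep = "|"))
    res <- tryCatch(
      permutation_pvalue(x, y, B = B,
                         exhaustive_threshold = exhaustive_threshold,
                         seed = sub_seed),
      error = function(e) conditionMessage(e)
    )
    if (is.character(res)) {
      rec$status[i] <- res
      next
    }
    ok <- complete.cases(x, y)
    rec$n[i] <- res$n
    rec$gcc_xy[i] <- res$gcc_xy
    rec$gcc_yx[i] <- res$gcc_yx
    rec$gcc[i] <- res$gcc
    rec$direction[i] <- res$direction
    rec$pcc[i] <- cor(x[ok], y[ok], method = "pearson")
    rec$scc[i] <- cor(x[ok], y[ok], method = "spearman")
    rec$p[i] <- res$p
  }
  ok <- !is.na(rec$p)
  if (any(ok)) rec$q[ok] <- fdr_qvalues(rec$p[ok])
  rec
}

# Deterministic sub-seed fan-out; kept below 2^31. Character keys are
# hashed so per-pair seeds depend on the pair's identity, never on its
# position in an evaluation order.
derive_seed <- function(seed, key) {
  h <- if (is.character(key)) {
    Reduce(function(a, ch) (a * 31 + ch) %% 2147483647,
           utf8ToInt(key), accumulate = FALSE, init = 7)
  } else {
    as.double(key) * 16807
  }
  as.integer((as.double(seed) * 48271 + h) %% 2147483647)
}
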