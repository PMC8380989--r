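#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA (equal-variance F test) of a
#' response across group labels, the per-trait comparison behind
#' letter-annotated group mean tables.
#'
#' @param values numeric response vector.
#' @param groups group labels, same length.
#' @return A list with `F`, `p`, `df_between`, `df_within`.
#' @export
anova_oneway <- function(values, groups) {
  ok <- complete.cases(values, groups)
  values <- values[ok]
  groups <- factor(groups[ok])
  k <- nlevels(groups)
  n <- length(values)
  if (k < 2 || n - k < 2) {
    stop("insufficient-data error: need >= 2 groups and >= 2 residual df",
         call. = FALSE)
  }
  gm <- tapply(values, groups, mean)
  ssw <- sum((values - gm[groups])^2)
  if (ssw == 0) {
    stop("zero residual variance: F undefined", call. = FALSE)
  }
  fit <- oneway.test(values ~ groups, var.equal = TRUE)
  list(F = unname(fit$statistic), p = unname(fit$p.value),
       df_between = k - 1, df_within = n - k)
}

#' Tukey-Kramer pairwise comparisons
#'
#' All pairwise group comparisons after one-way ANOVA, using the
#' studentized range distribution with Tukey-Kramer standard errors for
#' unbalanced groups:
#' \eqn{q_{ij} = |\bar y_i - \bar y_j| / \sqrt{(MSE/2)(1/n_i + 1/n_j)}}.
#'
#' @inheritParams anova_oneway
#' @return A symmetric matrix of adjusted p-values with group names on
#'   both dimensions (diagonal NA).
#' @export
tukey_hsd <- function(values, groups) {
  ok <- complete.cases(values, groups)
  values <- values[ok]
  groups <- factor(groups[ok])
  k <- nlevels(groups)
  n <- length(values)
  if (k < 2 || n - k < 1) {
    stop("insufficient-data error for Tukey's range test", call. = FALSE)
  }
  means <- tapply(values, groups, mean)
  sizes <- tapply(values, groups, length)
  mse <- sum((values - means[groups])^2) / (n - k)
  if (mse == 0) stop("zero residual variance: range test undefined",
                     call. = FALSE)
  pm <- matrix(NA_real_, k, k, dimnames = list(levels(groups),
                                               levels(groups)))
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      se <- sqrt(mse / 2 * (1 / sizes[i] + 1 / sizes[j]))
      q <- abs(means[i] - means[j]) / se
      pm[i, j] <- pm[j, i] <- ptukey(q, nmeans = k, df = n - k,
                                     lower.tail = FALSE)
    }
  }
  pm
}

#' Compact letter display from a pairwise p-value matrix
#'
#' Insert-and-absorb letter assignment: groups sharing no letter differ
#' significantly at `alpha`; groups sharing at least one letter are not
#' declared different. Starting from one set holding all groups, each
#' significant pair splits every set containing both; sets contained in
#' others are absorbed; letters are assigned alphabetically. The output
#' is verified against the p matrix and an assignment failure is an
#' error, never a silent inconsistency.
#'
#' @param pmat symmetric matrix of pairwise p-values (as from
#'   [tukey_hsd()]).
#' @param alpha significance level (default 0.05).
#' @return Named character vector of letter strings per group.
#' @export
compact_letters <- function(pmat, alpha = 0.05) {
  k <- nrow(pmat)
  labels <- rownames(pmat)
  sets <- list(seq_len(k))
  sig_pairs <- which(upper.tri(pmat) & pmat < alpha, arr.ind = TRUE)
  if (nrow(sig_pairs) > 0) {
    for (r in seq_len(nrow(sig_pairs))) {
      i <- sig_pairs[r, 1]; j <- sig_pairs[r, 2]
      new_sets <- list()
      for (s in sets) {
        if (i %in% s && j %in% s) {
          new_sets <- c(new_sets, list(setdiff(s, i)), list(setdiff(s, j)))
        } else {
          new_sets <- c(new_sets, list(s))
        }
      }
      # absorb: drop duplicates and sets strictly contained in another
      new_sets <- unique(lapply(new_sets, sort))
      new_sets <- new_sets[lengths(new_sets) > 0]
      keep <- vapply(seq_along(new_sets), function(a) {
        !any(vapply(seq_along(new_sets), function(b) {
          b != a && all(new_sets[[a]] %in% new_sets[[b]])
        }, TRUE))
      }, TRUE)
      sets <- new_sets[keep]
    }
  }
  # assign letters in order of each set's first group, so the first
  # group always carries "a"
  sets <- sets[order(vapply(sets, min, 0L))]
  letters_out <- rep("", k)
  for (s in seq_along(sets)) {
    letters_out[sets[[s]]] <- paste0(letters_out[sets[[s]]],
                                     make_letter(s))
  }
  names(letters_out) <- labels
  # post-hoc verification of the display invariant
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      shared <- length(intersect(strsplit(letters_out[i], "")[[1]],
                                 strsplit(letters_out[j], "")[[1]])) > 0
      if (!is.na(pmat[i, j])) {
        if (pmat[i, j] < alpha && shared) {
          stop("letter assignment contradicts the p matrix", call. = FALSE)
        }
        if (pmat[i, j] >= alpha && !shared) {
          stop("letter assignment contradicts the p matrix", call. = FALSE)
        }
      }
    }
  }
  letters_out
}

make_letter <- function(i) {
  if (i <= 26) letters[i] else paste0(letters[(i - 1) %/% 26],
                                      letters[(i - 1) %% 26 + 1])
}

#' Group means with standard errors and compact letters
#'
#' The per-trait descriptive summary style of letter-annotated
#' composition tables: group mean, standard error, and a compact letter
#' display from Tukey-Kramer comparisons at `alpha`.
#'
#' @inheritParams anova_oneway
#' @param alpha significance level (default 0.05).
#' @return A `data.frame` with `group`, `n`, `mean`, `se`, `letters`.
#' @export
group_summary <- function(values, groups, alpha = 0.05) {
  ok <- complete.cases(values, groups)
  values <- values[ok]
  groups <- factor(groups[ok])
  cld <- compact_letters(tukey_hsd(values, groups), alpha)
  data.frame(
    group = levels(groups),
    n = as.integer(tapply(values, groups, length)),
    mean = as.numeric(tapply(values, groups, mean)),
    se = as.numeric(tapply(values, groups, sd) /
                      sqrt(tapply(values, groups, length))),
    letters = unname(cld[levels(groups)]),
    stringsAsFactors = FALSE
  )
}

#' Principal component analysis of a trait panel
#'
#' Eigen-decomposition via `princomp` of the correlation matrix by
#' default (`scale = TRUE`), because cell wall variables carry mixed
#' units; covariance mode is available. The sign indeterminacy of each
#' component is fixed deterministically: the largest-magnitude loading
#' of every component is made positive. Scores times transposed
#' loadings reconstructs the centered (and scaled) data.
#'
#' @param x numeric matrix or data.frame, samples by variables, no
#'   missing values.
#' @param scale use the correlation matrix (default TRUE).
#' @return A list of class `pca_result` with `scores`, `loadings`,
#'   `variance` (fractions summing to 1), `center`, `scale`.
#' @export
pca_traits <- function(x, scale = TRUE) {
  x <- as.matrix(x)
  if (nrow(x) < 2 || ncol(x) < 2) {
    stop("need >= 2 samples and >= 2 variables", call. = FALSE)
  }
  if (anyNA(x)) stop("missing values must be handled before PCA",
                     call. = FALSE)
  if (scale && any(apply(x, 2, sd) == 0)) {
    stop("domain error: constant column with scale = TRUE", call. = FALSE)
  }
  fit <- princomp(x, cor = scale)
  loadings <- unclass(fit$loadings)
  scores <- fit$scores
  for (c in seq_len(ncol(loadings))) {
    top <- which.max(abs(loadings[, c]))
    if (loadings[top, c] < 0) {
      loadings[, c] <- -loadings[, c]
      scores[, c] <- -scores[, c]
    }
  }
  structure(list(scores = scores, loadings = loadings,
                 variance = fit$sdev^2 / sum(fit$sdev^2),
                 center = fit$center,
                 scale = if (scale) fit$scale else rep(1, ncol(x))),
            class = "pca_result")
}
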