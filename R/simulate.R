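#' Configuration for the synthetic developmental dataset
#'
#' The generator emulates the statistical structure the lag analysis
#' assumes: several genotypes measured in biological replicate along an
#' ordered pseudo-time series; transcript abundance following a shared
#' unimodal pulse peaking mid-series (scaled per gene and per genotype,
#' with one "upland-like" genotype at a lower scale); lagged cumulative
#' deposition of lignin and pCA driven by the pathway-mean expression
#' `d` positions earlier; a concurrent trait (FA) tracking expression
#' with no lag; enzymatic digestibility declining linearly in the
#' accumulated phenolics; and multiplicative lognormal measurement noise
#' with a fixed coefficient of variation.
#'
#' @param n_genotypes number of genotypes (default 3).
#' @param n_replicates biological replicates per genotype (default 3).
#' @param positions ordered position labels, young to old (default
#'   `c("V3","E4","R3")`).
#' @param series series kind for the keys, `"stage"` or `"segment"`.
#' @param lag integer deposition lag `d` in positions (default 1); must
#'   be smaller than the number of positions.
#' @param expression_peak 0-based position index of the expression
#'   maximum (default 1, the middle of a 3-point series).
#' @param rise_ratio,fall_ratio per-step ratios of the expression pulse
#'   before/after the peak (defaults 0.5 and 1/3, giving the roughly
#'   twofold and threefold peak contrasts typical of mid-elongation
#'   expression maxima).
#' @param genotype_scale multiplicative expression scale per genotype;
#'   default `c(1, 0.9, 0.65)` (the last genotype is the low-expression,
#'   upland-like one).
#' @param gene_amplitude per-gene amplitudes; default a geometric spread
#'   over 11 phenylpropanoid-pathway transcripts.
#' @param lignin_baseline,lignin_gain,pca_baseline,pca_gain baseline and
#'   deposition gain (kappa) of the two lagged cumulative traits.
#' @param fa_baseline,fa_gain affine coefficients of the concurrent trait.
#' @param ed_baseline digestibility baselines for ED16/ED24/ED48.
#' @param ed_slope_lignin,ed_slope_pca linear decline of digestibility
#'   per unit of accumulated lignin and pCA.
#' @param noise_cv coefficient of variation of the multiplicative
#'   lognormal noise (default 0.2; 0 gives a noiseless closed-form
#'   oracle dataset).
#' @param n_polysaccharide optional count of structureless (white noise)
#'   monosaccharide columns appended to the trait matrix (default 0).
#' @param seed integer RNG seed.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genotypes = 3, n_replicates = 3,
                       positions = c("V3", "E4", "R3"),
                       series = "stage",
                       lag = 1, expression_peak = 1,
                       rise_ratio = 0.5, fall_ratio = 1 / 3,
                       genotype_scale = c(1, 0.9, 0.65),
                       gene_amplitude = NULL,
                       lignin_baseline = 40, lignin_gain = 80,
                       pca_baseline = 5, pca_gain = 12,
                       fa_baseline = 2, fa_gain = 3,
                       ed_baseline = c(ED16 = 250, ED24 = 300, ED48 = 350),
                       ed_slope_lignin = 0.5, ed_slope_pca = 1,
                       noise_cv = 0.2, n_polysaccharide = 0, seed = 1) {
  if (is.null(gene_amplitude)) {
    genes <- c("4CL", "C3H", "C4H", "CAD", "CCoAOMT", "CCR1", "F5H",
               "HCT", "COMT1", "COMT2", "COMT3")
    gene_amplitude <- setNames(
      exp(seq(log(0.5), log(2), length.out = length(genes))), genes)
  }
  if (length(genotype_scale) != n_genotypes) {
    genotype_scale <- rep_len(genotype_scale, n_genotypes)
  }
  cfg <- structure(list(
    n_genotypes = n_genotypes, n_replicates = n_replicates,
    positions = positions, series = series, lag = as.integer(lag),
    expression_peak = expression_peak,
    rise_ratio = rise_ratio, fall_ratio = fall_ratio,
    genotype_scale = genotype_scale, gene_amplitude = gene_amplitude,
    lignin_baseline = lignin_baseline, lignin_gain = lignin_gain,
    pca_baseline = pca_baseline, pca_gain = pca_gain,
    fa_baseline = fa_baseline, fa_gain = fa_gain,
    ed_baseline = ed_baseline,
    ed_slope_lignin = ed_slope_lignin, ed_slope_pca = ed_slope_pca,
    noise_cv = noise_cv, n_polysaccharide = n_polysaccharide,
    seed = as.integer(seed)), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$lag < 0 || cfg$lag >= length(cfg$positions)) {
    stop("config error: lag must satisfy 0 <= lag < number of positions",
         call. = FALSE)
  }
  if (cfg$noise_cv < 0) stop("config error: noise_cv must be >= 0",
                             call. = FALSE)
  gains <- c(cfg$lignin_gain, cfg$pca_gain, cfg$fa_gain,
             cfg$genotype_scale, cfg$gene_amplitude,
             cfg$rise_ratio, cfg$fall_ratio)
  if (any(gains <= 0)) stop("config error: gains and scales must be > 0",
                            call. = FALSE)
  if (cfg$expression_peak < 0 ||
      cfg$expression_peak >= length(cfg$positions)) {
    stop("config error: expression_peak outside the series", call. = FALSE)
  }
  invisible(cfg)
}

# Shared unimodal pulse over 0-based positions; maximum at the peak.
sim_pulse <- function(cfg) {
  t <- seq_along(cfg$positions) - 1
  ifelse(t <= cfg$expression_peak,
         cfg$rise_ratio^(cfg$expression_peak - t),
         cfg$fall_ratio^(t - cfg$expression_peak))
}

sim_keys <- function(cfg) {
  grid <- expand.grid(replicate = seq_len(cfg$n_replicates),
                      position = seq_along(cfg$positions) - 1L,
                      genotype = sim_genotype_labels(cfg),
                      stringsAsFactors = FALSE)
  keys <- sample_keys(grid$genotype, cfg$series, grid$position,
                      grid$replicate)
  keys <- keys[canonical_order(keys), , drop = FALSE]
  rownames(keys) <- NULL
  keys
}

sim_genotype_labels <- function(cfg) {
  if (cfg$n_genotypes == 3) c("A4", "AP13", "VS16")
  else sprintf("G%02d", seq_len(cfg$n_genotypes))
}

# Mean-one multiplicative lognormal noise factors for a given CV.
lognormal_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sigma <- sqrt(log(1 + cv^2))
  exp(rnorm(n, mean = -sigma^2 / 2, sd = sigma))
}

# Noiseless genotype mean profiles: genes x positions x genotypes
sim_mean_expression <- function(cfg) {
  pulse <- sim_pulse(cfg)
  amp <- cfg$gene_amplitude
  arr <- array(0, dim = c(length(amp), length(pulse), cfg$n_genotypes),
               dimnames = list(names(amp), cfg$positions,
                               sim_genotype_labels(cfg)))
  for (j in seq_len(cfg$n_genotypes)) {
    arr[, , j] <- outer(amp, pulse) * cfg$genotype_scale[j]
  }
  arr
}

#' Simulate relative expression along the developmental series
#'
#' Per gene g and genotype j the mean profile is
#' `amplitude_g * scale_j * pulse(t)` with a shared unimodal pulse whose
#' maximum sits at `expression_peak`; replicate values multiply the mean
#' by mean-one lognormal noise. Deterministic given `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return An [expression_matrix()].
#' @export
simulate_expression <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(derive_seed(cfg$seed, 1L))
  keys <- sim_keys(cfg)
  mu <- sim_mean_expression(cfg)
  genes <- rownames(mu)
  values <- matrix(0, nrow(keys), length(genes),
                   dimnames = list(NULL, genes))
  for (i in seq_len(nrow(keys))) {
    values[i, ] <- mu[, keys$position[i] + 1L, keys$genotype[i]]
  }
  values <- values * matrix(lognormal_noise(length(values), cfg$noise_cv),
                            nrow(values), ncol(values))
  expression_matrix(keys, values)
}

# Noiseless trait means per genotype x position; columns are traits.
sim_mean_traits <- function(cfg) {
  mu <- sim_mean_expression(cfg)
  gbar <- apply(mu, c(2, 3), mean)  # positions x genotypes, pathway mean
  npos <- length(cfg$positions)
  lab <- sim_genotype_labels(cfg)
  out <- list()
  for (j in seq_along(lab)) {
    g <- gbar[, j]
    lag_cum <- vapply(seq_len(npos), function(t) {
      upto <- t - cfg$lag  # positions tau <= t - d (1-based count)
      if (upto < 1) 0 else sum(g[seq_len(upto)])
    }, 0)
    lignin <- cfg$lignin_baseline + cfg$lignin_gain * lag_cum
    pca <- cfg$pca_baseline + cfg$pca_gain * lag_cum
    fa <- cfg$fa_baseline + cfg$fa_gain * g
    ed <- vapply(cfg$ed_baseline, function(e0) {
      pmax(0, e0 - cfg$ed_slope_lignin * lignin - cfg$ed_slope_pca * pca)
    }, numeric(npos))
    m <- cbind(lignin = lignin, pCA = pca, FA = fa, ed)
    out[[lab[j]]] <- m
  }
  out
}

sim_trait_meta <- function(cfg) {
  base <- data.frame(
    name = c("lignin", "pCA", "FA", names(cfg$ed_baseline)),
    class = c("lignin", "HCA", "HCA",
              rep("digestibility", length(cfg$ed_baseline))),
    units = c(rep("ug/mg AIR", 3),
              rep("ug/mg reducing sugar", length(cfg$ed_baseline))),
    stringsAsFactors = FALSE
  )
  if (cfg$n_polysaccharide > 0) {
    base <- rbind(base, data.frame(
      name = sprintf("PS%d", seq_len(cfg$n_polysaccharide)),
      class = "polysaccharide", units = "ug/mg AIR",
      stringsAsFactors = FALSE))
  }
  base
}

#' Simulate cell wall traits consistent with an expression matrix
#'
#' Lagged cumulative traits (lignin, pCA) accumulate the pathway-mean
#' expression from `lag` positions earlier, so the trait increment at
#' position t reflects expression at t - lag. The concurrent trait (FA)
#' is an increasing affine function of current pathway-mean expression.
#' Digestibility declines linearly in accumulated lignin and pCA,
#' truncated at zero. Deterministic means use the noiseless expression
#' profiles; replicate values multiply in mean-one lognormal noise.
#'
#' @param cfg a [sim_config()]; must be the configuration `expr` was
#'   generated from.
#' @param expr the matching [expression_matrix()] (keys are checked).
#' @return A [trait_matrix()].
#' @export
simulate_cellwall <- function(cfg, expr) {
  validate_sim_config(cfg)
  keys <- sim_keys(cfg)
  if (!identical(key_id(keys), key_id(expr$keys))) {
    stop("alignment error: expression keys do not match the configuration",
         call. = FALSE)
  }
  set.seed(derive_seed(cfg$seed, 2L))
  means <- sim_mean_traits(cfg)
  meta <- sim_trait_meta(cfg)
  values <- matrix(NA_real_, nrow(keys), nrow(meta),
                   dimnames = list(NULL, meta$name))
  core <- setdiff(meta$name, sprintf("PS%d", seq_len(cfg$n_polysaccharide)))
  for (i in seq_len(nrow(keys))) {
    values[i, core] <- means[[keys$genotype[i]]][keys$position[i] + 1L, core]
  }
  if (cfg$n_polysaccharide > 0) {
    ps <- sprintf("PS%d", seq_len(cfg$n_polysaccharide))
    values[, ps] <- 30  # flat mean: structureless control columns
  }
  values <- values * matrix(lognormal_noise(length(values), cfg$noise_cv),
                            nrow(values), ncol(values))
  trait_matrix(keys, values, meta)
}

#' Generate a complete synthetic dataset with its ground truth
#'
#' Runs [simulate_expression()] and [simulate_cellwall()] and returns a
#' machine-readable truth record for parameter-recovery tests: the true
#' lag, the expected correlation sign of every lag-informative trait
#' (positive for the accumulating phenolics, negative for
#' digestibility), and the concurrent traits whose lagged-change sign is
#' a construction artifact rather than a recoverable parameter.
#'
#' @param cfg a [sim_config()].
#' @return A list with `expression`, `traits`, and `truth`.
#' @export
generate_dataset <- function(cfg = sim_config()) {
  expr <- simulate_expression(cfg)
  traits <- simulate_cellwall(cfg, expr)
  truth <- list(
    lag = cfg$lag,
    expected_sign = c(
      lignin = 1, pCA = 1,
      setNames(rep(-1, length(cfg$ed_baseline)), names(cfg$ed_baseline))),
    concurrent_traits = "FA",
    expression_peak = cfg$expression_peak,
    noise_cv = cfg$noise_cv,
    seed = cfg$seed
  )
  list(expression = expr, traits = traits, truth = truth)
}
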