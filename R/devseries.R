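#' Declare one lag model relating expression to cell wall traits
#'
#' Three model families relate gene expression (GE) at series position N
#' to cell wall (CW) traits:
#' \describe{
#'   \item{concurrent}{GE(N) vs CW(N), same sample (`k = 0`).}
#'   \item{delta}{GE(N) vs CW(N+k) - CW(N): expression versus the
#'     subsequent change in the trait (`k >= 1`).}
#'   \item{cumulative}{GE(N) vs the CW level at N+k, or at explicitly
#'     fixed GE/CW positions (e.g. segment S1 expression against
#'     whole-tiller R3 composition).}
#' }
#' Pairing across positions is by (genotype, replicate) by default;
#' `"by_genotype_mean"` averages replicates first. `direction` controls
#' whether the offset runs young-to-old (default) or old-to-young (the
#' reversed reading of a segment series).
#'
#' @param name model label used in reports.
#' @param mode `"concurrent"`, `"delta"`, or `"cumulative"`.
#' @param k non-negative integer offset in series positions.
#' @param series series kind the model draws from (`"stage"` or
#'   `"segment"`); ignored when fixed positions name their own series.
#' @param genotypes optional genotype subset.
#' @param ge_fixed,cw_fixed optional fixed selectors, each a list with
#'   `series` and `position`, overriding the sliding offset (cumulative
#'   mode only).
#' @param pairing `"by_replicate"` or `"by_genotype_mean"`.
#' @param direction `"young_to_old"` or `"old_to_young"`.
#' @param q_cutoff significance cutoff attached to the model's records;
#'   defaults to 0.05 for delta models and 0.01 otherwise (the change
#'   versus cumulative conventions).
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(name, mode = c("concurrent", "delta", "cumulative"),
                       k = 0L, series = "stage", genotypes = NULL,
                       ge_fixed = NULL, cw_fixed = NULL,
                       pairing = c("by_replicate", "by_genotype_mean"),
                       direction = c("young_to_old", "old_to_young"),
                       q_cutoff = NULL) {
  mode <- match.arg(mode)
  pairing <- match.arg(pairing)
  direction <- match.arg(direction)
  k <- as.integer(k)
  fixed <- !is.null(ge_fixed) || !is.null(cw_fixed)
  if (mode == "concurrent" && k != 0L) {
    stop("concurrent mode requires k = 0", call. = FALSE)
  }
  if (mode %in% c("delta", "cumulative") && k < 1L && !fixed) {
    stop(mode, " mode requires k >= 1 unless positions are fixed",
         call. = FALSE)
  }
  if (is.null(q_cutoff)) q_cutoff <- if (mode == "delta") 0.05 else 0.01
  structure(list(name = name, mode = mode, k = k, series = series,
                 genotypes = genotypes, ge_fixed = ge_fixed,
                 cw_fixed = cw_fixed, pairing = pairing,
                 direction = direction, q_cutoff = q_cutoff),
            class = "model_spec")
}

select_rows <- function(keys, series = NULL, genotypes = NULL,
                        positions = NULL) {
  keep <- rep(TRUE, nrow(keys))
  if (!is.null(series)) keep <- keep & keys$series == series
  if (!is.null(genotypes)) keep <- keep & keys$genotype %in% genotypes
  if (!is.null(positions)) keep <- keep & keys$position %in% positions
  which(keep)
}

# Collapse replicates to genotype x position means.
mean_by_genotype <- function(keys, values) {
  grp <- paste(keys$genotype, keys$series, keys$position, sep = "|")
  ug <- unique(grp)
  out_keys <- keys[match(ug, grp), c("genotype", "series", "position")]
  out_keys$replicate <- 1L
  rownames(out_keys) <- NULL
  out_values <- do.call(rbind, lapply(ug, function(g) {
    colMeans(values[grp == g, , drop = FALSE], na.rm = TRUE)
  }))
  list(keys = out_keys, values = out_values)
}

prepare_model_inputs <- function(expr, traits, spec) {
  al <- align_samples(expr, traits)
  keys <- al$keys
  ge <- expr$values[al$idx_a, , drop = FALSE]
  cw <- traits$values[al$idx_b, , drop = FALSE]
  if (spec$pairing == "by_genotype_mean") {
    mg <- mean_by_genotype(keys, ge)
    mc <- mean_by_genotype(keys, cw)
    keys <- mg$keys
    ge <- mg$values
    cw <- mc$values
  }
  list(keys = keys, ge = ge, cw = cw,
       classes = setNames(traits$traits$class, traits$traits$name))
}

new_model_dataset <- function(spec, ge_keys, cw_keys, ge, cw,
                              outcome_kind, classes) {
  if (nrow(ge) == 0) {
    stop("empty-dataset error: model '", spec$name,
         "' selects no paired rows", call. = FALSE)
  }
  structure(list(spec = spec, ge_keys = ge_keys, cw_keys = cw_keys,
                 ge = ge, cw = cw, outcome_kind = outcome_kind,
                 outcome_classes = classes[colnames(cw)]),
            class = "model_dataset")
}

#' Build the concurrent model dataset (GE(N) vs CW(N))
#'
#' Pairs expression and trait values from the identical sample key.
#'
#' @param expr an [expression_matrix()].
#' @param traits a [trait_matrix()].
#' @param spec a [model_spec()] with mode `"concurrent"`.
#' @return A `model_dataset` with `outcome_kind = "level"`.
#' @export
build_concurrent <- function(expr, traits, spec) {
  inp <- prepare_model_inputs(expr, traits, spec)
  sel <- select_rows(inp$keys, spec$series, spec$genotypes)
  new_model_dataset(spec,
                    inp$keys[sel, , drop = FALSE],
                    inp$keys[sel, , drop = FALSE],
                    inp$ge[sel, , drop = FALSE],
                    inp$cw[sel, , drop = FALSE],
                    "level", inp$classes)
}

# positions ordered along the model's direction
ordered_positions <- function(keys, spec) {
  pos <- sort(unique(keys$position))
  if (spec$direction == "old_to_young") rev(pos) else pos
}

# Pair rows at position index i with rows at index i+k along the
# direction, matched within genotype (and replicate, unless averaged).
offset_pairs <- function(keys, spec) {
  pos <- ordered_positions(keys, spec)
  k <- spec$k
  if (k >= length(pos)) {
    stop("empty-dataset error: offset k = ", k,
         " exceeds the series span", call. = FALSE)
  }
  from <- integer(0); to <- integer(0)
  for (i in seq_len(length(pos) - k)) {
    a <- which(keys$position == pos[i])
    b <- which(keys$position == pos[i + k])
    mid_a <- paste(keys$genotype[a], keys$replicate[a])
    mid_b <- paste(keys$genotype[b], keys$replicate[b])
    m <- match(mid_a, mid_b)
    keep <- !is.na(m)
    from <- c(from, a[keep])
    to <- c(to, b[m[keep]])
  }
  list(from = from, to = to)
}

#' Build a delta model dataset (GE(N) vs CW(N+k) - CW(N))
#'
#' Expression at position N is paired with the change in each trait
#' between N and N+k, matched within genotype and replicate, with
#' transitions enumerated over every valid N.
#'
#' @inheritParams build_concurrent
#' @param spec a [model_spec()] with mode `"delta"` and `k >= 1`.
#' @return A `model_dataset` with `outcome_kind = "delta"`.
#' @export
build_delta <- function(expr, traits, spec) {
  if (spec$mode == "delta" && spec$k < 1L) {
    stop("delta mode with k = 0 is degenerate (all-zero outcomes)",
         call. = FALSE)
  }
  inp <- prepare_model_inputs(expr, traits, spec)
  sel <- select_rows(inp$keys, spec$series, spec$genotypes)
  keys <- inp$keys[sel, , drop = FALSE]
  pr <- offset_pairs(keys, spec)
  new_model_dataset(spec,
                    keys[pr$from, , drop = FALSE],
                    keys[pr$to, , drop = FALSE],
                    inp$ge[sel, , drop = FALSE][pr$from, , drop = FALSE],
                    inp$cw[sel, , drop = FALSE][pr$to, , drop = FALSE] -
                      inp$cw[sel, , drop = FALSE][pr$from, , drop = FALSE],
                    "delta", inp$classes)
}

#' Build a cumulative model dataset (GE(N) vs CW(N+k) levels)
#'
#' Expression at position N (or at a fixed selector, e.g. segment S1) is
#' paired with the trait level at position N+k (or at a fixed selector,
#' e.g. stage R3). Fixed selectors are matched by genotype and
#' replicate, which allows pairing across series kinds. `k = 0` with no
#' fixed selectors is identical to the concurrent model.
#'
#' @inheritParams build_concurrent
#' @param spec a [model_spec()] with mode `"cumulative"`.
#' @return A `model_dataset` with `outcome_kind = "level"`.
#' @export
build_cumulative <- function(expr, traits, spec) {
  inp <- prepare_model_inputs(expr, traits, spec)
  if (!is.null(spec$ge_fixed) || !is.null(spec$cw_fixed)) {
    ge_sel <- spec$ge_fixed %||% list(series = spec$series, position = NULL)
    cw_sel <- spec$cw_fixed %||% list(series = spec$series, position = NULL)
    a <- select_rows(inp$keys, ge_sel$series, spec$genotypes,
                     ge_sel$position)
    b <- select_rows(inp$keys, cw_sel$series, spec$genotypes,
                     cw_sel$position)
    mid_a <- paste(inp$keys$genotype[a], inp$keys$replicate[a])
    mid_b <- paste(inp$keys$genotype[b], inp$keys$replicate[b])
    m <- match(mid_a, mid_b)
    keep <- !is.na(m)
    from <- a[keep]; to <- b[m[keep]]
  } else {
    sel <- select_rows(inp$keys, spec$series, spec$genotypes)
    keys <- inp$keys[sel, , drop = FALSE]
    pr <- offset_pairs(keys, spec)
    from <- sel[pr$from]; to <- sel[pr$to]
  }
  new_model_dataset(spec,
                    inp$keys[from, , drop = FALSE],
                    inp$keys[to, , drop = FALSE],
                    inp$ge[from, , drop = FALSE],
                    inp$cw[to, , drop = FALSE],
                    "level", inp$classes)
}

#' Build the dataset a model spec describes
#'
#' Dispatches on the spec's mode.
#'
#' @inheritParams build_concurrent
#' @param spec a [model_spec()].
#' @return A `model_dataset`.
#' @export
build_model_dataset <- function(expr, traits, spec) {
  switch(spec$mode,
         concurrent = build_concurrent(expr, traits, spec),
         delta = build_delta(expr, traits, spec),
         cumulative = build_cumulative(expr, traits, spec))
}

#' Run the correlation family of one model dataset
#'
#' One correlation record per (gene, CW outcome) pair — e.g. 11 genes x
#' 6 traits = 66 tests for the full panel — with permutation p-values
#' and q-values computed within this model's family only. Pairs with
#' constant values or fewer than 3 complete rows are flagged in
#' `status`, never silently zeroed.
#'
#' @param ds a `model_dataset`.
#' @param B,exhaustive_threshold,seed see [permutation_pvalue()].
#' @return A `data.frame` of correlation records with columns `model`,
#'   `gene`, `outcome`, `outcome_class`, `n`, `gcc_xy`, `gcc_yx`, `gcc`,
#'   `direction`, `pcc`, `scc`, `p`, `q`, `q_cutoff`, `status`.
#' @export
run_model <- function(ds, B = 2000, exhaustive_threshold = 6, seed = NULL) {
  if (nrow(ds$ge) < 3) {
    stop("insufficient-data error: fewer than 3 rows", call. = FALSE)
  }
  genes <- colnames(ds$ge)
  outcomes <- colnames(ds$cw)
  grid <- expand.grid(gene = genes, outcome = outcomes,
                      stringsAsFactors = FALSE)
  rec <- data.frame(
    model = ds$spec$name, gene = grid$gene, outcome = grid$outcome,
    outcome_class = unname(ds$outcome_classes[grid$outcome]),
    n = NA_integer_, gcc_xy = NA_real_, gcc_yx = NA_real_, gcc = NA_real_,
    direction = NA_character_, pcc = NA_real_, scc = NA_real_,
    p = NA_real_, q = NA_real_, q_cutoff = ds$spec$q_cutoff, status = "ok",
    stringsAsFactors = FALSE
  )
  for (i in seq_len(nrow(grid))) {
    x <- ds$ge[, grid$gene[i]]
    y <- ds$cw[, grid$outcome[i]]
    sub_seed <- if (is.null(seed)) NULL else
      derive_seed(seed, paste(grid$gene[i], grid$outcome[i], sep = "|"))
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
    rec$pcc[i] <- suppressWarnings(cor(x[ok], y[ok]))
    rec$scc[i] <- suppressWarnings(cor(x[ok], y[ok], method = "spearman"))
    rec$p[i] <- res$p
  }
  ok <- !is.na(rec$p)
  if (any(ok)) rec$q[ok] <- fdr_qvalues(rec$p[ok])
  rec
}

#' Matrix of significant coefficients, genes by outcomes
#'
#' Reshapes a model's records into the gene x outcome display matrix of
#' symmetrized GCCs, keeping only records with `q` below the model's
#' cutoff (others are NA).
#'
#' @param records output of [run_model()].
#' @param q_cutoff cutoff; defaults to the records' attached cutoff.
#' @return A numeric matrix, genes in rows, outcomes in columns.
#' @export
significant_gcc_matrix <- function(records, q_cutoff = NULL) {
  q_cutoff <- q_cutoff %||% records$q_cutoff[1]
  genes <- unique(records$gene)
  outcomes <- unique(records$outcome)
  m <- matrix(NA_real_, length(genes), length(outcomes),
              dimnames = list(genes, outcomes))
  sig <- !is.na(records$q) & records$q < q_cutoff
  m[cbind(match(records$gene[sig], genes),
          match(records$outcome[sig], outcomes))] <- records$gcc[sig]
  m
}
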