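#' Efficiency-adjusted relative expression from Cq values
#'
#' Converts quantification cycles to relative expression against a
#' reference transcript. Technical replicates are averaged on the Cq
#' scale (Cq noise is approximately additive in cycles), then
#' \deqn{R = E_{ref}^{Cq_{ref}} / E_{gene}^{Cq_{gene}}}
#' with per-amplicon amplification factors `E` (1 < E <= 2; E = 2 is
#' perfect doubling). With equal efficiencies this reduces to
#' \eqn{2^{-\Delta Cq}}, and adding a constant to every Cq of a sample
#' leaves R unchanged.
#'
#' @param cq `data.frame` with columns `genotype`, `series`, `position`,
#'   `replicate`, `gene`, `tech_rep`, `cq`.
#' @param efficiency `data.frame` with columns `gene` and `E`; must
#'   cover every assayed gene and the reference.
#' @param reference_gene reference transcript label (default `"Ubi10"`).
#' @return An [expression_matrix()] of the non-reference genes. Samples
#'   lacking a reference Cq are dropped with a warning.
#' @export
relative_expression <- function(cq, efficiency, reference_gene = "Ubi10") {
  need <- c("genotype", "series", "position", "replicate", "gene", "cq")
  if (!all(need %in% names(cq))) {
    stop("cq table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(cq$cq)) || any(cq$cq <= 0)) {
    stop("Cq values must be finite and > 0", call. = FALSE)
  }
  eff <- setNames(efficiency$E, efficiency$gene)
  genes <- unique(cq$gene)
  no_eff <- setdiff(genes, names(eff))
  if (length(no_eff) > 0) {
    stop("config error: missing efficiency for: ",
         paste(no_eff, collapse = ", "), call. = FALSE)
  }
  if (any(eff <= 1 | eff > 2)) {
    stop("amplification factors must satisfy 1 < E <= 2", call. = FALSE)
  }
  # average technical replicates on the Cq scale
  agg <- aggregate(cq ~ genotype + series + position + replicate + gene,
                   data = cq, FUN = mean)
  sid <- paste(agg$genotype, agg$series, agg$position, agg$replicate,
               sep = "|")
  samples <- unique(sid)
  targets <- setdiff(genes, reference_gene)
  if (length(targets) == 0) stop("no non-reference genes", call. = FALSE)
  keys_all <- unique(agg[, c("genotype", "series", "position", "replicate")])
  rownames(keys_all) <- NULL
  ref_rows <- agg$gene == reference_gene
  ref_cq <- setNames(agg$cq[ref_rows], sid[ref_rows])
  have_ref <- samples %in% names(ref_cq)
  if (any(!have_ref)) {
    warning(sum(!have_ref), " sample(s) dropped: no reference Cq",
            call. = FALSE)
  }
  samples <- samples[have_ref]
  keys <- keys_all[match(samples, key_id(keys_all)), , drop = FALSE]
  keys$position <- as.integer(keys$position)
  keys$replicate <- as.integer(keys$replicate)
  rownames(keys) <- NULL
  values <- matrix(NA_real_, length(samples), length(targets),
                   dimnames = list(NULL, targets))
  e_ref <- eff[[reference_gene]]
  for (g in targets) {
    rows <- agg$gene == g
    m <- match(sid[rows], samples)
    keep <- !is.na(m)
    values[m[keep], g] <-
      e_ref^ref_cq[sid[rows][keep]] / eff[[g]]^agg$cq[rows][keep]
  }
  ord <- canonical_order(keys)
  expression_matrix(keys[ord, , drop = FALSE],
                    values[ord, , drop = FALSE])
}

#' Elementwise log10 of a positive expression matrix
#'
#' The display transform used for relative-expression heat maps.
#'
#' @param expr an [expression_matrix()] or positive numeric matrix.
#' @return A numeric matrix of log10 values.
#' @export
log10_matrix <- function(expr) {
  values <- if (inherits(expr, "expression_matrix")) expr$values else
    as.matrix(expr)
  if (any(values <= 0, na.rm = TRUE)) {
    stop("domain error: log10 requires strictly positive values",
         call. = FALSE)
  }
  log10(values)
}

#' Geometric mean expression per developmental group
#'
#' Summarizes relative expression by pseudo-time position: the geometric
#' mean across all genes and samples of each group, plus the matrix of
#' between-group ratios (how many fold higher one position is than
#' another).
#'
#' @param expr an [expression_matrix()].
#' @param series restrict to one series kind (`"stage"`, `"segment"`,
#'   or `NULL` for all samples).
#' @return A list with `summary` (`data.frame`: position, n_values,
#'   geomean) and `ratios` (position x position matrix of geomean
#'   ratios).
#' @export
geometric_mean_summary <- function(expr, series = NULL) {
  keys <- expr$keys
  values <- expr$values
  if (!is.null(series)) {
    keep <- keys$series == series
    keys <- keys[keep, , drop = FALSE]
    values <- values[keep, , drop = FALSE]
  }
  positions <- sort(unique(keys$position))
  geo <- vapply(positions, function(p) {
    v <- values[keys$position == p, , drop = FALSE]
    v <- v[!is.na(v)]
    if (length(v) == 0) NA_real_ else exp(mean(log(v)))
  }, 0)
  ratios <- outer(geo, geo, `/`)
  dimnames(ratios) <- list(positions, positions)
  list(
    summary = data.frame(position = positions,
                         n_values = vapply(positions, function(p)
                           sum(!is.na(values[keys$position == p, ])), 0L),
                         geomean = geo),
    ratios = ratios
  )
}
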