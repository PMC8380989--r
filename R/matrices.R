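#' Trait matrix: samples by cell wall variables
#'
#' Couples a sample key table with a numeric matrix of trait values and
#' per-trait metadata (class and units). Trait classes follow the cell
#' wall vocabulary: `"lignin"`, `"HCA"` (hydroxycinnamic acids pCA/FA),
#' `"digestibility"` (enzymatic digestibility yields), and
#' `"polysaccharide"` (monosaccharide components). Missing values are
#' allowed and are dropped pairwise downstream.
#'
#' @param keys key `data.frame` (see [sample_keys()]).
#' @param values numeric matrix, rows matching `keys`, columns traits.
#' @param traits `data.frame` with columns `name`, `class`, `units`;
#'   defaults to unclassified traits named from `colnames(values)`.
#' @return An object of class `trait_matrix`.
#' @export
trait_matrix <- function(keys, values, traits = NULL) {
  validate_keys(keys)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(traits)) {
    traits <- data.frame(name = colnames(values),
                         class = "polysaccharide",
                         units = NA_character_,
                         stringsAsFactors = FALSE)
  }
  obj <- structure(list(keys = keys, values = values, traits = traits),
                   class = "trait_matrix")
  validate_trait_matrix(obj)
  obj
}

trait_classes <- c("lignin", "HCA", "digestibility", "polysaccharide")

validate_trait_matrix <- function(x) {
  if (nrow(x$keys) != nrow(x$values)) {
    stop("row count of values must equal key count", call. = FALSE)
  }
  if (nrow(x$traits) != ncol(x$values)) {
    stop("trait metadata rows must equal value columns", call. = FALSE)
  }
  if (!all(x$traits$class %in% trait_classes)) {
    stop("trait classes must be one of: ",
         paste(trait_classes, collapse = ", "), call. = FALSE)
  }
  if (!identical(colnames(x$values), x$traits$name)) {
    colnames(x$values) <- x$traits$name
  }
  conc <- x$values[, x$traits$class %in%
                     c("lignin", "HCA", "digestibility"), drop = FALSE]
  if (any(conc < 0, na.rm = TRUE)) {
    stop("concentration and digestibility values must be >= 0", call. = FALSE)
  }
  invisible(x)
}

#' Expression matrix: samples by transcripts
#'
#' Relative expression values (dimensionless, strictly positive so they
#' are log-transformable), typically efficiency-adjusted delta-Cq ratios
#' against a reference transcript.
#'
#' @param keys key `data.frame` (see [sample_keys()]).
#' @param values numeric matrix, rows matching `keys`, columns transcripts.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(keys, values) {
  validate_keys(keys)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(keys) != nrow(values)) {
    stop("row count of values must equal key count", call. = FALSE)
  }
  if (any(values <= 0, na.rm = TRUE)) {
    stop("relative expression must be strictly positive", call. = FALSE)
  }
  structure(list(keys = keys, values = values,
                 transcripts = colnames(values)),
            class = "expression_matrix")
}

#' @export
print.trait_matrix <- function(x, ...) {
  cat("trait_matrix:", nrow(x$values), "samples x", ncol(x$values),
      "traits\n")
  cat("classes:", paste(sprintf("%s:%d", names(table(x$traits$class)),
                                table(x$traits$class)), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix:", nrow(x$values), "samples x", ncol(x$values),
      "transcripts\n")
  invisible(x)
}

#' Align two sample-keyed matrices
#'
#' Returns the keys present in both objects, in canonical order, together
#' with the row indices into each input and the keys dropped from either
#' side. Used to pair expression and trait measurements of the same
#' biological samples.
#'
#' @param a,b `trait_matrix` or `expression_matrix` objects.
#' @return A list with `keys` (canonical common keys), `idx_a`, `idx_b`
#'   (row indices into `a` and `b`), and `dropped_a`, `dropped_b`.
#' @export
align_samples <- function(a, b) {
  ida <- key_id(a$keys)
  idb <- key_id(b$keys)
  common <- intersect(ida, idb)
  if (length(common) == 0) {
    stop("no sample keys in common; cannot align", call. = FALSE)
  }
  keys <- a$keys[match(common, ida), , drop = FALSE]
  ord <- canonical_order(keys)
  keys <- keys[ord, , drop = FALSE]
  rownames(keys) <- NULL
  common <- common[ord]
  list(
    keys = keys,
    idx_a = match(common, ida),
    idx_b = match(common, idb),
    dropped_a = a$keys[!(ida %in% common), , drop = FALSE],
    dropped_b = b$keys[!(idb %in% common), , drop = FALSE]
  )
}
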