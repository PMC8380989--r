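#' Sample keys for a developmental series
#'
#' A sample key identifies one biological sample by genotype, series kind
#' (`"stage"` for whole tillers, `"segment"` for internode segments of one
#' stage), an ordinal pseudo-time position (young to old), and a biological
#' replicate index. Keys are stored as a plain `data.frame` with columns
#' `genotype`, `series`, `position`, `replicate`.
#'
#' @param genotype character vector of genotype labels.
#' @param series character vector, each `"stage"` or `"segment"`.
#' @param position integer vector of ordinal pseudo-time positions (>= 0).
#' @param replicate integer vector of replicate indices (>= 1).
#' @return A validated key `data.frame`.
#' @examples
#' sample_keys("A4", "stage", 0L, 1L)
#' @export
sample_keys <- function(genotype, series, position, replicate) {
  keys <- data.frame(
    genotype = as.character(genotype),
    series = as.character(series),
    position = as.integer(position),
    replicate = as.integer(replicate),
    stringsAsFactors = FALSE
  )
  validate_keys(keys)
  keys
}

validate_keys <- function(keys) {
  need <- c("genotype", "series", "position", "replicate")
  missing_cols <- setdiff(need, names(keys))
  if (length(missing_cols) > 0) {
    stop("key columns missing: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!all(keys$series %in% c("stage", "segment"))) {
    stop("series must be 'stage' or 'segment'", call. = FALSE)
  }
  if (any(keys$position < 0L) || any(is.na(keys$position))) {
    stop("positions must be non-negative integers", call. = FALSE)
  }
  if (any(keys$replicate < 1L) || any(is.na(keys$replicate))) {
    stop("replicate indices must be >= 1", call. = FALSE)
  }
  if (anyDuplicated(keys[, need]) > 0) {
    stop("duplicate sample keys (genotype, series, position, replicate)",
         call. = FALSE)
  }
  invisible(keys)
}

#' Canonical ordering of sample keys
#'
#' The canonical order is (genotype, series, position, replicate),
#' each ascending. It is total and invariant to the input permutation.
#'
#' @param keys a key `data.frame` (see [sample_keys()]).
#' @return An integer permutation that sorts `keys` canonically.
#' @export
canonical_order <- function(keys) {
  order(keys$genotype, keys$series, keys$position, keys$replicate)
}

key_id <- function(keys) {
  paste(keys$genotype, keys$series, keys$position, keys$replicate, sep = "|")
}

#' Default position encodings for stage and segment series
#'
#' Whole-tiller stages V3, E4, R3 map to pseudo-time 0, 1, 2; segments of
#' the E4 tiller map S3 (top, youngest) = 0, S2 = 1, S1 (bottom, most
#' mature) = 2. Both orderings run young to old and can be overridden
#' wherever a position label is resolved.
#'
#' @return A named list with `stage` and `segment` label-to-ordinal maps.
#' @export
default_series_levels <- function() {
  list(
    stage = c(V3 = 0L, E4 = 1L, R3 = 2L),
    segment = c(S3 = 0L, S2 = 1L, S1 = 2L)
  )
}

resolve_positions <- function(pos, series, levels = default_series_levels()) {
  if (is.numeric(pos)) return(as.integer(pos))
  pos <- as.character(pos)
  suppressWarnings(num <- as.integer(pos))
  if (!anyNA(num)) return(num)
  out <- integer(length(pos))
  for (i in seq_along(pos)) {
    map <- levels[[series[i]]]
    if (is.null(map) || is.na(map[pos[i]])) {
      stop("cannot resolve position label '", pos[i], "' for series '",
           series[i], "'", call. = FALSE)
    }
    out[i] <- map[[pos[i]]]
  }
  out
}
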