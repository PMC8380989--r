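#' Default trait-class resolution by trait name
#'
#' Maps the conventional cell wall variable names to trait classes:
#' `lignin` to `"lignin"`; `pCA` and `FA` to `"HCA"`; `ED16`/`ED24`/`ED48`
#' (enzymatic digestibility yield after 16/24/48 h) to `"digestibility"`;
#' anything else to `"polysaccharide"`.
#'
#' @param names character vector of trait names.
#' @return Character vector of trait classes.
#' @export
default_trait_classes <- function(names) {
  cls <- rep("polysaccharide", length(names))
  cls[names %in% "lignin"] <- "lignin"
  cls[names %in% c("pCA", "FA")] <- "HCA"
  cls[grepl("^ED[0-9]+$", names)] <- "digestibility"
  cls
}

default_schema <- function() {
  list(genotype = "genotype", series = "series", position = "position",
       replicate = "replicate", variable = "variable", value = "value",
       class = "class", units = "units")
}

#' Read a long-format trait table from TSV
#'
#' The canonical dialect is tab-separated UTF-8 with `.` decimals, one row
#' per sample x variable. Required columns (renameable through `schema`):
#' genotype, series, position, replicate, variable, value. Optional
#' columns: class, units. Position entries may be ordinals or labels
#' resolved through `series_levels` (default V3/E4/R3 and S3/S2/S1, young
#' to old). Unparseable numeric cells become missing values with one
#' warning reporting the count.
#'
#' @param path TSV file path.
#' @param schema named list mapping the logical column names to the file's
#'   column names; defaults to identity.
#' @param series_levels label-to-ordinal maps, see [default_series_levels()].
#' @return A [trait_matrix()].
#' @export
read_trait_table <- function(path, schema = NULL,
                             series_levels = default_series_levels()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sc <- utils::modifyList(default_schema(), as.list(schema %||% list()))
  raw <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, colClasses = "character")
  need <- c("genotype", "series", "position", "replicate", "variable",
            "value")
  missing_cols <- unlist(sc[need])[!unlist(sc[need]) %in% names(raw)]
  if (length(missing_cols) > 0) {
    stop("schema error: missing key columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  series <- raw[[sc$series]]
  keys_long <- data.frame(
    genotype = raw[[sc$genotype]],
    series = series,
    position = resolve_positions(raw[[sc$position]], series, series_levels),
    replicate = as.integer(raw[[sc$replicate]]),
    stringsAsFactors = FALSE
  )
  variable <- raw[[sc$variable]]
  suppressWarnings(value <- as.numeric(raw[[sc$value]]))
  bad <- is.na(value) & !(is.na(raw[[sc$value]]) |
                            raw[[sc$value]] %in% c("", "NA"))
  if (any(bad)) {
    value[bad] <- NA_real_
    warning(sum(bad), " unparseable numeric cell(s) set to missing",
            call. = FALSE)
  }
  cell <- paste(key_id(keys_long), variable, sep = "|")
  if (anyDuplicated(cell) > 0) {
    stop("integrity error: duplicate sample x variable rows", call. = FALSE)
  }
  keys <- unique(keys_long)
  rownames(keys) <- NULL
  keys <- keys[canonical_order(keys), , drop = FALSE]
  rownames(keys) <- NULL
  validate_keys(keys)
  vars <- unique(variable)
  values <- matrix(NA_real_, nrow(keys), length(vars),
                   dimnames = list(NULL, vars))
  ri <- match(key_id(keys_long), key_id(keys))
  ci <- match(variable, vars)
  values[cbind(ri, ci)] <- value
  if (!is.null(raw[[sc$class]])) {
    cls <- vapply(vars, function(v) raw[[sc$class]][match(v, variable)], "")
  } else {
    cls <- default_trait_classes(vars)
  }
  if (!is.null(raw[[sc$units]])) {
    units <- vapply(vars, function(v) raw[[sc$units]][match(v, variable)], "")
  } else {
    units <- rep(NA_character_, length(vars))
  }
  trait_matrix(keys, values,
               data.frame(name = vars, class = cls, units = units,
                          stringsAsFactors = FALSE))
}

#' Read a long-format expression table from TSV
#'
#' Same dialect as [read_trait_table()]; values must be strictly positive
#' relative expression.
#'
#' @inheritParams read_trait_table
#' @return An [expression_matrix()].
#' @export
read_expression_table <- function(path, schema = NULL,
                                  series_levels = default_series_levels()) {
  tm <- read_trait_table(path, schema, series_levels)
  expression_matrix(tm$keys, tm$values)
}

#' Write a trait or expression matrix as a tidy long TSV
#'
#' One row per sample x variable. Values are rendered with 17 significant
#' digits so that reading the file back reproduces them exactly
#' (`read_trait_table(write_long_table(m))` is the identity on keys and
#' values). Missing values are written as `NA`.
#'
#' @param m a `trait_matrix` or `expression_matrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_long_table <- function(m, path) {
  keys <- m$keys
  values <- m$values
  vars <- colnames(values)
  n <- nrow(values)
  p <- ncol(values)
  long <- data.frame(
    genotype = rep(keys$genotype, times = p),
    series = rep(keys$series, times = p),
    position = rep(keys$position, times = p),
    replicate = rep(keys$replicate, times = p),
    variable = rep(vars, each = n),
    value = ifelse(is.na(as.vector(values)), "NA",
                   sprintf("%.17g", as.vector(values))),
    stringsAsFactors = FALSE
  )
  if (inherits(m, "trait_matrix")) {
    long$class <- rep(m$traits$class, each = n)
    long$units <- rep(m$traits$units, each = n)
  }
  ok <- tryCatch({
    write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE,
                na = "NA")
    TRUE
  }, error = function(e) {
    stop("cannot write ", path, ": ", conditionMessage(e), call. = FALSE)
  })
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a pipeline run configuration from YAML
#'
#' The YAML file may carry a `simulate` block (fields of [sim_config()]),
#' a `models` list (fields of [model_spec()]), permutation settings
#' (`B`, `seed`, `exhaustive_threshold`), and cutoffs
#' (`q_delta`, `q_cumulative`, `q_network`).
#'
#' @param path YAML file path.
#' @return A named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  yaml::read_yaml(path)
}
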