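#' Expected correlation signs by trait class
#'
#' The sign rule used to call a significant correlation "expected":
#' phenylpropanoid-derived components (lignin and the HCAs pCA/FA)
#' should correlate positively with phenylpropanoid pathway expression,
#' and enzymatic digestibility negatively.
#'
#' @return Named numeric vector mapping trait class to expected sign.
#' @export
default_expectation_rule <- function() {
  c(lignin = 1, HCA = 1, digestibility = -1)
}

#' Classify correlation records as expected, unexpected, or neutral
#'
#' Records with `q` below the cutoff are labeled `"expected"` when the
#' sign of the symmetrized GCC matches the rule for their outcome class
#' and `"unexpected"` otherwise; non-significant (or failed) records are
#' `"neutral"`. Every outcome class present must have a rule entry.
#'
#' @param records output of [run_model()].
#' @param rule named sign vector, see [default_expectation_rule()].
#' @param q_cutoff significance cutoff; defaults to the records'
#'   attached `q_cutoff`.
#' @return `records` with an added `label` column.
#' @export
classify_records <- function(records, rule = default_expectation_rule(),
                             q_cutoff = NULL) {
  q_cutoff <- q_cutoff %||% records$q_cutoff[1]
  no_rule <- setdiff(unique(records$outcome_class), names(rule))
  if (length(no_rule) > 0) {
    stop("config error: no expected sign for outcome class(es): ",
         paste(no_rule, collapse = ", "), call. = FALSE)
  }
  expected_sign <- rule[records$outcome_class]
  sig <- !is.na(records$q) & records$q < q_cutoff & !is.na(records$gcc)
  records$label <- "neutral"
  records$label[sig & sign(records$gcc) == expected_sign] <- "expected"
  records$label[sig & sign(records$gcc) != expected_sign] <- "unexpected"
  records
}

#' Score one model by precision and recall
#'
#' Precision is the number of expected significant correlations over all
#' significant correlations (undefined when none are significant);
#' recall is the expected count over the number of testable
#' gene-outcome pairs (`possible_expected`, by default the model's gene
#' count times outcome count, e.g. 11 x 6 = 66 for the full panel).
#' Full precision is retained internally; reports round to 2 decimals.
#'
#' @param labeled output of [classify_records()], or a list with
#'   `expected` and `unexpected` counts.
#' @param possible_expected denominator for recall; defaults to the
#'   number of gene-outcome pairs in `labeled`.
#' @param name model name for the score row.
#' @return A one-row `data.frame`: `model`, `expected`, `unexpected`,
#'   `possible`, `precision` (NA when undefined), `recall`.
#' @export
score_model <- function(labeled, possible_expected = NULL, name = NULL) {
  if (is.data.frame(labeled)) {
    expected <- sum(labeled$label == "expected")
    unexpected <- sum(labeled$label == "unexpected")
    possible_expected <- possible_expected %||% nrow(labeled)
    name <- name %||% labeled$model[1]
  } else {
    expected <- labeled$expected
    unexpected <- labeled$unexpected
    name <- name %||% "model"
  }
  if (is.null(possible_expected) || possible_expected <= 0) {
    stop("config error: possible_expected must be > 0", call. = FALSE)
  }
  total <- expected + unexpected
  data.frame(
    model = name,
    expected = expected,
    unexpected = unexpected,
    possible = possible_expected,
    precision = if (total > 0) expected / total else NA_real_,
    recall = expected / possible_expected,
    stringsAsFactors = FALSE
  )
}

#' Assemble and sort the model comparison table
#'
#' Rows are sorted by precision descending, with undefined precision
#' after all defined values; ties break by expected count descending,
#' then model name. A `display` copy renders precision and recall to 2
#' decimals with undefined precision shown as `"-"`.
#'
#' @param scores a `data.frame` of [score_model()] rows.
#' @return A list with `scores` (sorted, full precision) and `display`
#'   (character rendering).
#' @export
model_table <- function(scores) {
  stopifnot(is.data.frame(scores))
  ord <- order(is.na(scores$precision), -ifelse(is.na(scores$precision),
                                                0, scores$precision),
               -scores$expected, scores$model)
  scores <- scores[ord, , drop = FALSE]
  rownames(scores) <- NULL
  display <- scores
  display$precision <- ifelse(is.na(scores$precision), "-",
                              sprintf("%.2f", scores$precision))
  display$recall <- sprintf("%.2f", scores$recall)
  list(scores = scores, display = display)
}

#' Score a model on the lag-informative outcomes of a synthetic truth
#'
#' For parameter-recovery studies: restricts the records to the
#' outcomes whose expected sign the generator's truth record defines
#' (the lagged phenolics and digestibility; concurrent-tracking traits
#' like FA are excluded because their lagged-change sign is a
#' construction artifact, not a recoverable parameter) and scores
#' precision/recall against those true signs.
#'
#' @param records output of [run_model()].
#' @param truth truth record from [generate_dataset()].
#' @param q_cutoff cutoff; defaults to the records' attached cutoff.
#' @return A one-row `data.frame` as from [score_model()].
#' @export
score_against_truth <- function(records, truth, q_cutoff = NULL) {
  q_cutoff <- q_cutoff %||% records$q_cutoff[1]
  keep <- records$outcome %in% names(truth$expected_sign)
  rec <- records[keep, , drop = FALSE]
  expected_sign <- truth$expected_sign[rec$outcome]
  sig <- !is.na(rec$q) & rec$q < q_cutoff & !is.na(rec$gcc)
  rec$label <- "neutral"
  rec$label[sig & sign(rec$gcc) == expected_sign] <- "expected"
  rec$label[sig & sign(rec$gcc) != expected_sign] <- "unexpected"
  score_model(rec, possible_expected = nrow(rec))
}
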