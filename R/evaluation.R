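# Scoring pipeline output against gold annotations: recall, precision,
# accuracy and F1, per variable and per category (one-vs-rest).

#' Confusion counts for one positive class
#'
#' Aligned prediction/gold vectors are scored one-vs-rest against
#' `positive_class`, which makes multiclass variables (side categories,
#' count bins, interval groups) reducible to binary counts per category.
#'
#' @param predictions,gold Equal-length vectors (coerced to character;
#'   logical vectors use `TRUE` as the natural positive class).
#' @param positive_class The class counted as positive.
#' @return One-row tibble with `tp`, `fp`, `fn`, `tn`
#'   (tp+fp+fn+tn = length of the input).
#' @export
#' @examples
#' confusion_counts(c("a", "b", "a"), c("a", "a", "a"), "a")
confusion_counts <- function(predictions, gold, positive_class = TRUE) {
  if (length(predictions) != length(gold)) {
    stop("predictions and gold are not aligned (different lengths)",
         call. = FALSE)
  }
  p <- as.character(predictions) == as.character(positive_class)
  g <- as.character(gold) == as.character(positive_class)
  tibble(
    tp = sum(p & g), fp = sum(p & !g), fn = sum(!p & g), tn = sum(!p & !g)
  )
}

#' Recall, precision, accuracy and F1 from confusion counts
#'
#' F1 is the harmonic mean of precision and recall. Degenerate denominators
#' follow least-surprise conventions: with no predicted positives
#' (tp+fp = 0), precision is 1 when there was nothing to find (fn = 0) and
#' 0 otherwise; recall symmetrically; F1 is 0 whenever tp = 0 and any error
#' exists, and 1 when the variable is perfectly (if vacuously) predicted.
#'
#' @param counts One-row tibble/list with `tp`, `fp`, `fn`, `tn`.
#' @return One-row tibble with `recall`, `precision`, `accuracy`, `f1` in
#'   \[0, 1\].
#' @export
#' @examples
#' prf_metrics(list(tp = 1, fp = 1, fn = 0, tn = 98))  # P=.5, R=1, F1=.67
prf_metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn; tn <- counts$tn
  total <- tp + fp + fn + tn
  if (total == 0) stop("no evaluated cases (total = 0)", call. = FALSE)
  precision <- if (tp + fp > 0) tp / (tp + fp) else as.numeric(fn == 0)
  recall <- if (tp + fn > 0) tp / (tp + fn) else as.numeric(fp == 0)
  f1 <- if (tp == 0) {
    as.numeric(fp + fn == 0)
  } else {
    2 * precision * recall / (precision + recall)
  }
  tibble(recall = recall, precision = precision,
         accuracy = (tp + tn) / total, f1 = f1)
}

# The evaluation frame: one row per procedure with the categorical variables
# under evaluation, derived from summaries (+ optional assignments).
#' @noRd
.eval_frame <- function(summaries, assignments = NULL) {
  out <- tibble(
    report_id = summaries$report_id,
    adenoma_present = summaries$adenoma_present,
    adenoma_side = summaries$adenoma_side,
    advanced_adenoma_present = summaries$adenoma_advanced,
    advanced_adenoma_side = summaries$advanced_adenoma_side,
    ssl_present = summaries$ssl_present,
    ssl_side = summaries$ssl_side,
    advanced_ssl_present = summaries$ssl_advanced,
    advanced_ssl_side = summaries$advanced_ssl_side,
    adenoma_count_bin = as.character(bin_count(summaries$n_adenomas)),
    ssl_count_bin = as.character(bin_count(summaries$n_ssls))
  )
  if (!is.null(assignments)) {
    out <- left_join(
      out,
      tibble(report_id = assignments$report_id,
             interval_group = as.character(assignments$interval_group)),
      by = "report_id")
  }
  out
}

#' @noRd
.eval_variable_levels <- function() {
  list(
    adenoma_present = TRUE,
    adenoma_side = .side_levels,
    advanced_adenoma_present = TRUE,
    advanced_adenoma_side = .side_levels,
    ssl_present = TRUE,
    ssl_side = .side_levels,
    advanced_ssl_present = TRUE,
    advanced_ssl_side = .side_levels,
    adenoma_count_bin = levels(bin_count(0)),
    ssl_count_bin = levels(bin_count(0)),
    interval_group = .interval_groups
  )
}

#' Evaluate pipeline summaries against gold annotations
#'
#' Scores every evaluated variable (presence flags, side categories, count
#' bins and, when assignments are given, the interval group) with recall,
#' precision, accuracy and F1. Binary variables are scored with positive
#' class TRUE; multiclass variables one-vs-rest per category. Procedures
#' absent from the gold set are excluded and their number reported.
#'
#' @param pred_summaries,gold_summaries `ProcedureSummary` tibbles keyed by
#'   `report_id`.
#' @param pred_assignments,gold_assignments Optional interval assignments
#'   from [assign_interval()].
#' @param digits Decimal places for the reported metrics (default 2, the
#'   conventional reporting precision; use NULL for unrounded).
#' @return Tibble with `variable`, `category`, `recall`, `precision`,
#'   `accuracy`, `f1`; attribute `n_excluded` counts predictions without a
#'   gold record.
#' @export
evaluate_summaries <- function(pred_summaries, gold_summaries,
                               pred_assignments = NULL,
                               gold_assignments = NULL, digits = 2) {
  pred <- .eval_frame(pred_summaries, pred_assignments)
  gold <- .eval_frame(gold_summaries, gold_assignments)
  n_excluded <- sum(!pred$report_id %in% gold$report_id)
  both <- inner_join(pred, gold, by = "report_id",
                     suffix = c("_pred", "_gold"))
  if (nrow(both) == 0) stop("no report_id overlap with gold", call. = FALSE)
  vars <- .eval_variable_levels()
  if (is.null(pred_assignments) || is.null(gold_assignments)) {
    vars$interval_group <- NULL
  }
  rows <- list()
  for (v in names(vars)) {
    pv <- both[[paste0(v, "_pred")]]
    gv <- both[[paste0(v, "_gold")]]
    for (lev in vars[[v]]) {
      m <- prf_metrics(confusion_counts(pv, gv, lev))
      rows[[length(rows) + 1]] <- tibble(
        variable = v,
        category = as.character(lev),
        recall = m$recall, precision = m$precision,
        accuracy = m$accuracy, f1 = m$f1
      )
    }
  }
  out <- bind_rows(rows)
  if (!is.null(digits)) {
    out <- mutate(out, dplyr::across(c("recall", "precision", "accuracy",
                                       "f1"), ~ round(.x, digits)))
  }
  attr(out, "n_excluded") <- n_excluded
  out
}
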