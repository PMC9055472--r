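# Per-procedure rollup of polyp findings into the final summary format used
# for detection rates and surveillance-interval assignment.

#' @noRd
.side_levels <- c("none", "right_only", "left_only", "both")

# Side category from per-finding left/right evidence; findings with unknown
# side contribute to presence and counts but not to the side category.
#' @noRd
.side_category <- function(any_left, any_right) {
  case_when(
    any_left & any_right ~ "both",
    any_right ~ "right_only",
    any_left ~ "left_only",
    TRUE ~ "none"
  )
}

# Advanced-lesion definitions:
#  - advanced adenoma: >= 10 mm, high-grade dysplasia, or villous /
#    tubulovillous features (missing size does not satisfy the size rule);
#  - advanced SSL: >= 10 mm or any (low- or high-grade) dysplasia.
#' @noRd
.is_advanced_adenoma <- function(is_adenoma, size_mm, dysplasia, subtype) {
  is_adenoma & (
    (!is.na(size_mm) & size_mm >= 10) |
      dysplasia == "high" |
      subtype %in% c("villous", "tubulovillous")
  )
}

#' @noRd
.is_advanced_ssl <- function(is_ssl, size_mm, dysplasia) {
  is_ssl & ((!is.na(size_mm) & size_mm >= 10) | dysplasia %in% c("low", "high"))
}

#' Summarize polyp findings per procedure
#'
#' Rolls a findings table up to one row per colonoscopy: presence and
#' advanced flags for conventional adenomas and sessile serrated lesions
#' (SSLs), side categories (none / right_only / left_only / both), summed
#' polyp counts, maximum sizes, and the feature flags the surveillance
#' decision table consumes. A finding with multiplicity `count = c`
#' contributes c lesions to the class total. Carcinoma is tracked separately
#' and never sets the adenoma flags; hyperplastic polyps and TSAs are
#' serrated but are not SSLs.
#'
#' @param findings Tibble from [build_findings()] with a `report_id` column.
#' @param procedures Tibble of procedure metadata (one row per colonoscopy;
#'   must contain `report_id`, and any of `endoscopist_id`, `patient_id`,
#'   `age`, `sex`, `indication`, `exam_date` are carried through).
#'   Procedures with no findings receive an all-negative summary.
#' @return Tibble with one row per procedure (a `ProcedureSummary`).
#' @export
summarize_procedures <- function(findings, procedures) {
  stopifnot("report_id" %in% names(procedures))
  for (col in c("review_flag", "mismatch_flag")) {
    if (!col %in% names(findings)) findings[[col]] <- FALSE
  }
  if (nrow(findings) == 0) {
    per <- tibble(report_id = character(0))
  } else {
    f <- findings |>
      mutate(
        is_adenoma = .data$histology_category == "adenoma",
        is_ssl = .data$histology_subtype == "ssl",
        is_carcinoma = .data$histology_category == "carcinoma",
        adv_adenoma = .is_advanced_adenoma(.data$is_adenoma, .data$size_mm,
                                           .data$dysplasia,
                                           .data$histology_subtype),
        adv_ssl = .is_advanced_ssl(.data$is_ssl, .data$size_mm,
                                   .data$dysplasia)
      )
    per <- f |>
      group_by(.data$report_id) |>
      summarise(
        n_adenomas = sum(.data$count[.data$is_adenoma]),
        n_ssls = sum(.data$count[.data$is_ssl]),
        carcinoma_present = any(.data$is_carcinoma),
        adenoma_advanced = any(.data$adv_adenoma),
        ssl_advanced = any(.data$adv_ssl),
        adenoma_side = .side_category(
          any(.data$is_adenoma & .data$side == "left"),
          any(.data$is_adenoma & .data$side == "right")),
        ssl_side = .side_category(
          any(.data$is_ssl & .data$side == "left"),
          any(.data$is_ssl & .data$side == "right")),
        advanced_adenoma_side = .side_category(
          any(.data$adv_adenoma & .data$side == "left"),
          any(.data$adv_adenoma & .data$side == "right")),
        advanced_ssl_side = .side_category(
          any(.data$adv_ssl & .data$side == "left"),
          any(.data$adv_ssl & .data$side == "right")),
        max_adenoma_size_mm = .max_or_na(.data$size_mm[.data$is_adenoma]),
        max_ssl_size_mm = .max_or_na(.data$size_mm[.data$is_ssl]),
        any_villous_or_hgd = any(.data$is_adenoma &
          (.data$histology_subtype %in% c("villous", "tubulovillous") |
             .data$dysplasia == "high")),
        any_ssl_dysplasia = any(.data$is_ssl &
                                  .data$dysplasia %in% c("low", "high")),
        any_tsa = any(.data$histology_subtype == "tsa"),
        any_hp_ge10mm = any(.data$histology_subtype == "hyperplastic" &
                              !is.na(.data$size_mm) & .data$size_mm >= 10),
        any_review_flag = any(.data$review_flag %in% TRUE),
        any_mismatch_flag = any(.data$mismatch_flag %in% TRUE)
      )
  }
  out <- procedures |>
    left_join(per, by = "report_id")
  defaults <- list(
    n_adenomas = 0L, n_ssls = 0L, carcinoma_present = FALSE,
    adenoma_advanced = FALSE, ssl_advanced = FALSE,
    adenoma_side = "none", ssl_side = "none",
    advanced_adenoma_side = "none", advanced_ssl_side = "none",
    max_adenoma_size_mm = NA_real_, max_ssl_size_mm = NA_real_,
    any_villous_or_hgd = FALSE, any_ssl_dysplasia = FALSE, any_tsa = FALSE,
    any_hp_ge10mm = FALSE, any_review_flag = FALSE, any_mismatch_flag = FALSE
  )
  for (col in names(defaults)) {
    if (!col %in% names(out)) out[[col]] <- defaults[[col]]
    miss <- is.na(out[[col]]) &
      !col %in% c("max_adenoma_size_mm", "max_ssl_size_mm")
    out[[col]][miss] <- defaults[[col]]
  }
  out |>
    mutate(
      n_adenomas = as.integer(.data$n_adenomas),
      n_ssls = as.integer(.data$n_ssls),
      adenoma_present = .data$n_adenomas >= 1L,
      ssl_present = .data$n_ssls >= 1L
    )
}

#' @noRd
.max_or_na <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) NA_real_ else max(x)
}

#' Summarize the findings of a single procedure
#'
#' Convenience wrapper around [summarize_procedures()] for one colonoscopy.
#'
#' @param findings Findings tibble for one procedure (a `report_id` column
#'   is added if absent).
#' @param report_id Identifier used when `findings` has no `report_id`.
#' @return One-row `ProcedureSummary` tibble.
#' @export
summarize_procedure <- function(findings, report_id = "procedure") {
  if (!"report_id" %in% names(findings)) {
    findings$report_id <- rep(report_id, nrow(findings))
  }
  rid <- if (nrow(findings) > 0) findings$report_id[1] else report_id
  summarize_procedures(findings, tibble(report_id = rid))
}

#' Bin a lesion count into the reporting bins
#'
#' Counts are reported in the bins 0, 1-2, 3-4, 5-10, >10 for both adenomas
#' and SSLs.
#'
#' @param n Integer vector of lesion counts (>= 0).
#' @return Factor with levels `0`, `1-2`, `3-4`, `5-10`, `>10`.
#' @export
#' @examples
#' bin_count(c(0, 2, 11))
bin_count <- function(n) {
  stopifnot(all(n >= 0, na.rm = TRUE))
  lab <- case_when(
    n == 0 ~ "0",
    n <= 2 ~ "1-2",
    n <= 4 ~ "3-4",
    n <= 10 ~ "5-10",
    TRUE ~ ">10"
  )
  factor(lab, levels = c("0", "1-2", "3-4", "5-10", ">10"))
}
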