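# Surveillance-interval assignment per the 2020 US Multi-Society Task Force
# recommendations, driven by a versioned decision-table file.

#' Load a surveillance decision table
#'
#' The decision table is data, not code: a TSV with columns `priority`
#' (lower = more restrictive, evaluated first), `rule_id`, `interval_group`,
#' `condition` (a vectorized R predicate over `ProcedureSummary` columns;
#' the helper `ge(x, v)` compares sizes treating missing as FALSE) and
#' `description`. Institutions can ship their own table; the bundled one
#' transcribes the 2020 US Multi-Society Task Force recommendations into the
#' six interval groups (1, 3, 3-5, 5-10, 7-10, 10 years) plus `refer` for
#' carcinoma. The rule set must be total: the lowest-priority rule must have
#' condition `TRUE`.
#'
#' @param path Path to the TSV (default: the bundled USMSTF 2020 table).
#' @return Tibble of rules ordered by priority, class `colonlp_rules`.
#' @export
load_decision_rules <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "usmstf2020_rules.tsv", package = "colonlp")
  }
  rules <- as_tibble(read.delim(path, sep = "\t", stringsAsFactors = FALSE))
  required <- c("priority", "rule_id", "interval_group", "condition")
  if (!all(required %in% names(rules))) {
    stop("decision table must have columns: ",
         paste(required, collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(rules$interval_group, .interval_groups)
  if (length(bad) > 0) {
    stop("unknown interval group in decision table: ", bad[1], call. = FALSE)
  }
  rules <- arrange(rules, .data$priority)
  if (!any(trimws(rules$condition) == "TRUE")) {
    stop("decision table has no default TRUE rule; the rule set must be total",
         call. = FALSE)
  }
  structure(rules, class = c("colonlp_rules", class(rules)))
}

#' @rdname load_decision_rules
#' @export
default_decision_rules <- function() load_decision_rules()

# Evaluation environment for rule conditions: NA-safe size comparison.
#' @noRd
.rule_helpers <- function() {
  list(ge = function(x, v) !is.na(x) & x >= v)
}

#' Assign surveillance intervals to procedure summaries
#'
#' Evaluates the decision-table rules in priority order; the first rule
#' whose condition holds wins. The rule set is total, so every summary
#' receives exactly one interval group. The shipped order is: carcinoma ->
#' refer; >10 adenomas -> 1 year; high-risk neoplasia (5-10 adenomas,
#' adenoma >= 10 mm, villous/tubulovillous or high-grade dysplasia, SSL
#' >= 10 mm or with dysplasia, TSA, 5-10 SSLs) -> 3 years; 3-4 adenomas or
#' 3-4 SSLs or hyperplastic polyp >= 10 mm -> 3-5 years; 1-2 SSLs -> 5-10
#' years; 1-2 tubular adenomas -> 7-10 years; otherwise 10 years.
#'
#' @param summaries `ProcedureSummary` tibble from [summarize_procedures()].
#' @param rules Decision table from [load_decision_rules()].
#' @param mapping Named numeric vector mapping interval groups to years;
#'   see [default_interval_mapping()]. `refer` maps to NA.
#' @return Tibble with `report_id`, `interval_group` (factor over the six
#'   groups plus refer), `interval_years`, `rule_id`.
#' @export
#' @examples
#' s <- summarize_procedure(
#'   tibble::tibble(sentence_ordinal = 1, sentence_text = "x",
#'                  specimen_ordinal = 1, specimen_text = "x",
#'                  mismatch_flag = FALSE, location_segment = "sigmoid",
#'                  cm_from_anal_verge = NA_real_, side = "left",
#'                  size_mm = 5, count = 1L, histology_category = "adenoma",
#'                  histology_subtype = "tubular", dysplasia = "none",
#'                  review_flag = FALSE))
#' assign_interval(s)
assign_interval <- function(summaries, rules = default_decision_rules(),
                            mapping = default_interval_mapping()) {
  n <- nrow(summaries)
  group <- rep(NA_character_, n)
  rule_id <- rep(NA_character_, n)
  mask <- c(as.list(summaries), .rule_helpers())
  for (i in seq_len(nrow(rules))) {
    cond <- eval(parse(text = rules$condition[i]), envir = mask,
                 enclos = baseenv())
    cond <- rep_len(cond %in% TRUE, n)
    take <- cond & is.na(group)
    group[take] <- rules$interval_group[i]
    rule_id[take] <- rules$rule_id[i]
  }
  tibble(
    report_id = summaries$report_id,
    interval_group = factor(group, levels = .interval_groups),
    interval_years = interval_years(group, mapping),
    rule_id = rule_id
  )
}

#' Numeric value of an interval group
#'
#' @param interval_group Character or factor vector of interval groups.
#' @param mapping Named numeric vector; see [default_interval_mapping()].
#' @return Numeric years; NA for `refer`.
#' @export
#' @examples
#' interval_years("y7_10")
interval_years <- function(interval_group, mapping = default_interval_mapping()) {
  unname(mapping[as.character(interval_group)])
}
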