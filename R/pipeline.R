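# Corpus I/O (JSONL) and the end-to-end pipeline driver.

#' @noRd
.write_jsonl <- function(df, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  if (nrow(df) == 0) return(invisible(path))
  lines <- vapply(seq_len(nrow(df)), function(i) {
    as.character(jsonlite::toJSON(as.list(df[i, ]), auto_unbox = TRUE,
                                  na = "null", digits = NA))
  }, character(1))
  writeLines(lines, con)
  invisible(path)
}

#' Read a JSONL report corpus
#'
#' One JSON object per line; colonoscopy and pathology records are
#' distinguished by their `record_type` field.
#'
#' @param path Path to the JSONL file.
#' @return List with `colonoscopy` and `pathology` tibbles.
#' @export
read_corpus <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  recs <- lapply(lines, function(l) {
    x <- jsonlite::fromJSON(l, simplifyVector = TRUE)
    x[vapply(x, is.null, logical(1))] <- NA
    as_tibble(x)
  })
  all <- bind_rows(recs)
  if (nrow(all) == 0) {
    return(list(colonoscopy = tibble(), pathology = tibble()))
  }
  list(
    colonoscopy = filter(all, .data$record_type == "colonoscopy"),
    pathology = filter(all, .data$record_type == "pathology")
  )
}

#' Run the full extraction pipeline over a corpus
#'
#' For every colonoscopy report: split the findings section into sentences,
#' keep the biopsy-marked ones, parse the paired pathology diagnosis
#' section into specimens, link sentences to specimens in sequence order
#' (label-based pairing when explicit "#k" labels are usable), extract the
#' polyp findings, roll them up to one `ProcedureSummary` per procedure and
#' assign the surveillance-interval group. Count mismatches between a
#' report and its pathology report are flagged per linked item and rolled
#' up per procedure; they never stop processing.
#'
#' @param colonoscopy Tibble of colonoscopy reports (`report_id`,
#'   `findings_text`, plus metadata carried into the summaries).
#' @param pathology Tibble of pathology reports (`colonoscopy_report_id`,
#'   `diagnosis_text`); may be empty.
#' @param lexicon A `colonlp_lexicon`.
#' @param rules Decision table for [assign_interval()].
#' @return List: `findings`, `summaries`, `assignments`, `links`, and
#'   `mismatches` (per-procedure flag tibble).
#' @export
process_corpus <- function(colonoscopy, pathology = NULL,
                           lexicon = default_lexicon(),
                           rules = default_decision_rules()) {
  stopifnot(all(c("report_id", "findings_text") %in% names(colonoscopy)))
  n <- nrow(colonoscopy)
  diag_by_report <- character(0)
  if (!is.null(pathology) && nrow(pathology) > 0) {
    diag_by_report <- setNames(pathology$diagnosis_text,
                               pathology$colonoscopy_report_id)
  }
  links <- vector("list", n)
  for (i in seq_len(n)) {
    rid <- colonoscopy$report_id[i]
    sent <- detect_biopsy_sentences(
      split_findings(colonoscopy$findings_text[i]), lexicon)
    spec <- if (rid %in% names(diag_by_report)) {
      parse_specimens(diag_by_report[[rid]])
    } else {
      tibble(ordinal = integer(0), raw_text = character(0))
    }
    li <- .link_one(sent, spec)
    if (nrow(li) > 0) li$report_id <- rid
    links[[i]] <- li
  }
  links <- bind_rows(links)
  if (nrow(links) == 0) {
    links <- tibble(report_id = character(0),
                    sentence_ordinal = integer(0),
                    sentence_text = character(0),
                    specimen_ordinal = integer(0),
                    specimen_text = character(0),
                    mismatch_flag = logical(0))
  }
  findings <- build_findings(links, lexicon)
  meta_cols <- intersect(c("report_id", "patient_id", "endoscopist_id",
                           "exam_date", "age", "sex", "indication"),
                         names(colonoscopy))
  procedures <- colonoscopy[, meta_cols, drop = FALSE]
  summaries <- summarize_procedures(findings, procedures)
  assignments <- assign_interval(summaries, rules)
  mismatches <- summaries |>
    select("report_id", mismatch_flag = "any_mismatch_flag")
  list(findings = findings, summaries = summaries,
       assignments = assignments, links = links, mismatches = mismatches)
}

#' Write pipeline outputs
#'
#' Writes findings and summaries as JSONL and the summaries/assignments as
#' CSV next to machine-readable JSON, mirroring the structured-output
#' interfaces of the pipeline.
#'
#' @param result List from [process_corpus()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the output directory.
#' @export
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  .write_jsonl(result$findings, file.path(out_dir, "findings.jsonl"))
  summaries <- left_join(
    result$summaries,
    result$assignments |>
      mutate(interval_group = as.character(.data$interval_group)) |>
      select("report_id", "interval_group", "interval_years", "rule_id"),
    by = "report_id")
  .write_jsonl(summaries, file.path(out_dir, "summaries.jsonl"))
  utils::write.csv(summaries, file.path(out_dir, "summaries.csv"),
                   row.names = FALSE)
  invisible(out_dir)
}
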