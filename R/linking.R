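# Preprocessing: sentence splitting, biopsy-sentence detection, specimen
# parsing, and sequence linking of findings sentences to pathology specimens.

# Explicit specimen labels usable in findings sentences: "#2" or "(2)".
#' @noRd
.label_regex <- "#\\s*(\\d+)|\\((\\d+)\\)"

# Specimen enumerators at item starts: "1." / "1)" (followed by whitespace,
# which keeps decimals like "1.2 cm" intact) or "#1".
#' @noRd
.enum_regex <- "(?<=^|\\s)(?:#\\s*\\d+\\s*[.):]?|\\d{1,2}[.)])(?=\\s)"

#' Split a findings section into sentences
#'
#' Sentences end at a newline or at a period followed by whitespace; a
#' trailing period closes the last sentence. Periods inside decimal numbers
#' ("1.2 cm") are never followed by whitespace and therefore never split.
#'
#' @param findings_text A single string (may be empty).
#' @return Character vector of sentences in document order (length 0 for
#'   empty input).
#' @export
#' @examples
#' split_findings("A 5 mm polyp at sigmoid. Bx was done.")
split_findings <- function(findings_text) {
  stopifnot(length(findings_text) == 1L)
  if (is.na(findings_text) || !nzchar(trimws(findings_text))) {
    return(character(0))
  }
  parts <- stringr::str_split_1(findings_text, "\\r?\\n|(?<=\\.)\\s+")
  parts <- stringr::str_remove(parts, "\\.\\s*$")
  parts <- stringr::str_squish(parts)
  parts[nzchar(parts)]
}

#' Detect biopsy-marked sentences
#'
#' A sentence is biopsy-marked when it contains a `biopsy_marker` lexicon
#' concept (bx, polypectomy, EMR, removed, ...) or an explicit specimen
#' label ("#1", "(1)"). Marked sentences are numbered 1..k in order of
#' appearance.
#'
#' @param sentences Character vector from [split_findings()] (normalized or
#'   raw; normalization is applied internally).
#' @param lexicon A `colonlp_lexicon`.
#' @return Tibble with columns `ordinal`, `sentence_text` (normalized),
#'   `marker_start`, `marker_end` (span of the first biopsy phrase), `label`
#'   (integer specimen label or NA).
#' @export
detect_biopsy_sentences <- function(sentences, lexicon) {
  empty <- tibble(ordinal = integer(), sentence_text = character(),
                  marker_start = integer(), marker_end = integer(),
                  label = integer())
  if (length(sentences) == 0) return(empty)
  norm <- normalize_text(sentences, lexicon)
  pat <- .biopsy_detect_regex(lexicon)
  loc <- stringr::str_locate(norm, stringr::regex(pat))
  hit <- which(!is.na(loc[, 1]))
  if (length(hit) == 0) return(empty)
  lab <- stringr::str_match(norm[hit], .label_regex)
  label <- suppressWarnings(as.integer(ifelse(is.na(lab[, 2]), lab[, 3],
                                              lab[, 2])))
  tibble(
    ordinal = seq_along(hit),
    sentence_text = norm[hit],
    marker_start = as.integer(loc[hit, 1]),
    marker_end = as.integer(loc[hit, 2]),
    label = label
  )
}

# Combined alternation of all biopsy-marker surface patterns + labels.
#' @noRd
.biopsy_detect_regex <- function(lexicon) {
  pats <- filter(lexicon$entries, .data$category == "biopsy_marker")$pattern
  paste(c(pats, .label_regex), collapse = "|")
}

#' Parse the diagnosis section of a pathology report into specimens
#'
#' The diagnosis text is split into specimen items at enumerators ("1.",
#' "1)", "#1") or at newlines that start a new item; a non-empty diagnosis
#' with no enumerators is a single specimen. Items are returned in document
#' order with contiguous ordinals starting at 1.
#'
#' @param diagnosis_text A single string.
#' @return Tibble with columns `ordinal`, `raw_text`.
#' @export
#' @examples
#' parse_specimens("1. Tubular adenoma 2. Hyperplastic polyp")
parse_specimens <- function(diagnosis_text) {
  stopifnot(length(diagnosis_text) == 1L)
  empty <- tibble(ordinal = integer(), raw_text = character())
  if (is.na(diagnosis_text) || !nzchar(trimws(diagnosis_text))) return(empty)
  txt <- stringr::str_replace_all(diagnosis_text, "\\r?\\n", " \n ")
  enum <- stringr::str_locate_all(txt, .enum_regex)[[1]]
  if (nrow(enum) >= 1) {
    starts <- enum[, 1]
    ends <- c(starts[-1] - 1L, nchar(txt))
    items <- stringr::str_sub(txt, starts, ends)
    items <- stringr::str_remove(items, paste0("^", .enum_regex, "\\s*"))
    # leading text before the first enumerator is not a specimen
  } else {
    items <- stringr::str_split_1(txt, "\\n")
  }
  items <- stringr::str_squish(items)
  items <- items[nzchar(items)]
  if (length(items) == 0) return(empty)
  tibble(ordinal = seq_along(items), raw_text = items)
}

#' Link biopsy sentences to pathology specimens
#'
#' Pairs the i-th biopsy-marked findings sentence with the i-th specimen in
#' the pathology diagnosis section, following the order of specimens. When a
#' findings sentence carries an explicit specimen label ("#2") and the
#' labels form a usable index into the specimen list, label-based pairing
#' overrides sequence order. When the sentence count k and the specimen
#' count m differ, the first min(k, m) pairs are linked and every surplus
#' sentence or specimen is emitted unlinked with `mismatch_flag = TRUE`;
#' mismatches are reported, never silently dropped. A procedure with no
#' pathology report yields zero links.
#'
#' @param colonoscopy One-row list/tibble with at least `report_id` and
#'   `findings_text`, or a character findings text.
#' @param pathology One-row list/tibble with `diagnosis_text`, a character
#'   string, or `NULL` when no pathology report exists.
#' @param lexicon A `colonlp_lexicon`.
#' @return Tibble with one row per linked or surplus item: `sentence_ordinal`,
#'   `sentence_text`, `specimen_ordinal`, `specimen_text`, `mismatch_flag`.
#' @export
link_reports <- function(colonoscopy, pathology, lexicon) {
  findings_text <- if (is.character(colonoscopy)) colonoscopy else
    colonoscopy$findings_text
  diagnosis_text <- if (is.null(pathology)) NA_character_ else
    if (is.character(pathology)) pathology else pathology$diagnosis_text
  sent <- detect_biopsy_sentences(split_findings(findings_text), lexicon)
  spec <- if (is.na(diagnosis_text)) {
    tibble(ordinal = integer(), raw_text = character())
  } else {
    parse_specimens(diagnosis_text)
  }
  .link_one(sent, spec)
}

# Core pairing on already-parsed inputs.
#' @noRd
.link_one <- function(sent, spec) {
  k <- nrow(sent); m <- nrow(spec)
  if (is.null(sent$label)) sent$label <- rep(NA_integer_, k)
  use_labels <- k > 0 && m > 0 && all(!is.na(sent$label)) &&
    !anyDuplicated(sent$label) && all(sent$label >= 1 & sent$label <= m)
  if (use_labels) {
    pair_spec <- sent$label
  } else {
    pair_spec <- ifelse(seq_len(k) <= m, seq_len(k), NA_integer_)
    if (k == 0) pair_spec <- integer(0)
  }
  spec_text <- rep(NA_character_, k)
  got <- !is.na(pair_spec)
  spec_text[got] <- spec$raw_text[pair_spec[got]]
  linked <- tibble(
    sentence_ordinal = sent$ordinal,
    sentence_text = sent$sentence_text,
    specimen_ordinal = as.integer(pair_spec),
    specimen_text = spec_text,
    mismatch_flag = is.na(pair_spec)
  )
  surplus_spec <- setdiff(spec$ordinal, pair_spec)
  if (length(surplus_spec) > 0) {
    linked <- bind_rows(linked, tibble(
      sentence_ordinal = NA_integer_,
      sentence_text = NA_character_,
      specimen_ordinal = as.integer(surplus_spec),
      specimen_text = spec$raw_text[surplus_spec],
      mismatch_flag = TRUE
    ))
  }
  linked
}
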