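# Extraction of polyp location, side, size, count and histology from linked
# sentence / specimen text.

# Distance from the anal verge: "at 65 cm", "65 cm from the av",
# "65 cm from the anal verge". A bare "<n> cm" without either the "at"
# preposition or an anal-verge mention is a size, not a distance.
#' @noRd
.distance_regex <- paste0(
  "(?:at\\s+(\\d+(?:\\.\\d+)?)\\s*cm\\b(?:\\s+from(?:\\s+the)?",
  "\\s+(?:av|anal\\s+verge))?)",
  "|(?:(\\d+(?:\\.\\d+)?)\\s*cm\\s+from(?:\\s+the)?\\s+(?:av|anal\\s+verge))"
)

# Size mention with optional range ("5-7 mm", "0.5-1.2 cm").
#' @noRd
.size_regex <- paste0(
  "(\\d+(?:\\.\\d+)?)(?:\\s*[-~–]\\s*(\\d+(?:\\.\\d+)?))?\\s*(mm|cm)\\b"
)

#' Derive colon side from segment and insertion depth
#'
#' The left colon runs from the rectum to the splenic flexure (rectum,
#' rectosigmoid, sigmoid, descending colon, splenic flexure); the right
#' colon from the transverse colon to the cecum (transverse, hepatic
#' flexure, ascending, cecum, ileocecal valve). When only a distance from
#' the anal verge is known, >= 60 cm is attributed to the right colon. An
#' explicit segment always wins over a distance.
#'
#' @param segment Character vector of segment names (or "unknown").
#' @param cm_from_anal_verge Numeric vector (NA when absent).
#' @return Character vector: "left", "right" or "unknown".
#' @export
#' @examples
#' polyp_side("sigmoid", NA)
#' polyp_side("unknown", 65)
polyp_side <- function(segment, cm_from_anal_verge = NA_real_) {
  case_when(
    segment %in% .left_segments ~ "left",
    segment %in% .right_segments ~ "right",
    !is.na(cm_from_anal_verge) & cm_from_anal_verge >= .right_colon_cm ~ "right",
    !is.na(cm_from_anal_verge) ~ "left",
    TRUE ~ "unknown"
  )
}

#' Extract polyp location from a findings sentence
#'
#' The anatomical segment comes from the lexicon `location` concepts; the
#' distance from the anal verge from patterns like "at 65 cm" or
#' "65 cm from the AV". Side follows [polyp_side()]. A sentence naming
#' several distinct segments is flagged (`n_segments` > 1); callers that
#' emit one finding per segment use [build_findings()].
#'
#' @param sentence_text Character vector of normalized sentences.
#' @param lexicon A `colonlp_lexicon`.
#' @return Tibble with one row per sentence: `location_segment`,
#'   `cm_from_anal_verge`, `side`, `n_segments`.
#' @export
#' @examples
#' extract_location(normalize_text("polyp at 65 cm from AV"), default_lexicon())
extract_location <- function(sentence_text, lexicon) {
  segs <- .segment_mentions(sentence_text, lexicon)
  first <- segs |>
    group_by(.data$text_id) |>
    summarise(location_segment = .data$segment[1], n_segments = n())
  cm <- .extract_cm(sentence_text)
  out <- tibble(text_id = seq_along(sentence_text),
                cm_from_anal_verge = cm) |>
    left_join(first, by = "text_id") |>
    mutate(
      location_segment = if_else(is.na(.data$location_segment), "unknown",
                                 .data$location_segment),
      n_segments = if_else(is.na(.data$n_segments), 0L, .data$n_segments),
      side = polyp_side(.data$location_segment, .data$cm_from_anal_verge)
    )
  select(out, "location_segment", "cm_from_anal_verge", "side", "n_segments")
}

# All distinct segment mentions per text, in span order.
#' @noRd
.segment_mentions <- function(sentence_text, lexicon) {
  m <- .match_concepts_batch(sentence_text, lexicon, categories = "location")
  m |>
    mutate(segment = stringr::str_remove(.data$canonical, "^segment_")) |>
    distinct(.data$text_id, .data$segment, .keep_all = TRUE) |>
    arrange(.data$text_id, .data$start)
}

#' @noRd
.extract_cm <- function(sentence_text) {
  m <- stringr::str_match(sentence_text, .distance_regex)
  val <- ifelse(is.na(m[, 2]), m[, 3], m[, 2])
  as.numeric(val)
}

#' Extract polyp size in millimetres
#'
#' Sizes written in cm are converted to mm; ranges ("5-7 mm") resolve to
#' their maximum; distances from the anal verge are excluded. When a
#' sentence carries several size mentions the maximum is kept.
#'
#' @param sentence_text Character vector of normalized sentences.
#' @return Numeric vector of sizes in mm (NA when no parseable size).
#' @export
#' @examples
#' extract_size("1.2 cm polyp")
#' extract_size("5-7 mm polyps")
extract_size <- function(sentence_text) {
  txt <- stringr::str_replace_all(sentence_text, .distance_regex, " ")
  locs <- stringr::str_match_all(txt, .size_regex)
  vapply(locs, function(m) {
    if (is.null(m) || nrow(m) == 0) return(NA_real_)
    lo <- as.numeric(m[, 2])
    hi <- as.numeric(m[, 3])
    val <- pmax(lo, hi, na.rm = TRUE)
    val <- ifelse(m[, 4] == "cm", val * 10, val)
    max(val)
  }, numeric(1))
}

#' @noRd
.count_words <- setNames(1:12, c("one", "two", "three", "four", "five",
                                 "six", "seven", "eight", "nine", "ten",
                                 "eleven", "twelve"))

#' Extract polyp multiplicity from a findings sentence
#'
#' Explicit multiplicity is parsed from "x3"-style suffixes, "3 polyps"
#' digit forms, or count words ("two polyps"). A sentence with no stated
#' multiplicity describes a single polyp.
#'
#' @param sentence_text Character vector of normalized sentences.
#' @return Integer vector (>= 1).
#' @export
#' @examples
#' extract_count("two polyps, bx")
#' extract_count("polyps x3")
extract_count <- function(sentence_text) {
  x <- stringr::str_match(sentence_text, "(?:x|×)\\s*(\\d{1,2})\\b")[, 2]
  d <- stringr::str_match(
    sentence_text,
    "\\b(\\d{1,2})\\s+(?:(?:small|tiny|flat|sessile|pedunculated)\\s+)?polyps?\\b"
  )[, 2]
  w <- stringr::str_match(
    sentence_text,
    paste0("\\b(", paste(names(.count_words), collapse = "|"),
           ")\\b(?:\\s+\\w+){0,3}?\\s+polyps?")
  )[, 2]
  out <- suppressWarnings(as.integer(x))
  out[is.na(out)] <- suppressWarnings(as.integer(d[is.na(out)]))
  miss <- is.na(out) & !is.na(w)
  out[miss] <- .count_words[w[miss]]
  out[is.na(out) | out < 1] <- 1L
  as.integer(out)
}

#' Extract histology from a specimen diagnosis text
#'
#' Histology concepts are looked up in the lexicon and mapped to the
#' (category, subtype, dysplasia) triple: adenomas (tubular, tubulovillous,
#' villous), serrated polyps (hyperplastic, SSL -- including SSA/P surface
#' forms -- and TSA) and carcinoma. Dysplasia grading is carried separately
#' ("with high grade dysplasia" sets grade high; ungraded "dysplasia" counts
#' as low). A negation cue ("no", "without", "negative for") suppresses
#' concepts that follow it up to the next comma, semicolon or period, so
#' "tubular adenoma, no dysplasia" keeps the adenoma and drops the
#' dysplasia.
#'
#' @param specimen_text Character vector of normalized diagnosis items.
#' @param lexicon A `colonlp_lexicon`.
#' @return Tibble with one row per input: `histology_category`
#'   (adenoma/serrated/carcinoma/other), `histology_subtype`
#'   (tubular/tubulovillous/villous/hyperplastic/ssl/tsa/none), `dysplasia`
#'   (none/low/high).
#' @export
#' @examples
#' extract_histology("tubular adenoma with high grade dysplasia",
#'                   default_lexicon())
extract_histology <- function(specimen_text, lexicon) {
  n <- length(specimen_text)
  m <- .match_concepts_batch(specimen_text, lexicon,
                             categories = c("histology", "negation"))
  if (nrow(m) > 0) {
    m$negated <- .negated_spans(specimen_text, m)
    m <- filter(m, .data$category == "histology", !.data$negated)
    m <- left_join(m, .histology_map, by = "canonical")
  } else {
    m <- mutate(m, histology_category = character(),
                histology_subtype = character(), dysplasia = character())
  }
  per <- m |>
    group_by(.data$text_id) |>
    summarise(
      histology_category = .first_non_na(.data$histology_category),
      histology_subtype = .first_non_na(.data$histology_subtype),
      dysplasia = if (any(.data$dysplasia %in% "high")) "high"
        else if (any(.data$dysplasia %in% "low")) "low" else "none"
    )
  out <- tibble(text_id = seq_len(n)) |>
    left_join(per, by = "text_id") |>
    mutate(
      histology_category = if_else(is.na(.data$histology_category), "other",
                                   .data$histology_category),
      histology_subtype = if_else(is.na(.data$histology_subtype), "none",
                                  .data$histology_subtype),
      dysplasia = if_else(is.na(.data$dysplasia), "none", .data$dysplasia)
    )
  select(out, "histology_category", "histology_subtype", "dysplasia")
}

#' @noRd
.first_non_na <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) NA_character_ else x[1]
}

# TRUE for matches inside the scope of a preceding negation cue (same
# clause: cue position to the next , ; or .).
#' @noRd
.negated_spans <- function(texts, matches) {
  neg <- filter(matches, .data$category == "negation")
  out <- logical(nrow(matches))
  if (nrow(neg) == 0) return(out)
  for (i in seq_len(nrow(neg))) {
    tid <- neg$text_id[i]
    txt <- texts[tid]
    tail_txt <- stringr::str_sub(txt, neg$end[i] + 1)
    stop_at <- stringr::str_locate(tail_txt, "[,;.]")[1]
    scope_end <- if (is.na(stop_at)) nchar(txt) else neg$end[i] + stop_at - 1
    inside <- matches$text_id == tid & matches$category == "histology" &
      matches$start > neg$end[i] & matches$start <= scope_end
    out <- out | inside
  }
  out
}

#' Build polyp findings from linked sentence/specimen pairs
#'
#' Composes the extraction operations into one `PolypFinding` per linked
#' pair: location, size and count from the findings sentence; histology from
#' the specimen text. Unlinked biopsy sentences (no specimen) yield findings
#' with histology (other, none, none); unlinked specimens yield findings
#' with unknown location. A sentence naming several distinct segments emits
#' one finding per segment, each flagged `review_flag = TRUE`.
#'
#' @param linked Tibble as returned by [link_reports()], optionally with a
#'   `report_id` column.
#' @param lexicon A `colonlp_lexicon`.
#' @return Tibble of findings: `report_id` (if supplied), `sentence_ordinal`,
#'   `specimen_ordinal`, `location_segment`, `cm_from_anal_verge`, `side`,
#'   `size_mm`, `count`, `histology_category`, `histology_subtype`,
#'   `dysplasia`, `mismatch_flag`, `review_flag`.
#' @export
build_findings <- function(linked, lexicon) {
  if (nrow(linked) == 0) {
    out <- as_tibble(linked)
    out$location_segment <- character(0)
    out$cm_from_anal_verge <- numeric(0)
    out$side <- character(0)
    out$size_mm <- numeric(0)
    out$count <- integer(0)
    out$histology_category <- character(0)
    out$histology_subtype <- character(0)
    out$dysplasia <- character(0)
    out$review_flag <- logical(0)
    return(out)
  }
  sent <- normalize_text(linked$sentence_text, lexicon)
  spec <- normalize_text(linked$specimen_text, lexicon)
  loc <- extract_location(sent, lexicon)
  hist <- extract_histology(spec, lexicon)
  base <- as_tibble(linked) |>
    mutate(
      location_segment = loc$location_segment,
      cm_from_anal_verge = loc$cm_from_anal_verge,
      side = loc$side,
      n_segments = loc$n_segments,
      size_mm = extract_size(sent),
      count = extract_count(sent),
      histology_category = hist$histology_category,
      histology_subtype = hist$histology_subtype,
      dysplasia = hist$dysplasia,
      review_flag = .data$n_segments > 1
    )
  # sentences with no text (surplus specimens) carry no location/size/count
  no_sent <- is.na(base$sentence_text)
  base$location_segment[no_sent] <- "unknown"
  base$side[no_sent] <- "unknown"
  base$size_mm[no_sent] <- NA_real_
  base$count[no_sent] <- 1L
  # expand multi-segment sentences: one finding per distinct segment
  multi <- filter(base, .data$n_segments > 1)
  if (nrow(multi) > 0) {
    segs <- .segment_mentions(sent, lexicon)
    expanded <- lapply(which(base$n_segments > 1), function(i) {
      s <- filter(segs, .data$text_id == i)$segment
      rows <- base[rep(i, length(s)), , drop = FALSE]
      rows$location_segment <- s
      rows$side <- polyp_side(s, rows$cm_from_anal_verge)
      rows
    })
    base <- bind_rows(filter(base, .data$n_segments <= 1),
                      bind_rows(expanded))
  }
  select(base, -"n_segments") |>
    arrange(.data$sentence_ordinal)
}
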