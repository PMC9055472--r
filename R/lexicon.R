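# Lexicon loading, text normalization and concept matching.

#' Load a lexicon from a TSV file
#'
#' The lexicon file is UTF-8 tab-separated with a header row
#' `surface_form  language  canonical  category` and `#`-prefixed comment
#' lines. Each row maps one surface form (a medical term, synonym or
#' endoscopic abbreviation) to a canonical concept in one of the controlled
#' categories: `histology`, `location`, `biopsy_marker`, `size_unit`,
#' `count_word`, `negation`, `noise_term`.
#'
#' Surface forms are normalized (NFKC, lower case, collapsed whitespace)
#' before indexing, so matching is case-insensitive. Two rows that map the
#' same normalized (surface form, category) to different canonicals are a
#' validation error; exact duplicate rows are collapsed.
#'
#' @param path Path to the TSV file.
#' @return A `colonlp_lexicon` object: a list with `entries` (a tibble with
#'   one row per entry and a precompiled `pattern` column) and the source
#'   `path`.
#' @seealso [default_lexicon()], [match_concepts()], [normalize_text()]
#' @export
#' @examples
#' lex <- default_lexicon()
#' lexicon_lookup(lex, "s-colon")
load_lexicon <- function(path) {
  if (!file.exists(path)) {
    stop("lexicon file not found: ", path, call. = FALSE)
  }
  raw <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- !grepl("^\\s*#", raw) & nzchar(trimws(raw))
  lines <- raw[keep]
  line_no <- which(keep)
  if (length(lines) == 0) {
    stop("lexicon file is empty (no header): ", path, call. = FALSE)
  }
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  required <- c("surface_form", "language", "canonical", "category")
  if (!identical(trimws(header), required)) {
    stop("lexicon header must be: ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  body <- lines[-1]
  body_no <- line_no[-1]
  fields <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 4L)
  if (length(bad) > 0) {
    stop("malformed lexicon row at line ", body_no[bad[1]],
         " (expected 4 tab-separated fields)", call. = FALSE)
  }
  entries <- tibble(
    surface_form = trimws(vapply(fields, `[[`, "", 1L)),
    language = trimws(vapply(fields, `[[`, "", 2L)),
    canonical = trimws(vapply(fields, `[[`, "", 3L)),
    category = trimws(vapply(fields, `[[`, "", 4L))
  )
  entries$surface_norm <- .basic_normalize(entries$surface_form)
  empty <- which(!nzchar(entries$surface_norm))
  if (length(empty) > 0) {
    stop("empty surface form at line ", body_no[empty[1]], call. = FALSE)
  }
  bad_cat <- which(!entries$category %in% .lexicon_categories)
  if (length(bad_cat) > 0) {
    stop("unknown category '", entries$category[bad_cat[1]], "' at line ",
         body_no[bad_cat[1]], call. = FALSE)
  }
  dup <- entries |>
    distinct(.data$surface_norm, .data$category, .data$canonical) |>
    count(.data$surface_norm, .data$category) |>
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop("conflicting canonical concepts for surface form '",
         dup$surface_norm[1], "' in category '", dup$category[1], "'",
         call. = FALSE)
  }
  entries <- distinct(entries, .data$surface_norm, .data$category,
                      .keep_all = TRUE)
  entries$pattern <- .surface_pattern(entries$surface_norm, entries$category)
  entries$nchar <- nchar(entries$surface_norm)
  structure(list(entries = entries, path = path), class = "colonlp_lexicon")
}

#' Shipped English + endoscopic-abbreviation starter lexicon
#'
#' Loads the lexicon bundled with the package: English histology and segment
#' terms plus common endoscopic abbreviations (bx, S-colon, A-colon, HF, SF,
#' ICV, EMR, HP, TA, TVA, SSL/SSA/P, TSA, ...). The file format supports a
#' `language` column so Korean or other entries can be added by users; none
#' are shipped.
#'
#' @return A `colonlp_lexicon`.
#' @export
default_lexicon <- function() {
  load_lexicon(system.file("extdata", "lexicon_en.tsv", package = "colonlp"))
}

#' @export
print.colonlp_lexicon <- function(x, ...) {
  cat("<colonlp_lexicon> ", nrow(x$entries), " entries (",
      paste(unique(x$entries$category), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Look up a surface form in a lexicon
#'
#' @param lexicon A `colonlp_lexicon`.
#' @param surface_form Character vector of surface forms (normalized before
#'   lookup, so case does not matter).
#' @param category Optional category to restrict the lookup.
#' @return Tibble of matching entries (zero rows if absent).
#' @export
lexicon_lookup <- function(lexicon, surface_form, category = NULL) {
  stopifnot(inherits(lexicon, "colonlp_lexicon"))
  wanted <- .basic_normalize(surface_form)
  out <- filter(lexicon$entries, .data$surface_norm %in% !!wanted)
  if (!is.null(category)) out <- filter(out, .data$category %in% !!category)
  select(out, "surface_form", "language", "canonical", "category")
}

# NFKC + lower + collapse whitespace; no noise removal (used for surfaces).
#' @noRd
.basic_normalize <- function(text) {
  text[is.na(text)] <- ""
  out <- stringi::stri_trans_nfkc(text)
  out <- stringr::str_to_lower(out)
  out <- stringr::str_squish(out)
  out
}

# Boundary-protected regex for a normalized surface form. Letters/digits may
# not abut the match; histology/location/marker nouns accept an optional
# plural "s".
#' @noRd
.surface_pattern <- function(surface_norm, category) {
  esc <- stringr::str_replace_all(surface_norm, "([.^$*+?()\\[\\]{}|\\\\/])",
                                  "\\\\\\1")
  esc <- stringr::str_replace_all(esc, stringr::fixed(" "), "\\s+")
  plural <- category %in% c("histology", "location", "biopsy_marker") &
    !stringr::str_ends(surface_norm, "s")
  paste0("(?<![a-z0-9])", esc, ifelse(plural, "(?:s)?", ""), "(?![a-z0-9])")
}

#' Normalize report text
#'
#' Applies Unicode NFKC normalization (mixed-script reports often carry
#' full-width characters), lower-cases, removes any `noise_term` phrases in
#' the lexicon, and collapses runs of whitespace. Empty input maps to empty
#' output. All matching functions expect normalized text.
#'
#' @param text Character vector.
#' @param lexicon A `colonlp_lexicon` supplying the removable noise phrases;
#'   `NULL` skips noise removal.
#' @return Character vector of the same length.
#' @export
#' @examples
#' normalize_text("  Tubular   ADENOMA ")
normalize_text <- function(text, lexicon = NULL) {
  out <- .basic_normalize(text)
  if (!is.null(lexicon)) {
    noise <- filter(lexicon$entries, .data$category == "noise_term")
    for (pat in noise$pattern) {
      out <- stringr::str_remove_all(out, stringr::regex(pat))
    }
    out <- stringr::str_squish(out)
  }
  out
}

#' Match lexicon concepts in text
#'
#' Finds every occurrence of a lexicon surface form in `text` (at word
#' boundaries, case-insensitively via prior normalization) and resolves
#' overlaps by maximal span: the longest candidate wins, ties broken by the
#' leftmost start, so "tubulovillous adenoma" is never shadowed by its
#' "adenoma" substring. Returned matches are pairwise non-overlapping and
#' sorted by start position.
#'
#' @param text A single string (normalized; see [normalize_text()]).
#' @param lexicon A `colonlp_lexicon`.
#' @param categories Optional character vector restricting the categories
#'   searched.
#' @return Tibble with columns `start`, `end` (1-based, inclusive),
#'   `canonical`, `category`, `surface`.
#' @export
#' @examples
#' match_concepts(normalize_text("Tubulovillous adenoma, S-colon"),
#'                default_lexicon())
match_concepts <- function(text, lexicon, categories = NULL) {
  stopifnot(length(text) == 1L)
  res <- .match_concepts_batch(text, lexicon, categories)
  select(res, -"text_id")
}

# Vectorized matcher: one row per selected match, with text_id indexing the
# input vector. Used by the pipeline so the per-pattern regex scan runs once
# over the whole corpus.
#' @noRd
.match_concepts_batch <- function(texts, lexicon, categories = NULL) {
  entries <- lexicon$entries
  if (!is.null(categories)) {
    entries <- filter(entries, .data$category %in% categories)
  }
  texts[is.na(texts)] <- ""
  cand <- vector("list", nrow(entries))
  for (i in seq_len(nrow(entries))) {
    loc <- stringr::str_locate_all(texts, stringr::regex(entries$pattern[i]))
    hit <- which(vapply(loc, nrow, 0L) > 0)
    if (length(hit) == 0) next
    mats <- loc[hit]
    cand[[i]] <- tibble(
      text_id = rep(hit, vapply(mats, nrow, 0L)),
      start = as.integer(unlist(lapply(mats, function(m) unname(m[, 1])))),
      end = as.integer(unlist(lapply(mats, function(m) unname(m[, 2])))),
      canonical = entries$canonical[i],
      category = entries$category[i],
      surface = entries$surface_norm[i]
    )
  }
  cand <- bind_rows(cand)
  empty <- tibble(text_id = integer(), start = integer(), end = integer(),
                  canonical = character(), category = character(),
                  surface = character())
  if (nrow(cand) == 0) return(empty)
  cand <- arrange(cand, .data$text_id, .data$start, .data$end)
  # fast path: texts whose candidates already don't overlap
  cand <- cand |>
    group_by(.data$text_id) |>
    mutate(.overlaps = n() > 1 &&
             any(.data$start[-1] <= .data$end[-n()])) |>
    ungroup()
  clean <- filter(cand, !.data$.overlaps)
  messy <- filter(cand, .data$.overlaps)
  if (nrow(messy) > 0) {
    resolved <- lapply(split(messy, messy$text_id), .select_maximal_spans)
    messy <- bind_rows(resolved)
  }
  out <- bind_rows(clean, messy) |>
    select(-".overlaps") |>
    arrange(.data$text_id, .data$start)
  out
}

# Longest-span-first greedy selection with leftmost tie-break.
#' @noRd
.select_maximal_spans <- function(df) {
  df <- df[order(-(df$end - df$start), df$start), , drop = FALSE]
  taken_start <- integer(0)
  taken_end <- integer(0)
  keep <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    s <- df$start[i]; e <- df$end[i]
    if (!any(s <= taken_end & e >= taken_start)) {
      keep[i] <- TRUE
      taken_start <- c(taken_start, s)
      taken_end <- c(taken_end, e)
    }
  }
  df[keep, , drop = FALSE]
}
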