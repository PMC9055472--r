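lex <- default_lexicon()

test_that("sentence splitting respects decimals and document order", {
  expect_equal(split_findings(""), character(0))
  expect_equal(split_findings("A 5 mm polyp at sigmoid. Bx was done."),
               c("A 5 mm polyp at sigmoid", "Bx was done"))
  # no split inside the decimal: "1.2" survives intact
  s <- split_findings("Polyp, 1.2 cm, A-colon. Removed.")
  expect_length(s, 2)
  expect_true(grepl("1.2", s[1], fixed = TRUE))
  expect_equal(split_findings("line one\nline two"),
               c("line one", "line two"))
})

test_that("biopsy sentences are detected by marker or label, in order", {
  expect_equal(nrow(detect_biopsy_sentences(
    c("Diverticulum seen", "Mucosa normal"), lex)), 0)
  b <- detect_biopsy_sentences(
    c("Polyp at sigmoid, bx", "Diverticulum seen"), lex)
  expect_equal(b$ordinal, 1L)
  expect_match(b$sentence_text, "sigmoid")
  b2 <- detect_biopsy_sentences(
    c("Polyp, polypectomy", "No lesion", "#2 small polyp"), lex)
  expect_equal(b2$ordinal, c(1L, 2L))
  expect_equal(b2$label, c(NA_integer_, 2L))
})

test_that("specimen parsing splits on enumerators and defaults to one item", {
  expect_equal(nrow(parse_specimens("")), 0)
  sp <- parse_specimens("1. Tubular adenoma 2. Hyperplastic polyp")
  expect_equal(sp$ordinal, c(1L, 2L))
  expect_equal(sp$raw_text, c("Tubular adenoma", "Hyperplastic polyp"))
  one <- parse_specimens("Colon, sigmoid, polypectomy: Tubular adenoma")
  expect_equal(one$ordinal, 1L)
  # a decimal size inside an item must not open a new item
  sp2 <- parse_specimens("1. Polyp 0.4 cm, tubular adenoma\n2. SSL")
  expect_equal(nrow(sp2), 2)
})

test_that("linking follows specimen sequence and flags count mismatches", {
  colo <- "Polyp at sigmoid, bx. A polyp at cecum, polypectomy."
  path2 <- "1. Tubular adenoma\n2. Hyperplastic polyp"
  l <- link_reports(colo, path2, lex)
  expect_equal(l$specimen_ordinal, c(1L, 2L))
  expect_false(any(l$mismatch_flag))

  # 3 biopsy sentences vs 2 specimens: 2 links + 1 flagged surplus sentence
  colo3 <- paste(colo, "Another polyp at rectum, removed.")
  l3 <- link_reports(colo3, path2, lex)
  expect_equal(sum(!l3$mismatch_flag), 2)
  expect_equal(sum(l3$mismatch_flag), 1)
  expect_true(is.na(l3$specimen_ordinal[l3$mismatch_flag]))

  # surplus specimens are emitted unlinked, never dropped
  l1 <- link_reports("Polyp at sigmoid, bx.", path2, lex)
  expect_equal(nrow(l1), 2)
  expect_equal(sum(l1$mismatch_flag), 1)

  # no pathology report -> zero links
  expect_equal(nrow(link_reports(colo, NULL, lex)), 2) # sentences unlinked
  expect_true(all(link_reports(colo, NULL, lex)$mismatch_flag))
})

test_that("explicit specimen labels override sequence order", {
  colo <- "#2 polyp at cecum, bx. #1 polyp at sigmoid, bx."
  path <- "#1. Tubular adenoma\n#2. Hyperplastic polyp"
  l <- link_reports(colo, path, lex)
  expect_equal(l$specimen_ordinal, c(2L, 1L))
  expect_match(l$specimen_text[1], "hyperplastic", ignore.case = TRUE)
  expect_false(any(l$mismatch_flag))
})

test_that("sequence links preserve order and link exactly min(k, m) pairs", {
  corp <- clean_corpus(n = 60, seed = 5)
  links <- corp$result$links
  for (df in split(links, links$report_id)) {
    both <- df[!is.na(df$sentence_ordinal) & !is.na(df$specimen_ordinal), ]
    both <- both[order(both$sentence_ordinal), ]
    if (nrow(both) > 1) {
      expect_true(all(diff(both$specimen_ordinal) > 0))
    }
    k <- sum(!is.na(df$sentence_ordinal))
    m <- sum(!is.na(df$specimen_ordinal))
    expect_equal(nrow(both), min(k, m))
  }
})
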