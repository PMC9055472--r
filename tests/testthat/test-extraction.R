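lex <- default_lexicon()

test_that("location extraction: segment wins, cm is the fallback", {
  out <- extract_location(normalize_text(c(
    "sigmoid colon, 5 mm polyp",
    "polyp at 65 cm from av",
    "polyp at 59 cm",
    "a polyp at the hf, bx",
    "1.2 cm polyp at 70 cm, removed",   # segment absent, size + distance
    "nothing here"
  )), lex)
  expect_equal(out$location_segment,
               c("sigmoid", "unknown", "unknown", "hepatic_flexure",
                 "unknown", "unknown"))
  expect_equal(out$cm_from_anal_verge, c(NA, 65, 59, NA, 70, NA))
  expect_equal(out$side, c("left", "right", "left", "right", "right",
                           "unknown"))
})

test_that("side assignment matches the left/right partition for all segments", {
  left <- c("rectum", "rectosigmoid", "sigmoid", "descending",
            "splenic_flexure")
  right <- c("transverse", "hepatic_flexure", "ascending", "cecum",
             "ileocecal_valve")
  expect_equal(polyp_side(left), rep("left", 5))
  expect_equal(polyp_side(right), rep("right", 5))
  # cm rule at the 60 cm boundary, only when the segment is unknown
  expect_equal(polyp_side("unknown", c(59, 60, 61)),
               c("left", "right", "right"))
  expect_equal(polyp_side("sigmoid", 99), "left") # explicit segment wins
  expect_equal(polyp_side("unknown", NA), "unknown")
})

test_that("size extraction converts units and resolves ranges to the max", {
  expect_equal(extract_size("12 mm polyp"), 12)
  expect_equal(extract_size("1.2 cm polyp"), 12)
  expect_equal(extract_size("5-7 mm polyps"), 7)
  expect_true(is.na(extract_size("a small polyp, bx")))
  # distances from the anal verge are not sizes
  expect_true(is.na(extract_size("polyp at 65 cm from the av")))
  expect_equal(extract_size("1.2 cm polyp at 65 cm"), 12)
  # unit invariance: "X cm" == "10 X mm" over a grid
  for (x in c(0.3, 0.5, 1, 1.2, 2.5)) {
    expect_equal(extract_size(sprintf("%g cm polyp", x)),
                 extract_size(sprintf("%g mm polyp", 10 * x)))
  }
})

test_that("count extraction parses words, digits, x-suffixes; default 1", {
  expect_equal(extract_count("a polyp"), 1L)
  expect_equal(extract_count("two polyps, bx"), 2L)
  expect_equal(extract_count("polyps x3"), 3L)
  expect_equal(extract_count("3 polyps at the cecum"), 3L)
  # a size digit is not a count
  expect_equal(extract_count("two 4 mm polyps at the s-colon, bx"), 2L)
  expect_equal(extract_count("a 12 mm polyp"), 1L)
})

test_that("histology extraction maps concepts and honours negation scope", {
  h <- extract_histology(c(
    "tubular adenoma with high grade dysplasia",
    "sessile serrated lesion",
    "adenocarcinoma",
    "tubular adenoma, no dysplasia",
    "hyperplastic polyps, x2",
    "sessile serrated adenoma/polyp with low grade dysplasia",
    "unremarkable colonic mucosa"
  ), lex)
  expect_equal(h$histology_category,
               c("adenoma", "serrated", "carcinoma", "adenoma", "serrated",
                 "serrated", "other"))
  expect_equal(h$histology_subtype,
               c("tubular", "ssl", "none", "tubular", "hyperplastic",
                 "ssl", "none"))
  expect_equal(h$dysplasia,
               c("high", "none", "none", "none", "none", "low", "none"))
})

test_that("findings composition combines sentence and specimen evidence", {
  l <- link_reports("A 12 mm polyp at the sigmoid colon, bx.",
                    "1. Colon, sigmoid, polypectomy: Tubular adenoma.", lex)
  f <- build_findings(l, lex)
  expect_equal(f$location_segment, "sigmoid")
  expect_equal(f$side, "left")
  expect_equal(f$size_mm, 12)
  expect_equal(f$count, 1L)
  expect_equal(f$histology_category, "adenoma")
  expect_equal(f$histology_subtype, "tubular")

  expect_equal(nrow(build_findings(
    link_reports("No lesion seen.", NULL, lex), lex)), 0)

  # unlinked biopsy sentence: histology (other, none, none)
  f2 <- build_findings(link_reports("A polyp at the a-colon, bx.", NULL, lex),
                       lex)
  expect_equal(f2$histology_category, "other")
  expect_equal(f2$location_segment, "ascending")
  expect_true(f2$mismatch_flag)

  # a sentence naming two segments emits one flagged finding per segment
  f3 <- build_findings(link_reports(
    "Polyps at the sigmoid colon and the cecum, bx.",
    "1. Tubular adenoma.", lex), lex)
  expect_equal(sort(f3$location_segment), c("cecum", "sigmoid"))
  expect_true(all(f3$review_flag))
})
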