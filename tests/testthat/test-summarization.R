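test_that("summary flags follow the advanced-lesion definitions", {
  # adenoma >= 10 mm on the right
  s <- summarize_procedure(finding_row(size_mm = 12, segment = "ascending"))
  expect_true(s$adenoma_present && s$adenoma_advanced)
  expect_equal(s$adenoma_side, "right_only")
  expect_equal(s$advanced_adenoma_side, "right_only")

  # SSL with low-grade dysplasia is advanced regardless of size
  s2 <- summarize_procedure(finding_row(size_mm = 6, category = "serrated",
                                        subtype = "ssl", dysplasia = "low"))
  expect_true(s2$ssl_present && s2$ssl_advanced && s2$any_ssl_dysplasia)

  # left + right adenomas -> both, counts sum over findings
  s3 <- summarize_procedure(dplyr::bind_rows(
    finding_row(segment = "sigmoid"), finding_row(segment = "cecum")))
  expect_equal(s3$adenoma_side, "both")
  expect_equal(s3$n_adenomas, 2L)

  # multiplicity contributes to the class count
  s4 <- summarize_procedure(finding_row(count = 3))
  expect_equal(s4$n_adenomas, 3L)

  # carcinoma never sets the adenoma flags; HPs are serrated but not SSLs
  s5 <- summarize_procedure(dplyr::bind_rows(
    finding_row(category = "carcinoma", subtype = "none", size_mm = 30),
    finding_row(category = "serrated", subtype = "hyperplastic")))
  expect_true(s5$carcinoma_present)
  expect_false(s5$adenoma_present)
  expect_false(s5$ssl_present)

  # unknown side contributes to presence/counts but not side categories
  s6 <- summarize_procedure(finding_row(segment = "unknown", side = "unknown"))
  expect_true(s6$adenoma_present)
  expect_equal(s6$adenoma_side, "none")

  # missing size never satisfies the >= 1 cm criterion
  s7 <- summarize_procedure(finding_row(size_mm = NA))
  expect_false(s7$adenoma_advanced)
})

test_that("advanced flags equal a brute-force re-evaluation on a grid", {
  sizes <- c(NA, 5, 9, 10, 15)
  dys <- c("none", "low", "high")
  subtypes <- c("tubular", "tubulovillous", "villous", "none")
  for (sz in sizes) for (d in dys) for (st in subtypes) {
    s <- summarize_procedure(finding_row(size_mm = sz, dysplasia = d,
                                         subtype = st))
    expected <- (!is.na(sz) && sz >= 10) || d == "high" ||
      st %in% c("tubulovillous", "villous")
    expect_equal(s$adenoma_advanced, expected,
                 info = sprintf("size=%s dys=%s sub=%s", sz, d, st))
  }
  for (sz in sizes) for (d in dys) {
    s <- summarize_procedure(finding_row(size_mm = sz, dysplasia = d,
                                         category = "serrated",
                                         subtype = "ssl"))
    expected <- (!is.na(sz) && sz >= 10) || d %in% c("low", "high")
    expect_equal(s$ssl_advanced, expected,
                 info = sprintf("ssl size=%s dys=%s", sz, d))
  }
})

test_that("summaries are invariant to the order of findings", {
  f <- dplyr::bind_rows(
    finding_row(segment = "cecum", size_mm = 12),
    finding_row(segment = "sigmoid", size_mm = 4, count = 2L),
    finding_row(category = "serrated", subtype = "ssl", size_mm = 5,
                segment = "ascending"))
  s1 <- summarize_procedure(f)
  s2 <- summarize_procedure(f[c(3, 1, 2), ])
  expect_equal(s1, s2)
})

test_that("procedures without findings get all-negative summaries", {
  s <- summarize_procedures(
    finding_row()[0, ],
    tibble::tibble(report_id = c("a", "b"), endoscopist_id = "E1"))
  expect_equal(nrow(s), 2)
  expect_false(any(s$adenoma_present))
  expect_equal(s$adenoma_side, c("none", "none"))
  expect_equal(s$n_adenomas, c(0L, 0L))
})

test_that("lesion counts bin into the reporting bins", {
  expect_equal(as.character(bin_count(c(0, 1, 2, 3, 4, 5, 10, 11, 20))),
               c("0", "1-2", "1-2", "3-4", "3-4", "5-10", "5-10", ">10",
                 ">10"))
  expect_error(bin_count(-1))
})
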