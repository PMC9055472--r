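test_that("configs validate before any sampling", {
  expect_error(synth_config(n_procedures = -1), "nonnegative")
  bad <- default_endoscopist_profiles()
  bad$share <- bad$share * 2
  expect_error(synth_config(endoscopist_profiles = bad), "sum to 1")
  bad2 <- default_endoscopist_profiles()
  bad2$adr[1] <- 1.5
  expect_error(synth_config(endoscopist_profiles = bad2), "\\[0, 1\\]")
})

test_that("same config and seed produce an identical corpus", {
  cfg <- synth_config(n_procedures = 10, seed = 77)
  a <- generate_corpus(cfg)
  b <- generate_corpus(cfg)
  expect_identical(a$colonoscopy, b$colonoscopy)
  expect_identical(a$pathology, b$pathology)
  expect_identical(a$gold_findings, b$gold_findings)
  # and the written files are byte-identical
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_corpus(cfg, d1); generate_corpus(cfg, d2)
  expect_identical(readLines(file.path(d1, "corpus.jsonl")),
                   readLines(file.path(d2, "corpus.jsonl")))
})

test_that("degenerate and empty configurations behave", {
  prof <- default_endoscopist_profiles()
  prof$adr <- 0
  prof$sdr <- 0
  cfg <- synth_config(n_procedures = 50, seed = 3,
                      endoscopist_profiles = prof, hp_probability = 0,
                      tsa_probability = 0, carcinoma_probability = 0)
  corp <- generate_corpus(cfg)
  expect_false(any(corp$gold_summaries$adenoma_present))
  expect_equal(nrow(corp$pathology), 0)
  # n = 0: empty but well-formed outputs
  d <- withr::local_tempdir()
  empty <- generate_corpus(synth_config(n_procedures = 0, seed = 1), d)
  expect_equal(nrow(empty$colonoscopy), 0)
  expect_true(file.exists(file.path(d, "manifest.json")))
  expect_equal(jsonlite::fromJSON(file.path(d, "manifest.json"))$n_procedures,
               0)
})

test_that("gold records are internally consistent", {
  corp <- clean_corpus(n = 60, seed = 5)$corpus
  re_sum <- summarize_procedures(
    corp$gold_findings,
    dplyr::select(corp$colonoscopy, report_id, endoscopist_id, age))
  expect_equal(re_sum$adenoma_present, corp$gold_summaries$adenoma_present)
  expect_equal(re_sum$n_adenomas, corp$gold_summaries$n_adenomas)
  re_asg <- assign_interval(re_sum)
  expect_equal(as.character(re_asg$interval_group),
               as.character(corp$gold_assignments$interval_group))
  # every procedure with >= 1 biopsied polyp has exactly one pathology report
  with_polyp <- unique(corp$gold_findings$report_id)
  expect_setequal(corp$pathology$colonoscopy_report_id, with_polyp)
})

test_that("the gold ADR of a 2000-procedure corpus sits in its binomial band", {
  # overall configured ADR is the share-weighted profile mean (0.368);
  # the 99% binomial interval is the stated oracle for the empirical rate
  corp <- clean_corpus()
  prof <- default_endoscopist_profiles()
  p <- sum(prof$share * prof$adr)
  n <- nrow(corp$corpus$gold_summaries)
  lo <- qbinom(0.005, n, p) / n
  hi <- qbinom(0.995, n, p) / n
  adr <- mean(corp$corpus$gold_summaries$adenoma_present)
  expect_gte(adr, lo)
  expect_lte(adr, hi)
})

test_that("JSONL corpus round-trips through the reader", {
  d <- withr::local_tempdir()
  cfg <- synth_config(n_procedures = 25, seed = 19)
  corp <- generate_corpus(cfg, d)
  back <- read_corpus(file.path(d, "corpus.jsonl"))
  expect_equal(nrow(back$colonoscopy), 25)
  expect_equal(back$colonoscopy$findings_text, corp$colonoscopy$findings_text)
  expect_equal(back$pathology$diagnosis_text, corp$pathology$diagnosis_text)
  res <- process_corpus(back$colonoscopy, back$pathology)
  ev <- evaluate_summaries(res$summaries, corp$gold_summaries)
  expect_true(all(ev$f1 == 1))
})
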