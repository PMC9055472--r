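test_that("detection rates are positive-procedure proportions", {
  s <- tibble::tibble(
    report_id = sprintf("r%d", 1:10), age = 60,
    adenoma_present = c(rep(TRUE, 4), rep(FALSE, 6)),
    adenoma_advanced = c(TRUE, rep(FALSE, 9)),
    ssl_present = c(TRUE, TRUE, rep(FALSE, 8)),
    ssl_advanced = FALSE)
  r <- detection_rates(s)
  expect_equal(r$adr, 0.4)
  expect_equal(r$sdr, 0.2)
  expect_equal(r$adv_adr, 0.1)
  expect_equal(r$adv_sdr, 0)
  expect_error(detection_rates(s[0, ]), "empty cohort")
  # all-positive and all-negative extremes
  expect_equal(detection_rates(dplyr::mutate(s, adenoma_present = TRUE))$adr, 1)
  expect_equal(detection_rates(dplyr::mutate(s, adenoma_present = FALSE))$adr, 0)
  # age filter applies before computation
  s$age[1:5] <- 40
  expect_equal(detection_rates(s)$n_procedures, 5)
})

test_that("per-endoscopist profiles respect the strict volume threshold", {
  s <- tibble::tibble(
    report_id = sprintf("r%d", 1:1001), age = 60,
    endoscopist_id = c(rep("A", 501), rep("B", 500)),
    adenoma_present = FALSE, adenoma_advanced = FALSE,
    ssl_present = FALSE, ssl_advanced = FALSE)
  p <- per_endoscopist(s)
  expect_equal(p$endoscopist_id, "A")   # B has exactly 500 -> excluded
  expect_equal(p$adr, 0)
  expect_equal(p$n_procedures, 501)
})

test_that("range statistics reproduce reported differences and fold ratios", {
  prof <- profiles_from_counts(tibble::tibble(
    endoscopist_id = c("hi", "lo"),
    n_procedures = c(1876, 1615),
    n_adenoma_positive = c(1055, 264),
    n_advanced_adenoma_positive = c(0, 0),
    n_ssl_positive = c(124, 6),
    n_advanced_ssl_positive = c(0, 0)))
  rs <- range_stats(prof, "adr")
  expect_equal(rs$difference_pct, 39.9)
  expect_equal(rs$fold_ratio, 3.4)
  expect_equal(rs$max_id, "hi")
  rs2 <- range_stats(prof, "sdr")
  expect_equal(rs2$difference_pct, 6.2)
  expect_equal(rs2$fold_ratio, 16.5)
  # identical profiles: difference 0, fold 1; zero minimum: fold undefined
  same <- profiles_from_counts(tibble::tibble(
    endoscopist_id = c("a", "b"), n_procedures = 100,
    n_adenoma_positive = 40, n_advanced_adenoma_positive = 0,
    n_ssl_positive = 0, n_advanced_ssl_positive = 0))
  expect_equal(range_stats(same, "adr")$difference_pct, 0)
  expect_equal(range_stats(same, "adr")$fold_ratio, 1)
  expect_true(is.na(range_stats(same, "sdr")$fold_ratio))
  expect_error(range_stats(same[1, ], "adr"), "at least 2")
})

test_that("interval distributions normalize within bands", {
  # the bundled band totals include a handful of procedures outside the six
  # listed groups, so fixture percentages sum to just under 100
  counts <- dplyr::filter(tenyr_interval_band_counts(), rate == "adr")
  d <- interval_distribution_from_counts(counts)
  sums <- tapply(d$pct, d$band, sum)
  expect_true(all(sums > 99.5 & sums <= 100.01))
  # from assignments: empty bands yield zero rows, percentages still sum
  asg <- tibble::tibble(
    report_id = sprintf("r%d", 1:6),
    endoscopist_id = c(rep("A", 3), rep("B", 3)),
    interval_group = c("y10", "y10", "y3", "y10", "y7_10", "y7_10"))
  prof <- tibble::tibble(endoscopist_id = c("A", "B"),
                         adr_pct = c(50, 20))
  prof$band <- factor(c("high", "low"), levels = c("low", "mid", "high"))
  dist <- interval_distribution(asg, prof)
  expect_equal(sum(dist$n[dist$band == "mid"]), 0)
  expect_equal(dist$pct[dist$band == "high" & dist$interval_group == "y10"],
               round(200 / 3, 2))
})

test_that("banding uses inclusive middle edges on reported percentages", {
  prof <- profiles_from_counts(tibble::tibble(
    endoscopist_id = c("a", "b", "c", "d"),
    n_procedures = 1000,
    n_adenoma_positive = c(299, 300, 450, 451),
    n_advanced_adenoma_positive = 0, n_ssl_positive = 0,
    n_advanced_ssl_positive = 0))
  b <- band_endoscopists(prof, "adr")
  expect_equal(as.character(b$band), c("low", "mid", "mid", "high"))
})

test_that("group comparisons match the textbook statistics", {
  even <- compare_groups(matrix(c(10, 10, 10, 10), 2))
  expect_equal(even$statistic, 0)
  expect_equal(even$p_value, 1)
  # hand computation: all expected cells 15, sum((O-E)^2/E) = 4*25/15
  skewed <- compare_groups(matrix(c(20, 10, 10, 20), 2))
  expect_equal(skewed$statistic, 4 * 25 / 15)
  expect_error(compare_groups(matrix(c(0, 0, 5, 5), 2)), "empty margin")
  tt <- compare_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(tt$statistic, 0)
})

test_that("overall counts equal the sum over endoscopists", {
  corp <- clean_corpus()
  prof <- per_endoscopist(corp$result$summaries, corp$result$assignments,
                          cohort_filter(min_procedures = 0))
  ov <- detection_rates(corp$result$summaries)
  expect_equal(sum(prof$n_adenoma_positive), ov$n_adenoma_positive)
  expect_equal(sum(prof$n_ssl_positive), ov$n_ssl_positive)
  expect_equal(sum(prof$n_procedures), ov$n_procedures)
})
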