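# Shared synthetic corpora, generated once per test run. Seeds are fixed so
# the suite is deterministic; the clean corpus doubles as the round-trip and
# rate-recovery fixture.

.corpus_cache <- new.env(parent = emptyenv())

clean_corpus <- function(n = 2000, seed = 101) {
  key <- sprintf("clean_%d_%d", n, seed)
  if (!exists(key, envir = .corpus_cache)) {
    cfg <- synth_config(n_procedures = n, seed = seed)
    corp <- generate_corpus(cfg)
    res <- process_corpus(corp$colonoscopy, corp$pathology)
    assign(key, list(config = cfg, corpus = corp, result = res),
           envir = .corpus_cache)
  }
  get(key, envir = .corpus_cache)
}

mismatch_corpus <- function(n = 1000, seed = 202, p = 0.1) {
  key <- sprintf("mis_%d_%d", n, seed)
  if (!exists(key, envir = .corpus_cache)) {
    cfg <- synth_config(n_procedures = n, seed = seed,
                        specimen_mismatch_probability = p)
    corp <- generate_corpus(cfg)
    res <- process_corpus(corp$colonoscopy, corp$pathology)
    assign(key, list(config = cfg, corpus = corp, result = res),
           envir = .corpus_cache)
  }
  get(key, envir = .corpus_cache)
}

# A hand-built findings row with sensible defaults, for summarization and
# guideline tests.
finding_row <- function(report_id = "r1", segment = "sigmoid",
                        side = NULL, size_mm = 5, count = 1L,
                        category = "adenoma", subtype = "tubular",
                        dysplasia = "none", cm = NA_real_) {
  tibble::tibble(
    report_id = report_id,
    location_segment = segment,
    cm_from_anal_verge = cm,
    side = if (is.null(side)) polyp_side(segment, cm) else side,
    size_mm = size_mm,
    count = as.integer(count),
    histology_category = category,
    histology_subtype = subtype,
    dysplasia = dysplasia,
    review_flag = FALSE,
    mismatch_flag = FALSE
  )
}

# Random but internally consistent ProcedureSummary rows for property tests.
random_summaries <- function(n, seed) {
  withr::with_seed(seed, {
    n_adenomas <- sample(0:15, n, replace = TRUE,
                         prob = c(0.4, rep(0.04, 15)))
    n_ssls <- sample(0:8, n, replace = TRUE, prob = c(0.6, rep(0.05, 8)))
    max_a <- ifelse(n_adenomas == 0, NA_real_,
                    sample(c(NA, 2:25), n, replace = TRUE))
    max_s <- ifelse(n_ssls == 0, NA_real_,
                    sample(c(NA, 2:20), n, replace = TRUE))
    tibble::tibble(
      report_id = sprintf("r%05d", seq_len(n)),
      n_adenomas = n_adenomas,
      n_ssls = n_ssls,
      adenoma_present = n_adenomas > 0,
      ssl_present = n_ssls > 0,
      carcinoma_present = stats::runif(n) < 0.01,
      adenoma_advanced = n_adenomas > 0 & stats::runif(n) < 0.15,
      ssl_advanced = n_ssls > 0 & stats::runif(n) < 0.2,
      adenoma_side = sample(c("none", "right_only", "left_only", "both"),
                            n, replace = TRUE),
      ssl_side = sample(c("none", "right_only", "left_only", "both"),
                        n, replace = TRUE),
      advanced_adenoma_side = "none",
      advanced_ssl_side = "none",
      max_adenoma_size_mm = max_a,
      max_ssl_size_mm = max_s,
      any_villous_or_hgd = n_adenomas > 0 & stats::runif(n) < 0.1,
      any_ssl_dysplasia = n_ssls > 0 & stats::runif(n) < 0.1,
      any_tsa = stats::runif(n) < 0.01,
      any_hp_ge10mm = stats::runif(n) < 0.02
    )
  })
}

# Interval ordering for monotonicity checks: refer (carcinoma) is the most
# restrictive outcome, y10 the least.
interval_rank <- function(group) {
  ord <- c(refer = 0, y1 = 1, y3 = 2, y3_5 = 3, y5_10 = 4, y7_10 = 5,
           y10 = 6)
  unname(ord[as.character(group)])
}
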