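# Synthetic paired-report generator: templated colonoscopy findings and
# pathology diagnosis sections with gold labels, so the whole pipeline is
# testable without clinical data.

#' Default synthetic endoscopist profiles
#'
#' Five endoscopists spanning ADR 0.16-0.56 and SDR 0.004-0.066, mirroring
#' the spread observed across screening programs, with equal procedure
#' shares. `adv_adenoma_frac` (`adv_ssl_frac`) is the probability that an
#' adenoma-positive (SSL-positive) procedure harbours an advanced lesion.
#'
#' @return Tibble with columns `endoscopist_id`, `adr`, `sdr`,
#'   `adv_adenoma_frac`, `adv_ssl_frac`, `share`.
#' @export
default_endoscopist_profiles <- function() {
  tibble(
    endoscopist_id = paste0("E", 1:5),
    adr = c(0.16, 0.27, 0.38, 0.47, 0.56),
    sdr = c(0.004, 0.018, 0.030, 0.045, 0.066),
    adv_adenoma_frac = 0.08,
    adv_ssl_frac = 0.16,
    share = 0.2
  )
}

#' Configuration for the synthetic corpus generator
#'
#' Defaults emulate a screening cohort: per-endoscopist detection targets
#' via [default_endoscopist_profiles()], a lesion-count distribution
#' concentrated on 1-2 polyps with a tail to 12, sizes mostly 2-9 mm with
#' advanced lesions at 10-20 mm, all 10 anatomical segments plus cm-only
#' location mentions, and an adenoma subtype mixture dominated by tubular
#' adenomas. Noise channels (specimen-count mismatches, distractor
#' sentences) default to the values noted per field; the same
#' (config, seed) pair always yields an identical corpus.
#'
#' @param n_procedures Number of colonoscopies to generate.
#' @param seed Integer seed; the generator draws from a single RNG stream in
#'   procedure order.
#' @param endoscopist_profiles See [default_endoscopist_profiles()].
#' @param polyps_per_positive Probability weights over 1..12 adenomas in an
#'   adenoma-positive procedure.
#' @param ssls_per_positive Probability weights over 1..6 SSLs in an
#'   SSL-positive procedure.
#' @param cm_mention_prob Probability a polyp's location is written as a
#'   distance from the anal verge instead of a named segment.
#' @param abbreviation_probability Probability a segment or marker is
#'   rendered as its endoscopic abbreviation.
#' @param label_probability Probability a procedure's biopsy sentences carry
#'   explicit "#k" specimen labels.
#' @param hp_probability Probability of incidental hyperplastic polyps.
#' @param hp_ge10_probability Probability a hyperplastic polyp is >= 10 mm.
#' @param tsa_probability Probability of a traditional serrated adenoma.
#' @param carcinoma_probability Probability of a carcinoma.
#' @param lgd_probability Probability a non-advanced adenoma carries
#'   low-grade dysplasia wording.
#' @param missing_size_probability Probability a polyp's size is not stated.
#' @param distractor_sentence_probability Probability of inserting
#'   non-biopsy distractor sentences into the findings section.
#' @param specimen_mismatch_probability Probability of dropping one specimen
#'   from the pathology report (injected linkage noise, gold-flagged).
#' @return A validated `colonlp_synth_config` list.
#' @export
synth_config <- function(n_procedures = 1000,
                         seed = 20200101,
                         endoscopist_profiles = default_endoscopist_profiles(),
                         polyps_per_positive = c(0.55, 0.25, 0.10, 0.05,
                                                 0.02, 0.01, 0.006, 0.004,
                                                 0.002, 0.002, 0.002, 0.004),
                         ssls_per_positive = c(0.70, 0.20, 0.06, 0.02,
                                               0.01, 0.01),
                         cm_mention_prob = 0.12,
                         abbreviation_probability = 0.4,
                         label_probability = 0.2,
                         hp_probability = 0.18,
                         hp_ge10_probability = 0.01,
                         tsa_probability = 0.004,
                         carcinoma_probability = 0.0015,
                         lgd_probability = 0.15,
                         missing_size_probability = 0.05,
                         distractor_sentence_probability = 0.3,
                         specimen_mismatch_probability = 0) {
  cfg <- list(
    n_procedures = as.integer(n_procedures), seed = as.integer(seed),
    endoscopist_profiles = as_tibble(endoscopist_profiles),
    polyps_per_positive = polyps_per_positive / sum(polyps_per_positive),
    ssls_per_positive = ssls_per_positive / sum(ssls_per_positive),
    cm_mention_prob = cm_mention_prob,
    abbreviation_probability = abbreviation_probability,
    label_probability = label_probability,
    hp_probability = hp_probability,
    hp_ge10_probability = hp_ge10_probability,
    tsa_probability = tsa_probability,
    carcinoma_probability = carcinoma_probability,
    lgd_probability = lgd_probability,
    missing_size_probability = missing_size_probability,
    distractor_sentence_probability = distractor_sentence_probability,
    specimen_mismatch_probability = specimen_mismatch_probability
  )
  .validate_synth_config(cfg)
  structure(cfg, class = "colonlp_synth_config")
}

#' @noRd
.validate_synth_config <- function(cfg) {
  if (is.na(cfg$n_procedures) || cfg$n_procedures < 0) {
    stop("n_procedures must be a nonnegative integer", call. = FALSE)
  }
  p <- cfg$endoscopist_profiles
  need <- c("endoscopist_id", "adr", "sdr", "adv_adenoma_frac",
            "adv_ssl_frac", "share")
  if (!all(need %in% names(p))) {
    stop("endoscopist_profiles needs columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (abs(sum(p$share) - 1) > 1e-8) {
    stop("endoscopist shares must sum to 1", call. = FALSE)
  }
  probs <- c(p$adr, p$sdr, p$adv_adenoma_frac, p$adv_ssl_frac, p$share,
             cfg$cm_mention_prob, cfg$abbreviation_probability,
             cfg$label_probability, cfg$hp_probability,
             cfg$hp_ge10_probability, cfg$tsa_probability,
             cfg$carcinoma_probability, cfg$lgd_probability,
             cfg$missing_size_probability,
             cfg$distractor_sentence_probability,
             cfg$specimen_mismatch_probability)
  if (any(is.na(probs)) || any(probs < 0) || any(probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  invisible(cfg)
}

# Rendering inventories --------------------------------------------------

#' @noRd
.segment_render <- list(
  rectum = c(full = "rectum", abbrev = "rectum"),
  rectosigmoid = c(full = "rectosigmoid junction", abbrev = "rs junction"),
  sigmoid = c(full = "sigmoid colon", abbrev = "s-colon"),
  descending = c(full = "descending colon", abbrev = "d-colon"),
  splenic_flexure = c(full = "splenic flexure", abbrev = "sf"),
  transverse = c(full = "transverse colon", abbrev = "t-colon"),
  hepatic_flexure = c(full = "hepatic flexure", abbrev = "hf"),
  ascending = c(full = "ascending colon", abbrev = "a-colon"),
  cecum = c(full = "cecum", abbrev = "cecum"),
  ileocecal_valve = c(full = "ileocecal valve", abbrev = "icv")
)

#' @noRd
.segment_weights <- c(rectum = 0.05, rectosigmoid = 0.04, sigmoid = 0.20,
                      descending = 0.12, splenic_flexure = 0.04,
                      transverse = 0.15, hepatic_flexure = 0.07,
                      ascending = 0.22, cecum = 0.08, ileocecal_valve = 0.03)

#' @noRd
.distractors <- c(
  "The bowel preparation was good",
  "A few diverticula were seen in the sigmoid colon",
  "The terminal ileum was normal",
  "Internal hemorrhoids were noted",
  "The mucosa was unremarkable, see note"
)

#' @noRd
.negative_findings <- c(
  "The colonoscopy was normal to the cecum. No polyp was seen.",
  "The exam was unremarkable. The cecum and the icv appeared normal.",
  "No polyp or mass was seen. Withdrawal was uneventful."
)

# Sampling ---------------------------------------------------------------

# One polyp finding as a plain list. class: adenoma / ssl / hp / tsa /
# carcinoma; advanced_via: none / size / feature.
#' @noRd
.sample_finding <- function(cfg, class, advanced, count = 1L) {
  cm_only <- runif(1) < cfg$cm_mention_prob
  if (cm_only) {
    segment <- "unknown"
    cm <- sample(15:85, 1)
  } else {
    segment <- sample(names(.segment_weights), 1, prob = .segment_weights)
    cm <- NA_real_
  }
  size <- sample(2:9, 1)
  dysplasia <- "none"
  subtype <- switch(class, adenoma = "tubular", ssl = "ssl",
                    hp = "hyperplastic", tsa = "tsa", carcinoma = "none")
  category <- switch(class, adenoma = "adenoma", ssl = , hp = ,
                     tsa = "serrated", carcinoma = "carcinoma")
  if (class == "adenoma") {
    if (advanced) {
      via <- sample(c("size", "hgd", "tv", "villous"), 1,
                    prob = c(0.55, 0.25, 0.15, 0.05))
      if (via == "size") size <- sample(10:20, 1)
      if (via == "hgd") dysplasia <- "high"
      if (via == "tv") subtype <- "tubulovillous"
      if (via == "villous") subtype <- "villous"
    } else if (runif(1) < cfg$lgd_probability) {
      dysplasia <- "low"
    }
  } else if (class == "ssl") {
    if (advanced) {
      via <- sample(c("size", "lgd", "hgd"), 1, prob = c(0.5, 0.35, 0.15))
      if (via == "size") size <- sample(10:18, 1)
      if (via == "lgd") dysplasia <- "low"
      if (via == "hgd") dysplasia <- "high"
    }
  } else if (class == "hp") {
    if (runif(1) < cfg$hp_ge10_probability) size <- sample(10:14, 1)
  } else if (class == "carcinoma") {
    size <- sample(15:40, 1)
  }
  # sizes may be unstated, but never on lesions whose advanced status
  # depends on the size criterion
  size_missing <- runif(1) < cfg$missing_size_probability && size < 10
  list(class = class, segment = segment, cm = cm,
       size_mm = if (size_missing) NA_real_ else as.numeric(size),
       count = as.integer(count), histology_category = category,
       histology_subtype = subtype, dysplasia = dysplasia)
}

# Split a lesion total into findings with multiplicities 1-3.
#' @noRd
.split_counts <- function(total) {
  out <- integer(0)
  while (total > 0) {
    c_i <- min(total, sample(1:3, 1, prob = c(0.7, 0.25, 0.05)))
    out <- c(out, c_i)
    total <- total - c_i
  }
  out
}

#' @noRd
.sample_findings_for_procedure <- function(cfg, prof) {
  findings <- list()
  if (runif(1) < prof$adr) {
    total <- sample(1:12, 1, prob = cfg$polyps_per_positive)
    counts <- .split_counts(total)
    adv <- runif(1) < prof$adv_adenoma_frac
    adv_idx <- if (adv) sample(seq_along(counts), 1) else 0L
    for (j in seq_along(counts)) {
      findings[[length(findings) + 1]] <-
        .sample_finding(cfg, "adenoma", advanced = j == adv_idx,
                        count = counts[j])
    }
  }
  if (runif(1) < prof$sdr) {
    total <- sample(1:6, 1, prob = cfg$ssls_per_positive)
    counts <- .split_counts(total)
    counts <- counts[counts <= 2]
    if (length(counts) == 0) counts <- 1L
    adv <- runif(1) < prof$adv_ssl_frac
    adv_idx <- if (adv) sample(seq_along(counts), 1) else 0L
    for (j in seq_along(counts)) {
      findings[[length(findings) + 1]] <-
        .sample_finding(cfg, "ssl", advanced = j == adv_idx,
                        count = counts[j])
    }
  }
  if (runif(1) < cfg$hp_probability) {
    for (j in seq_len(sample(1:2, 1, prob = c(0.8, 0.2)))) {
      findings[[length(findings) + 1]] <-
        .sample_finding(cfg, "hp", advanced = FALSE)
    }
  }
  if (runif(1) < cfg$tsa_probability) {
    findings[[length(findings) + 1]] <-
      .sample_finding(cfg, "tsa", advanced = FALSE)
  }
  if (runif(1) < cfg$carcinoma_probability) {
    findings[[length(findings) + 1]] <-
      .sample_finding(cfg, "carcinoma", advanced = FALSE)
  }
  if (length(findings) > 1) findings <- findings[sample(length(findings))]
  findings
}

# Rendering --------------------------------------------------------------

#' @noRd
.render_segment <- function(f, cfg) {
  if (f$segment == "unknown") {
    if (runif(1) < 0.5) {
      sprintf("at %d cm from the AV", f$cm)
    } else {
      sprintf("at %d cm", f$cm)
    }
  } else {
    style <- if (runif(1) < cfg$abbreviation_probability) "abbrev" else "full"
    paste0(sample(c("at the ", "in the "), 1),
           .segment_render[[f$segment]][[style]])
  }
}

#' @noRd
.render_size <- function(f, use_cm_ok) {
  if (is.na(f$size_mm)) return("small")
  if (use_cm_ok && f$size_mm >= 10 && f$size_mm %% 1 == 0 &&
      runif(1) < 0.3) {
    return(sprintf("%.1f cm", f$size_mm / 10))
  }
  sprintf("%d mm", as.integer(f$size_mm))
}

#' @noRd
.render_finding_sentence <- function(f, cfg) {
  seg <- .render_segment(f, cfg)
  marker <- if (runif(1) < cfg$abbreviation_probability) "bx" else
    sample(c("polypectomy", "biopsy"), 1)
  if (f$count == 1L) {
    size <- .render_size(f, use_cm_ok = TRUE)
    size_adj <- if (size == "small") "small" else paste0(size)
    tmpl <- sample(1:3, 1)
    if (tmpl == 1) {
      sprintf("A %s polyp %s, %s.", size_adj, seg, marker)
    } else if (tmpl == 2) {
      sprintf("%s sessile polyp %s, %s done.", size_adj, seg, marker)
    } else {
      sprintf("A %s polyp %s was %s.", size_adj, seg,
              sample(c("removed", "resected"), 1))
    }
  } else {
    word <- names(.count_words)[f$count]
    size <- .render_size(f, use_cm_ok = FALSE)
    tmpl <- sample(1:3, 1)
    if (tmpl == 1) {
      sprintf("%s %s polyps %s, %s.", word, size, seg, marker)
    } else if (tmpl == 2) {
      sprintf("%s polyps %s, up to %s, %s.", word, seg, size, marker)
    } else if (!is.na(f$size_mm) && f$size_mm > 2) {
      sprintf("%s polyps %s, %d-%d mm, %s.", word, seg,
              max(1L, as.integer(f$size_mm) - 2L), as.integer(f$size_mm),
              marker)
    } else {
      sprintf("%s %s polyps %s, %s.", word, size, seg, marker)
    }
  }
}

#' @noRd
.render_histology <- function(f) {
  base <- switch(paste(f$histology_category, f$histology_subtype),
    "adenoma tubular" = "tubular adenoma",
    "adenoma tubulovillous" = "tubulovillous adenoma",
    "adenoma villous" = "villous adenoma",
    "serrated hyperplastic" = "hyperplastic polyp",
    "serrated ssl" = sample(c("sessile serrated lesion",
                              "sessile serrated adenoma/polyp",
                              "sessile serrated adenoma"), 1),
    "serrated tsa" = "traditional serrated adenoma",
    "carcinoma none" = "adenocarcinoma",
    "polyp"
  )
  if (f$count > 1L) base <- paste0(base, "s")
  if (f$dysplasia == "high") {
    base <- paste0(base, " with high grade dysplasia")
  } else if (f$dysplasia == "low" && f$histology_category != "carcinoma") {
    base <- paste0(base, " with low grade dysplasia")
  }
  if (f$count > 1L) base <- sprintf("%s, x%d", base, f$count)
  base
}

#' @noRd
.render_specimen <- function(f, enum) {
  proc <- sample(c("polypectomy", "biopsy", "endoscopic mucosal resection"),
                 1)
  site <- if (f$segment == "unknown") "Colon" else
    paste0("Colon, ", .segment_render[[f$segment]][["full"]])
  sprintf("%s %s, %s: %s.", enum, site, proc, .render_histology(f))
}

#' Sample one synthetic procedure
#'
#' Draws one colonoscopy (with metadata), its pathology report when any
#' polyp was biopsied, and the gold record, using the current RNG state.
#' Prefer [generate_corpus()] for whole corpora; this operation exposes the
#' unit draw.
#'
#' @param config A [synth_config()].
#' @param index Procedure index (used for identifiers).
#' @return List with `colonoscopy` (one-row tibble), `pathology` (one-row
#'   tibble or NULL), `gold_findings` (tibble, possibly empty),
#'   `mismatch_injected` (logical).
#' @export
sample_procedure <- function(config, index = 1L) {
  .validate_synth_config(config)
  prof_i <- sample(nrow(config$endoscopist_profiles), 1,
                   prob = config$endoscopist_profiles$share)
  prof <- config$endoscopist_profiles[prof_i, ]
  report_id <- sprintf("C%06d", index)
  meta <- tibble(
    record_type = "colonoscopy",
    report_id = report_id,
    patient_id = sprintf("P%06d", index),
    endoscopist_id = prof$endoscopist_id,
    exam_date = as.character(as.Date("2010-01-01") + sample(0:3651, 1)),
    age = max(50L, as.integer(round(stats::rnorm(1, 58.6, 6.4)))),
    sex = sample(c("male", "female"), 1, prob = c(0.59, 0.41)),
    indication = sample(c("screening", "surveillance", "other"), 1,
                        prob = c(0.80, 0.15, 0.05))
  )
  findings <- .sample_findings_for_procedure(config, prof)
  mismatch_injected <- FALSE
  if (length(findings) == 0) {
    meta$findings_text <- sample(.negative_findings, 1)
    gold <- .gold_findings_tibble(findings, report_id)
    return(list(colonoscopy = meta, pathology = NULL, gold_findings = gold,
                mismatch_injected = FALSE))
  }
  use_labels <- runif(1) < config$label_probability
  sentences <- character(length(findings))
  specimens <- character(length(findings))
  for (j in seq_along(findings)) {
    s <- .render_finding_sentence(findings[[j]], config)
    if (use_labels) s <- sprintf("#%d %s", j, s)
    sentences[j] <- s
    enum <- if (use_labels) sprintf("#%d.", j) else sprintf("%d.", j)
    specimens[j] <- .render_specimen(findings[[j]], enum)
  }
  if (runif(1) < config$distractor_sentence_probability) {
    extra <- sample(.distractors, sample(1:2, 1, prob = c(0.7, 0.3)))
    pos <- sort(sample(length(sentences) + 1, length(extra),
                       replace = TRUE))
    merged <- sentences
    for (k in rev(seq_along(extra))) {
      merged <- append(merged, paste0(extra[k], "."), after = pos[k] - 1)
    }
    sentences <- merged
  }
  if (runif(1) < config$specimen_mismatch_probability) {
    specimens <- specimens[-length(specimens)]
    mismatch_injected <- TRUE
  }
  meta$findings_text <- paste(sentences, collapse = " ")
  pathology <- tibble(
    record_type = "pathology",
    report_id = paste0(!!report_id, "-P"),
    colonoscopy_report_id = !!report_id,
    diagnosis_text = paste(specimens, collapse = "\n")
  )
  list(colonoscopy = meta, pathology = pathology,
       gold_findings = .gold_findings_tibble(findings, report_id),
       mismatch_injected = mismatch_injected)
}

#' @noRd
.gold_findings_tibble <- function(findings, report_id) {
  if (length(findings) == 0) {
    return(tibble(report_id = character(0), ordinal = integer(0),
                  location_segment = character(0),
                  cm_from_anal_verge = numeric(0), side = character(0),
                  size_mm = numeric(0), count = integer(0),
                  histology_category = character(0),
                  histology_subtype = character(0), dysplasia = character(0)))
  }
  tibble(
    report_id = report_id,
    ordinal = seq_along(findings),
    location_segment = vapply(findings, `[[`, "", "segment"),
    cm_from_anal_verge = vapply(findings, function(f) as.numeric(f$cm), 0),
    side = polyp_side(vapply(findings, `[[`, "", "segment"),
                      vapply(findings, function(f) as.numeric(f$cm), 0)),
    size_mm = vapply(findings, `[[`, 0, "size_mm"),
    count = vapply(findings, `[[`, 0L, "count"),
    histology_category = vapply(findings, `[[`, "", "histology_category"),
    histology_subtype = vapply(findings, `[[`, "", "histology_subtype"),
    dysplasia = vapply(findings, `[[`, "", "dysplasia")
  )
}

#' Generate a synthetic paired-report corpus with gold labels
#'
#' Draws `config$n_procedures` procedures from a single RNG stream seeded
#' with `config$seed` (procedure order, so the same configuration always
#' produces an identical corpus), renders the reports, and computes the
#' gold summaries and surveillance assignments from the gold findings with
#' the same rollup and decision table the pipeline uses, so gold records
#' are internally consistent by construction.
#'
#' @param config A [synth_config()].
#' @param out_dir Optional directory; when given, writes `corpus.jsonl`
#'   (colonoscopy and pathology records distinguished by `record_type`),
#'   `gold.jsonl` and `manifest.json`.
#' @return (Invisibly when writing) a list: `colonoscopy`, `pathology`,
#'   `gold_findings`, `gold_summaries`, `gold_assignments` tibbles and
#'   `manifest` (config echo plus injected-mismatch count).
#' @export
generate_corpus <- function(config, out_dir = NULL) {
  .validate_synth_config(config)
  out <- .with_seed(config$seed, {
    colos <- vector("list", config$n_procedures)
    paths <- vector("list", config$n_procedures)
    golds <- vector("list", config$n_procedures)
    mism <- logical(config$n_procedures)
    for (i in seq_len(config$n_procedures)) {
      p <- sample_procedure(config, index = i)
      colos[[i]] <- p$colonoscopy
      paths[[i]] <- p$pathology
      golds[[i]] <- p$gold_findings
      mism[i] <- p$mismatch_injected
    }
    list(colos = colos, paths = paths, golds = golds, mism = mism)
  })
  colonoscopy <- bind_rows(out$colos)
  pathology <- bind_rows(out$paths)
  gold_findings <- bind_rows(out$golds)
  procedures <- if (nrow(colonoscopy) > 0) {
    select(colonoscopy, "report_id", "endoscopist_id", "patient_id",
           "exam_date", "age", "sex", "indication")
  } else {
    tibble(report_id = character(0), endoscopist_id = character(0),
           patient_id = character(0), exam_date = character(0),
           age = integer(0), sex = character(0), indication = character(0))
  }
  gold_summaries <- summarize_procedures(gold_findings, procedures)
  gold_assignments <- assign_interval(gold_summaries)
  manifest <- list(
    n_procedures = config$n_procedures,
    seed = config$seed,
    specimen_mismatch_probability = config$specimen_mismatch_probability,
    n_mismatch_injected = sum(out$mism),
    n_pathology_reports = nrow(pathology)
  )
  res <- list(colonoscopy = colonoscopy, pathology = pathology,
              gold_findings = gold_findings,
              gold_summaries = gold_summaries,
              gold_assignments = gold_assignments,
              mismatch_injected = tibble(
                report_id = if (nrow(colonoscopy) > 0)
                  colonoscopy$report_id else character(0),
                mismatch_injected = out$mism),
              manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    .write_jsonl(bind_rows(colonoscopy, pathology),
                 file.path(out_dir, "corpus.jsonl"))
    gold <- gold_summaries |>
      left_join(select(gold_assignments, "report_id", "interval_group",
                       "interval_years"), by = "report_id") |>
      mutate(interval_group = as.character(.data$interval_group)) |>
      left_join(res$mismatch_injected, by = "report_id")
    .write_jsonl(gold, file.path(out_dir, "gold.jsonl"))
    .write_jsonl(gold_findings, file.path(out_dir, "gold_findings.jsonl"))
    writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
               file.path(out_dir, "manifest.json"))
    return(invisible(res))
  }
  res
}

# Seed handling: run code under a fixed seed, restoring the caller's RNG
# state afterwards.
#' @noRd
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
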