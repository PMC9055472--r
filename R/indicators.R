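# Detection rates, per-endoscopist profiles, range statistics, interval
# distributions and group comparisons.

#' Cohort filter for indicator computation
#'
#' Filters are applied before any rate computation: patients at least
#' `min_age` years old, exams inside `date_range`, indications in
#' `indications`, and (for per-endoscopist reporting) endoscopists with
#' strictly more than `min_procedures` procedures.
#'
#' @param min_age Minimum patient age in years (default 50).
#' @param date_range Length-2 Date vector (inclusive) or NULL.
#' @param min_procedures Per-endoscopist volume threshold, strict `>`
#'   (default 500).
#' @param indications Character vector of included indications or NULL for
#'   all.
#' @return A `colonlp_filter` list.
#' @export
cohort_filter <- function(min_age = 50, date_range = NULL,
                          min_procedures = 500, indications = NULL) {
  structure(list(min_age = min_age, date_range = date_range,
                 min_procedures = min_procedures, indications = indications),
            class = "colonlp_filter")
}

#' Apply a cohort filter to procedure summaries
#'
#' @param summaries `ProcedureSummary` tibble.
#' @param filter A [cohort_filter()].
#' @return Filtered tibble (volume thresholding is applied later, per
#'   endoscopist).
#' @export
apply_cohort_filter <- function(summaries, filter = cohort_filter()) {
  out <- summaries
  if (!is.null(filter$min_age) && "age" %in% names(out)) {
    out <- out[!is.na(out$age) & out$age >= filter$min_age, ]
  }
  if (!is.null(filter$date_range) && "exam_date" %in% names(out)) {
    d <- as.Date(out$exam_date)
    out <- out[!is.na(d) & d >= filter$date_range[1] &
                 d <= filter$date_range[2], ]
  }
  if (!is.null(filter$indications) && "indication" %in% names(out)) {
    out <- out[out$indication %in% filter$indications, ]
  }
  out
}

#' Overall detection rates
#'
#' ADR (SDR) is the proportion of colonoscopies detecting at least one
#' adenoma (SSL); the advanced variants use the advanced flags. Rates are
#' proportions in \[0, 1\]; `pct` columns carry the percentage rounded to
#' 0.1 as reported.
#'
#' @param summaries `ProcedureSummary` tibble.
#' @param filter A [cohort_filter()] applied first.
#' @return One-row tibble with `n_procedures`, positive counts, `adr`,
#'   `adv_adr`, `sdr`, `adv_sdr` and their `*_pct` versions.
#' @export
detection_rates <- function(summaries, filter = cohort_filter()) {
  s <- apply_cohort_filter(summaries, filter)
  if (nrow(s) == 0) {
    stop("empty cohort: no procedures after filtering; rates are undefined",
         call. = FALSE)
  }
  .profile_from_flags(s)
}

#' @noRd
.profile_from_flags <- function(s) {
  tibble(
    n_procedures = nrow(s),
    n_adenoma_positive = sum(s$adenoma_present),
    n_advanced_adenoma_positive = sum(s$adenoma_advanced),
    n_ssl_positive = sum(s$ssl_present),
    n_advanced_ssl_positive = sum(s$ssl_advanced)
  ) |>
    .add_rates()
}

#' @noRd
.add_rates <- function(p) {
  mutate(
    p,
    adr = .data$n_adenoma_positive / .data$n_procedures,
    adv_adr = .data$n_advanced_adenoma_positive / .data$n_procedures,
    sdr = .data$n_ssl_positive / .data$n_procedures,
    adv_sdr = .data$n_advanced_ssl_positive / .data$n_procedures,
    adr_pct = round(100 * .data$adr, 1),
    adv_adr_pct = round(100 * .data$adv_adr, 1),
    sdr_pct = round(100 * .data$sdr, 1),
    adv_sdr_pct = round(100 * .data$adv_sdr, 1)
  )
}

#' Per-endoscopist indicator profiles
#'
#' One profile per endoscopist with strictly more than
#' `filter$min_procedures` procedures in the filtered cohort: procedure and
#' positive counts, detection rates, and (when `assignments` is given) the
#' mean surveillance interval in years, averaged over non-refer assignments
#' with the number of refer cases reported separately.
#'
#' @param summaries `ProcedureSummary` tibble with `endoscopist_id`.
#' @param assignments Optional tibble from [assign_interval()].
#' @param filter A [cohort_filter()].
#' @return Tibble of `EndoscopistProfile` rows.
#' @export
per_endoscopist <- function(summaries, assignments = NULL,
                            filter = cohort_filter()) {
  s <- apply_cohort_filter(summaries, filter)
  if (!is.null(assignments)) {
    s <- s[, setdiff(names(s), c("interval_years", "interval_group"))]
    s <- left_join(s,
                   select(assignments, "report_id", "interval_years",
                          "interval_group"),
                   by = "report_id")
  }
  prof <- s |>
    group_by(.data$endoscopist_id) |>
    summarise(
      n_procedures = n(),
      n_adenoma_positive = sum(.data$adenoma_present),
      n_advanced_adenoma_positive = sum(.data$adenoma_advanced),
      n_ssl_positive = sum(.data$ssl_present),
      n_advanced_ssl_positive = sum(.data$ssl_advanced),
      mean_interval_years = if ("interval_years" %in% names(s)) {
        round(mean(.data$interval_years, na.rm = TRUE), 1)
      } else NA_real_,
      n_refer = if ("interval_group" %in% names(s)) {
        sum(.data$interval_group == "refer", na.rm = TRUE)
      } else NA_integer_
    ) |>
    filter(.data$n_procedures > !!filter$min_procedures) |>
    .add_rates()
  prof
}

#' Build endoscopist profiles from pre-aggregated counts
#'
#' Accepts a counts table (one row per endoscopist with `endoscopist_id`,
#' `n_procedures`, `n_adenoma_positive`, `n_advanced_adenoma_positive`,
#' `n_ssl_positive`, `n_advanced_ssl_positive` and optionally
#' `mean_interval_years`) and derives the rate columns, so published or
#' externally aggregated per-endoscopist counts can flow through
#' [range_stats()] and [interval_distribution_from_counts()].
#'
#' @param counts Counts tibble as above.
#' @return `EndoscopistProfile` tibble.
#' @export
profiles_from_counts <- function(counts) {
  required <- c("endoscopist_id", "n_procedures", "n_adenoma_positive",
                "n_advanced_adenoma_positive", "n_ssl_positive",
                "n_advanced_ssl_positive")
  stopifnot(all(required %in% names(counts)))
  .add_rates(as_tibble(counts))
}

#' Overall profile from per-endoscopist profiles
#'
#' Sums the per-endoscopist counts (conservation: overall positives equal
#' the sum over endoscopists) and recomputes rates; the mean interval is the
#' procedure-weighted mean of the per-endoscopist means.
#'
#' @param profiles `EndoscopistProfile` tibble.
#' @return One-row tibble.
#' @export
overall_profile <- function(profiles) {
  out <- tibble(
    n_procedures = sum(profiles$n_procedures),
    n_adenoma_positive = sum(profiles$n_adenoma_positive),
    n_advanced_adenoma_positive = sum(profiles$n_advanced_adenoma_positive),
    n_ssl_positive = sum(profiles$n_ssl_positive),
    n_advanced_ssl_positive = sum(profiles$n_advanced_ssl_positive)
  ) |>
    .add_rates()
  if ("mean_interval_years" %in% names(profiles) &&
      !anyNA(profiles$mean_interval_years)) {
    out$mean_interval_years <- round(
      sum(profiles$n_procedures * profiles$mean_interval_years) /
        sum(profiles$n_procedures), 1)
  }
  out
}

#' Spread of a detection rate across endoscopists
#'
#' Reports the max-min difference and the max/min fold ratio of one rate
#' across endoscopist profiles, on the percentage scale rounded to 0.1 (the
#' scale on which the rates themselves are reported). The fold ratio is
#' undefined (NA) when the minimum rate is 0.
#'
#' @param profiles `EndoscopistProfile` tibble (>= 2 rows).
#' @param rate_name One of `"adr"`, `"adv_adr"`, `"sdr"`, `"adv_sdr"`.
#' @return One-row tibble: `rate_name`, `difference_pct`, `fold_ratio`,
#'   `max_id`, `min_id`, `max_pct`, `min_pct`.
#' @export
range_stats <- function(profiles, rate_name = c("adr", "adv_adr", "sdr",
                                                "adv_sdr")) {
  rate_name <- match.arg(rate_name)
  if (nrow(profiles) < 2) {
    stop("range statistics need at least 2 endoscopist profiles",
         call. = FALSE)
  }
  pct <- profiles[[paste0(rate_name, "_pct")]]
  i_max <- which.max(pct)
  i_min <- which.min(pct)
  fold <- if (pct[i_min] == 0) NA_real_ else
    round(pct[i_max] / pct[i_min], 1)
  tibble(
    rate_name = rate_name,
    difference_pct = round(pct[i_max] - pct[i_min], 1),
    fold_ratio = fold,
    max_id = as.character(profiles$endoscopist_id[i_max]),
    min_id = as.character(profiles$endoscopist_id[i_min]),
    max_pct = pct[i_max],
    min_pct = pct[i_min]
  )
}

#' @noRd
.band_levels <- c("low", "mid", "high")

#' Band endoscopists by a detection rate
#'
#' Band edges are inclusive on the middle band: low < edges\[1\] <= mid <=
#' edges\[2\] < high, applied to the 0.1-rounded percentage. Defaults are
#' 30/45 for ADR and 2/4 for SDR.
#'
#' @param profiles `EndoscopistProfile` tibble.
#' @param rate_name `"adr"` or `"sdr"`.
#' @param edges Length-2 numeric band edges on the percentage scale.
#' @return `profiles` with a `band` factor column (low/mid/high).
#' @export
band_endoscopists <- function(profiles, rate_name = c("adr", "sdr"),
                              edges = NULL) {
  rate_name <- match.arg(rate_name)
  if (is.null(edges)) edges <- if (rate_name == "adr") c(30, 45) else c(2, 4)
  pct <- profiles[[paste0(rate_name, "_pct")]]
  band <- case_when(
    pct < edges[1] ~ "low",
    pct <= edges[2] ~ "mid",
    TRUE ~ "high"
  )
  mutate(profiles, band = factor(band, levels = .band_levels))
}

#' Surveillance-interval distribution stratified by endoscopist rate bands
#'
#' Joins each procedure's interval assignment to its endoscopist's band and
#' tabulates counts and within-band percentages per interval group.
#'
#' @param assignments Tibble from [assign_interval()] plus an
#'   `endoscopist_id` column (or joinable via `summaries`).
#' @param profiles Banded profiles from [band_endoscopists()].
#' @return Tibble: `band`, `interval_group`, `n`, `band_n`, `pct` (rounded
#'   to 2 decimals; percentages within a band sum to 100 up to rounding).
#' @export
interval_distribution <- function(assignments, profiles) {
  stopifnot("band" %in% names(profiles))
  joined <- inner_join(assignments,
                       select(profiles, "endoscopist_id", "band"),
                       by = "endoscopist_id")
  .band_table(joined)
}

#' Interval distribution from a pre-aggregated counts table
#'
#' @param counts Tibble with `band`, `interval_group`, `n` and `band_n`
#'   (total procedures in the band, used as the percentage denominator).
#' @return As [interval_distribution()].
#' @export
interval_distribution_from_counts <- function(counts) {
  counts |>
    mutate(
      band = factor(.data$band, levels = .band_levels),
      interval_group = factor(.data$interval_group,
                              levels = .interval_groups),
      pct = round(100 * .data$n / .data$band_n, 2)
    ) |>
    arrange(.data$band, .data$interval_group)
}

#' @noRd
.band_table <- function(joined) {
  joined |>
    mutate(interval_group = factor(.data$interval_group,
                                   levels = .interval_groups)) |>
    count(.data$band, .data$interval_group, .drop = FALSE) |>
    group_by(.data$band) |>
    mutate(band_n = sum(.data$n)) |>
    ungroup() |>
    mutate(pct = if_else(.data$band_n > 0,
                         round(100 * .data$n / .data$band_n, 2), 0)) |>
    arrange(.data$band, .data$interval_group)
}

#' Compare proportions or quantitative variables between groups
#'
#' Proportions are compared with the chi-square test on the contingency
#' table (without continuity correction, i.e. the textbook
#' \eqn{\sum (O-E)^2/E} statistic); quantitative variables with the
#' two-sample two-tailed t test.
#'
#' @param x A contingency table/matrix of counts, or a numeric vector.
#' @param y Second numeric sample (t test only).
#' @return Tibble with `method`, `statistic`, `df`, `p_value`.
#' @export
#' @examples
#' compare_groups(matrix(c(20, 10, 10, 20), nrow = 2))
compare_groups <- function(x, y = NULL) {
  if (is.matrix(x) || is.table(x)) {
    if (any(rowSums(x) == 0) || any(colSums(x) == 0)) {
      stop("contingency table has an empty margin; expected counts of 0",
           call. = FALSE)
    }
    ht <- suppressWarnings(chisq.test(x, correct = FALSE))
    tibble(method = "chi-square", statistic = unname(ht$statistic),
           df = unname(ht$parameter), p_value = ht$p.value)
  } else {
    stopifnot(is.numeric(x), is.numeric(y))
    if (stats::var(c(x, y)) == 0) {
      # identical constant samples: t = 0 by convention
      return(tibble(method = "t-test", statistic = 0,
                    df = length(x) + length(y) - 2, p_value = 1))
    }
    ht <- t.test(x, y, var.equal = TRUE)
    tibble(method = "t-test", statistic = unname(ht$statistic),
           df = unname(ht$parameter), p_value = ht$p.value)
  }
}

#' Bundled 10-year screening-program example counts
#'
#' Example per-endoscopist counts from a 10-year single-center screening
#' colonoscopy program (25 endoscopists, 54,562 procedures): procedure
#' volumes, adenoma / advanced-adenoma / SSL / advanced-SSL positive counts
#' and mean surveillance intervals. Used to exercise the indicator layer on
#' realistic aggregated data.
#'
#' @return Counts tibble suitable for [profiles_from_counts()].
#' @export
tenyr_endoscopist_counts <- function() {
  as_tibble(read.csv(system.file("extdata", "tenyr_endoscopist_counts.csv",
                                 package = "colonlp"),
                     stringsAsFactors = FALSE))
}

#' Bundled 10-year interval-distribution example counts
#'
#' Companion to [tenyr_endoscopist_counts()]: procedures per surveillance
#' interval group within endoscopist performance bands (ADR <30% / 30-45% /
#' >45%; SDR <2% / 2-4% / >4%).
#'
#' @return Tibble with `rate`, `band`, `band_n`, `interval_group`, `n`.
#' @export
tenyr_interval_band_counts <- function() {
  as_tibble(read.csv(system.file("extdata", "tenyr_interval_band_counts.csv",
                                 package = "colonlp"),
                     stringsAsFactors = FALSE))
}
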