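#' Demographic profile of target reports
#'
#' Counts and percentages per target report (not per drug--event pair) for
#' sex, age band, reporter type and country. Age bands are left-closed on
#' ages normalized to years (so an age of exactly 60 falls in 60--74).
#' Every target report lands in exactly one level of each category —
#' missing values form an explicit `"unknown"` level — and the percentage
#' denominator is the total number of target reports throughout, so each
#' category sums to 100.
#'
#' @param events A `drug_event_set` from [extract_event_sets()].
#' @param top_countries Number of most-frequent countries kept before
#'   collapsing the remainder to `"other"`.
#' @return Tibble with columns `category`, `level`, `count`, `percent`.
#' @export
summarize_demographics <- function(events, top_countries = 1L) {
  stopifnot(inherits(events, "drug_event_set"))
  meta <- dplyr::filter(events$report_meta, .data$is_target)
  n_total <- nrow(meta)

  age_bin <- function(age) {
    out <- as.character(cut(
      age,
      breaks = c(-Inf, 18, 45, 60, 75, 90, Inf), right = FALSE,
      labels = c("<18", "18-44", "45-59", "60-74", "75-89", ">=90")
    ))
    tidyr::replace_na(out, "unknown")
  }
  known_countries <- meta |>
    dplyr::filter(!is.na(.data$country)) |>
    dplyr::count(.data$country, sort = TRUE) |>
    dplyr::slice_head(n = top_countries)
  country_lvl <- dplyr::case_when(
    is.na(meta$country) ~ "unknown",
    meta$country %in% known_countries$country ~ meta$country,
    TRUE ~ "other"
  )

  levels_tbl <- dplyr::bind_rows(
    tibble::tibble(category = "sex",
                   level = dplyr::recode(meta$sex, UNK = "unknown")),
    tibble::tibble(category = "age", level = age_bin(meta$age_years)),
    tibble::tibble(category = "reporter", level = meta$reporter),
    tibble::tibble(category = "country", level = country_lvl)
  )
  levels_tbl |>
    dplyr::count(.data$category, .data$level, name = "count") |>
    dplyr::mutate(percent = 100 * .data$count / n_total) |>
    dplyr::arrange(.data$category, dplyr::desc(.data$count))
}

outcome_labels <- c(
  DE = "death", LT = "life threatening", HO = "hospitalization",
  DS = "disability", CA = "congenital anomaly",
  RI = "required intervention", OT = "other serious"
)
# severity order for the worst-outcome-per-report policy
outcome_severity <- c("DE", "LT", "DS", "HO", "CA", "RI", "OT")

#' Outcome distribution of target reports
#'
#' Under the default `"per_code"` policy each outcome code is counted at
#' most once per report and percentages use the total number of counted
#' codes as denominator (a report with both hospitalization and death
#' contributes to both rows). The `"worst"` policy keeps only the most
#' severe code per report (death > life-threatening > disability >
#' hospitalization > other) with reports as denominator. Unknown codes are
#' counted under "other serious" with a warning.
#'
#' @param events A `drug_event_set`.
#' @param outc OUTC record tibble.
#' @param policy `"per_code"` (default) or `"worst"`.
#' @return Tibble `category`, `level`, `count`, `percent`.
#' @export
summarize_outcomes <- function(events, outc, policy = c("per_code", "worst")) {
  policy <- rlang::arg_match(policy)
  stopifnot(inherits(events, "drug_event_set"))
  target_ids <- events$report_meta$report_id[events$report_meta$is_target]
  rows <- outc |>
    dplyr::filter(.data$report_id %in% target_ids)
  if (any(!rows$outcome %in% names(outcome_labels))) {
    warn(sprintf("%d outcome code(s) outside the known set counted as 'other serious'",
                 sum(!rows$outcome %in% names(outcome_labels))))
    rows$outcome[!rows$outcome %in% names(outcome_labels)] <- "OT"
  }
  rows <- dplyr::distinct(rows, .data$report_id, .data$outcome)
  if (policy == "worst") {
    rows <- rows |>
      dplyr::mutate(sev = match(.data$outcome, outcome_severity)) |>
      dplyr::slice_min(.data$sev, n = 1, by = "report_id",
                       with_ties = FALSE) |>
      dplyr::select(-"sev")
  }
  rows |>
    dplyr::count(outcome = .data$outcome, name = "count") |>
    dplyr::mutate(
      category = paste0("outcome_", policy),
      level = unname(outcome_labels[.data$outcome]),
      percent = 100 * .data$count / sum(.data$count)
    ) |>
    dplyr::select("category", "level", "count", "percent") |>
    dplyr::arrange(dplyr::desc(.data$count))
}

tto_bin <- function(days) {
  dplyr::case_when(
    is.na(days) ~ "unknown",
    days < 7 ~ "<7",
    days < 28 ~ "7-28",
    days < 60 ~ "28-60",
    TRUE ~ ">=60"
  )
}

#' Time to onset of target reports
#'
#' Days from the start of therapy with the target drug to the adverse
#' event. The therapy anchor is the earliest day-precision start date among
#' THER rows whose `drug_seq` matches a synonym-matched drug row in an
#' accepted role; the event anchor is the DEMO event date. Both anchors
#' must carry day precision, otherwise the report's onset is unknown; a
#' negative difference (data error in the source) is also treated as
#' unknown but tallied separately. The median and interquartile range use
#' linear interpolation over the known onsets.
#'
#' @param events A `drug_event_set`.
#' @param ther THER record tibble.
#' @param drug DRUG record tibble.
#' @param synonyms A [synonym_list()].
#' @param roles Accepted role codes for the therapy anchor.
#' @return List with `records` (tibble `report_id`, `days`, `bin`; one row
#'   per target report), `summary` (one-row tibble with `n_known`,
#'   `n_unknown`, `n_negative`, `median`, `q1`, `q3`), and `bins` (tibble
#'   `bin`, `count`, `percent` over all target reports).
#' @export
compute_tto <- function(events, ther, drug, synonyms = synonym_list(),
                        roles = "PS") {
  stopifnot(inherits(events, "drug_event_set"))
  meta <- dplyr::filter(events$report_meta, .data$is_target)

  anchor_rows <- drug |>
    dplyr::filter(.data$report_id %in% meta$report_id,
                  .data$role %in% roles,
                  drug_matches(.data$drugname, .data$active_ingredient,
                               synonyms)) |>
    dplyr::select("report_id", "drug_seq")
  starts <- ther |>
    dplyr::inner_join(anchor_rows, by = c("report_id", "drug_seq")) |>
    dplyr::filter(pd_precision(.data$start_date) == "day") |>
    dplyr::summarise(start_date = min(.data$start_date),
                     .by = "report_id")

  records <- meta |>
    dplyr::select("report_id", "event_date") |>
    dplyr::left_join(starts, by = "report_id") |>
    dplyr::mutate(
      days = pd_days_between(.data$start_date, .data$event_date),
      negative = !is.na(.data$days) & .data$days < 0,
      days = dplyr::if_else(.data$negative, NA_real_, .data$days),
      bin = tto_bin(.data$days)
    )
  known <- records$days[!is.na(records$days)]
  q <- if (length(known) > 0) {
    quantile(known, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  } else {
    rep(NA_real_, 3)
  }
  bins <- tibble::tibble(bin = c("<7", "7-28", "28-60", ">=60", "unknown")) |>
    dplyr::left_join(dplyr::count(records, .data$bin, name = "count"),
                     by = "bin") |>
    dplyr::mutate(count = as.integer(tidyr::replace_na(.data$count, 0L)),
                  percent = 100 * .data$count / nrow(records))
  list(
    records = dplyr::select(records, "report_id", "days", "bin"),
    summary = tibble::tibble(
      n_known = length(known),
      n_unknown = sum(is.na(records$days)),
      n_negative = sum(records$negative),
      median = q[2], q1 = q[1], q3 = q[3]
    ),
    bins = bins
  )
}

#' Annual counts of target reports
#'
#' Counts of deduplicated target reports keyed by receipt year (year
#' precision of the receipt date suffices). Reports without a usable year
#' appear as an `NA`-year row.
#'
#' @param events A `drug_event_set`.
#' @return Tibble `year` (integer, `NA` for unknown), `count`.
#' @export
annual_counts <- function(events) {
  stopifnot(inherits(events, "drug_event_set"))
  events$report_meta |>
    dplyr::filter(.data$is_target) |>
    dplyr::count(year = .data$receipt_year, name = "count") |>
    dplyr::arrange(.data$year)
}

#' Bar chart of annual report counts
#'
#' @param counts Output of [annual_counts()].
#' @return A ggplot object.
#' @export
plot_annual_counts <- function(counts) {
  dat <- dplyr::filter(counts, !is.na(.data$year))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$year, y = .data$count)) +
    ggplot2::geom_col(fill = "#2166ac") +
    ggplot2::labs(x = "Receipt year", y = "Target reports") +
    ggplot2::theme_minimal()
}
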