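#' Default System Organ Class exclusion list
#'
#' SOCs whose PT-level findings are conventionally attributed to progression
#' of the underlying disease (renal/skeletal/vascular/neoplastic and related
#' conditions in the treated population) rather than to the drug, and
#' therefore removed from the PT-level signal table.
#'
#' @return Character vector of six SOC names.
#' @export
default_soc_exclusions <- function() {
  c(
    "Musculoskeletal and connective tissue disorders",
    "Neoplasms benign, malignant and unspecified (incl. cysts and polyps)",
    "Renal and urinary disorders",
    "Vascular disorders",
    "Pregnancy, puerperium and perinatal conditions",
    "Nervous system disorders"
  )
}

#' Remove rows whose SOC is excluded
#'
#' Case-insensitive filter on the `soc` column. Exclusion names not present
#' in the table trigger a warning and are ignored; the number of removed
#' rows is recorded in the `"n_excluded"` attribute. Filtering commutes with
#' ranking.
#'
#' @param stats Signal-statistics tibble carrying a `soc` column.
#' @param exclusions Character vector of SOC names
#'   (default [default_soc_exclusions()]).
#' @return Filtered tibble with attribute `"n_excluded"`.
#' @export
apply_soc_exclusions <- function(stats, exclusions = default_soc_exclusions()) {
  stopifnot("soc" %in% names(stats))
  if (length(exclusions) == 0L) {
    return(structure(stats, n_excluded = 0L))
  }
  excl <- tolower(trimws(exclusions))
  known <- tolower(trimws(stats$soc))
  unknown <- setdiff(excl, known)
  if (length(unknown) > 0L) {
    warn(paste0("exclusion name(s) not present in the table: ",
                paste(unknown, collapse = "; ")))
  }
  keep <- is.na(known) | !known %in% excl
  structure(stats[keep, ], n_excluded = sum(!keep))
}

#' Rank a signal table for reporting
#'
#' Stable descending sort by case count or by ROR; ties are broken by the
#' other key, then by term name.
#'
#' @param stats Signal-statistics tibble.
#' @param by `"count"` (case count `a`) or `"ror"`.
#' @return Reordered tibble.
#' @export
rank_signal_table <- function(stats, by = c("count", "ror")) {
  by <- rlang::arg_match(by)
  if (by == "count") {
    dplyr::arrange(stats, dplyr::desc(.data$a), dplyr::desc(.data$ror),
                   .data$term)
  } else {
    dplyr::arrange(stats, dplyr::desc(.data$ror), dplyr::desc(.data$a),
                   .data$term)
  }
}

#' Forest-plot-ready extract of a signal table
#'
#' @param stats Signal-statistics tibble.
#' @return Tibble `term`, `estimate`, `lo`, `hi` (ROR and its 95% CI).
#' @export
forest_data <- function(stats) {
  stats |>
    dplyr::filter(!is.na(.data$ror)) |>
    dplyr::transmute(term = .data$term, estimate = .data$ror,
                     lo = .data$ror_lo95, hi = .data$ror_hi95)
}

fmt_num <- function(x, digits) {
  ifelse(is.na(x), "", sprintf(paste0("%.", digits, "f"), x))
}
fmt_p <- function(p) {
  dplyr::case_when(
    is.na(p) ~ "",
    p < 0.001 ~ "<0.001",
    TRUE ~ sprintf("%.3f", p)
  )
}

#' Human-readable signal report table
#'
#' Formats a flagged statistics table the way pharmacovigilance papers print
#' them: point estimate with 95% CI in one column per method, rounded to
#' `digits` decimals; full precision stays in the machine-readable output.
#'
#' @param stats Output of [flag_signals()] (optionally SOC-annotated).
#' @param digits Decimal places for ratios and chi-square.
#' @return Tibble of formatted character columns.
#' @export
format_signal_report <- function(stats, digits = 2) {
  has_soc <- "soc" %in% names(stats)
  out <- tibble::tibble(
    term = stats$term,
    soc = if (has_soc) stats$soc else NULL,
    cases = stats$a,
    ror_95ci = ifelse(is.na(stats$ror), "",
                      sprintf("%s (%s, %s)", fmt_num(stats$ror, digits),
                              fmt_num(stats$ror_lo95, digits),
                              fmt_num(stats$ror_hi95, digits))),
    prr_95ci = ifelse(is.na(stats$prr), "",
                      sprintf("%s (%s, %s)", fmt_num(stats$prr, digits),
                              fmt_num(stats$prr_lo95, digits),
                              fmt_num(stats$prr_hi95, digits))),
    chi2 = fmt_num(stats$chi2, digits),
    ic_ic025 = ifelse(is.na(stats$ic), "",
                      sprintf("%s (%s)", fmt_num(stats$ic, digits),
                              fmt_num(stats$ic025, digits))),
    ebgm_ebgm05 = ifelse(is.na(stats$ebgm), "",
                         sprintf("%s (%s)", fmt_num(stats$ebgm, digits),
                                 fmt_num(stats$ebgm05, digits))),
    p = fmt_p(stats$p),
    p_adj = fmt_p(stats$p_adj),
    signal = stats$signal
  )
  out
}

#' End-to-end pipeline configuration
#'
#' Exactly one of `input_dir` (a directory of FAERS-style table files, see
#' [read_faers_bundle()]) or `sim` (a [sim_config()], for synthetic runs)
#' must be given.
#'
#' @param input_dir Directory with DEMO/DRUG/REAC/THER/OUTC files.
#' @param sim A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @param synonyms A [synonym_list()].
#' @param meddra_map PT-to-SOC map tibble or path readable by
#'   [read_meddra_map()]; `NULL` disables SOC-level output and SOC
#'   exclusions.
#' @param roles Accepted role codes for target reports.
#' @param criteria A [signal_criteria()].
#' @param soc_exclusions SOC names removed from the PT-level report
#'   (PT level only; the SOC-level table is never filtered).
#' @param sort_by Report ordering, `"count"` or `"ror"`.
#' @param digits Rounding for the human-readable report.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(out_dir, input_dir = NULL, sim = NULL,
                            synonyms = synonym_list(), meddra_map = NULL,
                            roles = "PS", criteria = signal_criteria(),
                            soc_exclusions = default_soc_exclusions(),
                            sort_by = c("count", "ror"), digits = 2) {
  if (is.null(input_dir) == is.null(sim)) {
    abort("give exactly one of `input_dir` or `sim`")
  }
  if (!is.null(input_dir) && !dir.exists(input_dir)) {
    abort(paste0("input directory not found: ", input_dir))
  }
  if (!is.null(sim)) stopifnot(inherits(sim, "sim_config"))
  if (is.character(meddra_map) && length(meddra_map) == 1L) {
    meddra_map <- read_meddra_map(meddra_map)
  }
  structure(
    list(
      input_dir = input_dir, sim = sim, out_dir = out_dir,
      synonyms = synonyms, meddra_map = meddra_map, roles = roles,
      criteria = criteria, soc_exclusions = soc_exclusions,
      sort_by = rlang::arg_match(sort_by), digits = digits
    ),
    class = "pipeline_config"
  )
}

#' Run the full pipeline
#'
#' Executes read (or simulate) -> validate -> deduplicate -> extract pair
#' sets -> fourfold tables -> statistics -> FDR -> flags -> SOC exclusions
#' -> descriptives, and writes delimited outputs plus a machine-readable run
#' manifest to `config$out_dir`: `pt_signals.tsv` (full precision),
#' `pt_signals_report.tsv` (formatted), `soc_signals.tsv` +
#' `soc_signals_report.tsv` (when a map is given), `forest_pt.csv`,
#' `descriptives.tsv`, `tto.tsv`, `annual_counts.tsv`, `manifest.json`.
#' All computation precedes all writing, so a failing stage leaves no
#' partial outputs; given identical inputs the outputs are byte-identical.
#'
#' @param config A [pipeline_config()].
#' @return The manifest (list), invisibly.
#' @export
run_faers_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  warnings_seen <- character()
  run <- function(stage, expr) {
    withCallingHandlers(
      tryCatch(expr, error = function(e) {
        abort(paste0("pipeline stage '", stage, "' failed: ",
                     conditionMessage(e)))
      }),
      warning = function(w) {
        warnings_seen <<- c(warnings_seen,
                            paste0(stage, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      }
    )
  }

  bundle <- run("input", {
    if (!is.null(config$sim)) simulate_faers(config$sim)$bundle
    else read_faers_bundle(config$input_dir)
  })
  validation <- run("validate", validate_bundle(bundle))
  kept <- run("dedup", dedupe_reports(bundle$demo))
  events <- run("extract", extract_event_sets(
    bundle, config$synonyms, roles = config$roles, dedupe = TRUE
  ))
  if (length(events$target_report_ids) == 0L) {
    warnings_seen <- c(warnings_seen,
                       "extract: no report matched the target-drug synonyms")
  }

  pt <- run("signals_pt", analyze_signals(
    events, level = "pt", meddra_map = config$meddra_map,
    criteria = config$criteria
  ))
  pt_stats <- pt$stats
  n_excluded <- 0L
  if (!is.null(config$meddra_map) && length(config$soc_exclusions) > 0L) {
    pt_stats <- run("exclusions",
                    apply_soc_exclusions(pt_stats, config$soc_exclusions))
    n_excluded <- attr(pt_stats, "n_excluded")
  }
  pt_stats <- rank_signal_table(pt_stats, config$sort_by)

  soc_stats <- NULL
  if (!is.null(config$meddra_map)) {
    soc <- run("signals_soc", analyze_signals(
      events, level = "soc", meddra_map = config$meddra_map,
      criteria = config$criteria
    ))
    soc_stats <- rank_signal_table(soc$stats, config$sort_by)
  }

  demographics <- run("descriptives", dplyr::bind_rows(
    summarize_demographics(events),
    summarize_outcomes(events, bundle$outc)
  ))
  tto <- run("descriptives", compute_tto(
    events, bundle$ther, bundle$drug, config$synonyms, roles = config$roles
  ))
  annual <- run("descriptives", annual_counts(events))

  manifest <- list(
    package = "faersignal",
    package_version = as.character(utils::packageVersion("faersignal")),
    # hash of the analytic configuration only, so runs into different output
    # directories compare equal
    config_hash = rlang::hash(unclass(config)[setdiff(names(config),
                                                      "out_dir")]),
    counts = list(
      demo_rows = nrow(bundle$demo),
      cases = nrow(kept),
      target_reports = length(events$target_report_ids),
      target_pairs = nrow(events$target_pairs),
      background_pairs = nrow(events$background_pairs),
      pt_terms = nrow(pt$stats),
      pt_rows_excluded_by_soc = n_excluded,
      pt_flagged = sum(pt_stats$signal),
      soc_terms = if (is.null(soc_stats)) 0L else nrow(soc_stats)
    ),
    criteria = list(
      min_a = config$criteria$min_a,
      p_adj_max = config$criteria$p_adj_max,
      policy = config$criteria$policy,
      fdr_family = "terms with a >= min_a and a defined p, per level"
    ),
    validation = as.list(setNames(validation$n,
                                  paste(validation$check, validation$table,
                                        sep = "."))),
    warnings = warnings_seen
  )

  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  write_tsv_plain <- function(x, name) {
    readr::write_tsv(x, file.path(out_dir, name), progress = FALSE)
  }
  write_tsv_plain(pt_stats, "pt_signals.tsv")
  write_tsv_plain(format_signal_report(pt_stats, config$digits),
                  "pt_signals_report.tsv")
  readr::write_csv(forest_data(pt_stats), file.path(out_dir, "forest_pt.csv"),
                   progress = FALSE)
  if (!is.null(soc_stats)) {
    write_tsv_plain(soc_stats, "soc_signals.tsv")
    write_tsv_plain(format_signal_report(soc_stats, config$digits),
                    "soc_signals_report.tsv")
  }
  write_tsv_plain(demographics, "descriptives.tsv")
  tto_out <- dplyr::bind_rows(
    dplyr::mutate(tto$bins, statistic = "bin_count",
                  value = as.numeric(.data$count)),
    tibble::tibble(
      bin = NA_character_, count = NA_integer_, percent = NA_real_,
      statistic = c("median_days", "q1_days", "q3_days", "n_known",
                    "n_unknown", "n_negative"),
      value = c(tto$summary$median, tto$summary$q1, tto$summary$q3,
                tto$summary$n_known, tto$summary$n_unknown,
                tto$summary$n_negative)
    )
  )
  write_tsv_plain(tto_out, "tto.tsv")
  write_tsv_plain(annual, "annual_counts.tsv")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
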