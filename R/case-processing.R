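#' Target-drug synonym list
#'
#' Drug names in spontaneous reports are free text; target reports are found
#' by case-insensitive substring match against a small synonym list. The
#' default covers the generic and US brand names of cinacalcet.
#'
#' @param names Character vector of synonyms (stored uppercase).
#' @return Uppercase character vector of class `synonym_list`.
#' @export
synonym_list <- function(names = c("CINACALCET", "SENSIPAR")) {
  names <- toupper(trimws(as.character(names)))
  names <- names[!is.na(names) & names != ""]
  if (length(names) == 0L) abort("synonym list must be nonempty")
  structure(unique(names), class = "synonym_list")
}

#' Read a synonym list or a PT-to-SOC map from delimited text
#'
#' `read_synonyms()` expects one synonym per line (single column). MedDRA is
#' licensed, so no terminology ships with the package: `read_meddra_map()`
#' reads a user-supplied two-column delimited file mapping Preferred Term to
#' System Organ Class.
#'
#' @param path File path.
#' @param delim Field delimiter for the map file.
#' @return `read_synonyms()` a [synonym_list()]; `read_meddra_map()` a tibble
#'   with columns `pt`, `soc`.
#' @export
read_synonyms <- function(path) {
  synonym_list(readr::read_lines(path, progress = FALSE))
}

#' @rdname read_synonyms
#' @export
read_meddra_map <- function(path, delim = "\t") {
  map <- readr::read_delim(path, delim = delim, col_types = "cc",
                           progress = FALSE)
  names(map)[1:2] <- c("pt", "soc")
  tibble::as_tibble(map[, c("pt", "soc")])
}

# matching key for PT strings: trim, collapse internal whitespace, casefold;
# outputs keep the original casing
pt_key <- function(pt) stringr::str_to_lower(stringr::str_squish(pt))

#' Deduplicate case versions
#'
#' FAERS cases are resubmitted as updated versions sharing a case id; the
#' analysis keeps only the most recent version of each case, judged by
#' receipt date (ties broken by the larger report id on its zero-padded
#' form). A version with no receipt date is treated as minimally dated and
#' survives only if it is the sole version of its case. Idempotent and
#' deterministic.
#'
#' @param demo DEMO record tibble.
#' @return The kept DEMO rows (one per case id), as a tibble.
#' @export
dedupe_reports <- function(demo) {
  demo |>
    dplyr::mutate(
      .date_key = pd_sort_key(.data$receipt_date),
      .id_key = stringr::str_pad(.data$report_id,
                                 max(nchar(.data$report_id), 1L), pad = "0")
    ) |>
    dplyr::arrange(dplyr::desc(.data$.date_key), dplyr::desc(.data$.id_key)) |>
    dplyr::distinct(.data$case_id, .keep_all = TRUE) |>
    dplyr::arrange(.data$report_id) |>
    dplyr::select(-".date_key", -".id_key")
}

#' Does a drug record match the target synonyms?
#'
#' True iff any synonym is a substring of the uppercased `drugname` or
#' uppercased `active_ingredient`, so `"SENSIPAR 30MG TABLET"` and
#' `"cinacalcet hcl"` both match the defaults.
#'
#' @param drugname,active_ingredient Character vectors (recycled per row).
#' @param synonyms A [synonym_list()].
#' @return Logical vector.
#' @export
drug_matches <- function(drugname, active_ingredient = NA_character_,
                         synonyms = synonym_list()) {
  stopifnot(inherits(synonyms, "synonym_list"))
  hit <- function(x) {
    x <- toupper(x)
    out <- rep(FALSE, length(x))
    for (s in synonyms) {
      out <- out | stringr::str_detect(x, stringr::fixed(s))
    }
    out & !is.na(x)
  }
  hit(drugname) | hit(active_ingredient)
}

#' Extract deduplicated drug--event pair sets
#'
#' The counting unit of the whole analysis: after case-version deduplication,
#' each kept report contributes one (report, PT) pair per distinct PT it
#' lists. Reports with at least one drug row matching the synonyms in an
#' accepted role (default: primary suspect only) are target reports; all
#' other kept reports form the background. Reports whose only matching rows
#' carry an excluded role stay in the background — the comparator is "all
#' other reports", not "reports never mentioning the drug".
#'
#' @param bundle A [faers_bundle()].
#' @param synonyms A [synonym_list()].
#' @param roles Character vector of accepted role codes (subset of
#'   `PS`, `SS`, `C`, `I`).
#' @param dedupe Apply [dedupe_reports()] first (default). Set `FALSE` only
#'   if `bundle$demo` is already one row per case.
#' @return An object of class `drug_event_set`: list with tibbles
#'   `target_pairs` and `background_pairs` (columns `report_id`, `pt`),
#'   `target_report_ids`, and `report_meta` (per kept report: sex, age in
#'   years, reporter, country, receipt year, event date).
#' @export
extract_event_sets <- function(bundle, synonyms = synonym_list(),
                               roles = "PS", dedupe = TRUE) {
  stopifnot(inherits(bundle, "faers_bundle"))
  roles <- rlang::arg_match(roles, c(role_codes, "UNK"), multiple = TRUE)
  demo <- if (dedupe) dedupe_reports(bundle$demo) else bundle$demo
  kept_ids <- demo$report_id

  matches <- bundle$drug |>
    dplyr::filter(.data$report_id %in% kept_ids,
                  .data$role %in% roles,
                  drug_matches(.data$drugname, .data$active_ingredient,
                               synonyms))
  target_ids <- unique(matches$report_id)

  pairs <- bundle$reac |>
    dplyr::filter(.data$report_id %in% kept_ids, !is.na(.data$pt)) |>
    dplyr::mutate(.key = pt_key(.data$pt)) |>
    dplyr::distinct(.data$report_id, .data$.key, .keep_all = TRUE) |>
    dplyr::select("report_id", "pt")

  is_target <- pairs$report_id %in% target_ids
  meta <- demo |>
    dplyr::transmute(
      report_id = .data$report_id,
      is_target = .data$report_id %in% target_ids,
      sex = .data$sex,
      age_years = age_in_years(.data$age_value, .data$age_unit),
      reporter = .data$reporter,
      country = .data$country,
      receipt_year = pd_year(.data$receipt_date),
      event_date = .data$event_date
    )

  structure(
    list(
      target_pairs = pairs[is_target, ],
      background_pairs = pairs[!is_target, ],
      target_report_ids = target_ids,
      report_meta = meta
    ),
    class = "drug_event_set"
  )
}

#' @export
print.drug_event_set <- function(x, ...) {
  cat("<drug_event_set>\n")
  cat(sprintf("  target reports : %d\n", length(x$target_report_ids)))
  cat(sprintf("  target pairs   : %d\n", nrow(x$target_pairs)))
  cat(sprintf("  background pairs: %d\n", nrow(x$background_pairs)))
  invisible(x)
}

#' Annotate (report, PT) pairs with System Organ Classes
#'
#' Joins a user-supplied PT-to-SOC map onto a pair set (matching on the
#' whitespace- and case-normalized PT). Unmapped PTs are reported and
#' excluded from SOC-level aggregation only. When `per_report_unique` is set
#' (the default) a report contributes at most one pair per SOC, mirroring the
#' per-report PT uniqueness of the pair sets; disable it to count the sum of
#' PT-level pairs instead.
#'
#' @param pairs Tibble with columns `report_id`, `pt`.
#' @param map Tibble with columns `pt`, `soc` (see [read_meddra_map()]).
#' @param per_report_unique Collapse to unique (report, SOC) pairs.
#' @return List with `pairs` (tibble `report_id`, `pt` or `soc`) and
#'   `unmapped` (character vector of PTs without a SOC).
#' @export
map_pt_to_soc <- function(pairs, map, per_report_unique = TRUE) {
  map <- dplyr::mutate(tibble::as_tibble(map), .key = pt_key(.data$pt))
  map <- dplyr::distinct(map, .data$.key, .keep_all = TRUE)
  joined <- pairs |>
    dplyr::mutate(.key = pt_key(.data$pt)) |>
    dplyr::left_join(dplyr::select(map, ".key", "soc"), by = ".key")
  unmapped <- sort(unique(joined$pt[is.na(joined$soc)]))
  mapped <- joined |>
    dplyr::filter(!is.na(.data$soc)) |>
    dplyr::select("report_id", "pt", "soc")
  if (per_report_unique) {
    mapped <- dplyr::distinct(mapped, .data$report_id, .data$soc)
  }
  list(pairs = mapped, unmapped = unmapped)
}
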