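#' @section FAERS quarterly tables:
#' Quarterly extracts ship one ASCII file per section, '$'-delimited with a
#' single header line. The five sections used here are DEMO (demographics and
#' administration), DRUG (one row per reported drug with a role code), REAC
#' (one row per MedDRA Preferred Term), THER (therapy start/end dates) and
#' OUTC (outcome codes). Column names drifted across years; `column_map`
#' makes the layout explicit configuration, defaulting to the modern one.
#' @name faers_io
#' @keywords internal
NULL

faers_kinds <- c("demo", "drug", "reac", "ther", "outc")

#' Default column maps for FAERS quarterly ASCII tables
#'
#' Maps the package's internal column names to the file column names of the
#' modern FAERS layout. Supply a modified map to [read_faers_table()] /
#' [write_faers_table()] for older quarters whose headers differ.
#'
#' @param kind One of `"demo"`, `"drug"`, `"reac"`, `"ther"`, `"outc"`.
#' @return Named character vector: names are internal columns, values are
#'   file columns.
#' @examples
#' faers_column_map("demo")
#' @export
faers_column_map <- function(kind) {
  kind <- rlang::arg_match(kind, faers_kinds)
  switch(kind,
    demo = c(
      report_id = "primaryid", case_id = "caseid", receipt_date = "fda_dt",
      event_date = "event_dt", sex = "sex", age_value = "age",
      age_unit = "age_cod", reporter = "occp_cod", country = "occr_country"
    ),
    drug = c(
      report_id = "primaryid", drug_seq = "drug_seq", role = "role_cod",
      drugname = "drugname", active_ingredient = "prod_ai"
    ),
    reac = c(report_id = "primaryid", pt = "pt"),
    ther = c(
      report_id = "primaryid", drug_seq = "dsg_drug_seq",
      start_date = "start_dt", end_date = "end_dt"
    ),
    outc = c(report_id = "primaryid", outcome = "outc_cod")
  )
}

# zero-row typed template for each record kind
faers_empty <- function(kind) {
  switch(kind,
    demo = tibble::tibble(
      report_id = character(), case_id = character(),
      receipt_date = character(), event_date = character(),
      sex = character(), age_value = double(), age_unit = character(),
      reporter = character(), country = character()
    ),
    drug = tibble::tibble(
      report_id = character(), drug_seq = integer(), role = character(),
      drugname = character(), active_ingredient = character()
    ),
    reac = tibble::tibble(report_id = character(), pt = character()),
    ther = tibble::tibble(
      report_id = character(), drug_seq = integer(),
      start_date = character(), end_date = character()
    ),
    outc = tibble::tibble(report_id = character(), outcome = character())
  )
}

reporter_levels <- c(
  "physician", "pharmacist", "other health-professional", "consumer", "unknown"
)
reporter_from_code <- c(
  MD = "physician", PH = "pharmacist", OT = "other health-professional",
  HP = "other health-professional", RN = "other health-professional",
  CN = "consumer"
)
reporter_to_code <- c(
  physician = "MD", pharmacist = "PH", `other health-professional` = "OT",
  consumer = "CN", unknown = ""
)
role_codes <- c("PS", "SS", "C", "I")
outcome_codes <- c("DE", "LT", "HO", "DS", "CA", "RI", "OT")
age_unit_codes <- c("YR", "DEC", "MON", "WK", "DY", "HR")

#' Read one FAERS-style '$'-delimited table
#'
#' Parsing is total: a line with the wrong field count is skipped and logged,
#' never fatal. Empty fields become missing; enum fields with codes outside
#' the known set are preserved as `"UNK"` and counted. Dates are normalized
#' to canonical partial dates (see [pd_parse()]). Gzip input and a UTF-8
#' byte-order mark are tolerated.
#'
#' @param path Path to the table file (optionally `.gz`).
#' @param kind Table kind, one of `"demo"`, `"drug"`, `"reac"`, `"ther"`,
#'   `"outc"`.
#' @param column_map Internal-to-file column name map; see
#'   [faers_column_map()].
#' @return A typed tibble of records. The attribute `"io_log"` holds a tibble
#'   of parse events (skipped lines, unknown codes) with counts.
#' @seealso [write_faers_table()], [read_faers_bundle()]
#' @export
read_faers_table <- function(path, kind, column_map = faers_column_map(kind)) {
  kind <- rlang::arg_match(kind, faers_kinds)
  if (!file.exists(path)) {
    abort(paste0("cannot read FAERS table: file not found: ", path))
  }
  lines <- readr::read_lines(path, progress = FALSE)
  if (length(lines) == 0L) {
    abort(paste0("cannot read FAERS table: empty file: ", path))
  }
  lines[1] <- sub("^\ufeff", "", lines[1])
  header <- stringr::str_split_1(lines[1], stringr::fixed("$"))
  missing_cols <- setdiff(unname(column_map), header)
  if (length(missing_cols) > 0L) {
    abort(paste0(
      "FAERS ", kind, " table ", path, " lacks mapped column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  log <- tibble::tibble(event = character(), detail = character(), n = integer())
  body <- lines[-1]
  if (length(body) > 0L) {
    parts <- stringr::str_split(body, stringr::fixed("$"))
    ok <- lengths(parts) == length(header)
    if (any(!ok)) {
      bad_lines <- which(!ok) + 1L
      log <- dplyr::add_row(log,
        event = "skipped_line",
        detail = paste("wrong field count at line(s)",
                       paste(head(bad_lines, 20L), collapse = ",")),
        n = length(bad_lines)
      )
    }
    parts <- parts[ok]
  } else {
    parts <- list()
  }
  if (length(parts) > 0L) {
    mat <- matrix(unlist(parts), ncol = length(header), byrow = TRUE)
    colnames(mat) <- header
    raw <- tibble::as_tibble(mat)[, unname(column_map)]
    names(raw) <- names(column_map)
  } else {
    raw <- faers_empty(kind)
    raw <- dplyr::mutate(raw, dplyr::across(dplyr::everything(), as.character))
  }
  typed <- faers_type_records(raw, kind)
  attr(typed$records, "io_log") <- dplyr::bind_rows(log, typed$log)
  typed$records
}

# raw character tibble (internal names) -> typed records + issue log.
# A column_map may omit optional columns; they come back all-missing.
faers_type_records <- function(raw, kind) {
  raw <- dplyr::mutate(
    raw,
    dplyr::across(dplyr::everything(), ~ dplyr::na_if(trimws(.x), ""))
  )
  for (nm in names(faers_empty(kind))) {
    if (!nm %in% names(raw)) raw[[nm]] <- rep(NA_character_, nrow(raw))
  }
  log <- tibble::tibble(event = character(), detail = character(), n = integer())
  note <- function(event, detail, n) {
    if (n > 0L) log <<- dplyr::add_row(log, event = event, detail = detail,
                                       n = as.integer(n))
    invisible(NULL)
  }
  recode_enum <- function(x, levels, missing_to, label) {
    up <- toupper(x)
    unknown <- !is.na(up) & !up %in% levels
    note("unknown_code", label, sum(unknown))
    up[unknown] <- "UNK"
    up[is.na(up)] <- missing_to
    up
  }
  out <- switch(kind,
    demo = {
      rep_raw <- toupper(raw$reporter %||% NA_character_)
      mapped <- unname(reporter_from_code[rep_raw])
      note("unknown_code", "reporter",
           sum(!is.na(rep_raw) & is.na(mapped) &
                 !tolower(rep_raw) %in% reporter_levels))
      # already-decoded labels (round-trip input) pass through
      mapped[is.na(mapped) & tolower(rep_raw) %in% reporter_levels] <-
        tolower(rep_raw[is.na(mapped) & tolower(rep_raw) %in% reporter_levels])
      mapped[is.na(mapped)] <- "unknown"
      tibble::tibble(
        report_id = raw$report_id,
        case_id = raw$case_id,
        receipt_date = pd_parse(raw$receipt_date),
        event_date = pd_parse(raw$event_date),
        sex = recode_enum(raw$sex, c("F", "M"), "UNK", "sex"),
        age_value = suppressWarnings(as.numeric(raw$age_value)),
        age_unit = recode_enum(raw$age_unit, age_unit_codes, "UNK", "age_unit"),
        reporter = mapped,
        country = raw$country
      )
    },
    drug = tibble::tibble(
      report_id = raw$report_id,
      drug_seq = suppressWarnings(as.integer(raw$drug_seq)),
      role = recode_enum(raw$role, role_codes, "UNK", "role"),
      drugname = raw$drugname,
      active_ingredient = raw$active_ingredient
    ),
    reac = tibble::tibble(report_id = raw$report_id, pt = raw$pt),
    ther = tibble::tibble(
      report_id = raw$report_id,
      drug_seq = suppressWarnings(as.integer(raw$drug_seq)),
      start_date = pd_parse(raw$start_date),
      end_date = pd_parse(raw$end_date)
    ),
    outc = tibble::tibble(
      report_id = raw$report_id,
      outcome = recode_enum(raw$outcome, outcome_codes, "UNK", "outcome")
    )
  )
  dropped <- is.na(out$report_id)
  note("dropped_record", "missing report_id", sum(dropped))
  list(records = out[!dropped, ], log = log)
}

#' Write one FAERS-style '$'-delimited table
#'
#' Inverse of [read_faers_table()]: stable column order, missing values as
#' empty fields, one header line. A literal `'$'` inside free text would
#' corrupt the record, so it is replaced by `dollar_sub` and the replacement
#' counted in the `"io_log"` attribute of the return value.
#'
#' @param records Typed record tibble as produced by [read_faers_table()] or
#'   the synthetic generator.
#' @inheritParams read_faers_table
#' @param dollar_sub Single character substituted for `'$'` in field text.
#' @return `path`, invisibly, with an `"io_log"` attribute.
#' @export
write_faers_table <- function(records, path, kind,
                              column_map = faers_column_map(kind),
                              dollar_sub = "/") {
  kind <- rlang::arg_match(kind, faers_kinds)
  stopifnot(is.character(dollar_sub), nchar(dollar_sub) == 1L)
  cols <- names(faers_empty(kind))
  stopifnot(all(cols %in% names(records)))
  out <- records[, cols]
  if (kind == "demo") {
    out$reporter <- unname(reporter_to_code[out$reporter])
    out$sex[out$sex == "UNK"] <- NA_character_
    out$age_unit[out$age_unit == "UNK"] <- NA_character_
  }
  if (kind == "drug") out$role[out$role == "UNK"] <- NA_character_
  if (kind == "outc") out$outcome[out$outcome == "UNK"] <- NA_character_
  chr <- purrr::map(out, function(x) {
    x <- if (is.numeric(x)) {
      ifelse(is.na(x), "", format(x, trim = TRUE, scientific = FALSE))
    } else {
      ifelse(is.na(x), "", as.character(x))
    }
    x
  })
  n_sub <- sum(purrr::map_int(chr, ~ sum(stringr::str_count(.x, stringr::fixed("$")))))
  chr <- purrr::map(chr, ~ stringr::str_replace_all(.x, stringr::fixed("$"), dollar_sub))
  header <- paste(unname(column_map[cols]), collapse = "$")
  body <- do.call(paste, c(chr, sep = "$"))
  readr::write_lines(c(header, body), path)
  log <- tibble::tibble(event = "dollar_substituted", detail = kind,
                        n = as.integer(n_sub))[n_sub > 0L, ]
  invisible(structure(path, io_log = log))
}

#' Bundle of FAERS record tables
#'
#' Groups the five typed record tibbles of one extract (or one simulation)
#' into a single object keyed by `report_id`.
#'
#' @param demo,drug,reac,ther,outc Typed record tibbles; missing tables
#'   default to empty.
#' @return An object of class `faers_bundle` (a named list of tibbles).
#' @export
faers_bundle <- function(demo = faers_empty("demo"), drug = faers_empty("drug"),
                         reac = faers_empty("reac"), ther = faers_empty("ther"),
                         outc = faers_empty("outc")) {
  bundle <- list(demo = tibble::as_tibble(demo), drug = tibble::as_tibble(drug),
                 reac = tibble::as_tibble(reac), ther = tibble::as_tibble(ther),
                 outc = tibble::as_tibble(outc))
  for (kind in faers_kinds) {
    missing_cols <- setdiff(names(faers_empty(kind)), names(bundle[[kind]]))
    if (length(missing_cols) > 0L) {
      abort(paste0("bundle ", kind, " table lacks column(s): ",
                   paste(missing_cols, collapse = ", ")))
    }
  }
  structure(bundle, class = "faers_bundle")
}

#' @export
print.faers_bundle <- function(x, ...) {
  cat("<faers_bundle>\n")
  for (kind in faers_kinds) {
    cat(sprintf("  %-5s %8d records\n", kind, nrow(x[[kind]])))
  }
  invisible(x)
}

#' Read or write a whole bundle directory
#'
#' A bundle directory holds one file per table: `DEMO.txt`, `DRUG.txt`,
#' `REAC.txt`, `THER.txt`, `OUTC.txt` (optionally gzipped on read).
#'
#' @param dir Directory path.
#' @param column_maps Named list of per-kind column maps.
#' @param bundle A [faers_bundle()].
#' @return `read_faers_bundle()` a `faers_bundle`; `write_faers_bundle()`
#'   `dir`, invisibly.
#' @export
read_faers_bundle <- function(dir, column_maps = NULL) {
  tables <- purrr::map(setNames(faers_kinds, faers_kinds), function(kind) {
    base <- file.path(dir, paste0(toupper(kind), ".txt"))
    path <- if (file.exists(base)) base else paste0(base, ".gz")
    cmap <- column_maps[[kind]] %||% faers_column_map(kind)
    read_faers_table(path, kind, cmap)
  })
  do.call(faers_bundle, tables)
}

#' @rdname read_faers_bundle
#' @export
write_faers_bundle <- function(bundle, dir, column_maps = NULL) {
  stopifnot(inherits(bundle, "faers_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (kind in faers_kinds) {
    cmap <- column_maps[[kind]] %||% faers_column_map(kind)
    write_faers_table(bundle[[kind]], file.path(dir, paste0(toupper(kind), ".txt")),
                      kind, cmap)
  }
  invisible(dir)
}

#' Consistency report for a bundle
#'
#' Pure reporting: counts orphan `report_id`s (rows in drug/reac/ther/outc
#' whose report is absent from DEMO), unknown enum codes, sub-day-precision
#' and missing dates, and therapy rows whose full-precision end date precedes
#' the start date. Never mutates or drops data.
#'
#' @param bundle A [faers_bundle()].
#' @return Tibble with columns `check`, `table`, `n`.
#' @export
validate_bundle <- function(bundle) {
  stopifnot(inherits(bundle, "faers_bundle"))
  demo_ids <- unique(bundle$demo$report_id)
  orphans <- purrr::map_int(
    bundle[c("drug", "reac", "ther", "outc")],
    ~ sum(!.x$report_id %in% demo_ids)
  )
  res <- tibble::tibble(
    check = "orphan_report_id",
    table = names(orphans),
    n = unname(as.integer(orphans))
  )
  unk <- tibble::tribble(
    ~check, ~table, ~n,
    "unknown_sex", "demo", sum(bundle$demo$sex == "UNK"),
    "unknown_reporter", "demo", sum(bundle$demo$reporter == "unknown"),
    "unknown_role", "drug", sum(bundle$drug$role == "UNK"),
    "unknown_outcome", "outc", sum(bundle$outc$outcome == "UNK")
  )
  date_checks <- tibble::tribble(
    ~check, ~table, ~n,
    "partial_receipt_date", "demo",
    sum(!is.na(bundle$demo$receipt_date) &
          pd_precision(bundle$demo$receipt_date) != "day"),
    "missing_event_date", "demo", sum(is.na(bundle$demo$event_date)),
    "partial_event_date", "demo",
    sum(!is.na(bundle$demo$event_date) &
          pd_precision(bundle$demo$event_date) != "day"),
    "missing_ther_start", "ther", sum(is.na(bundle$ther$start_date))
  )
  dur <- pd_days_between(bundle$ther$start_date, bundle$ther$end_date)
  neg <- tibble::tibble(check = "negative_therapy_duration", table = "ther",
                        n = sum(!is.na(dur) & dur < 0))
  out <- dplyr::bind_rows(res, unk, date_checks, neg)
  dplyr::mutate(out, n = as.integer(.data$n))
}

#' Normalize a reported age to years
#'
#' FAERS ages carry a unit code; descriptive age bins are in years. Unit
#' conversions: `YR` x1, `DEC` x10, `MON` /12, `WK` /52.18, `DY` /365.25,
#' `HR` /8766. An unusable unit yields a missing age.
#'
#' @param age_value Numeric vector of reported ages.
#' @param age_unit Character vector of unit codes.
#' @return Numeric vector of ages in years.
#' @examples
#' age_in_years(c(54, 5, 18), c("YR", "DEC", "MON"))
#' @export
age_in_years <- function(age_value, age_unit) {
  factor <- c(YR = 1, DEC = 10, MON = 1 / 12, WK = 1 / 52.18,
              DY = 1 / 365.25, HR = 1 / 8766)[age_unit]
  out <- age_value * unname(factor)
  out[is.na(age_value) | is.na(factor)] <- NA_real_
  out
}
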