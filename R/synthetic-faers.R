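#' Configuration for the synthetic spontaneous-report generator
#'
#' Defines the generative model for a FAERS-like bundle with known ground
#' truth. Each simulated report has exactly one primary-suspect (PS) drug;
#' the number of adverse-event terms per report and of drug rows per report
#' follow Poisson distributions truncated at 1 (every report carries at least
#' one PT and one drug). Preferred Terms within a report are drawn without
#' replacement from the baseline PT weights; for a report whose PS drug has
#' planted associations, the weights of the planted PTs are multiplied by the
#' planted relative risk and renormalized, so a relative risk of 1 is the
#' exact null. A configurable fraction of cases receives a superseded earlier
#' version (same case id, earlier receipt date, fresh report id, duplicated
#' child rows), which is what case-version deduplication must remove.
#'
#' Default missingness rates mirror the composition of real cinacalcet
#' reports (12.9% missing sex, 32.9% missing age, 51.5% missing event date);
#' the time-to-onset lognormal defaults reproduce a median onset of 82 days
#' with a heavy right tail.
#'
#' @param n_reports Number of distinct cases to simulate.
#' @param n_drugs,n_pts Sizes of the drug and PT dictionaries.
#' @param baseline_pt_weights,baseline_drug_weights Probability vectors
#'   (default uniform); must be nonnegative and sum to 1 within `1e-9`.
#' @param planted_signals Data frame with integer columns `drug`, `pt` and a
#'   numeric `rr` (relative risk, `>= 0`) giving drug--event associations to
#'   plant. `rr = 1` means no association; `rr = 0` removes the PT for that
#'   drug's reports.
#' @param events_per_report_mean,drugs_per_report_mean Poisson rates for the
#'   truncated-at-1 counts of PTs and drug rows per report. The realized mean
#'   is `lambda / (1 - exp(-lambda))`.
#' @param duplicate_rate Fraction of cases in `[0, 1)` receiving one
#'   superseded earlier version.
#' @param missing_sex_rate,missing_age_rate,missing_date_rate Fractions in
#'   `[0, 1]` of reports with missing sex, age, and event date.
#' @param partial_date_rate Fraction of the remaining dates truncated to
#'   month or year precision (split evenly), exercising partial-date
#'   handling.
#' @param tto_lognormal Length-2 numeric `(meanlog, sdlog)` for days from
#'   therapy start to event.
#' @param year_range Length-2 integer range of therapy-start years.
#' @param target_drug Integer id of the drug whose reports are labelled with
#'   names from `target_names` (the drug the downstream analysis targets).
#' @param target_names Synonym pool used as the target drug's `drugname`.
#' @param name_noise_rate Fraction of target drug rows given a formulation
#'   suffix (e.g. `" 30MG TABLET"`) to exercise substring matching.
#' @param seed Integer seed; generation is a pure function of the config.
#' @return A validated `sim_config` object (named list).
#' @seealso [simulate_faers()], [expected_fourfold()]
#' @export
sim_config <- function(n_reports = 2000,
                       n_drugs = 10,
                       n_pts = 100,
                       baseline_pt_weights = NULL,
                       baseline_drug_weights = NULL,
                       planted_signals = NULL,
                       events_per_report_mean = 1.56,
                       drugs_per_report_mean = 2.5,
                       duplicate_rate = 0.165,
                       missing_sex_rate = 0.129,
                       missing_age_rate = 0.329,
                       missing_date_rate = 0.515,
                       partial_date_rate = 0.05,
                       tto_lognormal = c(meanlog = log(82), sdlog = 2),
                       year_range = c(2004L, 2024L),
                       target_drug = 1L,
                       target_names = c("CINACALCET", "SENSIPAR"),
                       name_noise_rate = 0.3,
                       seed = 1L) {
  chk_prob_vec <- function(w, len, what) {
    if (is.null(w)) w <- rep(1 / len, len)
    if (length(w) != len || any(is.na(w)) || any(w < 0)) {
      abort(paste0(what, " must be a nonnegative vector of length ", len))
    }
    if (abs(sum(w) - 1) > 1e-9) {
      abort(paste0(what, " must sum to 1 (got ", format(sum(w)), ")"))
    }
    w
  }
  chk_rate <- function(x, what, open_top = FALSE) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1 ||
        (open_top && x >= 1)) {
      abort(paste0(what, " must be a fraction in [0, 1", if (open_top) ")" else "]"))
    }
    x
  }
  stopifnot(n_reports >= 1, n_drugs >= 1, n_pts >= 1,
            events_per_report_mean > 0, drugs_per_report_mean > 0,
            length(tto_lognormal) == 2, tto_lognormal[2] > 0,
            length(year_range) == 2, year_range[1] <= year_range[2],
            target_drug >= 1, target_drug <= n_drugs,
            length(target_names) >= 1)
  planted <- if (is.null(planted_signals)) {
    tibble::tibble(drug = integer(), pt = integer(), rr = double())
  } else {
    out <- tibble::as_tibble(planted_signals)
    stopifnot(all(c("drug", "pt", "rr") %in% names(out)))
    out <- dplyr::mutate(out, drug = as.integer(.data$drug),
                         pt = as.integer(.data$pt), rr = as.double(.data$rr))
    if (any(out$rr < 0)) abort("planted relative risks must be >= 0")
    if (any(out$drug < 1 | out$drug > n_drugs)) {
      abort("planted signal drug id out of range")
    }
    if (any(out$pt < 1) || length(unique(out$pt)) > n_pts ||
        any(out$pt > n_pts)) {
      abort("planted signal PT id out of range (need n_pts >= planted PTs)")
    }
    if (anyDuplicated(out[, c("drug", "pt")]) > 0L) {
      abort("planted signals must be unique per (drug, pt)")
    }
    out
  }
  cfg <- list(
    n_reports = as.integer(n_reports), n_drugs = as.integer(n_drugs),
    n_pts = as.integer(n_pts),
    baseline_pt_weights = chk_prob_vec(baseline_pt_weights, n_pts,
                                       "baseline_pt_weights"),
    baseline_drug_weights = chk_prob_vec(baseline_drug_weights, n_drugs,
                                         "baseline_drug_weights"),
    planted_signals = planted,
    events_per_report_mean = events_per_report_mean,
    drugs_per_report_mean = drugs_per_report_mean,
    duplicate_rate = chk_rate(duplicate_rate, "duplicate_rate", open_top = TRUE),
    missing_sex_rate = chk_rate(missing_sex_rate, "missing_sex_rate"),
    missing_age_rate = chk_rate(missing_age_rate, "missing_age_rate"),
    missing_date_rate = chk_rate(missing_date_rate, "missing_date_rate"),
    partial_date_rate = chk_rate(partial_date_rate, "partial_date_rate"),
    tto_lognormal = unname(as.numeric(tto_lognormal)),
    year_range = as.integer(year_range),
    target_drug = as.integer(target_drug),
    target_names = toupper(target_names),
    name_noise_rate = chk_rate(name_noise_rate, "name_noise_rate"),
    seed = as.integer(seed)
  )
  structure(cfg, class = "sim_config")
}

sim_pt_label <- function(i) sprintf("PT%04d", i)
sim_drug_label <- function(j) sprintf("DRUG%03d", j)

# zero-truncated Poisson draw (>= 1)
rtpois1 <- function(n, lambda) {
  qpois(runif(n, min = dpois(0, lambda), max = 1), lambda)
}

# mean of the zero-truncated Poisson
tpois1_mean <- function(lambda) lambda / (1 - exp(-lambda))

# per-drug renormalized PT weights after applying planted relative risks
sim_pt_weights <- function(config) {
  base <- config$baseline_pt_weights
  out <- vector("list", config$n_drugs)
  for (j in seq_len(config$n_drugs)) out[[j]] <- base
  planted <- config$planted_signals
  for (j in unique(planted$drug)) {
    w <- base
    rows <- planted[planted$drug == j, ]
    w[rows$pt] <- w[rows$pt] * rows$rr
    out[[j]] <- w / sum(w)
  }
  out
}

#' Simulate a FAERS-like report bundle with known ground truth
#'
#' Generates DEMO, DRUG, REAC, THER and OUTC records under the generative
#' model described in [sim_config()], plus a ground-truth object recording
#' exactly what was planted and tallied, so every downstream stage
#' (deduplication, target extraction, contingency tables) can be checked
#' against known answers. Generation is a pure function of `config` —
#' identical configs give identical bundles.
#'
#' @param config A [sim_config()].
#' @return A list of class `faers_sim` with elements
#'   \describe{
#'     \item{bundle}{a [faers_bundle()];}
#'     \item{truth}{a list: `planted` (drug, pt label, rr),
#'       `superseded_report_ids`, `target_report_ids` (current versions with
#'       the target drug as PS), `pair_counts` (per-PT tallies of target `a`
#'       and background `c` pairs over current versions),
#'       `n_target_pairs`, `n_background_pairs`, `n_cases`.}
#'   }
#' @export
simulate_faers <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, sim_generate(config))
}

sim_generate <- function(config) {
  n <- config$n_reports
  n_pts <- config$n_pts
  report_ids <- sprintf("R%07d", seq_len(n))
  case_ids <- sprintf("C%07d", seq_len(n))
  n_positive <- purrr::map_int(sim_pt_weights(config), ~ sum(.x > 0))

  k_ev <- rtpois1(n, config$events_per_report_mean)
  k_dr <- rtpois1(n, config$drugs_per_report_mean)
  ps_drug <- sample.int(config$n_drugs, n, replace = TRUE,
                        prob = config$baseline_drug_weights)
  k_ev <- pmin(k_ev, n_positive[ps_drug])

  # PTs per report: weighted sampling without replacement via exponential
  # race keys, so REAC rows are unique within a report by construction
  weights <- sim_pt_weights(config)
  pts_list <- vector("list", n)
  for (i in seq_len(n)) {
    keys <- rexp(n_pts) / weights[[ps_drug[i]]]
    pts_list[[i]] <- sort(order(keys)[seq_len(k_ev[i])])
  }
  reac <- tibble::tibble(
    report_id = rep(report_ids, k_ev),
    pt = sim_pt_label(unlist(pts_list))
  )

  # drug rows: the PS row first, then secondary/concomitant/interacting rows
  target <- config$target_drug
  name_of <- function(ids) {
    nm <- sim_drug_label(ids)
    is_t <- ids == target
    n_t <- sum(is_t)
    if (n_t > 0L) {
      base <- sample(config$target_names, n_t, replace = TRUE)
      suffix <- ifelse(
        runif(n_t) < config$name_noise_rate,
        sample(c(" 30MG TABLET", " HYDROCHLORIDE", " 60 MG", " ORAL"),
               n_t, replace = TRUE),
        ""
      )
      nm[is_t] <- paste0(base, suffix)
    }
    nm
  }
  ps_rows <- tibble::tibble(
    report_id = report_ids, drug_seq = 1L, role = "PS",
    drugname = name_of(ps_drug),
    active_ingredient = ifelse(ps_drug == target, "CINACALCET", NA_character_)
  )
  n_extra <- k_dr - 1L
  extra_ids <- sample.int(config$n_drugs, sum(n_extra), replace = TRUE,
                          prob = config$baseline_drug_weights)
  extra_rows <- tibble::tibble(
    report_id = rep(report_ids, n_extra),
    drug_seq = unlist(purrr::map(n_extra[n_extra > 0L], ~ seq_len(.x) + 1L),
                      use.names = FALSE) %||% integer(),
    role = sample(c("SS", "C", "I"), sum(n_extra), replace = TRUE,
                  prob = c(0.4, 0.4, 0.2)),
    drugname = name_of(extra_ids),
    active_ingredient = ifelse(extra_ids == target, "CINACALCET", NA_character_)
  )
  drug <- dplyr::arrange(dplyr::bind_rows(ps_rows, extra_rows),
                         .data$report_id, .data$drug_seq)

  # timeline: therapy start -> event (lognormal onset) -> receipt (lag)
  day0 <- as.Date(sprintf("%d-01-01", config$year_range[1]))
  day1 <- as.Date(sprintf("%d-06-30", config$year_range[2]))
  start <- day0 + floor(runif(n, 0, as.numeric(day1 - day0) + 1))
  tto_days <- pmax(0, round(rlnorm(n, config$tto_lognormal[1],
                                   config$tto_lognormal[2])))
  event <- start + tto_days
  receipt <- event + sample.int(120, n, replace = TRUE) + 6L

  truncate_dates <- function(x) {
    u <- runif(length(x))
    p <- config$partial_date_rate
    dplyr::case_when(
      u < p / 2 ~ substr(x, 1L, 6L),
      u < p ~ substr(x, 1L, 4L),
      TRUE ~ x
    )
  }
  event_chr <- truncate_dates(format_ymd(event))
  event_chr[runif(n) < config$missing_date_rate] <- NA_character_
  start_chr <- truncate_dates(format_ymd(start))

  sex <- ifelse(runif(n) < 0.543, "F", "M")
  sex[runif(n) < config$missing_sex_rate] <- "UNK"
  age <- pmin(pmax(rnorm(n, 60, 15), 0.5), 100)
  age_unit <- rep("YR", n)
  age_missing <- runif(n) < config$missing_age_rate
  age[age_missing] <- NA_real_
  age_unit[age_missing] <- "UNK"
  reporter <- sample(reporter_levels, n, replace = TRUE,
                     prob = c(0.1135, 0.2516, 0.3248, 0.3028, 0.0073))
  country <- ifelse(runif(n) < 0.8952, "US",
                    sample(c("JP", "FR", "DE", "GB", "CA"), n, replace = TRUE))

  demo <- tibble::tibble(
    report_id = report_ids, case_id = case_ids,
    receipt_date = format_ymd(receipt), event_date = event_chr,
    sex = sex, age_value = round(age, 1), age_unit = age_unit,
    reporter = reporter, country = country
  )

  ther <- tibble::tibble(
    report_id = report_ids, drug_seq = 1L,
    start_date = start_chr,
    end_date = ifelse(runif(n) < 0.7,
                      format_ymd(start + sample.int(400, n, replace = TRUE) + 29L),
                      NA_character_)
  )

  n_out <- sample(0:2, n, replace = TRUE, prob = c(0.55, 0.35, 0.10))
  outc_codes <- c("OT", "HO", "DE", "DS", "LT")
  outc_w <- c(0.432, 0.316, 0.185, 0.035, 0.032)
  outc <- tibble::tibble(
    report_id = rep(report_ids, n_out),
    outcome = unlist(purrr::map(n_out[n_out > 0L],
                                ~ sample(outc_codes, .x, prob = outc_w)),
                     use.names = FALSE) %||% character()
  )

  # superseded case versions: same case id, strictly earlier receipt date,
  # fresh report id; child rows copied so dedup has real work to undo
  dup <- which(runif(n) < config$duplicate_rate)
  sup_ids <- character()
  if (length(dup) > 0L) {
    sup_ids <- sprintf("R%07d", n + seq_along(dup))
    sup_demo <- demo[dup, ]
    sup_demo$report_id <- sup_ids
    sup_demo$receipt_date <- format_ymd(
      receipt[dup] - (sample.int(270, length(dup), replace = TRUE) + 29L)
    )
    demo <- dplyr::bind_rows(demo, sup_demo)
    relabel <- function(tbl) {
      sub <- tbl[tbl$report_id %in% report_ids[dup], ]
      sub$report_id <- sup_ids[match(sub$report_id, report_ids[dup])]
      sub
    }
    drug <- dplyr::bind_rows(drug, relabel(drug))
    reac <- dplyr::bind_rows(reac, relabel(reac))
    ther <- dplyr::bind_rows(ther, relabel(ther))
    outc <- dplyr::bind_rows(outc, relabel(outc))
  }

  is_target_report <- ps_drug == target
  pair_counts <- reac[reac$report_id %in% report_ids, ] |>
    dplyr::mutate(target = .data$report_id %in% report_ids[is_target_report]) |>
    dplyr::count(.data$pt, .data$target) |>
    tidyr::pivot_wider(names_from = "target", values_from = "n",
                       values_fill = 0L) |>
    dplyr::rename_with(~ dplyr::recode(.x, `TRUE` = "a", `FALSE` = "c"))
  for (col in c("a", "c")) {
    if (!col %in% names(pair_counts)) pair_counts[[col]] <- 0L
  }
  pair_counts <- dplyr::select(pair_counts, "pt", "a", "c")

  truth <- list(
    planted = dplyr::mutate(config$planted_signals,
                            pt_id = .data$pt, pt = sim_pt_label(.data$pt)),
    superseded_report_ids = sup_ids,
    target_report_ids = report_ids[is_target_report],
    pair_counts = pair_counts,
    n_target_pairs = sum(pair_counts$a),
    n_background_pairs = sum(pair_counts$c),
    n_cases = n
  )
  structure(list(bundle = faers_bundle(demo, drug, reac, ther, outc),
                 truth = truth, config = config),
            class = "faers_sim")
}

#' Expected fourfold-table cells under the generative model
#'
#' Analytic expectation of the contingency-table cells for one (drug, PT)
#' pair, used as an oracle in tests. Uses the first-order inclusion
#' probability `E[k] * w` for a PT in a report (exact for sampling with
#' replacement; an upper-bound approximation for the without-replacement
#' draws actually generated, accurate when events per report are few relative
#' to `n_pts`). Cells sum exactly to the expected total number of
#' (report, PT) pairs.
#'
#' @param config A [sim_config()].
#' @param drug,pt Integer ids of the drug (the "target" margin) and PT.
#' @return One-row tibble with real-valued columns `a`, `b`, `c`, `d`, `n`.
#' @export
expected_fourfold <- function(config, drug, pt) {
  stopifnot(inherits(config, "sim_config"))
  if (drug < 1 || drug > config$n_drugs) abort("drug id out of range")
  if (pt < 1 || pt > config$n_pts) abort("pt id out of range")
  e_k <- tpois1_mean(config$events_per_report_mean)
  pairs_by_drug <- config$n_reports * config$baseline_drug_weights * e_k
  w <- sim_pt_weights(config)
  a <- pairs_by_drug[drug] * w[[drug]][pt]
  b <- pairs_by_drug[drug] - a
  cc <- sum(purrr::map_dbl(seq_len(config$n_drugs), function(j) {
    if (j == drug) 0 else pairs_by_drug[j] * w[[j]][pt]
  }))
  total <- sum(pairs_by_drug)
  tibble::tibble(a = a, b = b, c = cc, d = total - a - b - cc, n = total)
}
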