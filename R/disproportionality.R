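#' Build fourfold (2x2) contingency tables from pair sets
#'
#' For every term (PT or SOC), the fourfold table partitions deduplicated
#' (report, term) pairs as: `a` target pairs with the term, `b` other target
#' pairs, `c` background pairs with the term, `d` other background pairs,
#' `n = a + b + c + d`. Summed over all terms, `a` recovers the number of
#' target pairs exactly — each pair lands in exactly one `a` cell.
#'
#' @param target_pairs,background_pairs Tibbles of disjoint unique pairs; the
#'   term column is `pt` or `soc` (autodetected).
#' @param terms Optional character vector restricting/ordering the output;
#'   defaults to every term present in either partition. Terms absent from a
#'   partition get a zero cell.
#' @return Tibble with columns `term`, `a`, `b`, `c`, `d`, `n`.
#' @seealso [signal_stats()], [build_fourfold()]
#' @export
fourfold_from_pairs <- function(target_pairs, background_pairs, terms = NULL) {
  term_col <- if ("soc" %in% names(target_pairs)) "soc" else "pt"
  n_target <- nrow(target_pairs)
  n_background <- nrow(background_pairs)
  tally <- function(pairs, nm) {
    out <- dplyr::count(pairs, term = .data[[term_col]], name = nm)
    out[!is.na(out$term), ]
  }
  tab <- dplyr::full_join(tally(target_pairs, "a"),
                          tally(background_pairs, "c"), by = "term")
  if (!is.null(terms)) {
    tab <- dplyr::right_join(tab, tibble::tibble(term = terms), by = "term")
  }
  tab |>
    dplyr::mutate(
      a = as.integer(tidyr::replace_na(.data$a, 0L)),
      c = as.integer(tidyr::replace_na(.data$c, 0L)),
      b = n_target - .data$a,
      d = n_background - .data$c,
      n = .data$a + .data$b + .data$c + .data$d
    ) |>
    dplyr::select("term", "a", "b", "c", "d", "n") |>
    dplyr::arrange(.data$term)
}

#' Fourfold table for a single term
#'
#' @param events A `drug_event_set` from [extract_event_sets()].
#' @param term A PT string (or SOC string with `level = "soc"` and a map).
#' @param level Count at Preferred Term or System Organ Class level.
#' @param meddra_map PT-to-SOC map, required for `level = "soc"`.
#' @return One-row tibble `term`, `a`, `b`, `c`, `d`, `n`.
#' @export
build_fourfold <- function(events, term, level = c("pt", "soc"),
                           meddra_map = NULL) {
  level <- rlang::arg_match(level)
  stopifnot(inherits(events, "drug_event_set"))
  tp <- events$target_pairs
  bp <- events$background_pairs
  if (level == "soc") {
    if (is.null(meddra_map)) abort("SOC-level tables need a `meddra_map`")
    tp <- map_pt_to_soc(tp, meddra_map)$pairs
    bp <- map_pt_to_soc(bp, meddra_map)$pairs
  }
  fourfold_from_pairs(tp, bp, terms = term)
}

#' Disproportionality statistics for fourfold tables
#'
#' Computes, per table: the reporting odds ratio `ROR = ad/(bc)` with Wald
#' 95% CI on the log scale (`SE = sqrt(1/a + 1/b + 1/c + 1/d)`); the
#' proportional reporting ratio `PRR = (a/(a+b)) / (c/(c+d))` with its own
#' `SE = sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d))`; the Pearson chi-square on 1
#' df without continuity correction, `N(ad-bc)^2 / ((a+b)(c+d)(a+c)(b+d))`,
#' and its upper-tail p-value; the information component
#' `IC = log2(aN / ((a+b)(a+c)))` with credibility bound
#' `IC025 = IC - 2 SE / ln 2`; and the empirical Bayes geometric mean
#' `EBGM = aN / ((a+b)(a+c))` (the unshrunk observed-to-expected ratio, so
#' `IC = log2(EBGM)` identically) with its 5th percentile
#' `EBGM05 = exp(ln EBGM - 1.645 SE)`.
#'
#' Tables with a zero cell get `NA` statistics and a reason by default — no
#' silent continuity correction; set `zero_cells = "haldane"` to add 0.5 to
#' every cell of affected tables instead. `ic_mode = "bayes"` replaces the
#' simplified IC/IC025 with the full Bayesian credibility version under
#' standard uninformative priors.
#'
#' @param tables Tibble with integer columns `a`, `b`, `c`, `d` (and
#'   optionally `term`), as from [fourfold_from_pairs()].
#' @param zero_cells `"undefined"` (default) or `"haldane"`.
#' @param ic_mode `"simplified"` (default) or `"bayes"`.
#' @param ebgm_percentile_z Normal deviate for the EBGM lower bound: 1.645
#'   gives the one-sided 5th percentile (default); use 1.96 for a two-sided
#'   95% bound.
#' @return The input tibble with statistic columns appended: `ror`,
#'   `ror_lo95`, `ror_hi95`, `prr`, `prr_lo95`, `prr_hi95`, `chi2`, `p`,
#'   `ic`, `ic025`, `ebgm`, `ebgm05`, `se_ln`, `se_ln_prr`,
#'   `undefined_reason`.
#' @examples
#' signal_stats(data.frame(a = 3, b = 7, c = 30, d = 960))
#' @export
signal_stats <- function(tables, zero_cells = c("undefined", "haldane"),
                         ic_mode = c("simplified", "bayes"),
                         ebgm_percentile_z = 1.645) {
  zero_cells <- rlang::arg_match(zero_cells)
  ic_mode <- rlang::arg_match(ic_mode)
  tab <- tibble::as_tibble(tables)
  stopifnot(all(c("a", "b", "c", "d") %in% names(tab)))
  if (any(tab$a < 0 | tab$b < 0 | tab$c < 0 | tab$d < 0, na.rm = TRUE)) {
    abort("fourfold cells must be nonnegative")
  }
  has_zero <- tab$a == 0 | tab$b == 0 | tab$c == 0 | tab$d == 0
  shift <- if (zero_cells == "haldane") ifelse(has_zero, 0.5, 0) else 0
  # double arithmetic throughout: cell products overflow integer range
  a <- as.numeric(tab$a) + shift; b <- as.numeric(tab$b) + shift
  cc <- as.numeric(tab$c) + shift; d <- as.numeric(tab$d) + shift
  n <- a + b + cc + d

  se_ln <- sqrt(1 / a + 1 / b + 1 / cc + 1 / d)
  se_ln_prr <- sqrt(1 / a - 1 / (a + b) + 1 / cc - 1 / (cc + d))
  ror <- (a * d) / (b * cc)
  prr <- (a / (a + b)) / (cc / (cc + d))
  ebgm <- a * n / ((a + b) * (a + cc))
  ic <- log2(ebgm)
  chi2 <- n * (a * d - b * cc)^2 /
    ((a + b) * (cc + d) * (a + cc) * (b + d))

  if (ic_mode == "bayes") {
    bayes <- bcpnn_bayes(a, b, cc, d)
    ic <- bayes$e_ic
    ic025 <- bayes$ic025
  } else {
    ic025 <- ic - 2 * se_ln / log(2)
  }

  out <- dplyr::mutate(
    tab,
    n = .data$a + .data$b + .data$c + .data$d,
    ror = ror,
    ror_lo95 = exp(log(ror) - 1.96 * se_ln),
    ror_hi95 = exp(log(ror) + 1.96 * se_ln),
    prr = prr,
    prr_lo95 = exp(log(prr) - 1.96 * se_ln_prr),
    prr_hi95 = exp(log(prr) + 1.96 * se_ln_prr),
    chi2 = chi2,
    p = pchisq(chi2, df = 1, lower.tail = FALSE),
    ic = ic,
    ic025 = ic025,
    ebgm = ebgm,
    ebgm05 = exp(log(ebgm) - ebgm_percentile_z * se_ln),
    se_ln = se_ln,
    se_ln_prr = se_ln_prr,
    undefined_reason = NA_character_
  )
  if (zero_cells == "undefined" && any(has_zero)) {
    stat_cols <- c("ror", "ror_lo95", "ror_hi95", "prr", "prr_lo95",
                   "prr_hi95", "chi2", "p", "ic", "ic025", "ebgm", "ebgm05",
                   "se_ln", "se_ln_prr")
    for (col in stat_cols) out[[col]][has_zero] <- NA_real_
    zero_cell_name <- function(i) {
      cells <- c("a", "b", "c", "d")[c(tab$a[i] == 0, tab$b[i] == 0,
                                       tab$c[i] == 0, tab$d[i] == 0)]
      paste0("zero cell(s): ", paste(cells, collapse = ","))
    }
    out$undefined_reason[has_zero] <-
      vapply(which(has_zero), zero_cell_name, character(1))
  }
  out
}

# Full-Bayes information component (credibility version) under standard
# uninformative priors gamma11 = alpha1 = beta1 = 1, alpha = beta = 2.
bcpnn_bayes <- function(a, b, cc, d,
                        alpha = 2, beta = 2, alpha1 = 1, beta1 = 1,
                        gamma11 = 1) {
  n <- a + b + cc + d
  gamma <- gamma11 * (n + alpha) * (n + beta) /
    ((a + b + alpha1) * (a + cc + beta1))
  e_ic <- log2((a + gamma11) * (n + alpha) * (n + beta) /
                 ((n + gamma) * (a + b + alpha1) * (a + cc + beta1)))
  v_ic <- (1 / log(2)^2) * (
    (n - a + gamma - gamma11) / ((a + gamma11) * (1 + n + gamma)) +
      (n - (a + b) + alpha - alpha1) / ((a + b + alpha1) * (1 + n + alpha)) +
      (n - (a + cc) + beta - beta1) / ((a + cc + beta1) * (1 + n + beta))
  )
  list(e_ic = e_ic, v_ic = v_ic, ic025 = e_ic - 2 * sqrt(v_ic))
}

#' Scalar disproportionality statistics for one table
#'
#' Plain per-table arithmetic over the four cells, used as the reference
#' path against which the vectorized [signal_stats()] is checked; both must
#' agree bit-for-bit on every table.
#'
#' @param a,b,c,d Nonnegative cell counts (all positive for defined
#'   statistics).
#' @inheritParams signal_stats
#' @return One-row tibble with the same statistic columns as
#'   [signal_stats()].
#' @export
compute_signal_stats <- function(a, b, c, d, ebgm_percentile_z = 1.645) {
  stopifnot(length(a) == 1L, length(b) == 1L, length(c) == 1L,
            length(d) == 1L, a >= 0, b >= 0, c >= 0, d >= 0)
  if (min(a, b, c, d) == 0) {
    return(signal_stats(tibble::tibble(a = a, b = b, c = c, d = d),
                        ebgm_percentile_z = ebgm_percentile_z))
  }
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  se_prr <- sqrt(1 / a - 1 / (a + b) + 1 / c - 1 / (c + d))
  ror <- a * d / (b * c)
  prr <- (a / (a + b)) / (c / (c + d))
  ebgm <- a * n / ((a + b) * (a + c))
  ic <- log2(ebgm)
  chi2 <- n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
  tibble::tibble(
    a = a, b = b, c = c, d = d, n = n,
    ror = ror,
    ror_lo95 = exp(log(ror) - 1.96 * se),
    ror_hi95 = exp(log(ror) + 1.96 * se),
    prr = prr,
    prr_lo95 = exp(log(prr) - 1.96 * se_prr),
    prr_hi95 = exp(log(prr) + 1.96 * se_prr),
    chi2 = chi2,
    p = pchisq(chi2, df = 1, lower.tail = FALSE),
    ic = ic,
    ic025 = ic - 2 * se / log(2),
    ebgm = ebgm,
    ebgm05 = exp(log(ebgm) - ebgm_percentile_z * se),
    se_ln = se,
    se_ln_prr = se_prr,
    undefined_reason = NA_character_
  )
}

#' Benjamini--Hochberg false-discovery-rate adjustment
#'
#' Step-up adjustment of a vector of p-values, returned in input order.
#' `NA` entries stay `NA` and do not count toward the family size.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @examples
#' adjust_fdr(c(0.001, 0.012, 0.03, 0.04, 0.2))
#' @export
adjust_fdr <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

#' Signal-flagging thresholds
#'
#' The screening criteria applied to each term: a minimum case count, strict
#' lower-bound rules per method (ROR and PRR 95% CI lower bound `> 1`,
#' `IC025 > 0`, `EBGM05 > 1`), the FDR-adjusted p-value threshold, and the
#' composite policy combining them. `"ror_primary"` (default) flags a term
#' when the count rule, the ROR rule and the adjusted-p rule all hold — the
#' other methods are supplementary; `"all_four"` additionally requires the
#' PRR, IC and EBGM rules; `"any"` requires any one method rule plus count
#' and adjusted p.
#'
#' @param min_a Minimum case count `a` (a smaller count forces every flag
#'   false).
#' @param p_adj_max Adjusted-p threshold (strict `<`).
#' @param policy Composite policy.
#' @return A `signal_criteria` object.
#' @export
signal_criteria <- function(min_a = 3L, p_adj_max = 0.05,
                            policy = c("ror_primary", "all_four", "any")) {
  policy <- rlang::arg_match(policy)
  stopifnot(min_a >= 1, p_adj_max > 0, p_adj_max <= 1)
  structure(list(min_a = as.integer(min_a), p_adj_max = p_adj_max,
                 policy = policy),
            class = "signal_criteria")
}

#' Apply signal criteria to a statistics table
#'
#' Adds per-method boolean flags and the composite flag. The FDR adjustment
#' is computed here if a `p_adj` column is absent, over the family of terms
#' meeting the count rule (`a >= min_a`) with a defined p-value — terms
#' below the count threshold are not tested and get `NA` adjusted p. All
#' threshold comparisons are strict; undefined statistics never flag.
#'
#' @param stats Output of [signal_stats()].
#' @param criteria A [signal_criteria()].
#' @return `stats` with columns `p_adj`, `sig_ror`, `sig_prr`, `sig_ic`,
#'   `sig_ebgm`, `sig_fdr`, `signal`.
#' @export
flag_signals <- function(stats, criteria = signal_criteria()) {
  stopifnot(inherits(criteria, "signal_criteria"))
  out <- tibble::as_tibble(stats)
  countable <- out$a >= criteria$min_a
  if (!"p_adj" %in% names(out)) {
    out$p_adj <- NA_real_
    family <- countable & !is.na(out$p)
    out$p_adj[family] <- adjust_fdr(out$p[family])
  }
  strict <- function(x, threshold) !is.na(x) & x > threshold
  out <- dplyr::mutate(
    out,
    sig_ror = countable & strict(.data$ror_lo95, 1),
    sig_prr = countable & strict(.data$prr_lo95, 1),
    sig_ic = countable & strict(.data$ic025, 0),
    sig_ebgm = countable & strict(.data$ebgm05, 1),
    sig_fdr = countable & !is.na(.data$p_adj) &
      .data$p_adj < criteria$p_adj_max
  )
  out$signal <- switch(criteria$policy,
    ror_primary = out$sig_ror & out$sig_fdr,
    all_four = out$sig_ror & out$sig_prr & out$sig_ic & out$sig_ebgm &
      out$sig_fdr,
    any = (out$sig_ror | out$sig_prr | out$sig_ic | out$sig_ebgm) &
      out$sig_fdr
  )
  out
}

#' Reconstruct a fourfold table from published margins and statistics
#'
#' Published signal tables print, per term, the case count `a`, the PRR and
#' the EBGM, but not the background cells. Because
#' `PRR = (a/(a+b)) / (c/(c+d))` and `EBGM = aN/((a+b)(a+c))`, the two
#' printed statistics pin down the remaining cells: with
#' `r1 = (a/(a+b))/PRR` (the background event proportion) and
#' `s = a/((a+b) EBGM)` (the overall event proportion),
#' `N = (r1 (a+b) - a) / (r1 - s)` and `c = r1 (N - a - b)`. Recomputing the
#' held-out statistics (ROR, CIs, chi-square, IC, EBGM05) from the
#' reconstructed real-valued table cross-checks the internal consistency of
#' a published row. The inversion is exact: feeding a table's own `a`,
#' `a+b`, PRR and EBGM back in recovers `c` and `N` to floating-point
#' accuracy.
#'
#' @param a Case count (`>= 1`).
#' @param a_plus_b Total target pairs (`> a`).
#' @param prr,ebgm Printed statistics (`> 0`).
#' @return One-row tibble with real-valued `a`, `b`, `c`, `d`, `n`.
#' @examples
#' cells <- reconstruct_fourfold(610, 47755, prr = 40.79, ebgm = 39.4)
#' signal_stats(cells)$ror # ~ 41.3
#' @export
reconstruct_fourfold <- function(a, a_plus_b, prr, ebgm) {
  stopifnot(a >= 1, a_plus_b > a, prr > 0, ebgm > 0)
  r1 <- (a / a_plus_b) / prr
  s <- a / (a_plus_b * ebgm)
  if (abs(r1 - s) < 1e-15 * max(r1, s)) {
    abort("degenerate inputs: background and overall event proportions equal")
  }
  n <- (r1 * a_plus_b - a) / (r1 - s)
  cc <- r1 * (n - a_plus_b)
  b <- a_plus_b - a
  d <- n - a_plus_b - cc
  if (!is.finite(n) || n <= a_plus_b || cc <= 0 || d <= 0) {
    abort("inconsistent inputs: reconstruction yields non-positive cells")
  }
  tibble::tibble(a = a, b = b, c = cc, d = d, n = n)
}
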