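#' Run the disproportionality analysis at PT or SOC level
#'
#' Convenience wrapper chaining [fourfold_from_pairs()], [signal_stats()] and
#' [flag_signals()] over every term in a `drug_event_set`, returning a
#' fitted-model-like object with [tidy()], [glance()] and [autoplot()]
#' methods.
#'
#' @param events A `drug_event_set` from [extract_event_sets()].
#' @param level `"pt"` (default) or `"soc"`.
#' @param meddra_map PT-to-SOC map tibble, required for SOC level; at PT
#'   level it is optional and, when given, adds a `soc` annotation column.
#' @param criteria A [signal_criteria()].
#' @inheritParams signal_stats
#' @return An object of class `faers_signals`.
#' @examples
#' sim <- simulate_faers(sim_config(n_reports = 500, seed = 7))
#' events <- extract_event_sets(sim$bundle)
#' sig <- analyze_signals(events)
#' glance(sig)
#' @export
analyze_signals <- function(events, level = c("pt", "soc"), meddra_map = NULL,
                            criteria = signal_criteria(),
                            zero_cells = c("undefined", "haldane"),
                            ic_mode = c("simplified", "bayes")) {
  level <- rlang::arg_match(level)
  stopifnot(inherits(events, "drug_event_set"))
  tp <- events$target_pairs
  bp <- events$background_pairs
  unmapped <- character()
  if (level == "soc") {
    if (is.null(meddra_map)) abort("SOC-level analysis needs a `meddra_map`")
    mt <- map_pt_to_soc(tp, meddra_map)
    mb <- map_pt_to_soc(bp, meddra_map)
    tp <- mt$pairs
    bp <- mb$pairs
    unmapped <- union(mt$unmapped, mb$unmapped)
  }
  # terms never co-reported with the target (a = 0) carry no information at
  # this margin and are omitted; build_fourfold() can still query them
  stats <- fourfold_from_pairs(tp, bp) |>
    dplyr::filter(.data$a > 0L) |>
    signal_stats(zero_cells = zero_cells, ic_mode = ic_mode) |>
    flag_signals(criteria)
  if (level == "pt" && !is.null(meddra_map)) {
    soc_lookup <- map_pt_to_soc(
      tibble::tibble(report_id = "x", pt = stats$term),
      meddra_map, per_report_unique = FALSE
    )$pairs
    stats <- dplyr::left_join(
      stats,
      dplyr::distinct(soc_lookup, pt = .data$pt, soc = .data$soc),
      by = c(term = "pt")
    )
  }
  structure(
    list(
      stats = stats,
      level = level,
      criteria = criteria,
      n_target_reports = length(events$target_report_ids),
      n_target_pairs = nrow(events$target_pairs),
      n_background_pairs = nrow(events$background_pairs),
      unmapped_pts = unmapped
    ),
    class = "faers_signals"
  )
}

#' @export
print.faers_signals <- function(x, ...) {
  cat(sprintf("<faers_signals> %s-level, %d terms, %d flagged (%s policy)\n",
              toupper(x$level), nrow(x$stats), sum(x$stats$signal),
              x$criteria$policy))
  invisible(x)
}

#' Tidy a disproportionality result
#'
#' One row per analyzed term with all statistics and flags.
#'
#' @param x A `faers_signals` object.
#' @param ... Unused.
#' @method tidy faers_signals
#' @export
tidy.faers_signals <- function(x, ...) {
  x$stats
}

#' One-row summary of a disproportionality result
#'
#' @param x A `faers_signals` object.
#' @param ... Unused.
#' @method glance faers_signals
#' @export
glance.faers_signals <- function(x, ...) {
  tibble::tibble(
    level = x$level,
    n_terms = nrow(x$stats),
    n_tested = sum(!is.na(x$stats$p_adj)),
    n_flagged = sum(x$stats$signal),
    policy = x$criteria$policy,
    min_a = x$criteria$min_a,
    n_target_reports = x$n_target_reports,
    n_target_pairs = x$n_target_pairs,
    n_background_pairs = x$n_background_pairs
  )
}

#' Forest plot of flagged signals
#'
#' Reporting odds ratios with 95% confidence intervals on a log axis, one
#' row per flagged term (or the strongest `max_terms` of them).
#'
#' @param object A `faers_signals` object.
#' @param max_terms Upper limit on rows shown.
#' @param flagged_only Show only composite-flagged terms (default); if no
#'   term is flagged, the strongest terms by ROR are shown instead.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot faers_signals
#' @export
autoplot.faers_signals <- function(object, max_terms = 30,
                                   flagged_only = TRUE, ...) {
  dat <- object$stats |>
    dplyr::filter(!is.na(.data$ror))
  if (flagged_only && any(dat$signal)) dat <- dplyr::filter(dat, .data$signal)
  dat <- dat |>
    dplyr::arrange(dplyr::desc(.data$ror)) |>
    head(max_terms) |>
    dplyr::mutate(term = factor(.data$term, levels = rev(.data$term)))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$ror, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ror_lo95, xmax = .data$ror_hi95),
      height = 0.25, colour = "grey30"
    ) +
    ggplot2::geom_point(ggplot2::aes(size = .data$a), colour = "#2166ac") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "Reporting odds ratio (95% CI, log scale)", y = NULL,
      size = "Cases",
      title = sprintf("Disproportionality signals (%s level)",
                      toupper(object$level))
    ) +
    ggplot2::theme_minimal()
}
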