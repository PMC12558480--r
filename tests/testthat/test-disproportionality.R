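test_that("fourfold cells count pairs exactly on a toy partition", {
  target <- mk_reac(c("r1", "r1", "r2"), c("X", "Y", "X"))
  background <- mk_reac(c("r3", "r4"), c("X", "Z"))
  tab <- fourfold_from_pairs(target, background)
  x <- tab[tab$term == "X", ]
  expect_equal(unlist(x[, c("a", "b", "c", "d", "n")]),
               c(a = 2, b = 1, c = 1, d = 1, n = 5))
  # partition identity: each target pair lands in exactly one a cell
  expect_equal(sum(tab$a), nrow(target))
  # absent term yields a = c = 0, not an error
  z <- fourfold_from_pairs(target, background, terms = "missing_term")
  expect_equal(unlist(z[, c("a", "c")]), c(a = 0, c = 0))
})

test_that("statistics reproduce hand-computed values on a small table", {
  s <- compute_signal_stats(3, 7, 30, 960)
  expect_equal(s$ror, 2880 / 210)
  expect_equal(s$prr, 0.3 / (30 / 990))
  expect_equal(s$ebgm, 3 * 1000 / (33 * 10))
  expect_equal(s$ic, log2(3 * 1000 / (33 * 10)))
  expect_equal(s$chi2, 22.57, tolerance = 0.01 / 22.57)
  # a perfectly balanced table carries no signal
  flat <- compute_signal_stats(5, 5, 5, 5)
  expect_equal(flat$ror, 1)
  expect_equal(flat$prr, 1)
  expect_equal(flat$ebgm, 1)
  expect_equal(flat$ic, 0)
  expect_equal(flat$chi2, 0)
})

test_that("chi-square matches the Pearson test without continuity correction", {
  tabs <- random_tables(25, seed = 5)
  for (i in seq_len(nrow(tabs))) {
    m <- matrix(unlist(tabs[i, c("a", "b", "c", "d")]), 2, byrow = TRUE)
    ref <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
    s <- compute_signal_stats(tabs$a[i], tabs$b[i], tabs$c[i], tabs$d[i])
    expect_equal(s$chi2, unname(ref$statistic))
    expect_equal(s$p, unname(ref$p.value))
  }
})

test_that("vectorized statistics equal the per-table scalar path bit-for-bit", {
  tabs <- random_tables(200, seed = 9)
  vec <- signal_stats(tabs)
  scal <- dplyr::bind_rows(purrr::pmap(
    tabs, function(a, b, c, d) compute_signal_stats(a, b, c, d)
  ))
  for (col in c("ror", "ror_lo95", "ror_hi95", "prr", "prr_lo95", "prr_hi95",
                "chi2", "p", "ic", "ic025", "ebgm", "ebgm05", "se_ln",
                "se_ln_prr")) {
    expect_identical(vec[[col]], scal[[col]], label = col)
  }
})

test_that("algebraic identities hold on random positive tables", {
  tabs <- random_tables(1000, seed = 13)
  s <- signal_stats(tabs)
  expect_equal(s$ic, log2(s$ebgm))
  expect_equal(s$ror,
               s$prr * ((tabs$a + tabs$b) / tabs$b) *
                 (tabs$d / (tabs$c + tabs$d)))
  expect_true(all(s$ror_lo95 <= s$ror & s$ror <= s$ror_hi95))
  expect_true(all(s$prr_lo95 <= s$prr & s$prr <= s$prr_hi95))
  expect_true(all(s$ic025 < s$ic))
  expect_true(all(s$ebgm05 < s$ebgm))
})

test_that("shifting mass into cell a strictly increases every statistic", {
  # hold margins a+b, a+c and N fixed while a grows
  base <- c(a = 10, b = 90, c = 200, d = 2000)
  grow <- function(a) compute_signal_stats(
    a, sum(base[c("a", "b")]) - a, sum(base[c("a", "c")]) - a,
    sum(base) - sum(base[c("a", "b")]) - sum(base[c("a", "c")]) + a
  )
  prev <- grow(10)
  for (a in c(20, 40, 80)) {
    cur <- grow(a)
    for (col in c("ror", "prr", "ic", "ebgm", "chi2")) {
      expect_gt(cur[[col]], prev[[col]], label = paste(col, "at a =", a))
    }
    prev <- cur
  }
})

test_that("zero cells yield undefined statistics unless Haldane is requested", {
  tab <- tibble::tibble(a = c(5, 0), b = c(5, 10), c = c(5, 10), d = c(5, 10))
  s <- signal_stats(tab)
  expect_true(is.na(s$ror[2]))
  expect_match(s$undefined_reason[2], "zero cell")
  expect_false(is.na(s$ror[1]))
  h <- signal_stats(tab, zero_cells = "haldane")
  expect_equal(h$ror[2], (0.5 * 10.5) / (10.5 * 10.5))
  # the defined row is untouched by the Haldane option
  expect_equal(h$ror[1], s$ror[1])
})

test_that("BH adjustment matches the hand-computed step-up", {
  expect_equal(adjust_fdr(c(0.001, 0.012, 0.03, 0.04, 0.2)),
               c(0.005, 0.03, 0.05, 0.05, 0.2))
  expect_equal(adjust_fdr(0.037), 0.037)
  expect_equal(adjust_fdr(rep(0.02, 7)), rep(0.02, 7))
  expect_error(adjust_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  # dominates the raw p, capped at 1, order-preserving on sorted input
  withr::with_seed(2, {
    p <- sort(runif(50))
    q <- adjust_fdr(p)
    expect_true(all(q >= p))
    expect_true(all(q <= 1))
    expect_true(all(diff(q) >= 0))
  })
})

test_that("flagging enforces the count rule and strict thresholds", {
  mk_stats <- function(a, ror_lo95, p, ic025 = 1, ebgm05 = 2, prr_lo95 = 2) {
    tibble::tibble(
      term = "t", a = a, ror = ror_lo95 + 1, ror_lo95 = ror_lo95,
      ror_hi95 = ror_lo95 + 2, prr = 2, prr_lo95 = prr_lo95, prr_hi95 = 3,
      chi2 = 10, p = p, ic = ic025 + 1, ic025 = ic025, ebgm = ebgm05 + 1,
      ebgm05 = ebgm05, se_ln = 0.1, se_ln_prr = 0.1,
      undefined_reason = NA_character_
    )
  }
  # a = 2 with an enormous ROR still cannot flag
  f <- flag_signals(mk_stats(2, ror_lo95 = 50, p = 1e-10))
  expect_false(f$signal)
  expect_true(is.na(f$p_adj))
  # boundary: a = 3, lower bound just above 1, adjusted p just below 0.05
  f2 <- flag_signals(mk_stats(3, ror_lo95 = 1.01, p = 0.04))
  expect_true(f2$signal)
  # IC025 exactly 0 fails the strict inequality
  f3 <- flag_signals(mk_stats(10, ror_lo95 = 2, p = 1e-4, ic025 = 0))
  expect_false(f3$sig_ic)
  expect_true(f3$sig_ror)
  # all_four policy needs every method
  f4 <- flag_signals(mk_stats(10, ror_lo95 = 2, p = 1e-4, ic025 = 0),
                     signal_criteria(policy = "all_four"))
  expect_false(f4$signal)
})

test_that("reconstruction inverts a table's own PRR and EBGM exactly", {
  tabs <- random_tables(1000, seed = 17)
  s <- signal_stats(tabs)
  for (i in sample.int(nrow(tabs), 60)) {
    rec <- reconstruct_fourfold(tabs$a[i], tabs$a[i] + tabs$b[i],
                                prr = s$prr[i], ebgm = s$ebgm[i])
    expect_equal(rec$c, tabs$c[i], tolerance = 1e-10)
    expect_equal(rec$n, tabs$a[i] + tabs$b[i] + tabs$c[i] + tabs$d[i],
                 tolerance = 1e-10)
  }
  expect_error(reconstruct_fourfold(10, 100, prr = 2, ebgm = 1 / 0.055),
               "degenerate|non-positive")
  expect_error(reconstruct_fourfold(10, 100, prr = 0.5, ebgm = 5),
               "non-positive")
})

test_that("full-Bayes credibility IC agrees with the simplified form on large tables", {
  s_simple <- signal_stats(tibble::tibble(a = 500, b = 47000, c = 17000,
                                          d = 5e7))
  s_bayes <- signal_stats(tibble::tibble(a = 500, b = 47000, c = 17000,
                                         d = 5e7), ic_mode = "bayes")
  expect_equal(s_bayes$ic, s_simple$ic, tolerance = 0.02)
  expect_lt(s_bayes$ic, s_simple$ic)
  expect_lt(s_bayes$ic025, s_bayes$ic)
  # shrinkage pulls a tiny count toward the null
  t_small <- tibble::tibble(a = 1, b = 9, c = 10, d = 10000)
  expect_lt(signal_stats(t_small, ic_mode = "bayes")$ic,
            signal_stats(t_small)$ic)
})
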