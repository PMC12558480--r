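test_that("generation is a pure function of the config", {
  cfg <- sim_config(n_reports = 200, n_drugs = 4, n_pts = 25,
                    duplicate_rate = 0.2, seed = 99)
  s1 <- simulate_faers(cfg)
  s2 <- simulate_faers(cfg)
  for (kind in c("demo", "drug", "reac", "ther", "outc")) {
    expect_identical(s1$bundle[[kind]], s2$bundle[[kind]], label = kind)
  }
  # and a different seed really changes the draw
  s3 <- simulate_faers(sim_config(n_reports = 200, n_drugs = 4, n_pts = 25,
                                  duplicate_rate = 0.2, seed = 100))
  expect_false(identical(s1$bundle$reac, s3$bundle$reac))
})

test_that("bundle structure honors the generative contract", {
  cfg <- sim_config(n_reports = 300, n_drugs = 6, n_pts = 40,
                    duplicate_rate = 0.1, seed = 5)
  sim <- simulate_faers(cfg)
  b <- sim$bundle
  # one DEMO row per case version; duplicates share case ids
  expect_equal(nrow(b$demo),
               300 + length(sim$truth$superseded_report_ids))
  expect_equal(dplyr::n_distinct(b$demo$case_id), 300)
  # exactly one PS drug row per report
  ps <- b$drug[b$drug$role == "PS", ]
  expect_equal(sort(unique(ps$report_id)), sort(unique(b$demo$report_id)))
  expect_equal(nrow(ps), nrow(b$demo))
  # PTs unique within a report, every report has at least one
  expect_equal(anyDuplicated(b$reac[, c("report_id", "pt")]), 0L)
  expect_true(all(b$demo$report_id %in% b$reac$report_id))
  # superseded versions are strictly older than the kept version
  sup <- b$demo[b$demo$report_id %in% sim$truth$superseded_report_ids, ]
  cur <- b$demo[match(sup$case_id, b$demo$case_id), ]
  expect_true(all(sup$receipt_date < cur$receipt_date))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(baseline_pt_weights = rep(0.5, 3), n_pts = 3),
               "sum to 1")
  expect_error(sim_config(baseline_pt_weights = c(-0.5, 1.5), n_pts = 2),
               "nonnegative")
  expect_error(sim_config(planted_signals = data.frame(drug = 1, pt = 50,
                                                       rr = 2), n_pts = 10),
               "out of range")
  expect_error(sim_config(planted_signals = data.frame(drug = 1, pt = 1,
                                                       rr = -2)),
               ">= 0")
  expect_error(sim_config(duplicate_rate = 1), "\\[0, 1\\)")
  expect_error(sim_config(missing_sex_rate = 1.3), "\\[0, 1\\]")
})

test_that("expected fourfold cells are symmetric, conserved, and ordered", {
  cfg0 <- sim_config(n_reports = 1000, n_drugs = 4, n_pts = 20, seed = 1)
  e0 <- expected_fourfold(cfg0, drug = 2, pt = 7)
  # uniform weights, no signals: expected ROR from expected cells = 1
  expect_equal((e0$a * e0$d) / (e0$b * e0$c), 1)
  expect_equal(e0$a + e0$b + e0$c + e0$d, e0$n)
  cfg5 <- sim_config(n_reports = 1000, n_drugs = 4, n_pts = 20,
                     planted_signals = data.frame(drug = 2, pt = 7, rr = 5),
                     seed = 1)
  e5 <- expected_fourfold(cfg5, drug = 2, pt = 7)
  ror_e <- (e5$a * e5$d) / (e5$b * e5$c)
  prr_e <- (e5$a / (e5$a + e5$b)) / (e5$c / (e5$c + e5$d))
  expect_gt(ror_e, prr_e)
  expect_gt(prr_e, 1)
  # conservation: cells always sum to the expected number of pairs
  expect_equal(e5$a + e5$b + e5$c + e5$d, e0$n)
  expect_error(expected_fourfold(cfg0, drug = 9, pt = 1), "out of range")
  expect_error(expected_fourfold(cfg0, drug = 1, pt = 99), "out of range")
})

test_that("realized pair tallies concentrate around the analytic expectation", {
  cfg <- sim_config(n_reports = 3000, n_drugs = 3, n_pts = 50,
                    planted_signals = data.frame(drug = 1, pt = 4, rr = 6),
                    duplicate_rate = 0, seed = 31)
  sim <- simulate_faers(cfg)
  e <- expected_fourfold(cfg, drug = 1, pt = 4)
  a_obs <- sim$truth$pair_counts$a[sim$truth$pair_counts$pt == "PT0004"]
  # within 5 sd of a Poisson-scale fluctuation
  expect_lt(abs(a_obs - e$a), 5 * sqrt(e$a))
})

test_that("a null generator yields downstream RORs centered on 1", {
  # planted rr = 1 is the exact null; the median pipeline ROR over many
  # replicates must sit within [0.9, 1.1]
  rors <- purrr::map_dbl(1:200, function(i) {
    cfg <- sim_config(n_reports = 600, n_drugs = 3, n_pts = 40,
                      planted_signals = data.frame(drug = 1, pt = 1, rr = 1),
                      events_per_report_mean = 2,
                      duplicate_rate = 0, missing_date_rate = 0, seed = 1000 + i)
    sim <- simulate_faers(cfg)
    ev <- extract_event_sets(sim$bundle)
    tab <- fourfold_from_pairs(ev$target_pairs, ev$background_pairs,
                               terms = "PT0001")
    (tab$a * tab$d) / (tab$b * tab$c)
  })
  expect_gte(median(rors, na.rm = TRUE), 0.9)
  expect_lte(median(rors, na.rm = TRUE), 1.1)
})
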