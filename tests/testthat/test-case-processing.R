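test_that("dedup keeps the most recent version of each case", {
  demo <- dplyr::bind_rows(
    mk_demo("r1", case_id = "C1", receipt = "20200101"),
    mk_demo("r2", case_id = "C1", receipt = "20210101"),
    mk_demo("r3", case_id = "C2", receipt = "20190601")
  )
  kept <- dedupe_reports(demo)
  expect_setequal(kept$report_id, c("r2", "r3"))
  # idempotent
  expect_equal(dedupe_reports(kept), kept)
})

test_that("equal receipt dates break ties toward the larger zero-padded id", {
  demo <- dplyr::bind_rows(
    mk_demo("r09", case_id = "C1", receipt = "20200101"),
    mk_demo("r10", case_id = "C1", receipt = "20200101")
  )
  expect_equal(dedupe_reports(demo)$report_id, "r10")
})

test_that("a version without a receipt date survives only when sole", {
  demo <- dplyr::bind_rows(
    mk_demo("r1", case_id = "C1", receipt = NA_character_),
    mk_demo("r2", case_id = "C1", receipt = "2005"),
    mk_demo("r3", case_id = "C2", receipt = NA_character_)
  )
  expect_setequal(dedupe_reports(demo)$report_id, c("r2", "r3"))
})

test_that("synonym matching is case-insensitive substring on name or ingredient", {
  syn <- synonym_list()
  expect_true(drug_matches("SENSIPAR 30MG TABLET", synonyms = syn))
  expect_true(drug_matches("cinacalcet hcl", synonyms = syn))
  expect_false(drug_matches("CALCITRIOL", synonyms = syn))
  expect_true(drug_matches("UNBRANDED TABLET", "CINACALCET HYDROCHLORIDE",
                           synonyms = syn))
  expect_false(drug_matches(NA_character_, NA_character_, synonyms = syn))
  expect_error(synonym_list(character()), "nonempty")
})

test_that("event-set extraction collapses within-report PTs and honors roles", {
  b <- faers_bundle(
    demo = mk_demo(c("r1", "r2")),
    drug = dplyr::bind_rows(
      mk_drug("r1", role = "PS"),
      mk_drug("r2", role = "SS")
    ),
    reac = mk_reac(c("r1", "r1", "r1", "r2"),
                   c("nausea", "Nausea ", "vomiting", "rash"))
  )
  ev <- extract_event_sets(b)
  expect_equal(nrow(ev$target_pairs), 2L) # duplicate nausea collapsed
  expect_equal(ev$background_pairs$pt, "rash") # SS-only report -> background
  # widening the role filter can only move reports into the target side
  ev_wide <- extract_event_sets(b, roles = c("PS", "SS"))
  expect_gte(nrow(ev_wide$target_pairs), nrow(ev$target_pairs))
  expect_equal(nrow(ev_wide$background_pairs), 0L)
})

test_that("extraction bookkeeping matches the generator's ground truth", {
  sim <- simulate_faers(sim_config(n_reports = 400, n_drugs = 5, n_pts = 30,
                                   duplicate_rate = 0.2, seed = 21))
  ev <- extract_event_sets(sim$bundle)
  expect_setequal(ev$target_report_ids, sim$truth$target_report_ids)
  expect_equal(nrow(ev$target_pairs), sim$truth$n_target_pairs)
  expect_equal(nrow(ev$background_pairs), sim$truth$n_background_pairs)
  # dedup removed exactly the injected superseded versions
  kept <- dedupe_reports(sim$bundle$demo)
  expect_equal(nrow(sim$bundle$demo) - nrow(kept),
               length(sim$truth$superseded_report_ids))
  expect_false(any(sim$truth$superseded_report_ids %in% kept$report_id))
})

test_that("PT-to-SOC mapping annotates pairs and isolates unmapped PTs", {
  pairs <- mk_reac(c("r1", "r1", "r2", "r3"),
                   c("nausea", "vomiting", "HYPOCALCAEMIA", "mystery pt"))
  m <- map_pt_to_soc(pairs, tiny_meddra_map())
  expect_equal(m$unmapped, "mystery pt")
  # r1's two GI PTs collapse to one (report, SOC) pair
  expect_equal(nrow(m$pairs), 2L)
  expect_setequal(m$pairs$soc[m$pairs$report_id == "r2"],
                  "Metabolism and nutrition disorders")
  # empty map: everything unmapped
  empty <- map_pt_to_soc(pairs, tibble::tibble(pt = character(),
                                               soc = character()))
  expect_equal(nrow(empty$pairs), 0L)
  expect_setequal(empty$unmapped, unique(pairs$pt))
})

test_that("SOC-level pair count equals sum of PT-level counts after per-report uniqueness", {
  # 3-report toy: r1 has two GI PTs (collapse to 1), r2 one GI, r3 one metabolic
  pairs <- mk_reac(c("r1", "r1", "r2", "r3"),
                   c("nausea", "vomiting", "nausea", "hypocalcaemia"))
  per_soc <- map_pt_to_soc(pairs, tiny_meddra_map())$pairs
  expect_equal(nrow(per_soc), 3L)
  sum_of_pts <- map_pt_to_soc(pairs, tiny_meddra_map(),
                              per_report_unique = FALSE)$pairs
  expect_equal(nrow(sum_of_pts), 4L)
})
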