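# small event set with full control over the demographic fields
demo_event_set <- function(demo, drug = mk_drug(demo$report_id),
                           reac = mk_reac(demo$report_id,
                                          rep("nausea", nrow(demo))),
                           ther = mk_ther(demo$report_id),
                           outc = faersignal:::faers_empty("outc")) {
  extract_event_sets(faers_bundle(demo, drug, reac, ther, outc))
}

test_that("sex and age summaries count each target report once", {
  demo <- dplyr::bind_rows(
    mk_demo("r1", sex = "F", age = 60),        # age 60 -> 60-74 (left-closed)
    mk_demo("r2", sex = "F", age = 5, age_unit = "DEC"), # 50 yr -> 45-59
    mk_demo("r3", sex = "M", age = NA, age_unit = "UNK")
  )
  d <- summarize_demographics(demo_event_set(demo))
  sex <- d[d$category == "sex", ]
  expect_equal(sex$count[sex$level == "F"], 2L)
  expect_equal(sex$percent[sex$level == "F"], 200 / 3, tolerance = 1e-10)
  expect_equal(sex$percent[sex$level == "M"], 100 / 3, tolerance = 1e-10)
  age <- d[d$category == "age", ]
  expect_equal(age$count[age$level == "60-74"], 1L)
  expect_equal(age$count[age$level == "45-59"], 1L)
  expect_equal(age$count[age$level == "unknown"], 1L)
  # each category exhausts the target reports and sums to 100
  sums <- tapply(d$percent, d$category, sum)
  expect_true(all(abs(sums - 100) < 0.1))
  expect_true(all(tapply(d$count, d$category, sum) == 3L))
})

test_that("outcome policies count codes versus worst case per report", {
  demo <- mk_demo(c("r1", "r2"))
  outc <- mk_outc(c("r1", "r1", "r2", "r2"), c("HO", "DE", "HO", "HO"))
  ev <- demo_event_set(demo, outc = outc)
  per_code <- summarize_outcomes(ev, outc)
  expect_equal(per_code$count[per_code$level == "hospitalization"], 2L)
  expect_equal(per_code$count[per_code$level == "death"], 1L)
  expect_equal(per_code$percent[per_code$level == "hospitalization"],
               200 / 3, tolerance = 1e-10)
  worst <- summarize_outcomes(ev, outc, policy = "worst")
  expect_equal(worst$count[worst$level == "death"], 1L)
  expect_equal(worst$count[worst$level == "hospitalization"], 1L)
  expect_equal(worst$percent, c(50, 50))
  # unknown codes fold into other serious, with a warning
  expect_warning(
    u <- summarize_outcomes(ev, mk_outc("r1", "ZZ")),
    "other serious"
  )
  expect_equal(u$level, "other serious")
})

test_that("time to onset is computed from day-precision anchors only", {
  demo <- dplyr::bind_rows(
    mk_demo("r1", event = "20200105"),
    mk_demo("r2", event = "20200401"),
    mk_demo("r3", event = "202004"),  # month precision -> unknown
    mk_demo("r4", event = "20191201") # event before start -> unknown
  )
  ther <- mk_ther(c("r1", "r2", "r3", "r4"), start = "20200101")
  ev <- demo_event_set(demo, ther = ther)
  tto <- compute_tto(ev, ther, mk_drug(demo$report_id))
  rec <- tto$records
  expect_equal(rec$days[rec$report_id == "r1"], 4)
  expect_equal(rec$bin[rec$report_id == "r1"], "<7")
  expect_equal(rec$days[rec$report_id == "r2"], 91)
  expect_equal(rec$bin[rec$report_id == "r2"], ">=60")
  expect_equal(rec$bin[rec$report_id == "r3"], "unknown")
  expect_equal(rec$bin[rec$report_id == "r4"], "unknown")
  expect_equal(tto$summary$n_negative, 1L)
  # bin counts + unknown account for every target report
  expect_equal(sum(tto$bins$count), nrow(rec))
})

test_that("onset quartiles use linear interpolation", {
  demo <- dplyr::bind_rows(
    mk_demo("r1", event = "20200103"), # 2 days
    mk_demo("r2", event = "20200109"), # 8 days
    mk_demo("r3", event = "20200321")  # 80 days
  )
  ther <- mk_ther(demo$report_id, start = "20200101")
  ev <- demo_event_set(demo, ther = ther)
  tto <- compute_tto(ev, ther, mk_drug(demo$report_id))
  expect_equal(tto$summary$median, 8)
  expect_equal(tto$summary$q1, 5)
  expect_equal(tto$summary$q3, 44)
  expect_equal(tto$bins$count[tto$bins$bin == "<7"], 1L)
  expect_equal(tto$bins$count[tto$bins$bin == "7-28"], 1L)
  expect_equal(tto$bins$count[tto$bins$bin == ">=60"], 1L)
})

test_that("annual counts key on the receipt year", {
  demo <- dplyr::bind_rows(
    mk_demo("r1", receipt = "20170301"),
    mk_demo("r2", receipt = "2017"),
    mk_demo("r3", receipt = "20180601")
  )
  counts <- annual_counts(demo_event_set(demo))
  expect_equal(counts$count[counts$year == 2017], 2L)
  expect_equal(counts$count[counts$year == 2018], 1L)
  # matches generator tallies on a synthetic bundle
  sim <- simulate_faers(sim_config(n_reports = 150, seed = 44))
  ev <- extract_event_sets(sim$bundle)
  counts2 <- annual_counts(ev)
  expect_equal(sum(counts2$count), length(sim$truth$target_report_ids))
})
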