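# hand-built record constructors: only the fields a test cares about vary
mk_demo <- function(report_id, case_id = report_id, receipt = "20200601",
                    event = NA_character_, sex = "F", age = 50,
                    age_unit = "YR", reporter = "consumer", country = "US") {
  tibble::tibble(
    report_id = report_id, case_id = case_id,
    receipt_date = receipt, event_date = event,
    sex = sex, age_value = age, age_unit = age_unit,
    reporter = reporter, country = country
  )
}

mk_drug <- function(report_id, drugname = "CINACALCET", role = "PS",
                    drug_seq = 1L, active_ingredient = NA_character_) {
  tibble::tibble(
    report_id = report_id, drug_seq = as.integer(drug_seq), role = role,
    drugname = drugname, active_ingredient = active_ingredient
  )
}

mk_reac <- function(report_id, pt) {
  tibble::tibble(report_id = report_id, pt = pt)
}

mk_ther <- function(report_id, start = "20200101", end = NA_character_,
                    drug_seq = 1L) {
  tibble::tibble(report_id = report_id, drug_seq = as.integer(drug_seq),
                 start_date = start, end_date = end)
}

mk_outc <- function(report_id, outcome) {
  tibble::tibble(report_id = report_id, outcome = outcome)
}

# three target reports + two background reports, no duplicate versions
toy_bundle <- function() {
  faers_bundle(
    demo = mk_demo(c("r1", "r2", "r3", "r4", "r5")),
    drug = dplyr::bind_rows(
      mk_drug(c("r1", "r2", "r3")),
      mk_drug(c("r4", "r5"), drugname = "CALCITRIOL")
    ),
    reac = mk_reac(
      c("r1", "r1", "r2", "r3", "r4", "r5"),
      c("nausea", "vomiting", "nausea", "hypocalcaemia", "nausea", "rash")
    ),
    ther = mk_ther(c("r1", "r2", "r3", "r4", "r5")),
    outc = mk_outc(c("r1", "r2"), c("HO", "DE"))
  )
}

tiny_meddra_map <- function() {
  tibble::tibble(
    pt = c("nausea", "vomiting", "hypocalcaemia", "rash"),
    soc = c("Gastrointestinal disorders", "Gastrointestinal disorders",
            "Metabolism and nutrition disorders",
            "Skin and subcutaneous tissue disorders")
  )
}

# uniformly-weighted random positive fourfold tables for property tests
random_tables <- function(n, seed) {
  withr::with_seed(seed, tibble::tibble(
    a = sample(1:500, n, replace = TRUE),
    b = sample(1:5000, n, replace = TRUE),
    c = sample(1:5000, n, replace = TRUE),
    d = sample(1:100000, n, replace = TRUE)
  ))
}
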