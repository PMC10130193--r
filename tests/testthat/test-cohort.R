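make_db <- function(drug_rows, demo_ids = NULL) {
  ids <- demo_ids %||% unique(drug_rows$case_id)
  link_tables(
    parse_jader_table(tibble::tibble(case_id = ids, sex = "male",
                                     age_category = "60s"), "demo"),
    parse_jader_table(drug_rows, "drug"),
    parse_jader_table(tibble::tibble(case_id = character(), pt_code = character(),
                                     pt_name = character(), onset_date = character()), "reac"),
    parse_jader_table(tibble::tibble(case_id = character(), pt_code = character(),
                                     pt_name = character()), "hist")
  )
}

drug_row <- function(case_id, drug_name, route = "oral",
                     involvement = "suspected") {
  tibble::tibble(case_id = case_id, drug_name = drug_name,
                 involvement = involvement, route = route,
                 start_date = "2020-01-01")
}

test_that("oral exposure honours route, pools involvement, maps synonyms", {
  db <- make_db(dplyr::bind_rows(
    drug_row("A", "aspirin", involvement = "concomitant"),
    drug_row("B", "aspirin", route = "intravenous"),
    drug_row("C", "Clopidogrel Sulfate"),
    drug_row("D", "warfarin potassium", involvement = "interaction")
  ))
  expo <- oral_exposures(db)
  expect_equal(expo$case_id[expo$drug == "aspirin"], "A")
  expect_equal(expo$drug[expo$case_id == "C"], "clopidogrel")
  expect_equal(expo$drug[expo$case_id == "D"], "warfarin")
  expect_false("B" %in% expo$case_id)
})

test_that("therapy classification assigns mono, the seven combination groups, and other", {
  sets <- list(
    A = "aspirin",
    B = c("aspirin", "clopidogrel"),
    C = c("aspirin", "warfarin"),
    D = c("aspirin", "apixaban"),
    E = c("clopidogrel", "warfarin"),
    F = c("ticagrelor", "rivaroxaban"),
    G = c("aspirin", "clopidogrel", "warfarin"),
    H = c("aspirin", "prasugrel", "edoxaban"),
    I = c("warfarin", "apixaban"),          # no such analyzed pair
    J = c("clopidogrel", "prasugrel"),      # two drugs, one class
    K = character(0)
  )
  rows <- purrr::imap(sets, function(d, id) {
    if (length(d) == 0) NULL else drug_row(id, d)
  }) |> purrr::list_rbind()
  db <- make_db(rows, demo_ids = names(sets))
  assign <- classify_therapy(oral_exposures(db), db$demo$case_id)
  got <- setNames(assign$therapy, assign$case_id)[names(sets)]
  expect_equal(unname(got), c(
    "mono:aspirin",
    "dual:aspirin+P2Y12", "dual:aspirin+warfarin", "dual:aspirin+DOAC",
    "dual:P2Y12+warfarin", "dual:P2Y12+DOAC",
    "triple:aspirin+P2Y12+warfarin", "triple:aspirin+P2Y12+DOAC",
    "other-combination", "other-combination", "unexposed"
  ))
  # every case gets exactly one category
  expect_equal(nrow(assign), length(sets))
})

test_that("classification is invariant to drug-record order", {
  rows <- dplyr::bind_rows(drug_row("A", "warfarin"), drug_row("A", "aspirin"),
                           drug_row("A", "clopidogrel"))
  db1 <- make_db(rows)
  db2 <- make_db(rows[3:1, ])
  a1 <- classify_therapy(oral_exposures(db1), "A")
  a2 <- classify_therapy(oral_exposures(db2), "A")
  expect_equal(a1$therapy, a2$therapy)
})

test_that("event flagging is patient-level and monotone in the PT set", {
  db <- toy_db()
  ev <- flag_event(db, ioh_pts())
  # T1 has two matching PTs but counts once; T3 has one; others none
  expect_equal(ev$event, c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(sum(ev$event), 2)

  smaller <- flag_event(db, 10038867)
  expect_true(sum(smaller$event) <= sum(ev$event))
  larger <- flag_event(db, c(ioh_pts()$pt_code, 90000001L))
  expect_true(sum(larger$event) >= sum(ev$event))
})

test_that("comorbidity flags come from the history table SMQ sets", {
  db <- toy_db()
  ht <- flag_comorbidity(db, hypertension_smq())
  expect_equal(ht$case_id[ht$comorbidity], "T2")
  dm <- flag_comorbidity(db, diabetes_smq())
  expect_false(any(dm$comorbidity))
})

test_that("injection-drug flag restricts triamcinolone to ocular routes", {
  db <- make_db(dplyr::bind_rows(
    drug_row("A", "ranibizumab", route = "intravenous"),
    drug_row("B", "triamcinolone acetonide", route = "oral"),
    drug_row("C", "triamcinolone acetonide", route = "intravitreal injections"),
    drug_row("D", "aspirin")
  ))
  inj <- flag_injection_drugs(db)
  got <- setNames(inj$injection, inj$case_id)
  expect_true(got[["A"]])    # anti-VEGF agents count regardless of route
  expect_false(got[["B"]])   # oral triamcinolone does not
  expect_true(got[["C"]])
  expect_false(got[["D"]])
})

test_that("age groups split at the 60s/70s boundary and partition all cases", {
  db <- toy_db()
  ag <- assign_age_groups(db)
  got <- setNames(ag$age_group, db$demo$age_category)
  expect_equal(unname(got[c("60s", "70s", "40s", "90s")]),
               c("younger", "elderly", "younger", "elderly"))
  expect_equal(sum(ag$age_group == "younger") + sum(ag$age_group == "elderly"),
               nrow(db$demo))
})

test_that("cohort counts match the generator's ground truth", {
  sim <- generate_database(sim_config(seed = 202, n_cases = 3000,
                                      p_blank_sex = 0, p_blank_age = 0,
                                      p_duplicate = 0))
  db <- as_jader_db(sim$tables)
  cohort <- build_cohort(db)
  truth <- sim$truth$latent

  expect_equal(nrow(cohort), nrow(truth))
  expect_equal(sum(cohort$event), sum(truth$event))
  expect_equal(sum(cohort$hypertension), sum(truth$hypertension))
  expect_equal(sum(cohort$diabetes), sum(truth$diabetes))
  expect_equal(sum(cohort$injection), sum(truth$injection))

  got_therapy <- setNames(cohort$therapy, cohort$case_id)
  expect_equal(unname(got_therapy[truth$case_id]), truth$therapy)

  # per-drug exposure counts equal the planted truth
  truth_counts <- table(unlist(truth$drugs))
  got_counts <- table(unlist(cohort$drugs))
  expect_equal(as.vector(got_counts[names(truth_counts)]),
               as.vector(truth_counts))
})
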