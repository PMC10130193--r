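tto_db <- function(drug_rows, reac_rows) {
  ids <- unique(c(drug_rows$case_id, reac_rows$case_id))
  link_tables(
    parse_jader_table(tibble::tibble(case_id = ids, sex = "male",
                                     age_category = "60s"), "demo"),
    parse_jader_table(drug_rows, "drug"),
    parse_jader_table(reac_rows, "reac"),
    parse_jader_table(tibble::tibble(case_id = character(), pt_code = character(),
                                     pt_name = character()), "hist")
  )
}

aspirin_row <- function(case_id, start_date) {
  tibble::tibble(case_id = case_id, drug_name = "aspirin",
                 involvement = "suspected", route = "oral",
                 start_date = start_date)
}

ioh_row <- function(case_id, onset_date) {
  tibble::tibble(case_id = case_id, pt_code = "10038867",
                 pt_name = "Retinal haemorrhage", onset_date = onset_date)
}

test_that("onset periods use the day-one convention, cap, and exclusion rules", {
  db <- tto_db(
    dplyr::bind_rows(
      aspirin_row("SAME", "2020-01-01"),
      aspirin_row("CAP", "2020-01-01"),
      aspirin_row("BEFORE", "2020-01-01"),
      aspirin_row("PARTIAL", "202001"),
      aspirin_row("TWOSTART", "2020-06-01"),
      aspirin_row("TWOSTART", "2020-01-01")
    ),
    dplyr::bind_rows(
      ioh_row("SAME", "2020-01-01"),       # same day -> period 1
      ioh_row("CAP", "2022-06-01"),        # raw 883 -> capped at 720
      ioh_row("BEFORE", "2019-12-31"),     # onset precedes start -> excluded
      ioh_row("PARTIAL", "2020-03-01"),    # partial start date -> excluded
      ioh_row("TWOSTART", "2020-01-10")    # earliest start is used
    )
  )
  out <- compute_onset_periods(db, "aspirin")
  got <- setNames(out$period_days, out$case_id)
  expect_equal(unname(got[["SAME"]]), 1)
  expect_equal(unname(got[["CAP"]]), 720)
  expect_true(out$capped[out$case_id == "CAP"])
  expect_false("BEFORE" %in% out$case_id)
  expect_false("PARTIAL" %in% out$case_id)
  expect_equal(unname(got[["TWOSTART"]]), 10)

  # raw 883 days: 2020-01-01 to 2022-06-01 inclusive day count
  expect_equal(as.integer(as.Date("2022-06-01") - as.Date("2020-01-01")) + 1, 883)
})

test_that("capping never changes bin membership below the horizon", {
  rec <- tibble::tibble(case_id = as.character(1:4), drug = "x",
                        period_days = c(360, 361, 719, 720),
                        capped = c(FALSE, FALSE, FALSE, TRUE))
  s <- summarize_tto(rec, min_cases = 3)
  expect_equal(s$d361_plus, 3L)
  expect_equal(s$d181_360, 1L)
})

test_that("the hand-computed bin distribution and median reproduce", {
  periods <- c(1, 2, 3, 7, 8, 30, 31, 90, 91, 360, 361)
  rec <- tibble::tibble(case_id = as.character(seq_along(periods)),
                        drug = "aspirin", period_days = periods,
                        capped = FALSE)
  s <- summarize_tto(rec)
  expect_true(s$eligible)           # 11 > 10
  expect_equal(s$median_days, 30)
  expect_equal(unlist(s[, c("d1_2", "d3_7", "d8_30", "d31_60", "d61_90",
                            "d91_180", "d181_360", "d361_plus")],
                      use.names = FALSE),
               c(2L, 2L, 2L, 1L, 1L, 1L, 1L, 1L))
  expect_equal(sum(s[, c("d1_2", "d3_7", "d8_30", "d31_60", "d61_90",
                         "d91_180", "d181_360", "d361_plus")]), s$n_cases)
})

test_that("eligibility is strict: exactly 10 cases are not enough", {
  rec <- tibble::tibble(case_id = as.character(1:10), drug = "x",
                        period_days = 1:10, capped = FALSE)
  expect_false(summarize_tto(rec)$eligible)
  rec11 <- dplyr::bind_rows(rec, tibble::tibble(case_id = "11", drug = "x",
                                                period_days = 11, capped = FALSE))
  expect_true(summarize_tto(rec11)$eligible)
})

test_that("degenerate and order-invariance properties of the summary hold", {
  rec <- tibble::tibble(case_id = as.character(1:12), drug = "x",
                        period_days = rep(40, 12), capped = FALSE)
  s <- summarize_tto(rec)
  expect_equal(c(s$q1, s$median_days, s$q3), c(40, 40, 40))

  set.seed(5)
  rec2 <- tibble::tibble(case_id = as.character(1:15), drug = "x",
                         period_days = sample(1:700, 15), capped = FALSE)
  s1 <- summarize_tto(rec2)
  s2 <- summarize_tto(rec2[sample(nrow(rec2)), ])
  expect_equal(s1, s2)

  # appending a record at the current median leaves the median unchanged
  med <- s1$median_days
  rec3 <- dplyr::bind_rows(rec2, tibble::tibble(case_id = "16", drug = "x",
                                                period_days = med, capped = FALSE))
  expect_equal(summarize_tto(rec3)$median_days, med)
})

test_that("the empirical median of simulated onset times tracks the true median", {
  set.seed(404)
  shape <- 0.9; scale <- 120
  true_med <- qweibull(0.5, shape, scale)
  n <- 500
  periods <- pmin(pmax(1, ceiling(rweibull(n, shape, scale))), 720)
  rec <- tibble::tibble(case_id = as.character(1:n), drug = "x",
                        period_days = periods, capped = FALSE)
  s <- summarize_tto(rec)
  # 99% order-statistic band for the sample median of n = 500 draws
  lo <- qweibull(qbeta(0.005, 250, 251), shape, scale)
  hi <- qweibull(qbeta(0.995, 251, 250), shape, scale)
  expect_gte(s$median_days, floor(lo))
  expect_lte(s$median_days, ceiling(hi) + 1)
  expect_lt(abs(s$median_days - true_med) / true_med, 0.25)
})
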