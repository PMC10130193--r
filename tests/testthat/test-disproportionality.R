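test_that("contingency cells rebuild from margins and validate consistency", {
  cells <- contingency_from_margins(61, 19200, 1586, 688467)
  expect_equal(cells$n10, 19139)
  expect_equal(cells$n01, 1525)
  expect_equal(cells$n00, 667742)
  expect_equal(with(cells, n11 + n10 + n01 + n00), 688467)
  expect_error(contingency_from_margins(50, 40, 100, 1000), "negative")
})

test_that("contingency counting over a cohort is patient-level", {
  cohort <- build_cohort(toy_db())
  # 2 aspirin-mono cases (1 with the event), 4 unexposed (1 with the event)
  tab <- build_contingency(cohort, "mono:aspirin")
  expect_equal(as.numeric(tab), c(1, 1, 1, 3))

  absent <- build_contingency(cohort, "mono:warfarin")
  expect_equal(absent$n11 + absent$n10, 0)

  expect_error(build_contingency(cohort, "mono:aspirin", universe = character(0)),
               "empty universe")
})

test_that("ROR is the cross-product ratio with a log-scale Wald interval", {
  r <- ror_ci(1, 1, 1, 1)
  expect_equal(r$ror, 1)
  # CI symmetric about 1 on the log scale
  expect_equal(r$ror_low * r$ror_high, 1, tolerance = 1e-12)

  # any zero cell leaves the ROR undefined, not corrected
  expect_true(all(is.na(ror_ci(0, 39, 1586, 686842))))
  expect_true(all(is.na(ror_ci(5, 0, 10, 100))))
})

test_that("swapping exposure rows inverts the ROR and reflects its interval", {
  set.seed(11)
  for (i in 1:50) {
    n <- 1 + rpois(4, c(20, 500, 100, 5000))
    a <- ror_ci(n[1], n[2], n[3], n[4])
    b <- ror_ci(n[3], n[4], n[1], n[2])
    expect_equal(b$ror, 1 / a$ror, tolerance = 1e-12)
    expect_equal(b$ror_low, 1 / a$ror_high, tolerance = 1e-12)
    expect_equal(b$ror_high, 1 / a$ror_low, tolerance = 1e-12)
  }
})

test_that("the information component shrinks towards zero and is defined at N11 = 0", {
  # independence-structured table: IC near 0
  ind <- ic_ci(1, 100, 100, 10000)
  expect_lt(abs(ind$ic), 0.05)

  # zero observed count: strictly negative IC, interval still defined
  z <- ic_ci(0, 39, 1586, 688467)
  expect_lt(z$ic, 0)
  expect_true(is.finite(z$ic_low) && is.finite(z$ic_high))

  # adding an event (N11+1, N+1+1) strictly increases the IC
  set.seed(21)
  for (i in 1:50) {
    npp <- 10000; n1p <- 50 + rpois(1, 200); np1 <- 50 + rpois(1, 200)
    n11 <- rpois(1, 5)
    expect_gt(ic_ci(n11 + 1, n1p, np1 + 1, npp + 1)$ic,
              ic_ci(n11, n1p, np1, npp)$ic)
  }
})

test_that("IC converges to the unshrunk log2 observed/expected in large tables", {
  base <- c(n11 = 30, n1p = 1000, np1 = 500, npp = 100000)
  target <- log2(base["n11"] * base["npp"] / (base["n1p"] * base["np1"]))
  err <- sapply(c(1, 10, 100, 1000), function(k) {
    abs(ic_ci(base["n11"] * k, base["n1p"] * k, base["np1"] * k,
              base["npp"] * k)$ic - target)
  })
  expect_true(all(diff(err) < 0))
  expect_lt(err[4], 1e-3)
})

test_that("ic_ci matches an independently transcribed BCPNN formula to 1e-12", {
  set.seed(31)
  for (i in 1:1000) {
    npp <- sample(1000:1e6, 1)
    n1p <- sample(1:(npp %/% 4), 1)
    np1 <- sample(1:(npp %/% 4), 1)
    n11 <- sample(0:min(n1p, np1), 1)
    got <- ic_ci(n11, n1p, np1, npp)
    want <- ic_oracle(n11, n1p, np1, npp)
    expect_equal(got$ic, unname(want["e_ic"]), tolerance = 1e-12)
    expect_equal(got$ic_var, unname(want["v_ic"]), tolerance = 1e-12)
  }
})

test_that("the dual criterion requires both lower limits to clear their bounds", {
  expect_true(signal_flag(1.08, 0.08))     # both criteria met
  expect_false(signal_flag(1.31, -0.57))   # ROR clears 1 but IC interval spans 0
  expect_false(signal_flag(0.86, 0.2))     # ROR interval includes 1
  expect_false(signal_flag(NA, 2))         # undefined ROR can never signal
})

test_that("an unprinted event margin is recoverable by grid search", {
  # build rows from a known margin, then recover it exactly
  true_np1 <- 1700
  npp <- 500000
  n1p <- c(12000, 5000, 2500, 900, 7000, 300, 15000, 620)
  n11 <- c(120, 80, 45, 20, 150, 12, 60, 25)
  cells <- contingency_from_margins(n11, n1p, true_np1, npp)
  printed <- round_half_up(with(cells, n11 * n00 / (n10 * n01)), 2)
  rows <- tibble::tibble(n11 = n11, n1p = n1p, ror = printed)
  expect_equal(infer_event_margin(rows, npp, range = c(1000, 3000)), true_np1)

  # contradictory rows cannot be calibrated
  bad <- tibble::tibble(n11 = c(10, 10), n1p = c(1000, 1000), ror = c(0.10, 99))
  expect_error(infer_event_margin(bad, npp, range = c(1000, 3000)),
               "calibration failure")
  expect_error(infer_event_margin(rows[1, ], npp), "at least two rows")
})

test_that("batch signal tables have one row per category and stratum", {
  sim <- generate_database(sim_config(seed = 303, n_cases = 4000))
  cohort <- build_cohort(as_jader_db(sim$tables))

  flat <- run_signal_table(cohort)
  expect_true(all(!duplicated(flat$category)))
  expect_true(all(c("total_aes", "events", "ror", "ic", "signal") %in% names(flat)))

  strat <- run_signal_table(cohort, strata = TRUE)
  expect_equal(nrow(strat), 2 * nrow(flat))
  # stratum cells partition the whole-cohort cells
  merged <- strat |>
    dplyr::group_by(category) |>
    dplyr::summarise(events = sum(events), total_aes = sum(total_aes))
  flat_m <- flat[match(merged$category, flat$category), ]
  expect_equal(merged$events, flat_m$events)
  expect_equal(merged$total_aes, flat_m$total_aes)
})

test_that("a planted reporting-rate multiplier is flagged while null drugs mostly are not", {
  drugs <- default_drug_table() |>
    dplyr::mutate(log_or = ifelse(drug == "rivaroxaban", log(8), 0),
                  prevalence = pmax(prevalence, 0.005))
  cfg <- sim_config(seed = 404, n_cases = 120000, drugs = drugs,
                    p_blank_sex = 0, p_blank_age = 0, p_duplicate = 0)
  cohort <- build_cohort(as_jader_db(generate_database(cfg)$tables))
  st <- run_signal_table(cohort)
  expect_true(st$signal[st$category == "mono:rivaroxaban"])
  null_mono <- st[startsWith(st$category, "mono:") &
                    st$category != "mono:rivaroxaban", ]
  expect_lte(sum(null_mono$signal), 1)
})

test_that("the signal forest plot builds", {
  sim <- generate_database(sim_config(seed = 99, n_cases = 3000))
  cohort <- build_cohort(as_jader_db(sim$tables))
  p <- plot_signals(run_signal_table(cohort))
  expect_s3_class(p, "ggplot")
})
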