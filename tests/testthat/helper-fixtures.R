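# hand-built six-case database: two cases on aspirin monotherapy (one with
# an intraocular-hemorrhage PT), four unexposed (one with an event)
toy_tables <- function() {
  list(
    demo = tibble::tibble(
      case_id = paste0("T", 1:6),
      sex = c("male", "female", "male", "female", "male", "female"),
      age_category = c("60s", "70s", "50s", "80s", "40s", "90s")
    ),
    drug = tibble::tibble(
      case_id = c("T1", "T2"),
      drug_name = "aspirin",
      involvement = c("suspected", "concomitant"),
      route = "oral",
      start_date = c("2020-01-01", "2020-02-01")
    ),
    reac = tibble::tibble(
      case_id = c("T1", "T3", "T1"),
      pt_code = c("10038867", "10047655", "90000001"),
      pt_name = c("Retinal haemorrhage", "Vitreous haemorrhage", "Background AE"),
      onset_date = c("2020-03-01", "2020-04-01", "2020-03-05")
    ),
    hist = tibble::tibble(
      case_id = "T2",
      pt_code = "10020772",
      pt_name = "Hypertension"
    )
  )
}

toy_db <- function() {
  t <- toy_tables()
  link_tables(
    parse_jader_table(t$demo, "demo"),
    parse_jader_table(t$drug, "drug"),
    parse_jader_table(t$reac, "reac"),
    parse_jader_table(t$hist, "hist")
  )
}

# independently transcribed BCPNN information-component formulas (Bate et
# al. 1998 parameterization), written as plain scalar arithmetic so it
# shares no code path with ic_ci(); used as the oracle in equivalence tests
ic_oracle <- function(n11, n1p, np1, npp) {
  g1 <- 1; a1 <- 1; b1 <- 1; a <- 2; b <- 2
  g <- g1 * ((npp + a) * (npp + b)) / ((n1p + a1) * (np1 + b1))
  num <- (n11 + g1) * (npp + a) * (npp + b)
  den <- (npp + g) * (n1p + a1) * (np1 + b1)
  e_ic <- log(num / den) / log(2)
  v1 <- (npp - n11 + g - g1) / ((n11 + g1) * (1 + npp + g))
  v2 <- (npp - n1p + a - a1) / ((n1p + a1) * (1 + npp + a))
  v3 <- (npp - np1 + b - b1) / ((np1 + b1) * (1 + npp + b))
  v_ic <- (v1 + v2 + v3) / (log(2)^2)
  c(e_ic = e_ic, v_ic = v_ic)
}

# published monotherapy signal-table rows (exposed-case margin, event
# count, and the printed statistics) used as calibration inputs
published_mono_rows <- function() {
  tibble::tribble(
    ~drug,          ~n1p,  ~n11, ~ror, ~ror_low, ~ror_high, ~ic,   ~ic_low, ~ic_high,
    "aspirin",      19200, 61,   1.40, 1.08,     1.80,      0.45,  0.08,    0.83,
    "clopidogrel",  5260,  38,   3.20, 2.32,     4.43,      1.57,  1.10,    2.04,
    "ticagrelor",   39,    0,    NA,   NA,       NA,        -0.13, -3.05,   2.79,
    "ticlopidine",  2018,  8,    1.73, 0.86,     3.47,      0.67,  -0.30,   1.64,
    "prasugrel",    166,   2,    5.29, 1.31,     21.34,     1.12,  -0.57,   2.80,
    "warfarin",     11229, 41,   1.60, 1.17,     2.19,      0.64,  0.19,    1.10,
    "apixaban",     6040,  64,   4.79, 3.73,     6.16,      2.12,  1.76,    2.49,
    "dabigatran",   2864,  10,   1.52, 0.82,     2.84,      0.53,  -0.34,   1.41,
    "edoxaban",     3255,  10,   1.34, 0.72,     2.49,      0.37,  -0.50,   1.25,
    "rivaroxaban",  5288,  100,  8.84, 7.21,     10.85,     2.94,  2.64,    3.24
  )
}

published_combo_rows <- function() {
  tibble::tribble(
    ~category,                        ~n1p, ~n11, ~ror, ~ror_low, ~ror_high, ~ic,  ~ic_low, ~ic_high,
    "dual:aspirin+P2Y12",             7582, 60,   3.55, 2.74,     4.60,      1.72, 1.34,    2.10,
    "dual:aspirin+warfarin",          3538, 25,   3.12, 2.10,     4.63,      1.51, 0.93,    2.08,
    "dual:aspirin+DOAC",              1690, 14,   3.64, 2.15,     6.18,      1.61, 0.86,    2.37,
    "dual:P2Y12+warfarin",            1333, 12,   3.96, 2.24,     7.00,      1.67, 0.87,    2.48,
    "dual:P2Y12+DOAC",                1144, 6,    2.29, 1.02,     5.11,      0.94, -0.15,   2.04,
    "triple:aspirin+P2Y12+warfarin",  717,  10,   6.16, 3.29,     11.52,     2.05, 1.17,    2.93,
    "triple:aspirin+P2Y12+DOAC",      417,  2,    2.09, 0.52,     8.39,      0.61, -1.06,   2.28
  )
}

PUBLISHED_NPP <- 688467
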