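#' Default drug table for the simulator
#'
#' The ten target antithrombotics with their class, marginal exposure
#' prevalence, planted log reporting-rate multiplier (log odds ratio on
#' the event model) and the Weibull onset-time distribution (days). The
#' prevalences are the published per-drug exposure fractions of a
#' cleaned nationwide spontaneous-report database, and the planted log
#' odds ratios mirror the published monotherapy signal pattern, so the
#' default configuration emulates the reporting structure of the real
#' study population at a configurable scale.
#'
#' @return tibble with columns `drug`, `class`, `prevalence`, `log_or`,
#'   `weibull_shape`, `weibull_scale`.
#' @export
default_drug_table <- function() {
  tibble(
    drug = c("aspirin", "clopidogrel", "ticagrelor", "ticlopidine",
             "prasugrel", "warfarin", "apixaban", "dabigatran",
             "edoxaban", "rivaroxaban"),
    class = c("aspirin", rep("P2Y12", 4), "warfarin", rep("DOAC", 4)),
    prevalence = c(0.0279, 0.0076, 0.0001, 0.0029, 0.0005,
                   0.0163, 0.0088, 0.0042, 0.0047, 0.0077),
    log_or = log(c(1.40, 3.20, 1.00, 1.73, 5.29,
                   1.60, 4.79, 1.52, 1.34, 8.84)),
    weibull_shape = 0.9,
    weibull_scale = 120
  )
}

#' Simulation configuration for a synthetic four-table database
#'
#' Defines everything the generator needs: cohort size, demographic
#' distribution, per-drug exposure prevalences with an aspirin
#' co-prescription odds multiplier, the event model (baseline log-odds of
#' the event plus per-drug and covariate log odds ratios), covariate
#' prevalences, background adverse-event vocabulary, onset-time
#' distributions, missingness and duplicate-injection rates, and the
#' mandatory seed. The defaults emulate a JADER-like population with the
#' published exposure margins and signal pattern (see
#' [default_drug_table()]); the baseline event probability is the
#' event-reporting fraction of the cleaned database (1586/688467).
#'
#' @param seed integer seed; required, the generator is fully
#'   deterministic given the config.
#' @param n_cases number of cases.
#' @param drugs drug table, see [default_drug_table()].
#' @param co_rx_or odds multiplier on each non-aspirin drug's exposure
#'   for aspirin-exposed cases (co-prescription structure).
#' @param baseline_logit baseline log-odds of the event.
#' @param covariate_prev named probabilities for `hypertension`,
#'   `diabetes`, `injection`.
#' @param covariate_log_or named log odds ratios of the covariates on the
#'   event.
#' @param combo_log_or optional named extra log odds ratio per therapy
#'   category (added on top of the per-drug effects).
#' @param n_background_pts size of the background (non-event) PT
#'   vocabulary; codes are synthetic and disjoint from the event PT set.
#' @param ae_lambda mean extra background AEs per case (count is
#'   1 + Poisson).
#' @param sex_prob,age_prob demographic sampling distributions.
#' @param p_blank_sex,p_blank_age probability a demo field is blanked.
#' @param p_partial_date probability a date is degraded to year-month
#'   precision.
#' @param p_duplicate fraction of exact duplicate records injected into
#'   each of the drug/reac/hist tables.
#' @return a `sim_config` list, validated.
#' @export
sim_config <- function(seed,
                       n_cases = 20000,
                       drugs = default_drug_table(),
                       co_rx_or = 2,
                       baseline_logit = qlogis(1586 / 688467),
                       covariate_prev = c(hypertension = 0.15, diabetes = 0.10,
                                          injection = 0.002),
                       covariate_log_or = c(hypertension = 0, diabetes = 0,
                                            injection = log(30)),
                       combo_log_or = numeric(0),
                       n_background_pts = 100,
                       ae_lambda = 1,
                       sex_prob = c(male = 0.55, female = 0.45),
                       age_prob = NULL,
                       p_blank_sex = 0.03, p_blank_age = 0.03,
                       p_partial_date = 0.05,
                       p_duplicate = 0.01) {
  if (missing(seed)) abort("sim_config: seed is mandatory")
  if (is.null(age_prob)) {
    # unimodal age distribution peaking in the 70s, as in a real
    # spontaneous-report population
    age_prob <- setNames(c(3, 2, 3, 5, 8, 10, 14, 20, 20, 12, 3) / 100, AGE_BANDS)
  }
  probs <- c(drugs$prevalence, covariate_prev, p_blank_sex, p_blank_age,
             p_partial_date, p_duplicate, sex_prob, age_prob)
  if (any(probs < 0 | probs > 1)) abort("sim_config: probabilities must be in [0, 1]")
  max_prev <- max(plogis(qlogis(pmax(drugs$prevalence, 1e-12)) + abs(log(co_rx_or))))
  if (max_prev > 1) abort("sim_config: infeasible prevalence after co-prescription multiplier")
  stopifnot(all(c("hypertension", "diabetes", "injection") %in% names(covariate_prev)),
            all(c("hypertension", "diabetes", "injection") %in% names(covariate_log_or)))
  structure(list(seed = as.integer(seed), n_cases = as.integer(n_cases),
                 drugs = drugs, co_rx_or = co_rx_or,
                 baseline_logit = baseline_logit,
                 covariate_prev = covariate_prev,
                 covariate_log_or = covariate_log_or,
                 combo_log_or = combo_log_or,
                 n_background_pts = as.integer(n_background_pts),
                 ae_lambda = ae_lambda,
                 sex_prob = sex_prob, age_prob = age_prob,
                 p_blank_sex = p_blank_sex, p_blank_age = p_blank_age,
                 p_partial_date = p_partial_date,
                 p_duplicate = p_duplicate),
            class = "sim_config")
}

# therapy category from a logical exposure matrix, by the same class
# rules the pipeline applies
therapy_from_exposures <- function(expo, drugs) {
  class_of <- setNames(drugs$class, drugs$drug)
  n_exposed <- rowSums(expo)
  out <- rep("unexposed", nrow(expo))
  mono <- which(n_exposed == 1)
  if (length(mono) > 0) {
    out[mono] <- paste0("mono:", colnames(expo)[max.col(expo[mono, , drop = FALSE])])
  }
  multi <- which(n_exposed > 1)
  out[multi] <- vapply(multi, function(i) {
    key <- paste(sort(unique(class_of[colnames(expo)[expo[i, ]]])), collapse = "|")
    if (key %in% names(COMBINATION_GROUPS)) unname(COMBINATION_GROUPS[key])
    else "other-combination"
  }, character(1))
  out
}

#' Generate a synthetic four-table database with known ground truth
#'
#' Samples a complete spontaneous-report database in the four-table
#' layout under the configured model: demographics from the configured
#' band distributions; per-drug Bernoulli exposures with aspirin
#' co-prescription; the event as a per-case Bernoulli whose log-odds is
#' baseline plus the sum of exposed-drug, therapy-category and covariate
#' effects; event PTs drawn uniformly from the 17-code event set on top
#' of a disjoint background AE vocabulary; comorbidity history PTs for
#' the hypertension/diabetes flags; ocular-injection drug records for
#' injection users; drug start and event onset dates consistent with the
#' per-drug Weibull onset distribution; and finally blanked demo fields,
#' partially-precise dates and exact duplicate records injected at the
#' configured rates — all logged in the ground truth, which is
#' sufficient to recompute every pipeline count exactly.
#'
#' @param cfg a [sim_config()].
#' @return list with `tables` (demo/drug/reac/hist as raw character
#'   tibbles in the CSV dialect) and `truth` (list: `latent` per-case
#'   tibble pre-missingness, `injected` counts, `config`).
#' @export
generate_database <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_cases
  drugs <- cfg$drugs
  nd <- nrow(drugs)
  case_id <- sprintf("C%07d", seq_len(n))

  sex <- sample(names(cfg$sex_prob), n, replace = TRUE, prob = cfg$sex_prob)
  age <- sample(names(cfg$age_prob), n, replace = TRUE, prob = cfg$age_prob)

  # exposures: aspirin first, then co-prescription-adjusted Bernoullis
  expo <- matrix(FALSE, n, nd, dimnames = list(NULL, drugs$drug))
  asp_idx <- match("aspirin", drugs$drug)
  if (!is.na(asp_idx)) {
    expo[, asp_idx] <- runif(n) < drugs$prevalence[asp_idx]
  }
  for (j in seq_len(nd)) {
    if (!is.na(asp_idx) && j == asp_idx) next
    lp <- qlogis(pmax(drugs$prevalence[j], 1e-12))
    if (!is.na(asp_idx)) lp <- lp + log(cfg$co_rx_or) * expo[, asp_idx]
    expo[, j] <- runif(n) < plogis(lp)
  }
  therapy <- therapy_from_exposures(expo, drugs)

  hypertension <- runif(n) < cfg$covariate_prev[["hypertension"]]
  diabetes <- runif(n) < cfg$covariate_prev[["diabetes"]]
  injection <- runif(n) < cfg$covariate_prev[["injection"]]

  lp <- cfg$baseline_logit +
    drop(expo %*% drugs$log_or) +
    cfg$covariate_log_or[["hypertension"]] * hypertension +
    cfg$covariate_log_or[["diabetes"]] * diabetes +
    cfg$covariate_log_or[["injection"]] * injection
  if (length(cfg$combo_log_or) > 0) {
    extra <- cfg$combo_log_or[therapy]
    lp <- lp + ifelse(is.na(extra), 0, extra)
  }
  event <- runif(n) < plogis(lp)

  # calendar anchors: one base date per case, drug starts staggered after it
  base_day <- sample.int(5844, n, replace = TRUE) - 1L  # 2005-01-01 .. 2020-12-31
  origin <- as.Date("2005-01-01")

  exp_idx <- which(expo, arr.ind = TRUE)
  drug_tbl <- tibble(
    case = exp_idx[, 1],
    case_id = case_id[exp_idx[, 1]],
    drug_name = drugs$drug[exp_idx[, 2]],
    involvement = sample(INVOLVEMENT_LEVELS, nrow(exp_idx), replace = TRUE,
                         prob = c(0.6, 0.35, 0.05)),
    route = "oral",
    start_day = base_day[exp_idx[, 1]] + sample.int(61, nrow(exp_idx), replace = TRUE) - 1L,
    shape = drugs$weibull_shape[exp_idx[, 2]],
    scale = drugs$weibull_scale[exp_idx[, 2]]
  ) |> arrange(.data$case, .data$drug_name)

  # injection users: one ocular-injection drug record each
  inj_cases <- which(injection)
  inj_agents <- injection_agents()
  inj_tbl <- NULL
  if (length(inj_cases) > 0) {
    agent <- sample(inj_agents$agent, length(inj_cases), replace = TRUE)
    restricted <- agent %in% inj_agents$agent[inj_agents$route_restricted]
    route <- ifelse(restricted,
                    sample(OCULAR_INJECTION_ROUTES, length(inj_cases), replace = TRUE),
                    "intravitreal injections")
    inj_tbl <- tibble(case = inj_cases, case_id = case_id[inj_cases],
                      drug_name = agent,
                      involvement = "concomitant", route = route,
                      start_day = NA_integer_, shape = NA_real_, scale = NA_real_)
  }

  # event onset: Weibull days after the earliest exposed-drug start
  first_start <- drug_tbl |>
    group_by(.data$case) |>
    summarise(start_day = min(.data$start_day),
              shape = .data$shape[which.min(.data$start_day)],
              scale = .data$scale[which.min(.data$start_day)],
              .groups = "drop")
  ev_cases <- which(event)
  ev <- tibble(case = ev_cases) |>
    left_join(first_start, by = "case") |>
    mutate(
      delay = ifelse(is.na(.data$start_day), 0L,
                     as.integer(floor(rweibull(length(ev_cases),
                                               dplyr::coalesce(.data$shape, 1),
                                               dplyr::coalesce(.data$scale, 120))))),
      onset_day = ifelse(is.na(.data$start_day),
                         base_day[.data$case], .data$start_day + .data$delay)
    )
  event_pts <- ioh_pts()
  ev$pt_code <- sample(event_pts$pt_code, nrow(ev), replace = TRUE)
  ev$pt_name <- event_pts$pt_name[match(ev$pt_code, event_pts$pt_code)]

  # background AEs: synthetic codes disjoint from the event PT set
  bg_codes <- 90000000L + seq_len(cfg$n_background_pts)
  n_bg <- 1L + rpois(n, cfg$ae_lambda)
  bg <- tibble(case = rep(seq_len(n), n_bg)) |>
    mutate(pt_code = sample(bg_codes, dplyr::n(), replace = TRUE),
           onset_day = base_day[.data$case] + sample.int(366, dplyr::n(), replace = TRUE) - 1L) |>
    distinct(.data$case, .data$pt_code, .keep_all = TRUE) |>
    mutate(pt_name = paste("Background AE", .data$pt_code))

  reac_tbl <- bind_rows(
    bg |> select("case", "pt_code", "pt_name", "onset_day"),
    ev |> select("case", "pt_code", "pt_name", "onset_day")
  ) |>
    arrange(.data$case, .data$pt_code) |>
    mutate(case_id = case_id[.data$case])

  # primary-disease history for the comorbidity flags
  ht_pts <- hypertension_smq()
  dm_pts <- diabetes_smq()
  ht_cases <- which(hypertension)
  dm_cases <- which(diabetes)
  hist_tbl <- bind_rows(
    tibble(case = ht_cases,
           pt_code = sample(ht_pts$pt_code, length(ht_cases), replace = TRUE)) |>
      mutate(pt_name = ht_pts$pt_name[match(.data$pt_code, ht_pts$pt_code)]),
    tibble(case = dm_cases,
           pt_code = sample(dm_pts$pt_code, length(dm_cases), replace = TRUE)) |>
      mutate(pt_name = dm_pts$pt_name[match(.data$pt_code, dm_pts$pt_code)])
  ) |>
    arrange(.data$case, .data$pt_code) |>
    mutate(case_id = case_id[.data$case])

  # demographic blanking
  blank_sex <- runif(n) < cfg$p_blank_sex
  blank_age <- runif(n) < cfg$p_blank_age
  demo_out <- tibble(case_id = case_id,
                     sex = ifelse(blank_sex, "", sex),
                     age_category = ifelse(blank_age, "", age))

  # date degradation to year-month precision
  all_drug <- bind_rows(drug_tbl, inj_tbl)
  start_date <- origin + all_drug$start_day
  partial_start <- !is.na(all_drug$start_day) & runif(nrow(all_drug)) < cfg$p_partial_date
  drug_out <- tibble(
    case_id = all_drug$case_id,
    drug_name = all_drug$drug_name,
    involvement = all_drug$involvement,
    route = all_drug$route,
    start_date = format_partial_date(start_date,
                                     dplyr::case_when(is.na(all_drug$start_day) ~ "missing",
                                                      partial_start ~ "month",
                                                      TRUE ~ "day"))
  )
  onset_date <- origin + reac_tbl$onset_day
  partial_onset <- runif(nrow(reac_tbl)) < cfg$p_partial_date
  reac_out <- tibble(
    case_id = reac_tbl$case_id,
    pt_code = as.character(reac_tbl$pt_code),
    pt_name = reac_tbl$pt_name,
    onset_date = format_partial_date(onset_date,
                                     ifelse(partial_onset, "month", "day"))
  )
  hist_out <- tibble(case_id = hist_tbl$case_id,
                     pt_code = as.character(hist_tbl$pt_code),
                     pt_name = hist_tbl$pt_name)

  # exact-duplicate injection (base tables are duplicate-free by construction)
  inject_dups <- function(df, p) {
    k <- round(p * nrow(df))
    if (k == 0) return(list(df = df, k = 0L))
    idx <- sample.int(nrow(df), k)
    list(df = bind_rows(df, df[idx, ]), k = as.integer(k))
  }
  d_drug <- inject_dups(drug_out, cfg$p_duplicate)
  d_reac <- inject_dups(reac_out, cfg$p_duplicate)
  d_hist <- inject_dups(hist_out, cfg$p_duplicate)

  latent <- tibble(
    case_id = case_id, sex = sex, age_category = age,
    drugs = {
      sets <- vector("list", n)
      sets[] <- list(character(0))
      exposed <- which(rowSums(expo) > 0)
      sets[exposed] <- lapply(exposed, function(i) colnames(expo)[expo[i, ]])
      sets
    },
    therapy = therapy, event = event,
    hypertension = hypertension, diabetes = diabetes, injection = injection,
    complete_demo = !blank_sex & !blank_age
  )

  list(
    tables = list(demo = demo_out, drug = d_drug$df,
                  reac = d_reac$df, hist = d_hist$df),
    truth = list(
      latent = latent,
      injected = list(duplicates = c(drug = d_drug$k, reac = d_reac$k,
                                     hist = d_hist$k),
                      blank_sex = sum(blank_sex), blank_age = sum(blank_age),
                      partial_start_dates = sum(partial_start),
                      partial_onset_dates = sum(partial_onset)),
      config = cfg
    )
  )
}

#' Parse generated tables into a case database
#'
#' Runs the standard parsing + cleaning + linkage over the in-memory
#' tables of [generate_database()], exactly as if they had been round-
#' tripped through CSV.
#'
#' @param tables the `tables` element of a [generate_database()] result.
#' @return a `jader_db`.
#' @export
as_jader_db <- function(tables) {
  link_tables(
    demo = parse_jader_table(tables$demo, "demo"),
    drug = parse_jader_table(tables$drug, "drug"),
    reac = parse_jader_table(tables$reac, "reac"),
    hist = parse_jader_table(tables$hist, "hist")
  )
}

#' Named scenario presets for the simulator
#'
#' * `"null"`: every drug and combination log odds ratio zero — no true
#'   signals; used for false-positive coverage checks.
#' * `"paper-like"`: the default configuration — ten drugs at the
#'   published exposure prevalences with planted log odds ratios
#'   mirroring the published monotherapy signal pattern.
#' * `"separation"`: no injection-drug users at all, so the
#'   injection covariate of the factor model is inestimable and must be
#'   reported as NA.
#'
#' @param seed integer seed stored in every preset.
#' @param n_cases cohort size per preset.
#' @return named list of [sim_config()] objects.
#' @export
scenario_presets <- function(seed, n_cases = 20000) {
  null_drugs <- default_drug_table() |> mutate(log_or = 0)
  list(
    "null" = sim_config(seed = seed, n_cases = n_cases, drugs = null_drugs),
    "paper-like" = sim_config(seed = seed, n_cases = n_cases),
    "separation" = sim_config(seed = seed, n_cases = n_cases,
                              covariate_prev = c(hypertension = 0.15,
                                                 diabetes = 0.10,
                                                 injection = 0))
  )
}

#' Write a generated database to a directory
#'
#' Writes the four CSV tables plus `ground_truth.json` (list-columns
#' flattened).
#'
#' @param sim result of [generate_database()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(sim$tables)) {
    write_csv(sim$tables[[nm]], file.path(dir, paste0(nm, ".csv")))
  }
  latent <- sim$truth$latent |>
    mutate(drugs = map_chr(.data$drugs, paste, collapse = ";"))
  truth <- list(latent = latent, injected = sim$truth$injected,
                seed = sim$truth$config$seed,
                n_cases = sim$truth$config$n_cases)
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
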