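#' Oral exposures to the target antithrombotics
#'
#' A case is exposed to a target drug when at least one of its drug records
#' names that drug (after synonym normalization) with route "oral". All
#' involvement categories — suspected, concomitant, interaction — count,
#' so concomitant reporting of an antithrombotic contributes exposure.
#'
#' @param db a `jader_db`.
#' @param class_map tibble mapping `class` to `drug` (default:
#'   [drug_class_map()], the ten oral antiplatelets/anticoagulants).
#' @param synonyms synonym table for [normalize_drug_names()].
#' @return tibble with columns `case_id`, `drug`, one row per exposed
#'   case-drug pair (patient-level: repeats collapse to one row).
#' @export
oral_exposures <- function(db, class_map = drug_class_map(),
                           synonyms = drug_synonyms()) {
  stopifnot(inherits(db, "jader_db"))
  db$drug |>
    mutate(drug = normalize_drug_names(.data$drug_name, synonyms)) |>
    filter(.data$route == "oral", .data$drug %in% class_map$drug) |>
    distinct(.data$case_id, .data$drug)
}

# the seven analyzed combination groups, keyed by sorted class set
COMBINATION_GROUPS <- c(
  "DOAC|P2Y12"            = "dual:P2Y12+DOAC",
  "P2Y12|warfarin"        = "dual:P2Y12+warfarin",
  "DOAC|aspirin"          = "dual:aspirin+DOAC",
  "aspirin|warfarin"      = "dual:aspirin+warfarin",
  "P2Y12|aspirin"         = "dual:aspirin+P2Y12",
  "P2Y12|aspirin|warfarin" = "triple:aspirin+P2Y12+warfarin",
  "DOAC|P2Y12|aspirin"    = "triple:aspirin+P2Y12+DOAC"
)

#' Assign each case a therapy category
#'
#' Categories partition the database: `mono:<drug>` when exactly one target
#' drug is reported; one of the seven analyzed combination groups (dual
#' aspirin+P2Y12, aspirin+warfarin, aspirin+DOAC, P2Y12+warfarin,
#' P2Y12+DOAC; triple aspirin+P2Y12+warfarin, aspirin+P2Y12+DOAC) when the
#' exact set of drug classes present matches; `other-combination` for any
#' other multi-drug pattern; `unexposed` otherwise. Mono/dual/triple rows
#' are therefore disjoint, non-nested groups. Two drugs of one class
#' without a partner class (e.g. clopidogrel + prasugrel) are not
#' monotherapy and fall into `other-combination`.
#'
#' @param exposures output of [oral_exposures()].
#' @param case_ids character vector of all cleaned case ids (defines the
#'   `unexposed` remainder).
#' @param class_map see [drug_class_map()].
#' @return tibble with columns `case_id`, `therapy`.
#' @export
classify_therapy <- function(exposures, case_ids,
                             class_map = drug_class_map()) {
  class_of <- setNames(class_map$class, class_map$drug)
  per_case <- exposures |>
    group_by(.data$case_id) |>
    summarise(
      n_drugs = dplyr::n_distinct(.data$drug),
      one_drug = dplyr::first(.data$drug),
      class_key = paste(sort(unique(class_of[.data$drug])), collapse = "|"),
      .groups = "drop"
    ) |>
    mutate(therapy = dplyr::case_when(
      .data$n_drugs == 1 ~ paste0("mono:", .data$one_drug),
      .data$class_key %in% names(COMBINATION_GROUPS) ~
        unname(COMBINATION_GROUPS[.data$class_key]),
      TRUE ~ "other-combination"
    )) |>
    select("case_id", "therapy")
  tibble(case_id = case_ids) |>
    left_join(per_case, by = "case_id") |>
    mutate(therapy = dplyr::coalesce(.data$therapy, "unexposed"))
}

#' Flag cases reporting an event defined by a preferred-term set
#'
#' Patient-level: a case is flagged when at least one of its adverse-event
#' records carries a PT in the set; several matching PTs still count once.
#' Enlarging the PT set can only enlarge the flagged set (monotone).
#'
#' @param db a `jader_db`.
#' @param pt_codes integer PT codes, or a tibble with a `pt_code` column
#'   (e.g. [ioh_pts()]).
#' @return tibble with columns `case_id`, `event` (logical), one row per
#'   case in the database.
#' @export
flag_event <- function(db, pt_codes = ioh_pts()) {
  stopifnot(inherits(db, "jader_db"))
  codes <- if (is.data.frame(pt_codes)) pt_codes$pt_code else pt_codes
  hit <- unique(db$reac$case_id[db$reac$pt_code %in% codes])
  tibble(case_id = db$demo$case_id, event = db$demo$case_id %in% hit)
}

#' Flag cases with a comorbidity defined by an SMQ preferred-term set
#'
#' As [flag_event()] but over the primary-disease (`hist`) table, used for
#' the hypertension and diabetes SMQ definitions.
#'
#' @inheritParams flag_event
#' @param pt_codes e.g. [hypertension_smq()] or [diabetes_smq()].
#' @return tibble with columns `case_id`, `comorbidity` (logical).
#' @export
flag_comorbidity <- function(db, pt_codes) {
  stopifnot(inherits(db, "jader_db"))
  codes <- if (is.data.frame(pt_codes)) pt_codes$pt_code else pt_codes
  hit <- unique(db$hist$case_id[db$hist$pt_code %in% codes])
  tibble(case_id = db$demo$case_id, comorbidity = db$demo$case_id %in% hit)
}

#' Flag cases using intravitreal / posterior sub-Tenon injection agents
#'
#' True when a drug record names one of the injection agents. Agents marked
#' route-restricted (triamcinolone acetonide) count only when given as
#' "intraocular injections", "intravitreal injections" or "posterior
#' sub-Tenon injections"; the anti-VEGF agents count regardless of route.
#'
#' @inheritParams flag_event
#' @param agents tibble with columns `agent`, `route_restricted`
#'   (default [injection_agents()]).
#' @param synonyms synonym table for name normalization.
#' @return tibble with columns `case_id`, `injection` (logical).
#' @export
flag_injection_drugs <- function(db, agents = injection_agents(),
                                 synonyms = drug_synonyms()) {
  stopifnot(inherits(db, "jader_db"))
  drg <- db$drug |>
    mutate(drug = normalize_drug_names(.data$drug_name, synonyms))
  free <- tolower(agents$agent[!agents$route_restricted])
  restricted <- tolower(agents$agent[agents$route_restricted])
  hit <- drg |>
    filter(.data$drug %in% free |
             (.data$drug %in% restricted &
                .data$route %in% OCULAR_INJECTION_ROUTES)) |>
    pull(.data$case_id) |>
    unique()
  tibble(case_id = db$demo$case_id, injection = db$demo$case_id %in% hit)
}

#' Split cases into younger and elderly age groups
#'
#' Younger: decade bands "under 10s" through "60s"; elderly: "70s" through
#' "100s". Requires a cleaned database (no unknown ages), so the two
#' groups partition all cases.
#'
#' @inheritParams flag_event
#' @return tibble with columns `case_id`, `age_group`
#'   (`"younger"`/`"elderly"`).
#' @export
assign_age_groups <- function(db) {
  stopifnot(inherits(db, "jader_db"))
  tibble(
    case_id = db$demo$case_id,
    age_group = ifelse(db$demo$age_category %in% ELDERLY_BANDS,
                       "elderly", "younger")
  )
}

#' Build the per-case analysis cohort
#'
#' Combines exposures, therapy categories, event and covariate flags and
#' age groups into one tibble with a row per cleaned case — the input to
#' [run_signal_table()], [build_design()] and the time-to-onset summary.
#'
#' @param db a `jader_db`.
#' @param class_map,synonyms drug maps (defaults: shipped tables).
#' @param event_pts PT set defining the event (default [ioh_pts()]).
#' @param hypertension_pts,diabetes_pts SMQ PT sets for the comorbidity
#'   flags.
#' @param agents injection-agent table.
#' @return tibble with columns `case_id`, `sex`, `age_category`,
#'   `age_group`, `drugs` (list-column of exposed target drugs), `therapy`,
#'   `event`, `hypertension`, `diabetes`, `injection`.
#' @export
build_cohort <- function(db,
                         class_map = drug_class_map(),
                         synonyms = drug_synonyms(),
                         event_pts = ioh_pts(),
                         hypertension_pts = hypertension_smq(),
                         diabetes_pts = diabetes_smq(),
                         agents = injection_agents()) {
  stopifnot(inherits(db, "jader_db"))
  expo <- oral_exposures(db, class_map, synonyms)
  therapy <- classify_therapy(expo, db$demo$case_id, class_map)
  drug_sets <- expo |>
    group_by(.data$case_id) |>
    summarise(drugs = list(sort(unique(.data$drug))), .groups = "drop")
  ev <- flag_event(db, event_pts)
  ht <- flag_comorbidity(db, hypertension_pts) |> rename(hypertension = "comorbidity")
  dm <- flag_comorbidity(db, diabetes_pts) |> rename(diabetes = "comorbidity")
  inj <- flag_injection_drugs(db, agents, synonyms)
  ag <- assign_age_groups(db)

  db$demo |>
    select("case_id", "sex", "age_category") |>
    left_join(ag, by = "case_id") |>
    left_join(drug_sets, by = "case_id") |>
    mutate(drugs = lapply(.data$drugs, function(d) if (is.null(d)) character(0) else d)) |>
    left_join(therapy, by = "case_id") |>
    left_join(ev, by = "case_id") |>
    left_join(ht, by = "case_id") |>
    left_join(dm, by = "case_id") |>
    left_join(inj, by = "case_id")
}
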