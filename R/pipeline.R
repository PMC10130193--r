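#' Validate a pipeline run configuration
#'
#' A run configuration is a named list (or a YAML file with the same
#' keys): `input_dir` (directory with demo/drug/reac/hist CSVs), `out_dir`,
#' and optional overrides: `encoding`, `strata` (default TRUE),
#' `comparator` (`"within"`/`"global"`), `day_one` (TRUE), `min_cases`
#' (10), `ioh_pts`, `hypertension_smq`, `diabetes_smq`, `drug_classes`,
#' `drug_synonyms`, `injection_agents` (paths replacing the shipped term
#' lists). All referenced paths must exist at validation time; validation
#' happens before any computation.
#'
#' @param config named list or path to a YAML file.
#' @return the validated config list with defaults filled in.
#' @export
validate_run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) abort(sprintf("config file not found: %s", config))
    config <- yaml::read_yaml(config)
  }
  defaults <- list(encoding = "UTF-8", strata = TRUE, comparator = "within",
                   day_one = TRUE, min_cases = 10)
  config <- modifyList(defaults, config)
  if (is.null(config$input_dir) || is.null(config$out_dir)) {
    abort("config must name input_dir and out_dir")
  }
  if (!dir.exists(config$input_dir)) {
    abort(sprintf("input_dir does not exist: %s", config$input_dir))
  }
  for (f in c("demo.csv", "drug.csv", "reac.csv", "hist.csv")) {
    p <- file.path(config$input_dir, f)
    if (!file.exists(p)) abort(sprintf("missing input table: %s", p))
  }
  for (key in c("ioh_pts", "hypertension_smq", "diabetes_smq",
                "drug_classes", "drug_synonyms", "injection_agents")) {
    if (!is.null(config[[key]]) && !file.exists(config[[key]])) {
      abort(sprintf("%s path does not exist: %s", key, config[[key]]))
    }
  }
  config
}

#' Run the full pipeline: clean, cohort, signals, factors, time-to-onset
#'
#' Executes every stage in order on the four input tables and writes the
#' result tables under `out_dir`:
#' `signals_monotherapy.csv`, `signals_combination.csv`,
#' `signals_age_subgroup.csv`, `factor_analysis.csv`,
#' `time_to_onset.csv`, plus `manifest.json` recording input file
#' digests, the cleaning provenance (records dropped at each step),
#' package version and all parameters. The pipeline is deterministic:
#' rerunning with identical inputs and config reproduces byte-identical
#' outputs.
#'
#' @param config see [validate_run_config()].
#' @return the manifest, invisibly.
#' @export
run_all <- function(config) {
  config <- validate_run_config(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  term <- list(
    ioh = ioh_pts(config$ioh_pts),
    ht = hypertension_smq(config$hypertension_smq),
    dm = diabetes_smq(config$diabetes_smq),
    classes = drug_class_map(config$drug_classes),
    synonyms = drug_synonyms(config$drug_synonyms),
    agents = injection_agents(config$injection_agents)
  )

  db <- stage("clean", read_jader_db(config$input_dir, config$encoding))
  cohort <- stage("cohort", build_cohort(
    db, class_map = term$classes, synonyms = term$synonyms,
    event_pts = term$ioh, hypertension_pts = term$ht,
    diabetes_pts = term$dm, agents = term$agents))

  signals <- stage("signals", run_signal_table(cohort))
  mono <- signals |> filter(startsWith(.data$category, "mono:"))
  combo <- signals |> filter(!startsWith(.data$category, "mono:"))
  age <- if (isTRUE(config$strata)) {
    stage("signals", run_signal_table(cohort, strata = TRUE,
                                      comparator = config$comparator))
  } else NULL

  factors <- stage("factors", fit_factor_models(cohort, class_map = term$classes))

  tto <- stage("tto", {
    mono_drugs <- intersect(term$classes$drug, unique(unlist(cohort$drugs)))
    recs <- map(mono_drugs, function(d) {
      mono_cases <- cohort$case_id[cohort$therapy == paste0("mono:", d)]
      compute_onset_periods(db, d, event_pts = term$ioh,
                            cases = mono_cases, synonyms = term$synonyms,
                            day_one = isTRUE(config$day_one))
    }) |> purrr::list_rbind()
    recs <- recs[recs$case_id %in% cohort$case_id[cohort$event], , drop = FALSE]
    if (nrow(recs) == 0) tibble() else
      summarize_tto(recs, min_cases = config$min_cases)
  })

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- list(signals_monotherapy = mono,
                  signals_combination = combo,
                  signals_age_subgroup = age,
                  factor_analysis = factors,
                  time_to_onset = tto)
  for (nm in names(outputs)) {
    if (!is.null(outputs[[nm]])) {
      write_csv(outputs[[nm]], file.path(config$out_dir, paste0(nm, ".csv")))
    }
  }

  inputs <- file.path(config$input_dir, c("demo.csv", "drug.csv", "reac.csv", "hist.csv"))
  manifest <- list(
    package = "pvsignal",
    version = as.character(packageVersion("pvsignal")),
    inputs = as.list(setNames(unname(tools::md5sum(inputs)), basename(inputs))),
    provenance = db$provenance,
    parameters = config[setdiff(names(config), c("input_dir", "out_dir"))],
    n_cases = nrow(cohort),
    outputs = paste0(names(outputs)[!vapply(outputs, is.null, logical(1))], ".csv")
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
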