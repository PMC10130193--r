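#' Shipped term lists and drug maps
#'
#' The case and covariate definitions used by the intraocular-hemorrhage
#' analysis ship with the package as plain CSV files and are loaded by these
#' accessors. Each accessor takes an optional `path` so users can substitute
#' their own list (e.g. a newer MedDRA version) without touching package
#' internals.
#'
#' * `ioh_pts()` — the 17 MedDRA preferred terms (PTs) under HLT 10064464
#'   "Ocular haemorrhagic disorders" that define an intraocular hemorrhage,
#'   external/traumatic causes excluded.
#' * `hypertension_smq()` — PTs of SMQ 20000147 (Hypertension).
#' * `diabetes_smq()` — PTs of SMQ 20000041 (Hyperglycaemia/new onset
#'   diabetes mellitus).
#' * `drug_class_map()` — the ten oral antithrombotics under study and their
#'   class (aspirin; P2Y12 inhibitors clopidogrel, ticagrelor, ticlopidine,
#'   prasugrel; warfarin; DOACs apixaban, dabigatran, edoxaban, rivaroxaban).
#' * `drug_synonyms()` — salt-form and variant names mapped to canonical
#'   drug names (e.g. "clopidogrel sulfate" to "clopidogrel").
#' * `injection_agents()` — intravitreal / posterior sub-Tenon injection
#'   agents (aflibercept, brolucizumab, faricimab, ranibizumab,
#'   triamcinolone acetonide); `route_restricted` marks agents counted only
#'   when given by an ocular-injection route.
#'
#' @param path optional path to a CSV replacing the shipped list.
#' @return a tibble; PT lists have columns `pt_code`, `pt_name`.
#' @name term_lists
NULL

.term_cache <- new.env(parent = emptyenv())

read_shipped <- function(file, path = NULL) {
  if (is.null(path)) {
    if (!is.null(.term_cache[[file]])) return(.term_cache[[file]])
    path <- system.file("extdata", file, package = "pvsignal", mustWork = TRUE)
    .term_cache[[file]] <- read_csv(path, show_col_types = FALSE, progress = FALSE)
    return(.term_cache[[file]])
  }
  read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' @rdname term_lists
#' @export
ioh_pts <- function(path = NULL) read_shipped("ioh_pts.csv", path)

#' @rdname term_lists
#' @export
hypertension_smq <- function(path = NULL) read_shipped("hypertension_smq.csv", path)

#' @rdname term_lists
#' @export
diabetes_smq <- function(path = NULL) read_shipped("diabetes_smq.csv", path)

#' @rdname term_lists
#' @export
drug_class_map <- function(path = NULL) {
  map <- read_shipped("drug_classes.csv", path)
  stopifnot(all(c("class", "drug") %in% names(map)))
  map
}

#' @rdname term_lists
#' @export
drug_synonyms <- function(path = NULL) read_shipped("drug_synonyms.csv", path)

#' @rdname term_lists
#' @export
injection_agents <- function(path = NULL) read_shipped("injection_agents.csv", path)

# routes under which a route-restricted injection agent counts
OCULAR_INJECTION_ROUTES <- c("intraocular injections",
                             "intravitreal injections",
                             "posterior sub-tenon injections")

#' Normalize free-text drug names against a synonym table
#'
#' Lower-cases, trims and squeezes whitespace, then maps synonyms (salt
#' forms, spelling variants) to canonical names.
#'
#' @param x character vector of drug names.
#' @param synonyms tibble with columns `synonym`, `canonical`;
#'   defaults to the shipped table.
#' @return character vector of normalized names.
#' @export
normalize_drug_names <- function(x, synonyms = drug_synonyms()) {
  x <- str_squish(tolower(as.character(x)))
  idx <- match(x, str_squish(tolower(synonyms$synonym)))
  out <- ifelse(is.na(idx), x, synonyms$canonical[idx])
  out
}
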