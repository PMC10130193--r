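#' Read one table of the four-table spontaneous-report layout
#'
#' Reads a delimited text file in the JADER-style layout and returns a
#' validated tibble. The four table kinds and their mandatory columns are:
#'
#' * `demo`: `case_id`, `sex`, `age_category`
#' * `drug`: `case_id`, `drug_name`, `involvement`, `route`, `start_date`
#' * `reac`: `case_id`, `pt_code`, `pt_name`, `onset_date`
#' * `hist`: `case_id`, `pt_code`, `pt_name`
#'
#' Unknown columns are preserved but ignored by the pipeline. Dates may be
#' partial (see [parse_partial_date()]); a precision column is added next
#' to each parsed date. Blank or unrecognized sex / age values become `NA`
#' ("blank/unknown") and are removed later by [clean_demo()].
#'
#' @param path path to a delimited text file with a header row.
#' @param kind one of `"demo"`, `"drug"`, `"reac"`, `"hist"`.
#' @param encoding file encoding; the real database is Shift-JIS
#'   (`"Shift_JIS"`), synthetic fixtures are UTF-8.
#' @return a tibble of parsed records.
#' @export
read_jader_table <- function(path, kind = c("demo", "drug", "reac", "hist"),
                             encoding = "UTF-8") {
  kind <- match.arg(kind)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- read_csv(path, col_types = cols(.default = col_character()),
                  locale = locale(encoding = encoding),
                  show_col_types = FALSE, progress = FALSE)
  parse_jader_table(raw, kind)
}

jader_required_cols <- list(
  demo = c("case_id", "sex", "age_category"),
  drug = c("case_id", "drug_name", "involvement", "route", "start_date"),
  reac = c("case_id", "pt_code", "pt_name", "onset_date"),
  hist = c("case_id", "pt_code", "pt_name")
)

#' Validate and type an in-memory spontaneous-report table
#'
#' The parsing behind [read_jader_table()], usable directly on a data frame
#' (e.g. one produced by [generate_database()]).
#'
#' @param df data frame with the mandatory columns for `kind`.
#' @inheritParams read_jader_table
#' @return a tibble of parsed records.
#' @export
parse_jader_table <- function(df, kind = c("demo", "drug", "reac", "hist")) {
  kind <- match.arg(kind)
  req <- jader_required_cols[[kind]]
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0) {
    abort(sprintf("%s table is missing mandatory column(s): %s",
                  kind, paste(missing_cols, collapse = ", ")))
  }
  df <- as_tibble(df)
  df$case_id <- str_trim(as.character(df$case_id))
  if (any(is.na(df$case_id) | df$case_id == "")) {
    abort(sprintf("%s table contains empty case_id values", kind))
  }
  if (kind == "demo") {
    sex <- tolower(str_trim(as.character(df$sex)))
    df$sex <- ifelse(sex %in% c("male", "female"), sex, NA_character_)
    age <- tolower(str_trim(as.character(df$age_category)))
    df$age_category <- ifelse(age %in% AGE_BANDS, age, NA_character_)
  }
  if (kind == "drug") {
    inv <- tolower(str_trim(as.character(df$involvement)))
    if (!all(inv %in% INVOLVEMENT_LEVELS)) {
      abort("drug table: involvement must be one of suspected/concomitant/interaction")
    }
    df$involvement <- inv
    df$route <- tolower(str_squish(as.character(df$route)))
    pd <- parse_partial_date(df$start_date)
    df$start_date <- pd$date
    df$start_precision <- pd$precision
  }
  if (kind %in% c("reac", "hist")) {
    code <- suppressWarnings(as.integer(df$pt_code))
    if (any(is.na(code) | code <= 0)) {
      abort(sprintf("%s table: pt_code must be a positive integer", kind))
    }
    df$pt_code <- code
  }
  if (kind == "reac") {
    pd <- parse_partial_date(df$onset_date)
    df$onset_date <- pd$date
    df$onset_precision <- pd$precision
  }
  df
}

#' Drop records with blank/unknown sex or age
#'
#' Reports without usable demographics cannot enter patient-level counting
#' and are excluded at the start of cleaning. The number of dropped records
#' is attached as attribute `n_dropped`.
#'
#' @param demo a demo tibble from [read_jader_table()].
#' @return the retained records, with attribute `n_dropped`.
#' @export
clean_demo <- function(demo) {
  keep <- !is.na(demo$sex) & !is.na(demo$age_category)
  out <- demo[keep, , drop = FALSE]
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Remove exact duplicate records within one table
#'
#' Two records are duplicates when their full field tuple is identical; the
#' first occurrence is kept and order is otherwise preserved. The number
#' removed is attached as attribute `n_dropped`.
#'
#' @param df a table of records.
#' @return the deduplicated tibble, with attribute `n_dropped`.
#' @export
dedupe <- function(df) {
  out <- dplyr::distinct(df)
  attr(out, "n_dropped") <- nrow(df) - nrow(out)
  out
}

#' Clean and link the four tables into a case-level database
#'
#' Applies the cleaning sequence — demographic exclusions on `demo`, exact
#' deduplication on every table, then linkage by case identifier, dropping
#' drug/reac/hist records whose case no longer exists — and returns a
#' `jader_db` object: the four cleaned tibbles plus a provenance log with
#' the record count entering and dropped at every step, so that
#' records-in equals records-out plus records-dropped at each stage.
#'
#' @param demo,drug,reac,hist parsed tibbles (see [read_jader_table()]).
#' @return an object of class `jader_db`: a list with elements `demo`,
#'   `drug`, `reac`, `hist` and `provenance`.
#' @export
link_tables <- function(demo, drug, reac, hist) {
  prov <- list()
  prov$demo_in <- nrow(demo)
  demo <- dedupe(demo)
  prov$demo_duplicates <- attr(demo, "n_dropped")
  demo <- clean_demo(demo)
  prov$demo_missing_sex_age <- attr(demo, "n_dropped")

  tables <- list(drug = drug, reac = reac, hist = hist)
  for (nm in names(tables)) {
    tab <- tables[[nm]]
    prov[[paste0(nm, "_in")]] <- nrow(tab)
    tab <- dedupe(tab)
    prov[[paste0(nm, "_duplicates")]] <- attr(tab, "n_dropped")
    linked <- tab[tab$case_id %in% demo$case_id, , drop = FALSE]
    prov[[paste0(nm, "_unlinked")]] <- nrow(tab) - nrow(linked)
    tables[[nm]] <- linked
  }
  prov$cases <- nrow(demo)

  structure(list(demo = as_tibble(demo), drug = tables$drug,
                 reac = tables$reac, hist = tables$hist,
                 provenance = prov),
            class = "jader_db")
}

#' Read all four tables from a directory and build the case database
#'
#' Convenience wrapper: expects `demo.csv`, `drug.csv`, `reac.csv`,
#' `hist.csv` under `dir` and runs [link_tables()].
#'
#' @param dir directory containing the four CSV files.
#' @inheritParams read_jader_table
#' @return a `jader_db` object.
#' @export
read_jader_db <- function(dir, encoding = "UTF-8") {
  link_tables(
    demo = read_jader_table(file.path(dir, "demo.csv"), "demo", encoding),
    drug = read_jader_table(file.path(dir, "drug.csv"), "drug", encoding),
    reac = read_jader_table(file.path(dir, "reac.csv"), "reac", encoding),
    hist = read_jader_table(file.path(dir, "hist.csv"), "hist", encoding)
  )
}

#' Serialize a case database back to the four-file CSV layout
#'
#' Writes `demo.csv`, `drug.csv`, `reac.csv`, `hist.csv` (dates re-encoded
#' in the partial-date dialect) and `provenance.json` under `dir`.
#'
#' @param db a `jader_db`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_jader_db <- function(db, dir) {
  stopifnot(inherits(db, "jader_db"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_csv(db$demo, file.path(dir, "demo.csv"))
  drug <- db$drug
  drug$start_date <- format_partial_date(drug$start_date, drug$start_precision)
  drug$start_precision <- NULL
  write_csv(drug, file.path(dir, "drug.csv"))
  reac <- db$reac
  reac$onset_date <- format_partial_date(reac$onset_date, reac$onset_precision)
  reac$onset_precision <- NULL
  write_csv(reac, file.path(dir, "reac.csv"))
  write_csv(db$hist, file.path(dir, "hist.csv"))
  jsonlite::write_json(db$provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' @export
print.jader_db <- function(x, ...) {
  cat("<jader_db>", x$provenance$cases, "cases\n")
  cat("  drug records:", nrow(x$drug),
      "| reac records:", nrow(x$reac),
      "| hist records:", nrow(x$hist), "\n")
  dropped <- x$provenance$demo_duplicates + x$provenance$demo_missing_sex_age
  cat("  demo records dropped in cleaning:", dropped, "\n")
  invisible(x)
}
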