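#' Days from first administration to first event, per case
#'
#' For each case exposed (orally) to the drug, the onset period is the day
#' count from the earliest full-precision start date of that drug to the
#' first full-precision onset date of an event PT. With the default
#' day-one convention the administration day counts as day 1, so a
#' same-day onset gives period 1. Cases are excluded when either date is
#' missing or only partially precise (year or year-month), or when the
#' onset precedes the start — the operational reading of "missing or
#' inaccurate" dates. Raw periods beyond `cap` days are truncated to the
#' cap and flagged `capped`.
#'
#' @param db a `jader_db`.
#' @param drug canonical drug name.
#' @param event_pts PT set defining the event (default [ioh_pts()]).
#' @param cases optional case-id subset (e.g. monotherapy cases only).
#' @param synonyms synonym table for drug-name normalization.
#' @param day_one if TRUE (default) the administration day is day 1;
#'   FALSE counts elapsed days, excluding same-day onsets.
#' @param cap truncation horizon in days (default 720).
#' @return tibble with columns `case_id`, `drug`, `period_days`, `capped`.
#' @export
compute_onset_periods <- function(db, drug, event_pts = ioh_pts(),
                                  cases = NULL, synonyms = drug_synonyms(),
                                  day_one = TRUE, cap = 720) {
  stopifnot(inherits(db, "jader_db"))
  codes <- if (is.data.frame(event_pts)) event_pts$pt_code else event_pts

  starts <- db$drug |>
    mutate(dn = normalize_drug_names(.data$drug_name, synonyms)) |>
    filter(.data$dn == drug, .data$route == "oral",
           .data$start_precision == "day") |>
    group_by(.data$case_id) |>
    summarise(start = min(.data$start_date), .groups = "drop")

  onsets <- db$reac |>
    filter(.data$pt_code %in% codes, .data$onset_precision == "day") |>
    group_by(.data$case_id) |>
    summarise(onset = min(.data$onset_date), .groups = "drop")

  out <- inner_join(starts, onsets, by = "case_id")
  if (!is.null(cases)) out <- out[out$case_id %in% cases, , drop = FALSE]
  out |>
    mutate(raw = as.integer(.data$onset - .data$start) + as.integer(day_one)) |>
    filter(.data$raw >= 1) |>
    mutate(period_days = pmin(.data$raw, cap),
           capped = .data$raw > cap,
           drug = .env$drug) |>
    select("case_id", "drug", "period_days", "capped")
}

TTO_BIN_BREAKS <- c(0, 2, 7, 30, 60, 90, 180, 360, Inf)
TTO_BIN_LABELS <- c("d1_2", "d3_7", "d8_30", "d31_60",
                    "d61_90", "d91_180", "d181_360", "d361_plus")

#' Summarize time-to-onset records per drug
#'
#' Median and interquartile range of the onset period (quantiles by linear
#' interpolation of order statistics) plus the case distribution over the
#' standard bins: days 1-2, 3-7, 8-30, 31-60, 61-90, 91-180, 181-360, and
#' 361 onward (capped periods fall in the last bin). A drug is eligible
#' only when it has strictly more than `min_cases` evaluable cases; others
#' are retained in the output with `eligible = FALSE` so the exclusion is
#' visible.
#'
#' @param records tibble from [compute_onset_periods()] (rows for several
#'   drugs may be stacked).
#' @param min_cases eligibility threshold; eligible means n > min_cases.
#' @param quantile_type order-statistic interpolation rule passed to
#'   [stats::quantile()] (default 7, R's linear interpolation).
#' @return tibble with one row per drug: `drug`, `n_cases`, `median_days`,
#'   `q1`, `q3`, one column per bin, `eligible`.
#' @export
summarize_tto <- function(records, min_cases = 10, quantile_type = 7) {
  records |>
    group_by(.data$drug) |>
    summarise(
      n_cases = dplyr::n(),
      median_days = unname(quantile(.data$period_days, 0.5, type = quantile_type)),
      q1 = unname(quantile(.data$period_days, 0.25, type = quantile_type)),
      q3 = unname(quantile(.data$period_days, 0.75, type = quantile_type)),
      bins = list(table(cut(.data$period_days, TTO_BIN_BREAKS,
                            labels = TTO_BIN_LABELS))),
      .groups = "drop"
    ) |>
    mutate(bins = map(.data$bins, function(b) as_tibble(t(as.matrix(b))))) |>
    tidyr::unnest("bins") |>
    mutate(across(dplyr::all_of(TTO_BIN_LABELS), as.integer),
           eligible = .data$n_cases > min_cases)
}
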