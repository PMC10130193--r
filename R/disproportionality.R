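#' Build 2x2 contingency cells from margins
#'
#' For disproportionality work the natural inputs are often the published
#' margins: N11 (cases with drug and event), N1+ (all cases with the drug,
#' "Total AEs"), N+1 (all cases with the event), N++ (database size). This
#' constructor recovers the four cells N11, N10 = N1+−N11,
#' N01 = N+1−N11, N00 = N++−N1+−N01 and validates non-negativity.
#'
#' @param n11,n1p,np1,npp integer margins (vectorized).
#' @return tibble with columns `n11`, `n10`, `n01`, `n00`.
#' @export
#' @examples
#' contingency_from_margins(61, 19200, 1586, 688467)
contingency_from_margins <- function(n11, n1p, np1, npp) {
  out <- tibble(n11 = as.numeric(n11),
                n10 = as.numeric(n1p) - as.numeric(n11),
                n01 = as.numeric(np1) - as.numeric(n11),
                n00 = as.numeric(npp) - as.numeric(n1p) - (as.numeric(np1) - as.numeric(n11)))
  if (any(unlist(out) < 0)) abort("inconsistent margins: negative cell")
  out
}

#' Count the 2x2 table for one therapy category against an event
#'
#' Patient-level counts over a cohort tibble: N11 = cases in the category
#' with the event, N10 = category without the event, N01/N00 the same for
#' every other case in the universe (the comparator is "all other cases",
#' whatever their exposure). Restricting `universe` to a stratum (e.g. one
#' age group) computes all four cells within that stratum.
#'
#' @param cohort tibble from [build_cohort()] (needs `therapy` and `event`).
#' @param category a therapy label, e.g. `"mono:aspirin"`.
#' @param universe optional logical vector or case-id subset restricting
#'   the analysis universe; default all cases.
#' @return one-row tibble with `n11`, `n10`, `n01`, `n00`.
#' @export
build_contingency <- function(cohort, category, universe = NULL) {
  if (!is.null(universe)) {
    cohort <- if (is.logical(universe)) cohort[universe, ] else
      cohort[cohort$case_id %in% universe, ]
  }
  if (nrow(cohort) == 0) abort("empty universe: no cases to count")
  exposed <- cohort$therapy == category
  tibble(n11 = sum(exposed & cohort$event),
         n10 = sum(exposed & !cohort$event),
         n01 = sum(!exposed & cohort$event),
         n00 = sum(!exposed & !cohort$event))
}

#' Reporting odds ratio with Wald confidence interval
#'
#' ROR = (N11·N00)/(N10·N01); the 95% CI is
#' exp(ln ROR ± z·sqrt(1/N11 + 1/N10 + 1/N01 + 1/N00)). When any cell is
#' zero the ROR is undefined and all three values are `NA` — no continuity
#' correction is applied.
#'
#' @param n11,n10,n01,n00 cell counts (vectorized).
#' @param z normal quantile for the interval (default 1.96 for 95%).
#' @return tibble with columns `ror`, `ror_low`, `ror_high`.
#' @export
#' @examples
#' ror_ci(61, 19139, 1525, 667742)
ror_ci <- function(n11, n10, n01, n00, z = 1.96) {
  defined <- n11 > 0 & n10 > 0 & n01 > 0 & n00 > 0
  ror <- ifelse(defined, (n11 * n00) / (n10 * n01), NA_real_)
  se <- ifelse(defined, sqrt(1/n11 + 1/n10 + 1/n01 + 1/n00), NA_real_)
  tibble(ror = ror,
         ror_low = exp(log(ror) - z * se),
         ror_high = exp(log(ror) + z * se))
}

#' BCPNN prior constants
#'
#' The Dirichlet/beta prior constants of the Bayesian Confidence
#' Propagation Neural Network information component:
#' gamma11 = 1, alpha1 = beta1 = 1, alpha = beta = 2. The joint prior
#' gamma is computed per table so the prior IC is centred at zero:
#' gamma = gamma11·(N+++alpha)(N+++beta) / ((N1++alpha1)(N+1+beta1)).
#'
#' @return named list of prior constants.
#' @export
bcpnn_priors <- function() {
  list(gamma11 = 1, alpha1 = 1, beta1 = 1, alpha = 2, beta = 2)
}

#' BCPNN information component with credibility interval
#'
#' The information component IC = log2 of the shrunk observed-to-expected
#' reporting ratio:
#' \deqn{E(IC_{11}) = \log_2 \frac{(N_{11}+\gamma_{11})(N_{++}+\alpha)(N_{++}+\beta)}
#'   {(N_{++}+\gamma)(N_{1+}+\alpha_1)(N_{+1}+\beta_1)}}
#' with variance
#' \deqn{V(IC_{11}) = \frac{1}{(\ln 2)^2}\left[
#'   \frac{N_{++}-N_{11}+\gamma-\gamma_{11}}{(N_{11}+\gamma_{11})(1+N_{++}+\gamma)} +
#'   \frac{N_{++}-N_{1+}+\alpha-\alpha_1}{(N_{1+}+\alpha_1)(1+N_{++}+\alpha)} +
#'   \frac{N_{++}-N_{+1}+\beta-\beta_1}{(N_{+1}+\beta_1)(1+N_{++}+\beta)}\right]}
#' and 95% interval E ± 2·sqrt(V). Unlike the ROR, the IC is defined even
#' when N11 = 0 (the Bayesian shrinkage pulls it below zero).
#'
#' @param n11,n1p,np1,npp margins (vectorized).
#' @param priors prior constants, see [bcpnn_priors()].
#' @return tibble with columns `ic`, `ic_var`, `ic_low`, `ic_high`.
#' @export
#' @examples
#' ic_ci(61, 19200, 1586, 688467)
ic_ci <- function(n11, n1p, np1, npp, priors = bcpnn_priors()) {
  g11 <- priors$gamma11; a1 <- priors$alpha1; b1 <- priors$beta1
  a <- priors$alpha; b <- priors$beta
  gamma <- g11 * (npp + a) * (npp + b) / ((n1p + a1) * (np1 + b1))
  ic <- log2((n11 + g11) * (npp + a) * (npp + b) /
               ((npp + gamma) * (n1p + a1) * (np1 + b1)))
  ic_var <- (1 / log(2))^2 * (
    (npp - n11 + gamma - g11) / ((n11 + g11) * (1 + npp + gamma)) +
    (npp - n1p + a - a1)      / ((n1p + a1)  * (1 + npp + a)) +
    (npp - np1 + b - b1)      / ((np1 + b1)  * (1 + npp + b))
  )
  hw <- 2 * sqrt(ic_var)
  tibble(ic = ic, ic_var = ic_var, ic_low = ic - hw, ic_high = ic + hw)
}

#' Add ROR, IC and the dual signal flag to a table of 2x2 counts
#'
#' Takes a tibble of cell counts (`n11`, `n10`, `n01`, `n00`) and appends
#' the reporting odds ratio with Wald CI, the BCPNN information component
#' with credibility interval, and the signal flag. A pair is a signal only
#' when both criteria hold: the lower 95% limit of the ROR exceeds 1 AND
#' the lower limit of the IC exceeds 0 — the dual criterion guards against
#' false positives from either statistic alone.
#'
#' @param counts tibble with columns `n11`, `n10`, `n01`, `n00`.
#' @param z normal quantile for the ROR interval.
#' @param priors BCPNN priors.
#' @return the input with columns `ror`, `ror_low`, `ror_high`, `ic`,
#'   `ic_var`, `ic_low`, `ic_high`, `signal` appended.
#' @export
signal_stats <- function(counts, z = 1.96, priors = bcpnn_priors()) {
  n1p <- counts$n11 + counts$n10
  np1 <- counts$n11 + counts$n01
  npp <- n1p + counts$n01 + counts$n00
  r <- ror_ci(counts$n11, counts$n10, counts$n01, counts$n00, z = z)
  i <- ic_ci(counts$n11, n1p, np1, npp, priors = priors)
  dplyr::bind_cols(counts, r, i) |>
    mutate(signal = signal_flag(.data$ror_low, .data$ic_low))
}

#' The dual signal criterion
#'
#' TRUE only when the ROR is defined with lower 95% CI limit > 1 and the
#' IC lower credibility limit > 0.
#'
#' @param ror_low lower ROR confidence limit (`NA` when undefined).
#' @param ic_low lower IC credibility limit.
#' @return logical vector.
#' @export
signal_flag <- function(ror_low, ic_low) {
  !is.na(ror_low) & ror_low > 1 & ic_low > 0
}

#' Recover an unprinted event margin from published table rows
#'
#' Published disproportionality tables usually print, per exposure row, the
#' exposed-case count N1+, the exposed-event count N11 and the rounded ROR,
#' plus the database size N++ — but not the total event-reporting count
#' N+1. Because every row's ROR depends on the same N+1, an integer grid
#' search over a plausible range recovers it: the returned value minimizes
#' the number of rows whose recomputed ROR fails to round (half-up, to the
#' printed precision) to the printed value, ties broken by the smallest
#' candidate. If no candidate reproduces at least half the rows the
#' calibration fails with an error.
#'
#' @param rows tibble with columns `n11`, `n1p`, `ror` (printed value);
#'   rows with undefined ROR (zero cells / `NA`) are ignored. At least two
#'   usable rows are required.
#' @param npp total database size.
#' @param range integer search range `c(low, high)` for N+1.
#' @param digits printed precision of the ROR column.
#' @return the calibrated integer N+1.
#' @export
infer_event_margin <- function(rows, npp, range = c(1000, 3000), digits = 2) {
  usable <- rows[!is.na(rows$ror) & rows$n11 > 0, , drop = FALSE]
  if (nrow(usable) < 2) abort("need at least two rows with a defined printed ROR")
  candidates <- seq(range[1], range[2])
  mismatches <- vapply(candidates, function(np1) {
    cells <- contingency_from_margins(usable$n11, usable$n1p, np1, npp)
    ror <- (cells$n11 * cells$n00) / (cells$n10 * cells$n01)
    sum(round_half_up(ror, digits) != usable$ror)
  }, numeric(1))
  best <- min(mismatches)
  if (best > nrow(usable) / 2) {
    abort("calibration failure: no candidate margin reproduces half the printed RORs")
  }
  candidates[which(mismatches == best)[1]]
}

#' Batch signal table over therapy categories, optionally age-stratified
#'
#' One row per therapy category (and per age stratum when `strata = TRUE`),
#' in the shape of a published signal table: exposed-case count
#' (`total_aes` = N1+), event count (`events` = N11), ROR with 95% CI, IC
#' with 95% credibility interval, and the dual signal flag. With
#' `comparator = "within"` (default) a stratified row computes all four
#' cells inside the stratum; `"global"` keeps the whole-database
#' comparator.
#'
#' @param cohort tibble from [build_cohort()].
#' @param categories therapy categories to tabulate; default every
#'   `mono:` and analyzed combination category present in the cohort.
#' @param strata if TRUE, repeat each category within younger/elderly.
#' @param comparator `"within"` or `"global"` (stratified rows only).
#' @param z,priors passed to [signal_stats()].
#' @return tibble with columns `category`, `stratum`, `total_aes`,
#'   `events`, `ror`, `ror_low`, `ror_high`, `ic`, `ic_low`, `ic_high`,
#'   `signal`.
#' @export
run_signal_table <- function(cohort, categories = NULL, strata = FALSE,
                             comparator = c("within", "global"),
                             z = 1.96, priors = bcpnn_priors()) {
  comparator <- match.arg(comparator)
  if (is.null(categories)) {
    present <- unique(cohort$therapy)
    categories <- c(
      sort(present[startsWith(present, "mono:")]),
      intersect(unname(COMBINATION_GROUPS), present)
    )
  }
  strata_levels <- if (strata) c("younger", "elderly") else NA_character_
  grid <- tidyr::expand_grid(category = categories, stratum = strata_levels)
  counts <- purrr::pmap(grid, function(category, stratum) {
    universe <- if (!is.na(stratum) && comparator == "within") {
      cohort$age_group == stratum
    } else NULL
    sub <- cohort
    if (!is.na(stratum) && comparator == "global") {
      # exposure cells restricted to the stratum, comparator cells global
      sub <- cohort |>
        mutate(therapy = ifelse(.data$age_group == stratum,
                                .data$therapy, "unexposed"))
    }
    build_contingency(sub, category, universe)
  }) |> purrr::list_rbind()
  dplyr::bind_cols(grid, counts) |>
    signal_stats(z = z, priors = priors) |>
    mutate(total_aes = .data$n11 + .data$n10, events = .data$n11) |>
    select("category", "stratum", "total_aes", "events",
           "ror", "ror_low", "ror_high",
           "ic", "ic_low", "ic_high", "signal")
}

#' Forest plot of a signal table
#'
#' RORs with 95% CIs on a log scale, signalled categories highlighted;
#' faceted by stratum when the table is age-stratified.
#'
#' @param signals output of [run_signal_table()].
#' @return a ggplot object.
#' @export
plot_signals <- function(signals) {
  dat <- signals[!is.na(signals$ror), , drop = FALSE]
  p <- ggplot(dat, aes(x = .data$ror, y = .data$category,
                       colour = .data$signal)) +
    geom_vline(xintercept = 1, linetype = "dashed", colour = "grey50") +
    geom_errorbarh(aes(xmin = .data$ror_low, xmax = .data$ror_high),
                   height = 0.2) +
    geom_point(size = 2) +
    scale_x_log10() +
    labs(x = "Reporting odds ratio (95% CI, log scale)", y = NULL,
         colour = "Signal") +
    theme_minimal()
  if (any(!is.na(dat$stratum))) p <- p + facet_wrap(~stratum)
  p
}
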