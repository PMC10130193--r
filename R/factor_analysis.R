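#' Design matrix for the per-drug factor model
#'
#' One row per case exposed (orally) to the index drug, with the event
#' outcome and the three binary risk-factor covariates: hypertension,
#' diabetes, and intravitreal / posterior sub-Tenon injection-drug use.
#'
#' @param cohort tibble from [build_cohort()].
#' @param drug one of the target drugs in `class_map`.
#' @param class_map see [drug_class_map()].
#' @return tibble with columns `case_id`, `event`, `hypertension`,
#'   `diabetes`, `injection`.
#' @export
build_design <- function(cohort, drug, class_map = drug_class_map()) {
  if (!drug %in% class_map$drug) {
    abort(sprintf("'%s' is not one of the target drugs", drug))
  }
  rows <- cohort[map_lgl(cohort$drugs, function(d) drug %in% d), , drop = FALSE]
  if (nrow(rows) == 0) abort(sprintf("no cases exposed to %s", drug))
  rows |> select("case_id", "event", "hypertension", "diabetes", "injection")
}

#' Detect inestimable (separated or constant) binary covariates
#'
#' A binary covariate cannot receive a finite maximum-likelihood odds
#' ratio when, within either of its levels, the outcome has zero events or
#' zero non-events — i.e. when any cell of the covariate-by-outcome 2x2
#' table is empty. Constant covariates are a special case (a whole level
#' is empty).
#'
#' @param data design tibble.
#' @param outcome name of the logical/0-1 outcome column.
#' @param covariates names of the binary covariate columns.
#' @return named logical vector, TRUE where the covariate is inestimable.
#' @export
detect_separation <- function(data, outcome = "event",
                              covariates = c("hypertension", "diabetes", "injection")) {
  y <- as.integer(data[[outcome]])
  vapply(covariates, function(v) {
    x <- as.integer(data[[v]])
    cells <- c(sum(x == 0 & y == 0), sum(x == 0 & y == 1),
               sum(x == 1 & y == 0), sum(x == 1 & y == 1))
    any(cells == 0)
  }, logical(1))
}

#' Multivariable logistic regression by Newton iteration
#'
#' Maximum-likelihood logistic fit of a binary outcome on binary
#' covariates, by Newton-Raphson (iteratively reweighted least squares)
#' with step-halving whenever a step would decrease the log-likelihood.
#' Convergence is declared when the largest absolute score (gradient)
#' component falls below `tol`. Covariates that are separated or constant
#' (see [detect_separation()]) are excluded before fitting and reported
#' with status `"NA"` rather than failing the model; a coefficient whose
#' magnitude exceeds `beta_bound` during iteration is treated the same
#' way and the model is refit without it. Non-convergence within
#' `max_iter` iterations is flagged in the result, not raised as an error.
#'
#' Inference is Wald: 95% CI = exp(beta ± 1.96·SE), two-sided p-value from
#' the normal reference for beta/SE.
#'
#' @param data design tibble (see [build_design()]).
#' @param outcome outcome column name.
#' @param covariates covariate column names.
#' @param tol convergence tolerance on the max absolute score.
#' @param max_iter maximum Newton iterations.
#' @param beta_bound divergence guard on |coefficient|.
#' @return an object of class `pv_logit` with methods [tidy.pv_logit()]
#'   and [glance.pv_logit()].
#' @export
fit_logistic <- function(data, outcome = "event",
                         covariates = c("hypertension", "diabetes", "injection"),
                         tol = 1e-8, max_iter = 25, beta_bound = 15) {
  y <- as.numeric(data[[outcome]])
  status <- setNames(rep("estimated", length(covariates)), covariates)
  status[detect_separation(data, outcome, covariates)] <- "NA"

  fit_once <- function(active) {
    X <- matrix(1, nrow = length(y), ncol = 1 + length(active))
    if (length(active) > 0) {
      X[, -1] <- vapply(data[active], as.numeric, numeric(length(y)))
    }
    colnames(X) <- c("(Intercept)", active)
    beta <- rep(0, ncol(X))
    loglik <- function(b) {
      eta <- drop(X %*% b)
      # numerically stable log(1 + exp(eta))
      sum(y * eta - (pmax(eta, 0) + log1p(exp(-abs(eta)))))
    }
    ll <- loglik(beta)
    ll_trace <- ll
    iter <- 0L
    converged <- FALSE
    score_norm <- Inf
    while (iter < max_iter) {
      iter <- iter + 1L
      p <- plogis(drop(X %*% beta))
      score <- drop(crossprod(X, y - p))
      score_norm <- max(abs(score))
      if (score_norm < tol) { converged <- TRUE; break }
      w <- pmax(p * (1 - p), .Machine$double.eps)
      H <- crossprod(X * w, X)
      step <- tryCatch(solve(H, score), error = function(e) NULL)
      if (is.null(step)) break
      # step-halve until the log-likelihood does not decrease
      lambda <- 1
      repeat {
        cand <- beta + lambda * step
        ll_new <- loglik(cand)
        if (ll_new >= ll || lambda < 2^-20) break
        lambda <- lambda / 2
      }
      beta <- cand
      ll <- ll_new
      ll_trace <- c(ll_trace, ll)
      if (any(abs(beta[-1]) > beta_bound)) break
    }
    p <- plogis(drop(X %*% beta))
    w <- pmax(p * (1 - p), .Machine$double.eps)
    H <- crossprod(X * w, X)
    vc <- tryCatch(solve(H), error = function(e) matrix(NA_real_, ncol(X), ncol(X)))
    list(beta = setNames(beta, colnames(X)),
         se = setNames(sqrt(diag(vc)), colnames(X)),
         vcov = vc, loglik = ll, ll_trace = ll_trace,
         iterations = iter, converged = converged, score_norm = score_norm)
  }

  repeat {
    active <- names(status)[status == "estimated"]
    f <- fit_once(active)
    diverged <- active[abs(f$beta[active]) > beta_bound]
    if (length(diverged) == 0) break
    status[diverged] <- "NA"
  }

  structure(list(fit = f, status = status, covariates = covariates,
                 outcome = outcome, n = nrow(data), n_events = sum(y)),
            class = "pv_logit")
}

#' Tidy a logistic factor-model fit
#'
#' Broom-style summary: one row per model term with the coefficient,
#' standard error, Wald z p-value, and the odds-ratio scale estimate with
#' 95% CI. Inestimable covariates appear with `status = "NA"` and missing
#' numbers, mirroring how published factor tables report them.
#'
#' @param x a `pv_logit`.
#' @param conf.level confidence level for the Wald interval.
#' @param ... unused.
#' @return tibble with columns `term`, `estimate`, `std.error`,
#'   `statistic`, `p.value`, `or`, `conf.low`, `conf.high`, `status`.
#' @export
tidy.pv_logit <- function(x, conf.level = 0.95, ...) {
  z <- qnorm(1 - (1 - conf.level) / 2)
  terms <- c("(Intercept)", x$covariates)
  est <- x$fit$beta[terms]
  se <- x$fit$se[terms]
  stat <- est / se
  out <- tibble(
    term = terms,
    estimate = unname(est),
    std.error = unname(se),
    statistic = unname(stat),
    p.value = unname(2 * pnorm(-abs(stat))),
    or = exp(unname(est)),
    conf.low = exp(unname(est - z * se)),
    conf.high = exp(unname(est + z * se)),
    status = c("estimated", unname(x$status))
  )
  na_rows <- out$status == "NA"
  out[na_rows, c("estimate", "std.error", "statistic", "p.value",
                 "or", "conf.low", "conf.high")] <- NA_real_
  out
}

#' One-line summary of a logistic factor-model fit
#'
#' @param x a `pv_logit`.
#' @param ... unused.
#' @return tibble with `n`, `n_events`, `logLik`, `converged`,
#'   `iterations`, `score_norm`, `df`.
#' @export
glance.pv_logit <- function(x, ...) {
  tibble(n = x$n, n_events = x$n_events, logLik = x$fit$loglik,
         converged = x$fit$converged, iterations = x$fit$iterations,
         score_norm = x$fit$score_norm,
         df = sum(x$status == "estimated") + 1L)
}

#' @export
print.pv_logit <- function(x, ...) {
  cat("<pv_logit>", x$n, "cases,", x$n_events, "events;",
      if (x$fit$converged) "converged" else "NOT converged",
      "in", x$fit$iterations, "iterations\n")
  print(tidy(x))
  invisible(x)
}

# broom-style generics, defined here so broom itself is not a dependency
#' @export
tidy <- function(x, ...) UseMethod("tidy")
#' @export
glance <- function(x, ...) UseMethod("glance")

#' Fit the factor model for every target drug in a cohort
#'
#' Runs [build_design()] + [fit_logistic()] per drug and stacks the tidied
#' covariate rows (intercept omitted) into one table shaped like a
#' published multivariable-analysis table. Drugs with no exposed cases
#' are skipped with a message.
#'
#' @param cohort tibble from [build_cohort()].
#' @param drugs drugs to fit; default all target drugs with >= 1 exposed
#'   case.
#' @param class_map see [drug_class_map()].
#' @param ... passed to [fit_logistic()].
#' @return tibble with a `drug` column followed by the [tidy.pv_logit()]
#'   columns.
#' @export
fit_factor_models <- function(cohort, drugs = NULL,
                              class_map = drug_class_map(), ...) {
  if (is.null(drugs)) {
    exposed <- unique(unlist(cohort$drugs))
    drugs <- intersect(class_map$drug, exposed)
  }
  map(drugs, function(d) {
    design <- tryCatch(build_design(cohort, d, class_map),
                       error = function(e) NULL)
    if (is.null(design)) {
      inform(sprintf("skipping %s: no exposed cases", d))
      return(NULL)
    }
    fit <- fit_logistic(design, ...)
    tidy(fit) |>
      filter(.data$term != "(Intercept)") |>
      mutate(drug = d, .before = 1)
  }) |> purrr::list_rbind()
}
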