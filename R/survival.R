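#' Build recurrence-free survival records from a clinical table
#'
#' Recurrence-free survival runs from diagnosis to first recurrence; cases
#' without recurrence are censored at last contact or death. Death without
#' recurrence is therefore censoring, not an event. This function validates
#' the time/event contract and returns the records unchanged otherwise, so
#' covariate columns pass through.
#'
#' @param clinical A data frame with `time_months` and `event` columns
#'   (`event` 1 = recurrence, 0 = censored) plus any covariates.
#'
#' @return A validated tibble of survival records.
#' @export
build_rfs <- function(clinical) {
  need <- c("time_months", "event")
  miss <- setdiff(need, names(clinical))
  if (length(miss) > 0L) {
    mc_abort(sprintf("clinical table lacks column(s): %s",
                     paste(miss, collapse = ", ")))
  }
  if (any(!is.finite(clinical$time_months) | clinical$time_months < 0)) {
    mc_abort("`time_months` must be nonnegative and finite.")
  }
  if (!all(clinical$event %in% c(0L, 1L))) {
    mc_abort("`event` must be 0 (censored) or 1 (recurrence).")
  }
  as_tibble(clinical)
}

#' Kaplan-Meier survival estimate per group
#'
#' Product-limit estimate of recurrence-free survival, one step function per
#' group, via [survival::survfit()].
#'
#' @param data Survival records (see [build_rfs()]).
#' @param group Optional grouping column (tidy-eval); omitted = one curve.
#' @param time,event Time and event columns (tidy-eval; defaults
#'   `time_months`, `event`).
#'
#' @return A tibble with one row per distinct time per group: `group`,
#'   `time`, `n_risk`, `n_event`, `n_censor`, `survival`.
#' @export
km_fit <- function(data, group = NULL, time = time_months, event = event) {
  t <- dplyr::pull(data, {{ time }})
  e <- dplyr::pull(data, {{ event }})
  g_quo <- rlang::enquo(group)
  if (rlang::quo_is_null(g_quo)) {
    g <- factor(rep("all", length(t)))
  } else {
    g <- factor(dplyr::pull(data, !!g_quo))
  }
  if (any(table(g) == 0L)) mc_abort("every group needs at least one record.")
  fit <- survfit(Surv(t, e) ~ g)
  s <- summary(fit, censored = TRUE)
  grp <- if (is.null(s$strata)) {
    rep(levels(g)[1], length(s$time))
  } else {
    sub("^g=", "", as.character(s$strata))
  }
  tibble(
    group = grp,
    time = s$time,
    n_risk = s$n.risk,
    n_event = s$n.event,
    n_censor = s$n.censor,
    survival = s$surv
  )
}

#' Two-or-more-group log-rank test
#'
#' Standard log-rank test with hypergeometric variance via
#' [survival::survdiff()]; p-value from the chi-square distribution with
#' (groups - 1) degrees of freedom.
#'
#' @inheritParams km_fit
#' @param group Grouping column (tidy-eval; required, >= 2 groups).
#'
#' @return A one-row tibble: `chisq`, `df`, `p_value`, `n`.
#' @export
logrank_test <- function(data, group, time = time_months, event = event) {
  t <- dplyr::pull(data, {{ time }})
  e <- dplyr::pull(data, {{ event }})
  g <- factor(dplyr::pull(data, {{ group }}))
  g <- droplevels(g)
  if (nlevels(g) < 2L) mc_abort("log-rank test needs at least two groups.")
  sd_fit <- survdiff(Surv(t, e) ~ g)
  df <- nlevels(g) - 1L
  tibble(
    chisq = sd_fit$chisq,
    df = df,
    p_value = pchisq(sd_fit$chisq, df = df, lower.tail = FALSE),
    n = length(t)
  )
}

#' Cox proportional hazards fit for categorical predictors
#'
#' Partial-likelihood fit via [survival::coxph()] with Efron handling of
#' tied event times. Monotone likelihood (complete separation of a level
#' from events) is flagged rather than reported as a spuriously finite
#' hazard ratio.
#'
#' @inheritParams km_fit
#' @param covariates Character vector of categorical covariate column names.
#'   The first level of each factor is the reference (HR = 1).
#'
#' @return A `cox_fit` object; use [tidy()] for the per-level hazard-ratio
#'   table and [glance()] for fit-level summaries including the
#'   `separation` flag.
#' @export
cox_fit <- function(data, covariates, time = time_months, event = event) {
  t <- dplyr::pull(data, {{ time }})
  e <- dplyr::pull(data, {{ event }})
  if (sum(e) < 1) mc_abort("at least one event is required.")
  miss <- setdiff(covariates, names(data))
  if (length(miss) > 0L) {
    mc_abort(sprintf("missing covariate column(s): %s",
                     paste(miss, collapse = ", ")))
  }
  covs <- lapply(data[covariates], function(v) droplevels(factor(v)))
  df <- data.frame(.time = t, .event = e, covs, check.names = FALSE)
  form <- stats::as.formula(paste(
    "Surv(.time, .event) ~",
    paste(sprintf("`%s`", covariates), collapse = " + ")
  ))
  fit <- withCallingHandlers(
    coxph(form, data = df, ties = "efron"),
    warning = function(w) {
      if (grepl("infinite|converge", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  beta <- coef(fit)
  se <- sqrt(diag(fit$var))
  separated <- !is.finite(beta) | abs(beta) > 10 | !is.finite(se) | se > 100
  level_n <- unlist(lapply(covs, table), use.names = FALSE)
  structure(
    list(fit = fit, covariates = covariates, covs = covs,
         separation = any(separated), separated_terms = names(beta)[separated],
         n = nrow(df), n_event = sum(e)),
    class = "cox_fit"
  )
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("<cox_fit> n = %d, events = %d%s\n", x$n, x$n_event,
              if (x$separation) " [SEPARATION FLAGGED]" else ""))
  print(tidy(x))
  invisible(x)
}

#' @method tidy cox_fit
#' @export
tidy.cox_fit <- function(x, conf_level = 0.95, ...) {
  beta <- coef(x$fit)
  se <- sqrt(diag(x$fit$var))
  z <- qnorm((1 + conf_level) / 2)
  rows <- purrr::map_dfr(seq_along(x$covariates), function(i) {
    cov <- x$covariates[i]
    v <- x$covs[[cov]]
    lv <- levels(v)
    terms <- paste0("`", cov, "`", lv[-1])
    # coxph strips backticks from term names when not needed
    terms_plain <- paste0(cov, lv[-1])
    idx <- match(terms, names(beta))
    idx[is.na(idx)] <- match(terms_plain, names(beta))[is.na(idx)]
    sep <- terms_plain %in% x$separated_terms |
      names(beta)[idx] %in% x$separated_terms
    tibble(
      term = cov,
      level = lv,
      n = as.integer(table(v)[lv]),
      hr = unname(c(1, exp(beta[idx]))),
      ci_low = unname(c(NA_real_, exp(beta[idx] - z * se[idx]))),
      ci_high = unname(c(NA_real_, exp(beta[idx] + z * se[idx]))),
      p_value = unname(c(NA_real_, 2 * pnorm(-abs(beta[idx] / se[idx])))),
      separation = unname(c(FALSE, sep))
    )
  })
  rows
}

#' @method glance cox_fit
#' @export
glance.cox_fit <- function(x, ...) {
  tibble(
    n = x$n, n_event = x$n_event,
    loglik = x$fit$loglik[2], loglik_null = x$fit$loglik[1],
    separation = x$separation
  )
}
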