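#' Exhaustive log-rank scan over marker split points
#'
#' Internal engine for [datadriven_cutpoint()]. Candidate thresholds are
#' midpoints between consecutive distinct marker values with both sides
#' holding at least `min_frac` of the cohort; for each candidate the
#' two-group log-rank chi-square (hypergeometric variance) is computed by
#' an incremental sweep over the event-time grid, so the whole scan costs
#' O(candidates x distinct event times).
#'
#' @return A tibble `threshold`, `frac_low`, `chisq`, ordered by threshold.
#' @noRd
logrank_scan <- function(time, event, marker, min_frac) {
  n <- length(time)
  ord <- order(marker)
  m_sorted <- marker[ord]
  t_sorted <- time[ord]
  e_sorted <- event[ord]

  grid <- sort(unique(time[event == 1]))
  K <- length(grid)
  if (K == 0L) mc_abort("all-censored cohort: no events to split on.")
  d_tot <- vapply(grid, function(g) sum(time == g & event == 1), numeric(1))
  n_risk <- vapply(grid, function(g) sum(time >= g), numeric(1))

  n_low_t <- numeric(K)   # at-risk count in the low group per grid time
  d_low_t <- numeric(K)   # low-group events per grid time

  # positions where the marker value changes define the candidate cuts
  distinct_end <- which(diff(m_sorted) > 0)
  if (length(distinct_end) == 0L) {
    mc_abort("marker is constant: no candidate cutpoints.")
  }
  res_thr <- res_frac <- res_chi <- numeric(0)
  last <- 0L
  for (cut_i in distinct_end) {
    for (j in (last + 1L):cut_i) {
      pos <- findInterval(t_sorted[j], grid)
      if (pos >= 1L) n_low_t[seq_len(pos)] <- n_low_t[seq_len(pos)] + 1
      if (e_sorted[j] == 1L) {
        k <- match(t_sorted[j], grid)
        d_low_t[k] <- d_low_t[k] + 1
      }
    }
    last <- cut_i
    frac <- cut_i / n
    if (frac < min_frac || frac > 1 - min_frac) next
    p <- n_low_t / n_risk
    U <- sum(d_low_t - d_tot * p)
    vterm <- ifelse(n_risk > 1,
                    d_tot * p * (1 - p) * (n_risk - d_tot) / (n_risk - 1), 0)
    V <- sum(vterm)
    chi <- if (V > 0) U^2 / V else 0
    res_thr <- c(res_thr, (m_sorted[cut_i] + m_sorted[cut_i + 1L]) / 2)
    res_frac <- c(res_frac, frac)
    res_chi <- c(res_chi, chi)
  }
  if (length(res_thr) == 0L) {
    mc_abort("no candidate satisfies the `min_frac` constraint.")
  }
  tibble(threshold = res_thr, frac_low = res_frac, chisq = res_chi)
}

#' Data-driven survival cutpoint by log-rank maximization
#'
#' Scans every admissible split of the continuous marker and selects the
#' threshold maximizing the two-group log-rank chi-square, the standard
#' first-split criterion of survival recursive partitioning. Seeded k-fold
#' cross-validation then checks whether the split generalizes: within each
#' fold a threshold is re-derived on the training cases, a one-covariate
#' Cox model fitted, and the held-out partial-likelihood deviance compared
#' with the null; `cv_supported` is `TRUE` when the total held-out deviance
#' reduction exceeds one standard error of the per-fold reductions (the
#' 1-SE convention of recursive-partitioning pruning), so noise splits are
#' rarely endorsed.
#'
#' @param data Survival records plus the marker column.
#' @param marker Column of continuous (log-scale) marker values (tidy-eval).
#' @param time,event Time and event columns (defaults `time_months`,
#'   `event`).
#' @param folds Cross-validation folds (default 10).
#' @param min_frac Minimum fraction of the cohort on each side of a
#'   candidate split (default 0.10, keeping discovered groups clinically
#'   non-trivial).
#' @param seed Integer seed for the fold assignment.
#' @param platform Optional platform label carried along for transfer
#'   checks.
#'
#' @return A `cutpoint_result`: `threshold`, `frac_low`, `split_statistic`,
#'   `cv_supported`, plus the full scan profile. `tidy()` returns the scan
#'   profile; `glance()` the selected split.
#' @export
datadriven_cutpoint <- function(data, marker, time = time_months,
                                event = event, folds = 10L, min_frac = 0.10,
                                seed, platform = NULL) {
  m <- dplyr::pull(data, {{ marker }})
  t <- dplyr::pull(data, {{ time }})
  e <- dplyr::pull(data, {{ event }})
  if (folds < 2L) mc_abort("`folds` must be at least 2.")
  if (min_frac <= 0 || min_frac >= 0.5) {
    mc_abort("`min_frac` must be in (0, 0.5).")
  }
  seed <- check_seed(seed)
  scan <- logrank_scan(t, e, m, min_frac)
  best <- scan[which.max(scan$chisq), ]

  fold_id <- withr::with_seed(
    seed, sample(rep(seq_len(folds), length.out = length(m)))
  )
  dev_red <- vapply(seq_len(folds), function(k) {
    tr <- fold_id != k
    red <- tryCatch({
      sc <- logrank_scan(t[tr], e[tr], m[tr], min_frac)
      thr_k <- sc$threshold[which.max(sc$chisq)]
      g_tr <- as.integer(m[tr] <= thr_k)
      g_te <- as.integer(m[!tr] <= thr_k)
      if (length(unique(g_te)) < 2L || sum(e[!tr]) == 0L) return(0)
      # infinite train-fold coefficients are handled by the guard below
      fit_tr <- suppressWarnings(coxph(Surv(t[tr], e[tr]) ~ g_tr,
                                       ties = "efron"))
      beta <- unname(coef(fit_tr))
      if (!is.finite(beta)) return(0)
      # with iter.max = 0 coxph reports the partial likelihood at `init`,
      # so evaluate at the training beta and at the null separately
      pl_at <- function(b) {
        coxph(Surv(t[!tr], e[!tr]) ~ g_te, ties = "efron", init = b,
              control = coxph.control(iter.max = 0))$loglik[1]
      }
      2 * (pl_at(beta) - pl_at(0))
    }, error = function(cond) 0)
    red
  }, numeric(1))

  # 1-SE support rule: total reduction must beat one SE of the fold sums
  se_total <- sd(dev_red) * sqrt(length(dev_red))
  structure(
    list(
      threshold = best$threshold,
      frac_low = best$frac_low,
      split_statistic = best$chisq,
      cv_supported = sum(dev_red) > max(se_total, 0, na.rm = TRUE),
      cv_deviance_reduction = sum(dev_red),
      folds = as.integer(folds),
      min_frac = min_frac,
      platform = platform,
      scan = scan,
      n = length(m)
    ),
    class = "cutpoint_result"
  )
}

#' @export
print.cutpoint_result <- function(x, ...) {
  cat(sprintf(
    "<cutpoint_result>%s threshold = %.4f (low fraction %.1f%%), log-rank chi-square = %.2f, cv_supported = %s\n",
    if (is.null(x$platform)) "" else paste0(" [", x$platform, "]"),
    x$threshold, 100 * x$frac_low, x$split_statistic, x$cv_supported
  ))
  invisible(x)
}

#' @method tidy cutpoint_result
#' @export
tidy.cutpoint_result <- function(x, ...) x$scan

#' @method glance cutpoint_result
#' @export
glance.cutpoint_result <- function(x, ...) {
  tibble(
    threshold = x$threshold, frac_low = x$frac_low,
    split_statistic = x$split_statistic, cv_supported = x$cv_supported,
    cv_deviance_reduction = x$cv_deviance_reduction,
    folds = x$folds, min_frac = x$min_frac,
    platform = x$platform %||% NA_character_, n = x$n
  )
}

#' Percentile cutpoint
#'
#' The k-th order statistic with `k = ceiling(pct/100 * n)`, so that at
#' least `pct` percent of cases fall at or below the returned threshold.
#' Used to transfer a previously established percentile-defined cutpoint
#' (for example, a published 15th-percentile threshold) onto new data.
#'
#' @param x Numeric marker values.
#' @param pct Percentile in (0, 100).
#' @return The threshold value.
#' @export
#' @examples
#' percentile_cutpoint(1:20, 15)  # 3
percentile_cutpoint <- function(x, pct) {
  if (length(x) == 0L) mc_abort("empty marker vector.")
  if (pct <= 0 || pct >= 100) mc_abort("`pct` must be in (0, 100).")
  sort(x)[ceiling(pct / 100 * length(x))]
}

#' Transfer a cutpoint across platforms
#'
#' Maps a threshold found on one platform's log scale onto the other
#' platform through the fitted linear conversion:
#' `threshold' = alpha + beta * threshold`. When the threshold comes from
#' [datadriven_cutpoint()] with a platform label, the label must match the
#' calibration model's source platform.
#'
#' @param threshold A numeric threshold or a `cutpoint_result`.
#' @param model A [calibration()] model mapping the threshold's platform
#'   onto the target platform.
#' @return The transferred numeric threshold.
#' @export
transfer_cutpoint <- function(threshold, model) {
  stopifnot(inherits(model, "calibration"))
  if (inherits(threshold, "cutpoint_result")) {
    if (!is.null(threshold$platform) && !is.null(model$from_platform) &&
        !identical(threshold$platform, model$from_platform)) {
      mc_abort(sprintf(
        "platform mismatch: cutpoint is on '%s' but the model converts from '%s'.",
        threshold$platform, model$from_platform
      ))
    }
    threshold <- threshold$threshold
  }
  apply_calibration(model, threshold)
}

#' Dichotomize a continuous marker at a threshold
#'
#' Low means at or below the threshold (the threshold value itself is
#' classified low).
#'
#' @param x Numeric marker values.
#' @param threshold Numeric threshold (or a `cutpoint_result`).
#' @return A factor with levels `low`, `high`.
#' @export
dichotomize <- function(x, threshold) {
  if (inherits(threshold, "cutpoint_result")) threshold <- threshold$threshold
  factor(ifelse(x <= threshold, "low", "high"), levels = .mc_levels)
}
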