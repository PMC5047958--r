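#' Three-group stratification by fluorescence class and chromogen score
#'
#' Combines the dichotomized fluorescence marker class with pathologist
#' chromogen positivity (percent positive >= 1) into the three clinically
#' meaningful strata: IF-low/DAB-low, IF-high/DAB-low, IF-high/DAB-high.
#' The fourth combination (IF-low yet DAB-high) contradicts the greater
#' sensitivity of fluorescence; it is excluded from the survival comparison
#' but reported with its count.
#'
#' @param data Survival records joined with the classifications.
#' @param if_class Column of `"low"`/`"high"` fluorescence labels
#'   (tidy-eval).
#' @param chromogen_percent Column of percent-positive chromogen scores.
#' @param time,event Time and event columns (defaults `time_months`,
#'   `event`).
#'
#' @return A list: `counts` (per-stratum tibble including the excluded
#'   combination), `km` (per-stratum Kaplan-Meier table), `logrank`
#'   (test across the strata present).
#' @export
chromogen_stratify <- function(data, if_class, chromogen_percent,
                               time = time_months, event = event) {
  d <- mutate(
    data,
    .if_class = as.character({{ if_class }}),
    .dab = ifelse({{ chromogen_percent }} >= 1, "high", "low"),
    .stratum = dplyr::case_when(
      .data$.if_class == "low" & .data$.dab == "low" ~ "IF_low_DAB_low",
      .data$.if_class == "high" & .data$.dab == "low" ~ "IF_high_DAB_low",
      .data$.if_class == "high" & .data$.dab == "high" ~ "IF_high_DAB_high",
      TRUE ~ "IF_low_DAB_high"
    )
  )
  counts <- d %>%
    count(.data$.stratum, name = "n") %>%
    rename(stratum = ".stratum") %>%
    mutate(excluded = .data$stratum == "IF_low_DAB_high")
  keep <- filter(d, .data$.stratum != "IF_low_DAB_high")
  km <- km_fit(keep, group = .stratum, time = {{ time }}, event = {{ event }})
  lr <- if (length(unique(keep$.stratum)) >= 2L) {
    logrank_test(keep, group = .stratum, time = {{ time }},
                 event = {{ event }})
  } else {
    tibble(chisq = NA_real_, df = NA_integer_, p_value = NA_real_,
           n = nrow(keep))
  }
  list(counts = counts, km = km, logrank = lr)
}

# survival analyses for one classification of the analysis cohort
classification_outcomes <- function(data, class_col, label) {
  d <- mutate(data, .class = factor(.data[[class_col]], levels = .mc_levels))
  km <- km_fit(d, group = .class)
  lr <- logrank_test(d, group = .class)
  covs <- ".class"
  if ("pr_status" %in% names(d) &&
      length(unique(stats::na.omit(d$pr_status))) > 1L) {
    covs <- c("pr_status", ".class")
  }
  # marker class enters with "high" as the reference so the reported HR is
  # low-vs-high, matching how the risk group is described
  d$.class <- stats::relevel(d$.class, ref = "high")
  cox <- cox_fit(d, covariates = covs)
  hr <- tidy(cox) %>%
    mutate(term = ifelse(.data$term == ".class", "marker_class", .data$term),
           classification = label)
  list(label = label, km = km, logrank = lr, cox = cox, hr = hr)
}

#' Run the full cross-platform validation pipeline
#'
#' Executes the complete analysis sequence on a measurements + clinical
#' table pair: log transform, case pairing, bidirectional difference-vs-mean
#' calibration, concordance before/after calibration, data-driven cutpoint
#' per platform, cutpoint transfer in both directions, cross-tabulation with
#' kappa of native-vs-transferred classifications, Kaplan-Meier/log-rank/Cox
#' per classification, AUC(t) series per platform, and (when a chromogen
#' column is present) the three-group fluorescence/chromogen stratification.
#'
#' @param measurements Measurements tibble (columns `case_id`,
#'   `platform_id`, `score`) or a path to one.
#' @param clinical Clinical tibble (columns `case_id`, `time_months`,
#'   `event`, optional covariates and `chromogen_percent`) or a path.
#' @param platform_x,platform_y The two platform labels; `x` is the
#'   reference platform of the first conversion equation.
#' @param folds,min_frac Cutpoint search settings (see
#'   [datadriven_cutpoint()]).
#' @param horizons Horizons (months) for the AUC(t) series; default years
#'   1 through 12.
#' @param seed Integer seed (drives the cross-validated cutpoint search).
#' @param conf_level Confidence level used throughout.
#'
#' @return A `marker_report` object; see [write_report()].
#' @export
run_pipeline <- function(measurements, clinical, platform_x, platform_y,
                         folds = 10L, min_frac = 0.10,
                         horizons = seq(12, 144, by = 12), seed,
                         conf_level = 0.95) {
  seed <- check_seed(seed)
  if (is.character(measurements)) measurements <- read_measurements(measurements)
  else measurements <- validate_measurements(measurements)
  if (is.character(clinical)) clinical <- read_clinical(clinical)
  else clinical <- validate_clinical(clinical)

  attrition <- list(n_measurement_rows = nrow(measurements),
                    n_clinical = nrow(clinical))

  meas <- log_transform(measurements)
  paired <- pair_cases(meas, platform_x, platform_y, quiet = TRUE)
  attrition$n_paired <- nrow(paired)
  attrition$n_dropped_x_only <- attr(paired, "n_dropped_x")
  attrition$n_dropped_y_only <- attr(paired, "n_dropped_y")

  # --- calibration, both directions ------------------------------------
  fit_xy <- ba_regression(paired)
  model_xy <- conversion_from_ba(fit_xy)
  swapped <- paired %>% rename(x = "y", y = "x")
  attr(swapped, "platform_x") <- platform_y
  attr(swapped, "platform_y") <- platform_x
  fit_yx <- ba_regression(swapped)
  model_yx <- conversion_from_ba(fit_yx)
  loa_xy <- limits_of_agreement(fit_xy, level = conf_level)

  ccc_raw <- ccc(paired, conf_level = conf_level)
  ccc_x_cal <- ccc(
    mutate(paired, x_cal = apply_calibration(model_xy, .data$x)),
    x_cal, y, conf_level = conf_level
  )
  ccc_y_cal <- ccc(
    mutate(paired, y_cal = apply_calibration(model_yx, .data$y)),
    y_cal, x, conf_level = conf_level
  )

  # --- outcome cohort ---------------------------------------------------
  cohort <- inner_join(paired, clinical, by = "case_id")
  attrition$n_outcome <- nrow(cohort)
  if (nrow(cohort) < 3L) {
    mc_abort("stage outcome_cohort: fewer than 3 paired cases with outcome data.")
  }

  cp_x <- datadriven_cutpoint(cohort, x, folds = folds, min_frac = min_frac,
                              seed = seed, platform = platform_x)
  cp_y <- datadriven_cutpoint(cohort, y, folds = folds, min_frac = min_frac,
                              seed = seed + 1L, platform = platform_y)
  thr_x_on_y <- transfer_cutpoint(cp_x, model_xy)
  thr_y_on_x <- transfer_cutpoint(cp_y, model_yx)

  cohort <- mutate(
    cohort,
    class_x_native = dichotomize(.data$x, cp_x$threshold),
    class_y_transferred = dichotomize(.data$y, thr_x_on_y),
    class_y_native = dichotomize(.data$y, cp_y$threshold),
    class_x_transferred = dichotomize(.data$x, thr_y_on_x)
  )

  tab_xy <- cross_tabulate(cohort, class_x_native, class_y_transferred)
  tab_yx <- cross_tabulate(cohort, class_x_transferred, class_y_native)
  agreement <- list(
    native_x_vs_transferred_y = list(
      table = tab_xy,
      percent = percent_agreement(tab_xy),
      kappa = cohens_kappa(tab_xy, conf_level = conf_level)
    ),
    transferred_x_vs_native_y = list(
      table = tab_yx,
      percent = percent_agreement(tab_yx),
      kappa = cohens_kappa(tab_yx, conf_level = conf_level)
    )
  )

  outcomes <- list(
    x_native = classification_outcomes(cohort, "class_x_native",
                                       paste0(platform_x, " (data-driven)")),
    y_transferred = classification_outcomes(
      cohort, "class_y_transferred",
      paste0(platform_y, " (transferred from ", platform_x, ")")),
    y_native = classification_outcomes(cohort, "class_y_native",
                                       paste0(platform_y, " (data-driven)")),
    x_transferred = classification_outcomes(
      cohort, "class_x_transferred",
      paste0(platform_x, " (transferred from ", platform_y, ")"))
  )

  roc <- list(
    x = auc_series(cohort, x, horizons = horizons),
    y = auc_series(cohort, y, horizons = horizons)
  )

  chromogen <- NULL
  if ("chromogen_percent" %in% names(cohort)) {
    chromogen <- chromogen_stratify(cohort, class_y_native,
                                    chromogen_percent)
  }

  structure(
    list(
      platforms = c(x = platform_x, y = platform_y),
      attrition = attrition,
      calibration = list(
        fit_xy = fit_xy, model_xy = model_xy,
        fit_yx = fit_yx, model_yx = model_yx,
        loa_xy = loa_xy,
        ccc_raw = ccc_raw, ccc_x_cal = ccc_x_cal, ccc_y_cal = ccc_y_cal
      ),
      cutpoints = list(x = cp_x, y = cp_y,
                       x_on_y = thr_x_on_y, y_on_x = thr_y_on_x),
      agreement = agreement,
      outcomes = outcomes,
      roc = roc,
      chromogen = chromogen,
      cohort = cohort,
      config = list(folds = folds, min_frac = min_frac,
                    horizons = horizons, seed = seed,
                    conf_level = conf_level),
      version = as.character(utils::packageVersion("markercal"))
    ),
    class = "marker_report"
  )
}

#' @export
print.marker_report <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}

fmt_or_na <- function(fmt, x) {
  ifelse(is.na(x), "NA", sprintf(fmt, x))
}

#' @export
format.marker_report <- function(x, ...) {
  px <- x$platforms[["x"]]; py <- x$platforms[["y"]]
  cal <- x$calibration
  out <- c(
    "== markercal pipeline report ==",
    sprintf("version: %s", x$version),
    sprintf("seed: %d", x$config$seed),
    sprintf("platforms: x=%s y=%s", px, py),
    sprintf("config: folds=%d min_frac=%.2f conf_level=%.2f horizons=%s",
            x$config$folds, x$config$min_frac, x$config$conf_level,
            paste(x$config$horizons, collapse = ",")),
    "",
    "-- cohort accounting --",
    sprintf("measurement rows: %d", x$attrition$n_measurement_rows),
    sprintf("clinical cases: %d", x$attrition$n_clinical),
    sprintf("paired cases: %d (dropped: %d only on %s, %d only on %s)",
            x$attrition$n_paired, x$attrition$n_dropped_y_only, px,
            x$attrition$n_dropped_x_only, py),
    sprintf("outcome cohort: %d", x$attrition$n_outcome),
    "",
    "-- calibration --",
    sprintf("conversion: %s = %.2f + %.2f x %s", py, cal$model_xy$alpha,
            cal$model_xy$beta, px),
    sprintf("conversion: %s = %.2f + %.2f x %s", px, cal$model_yx$alpha,
            cal$model_yx$beta, py),
    sprintf("difference-vs-mean fit (%s->%s): a=%.4f b=%.4f resid_sd=%.4f n=%d",
            px, py, cal$fit_xy$intercept_a, cal$fit_xy$slope_b,
            cal$fit_xy$resid_sd, cal$fit_xy$n),
    sprintf("limits of agreement (lower/upper intercept at slope %.4f): %.4f / %.4f",
            cal$loa_xy$slope[1], cal$loa_xy$intercept[1],
            cal$loa_xy$intercept[2]),
    sprintf("CCC raw: %.3f (%.3f, %.3f)", cal$ccc_raw$rho_c,
            cal$ccc_raw$ci_low, cal$ccc_raw$ci_high),
    sprintf("CCC %s-calibrated vs %s: %.3f (%.3f, %.3f)", px, py,
            cal$ccc_x_cal$rho_c, cal$ccc_x_cal$ci_low, cal$ccc_x_cal$ci_high),
    sprintf("CCC %s-calibrated vs %s: %.3f (%.3f, %.3f)", py, px,
            cal$ccc_y_cal$rho_c, cal$ccc_y_cal$ci_low, cal$ccc_y_cal$ci_high),
    "",
    "-- cutpoints --",
    sprintf("%s data-driven: threshold=%.4f low=%.1f%% chi2=%.2f cv_supported=%s",
            px, x$cutpoints$x$threshold, 100 * x$cutpoints$x$frac_low,
            x$cutpoints$x$split_statistic, x$cutpoints$x$cv_supported),
    sprintf("%s data-driven: threshold=%.4f low=%.1f%% chi2=%.2f cv_supported=%s",
            py, x$cutpoints$y$threshold, 100 * x$cutpoints$y$frac_low,
            x$cutpoints$y$split_statistic, x$cutpoints$y$cv_supported),
    sprintf("transferred %s->%s: %.4f", px, py, x$cutpoints$x_on_y),
    sprintf("transferred %s->%s: %.4f", py, px, x$cutpoints$y_on_x),
    "",
    "-- agreement of classifications --"
  )
  for (nm in names(x$agreement)) {
    a <- x$agreement[[nm]]
    out <- c(out,
      sprintf("%s: counts (ll,lh,hl,hh) = %d,%d,%d,%d of %d", nm,
              a$table$n_ll, a$table$n_lh, a$table$n_hl, a$table$n_hh,
              a$table$total),
      sprintf("%s: agreement = %.1f%%; kappa = %.3f (%s, %s); p = %.3g", nm,
              a$percent$agree_percent, a$kappa$kappa,
              fmt_or_na("%.3f", a$kappa$ci_low),
              fmt_or_na("%.3f", a$kappa$ci_high), a$kappa$p_value)
    )
  }
  out <- c(out, "", "-- survival by classification --")
  for (o in x$outcomes) {
    hr_row <- o$hr[o$hr$term == "marker_class" & o$hr$level == "low", ]
    out <- c(out,
      sprintf("%s: log-rank chi2=%.2f p=%.3g; low-vs-high HR=%s (%s-%s) p=%s n_low=%d%s",
              o$label, o$logrank$chisq, o$logrank$p_value,
              fmt_or_na("%.2f", hr_row$hr), fmt_or_na("%.2f", hr_row$ci_low),
              fmt_or_na("%.2f", hr_row$ci_high),
              fmt_or_na("%.3g", hr_row$p_value), hr_row$n,
              if (hr_row$separation) " [separation]" else "")
    )
  }
  out <- c(out, "", "-- AUC(t) --")
  for (side in c("x", "y")) {
    s <- x$roc[[side]]
    out <- c(out, sprintf(
      "%s: %s", x$platforms[[side]],
      paste(sprintf("%gm=%s", s$horizon_months, fmt_or_na("%.3f", s$auc)),
            collapse = " ")
    ))
  }
  if (!is.null(x$chromogen)) {
    out <- c(out, "", "-- chromogen stratification --")
    cc <- x$chromogen$counts
    out <- c(out,
      paste("counts:", paste(sprintf("%s=%d%s", cc$stratum, cc$n,
                                     ifelse(cc$excluded, " (excluded)", "")),
                             collapse = " ")),
      sprintf("log-rank across strata: chi2=%s df=%s p=%s",
              fmt_or_na("%.2f", x$chromogen$logrank$chisq),
              fmt_or_na("%d", as.numeric(x$chromogen$logrank$df)),
              fmt_or_na("%.3g", x$chromogen$logrank$p_value))
    )
  }
  out
}

#' Write a pipeline report to a text file
#'
#' Serialization is deterministic: the same inputs, configuration and seed
#' produce byte-identical files.
#'
#' @param report A `marker_report` from [run_pipeline()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "marker_report"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(format(report), con = con, sep = "\n")
  invisible(path)
}
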