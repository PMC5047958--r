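#' Lin's concordance correlation coefficient
#'
#' Agreement of paired continuous measurements with the identity line:
#' `rho_c = 2 s_xy / (s_x^2 + s_y^2 + (mean_x - mean_y)^2)` using
#' n-denominator (population) sample moments, the original estimator form.
#' The 95% confidence interval is obtained on the Fisher z scale with the
#' standard asymptotic variance and back-transformed.
#'
#' @param data A data frame holding the paired measurements.
#' @param x,y Columns with the paired values (tidy-eval).
#' @param conf_level Confidence level for the interval.
#'
#' @return A one-row tibble: `rho_c`, `ci_low`, `ci_high`, `n`.
#' @export
#' @examples
#' ccc(tibble::tibble(a = c(0, 1, 2), b = c(1, 2, 3)), a, b)  # 4/7
ccc <- function(data, x = x, y = y, conf_level = 0.95) {
  xv <- dplyr::pull(data, {{ x }})
  yv <- dplyr::pull(data, {{ y }})
  keep <- is.finite(xv) & is.finite(yv)
  xv <- xv[keep]; yv <- yv[keep]
  n <- length(xv)
  if (n < 3L) mc_abort("at least 3 complete pairs are required.")
  mx <- mean(xv); my <- mean(yv)
  sx2 <- mean((xv - mx)^2)
  sy2 <- mean((yv - my)^2)
  if (sx2 == 0 || sy2 == 0) mc_abort("zero variance in one of the vectors.")
  sxy <- mean((xv - mx) * (yv - my))
  rho_c <- 2 * sxy / (sx2 + sy2 + (mx - my)^2)
  r <- sxy / sqrt(sx2 * sy2)
  u <- (mx - my) / (sx2 * sy2)^0.25  # location-shift component
  # Lin's asymptotic variance of the Fisher z transform of rho_c
  if (abs(rho_c) >= 1 || r == 0) {
    ci <- c(rho_c, rho_c)
  } else {
    sz2 <- ((1 - r^2) * rho_c^2 / ((1 - rho_c^2) * r^2) +
              2 * rho_c^3 * (1 - rho_c) * u^2 / (r * (1 - rho_c^2)^2) -
              rho_c^4 * u^4 / (2 * r^2 * (1 - rho_c^2)^2)) / (n - 2)
    z <- atanh(rho_c) + c(-1, 1) * qnorm((1 + conf_level) / 2) * sqrt(sz2)
    ci <- tanh(z)
  }
  tibble(rho_c = rho_c, ci_low = ci[1], ci_high = ci[2], n = n)
}

#' Replicate coefficient of variation
#'
#' Per-case coefficient of variation (replicate sd over replicate mean,
#' sd with the n-1 denominator), aggregated across cases as the
#' root-mean-square of the per-case values and reported in percent. RMS
#' aggregation is used because per-case CVs estimate a common relative
#' noise scale whose natural pooling is on the variance scale.
#'
#' @param data A long data frame of replicate scores.
#' @param case Column identifying the case (tidy-eval; default `case_id`).
#' @param value Column with the replicate score (default `score`).
#'
#' @return A one-row tibble: `cov_percent`, `n_cases`.
#' @export
#' @examples
#' d <- tibble::tibble(case_id = c(1, 1), score = c(100, 102))
#' coefficient_of_variation(d)  # ~1.4%
coefficient_of_variation <- function(data, case = case_id, value = score) {
  d <- dplyr::transmute(data, case = {{ case }}, value = {{ value }})
  if (any(!is.finite(d$value) | d$value <= 0)) {
    mc_abort("all replicate values must be positive and finite.")
  }
  per_case <- d %>%
    group_by(.data$case) %>%
    summarise(n_rep = dplyr::n(), cv = sd(.data$value) / mean(.data$value),
              .groups = "drop")
  if (any(per_case$n_rep < 2L)) {
    mc_abort("every case needs at least 2 replicates.")
  }
  tibble(
    cov_percent = sqrt(mean(per_case$cv^2)) * 100,
    n_cases = nrow(per_case)
  )
}

#' 2x2 agreement table for dichotomized classifications
#'
#' Cross-classifies paired low/high labels from two platforms.
#' `agreement_table()` builds one directly from the four cell counts
#' (rows = platform 1, columns = platform 2); [cross_tabulate()] builds one
#' from per-case labels.
#'
#' @param n_ll,n_lh,n_hl,n_hh Cell counts: first index the platform-1 class,
#'   second the platform-2 class (`l` = low, `h` = high).
#'
#' @return An `agreement_table` object.
#' @export
#' @examples
#' agreement_table(38, 3, 6, 146)
agreement_table <- function(n_ll, n_lh, n_hl, n_hh) {
  cells <- c(n_ll = n_ll, n_lh = n_lh, n_hl = n_hl, n_hh = n_hh)
  if (any(cells < 0) || any(cells != round(cells))) {
    mc_abort("cell counts must be nonnegative integers.")
  }
  total <- sum(cells)
  if (total < 1) mc_abort("the table must contain at least one pair.")
  structure(
    list(n_ll = n_ll, n_lh = n_lh, n_hl = n_hl, n_hh = n_hh, total = total),
    class = "agreement_table"
  )
}

#' @rdname agreement_table
#' @param data A data frame with the two label columns.
#' @param x,y Columns of `"low"`/`"high"` labels (tidy-eval).
#' @export
cross_tabulate <- function(data, x = x, y = y) {
  lx <- as.character(dplyr::pull(data, {{ x }}))
  ly <- as.character(dplyr::pull(data, {{ y }}))
  bad <- setdiff(unique(c(lx, ly)), .mc_levels)
  if (length(bad) > 0L) {
    mc_abort(sprintf("labels outside {low, high}: %s",
                     paste(bad, collapse = ", ")))
  }
  agreement_table(
    n_ll = sum(lx == "low" & ly == "low"),
    n_lh = sum(lx == "low" & ly == "high"),
    n_hl = sum(lx == "high" & ly == "low"),
    n_hh = sum(lx == "high" & ly == "high")
  )
}

#' @export
print.agreement_table <- function(x, ...) {
  m <- as.matrix(x)
  cat("<agreement_table> rows: platform 1, cols: platform 2\n")
  print(m)
  invisible(x)
}

#' @export
as.matrix.agreement_table <- function(x, ...) {
  m <- matrix(c(x$n_ll, x$n_lh, x$n_hl, x$n_hh), nrow = 2, byrow = TRUE,
              dimnames = list(c("low", "high"), c("low", "high")))
  m
}

#' @method tidy agreement_table
#' @export
tidy.agreement_table <- function(x, ...) {
  tidyr::expand_grid(class_1 = .mc_levels, class_2 = .mc_levels) %>%
    mutate(n = c(x$n_ll, x$n_lh, x$n_hl, x$n_hh))
}

#' @method as_tibble agreement_table
#' @export
as_tibble.agreement_table <- function(x, ...) tidy(x)

#' Percent agreement of a 2x2 table
#'
#' @param table An [agreement_table()].
#' @return A one-row tibble: `agree_fraction`, `agree_percent`, `total`.
#' @export
#' @examples
#' percent_agreement(agreement_table(38, 3, 6, 146))  # 95.34%
percent_agreement <- function(table) {
  stopifnot(inherits(table, "agreement_table"))
  frac <- (table$n_ll + table$n_hh) / table$total
  tibble(agree_fraction = frac, agree_percent = frac * 100,
         total = table$total)
}

#' Cohen's kappa for a 2x2 agreement table
#'
#' `kappa = (p_o - p_e) / (1 - p_e)` with chance agreement `p_e` from the
#' marginal products. The confidence interval uses the large-sample standard
#' error under the alternative, `sqrt(p_o (1 - p_o) / (n (1 - p_e)^2))`;
#' the two-sided p-value for kappa = 0 uses the Fleiss standard error under
#' the null.
#'
#' @param table An [agreement_table()].
#' @param conf_level Confidence level.
#' @return A one-row tibble: `kappa`, `ci_low`, `ci_high`, `p_value`, `n`.
#' @export
#' @examples
#' cohens_kappa(agreement_table(38, 3, 6, 146))  # kappa 0.864
cohens_kappa <- function(table, conf_level = 0.95) {
  stopifnot(inherits(table, "agreement_table"))
  n <- table$total
  p_o <- (table$n_ll + table$n_hh) / n
  p_row <- c(table$n_ll + table$n_lh, table$n_hl + table$n_hh) / n
  p_col <- c(table$n_ll + table$n_hl, table$n_lh + table$n_hh) / n
  p_e <- sum(p_row * p_col)
  if (p_e >= 1) {
    mc_abort("degenerate marginals (p_e = 1): kappa undefined.")
  }
  kappa <- (p_o - p_e) / (1 - p_e)
  one_sided <- any(p_row == 0) || any(p_col == 0)
  if (one_sided) {
    # a rater never used one category: the large-sample CI is not valid
    ci <- c(NA_real_, NA_real_)
  } else {
    se_alt <- sqrt(p_o * (1 - p_o) / (n * (1 - p_e)^2))
    ci <- kappa + c(-1, 1) * qnorm((1 + conf_level) / 2) * se_alt
    ci <- pmin(ci, 1)
  }
  se_null <- sqrt(p_e + p_e^2 - sum(p_row * p_col * (p_row + p_col))) /
    ((1 - p_e) * sqrt(n))
  p_value <- 2 * pnorm(-abs(kappa / se_null))
  tibble(kappa = kappa, ci_low = ci[1], ci_high = ci[2],
         p_value = p_value, n = n)
}
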