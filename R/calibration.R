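#' Log-transform raw intensity scores
#'
#' Applies the natural log to a positive raw score column. Nonpositive
#' scores are a domain violation (the log-linear measurement model is
#' undefined there) and are rejected with the offending cases named rather
#' than silently offset.
#'
#' @param data A data frame of intensity records with a `case_id` column.
#' @param score Column holding the raw score (tidy-eval; default `score`).
#'
#' @return `data` with a `log_score` column added (or overwritten).
#' @export
#' @examples
#' log_transform(tibble::tibble(case_id = "a", score = exp(2)))
log_transform <- function(data, score = score) {
  s <- dplyr::pull(data, {{ score }})
  bad <- which(!is.finite(s) | s <= 0)
  if (length(bad) > 0L) {
    ids <- if ("case_id" %in% names(data)) {
      paste(utils::head(data$case_id[bad], 5L), collapse = ", ")
    } else {
      paste("rows", paste(utils::head(bad, 5L), collapse = ", "))
    }
    mc_abort(sprintf(
      "nonpositive score for %d case(s): %s", length(bad), ids
    ))
  }
  mutate(data, log_score = log({{ score }}))
}

#' Pair cases measured on two platforms
#'
#' Inner-joins the two platforms' records on `case_id`, returning one row
#' per case with both log scores side by side. Cases present on only one
#' platform are dropped; the counts are recorded in the `n_dropped_x` /
#' `n_dropped_y` attributes and reported via a message.
#'
#' @param measurements A long data frame of intensity records with columns
#'   `case_id`, `platform_id` and `log_score` (see [log_transform()]).
#' @param platform_x,platform_y The two platform labels; `x` is the
#'   reference axis of the difference-vs-mean regression.
#' @param quiet Suppress the drop-count message.
#'
#' @return A tibble `case_id`, `x`, `y` of paired log scores.
#' @export
pair_cases <- function(measurements, platform_x, platform_y, quiet = FALSE) {
  need <- c("case_id", "platform_id", "log_score")
  if (!all(need %in% names(measurements))) {
    mc_abort("`measurements` needs columns case_id, platform_id, log_score.")
  }
  rx <- filter(measurements, .data$platform_id == platform_x)
  ry <- filter(measurements, .data$platform_id == platform_y)
  if (nrow(rx) == 0L || nrow(ry) == 0L) {
    mc_abort("both platforms must contribute at least one record.")
  }
  for (side in list(list(rx, platform_x), list(ry, platform_y))) {
    dup <- side[[1]]$case_id[duplicated(side[[1]]$case_id)]
    if (length(dup) > 0L) {
      mc_abort(sprintf(
        "duplicate case_id on platform '%s': %s (ambiguous pairing)",
        side[[2]], paste(unique(utils::head(dup, 5L)), collapse = ", ")
      ))
    }
  }
  paired <- inner_join(
    select(rx, "case_id", x = "log_score"),
    select(ry, "case_id", y = "log_score"),
    by = "case_id"
  )
  if (nrow(paired) == 0L) mc_abort("no overlapping cases between platforms.")
  n_dx <- nrow(rx) - nrow(paired)
  n_dy <- nrow(ry) - nrow(paired)
  if (!quiet && (n_dx > 0L || n_dy > 0L)) {
    message(sprintf(
      "pair_cases: dropped %d case(s) missing on '%s', %d missing on '%s'; %d pairs retained.",
      n_dy, platform_x, n_dx, platform_y, nrow(paired)
    ))
  }
  attr(paired, "n_dropped_x") <- n_dx
  attr(paired, "n_dropped_y") <- n_dy
  attr(paired, "platform_x") <- platform_x
  attr(paired, "platform_y") <- platform_y
  paired
}

#' Difference-vs-mean regression (extended Bland-Altman fit)
#'
#' Ordinary least squares of the paired differences `D = y - x` on the pair
#' averages `A = (x + y) / 2`, the regression at the heart of the extended
#' Bland-Altman assay comparison for assays whose differences trend with
#' level. Its coefficients determine the linear conversion equation between
#' the platforms under the latent-true-value measurement model (see
#' [conversion_from_ba()]).
#'
#' @param data A paired data frame (see [pair_cases()]).
#' @param x,y Columns holding the paired log scores (tidy-eval).
#'
#' @return A `ba_fit` object with fields `intercept_a`, `slope_b`,
#'   `resid_sd`, `n`, and the platform labels when `data` carries them.
#' @export
#' @examples
#' d <- tibble::tibble(x = 1:10 / 2, y = 0.43 + 0.95 * (1:10 / 2))
#' ba_regression(d)
ba_regression <- function(data, x = x, y = y) {
  xv <- dplyr::pull(data, {{ x }})
  yv <- dplyr::pull(data, {{ y }})
  keep <- is.finite(xv) & is.finite(yv)
  xv <- xv[keep]; yv <- yv[keep]
  n <- length(xv)
  if (n < 3L) mc_abort("at least 3 complete pairs are required.")
  A <- (xv + yv) / 2
  D <- yv - xv
  if (var(A) == 0) mc_abort("pair averages are constant; slope undefined.")
  fit <- lm(D ~ A)
  # a zero-residual fit is legitimate here (noise-free platforms); silence
  # summary.lm's perfect-fit warning
  sigma <- withCallingHandlers(
    summary(fit)$sigma,
    warning = function(w) {
      if (grepl("perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  res <- structure(
    list(
      intercept_a = unname(coef(fit)[1]),
      slope_b = unname(coef(fit)[2]),
      resid_sd = sigma,
      n = n,
      platform_x = attr(data, "platform_x"),
      platform_y = attr(data, "platform_y"),
      data = tibble(mean = A, difference = D)
    ),
    class = "ba_fit"
  )
  res
}

#' @export
print.ba_fit <- function(x, ...) {
  cat(sprintf(
    "<ba_fit> difference = %.4f + %.4f * mean  (resid sd %.4f, n = %d)\n",
    x$intercept_a, x$slope_b, x$resid_sd, x$n
  ))
  invisible(x)
}

#' @method tidy ba_fit
#' @export
tidy.ba_fit <- function(x, ...) {
  tibble(
    term = c("intercept_a", "slope_b"),
    estimate = c(x$intercept_a, x$slope_b)
  )
}

#' @method glance ba_fit
#' @export
glance.ba_fit <- function(x, ...) {
  tibble(resid_sd = x$resid_sd, n = x$n)
}

#' Conversion equation from a difference-vs-mean fit
#'
#' Inverts the difference-vs-mean algebra: if `y - x = a + b * (x + y) / 2`,
#' then `y = alpha + beta * x` with `alpha = a / (1 - b/2)` and
#' `beta = (1 + b/2) / (1 - b/2)`. The residual sd is propagated by the same
#' `1 / (1 - b/2)` scale factor and stored as `pred_sd`, the half-width
#' basis of the prediction band on the target scale.
#'
#' @param fit A `ba_fit` from [ba_regression()].
#'
#' @return A `calibration` object mapping the x platform onto the y
#'   platform's scale.
#' @export
#' @examples
#' f <- ba_regression(tibble::tibble(x = 1:5, y = 0.43 + 0.95 * (1:5)))
#' conversion_from_ba(f)
conversion_from_ba <- function(fit) {
  stopifnot(inherits(fit, "ba_fit"))
  denom <- 1 - fit$slope_b / 2
  if (abs(denom) < .Machine$double.eps^0.5) {
    mc_abort("degenerate fit: slope_b = 2 leaves the conversion undefined.")
  }
  new_calibration(
    alpha = fit$intercept_a / denom,
    beta = (1 + fit$slope_b / 2) / denom,
    pred_sd = fit$resid_sd / abs(denom),
    from_platform = fit$platform_x,
    to_platform = fit$platform_y
  )
}

new_calibration <- function(alpha, beta, pred_sd = NA_real_,
                            from_platform = NULL, to_platform = NULL) {
  if (!is.numeric(beta) || beta <= 0) {
    mc_abort("calibration slope `beta` must be positive.")
  }
  structure(
    list(alpha = alpha, beta = beta, pred_sd = pred_sd,
         from_platform = from_platform, to_platform = to_platform),
    class = "calibration"
  )
}

#' Construct a calibration model directly
#'
#' @param alpha Additive coefficient (log units).
#' @param beta Multiplicative coefficient (must be positive).
#' @param pred_sd Residual/prediction sd on the target scale (optional).
#' @param from_platform,to_platform Platform labels (optional).
#'
#' @return A `calibration` object: target = `alpha + beta * source` on the
#'   log scale.
#' @export
calibration <- function(alpha, beta, pred_sd = NA_real_,
                        from_platform = NULL, to_platform = NULL) {
  new_calibration(alpha, beta, pred_sd, from_platform, to_platform)
}

#' @export
print.calibration <- function(x, ...) {
  from <- x$from_platform %||% "x"
  to <- x$to_platform %||% "y"
  cat(sprintf("<calibration> %s = %.4f + %.4f * %s\n", to, x$alpha, x$beta,
              from))
  invisible(x)
}

#' @method tidy calibration
#' @export
tidy.calibration <- function(x, ...) {
  tibble(
    from_platform = x$from_platform %||% NA_character_,
    to_platform = x$to_platform %||% NA_character_,
    alpha = x$alpha, beta = x$beta, pred_sd = x$pred_sd
  )
}

#' Invert a calibration model
#'
#' Exact algebraic inverse: if `y = alpha + beta * x` then
#' `x = -alpha/beta + (1/beta) * y`, with platforms swapped. Note that
#' refitting the regression in the opposite direction on noisy data gives a
#' slightly different (non-inverse) equation; this function is the exact
#' involution.
#'
#' @param model A `calibration` object.
#' @return The inverse `calibration`.
#' @export
invert_calibration <- function(model) {
  stopifnot(inherits(model, "calibration"))
  new_calibration(
    alpha = -model$alpha / model$beta,
    beta = 1 / model$beta,
    pred_sd = if (is.na(model$pred_sd)) NA_real_ else model$pred_sd / model$beta,
    from_platform = model$to_platform,
    to_platform = model$from_platform
  )
}

#' Apply a calibration model to log-scale values
#'
#' @param model A `calibration` object.
#' @param values Numeric log-scale scores on the model's source platform.
#' @return `alpha + beta * values`.
#' @export
apply_calibration <- function(model, values) {
  stopifnot(inherits(model, "calibration"))
  model$alpha + model$beta * values
}

#' Limits of agreement around the difference-vs-mean regression
#'
#' Lines at the fitted difference plus/minus `z * resid_sd` in
#' difference-vs-mean coordinates, where `z` is the standard normal quantile
#' of `(1 + level) / 2`. With `level = 0.95` these are the bands expected to
#' contain ~95% of between-assay differences.
#'
#' @param fit A `ba_fit`.
#' @param level Coverage fraction in (0, 1).
#'
#' @return A tibble with rows `lower` and `upper`: columns `bound`,
#'   `intercept`, `slope`.
#' @export
limits_of_agreement <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "ba_fit"))
  if (level <= 0 || level >= 1) mc_abort("`level` must be in (0, 1).")
  z <- qnorm((1 + level) / 2)
  tibble(
    bound = c("lower", "upper"),
    intercept = fit$intercept_a + c(-1, 1) * z * fit$resid_sd,
    slope = fit$slope_b
  )
}
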