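test_that("log-rank scan agrees with exhaustive survdiff over all splits", {
  withr::with_seed(41, {
    for (i in 1:8) {
      n <- 60
      d <- tibble::tibble(
        time_months = rexp(n, 0.03),
        event = rbinom(n, 1, 0.7),
        marker = rnorm(n)
      )
      if (sum(d$event) == 0) next
      scan <- markercal:::logrank_scan(d$time_months, d$event, d$marker,
                                       min_frac = 0.1)
      oracle <- oracle_best_split(d$time_months, d$event, d$marker,
                                  min_frac = 0.1)
      expect_equal(nrow(scan), nrow(oracle))
      expect_equal(scan$threshold, unname(oracle[, "threshold"]))
      expect_equal(scan$chisq, unname(oracle[, "chisq"]), tolerance = 1e-8)
    }
  })
})

test_that("the scan is invariant under strictly monotone marker rescaling", {
  withr::with_seed(43, {
    d <- tibble::tibble(
      time_months = rexp(80, 0.03),
      event = rbinom(80, 1, 0.7),
      marker = rnorm(80)
    )
    a <- markercal:::logrank_scan(d$time_months, d$event, d$marker, 0.1)
    b <- markercal:::logrank_scan(d$time_months, d$event, exp(d$marker), 0.1)
    # same membership sequence: identical fractions and statistics
    expect_equal(a$frac_low, b$frac_low)
    expect_equal(a$chisq, b$chisq, tolerance = 1e-10)
  })
})

test_that("data-driven cutpoint recovers the generating split and is deterministic", {
  d <- make_surv_cohort(n = 2000, seed = 51, hr_low = 3.7,
                        cut_quantile = 0.2)
  cp1 <- datadriven_cutpoint(d, log_score, seed = 99)
  cp2 <- datadriven_cutpoint(d, log_score, seed = 99)
  expect_equal(glance(cp1), glance(cp2))
  expect_lt(abs(cp1$frac_low - 0.20), 0.05)
  expect_true(cp1$cv_supported)
  expect_gte(cp1$frac_low, 0.10)
  expect_lte(cp1$frac_low, 0.90)
  # the selected threshold maximizes the scan profile
  expect_equal(cp1$split_statistic, max(tidy(cp1)$chisq))

  const <- dplyr::mutate(d, flat = 1)
  expect_error(datadriven_cutpoint(const, flat, seed = 1), "constant")

  cens <- dplyr::mutate(d, event = 0L)
  expect_error(datadriven_cutpoint(cens, log_score, seed = 1),
               "all-censored")
})

test_that("cross-validation rarely endorses a split when there is none", {
  supported <- vapply(1:50, function(i) {
    d <- make_surv_cohort(n = 400, seed = 6000 + i, hr_low = 1)
    datadriven_cutpoint(d, log_score, seed = 7000 + i)$cv_supported
  }, logical(1))
  expect_gte(mean(!supported), 0.90)
})

test_that("percentile cutpoint is the covering order statistic", {
  expect_equal(percentile_cutpoint(1:20, 15), 3)
  expect_equal(mean(1:20 <= percentile_cutpoint(1:20, 15)), 0.15)
  # just below 100: the maximum is the only covering threshold
  expect_equal(percentile_cutpoint(1:20, 99.9), 20)
  expect_equal(percentile_cutpoint(rep(4.2, 10), 15), 4.2)
  expect_error(percentile_cutpoint(numeric(0), 15), "empty")
  expect_error(percentile_cutpoint(1:5, 100), "pct")
})

test_that("cutpoint transfer is the calibration map with platform checks", {
  ident <- calibration(0, 1)
  expect_equal(transfer_cutpoint(1.7, ident), 1.7)
  expect_equal(transfer_cutpoint(2.0, calibration(0.43, 0.95)), 2.33)

  m <- calibration(0.3, 1.1, from_platform = "p1", to_platform = "p2")
  thr <- 1.234
  expect_equal(transfer_cutpoint(transfer_cutpoint(thr, m),
                                 invert_calibration(m)),
               thr, tolerance = 1e-12)

  d <- make_surv_cohort(n = 200, seed = 61)
  cp <- datadriven_cutpoint(d, log_score, seed = 1, platform = "p9")
  expect_error(transfer_cutpoint(cp, m), "mismatch")
})

test_that("dichotomization puts the threshold itself in the low class", {
  x <- c(1, 2, 3)
  expect_equal(as.character(dichotomize(x, 0.5)), rep("high", 3))
  expect_equal(as.character(dichotomize(x, 3)), rep("low", 3))
  expect_equal(as.character(dichotomize(x, 2)), c("low", "low", "high"))

  # frac_low is monotone non-decreasing in the threshold
  withr::with_seed(71, {
    v <- rnorm(50)
    ths <- sort(rnorm(20))
    fracs <- vapply(ths, function(th) mean(dichotomize(v, th) == "low"),
                    numeric(1))
    expect_true(all(diff(fracs) >= 0))
  })
})

test_that("transferred cutpoints classify concordantly across platforms", {
  # agreement approaches 1 as platform noise vanishes
  for (sig in c(0.05, 0.005)) {
    coh <- simulate_latent(323, seed = 81)
    m <- dplyr::bind_rows(
      apply_platform(coh, platform_spec("p1", sigma_e = sig), seed = 82),
      apply_platform(coh, platform_spec("p2", alpha = 0.43, beta = 0.95,
                                        sigma_e = sig), seed = 83)
    )
    s <- simulate_survival(coh, seed = 84)
    paired <- pair_cases(m, "p1", "p2", quiet = TRUE) |>
      dplyr::inner_join(s, by = "case_id")
    model <- conversion_from_ba(ba_regression(paired))
    cp <- datadriven_cutpoint(paired, x, seed = 85)
    cls_x <- dichotomize(paired$x, cp$threshold)
    cls_y <- dichotomize(paired$y, transfer_cutpoint(cp$threshold, model))
    agree <- mean(cls_x == cls_y)
    if (sig == 0.05) expect_gte(agree, 0.95) else expect_gte(agree, 0.99)
  }
})
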