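test_that("log transform validates its domain and names offenders", {
  d <- tibble::tibble(case_id = c("a", "b"), score = c(1, exp(2)))
  out <- log_transform(d)
  expect_equal(out$log_score, c(0, 2))

  bad <- tibble::tibble(case_id = c("a", "bad_case"), score = c(1, 0))
  expect_error(log_transform(bad), "bad_case")
})

test_that("case pairing inner-joins, reports drops, rejects ambiguity", {
  m <- tibble::tibble(
    case_id = c("1", "2", "3", "2", "3", "4"),
    platform_id = rep(c("p1", "p2"), each = 3),
    log_score = 1:6 / 2
  )
  expect_message(paired <- pair_cases(m, "p1", "p2"), "dropped")
  expect_equal(paired$case_id, c("2", "3"))
  expect_equal(attr(paired, "n_dropped_x"), 1L)
  expect_equal(attr(paired, "n_dropped_y"), 1L)

  same <- dplyr::filter(m, case_id %in% c("2", "3"))
  expect_silent(pair_cases(same, "p1", "p2"))

  dup <- dplyr::bind_rows(m, tibble::tibble(case_id = "1",
                                            platform_id = "p1",
                                            log_score = 9))
  expect_error(pair_cases(dup, "p1", "p2"), "duplicate")

  disjoint <- dplyr::mutate(m, case_id = ifelse(platform_id == "p2",
                                                paste0("z", case_id),
                                                case_id))
  expect_error(pair_cases(disjoint, "p1", "p2"), "overlapping")
})

test_that("difference-vs-mean regression matches the exact algebra", {
  x <- seq(0.5, 4, length.out = 40)

  ident <- ba_regression(tibble::tibble(x = x, y = x))
  expect_equal(ident$intercept_a, 0, tolerance = 1e-12)
  expect_equal(ident$slope_b, 0, tolerance = 1e-12)
  expect_equal(ident$resid_sd, 0, tolerance = 1e-10)

  # y = 0.43 + 0.95 x implies D = 0.441026 - 0.051282 A exactly
  aff <- ba_regression(tibble::tibble(x = x, y = 0.43 + 0.95 * x))
  expect_equal(aff$intercept_a, 0.441026, tolerance = 1e-5)
  expect_equal(aff$slope_b, -0.051282, tolerance = 1e-5)
  expect_equal(aff$resid_sd, 0, tolerance = 1e-10)

  off <- ba_regression(tibble::tibble(x = x, y = x + 0.5))
  expect_equal(off$intercept_a, 0.5, tolerance = 1e-12)
  expect_equal(off$slope_b, 0, tolerance = 1e-12)

  expect_error(ba_regression(tibble::tibble(x = c(1, 2), y = c(1, 2))),
               "3")
  expect_error(ba_regression(tibble::tibble(x = c(1, 2, 3),
                                            y = c(3, 2, 1))),
               "constant")
})

test_that("conversion algebra reproduces the printed platform equations", {
  expect_equal(unclass(conversion_from_ba(
    structure(list(intercept_a = 0, slope_b = 0, resid_sd = 0, n = 10,
                   platform_x = NULL, platform_y = NULL),
              class = "ba_fit")))[c("alpha", "beta")],
    list(alpha = 0, beta = 1))

  fit <- structure(list(intercept_a = 0.441026, slope_b = -0.051282,
                        resid_sd = 0, n = 323, platform_x = "aqua",
                        platform_y = "ts"),
                   class = "ba_fit")
  model <- conversion_from_ba(fit)
  expect_equal(model$alpha, 0.43, tolerance = 1e-5)
  expect_equal(model$beta, 0.95, tolerance = 1e-5)

  pure_offset <- structure(list(intercept_a = 0.5, slope_b = 0,
                                resid_sd = 0.1, n = 10, platform_x = NULL,
                                platform_y = NULL), class = "ba_fit")
  m2 <- conversion_from_ba(pure_offset)
  expect_equal(m2$alpha, 0.5)
  expect_equal(m2$beta, 1)
  expect_equal(m2$pred_sd, 0.1)

  degen <- structure(list(intercept_a = 0, slope_b = 2, resid_sd = 0,
                          n = 10, platform_x = NULL, platform_y = NULL),
                     class = "ba_fit")
  expect_error(conversion_from_ba(degen), "degenerate")
})

test_that("calibration inversion is the exact involution", {
  expect_equal(tidy(invert_calibration(calibration(0, 1)))[c("alpha", "beta")],
               tibble::tibble(alpha = 0, beta = 1))

  inv <- invert_calibration(calibration(0.43, 0.95, from_platform = "aqua",
                                        to_platform = "ts"))
  expect_equal(inv$alpha, -0.452632, tolerance = 1e-5)
  expect_equal(inv$beta, 1.052632, tolerance = 1e-5)
  expect_identical(inv$from_platform, "ts")
  # the separately refitted printed reverse equation differs by < 0.01
  expect_lt(abs(inv$alpha - (-0.45)), 0.01)
  expect_lt(abs(inv$beta - 1.06), 0.01)

  withr::with_seed(3, {
    for (i in 1:20) {
      m <- calibration(rnorm(1), exp(rnorm(1)))
      mm <- invert_calibration(invert_calibration(m))
      expect_equal(mm$alpha, m$alpha, tolerance = 1e-12)
      expect_equal(mm$beta, m$beta, tolerance = 1e-12)
    }
  })
})

test_that("applying a calibration is affine and round-trips", {
  ident <- calibration(0, 1)
  v <- c(-1, 0, 2.5)
  expect_equal(apply_calibration(ident, v), v)

  m <- calibration(0.43, 0.95)
  expect_equal(apply_calibration(m, 2.0), 2.33)
  expect_equal(apply_calibration(invert_calibration(m),
                                 apply_calibration(m, v)),
               v, tolerance = 1e-12)
})

test_that("limits of agreement use the right normal quantiles", {
  flat <- structure(list(intercept_a = 0.2, slope_b = 0.1, resid_sd = 0,
                         n = 10, platform_x = NULL, platform_y = NULL),
                    class = "ba_fit")
  loa0 <- limits_of_agreement(flat)
  expect_equal(loa0$intercept, c(0.2, 0.2))
  expect_equal(loa0$slope, c(0.1, 0.1))

  unit <- structure(list(intercept_a = 0, slope_b = 0, resid_sd = 1,
                         n = 10, platform_x = NULL, platform_y = NULL),
                    class = "ba_fit")
  expect_equal(limits_of_agreement(unit, 0.95)$intercept,
               c(-1.959964, 1.959964), tolerance = 1e-6)
  expect_equal(limits_of_agreement(unit, 0.5)$intercept,
               c(-0.674490, 0.674490), tolerance = 1e-6)
  expect_error(limits_of_agreement(unit, 1), "level")
})

test_that("noise-free synthetic platforms are recovered exactly and symmetrically", {
  coh <- simulate_latent(50, seed = 2)
  m <- dplyr::bind_rows(
    apply_platform(coh, platform_spec("p1", alpha = 0.1, beta = 1.2,
                                      sigma_e = 0), seed = 3),
    apply_platform(coh, platform_spec("p2", alpha = 0.43, beta = 0.95,
                                      sigma_e = 0), seed = 4)
  )
  paired <- pair_cases(m, "p1", "p2", quiet = TRUE)
  model <- conversion_from_ba(ba_regression(paired))
  # implied map p1 -> p2: alpha = a2 - a1 b2/b1, beta = b2/b1
  expect_equal(model$beta, 0.95 / 1.2, tolerance = 1e-10)
  expect_equal(model$alpha, 0.43 - 0.1 * 0.95 / 1.2, tolerance = 1e-10)

  swapped <- dplyr::rename(paired, x = y, y = x)
  back <- conversion_from_ba(ba_regression(swapped))
  inv <- invert_calibration(model)
  expect_equal(back$alpha, inv$alpha, tolerance = 1e-10)
  expect_equal(back$beta, inv$beta, tolerance = 1e-10)
})

test_that("calibration parameters are recovered under measurement noise", {
  n_rep <- 200
  ok <- vapply(seq_len(n_rep), function(i) {
    paired <- make_paired(n = 323, seed = 10000 + 7L * i, sigma_e = 0.05)
    model <- conversion_from_ba(ba_regression(paired))
    abs(model$alpha - 0.43) <= 0.05 && abs(model$beta - 0.95) <= 0.03
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})
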