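test_that("latent simulation honours its distributional contract", {
  # zero-variance cohort collapses onto the mean
  flat <- simulate_latent(5, mu_mean = 2, mu_sd = 0, seed = 1)
  expect_equal(flat$mu, rep(2, 5))
  expect_equal(dplyr::n_distinct(flat$case_id), 5L)

  # seed determinism, bit for bit
  a <- simulate_latent(1000, mu_mean = 2, mu_sd = 0.5, seed = 7)
  b <- simulate_latent(1000, mu_mean = 2, mu_sd = 0.5, seed = 7)
  expect_identical(a, b)

  # CLT bound on the sample mean at n = 10000
  big <- simulate_latent(10000, mu_mean = 2, mu_sd = 0.5, seed = 7)
  expect_lt(abs(mean(big$mu) - 2), 3 * 0.5 / sqrt(10000))

  expect_error(simulate_latent(0, seed = 1), "positive")
})

test_that("platform measurement is affine in the latent value", {
  coh <- tibble::tibble(case_id = c("a", "b"), mu = c(1, 2))
  noiseless <- platform_spec("p", alpha = 0.43, beta = 0.95, sigma_e = 0)
  rec <- apply_platform(coh, noiseless, seed = 1)
  expect_equal(rec$log_score, c(1.38, 2.33))
  expect_equal(rec$score, exp(c(1.38, 2.33)))

  identity <- platform_spec("id", alpha = 0, beta = 1, sigma_e = 0)
  expect_equal(apply_platform(coh, identity, seed = 1)$log_score, coh$mu)

  expect_error(platform_spec("p", beta = -1), "positive")
  expect_error(platform_spec("p", sigma_e = -0.1), "nonnegative")
})

test_that("two noisy platforms on one cohort are nearly concordant after calibration", {
  paired <- make_paired(n = 323, seed = 11, sigma_e = 0.05)
  model <- conversion_from_ba(ba_regression(paired))
  cal <- dplyr::mutate(paired, x_cal = apply_calibration(model, x))
  expect_gte(ccc(cal, x_cal, y)$rho_c, 0.98)
})

test_that("survival generator reproduces the null and recovers the hazard ratio", {
  # under hr_low = 1 the log-rank test keeps its nominal type-I error
  n_rep <- 200
  rejected <- vapply(seq_len(n_rep), function(i) {
    coh <- simulate_latent(200, seed = 100 + i)
    s <- simulate_survival(coh, hr_low = 1, seed = 300 + i)
    logrank_test(s, group = latent_low)$p_value < 0.05
  }, logical(1))
  bounds <- stats::qbinom(c(0.005, 0.995), n_rep, 0.05) / n_rep
  expect_gte(mean(rejected), bounds[1])
  expect_lte(mean(rejected), bounds[2])

  # baseline_rate = 0 means nobody ever recurs
  coh <- simulate_latent(50, seed = 1)
  s0 <- simulate_survival(coh, baseline_rate = 0, seed = 2)
  expect_true(all(s0$event == 0L))

  # Cox CI coverage of the generating hazard ratio
  n_rep <- 100
  covered <- vapply(seq_len(n_rep), function(i) {
    coh <- simulate_latent(2000, seed = 1000 + i)
    s <- simulate_survival(coh, cut_quantile = 0.2, hr_low = 3.7,
                           pr_neg_prob = 0, seed = 2000 + i)
    s$latent_low <- stats::relevel(s$latent_low, ref = "high")
    hr <- tidy(cox_fit(s, "latent_low"))
    row <- hr[hr$level == "low", ]
    row$ci_low <= 3.7 && 3.7 <= row$ci_high
  }, logical(1))
  expect_gte(mean(covered), 0.90)

  expect_error(simulate_survival(simulate_latent(5, seed = 1),
                                 censor_range = c(0.5, 300), seed = 1),
               "censor_range")
})

test_that("chromogen scores respect the detection floor and monotonicity", {
  coh <- simulate_latent(193, seed = 5)
  # floor placed so that 169 of 193 are undetectable
  chrom <- simulate_chromogen(coh, floor_quantile = 169 / 193)
  expect_equal(sum(chrom$chromogen_percent == 0), 169L)
  expect_equal(sum(chrom$chromogen_percent >= 1), 24L)

  # floor near zero: everyone positive, scores within the pathologist range
  all_pos <- simulate_chromogen(coh, floor_quantile = 1e-6)
  expect_true(all(all_pos$chromogen_percent >= 1 &
                    all_pos$chromogen_percent <= 95))

  # higher latent level never yields a lower percent among positives
  joined <- dplyr::inner_join(coh, chrom, by = "case_id") |>
    dplyr::filter(chromogen_percent > 0) |>
    dplyr::arrange(mu)
  expect_true(all(diff(joined$chromogen_percent) >= 0))
})

test_that("operator replicates carry the requested relative noise", {
  base <- tibble::tibble(case_id = sprintf("c%03d", 1:336),
                         score = exp(simulate_latent(336, seed = 42)$mu))

  silent <- simulate_replicates(base, cv_percent = 0, seed = 1)
  wide <- tidyr::pivot_wider(silent, names_from = replicate,
                             values_from = score, names_prefix = "rep")
  expect_equal(wide$rep1, wide$rep2)
  expect_equal(ccc(wide, rep1, rep2)$rho_c, 1)
  expect_equal(coefficient_of_variation(silent)$cov_percent, 0)

  noisy <- simulate_replicates(base, cv_percent = 1, seed = 2)
  cov_est <- coefficient_of_variation(noisy)$cov_percent
  expect_gte(cov_est, 0.7)
  expect_lte(cov_est, 1.3)
  wide2 <- tidyr::pivot_wider(noisy, names_from = replicate,
                              values_from = score, names_prefix = "rep")
  expect_gte(ccc(wide2, rep1, rep2)$rho_c, 0.99)
})
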