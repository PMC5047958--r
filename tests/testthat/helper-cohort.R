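# fixtures built in code: small paired-platform and survival datasets

# paired log scores from two platforms measuring the same latent cohort
make_paired <- function(n = 100, seed = 1, alpha = 0.43, beta = 0.95,
                        sigma_e = 0.05, mu_sd = 0.5) {
  coh <- simulate_latent(n, mu_mean = 2, mu_sd = mu_sd, seed = seed)
  m <- dplyr::bind_rows(
    apply_platform(coh, platform_spec("p1", sigma_e = sigma_e),
                   seed = seed + 1L),
    apply_platform(coh, platform_spec("p2", alpha = alpha, beta = beta,
                                      sigma_e = sigma_e), seed = seed + 2L)
  )
  pair_cases(m, "p1", "p2", quiet = TRUE)
}

# marker + survival tibble in the study regime
make_surv_cohort <- function(n = 500, seed = 1, hr_low = 3.7,
                             cut_quantile = 0.2, sigma_e = 0.05) {
  coh <- simulate_latent(n, seed = seed)
  m <- apply_platform(coh, platform_spec("p1", sigma_e = sigma_e),
                      seed = seed + 1L)
  s <- simulate_survival(coh, cut_quantile = cut_quantile, hr_low = hr_low,
                         seed = seed + 2L)
  dplyr::inner_join(m, s, by = "case_id")
}

# brute-force log-rank over all admissible splits using survival::survdiff,
# the independent oracle for the scan
oracle_best_split <- function(time, event, marker, min_frac) {
  vals <- sort(unique(marker))
  n <- length(marker)
  best <- list(chisq = -Inf, threshold = NA_real_)
  out <- list()
  for (i in seq_len(length(vals) - 1)) {
    thr <- (vals[i] + vals[i + 1]) / 2
    g <- marker <= thr
    frac <- mean(g)
    if (frac < min_frac || frac > 1 - min_frac) next
    chi <- survival::survdiff(survival::Surv(time, event) ~ g)$chisq
    out[[length(out) + 1]] <- c(threshold = thr, frac_low = frac, chisq = chi)
  }
  do.call(rbind, out)
}

# empirical rank AUC between cases and controls, the brute-force oracle for
# the uncensored time-dependent ROC
oracle_rank_auc <- function(risk_case, risk_ctrl) {
  tot <- 0
  for (a in risk_case) {
    for (b in risk_ctrl) {
      tot <- tot + (a > b) + 0.5 * (a == b)
    }
  }
  tot / (length(risk_case) * length(risk_ctrl))
}
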