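# Shared fixtures and independent oracles for the test suite.

# Single-sequence generator config (one SSA -> PRRT path), used wherever a
# clean two-line cohort is needed. True median ratio 28.1/15.1.
toy_config <- function(n_patients, seed, censor_rate = 0,
                       rho_s = 0.35, path = c("SSA", "PRRT"), ...) {
  synthetic_config(
    n_patients = n_patients, seed = seed,
    strata = tibble::tibble(histology = "NET G1/G2",
                            primary_site = "pancreas", weight = 1),
    sequence_graph = list("NET G1/G2" = tibble::tibble(path = list(path),
                                                       prob = 1)),
    copula_rho_spearman = rho_s, censor_rate = censor_rate, ...
  )
}

# Two-line pair table from a config.
toy_pairs <- function(cfg) {
  compute_ratios(suppressMessages(extract_pairs(generate_cohort(cfg)$records)))
}

# Small hand-written course table.
course <- function(pfs, event, therapy = paste0("T", seq_along(pfs)),
                   patient = "P1", histology = "NET G1/G2",
                   site = "pancreas") {
  tibble::tibble(
    patient_id = patient, histology = histology, primary_site = site,
    line_number = seq_along(pfs), therapy = therapy,
    pfs_months = pfs, progression_event = event
  )
}

# Permutation reference distribution for the log-rank statistic: the group
# labels are exchangeable under the null, giving a calibration of the p-value
# that does not rely on the chi-square approximation.
perm_logrank_p <- function(value, event, group, B = 4000, seed = 1) {
  obs <- logrank_test(value, event, group)$statistic
  withr::with_seed(seed, {
    perm <- replicate(B, {
      logrank_test(value, event, sample(group))$statistic
    })
  })
  mean(perm >= obs - 1e-12)
}

# Direct bivariate Gaussian-copula sampler with lognormal margins,
# independent of the cohort generator (oracle for the correlation module).
sim_copula_pairs <- function(n, rho_s, censor2_rate = 0, seed = 1) {
  rho <- 2 * sin(pi * rho_s / 6)
  withr::with_seed(seed, {
    z1 <- stats::rnorm(n)
    z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
    t1 <- stats::qlnorm(stats::pnorm(z1), log(15), 0.9)
    t2 <- stats::qlnorm(stats::pnorm(z2), log(20), 0.9)
    event2 <- rep(TRUE, n)
    if (censor2_rate > 0) {
      w <- stats::uniroot(function(w) mean(pmin(t2 / w, 1)) - censor2_rate,
                          c(1e-3, 1e9))$root
      cu <- stats::runif(n, 0, w)
      event2 <- t2 <= cu
      t2 <- pmin(t2, cu)
    }
    list(t1 = t1, t2 = t2, event2 = event2)
  })
}
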