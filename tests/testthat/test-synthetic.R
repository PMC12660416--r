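# Synthetic cohort generator: determinism, copula targeting, marginal
# fidelity, censoring placement, truth computation, sequencing frequencies.

test_that("the same config yields an identical cohort", {
  cfg <- synthetic_config(n_patients = 60, seed = 42)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$records, b$records)
  # and leaves the global RNG state alone
  withr::with_seed(1, {
    before <- .Random.seed
    invisible(generate_cohort(cfg))
    expect_identical(.Random.seed, before)
  })
})

test_that("successive-line PFS hits the Spearman target", {
  p <- toy_pairs(toy_config(5000, seed = 13, rho_s = 0.35))
  emp <- stats::cor(p$pfs1_months, p$pfs2_months, method = "spearman")
  expect_lt(abs(emp - 0.35), 0.03)

  p0 <- toy_pairs(toy_config(10000, seed = 14, rho_s = 0))
  emp0 <- stats::cor(p0$pfs1_months, p0$pfs2_months, method = "spearman")
  expect_lt(abs(emp0), 0.03)
})

test_that("uncensored marginals follow the configured distribution", {
  cfg <- toy_config(5000, seed = 15)
  r <- generate_cohort(cfg)$records
  for (th in c("SSA", "PRRT")) {
    x <- r$pfs_months[r$therapy == th & r$progression_event]
    sc <- cfg$marginals$scale[cfg$marginals$therapy == th]
    ks <- stats::ks.test(x, "plnorm", meanlog = log(sc), sdlog = 0.9)
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("censoring touches only the final line at about the configured rate", {
  cfg <- toy_config(2000, seed = 16, censor_rate = 0.3,
                    path = c("SSA", "PRRT", "everolimus"))
  r <- generate_cohort(cfg)$records
  last <- r$line_number == stats::ave(r$line_number, r$patient_id, FUN = max)
  expect_true(all(r$progression_event[!last]))
  expect_lt(abs(mean(!r$progression_event[last]) - 0.3), 0.05)

  cfg0 <- toy_config(200, seed = 17, censor_rate = 0)
  expect_true(all(generate_cohort(cfg0)$records$progression_event))
})

test_that("truth_ratios gives the generating-model medians", {
  # identical marginals: true median ratio 1 whatever the correlation
  marg <- tibble::tibble(therapy = c("SSA", "PRRT"), scale = 12, shape = 0.9)
  cfg <- toy_config(10, seed = 18, marginals = marg)
  expect_equal(truth_ratios(cfg)$true_median_ratio, 1)

  # therapy-2 multiplier 2, lognormal: exactly 2
  cfg2 <- toy_config(10, seed = 18, marginals = marg,
                     effect_multipliers = c(SSA = 1, PRRT = 2))
  expect_equal(truth_ratios(cfg2)$true_median_ratio, 2)

  # Weibull with equal shapes and rho = 0: Monte-Carlo median matches the
  # scale ratio (the quantile-ratio argument gives 2 exactly)
  cfg3 <- toy_config(10, seed = 18, marginals = marg,
                     effect_multipliers = c(SSA = 1, PRRT = 2),
                     rho_s = 0, marginal_family = "weibull")
  expect_equal(truth_ratios(cfg3)$true_median_ratio, 2, tolerance = 0.03)

  # default study-shaped config carries the headline sequence ratios
  tr <- truth_ratios(synthetic_config(n_patients = 10, seed = 1))
  get <- function(a, b) tr$true_median_ratio[tr$therapy1 == a & tr$therapy2 == b]
  expect_equal(get("SSA", "PRRT"), 28.1 / 15.1)
  expect_equal(get("platinum/etoposide", "FOLFOX/FOLFIRI"), 2.8 / 6)
})

test_that("sequence counts match their multinomial expectations", {
  cfg <- synthetic_config(n_patients = 1770, seed = 19)
  r <- generate_cohort(cfg)$records
  edges <- sequence_frequencies(r)
  ssa_prrt <- edges$count[edges$therapy1 == "SSA" & edges$therapy2 == "PRRT" &
                            edges$line1 == 1L]
  # expected probability of an SSA->PRRT first transition under the graph
  w <- cfg$strata$weight / sum(cfg$strata$weight)
  p_hist <- tapply(w, cfg$strata$histology, sum)
  p_edge <- sum(vapply(names(cfg$sequence_graph), function(h) {
    g <- cfg$sequence_graph[[h]]
    first2 <- vapply(g$path, function(p) p[1] == "SSA" && p[2] == "PRRT",
                     logical(1))
    p_hist[[h]] * sum(g$prob[first2])
  }, numeric(1)))
  bounds <- stats::qbinom(c(0.005, 0.995), 1770, p_edge)
  expect_gte(ssa_prrt, bounds[1])
  expect_lte(ssa_prrt, bounds[2])
})

test_that("invalid configurations are rejected", {
  expect_error(
    synthetic_config(
      n_patients = 10, seed = 1,
      strata = tibble::tibble(histology = "NET G1/G2",
                              primary_site = "pancreas", weight = 1),
      sequence_graph = list("NET G1/G2" = tibble::tibble(
        path = list(c("SSA", "PRRT")), prob = 0.7))),
    "sum to 1"
  )
  expect_error(
    toy_config(10, seed = 1,
               marginals = tibble::tibble(therapy = c("SSA", "PRRT"),
                                          scale = c(-1, 10), shape = 0.9)),
    "positive"
  )
  expect_error(synthetic_config(censor_rate = 1), "censor_rate")
  expect_error(
    toy_config(10, seed = 1, path = c("SSA", "PRRT", "missing-drug")),
    "no marginal parameters"
  )
})
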