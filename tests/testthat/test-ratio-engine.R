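# Sequence-pair extraction, ratio computation/classification, and the naive
# and censoring-aware median ratios.

test_that("extract_pairs builds consecutive-line pairs per mode", {
  crs <- course(c(12, 8, 6), c(TRUE, TRUE, TRUE),
                therapy = c("SSA", "PRRT", "everolimus"))
  p_all <- extract_pairs(crs, mode = "consecutive_all_lines")
  expect_equal(nrow(p_all), 2)
  expect_equal(p_all$therapy1, c("SSA", "PRRT"))
  expect_equal(p_all$therapy2, c("PRRT", "everolimus"))
  expect_equal(p_all$line2, p_all$line1 + 1L)

  p_1 <- extract_pairs(crs, mode = "after_line1_only")
  expect_equal(nrow(p_1), 1)
  expect_equal(p_1$therapy2, "PRRT")

  p_t <- extract_pairs(crs, mode = "after_specific_therapy", therapy = "PRRT")
  expect_equal(nrow(p_t), 1)
  expect_equal(p_t$therapy1, "PRRT")
})

test_that("pairs with censored or nonpositive PFS1 are excluded with a reason", {
  crs <- course(c(12, 8), c(FALSE, TRUE), therapy = c("SSA", "PRRT"))
  expect_message(p <- extract_pairs(crs), "excluded")
  expect_equal(nrow(p), 0)
  excl <- attr(p, "exclusions")
  expect_equal(excl$reason, "pfs1_censored")

  crs0 <- course(c(0, 8), c(TRUE, TRUE), therapy = c("SSA", "PRRT"))
  p0 <- suppressMessages(extract_pairs(crs0))
  expect_equal(attr(p0, "exclusions")$reason, "pfs1_nonpositive")
})

test_that("courses with fewer than 2 lines give an empty pair list, duplicates error", {
  one <- course(10, TRUE, therapy = "SSA")
  expect_equal(nrow(extract_pairs(one)), 0)
  dup <- dplyr::bind_rows(one, one)
  expect_error(extract_pairs(dup), "duplicated")
})

test_that("ratios carry the censoring semantics of PFS2", {
  pairs <- tibble::tibble(pfs1_months = c(10, 12, 8),
                          pfs2_months = c(18.6, 12, 6),
                          event2 = c(TRUE, TRUE, FALSE))
  r <- compute_ratios(pairs)
  expect_equal(r$ratio, c(1.86, 1, 0.75))
  expect_equal(r$event, c(TRUE, TRUE, FALSE))

  expect_error(compute_ratios(tibble::tibble(pfs1_months = 0, pfs2_months = 1,
                                             event2 = TRUE)), "undefined")
  expect_warning(
    rz <- compute_ratios(tibble::tibble(pfs1_months = 5, pfs2_months = 0,
                                        event2 = FALSE)),
    "pfs2 = 0"
  )
  expect_equal(rz$ratio, 0)
  expect_true(rz$event)  # progression at treatment start is an event
})

test_that("benefit classes partition and the thresholds are strict as printed", {
  cls <- classify_ratio(c(1.86, 1.0, 0.46, 1.3, 0.77, 1.33, 1.300001))
  expect_equal(as.character(cls$label),
               c("high", "intermediate", "low", "intermediate",
                 "intermediate", "high", "high"))
  expect_equal(cls$excellent, c(TRUE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE))
  # excellent implies high; every ratio gets exactly one class
  ratios <- withr::with_seed(3, rexp(500, 0.8))
  cls <- classify_ratio(ratios)
  expect_false(anyNA(cls$label))
  expect_true(all(cls$label[cls$excellent] == "high"))
})

test_that("naive median conventions behave as documented", {
  expect_equal(naive_median_ratio(c(0.5, 1, 2)), 1)
  expect_equal(naive_median_ratio(c(1, 2)), 1.5)
  expect_equal(naive_median_ratio(c(1, 2), convention = "lower"), 1)
})

test_that("KM median ratio matches hand oracles and the uncensored reduction", {
  # uncensored: coincides with the naive median (step convention)
  s <- km_median_ratio(c(0.5, 1, 2), c(TRUE, TRUE, TRUE))
  expect_equal(s$median, 1)
  # hand product-limit on the ratio axis
  s <- km_median_ratio(c(0.8, 1.2, 2, 3), c(TRUE, FALSE, TRUE, TRUE))
  expect_equal(s$median, 2)
  # no events: NE with warning
  expect_warning(s <- km_median_ratio(c(1, 2), c(FALSE, FALSE)), "not estimable")
  expect_true(is.na(s$median))
})

test_that("every ratio statistic is invariant under rescaling all durations", {
  pairs <- toy_pairs(toy_config(80, seed = 2, censor_rate = 0.3))
  for (c_ in c(0.1, 3.7)) {
    scaled <- pairs
    scaled$pfs1_months <- pairs$pfs1_months * c_
    scaled$pfs2_months <- pairs$pfs2_months * c_
    r2 <- compute_ratios(scaled[setdiff(names(scaled), c("ratio", "event"))])
    expect_equal(r2$ratio, pairs$ratio, tolerance = 1e-12)
    expect_equal(as.character(classify_ratio(r2$ratio)$label),
                 as.character(classify_ratio(pairs$ratio)$label))
    expect_equal(suppressWarnings(km_median_ratio(r2$ratio, r2$event)$median),
                 suppressWarnings(km_median_ratio(pairs$ratio, pairs$event)$median),
                 tolerance = 1e-12)
  }
})

test_that("promoting a censored ratio to an event cannot increase the KM median", {
  for (seed in 1:10) {
    dat <- withr::with_seed(seed, {
      n <- 40
      list(r = rlnorm(n, 0.3, 0.8), e = runif(n) < 0.6)
    })
    base <- suppressWarnings(km_median_ratio(dat$r, dat$e)$median)
    base <- ifelse(is.na(base), Inf, base)
    cens_idx <- which(!dat$e)
    for (j in cens_idx[seq_len(min(3, length(cens_idx)))]) {
      e2 <- dat$e
      e2[j] <- TRUE
      m2 <- suppressWarnings(km_median_ratio(dat$r, e2)$median)
      m2 <- ifelse(is.na(m2), Inf, m2)
      expect_lte(m2, base)
    }
  }
})

test_that("compare_ratio_groups delegates to the log-rank test on the ratio axis", {
  r <- c(0.5, 1, 2, 0.5, 1, 2)
  e <- rep(TRUE, 6)
  g <- rep(c("PRRT", "everolimus"), each = 3)
  lr <- compare_ratio_groups(r, e, g)
  expect_s3_class(lr, "logrank_test")
  expect_equal(lr$p_value, 1)
})

test_that("sequence summaries suppress small cells and partition the pairs", {
  pairs <- toy_pairs(toy_config(50, seed = 4, censor_rate = 0.2))
  # inject a second, tiny sequence cell
  tiny <- pairs[1:3, ]
  tiny$therapy2 <- "everolimus"
  tiny$patient_id <- paste0("X", 1:3)
  all_pairs <- dplyr::bind_rows(pairs, tiny)
  sm <- summarize_sequences(all_pairs, min_n = 4)
  expect_equal(nrow(sm), 2)  # one row per observed (therapy1, therapy2, histology)
  small <- sm[sm$therapy2 == "everolimus", ]
  expect_equal(small$n, 3L)
  expect_true(small$suppressed)
  expect_true(is.na(small$km_median) && is.na(small$naive_median))
  big <- sm[sm$therapy2 == "PRRT", ]
  expect_false(big$suppressed)
  expect_false(is.na(big$km_median))
  expect_equal(sum(sm$n), nrow(all_pairs))
})

test_that("for uncensored cells the KM median equals the naive median (step convention)", {
  pairs <- tibble::tibble(
    patient_id = paste0("P", 1:4), histology = "NET G1/G2",
    therapy1 = "SSA", therapy2 = "PRRT", line1 = 1L, line2 = 2L,
    pfs1_months = rep(1, 4), pfs2_months = c(1, 2, 3, 4),
    event2 = rep(TRUE, 4)
  )
  sm <- summarize_sequences(pairs, min_n = 4)
  expect_equal(sm$km_median, 2)  # lower middle order statistic
  expect_equal(sm$km_median,
               naive_median_ratio(c(1, 2, 3, 4), convention = "lower"))
})

test_that("KM median ratio is unbiased when censoring is ignorable on the ratio axis", {
  # censor the ratio observations directly with an independent uniform
  # window: the estimator itself recovers the generating median
  ests <- numeric(200)
  for (i in 1:200) {
    p <- toy_pairs(toy_config(60, seed = i))
    p <- withr::with_seed(100000 + i, {
      w <- stats::uniroot(function(w) mean(pmin(p$ratio / w, 1)) - 0.25,
                          c(1e-6, 1e9))$root
      cu <- stats::runif(nrow(p), 0, w)
      p$event <- p$ratio <= cu
      p$ratio <- pmin(p$ratio, cu)
      p
    })
    m <- suppressWarnings(km_median_ratio(p$ratio, p$event)$median)
    ests[i] <- ifelse(is.na(m), Inf, m)
  }
  expect_lt(abs(median(ests) - 28.1 / 15.1), 0.15)
})
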