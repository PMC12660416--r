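# Synthetic NEN-like cohort generator: histology strata, therapy sequencing
# graph, correlated line-wise PFS via a Gaussian copula, heavy-tailed
# months-scale marginals, administrative censoring of the final line only.

#' Default histology/primary-site strata
#'
#' Stratum weights reflecting a mixed neuroendocrine-neoplasm referral cohort
#' (well-differentiated NET G1/G2 dominated by small-intestinal and pancreatic
#' primaries, thoracic carcinoids, NET G3 and NEC).
#'
#' @return Tibble with columns `histology`, `primary_site`, `weight`
#'   (unnormalized).
#' @export
default_strata <- function() {
  tibble::tribble(
    ~histology,   ~primary_site,     ~weight,
    "NET G1/G2",  "small intestine", 44,
    "NET G1/G2",  "pancreas",        39,
    "NET G1/G2",  "CUP",              9,
    "NET G1/G2",  "colon/rectum",     5,
    "NET G1/G2",  "other",            7,
    "NEC",        "pancreas",        12,
    "NEC",        "colon/rectum",     8,
    "NEC",        "CUP",              5,
    "NEC",        "other",            4,
    "NET G3",     "pancreas",         9,
    "NET G3",     "small intestine",  3,
    "NET G3",     "CUP",              2,
    "NET G3",     "other",            2,
    "TC/AC",      "lung/thymus",     28
  )
}

#' Default therapy-sequencing graph
#'
#' Per-histology therapy paths with probabilities (summing to 1 within each
#' histology). The structure mirrors common sequencing practice: SSA-first
#' courses followed mostly by PRRT (less often everolimus or other therapies)
#' in NET G1/G2 and thoracic carcinoids, platinum/etoposide-first courses
#' followed by FOLFOX/FOLFIRI, CAPTEM or other therapies in NEC, and
#' CAPTEM-centric sequences in NET G3. A few paths have three lines so that
#' later-line pairs exist.
#'
#' @return Named list (histology) of tibbles with a list-column `path`
#'   (character vectors of therapy labels) and `prob`.
#' @export
default_sequence_graph <- function() {
  g <- function(...) {
    paths <- list(...)
    tibble::tibble(
      path = lapply(paths, `[[`, 1L),
      prob = vapply(paths, `[[`, numeric(1), 2L)
    )
  }
  list(
    "NET G1/G2" = g(
      list(c("SSA", "PRRT"), 0.340),
      list(c("SSA", "PRRT", "everolimus"), 0.115),
      list(c("SSA", "everolimus"), 0.098),
      list(c("SSA", "other"), 0.068),
      list(c("SSA", "CAPTEM"), 0.015),
      list(c("PRRT", "everolimus"), 0.061),
      list(c("PRRT", "Re-PRRT"), 0.045),
      list(c("PRRT", "other"), 0.068),
      list(c("everolimus", "other"), 0.083),
      list(c("other", "PRRT"), 0.107)
    ),
    "TC/AC" = g(
      list(c("SSA", "PRRT"), 0.30),
      list(c("SSA", "everolimus"), 0.20),
      list(c("SSA", "CAPTEM"), 0.10),
      list(c("PRRT", "everolimus"), 0.15),
      list(c("everolimus", "other"), 0.10),
      list(c("other", "PRRT", "everolimus"), 0.15)
    ),
    "NET G3" = g(
      list(c("platinum/etoposide", "CAPTEM"), 0.30),
      list(c("CAPTEM", "other"), 0.25),
      list(c("SSA", "CAPTEM"), 0.20),
      list(c("CAPTEM", "PRRT"), 0.15),
      list(c("other", "CAPTEM"), 0.10)
    ),
    "NEC" = g(
      list(c("platinum/etoposide", "FOLFOX/FOLFIRI"), 0.45),
      list(c("platinum/etoposide", "CAPTEM"), 0.10),
      list(c("platinum/etoposide", "other"), 0.31),
      list(c("other", "platinum/etoposide", "FOLFOX/FOLFIRI"), 0.14)
    )
  )
}

#' Default per-therapy marginal parameters
#'
#' `scale` is the marginal median PFS in months for each therapy label (across
#' all families: the lognormal meanlog, Weibull scale or exponential rate are
#' reparameterized so that `scale` is always the median); `shape` is the
#' lognormal sdlog (or Weibull shape). The months-scale medians encode a
#' markedly effective radioligand therapy (PRRT) relative to SSA, everolimus
#' on par with SSA, and short chemotherapy intervals in NEC.
#'
#' @return Tibble with columns `therapy`, `scale`, `shape`.
#' @export
default_marginals <- function() {
  tibble::tribble(
    ~therapy,              ~scale, ~shape,
    "SSA",                  15.1,   0.9,
    "PRRT",                 28.1,   0.9,
    "everolimus",           15.0,   0.9,
    "CAPTEM",                9.8,   0.9,
    "platinum/etoposide",    6.0,   0.9,
    "FOLFOX/FOLFIRI",        2.8,   0.9,
    "Re-PRRT",              13.2,   0.9,
    "other",                 8.9,   0.9
  )
}

#' Configure the synthetic cohort generator
#'
#' @param n_patients Number of patients (default 177).
#' @param seed Integer seed; the cohort is byte-identical for a fixed config.
#' @param strata Stratum tibble (`histology`, `primary_site`, `weight`), see
#'   [default_strata()].
#' @param sequence_graph Named list of per-histology path tibbles, see
#'   [default_sequence_graph()]; path probabilities must sum to 1 per
#'   histology and every path must have at least `min_lines` therapies.
#' @param marginal_family `"lognormal"` (default), `"weibull"` or
#'   `"exponential"`. `scale` is always the marginal median in months.
#' @param marginals Tibble (`therapy`, `scale`, `shape`), see
#'   [default_marginals()].
#' @param effect_multipliers Named numeric vector multiplying a therapy's
#'   median scale (default 1 for every therapy).
#' @param copula_rho_spearman Spearman correlation target linking
#'   successive-line PFS within a patient, in (-1, 1); converted to the latent
#'   Gaussian correlation via \eqn{\rho = 2\sin(\pi\rho_s/6)}.
#' @param censor_rate Expected fraction of final lines administratively
#'   censored, in [0, 1). Earlier lines are always event-terminated.
#' @param min_lines Minimum lines per patient (default 2).
#' @return A validated `synthetic_config` object.
#' @export
synthetic_config <- function(n_patients = 177,
                             seed = 20260101,
                             strata = default_strata(),
                             sequence_graph = default_sequence_graph(),
                             marginal_family = c("lognormal", "weibull",
                                                 "exponential"),
                             marginals = default_marginals(),
                             effect_multipliers = NULL,
                             copula_rho_spearman = 0.35,
                             censor_rate = 0.30,
                             min_lines = 2L) {
  marginal_family <- match.arg(marginal_family)
  if (is.null(effect_multipliers)) {
    effect_multipliers <- stats::setNames(rep(1, nrow(marginals)),
                                          marginals$therapy)
  }
  config <- structure(
    list(n_patients = as.integer(n_patients), seed = as.integer(seed),
         strata = tibble::as_tibble(strata),
         sequence_graph = sequence_graph,
         marginal_family = marginal_family,
         marginals = tibble::as_tibble(marginals),
         effect_multipliers = effect_multipliers,
         copula_rho_spearman = copula_rho_spearman,
         censor_rate = censor_rate,
         min_lines = as.integer(min_lines)),
    class = "synthetic_config"
  )
  validate_synthetic_config(config)
  config
}

validate_synthetic_config <- function(config) {
  with(config, {
    if (n_patients < 1) stop("n_patients must be >= 1", call. = FALSE)
    if (!all(c("histology", "primary_site", "weight") %in% names(strata)) ||
        any(strata$weight < 0) || sum(strata$weight) <= 0) {
      stop("invalid strata specification", call. = FALSE)
    }
    if (censor_rate < 0 || censor_rate >= 1) {
      stop("censor_rate must be in [0, 1)", call. = FALSE)
    }
    if (abs(copula_rho_spearman) >= 1) {
      stop("copula_rho_spearman must be in (-1, 1)", call. = FALSE)
    }
    if (any(marginals$scale <= 0) || any(marginals$shape <= 0)) {
      stop("marginal scales and shapes must be positive", call. = FALSE)
    }
    if (any(effect_multipliers <= 0)) {
      stop("effect multipliers must be positive", call. = FALSE)
    }
    hists <- unique(strata$histology)
    if (!all(hists %in% names(sequence_graph))) {
      stop("every stratum histology needs a sequence_graph entry", call. = FALSE)
    }
    max_len <- 0L
    for (h in names(sequence_graph)) {
      g <- sequence_graph[[h]]
      if (abs(sum(g$prob) - 1) > 1e-6 || any(g$prob < 0)) {
        stop("path probabilities must be nonnegative and sum to 1 (", h, ")",
             call. = FALSE)
      }
      lens <- lengths(g$path)
      if (any(lens < min_lines)) {
        stop("every path must have at least min_lines therapies (", h, ")",
             call. = FALSE)
      }
      max_len <- max(max_len, lens)
      labs <- unique(unlist(g$path))
      missing_marg <- setdiff(labs, marginals$therapy)
      if (length(missing_marg)) {
        stop("no marginal parameters for: ",
             paste(missing_marg, collapse = ", "), call. = FALSE)
      }
      missing_mult <- setdiff(labs, names(effect_multipliers))
      if (length(missing_mult)) {
        stop("no effect multiplier for: ",
             paste(missing_mult, collapse = ", "), call. = FALSE)
      }
    }
    rho <- 2 * sin(pi * copula_rho_spearman / 6)
    if (max_len > 1L && rho < -1 / (max_len - 1) + 1e-9) {
      stop("copula correlation too negative for the longest path", call. = FALSE)
    }
  })
  invisible(config)
}

# Quantile of the marginal PFS distribution; `scale` is the median months
# after applying the therapy effect multiplier.
marginal_quantile <- function(u, family, scale, shape) {
  switch(family,
    lognormal = stats::qlnorm(u, meanlog = log(scale), sdlog = shape),
    weibull = stats::qweibull(u, shape = shape,
                              scale = scale / log(2)^(1 / shape)),
    exponential = stats::qexp(u, rate = log(2) / scale)
  )
}

# Uniform administrative window calibrated so the expected censored fraction
# of the final-line durations equals `rate` (censoring independent of events).
calibrate_censor_window <- function(t_last, rate) {
  if (rate <= 0) return(Inf)
  f <- function(w) mean(pmin(t_last / w, 1)) - rate
  upper <- max(t_last) / rate * 10
  stats::uniroot(f, c(min(t_last) * 1e-6, upper), tol = 1e-8)$root
}

#' Generate a synthetic treatment-course cohort
#'
#' For each patient: draw a histology/primary-site stratum, draw a therapy
#' path from the sequencing graph, draw a latent Gaussian vector with
#' exchangeable correlation across that patient's lines (Spearman target
#' converted to the latent scale), map each coordinate through the configured
#' marginal quantile function scaled by the therapy's effect multiplier, and
#' apply administrative censoring to the final line only. Deterministic under
#' a fixed config (the global RNG state is left untouched).
#'
#' @param config A [synthetic_config()].
#' @return An object of class `synthetic_cohort`: list with `records` (a
#'   cohort tibble: `patient_id`, `histology`, `primary_site`, `line_number`,
#'   `therapy`, `pfs_months`, `progression_event`) and `truth` (generating
#'   parameters: `rho_spearman`, `rho_latent`, `median_ratios` from
#'   [truth_ratios()], `censor_rate`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  validate_synthetic_config(config)
  records <- withr::with_seed(config$seed, generate_records(config))
  structure(
    list(records = records,
         truth = list(
           rho_spearman = config$copula_rho_spearman,
           rho_latent = 2 * sin(pi * config$copula_rho_spearman / 6),
           median_ratios = truth_ratios(config),
           censor_rate = config$censor_rate
         )),
    class = "synthetic_cohort"
  )
}

generate_records <- function(config) {
  n <- config$n_patients
  strata <- config$strata
  si <- sample.int(nrow(strata), n, replace = TRUE,
                   prob = strata$weight / sum(strata$weight))
  histology <- strata$histology[si]
  primary_site <- strata$primary_site[si]

  paths <- vector("list", n)
  for (h in unique(histology)) {
    idx <- which(histology == h)
    g <- config$sequence_graph[[h]]
    pi_ <- sample.int(nrow(g), length(idx), replace = TRUE, prob = g$prob)
    paths[idx] <- g$path[pi_]
  }
  lens <- lengths(paths)
  rho <- 2 * sin(pi * config$copula_rho_spearman / 6)

  # Latent exchangeable-Gaussian draws, blocked by path length.
  z <- vector("list", n)
  for (L in sort(unique(lens))) {
    idx <- which(lens == L)
    sigma <- matrix(rho, L, L)
    diag(sigma) <- 1
    R <- chol(sigma)
    zm <- matrix(stats::rnorm(length(idx) * L), ncol = L) %*% R
    for (i in seq_along(idx)) z[[idx[i]]] <- zm[i, ]
  }

  pid <- sprintf("P%04d", seq_len(n))
  scale_of <- stats::setNames(config$marginals$scale, config$marginals$therapy)
  shape_of <- stats::setNames(config$marginals$shape, config$marginals$therapy)
  mult_of <- config$effect_multipliers

  rec <- tibble::tibble(
    patient_id = rep(pid, lens),
    histology = rep(histology, lens),
    primary_site = rep(primary_site, lens),
    line_number = unlist(lapply(lens, seq_len)),
    therapy = unlist(paths),
    latent = unlist(z)
  )
  u <- stats::pnorm(rec$latent)
  rec$pfs_months <- marginal_quantile(
    u, config$marginal_family,
    scale_of[rec$therapy] * mult_of[rec$therapy],
    shape_of[rec$therapy]
  )
  rec$latent <- NULL
  rec$progression_event <- TRUE

  last <- rec$line_number == rep(lens, lens)
  if (config$censor_rate > 0) {
    t_last <- rec$pfs_months[last]
    w <- calibrate_censor_window(t_last, config$censor_rate)
    cutoff <- stats::runif(sum(last), 0, w)
    censored <- cutoff < t_last
    rec$pfs_months[last][censored] <- cutoff[censored]
    rec$progression_event[last][censored] <- FALSE
  }
  rec
}

#' True median PFS ratio per consecutive therapy sequence
#'
#' The generating-model median of PFS2/PFS1 for every consecutive therapy
#' pair occurring in the sequencing graph. For lognormal marginals the ratio
#' of two (correlated) lognormals is lognormal, so the median is exactly the
#' ratio of the two median scales (multipliers included), independent of the
#' copula correlation and shapes. Other families use Monte-Carlo evaluation
#' (`mc_draws` copula draws, deterministic under the config seed).
#'
#' @param config A [synthetic_config()].
#' @param mc_draws Monte-Carlo draws for non-lognormal families.
#' @return Tibble with `therapy1`, `therapy2`, `true_median_ratio`.
#' @export
truth_ratios <- function(config, mc_draws = 1e5) {
  stopifnot(inherits(config, "synthetic_config"))
  pairs <- unique(do.call(rbind, lapply(config$sequence_graph, function(g) {
    do.call(rbind, lapply(g$path, function(p) {
      cbind(p[-length(p)], p[-1])
    }))
  })))
  scale_of <- stats::setNames(config$marginals$scale, config$marginals$therapy)
  shape_of <- stats::setNames(config$marginals$shape, config$marginals$therapy)
  mult_of <- config$effect_multipliers
  s1 <- scale_of[pairs[, 1]] * mult_of[pairs[, 1]]
  s2 <- scale_of[pairs[, 2]] * mult_of[pairs[, 2]]
  if (config$marginal_family == "lognormal") {
    med <- as.numeric(s2 / s1)
  } else {
    rho <- 2 * sin(pi * config$copula_rho_spearman / 6)
    med <- withr::with_seed(config$seed, {
      z1 <- stats::rnorm(mc_draws)
      z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(mc_draws)
      u1 <- stats::pnorm(z1)
      u2 <- stats::pnorm(z2)
      vapply(seq_len(nrow(pairs)), function(i) {
        t1 <- marginal_quantile(u1, config$marginal_family, s1[i],
                                shape_of[pairs[i, 1]])
        t2 <- marginal_quantile(u2, config$marginal_family, s2[i],
                                shape_of[pairs[i, 2]])
        stats::median(t2 / t1)
      }, numeric(1))
    })
  }
  tibble::tibble(therapy1 = unname(pairs[, 1]), therapy2 = unname(pairs[, 2]),
                 true_median_ratio = med)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d patients, %d treatment lines\n",
              length(unique(x$records$patient_id)), nrow(x$records)))
  cat(sprintf("  Spearman target %.2f, final-line censor rate %.2f\n",
              x$truth$rho_spearman, x$truth$censor_rate))
  invisible(x)
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf(
    "Synthetic cohort config: %d patients, seed %d, %s marginals,\n  rho_s = %.2f, censor rate %.2f, %d strata, %d histologies\n",
    x$n_patients, x$seed, x$marginal_family, x$copula_rho_spearman,
    x$censor_rate, nrow(x$strata), length(x$sequence_graph)))
  invisible(x)
}
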