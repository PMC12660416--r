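# k-sample log-rank test (unweighted), shared by duration and ratio analyses.

#' k-sample log-rank test for right-censored samples
#'
#' Standard (unweighted) log-rank test comparing the censored distributions of
#' two or more groups: observed-minus-expected event counts per group summed
#' over the pooled distinct event times, with the hypergeometric covariance,
#' yielding a chi-square statistic on k - 1 degrees of freedom. The test is
#' rank-based: any strictly increasing transform of the value axis leaves the
#' statistic unchanged, so values may be durations, ratios, or transforms
#' thereof (negative values are accepted). No small-sample continuity
#' correction is applied.
#'
#' @param value Numeric vector of finite observation values (months, ratios,
#'   or any monotone transform).
#' @param event Logical (or 0/1) event indicator.
#' @param group Grouping vector (factor, character or integer); must contain
#'   at least two distinct groups.
#'
#' @return An object of class `logrank_test`: list with `statistic` (chi-square
#'   scale), `df` (k - 1), `p_value`, per-group `observed` and `expected`
#'   event counts, and group sizes `n`.
#'
#' @examples
#' lr <- logrank_test(c(1, 2, 3, 10, 11, 12), rep(TRUE, 6), rep(c("a", "b"), each = 3))
#' lr$p_value
#' @export
logrank_test <- function(value, event, group) {
  obs <- check_censored_obs(value, event, require_nonnegative = FALSE)
  value <- obs$value
  event <- obs$event
  if (length(group) != length(value)) {
    stop("`group` must match the length of `value`", call. = FALSE)
  }
  if (anyNA(group)) stop("missing group labels are not allowed", call. = FALSE)
  group <- factor(group)
  group <- droplevels(group)
  k <- nlevels(group)
  if (k < 2L) stop("at least two groups are required", call. = FALSE)
  if (!any(event)) {
    stop("the log-rank test requires at least one event overall", call. = FALSE)
  }

  times <- sort(unique(value[event]))
  m <- length(times)
  # d_mat[g, j]: events in group g at time j; r_mat[g, j]: at risk in g at j.
  d_mat <- vapply(times, function(t) {
    tab <- tapply(event & value == t, group, sum)
    as.numeric(ifelse(is.na(tab), 0, tab))
  }, numeric(k))
  r_mat <- vapply(times, function(t) {
    tab <- tapply(value >= t, group, sum)
    as.numeric(ifelse(is.na(tab), 0, tab))
  }, numeric(k))
  d_mat <- matrix(d_mat, nrow = k)
  r_mat <- matrix(r_mat, nrow = k)
  d_j <- colSums(d_mat)
  r_j <- colSums(r_mat)

  expected <- r_mat %*% diag(d_j / r_j, nrow = m) |> rowSums()
  observed <- rowSums(d_mat)
  oe <- observed - expected

  # Hypergeometric covariance summed over event times.
  V <- matrix(0, k, k)
  for (j in seq_len(m)) {
    if (r_j[j] <= 1) next
    cj <- d_j[j] * (r_j[j] - d_j[j]) / (r_j[j] - 1)
    p <- r_mat[, j] / r_j[j]
    V <- V + cj * (diag(p, nrow = k) - tcrossprod(p))
  }

  idx <- seq_len(k - 1L)
  Vsub <- V[idx, idx, drop = FALSE]
  stat <- tryCatch(
    drop(t(oe[idx]) %*% solve(Vsub, oe[idx])),
    error = function(e) drop(t(oe[idx]) %*% MASS::ginv(Vsub) %*% oe[idx])
  )
  stat <- max(stat, 0)
  df <- k - 1L
  structure(
    list(statistic = stat, df = df,
         p_value = stats::pchisq(stat, df, lower.tail = FALSE),
         observed = stats::setNames(observed, levels(group)),
         expected = stats::setNames(expected, levels(group)),
         n = stats::setNames(as.integer(table(group)), levels(group))),
    class = "logrank_test"
  )
}

#' @export
print.logrank_test <- function(x, ...) {
  cat(sprintf("Log-rank test: chi-square = %.4g on %d df, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  tab <- data.frame(n = x$n, observed = x$observed,
                    expected = round(x$expected, 2))
  print(tab)
  invisible(x)
}
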