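# Right-censored one-sample estimation: product-limit curve, median, CI.
# The duration axis is agnostic: months or a dimensionless PFS ratio.

#' Fit a Kaplan-Meier (product-limit) curve
#'
#' Estimates the survival function of a right-censored sample. The value axis
#' may be a duration in months or a dimensionless PFS ratio; only ordering and
#' censoring status matter. At tied values, events are processed before
#' censorings (standard product-limit convention): censored observations remain
#' in the risk set at their own value and leave it afterwards.
#'
#' @param value Numeric vector of nonnegative, finite observation values.
#' @param event Logical vector (or 0/1), `TRUE` when the event (progression or
#'   death) was observed at `value`, `FALSE` when the observation is
#'   right-censored there.
#' @param conf_level Confidence level for the pointwise intervals (default
#'   0.95). Intervals use the complementary log-log (log(-log)) transform of
#'   Greenwood's variance.
#'
#' @return An object of class `km_curve`: a list with `times` (distinct event
#'   times, increasing), `survival`, `at_risk`, `events`, `n_total`,
#'   `n_events`, pointwise `ci_low`/`ci_high`, `conf_level` and
#'   `conf_type = "log-log"`.
#'
#' @examples
#' fit <- fit_km(c(1, 2, 3, 4), c(TRUE, FALSE, TRUE, TRUE))
#' fit$survival  # 0.75, 0.375, 0
#' @seealso [km_median_ci()], [km_curve_table()], [logrank_test()]
#' @export
fit_km <- function(value, event, conf_level = 0.95) {
  obs <- check_censored_obs(value, event, require_nonnegative = TRUE)
  curve <- km_compute(obs$value, obs$event)
  ci <- km_pointwise_ci(curve, conf_level)
  structure(
    c(curve, list(ci_low = ci$low, ci_high = ci$high,
                  conf_level = conf_level, conf_type = "log-log")),
    class = "km_curve"
  )
}

# Shared input validation for censored samples.
check_censored_obs <- function(value, event, require_nonnegative = TRUE) {
  if (length(value) == 0L) {
    stop("at least one observation is required", call. = FALSE)
  }
  if (!is.numeric(value)) stop("`value` must be numeric", call. = FALSE)
  if (is.numeric(event)) event <- event != 0
  if (!is.logical(event)) stop("`event` must be logical or 0/1", call. = FALSE)
  if (length(event) != length(value)) {
    stop("`value` and `event` must have the same length", call. = FALSE)
  }
  if (anyNA(value) || anyNA(event)) {
    stop("missing values are not allowed in censored observations", call. = FALSE)
  }
  if (!all(is.finite(value))) stop("all values must be finite", call. = FALSE)
  if (require_nonnegative && any(value < 0)) {
    stop("negative durations are not allowed", call. = FALSE)
  }
  list(value = as.numeric(value), event = event)
}

# Core product-limit computation; no sign restriction on the axis so the same
# routine serves copula margins evaluated on log-transformed values.
km_compute <- function(value, event) {
  times <- sort(unique(value[event]))
  at_risk <- vapply(times, function(t) sum(value >= t), integer(1))
  n_event <- vapply(times, function(t) sum(event & value == t), integer(1))
  frac <- 1 - n_event / at_risk
  survival <- cumprod(frac)
  # Greenwood cumulative variance term; Inf once the curve reaches zero.
  gw_terms <- ifelse(n_event == at_risk, Inf,
                     n_event / (at_risk * (at_risk - n_event)))
  list(times = times, survival = survival, at_risk = at_risk,
       events = n_event, greenwood = cumsum(gw_terms),
       n_total = length(value), n_events = sum(event))
}

km_pointwise_ci <- function(curve, conf_level) {
  s <- curve$survival
  if (length(s) == 0L) {
    return(list(low = numeric(0), high = numeric(0)))
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  se_cll <- sqrt(curve$greenwood) / abs(log(s))
  ok <- is.finite(se_cll) & s > 0 & s < 1
  low <- high <- rep(NA_real_, length(s))
  low[ok] <- s[ok]^exp(z * se_cll[ok])
  high[ok] <- s[ok]^exp(-z * se_cll[ok])
  list(low = low, high = high)
}

#' Median and confidence interval from a Kaplan-Meier curve
#'
#' The median is the smallest event time at which the survival curve is at or
#' below 0.5 (step-function convention: for an even uncensored sample this is
#' the lower of the two middle order statistics, not their average). The
#' confidence interval inverts the pointwise complementary log-log intervals:
#' a time belongs to the interval while 0.5 still lies between its pointwise
#' survival limits. Undefined quantities (curve never crossing the required
#' level) are returned as `NA` and printed as `"NE"` (not estimable).
#'
#' @param curve A `km_curve` from [fit_km()].
#' @param conf_level Confidence level; defaults to the level stored in `curve`.
#' @return An object of class `km_summary`: list with `median`, `ci_low`,
#'   `ci_high` (each `NA` when not estimable), `conf_level`,
#'   `conf_type = "log-log"`, `n` and `n_events`.
#' @examples
#' km_median_ci(fit_km(1:5, rep(TRUE, 5)))$median  # 3
#' @export
km_median_ci <- function(curve, conf_level = NULL) {
  stopifnot(inherits(curve, "km_curve"))
  if (is.null(conf_level)) conf_level <- curve$conf_level
  if (conf_level <= 0 || conf_level >= 1) {
    stop("`conf_level` must be in (0, 1)", call. = FALSE)
  }
  if (conf_level == curve$conf_level) {
    ci <- list(low = curve$ci_low, high = curve$ci_high)
  } else {
    ci <- km_pointwise_ci(curve, conf_level)
  }
  tol <- 1e-9
  first_below <- function(x) {
    i <- which(!is.na(x) & x <= 0.5 + tol)
    if (length(i)) curve$times[i[1]] else NA_real_
  }
  structure(
    list(median = first_below(curve$survival),
         ci_low = first_below(ci$low),
         ci_high = first_below(ci$high),
         conf_level = conf_level, conf_type = "log-log",
         n = curve$n_total, n_events = curve$n_events),
    class = "km_summary"
  )
}

#' Tidy export of a Kaplan-Meier curve
#'
#' @param curve A `km_curve`.
#' @return A tibble with one row per distinct event time: `time`, `at_risk`,
#'   `events`, `survival`, `ci_low`, `ci_high`.
#' @export
km_curve_table <- function(curve) {
  stopifnot(inherits(curve, "km_curve"))
  tibble::tibble(
    time = curve$times,
    at_risk = curve$at_risk,
    events = curve$events,
    survival = curve$survival,
    ci_low = curve$ci_low,
    ci_high = curve$ci_high
  )
}

# "NE" is the reporting convention for medians/CI bounds the curve never
# reaches (not estimable).
format_ne <- function(x, digits = 2) {
  ifelse(is.na(x), "NE", formatC(x, digits = digits, format = "fg"))
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: n = %d, events = %d, %d distinct event times\n",
              x$n_total, x$n_events, length(x$times)))
  s <- km_median_ci(x)
  print(s)
  invisible(x)
}

#' @export
print.km_summary <- function(x, ...) {
  cat(sprintf("median %s (%d%% CI %s-%s) [n = %d, events = %d, %s CI]\n",
              format_ne(x$median), round(100 * x$conf_level),
              format_ne(x$ci_low), format_ne(x$ci_high),
              x$n, x$n_events, x$conf_type))
  invisible(x)
}
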