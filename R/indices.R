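# HotSpots and accumulated thermal stress / cooling indices: degree heating
# weeks and months, degree cooling weeks, trailing-mean SST, and the
# standard bleaching alert rules.

#' Specify a thermal index variant
#'
#' Declarative description of an index: which accumulation (`dhw`, `dhm`,
#' `dcw`, or trailing `weekly_sst` / `monthly_sst`), which climatological
#' baseline (MMM or MMM_max) and how HotSpots are filtered before
#' accumulation -- either a constant threshold alpha (degC, searched over
#' [0, 1.5]) or a per-cell threshold beta * sigma_m (beta dimensionless,
#' searched over [0.1, 2.5]).  The degree cooling week ignores filtering
#' (its cool-spot cutoff is fixed at 0 degC).
#'
#' @param kind one of `"dhw"`, `"dhm"`, `"dcw"`, `"weekly_sst"`,
#'   `"monthly_sst"`.
#' @param baseline `"mmm"` or `"mmm_max"`.
#' @param filter_mode `"constant_alpha"` or `"sigma_scaled_beta"`.
#' @param alpha constant HotSpot filtering threshold, degC, in [0, 1.5].
#' @param beta sigma_m multiplier, dimensionless, in [0.1, 2.5].
#' @param alert_rule `"fixed_value"` (index-specific standard cutoffs) or
#'   `"sigma_scaled"` (DHW > 2.45 * sigma_m).
#' @return an object of class `index_spec`.
#' @export
index_spec <- function(kind = c("dhw", "dhm", "dcw", "weekly_sst", "monthly_sst"),
                       baseline = c("mmm", "mmm_max"),
                       filter_mode = c("constant_alpha", "sigma_scaled_beta"),
                       alpha = 1, beta = 1,
                       alert_rule = c("fixed_value", "sigma_scaled")) {
  kind <- match.arg(kind)
  baseline <- match.arg(baseline)
  filter_mode <- match.arg(filter_mode)
  alert_rule <- match.arg(alert_rule)
  if (filter_mode == "constant_alpha" && (alpha < 0 || alpha > 1.5)) {
    stop("alpha must lie in [0, 1.5]", call. = FALSE)
  }
  if (filter_mode == "sigma_scaled_beta" && (beta < 0.1 || beta > 2.5)) {
    stop("beta must lie in [0.1, 2.5]", call. = FALSE)
  }
  structure(list(kind = kind, baseline = baseline, filter_mode = filter_mode,
                 alpha = alpha, beta = beta, alert_rule = alert_rule),
            class = "index_spec")
}

#' Daily HotSpot series
#'
#' Positive-only SST anomaly above the climatological baseline:
#' `HS = max(SST - baseline, 0)`.
#'
#' @param sst_series numeric vector (or matrix, rows = records) of daily
#'   SST, degC.
#' @param baseline scalar or per-row baseline (MMM or MMM_max), degC.
#' @return HotSpot values, same shape as `sst_series`.
#' @export
hotspots <- function(sst_series, baseline) {
  if (any(!is.finite(baseline))) stop("baseline must be finite", call. = FALSE)
  pmax(sst_series - baseline, 0)
}

check_window <- function(x, need, pad_missing, what) {
  n <- if (is.matrix(x)) ncol(x) else length(x)
  if (n < need && !pad_missing) {
    stop(sprintf("%s needs a %d-value trailing window (got %d)", what, need, n),
         call. = FALSE)
  }
  invisible(n)
}

# Shared accumulation core: sum of values passing `v >= threshold`, with
# optional renormalization for missing days (<= 10% of the window).
accumulate_filtered <- function(v, threshold, window, divisor,
                                max_missing_frac = 0.1) {
  fin <- is.finite(v)
  n_missing <- sum(!fin)
  if (n_missing > max_missing_frac * window) {
    stop(sprintf("window has %d missing values (> %.0f%% of %d)",
                 n_missing, 100 * max_missing_frac, window), call. = FALSE)
  }
  s <- sum(v[fin & v >= threshold])
  if (n_missing > 0) s <- s * window / sum(fin)
  s / divisor
}

#' Degree heating week
#'
#' `(1/7) * sum over the trailing 84 days of HS_i where HS_i >= threshold`
#' (degC-weeks).  The full HotSpot value is accumulated once it passes the
#' filter, not the excess above it.  Up to 10% of window days may be
#' missing; the sum is then renormalized by `84 / valid days`.
#'
#' @param hs daily HotSpot series ending on the observation date: a vector
#'   of >= 84 values, or a matrix with 84 columns (rows = records).
#' @param threshold filtering threshold, degC (scalar, or per-row vector
#'   for sigma-scaled filtering of a matrix input).
#' @return DHW in degC-weeks (scalar or per-row vector); never negative.
#' @export
degree_heating_week <- function(hs, threshold = 1) {
  if (is.matrix(hs)) {
    if (ncol(hs) != 84) stop("HS window matrix must have 84 columns",
                             call. = FALSE)
    thr <- rep_len(threshold, nrow(hs))
    return(vapply(seq_len(nrow(hs)), function(i)
      accumulate_filtered(hs[i, ], thr[i], 84, 7), numeric(1)))
  }
  check_window(hs, 84, FALSE, "DHW")
  w <- hs[(length(hs) - 83):length(hs)]
  accumulate_filtered(w, threshold, 84, 7)
}

#' Degree heating month
#'
#' Sum of the trailing 12 monthly HotSpots at or above the filtering
#' threshold (degC-months).
#'
#' @param hs_monthly monthly HotSpot series (>= 12 values; the trailing 12
#'   are used), or a matrix with 12 columns.
#' @param threshold filtering threshold, degC.
#' @return DHM in degC-months.
#' @export
degree_heating_month <- function(hs_monthly, threshold = 1) {
  if (is.matrix(hs_monthly)) {
    if (ncol(hs_monthly) != 12) stop("monthly HS matrix must have 12 columns",
                                     call. = FALSE)
    thr <- rep_len(threshold, nrow(hs_monthly))
    return(vapply(seq_len(nrow(hs_monthly)), function(i)
      accumulate_filtered(hs_monthly[i, ], thr[i], 12, 1), numeric(1)))
  }
  check_window(hs_monthly, 12, FALSE, "DHM")
  w <- hs_monthly[(length(hs_monthly) - 11):length(hs_monthly)]
  accumulate_filtered(w, threshold, 12, 1)
}

#' Degree cooling week
#'
#' Accumulated cooling below the MMM baseline over the trailing 84 days:
#' `(1/7) * sum of (MMM - SST_i)` over days where the cool spot is
#' non-negative (the cutoff is fixed at 0 degC; no filtering threshold).
#'
#' @param sst_series daily SST (vector of >= 84 values, or matrix with 84
#'   columns).
#' @param mmm baseline MMM, degC (scalar or per-row).
#' @return DCW in degC-weeks.
#' @export
degree_cooling_week <- function(sst_series, mmm) {
  if (is.matrix(sst_series)) {
    if (ncol(sst_series) != 84) stop("SST window matrix must have 84 columns",
                                     call. = FALSE)
    m <- rep_len(mmm, nrow(sst_series))
    return(vapply(seq_len(nrow(sst_series)), function(i)
      accumulate_filtered(m[i] - sst_series[i, ], 0, 84, 7), numeric(1)))
  }
  check_window(sst_series, 84, FALSE, "DCW")
  w <- sst_series[(length(sst_series) - 83):length(sst_series)]
  accumulate_filtered(mmm - w, 0, 84, 7)
}

#' Trailing-mean SST
#'
#' Arithmetic mean of the trailing window ending on the observation date:
#' 7 days for weekly SST, one calendar month (given as ~30 trailing days)
#' for monthly SST.
#'
#' @param sst_series daily SST values ending on the observation date.
#' @param window number of trailing days (7 for weekly; pass the month's
#'   day count for monthly).
#' @return mean SST, degC.
#' @export
trailing_mean_sst <- function(sst_series, window = 7) {
  check_window(sst_series, window, FALSE, "trailing mean")
  mean(sst_series[(length(sst_series) - window + 1):length(sst_series)])
}

#' Standard bleaching alert
#'
#' Fixed-value rules: monthly SST > 30 degC; weekly SST > 31.5 degC;
#' DHW > 4 degC-weeks; DHM > 1 degC-month.  Sigma-scaled rule (DHW only):
#' alert when `DHW > 2.45 * sigma_m`, 2.45 degC^-1 being the global
#' reciprocal median of historical SST variability.  All comparisons are
#' strict.
#'
#' @param value index value(s).
#' @param spec an [index_spec()]; its `kind` and `alert_rule` pick the rule.
#' @param sigma_m per-record sigma_m, required for the sigma-scaled rule.
#' @return logical alert flag(s).
#' @export
standard_alert <- function(value, spec, sigma_m = NULL) {
  stopifnot(inherits(spec, "index_spec"))
  if (spec$alert_rule == "sigma_scaled") {
    if (is.null(sigma_m)) stop("sigma-scaled alert requires sigma_m",
                               call. = FALSE)
    return(value > 2.45 * sigma_m)
  }
  cutoff <- switch(spec$kind,
                   monthly_sst = 30, weekly_sst = 31.5, dhw = 4, dhm = 1,
                   dcw = stop("no standard alert is defined for DCW",
                              call. = FALSE))
  value > cutoff
}
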