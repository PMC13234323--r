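# Augmented Dickey-Fuller unit-root test.
#
# No unit-root package ships with this environment, so the test is
# implemented directly: an OLS Dickey-Fuller regression with augmentation
# lags chosen by AIC over 0..maxlag (Schwert's rule for maxlag, identical
# observation window during selection so ICs are comparable), and
# MacKinnon's (1994) regression-surface approximation for the p-value.
# The algorithm mirrors the de-facto standard implementation so results are
# directly comparable with mainstream statistical software.

# MacKinnon (1994) response-surface coefficients for the tau distribution,
# N = 1 (published tables; "c" = constant, "ct" = constant + trend).
.mackinnon <- list(
  c = list(max = 2.74, min = -18.83, star = -1.61,
           smallp = c(2.1659, 1.4412, 0.038269),
           largep = c(1.7339, 0.93202, -0.12745, -0.010368)),
  ct = list(max = 0.7, min = -16.18, star = -2.89,
            smallp = c(3.2512, 1.6047, 0.049588),
            largep = c(2.5261, 0.61654, -0.37956, -0.060285))
)

.mackinnon_p <- function(stat, regression = "c") {
  tab <- .mackinnon[[regression]]
  if (stat > tab$max) return(1)
  if (stat < tab$min) return(0)
  coefs <- if (stat <= tab$star) tab$smallp else tab$largep
  pnorm(sum(coefs * stat^(seq_along(coefs) - 1)))
}

# Dickey-Fuller design matrix: response dy[t], regressors
# [const, (trend), y[t-1], dy[t-1..lag]] for t = lag+1 .. n-1.
.df_design <- function(x, lag, regression) {
  n <- length(x)
  dx <- diff(x)
  nobs <- n - 1 - lag
  t_idx <- (lag + 1):(n - 1)          # indices into dx
  X <- cbind(const = rep(1, nobs))
  if (regression == "ct") X <- cbind(X, trend = seq_len(nobs))
  X <- cbind(X, level = x[t_idx])
  if (lag > 0) {
    for (j in seq_len(lag)) X <- cbind(X, dx[t_idx - j])
  }
  list(y = dx[t_idx], X = X, nobs = nobs)
}

#' Augmented Dickey-Fuller test
#'
#' Tests the null hypothesis of a unit root (the series drifts / trends
#' over time) against stationarity. Small p-values mean the series can be
#' treated as stationary. Augmentation lags are selected by AIC over
#' `0..maxlag` with `maxlag` from Schwert's rule,
#' `min(floor(n/2) - ntrend - 1, ceiling(12 (n/100)^(1/4)))`; the p-value
#' uses MacKinnon's (1994) approximation.
#'
#' @param x Numeric series without missing values.
#' @param regression `"c"` (constant, default) or `"ct"` (constant and
#'   linear trend) in the test regression.
#' @param maxlag Maximum augmentation lag (default: Schwert's rule).
#' @return A list with `statistic` (tau), `p_value`, `lag` (lags used) and
#'   `nobs`.
#' @references MacKinnon, J.G. (1994). Approximate asymptotic distribution
#'   functions for unit-root and cointegration tests. *Journal of Business
#'   & Economic Statistics*, 12, 167-176.
#' @export
adf_test <- function(x, regression = c("c", "ct"), maxlag = NULL) {
  regression <- match.arg(regression)
  x <- as.numeric(x)
  if (anyNA(x)) stop("`x` must not contain missing values.", call. = FALSE)
  n <- length(x)
  if (n < 10) stop("Series too short for an ADF test.", call. = FALSE)
  if (max(x) == min(x)) stop("`x` is constant.", call. = FALSE)
  ntrend <- nchar(regression)
  if (is.null(maxlag)) {
    maxlag <- min(n %/% 2 - ntrend - 1, ceiling(12 * (n / 100)^0.25))
  }
  maxlag <- as.integer(maxlag)
  if (maxlag < 0) stop("Series too short for the requested regression.", call. = FALSE)

  # Lag selection: same observation window for every candidate lag.
  d_full <- .df_design(x, maxlag, regression)
  n_fixed <- ncol(d_full$X) - maxlag   # deterministic terms + level
  ics <- vapply(0:maxlag, function(lag) {
    Xl <- d_full$X[, seq_len(n_fixed + lag), drop = FALSE]
    fit <- stats::lm.fit(Xl, d_full$y)
    ssr <- sum(fit$residuals^2)
    d_full$nobs * log(ssr / d_full$nobs) + 2 * ncol(Xl)
  }, numeric(1))
  best_lag <- which.min(ics) - 1L

  # Final regression at the selected lag uses all available observations.
  d <- .df_design(x, best_lag, regression)
  fit <- lm(d$y ~ d$X - 1)
  sm <- summary(fit)$coefficients
  lvl <- which(colnames(d$X) == "level")
  stat <- sm[lvl, "t value"]
  list(statistic = unname(stat),
       p_value = .mackinnon_p(unname(stat), regression),
       lag = best_lag,
       nobs = d$nobs)
}

#' Stationarity gate for post-error slowing estimation
#'
#' Checks whether a participant's ordered RT series follows a trend over
#' time using the Augmented Dickey-Fuller test. If the unit-root null is
#' rejected (`p < alpha`) the series counts as stationary and the
#' traditional post-error slowing estimator (mean post-error RT) is
#' appropriate; otherwise the matched (robust) pre/post-difference
#' estimator should be used.
#'
#' A constant series is stationary by convention and flagged.
#'
#' @param rt_series Numeric RT series in trial order; `NA`s (timeouts) are
#'   dropped. At least 30 non-missing values are required.
#' @param alpha Significance level of the gate.
#' @param regression Deterministic terms of the test regression, see
#'   [adf_test()].
#' @return A list with `stationary`, `p_value`, `statistic`, `lag`,
#'   `constant` (degenerate-series flag) and `method_used`
#'   (`"traditional"` or `"robust"`).
#' @export
adf_gate <- function(rt_series, alpha = 0.05, regression = "c") {
  rt <- rt_series[!is.na(rt_series)]
  if (length(rt) < 30) {
    stop("Need at least 30 non-missing RTs for the stationarity gate.",
         call. = FALSE)
  }
  if (max(rt) == min(rt)) {
    return(list(stationary = TRUE, p_value = NA_real_, statistic = NA_real_,
                lag = NA_integer_, constant = TRUE, method_used = "traditional"))
  }
  res <- adf_test(rt, regression = regression)
  stationary <- res$p_value < alpha
  list(stationary = stationary, p_value = res$p_value,
       statistic = res$statistic, lag = res$lag, constant = FALSE,
       method_used = if (stationary) "traditional" else "robust")
}
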