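# Complexity synchronization: cross-correlation of delta(t) series.

#' Average scaling series over channels
#'
#' Per-window mean of delta across channels, skipping missing values; a
#' window is missing only when every channel is missing there.
#'
#' @param series List of `scaling_series` sharing one window grid.
#' @param label Label for the averaged series.
#' @return A `scaling_series`.
#' @export
average_scaling <- function(series, label = "EEG-mean") {
  if (inherits(series, "scaling_series")) series <- list(series)
  check_shared_grid(series)
  mat <- vapply(series, function(s) s$deltas,
                numeric(length(series[[1L]]$times)))
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = 1L)
  deltas <- rowMeans(mat, na.rm = TRUE)
  deltas[!is.finite(deltas)] <- NA_real_
  structure(list(times = series[[1L]]$times, deltas = deltas,
                 reasons = rep("", length(deltas)), label = label,
                 params = series[[1L]]$params),
            class = "scaling_series")
}

#' Maximum lagged cross-correlation between two scaling series
#'
#' For every integer lag in `-max_lag..max_lag` (in window steps) the
#' Pearson correlation `cor(a[t], b[t + lag])` is computed over the jointly
#' non-missing overlapping windows (pairwise deletion per lag). Returns the
#' maximum, its lag, and the zero-lag coefficient. A positive lag means `b`
#' trails `a`. Ties are broken toward the smallest `|lag|`, then the
#' negative lag.
#'
#' @param a,b `scaling_series` on one window grid.
#' @param max_lag Largest lag magnitude scanned, in steps (default 10).
#' @param min_overlap Minimum jointly non-missing pairs for a lag to enter
#'   the scan (default 8, also required at lag 0).
#' @return List with `r_max`, `lag`, `r_zero_lag`, `n` (pairs at the
#'   maximizing lag) and `lags` (data frame of the full scan).
#' @export
max_crosscorr <- function(a, b, max_lag = 10L, min_overlap = 8L) {
  check_shared_grid(list(a, b))
  x <- a$deltas; y <- b$deltas
  n <- length(x)
  lags <- seq.int(-max_lag, max_lag)
  r <- rep(NA_real_, length(lags))
  np <- integer(length(lags))
  for (i in seq_along(lags)) {
    l <- lags[i]
    ia <- seq.int(max(1L, 1L - l), min(n, n - l))
    ib <- ia + l
    ok <- !is.na(x[ia]) & !is.na(y[ib])
    np[i] <- sum(ok)
    if (np[i] >= max(4L, if (l == 0L) min_overlap else 4L) &&
        stats::sd(x[ia][ok]) > 0 && stats::sd(y[ib][ok]) > 0)
      r[i] <- stats::cor(x[ia][ok], y[ib][ok])
  }
  i0 <- which(lags == 0L)
  if (is.na(r[i0]) || np[i0] < min_overlap)
    stop("insufficient jointly non-missing overlap at lag 0")
  # max over lags; ties -> smallest |lag|, then negative lag
  ord <- order(-r, abs(lags), lags)
  best <- ord[which(!is.na(r[ord]))[1L]]
  list(r_max = r[best], lag = lags[best], r_zero_lag = r[i0],
       n = np[best],
       lags = data.frame(lag = lags, r = r, n = np))
}

#' Fisher-z confidence interval for a correlation coefficient
#'
#' `z = atanh(r)` with standard error `1/sqrt(n - 3)`; the 95% bounds are
#' back-transformed with `tanh`. Exact for independent bivariate-normal
#' pairs; overlapping-window delta series are autocorrelated, so treat the
#' nominal interval as anti-conservative (see [cs_report]'s
#' `effective_n` option).
#'
#' @param r Correlation coefficient.
#' @param n Number of pairs (>= 4).
#' @param conf Confidence level (default 0.95).
#' @return Numeric vector `c(low, high)`; degenerate `[r, r]` when |r| = 1.
#' @export
corr_confidence <- function(r, n, conf = 0.95) {
  if (n < 4L) stop("need at least 4 pairs for a confidence interval")
  if (abs(r) >= 1) return(c(r, r))
  zc <- stats::qnorm(1 - (1 - conf) / 2)
  z <- atanh(r)
  hw <- zc / sqrt(n - 3)
  c(tanh(z - hw), tanh(z + hw))
}

# Effective sample size of two AR(1)-like series: n (1 - p1 p2)/(1 + p1 p2)
# with p = lag-1 autocorrelations. Guards overlap-induced autocorrelation.
effective_n <- function(x, y) {
  ac1 <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 3L || stats::sd(v) == 0) return(0)
    stats::cor(v[-1L], v[-length(v)])
  }
  p <- ac1(x) * ac1(y)
  p <- min(max(p, 0), 0.999)
  sum(!is.na(x) & !is.na(y)) * (1 - p) / (1 + p)
}

#' Complexity-synchronization report for a multichannel recording
#'
#' Runs the full pipeline: sliding-window scaling indices per channel,
#' averaging of the EEG-group series, and the three pairwise maximum lagged
#' cross-correlations (EEG-mean vs ECG, EEG-mean vs RESP, ECG vs RESP) with
#' 95% Fisher confidence intervals.
#'
#' @param rec An [mc_recording] with `"EEG"` (>= 1 channel), `"ECG"` and
#'   `"RESP"` role groups.
#' @param L_sec,step_sec Sliding-window parameters, see [sliding_delta].
#' @param params MDEA parameters, see [mdea_params].
#' @param max_lag Lag scan half-range in steps.
#' @param use_effective_n If `TRUE`, confidence intervals use an
#'   autocorrelation-corrected effective sample size instead of the raw
#'   pair count (default off).
#' @return Object of class `cs_report`: a data frame with one row per pair
#'   (`pair`, `r_max`, `lag`, `r_zero_lag`, `ci_low`, `ci_high`, `n`), with
#'   the per-channel series in attribute `series`.
#' @export
cs_report <- function(rec, L_sec = 60, step_sec = 20, params = mdea_params(),
                      max_lag = 10L, use_effective_n = FALSE) {
  stopifnot(inherits(rec, "mc_recording"))
  for (role in c("EEG", "ECG", "RESP")) role_labels(rec, role)
  series <- sliding_delta_multichannel(rec, L_sec, step_sec, params)
  eeg_mean <- average_scaling(series[role_labels(rec, "EEG")])
  ecg <- series[[role_labels(rec, "ECG")[1L]]]
  resp <- series[[role_labels(rec, "RESP")[1L]]]
  pairs <- list(`Ave. EEG-ECG`  = list(eeg_mean, ecg),
                `Ave. EEG-Resp.` = list(eeg_mean, resp),
                `ECG-Resp.`      = list(ecg, resp))
  rows <- lapply(names(pairs), function(nm) {
    ab <- pairs[[nm]]
    cc <- max_crosscorr(ab[[1L]], ab[[2L]], max_lag = max_lag)
    n_ci <- if (use_effective_n)
      max(4, effective_n(ab[[1L]]$deltas, ab[[2L]]$deltas)) else cc$n
    ci <- corr_confidence(cc$r_max, n_ci)
    data.frame(pair = nm, r_max = cc$r_max, lag = cc$lag,
               r_zero_lag = cc$r_zero_lag, ci_low = ci[1L], ci_high = ci[2L],
               n = cc$n)
  })
  out <- do.call(rbind, rows)
  attr(out, "series") <- c(list(`EEG-mean` = eeg_mean), series)
  class(out) <- c("cs_report", "data.frame")
  out
}

#' @export
print.cs_report <- function(x, ...) {
  cat("<cs_report> maximum lagged cross-correlations of delta(t) series\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
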