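# Sliding-window scaling extraction and complexity-index conversions.

#' Time-resolved scaling index of one channel
#'
#' Applies [mdea_slice] to consecutive windows of `L_sec` seconds stepped by
#' `step_sec` seconds (half-open sample windows, so adjacent steps never
#' share a boundary sample). Window times are reported at window centers.
#' A window whose fit is invalid yields a missing delta at exactly that
#' position; missing values are never interpolated.
#'
#' @param sig A [sampled_signal] of duration >= `L_sec`.
#' @param L_sec Window length in seconds (default 60, the standard slice).
#' @param step_sec Step between window starts in seconds (default 20).
#' @param params MDEA parameters, see [mdea_params].
#' @return Object of class `scaling_series`: list with `times` (s, window
#'   centers), `deltas` (NA where invalid), `reasons`, `label`, `params`.
#' @export
sliding_delta <- function(sig, L_sec = 60, step_sec = 20,
                          params = mdea_params()) {
  stopifnot(inherits(sig, "sampled_signal"))
  if (L_sec <= 0 || step_sec <= 0) stop("window and step must be positive")
  n <- length(sig$values)
  dur <- n / sig$fs
  if (dur < L_sec) stop("signal shorter than one window")
  Lp <- as.integer(round(L_sec * sig$fs))
  sp <- step_sec * sig$fs
  n_win <- floor((dur - L_sec) / step_sec) + 1L
  deltas <- rep(NA_real_, n_win)
  reasons <- character(n_win)
  for (k in seq_len(n_win)) {
    start <- as.integer(round((k - 1L) * sp)) + 1L
    fit <- mdea_slice(sig$values[start:(start + Lp - 1L)], params)
    if (fit$valid) deltas[k] <- fit$delta
    reasons[k] <- fit$reason
  }
  structure(list(times = (seq_len(n_win) - 1L) * step_sec + L_sec / 2,
                 deltas = deltas, reasons = reasons, label = sig$label,
                 params = c(params, list(L_sec = L_sec, step_sec = step_sec))),
            class = "scaling_series")
}

#' @export
print.scaling_series <- function(x, ...) {
  cat(sprintf("<scaling_series> '%s': %d windows, %d valid, delta in [%.3f, %.3f]\n",
              x$label, length(x$deltas), sum(!is.na(x$deltas)),
              suppressWarnings(min(x$deltas, na.rm = TRUE)),
              suppressWarnings(max(x$deltas, na.rm = TRUE))))
  invisible(x)
}

#' Time-resolved scaling indices for every channel of a recording
#'
#' @param rec An [mc_recording].
#' @inheritParams sliding_delta
#' @return Named list of `scaling_series`, one per channel, sharing one
#'   window grid.
#' @export
sliding_delta_multichannel <- function(rec, L_sec = 60, step_sec = 20,
                                       params = mdea_params()) {
  stopifnot(inherits(rec, "mc_recording"))
  lapply(rec$channels, sliding_delta, L_sec = L_sec, step_sec = step_sec,
         params = params)
}

#' Convert a scaling index to the waiting-time power-law index
#'
#' On the asymptotically ergodic branch (finite mean waiting time,
#' `2 <= mu <= 3`) `mu = 1 + 1/delta`; on the non-ergodic branch
#' (infinite mean, `1 <= mu <= 2`) `mu = 1 + delta`. A result outside its
#' branch range is returned with a warning, never clipped.
#'
#' @param delta Scaling index (> 0).
#' @param branch `"ergodic"` or `"non_ergodic"`.
#' @return The waiting-time index mu.
#' @export
delta_to_mu <- function(delta, branch = c("ergodic", "non_ergodic")) {
  branch <- match.arg(branch)
  if (any(delta <= 0)) stop("'delta' must be positive")
  mu <- if (branch == "ergodic") 1 + 1 / delta else 1 + delta
  rng <- if (branch == "ergodic") c(2, 3) else c(1, 2)
  if (any(mu < rng[1] - 1e-12 | mu > rng[2] + 1e-12))
    warning("mu = ", paste(signif(mu, 4), collapse = ", "),
            " outside the ", branch, " branch range [",
            rng[1], ", ", rng[2], "]")
  mu
}

#' Waiting-time index of a delta on a given branch (inverse of delta_to_mu)
#' @param mu Waiting-time index.
#' @param branch `"ergodic"` or `"non_ergodic"`.
#' @return The scaling index delta.
#' @export
mu_to_delta <- function(mu, branch = c("ergodic", "non_ergodic")) {
  branch <- match.arg(branch)
  if (branch == "ergodic") 1 / (mu - 1) else mu - 1
}

#' Convert the waiting-time index to the power-spectrum index
#'
#' `beta = 3 - mu`; `mu = 2` is the 1/f point (`beta = 1`).
#'
#' @param mu Waiting-time index, nominally in \[1, 3\].
#' @return The spectral index beta.
#' @export
mu_to_beta <- function(mu) {
  if (any(mu < 1 | mu > 3))
    warning("mu outside [1, 3]; beta = 3 - mu computed anyway")
  3 - mu
}

#' Inverse of [mu_to_beta]
#' @param beta Spectral index.
#' @return The waiting-time index mu.
#' @export
beta_to_mu <- function(beta) 3 - beta

#' Fractal dimension of the scaled record
#'
#' `D = 2 - delta` for a self-affine record with scaling index delta.
#'
#' @param delta Scaling index in (0, 2).
#' @return The fractal dimension D.
#' @export
delta_to_fractal_dim <- function(delta) {
  if (any(delta <= 0 | delta >= 2)) stop("'delta' must lie in (0, 2)")
  2 - delta
}

#' All complexity indices implied by one scaling index
#'
#' @param delta Scaling index.
#' @param branch Waiting-time branch, see [delta_to_mu].
#' @return Data frame with columns `delta`, `mu`, `beta`, `D`, `branch`.
#' @export
complexity_indices <- function(delta, branch = c("ergodic", "non_ergodic")) {
  branch <- match.arg(branch)
  mu <- suppressWarnings(delta_to_mu(delta, branch))
  data.frame(delta = delta, mu = mu, beta = mu_to_beta(mu),
             D = delta_to_fractal_dim(delta), branch = branch)
}

#' Scaling series as a data frame
#'
#' @param x A `scaling_series` or list of them sharing a window grid.
#' @param ... Unused.
#' @return Data frame with `time_sec` and one delta column per channel.
#' @export
as.data.frame.scaling_series <- function(x, ...) {
  df <- data.frame(time_sec = x$times)
  df[[x$label]] <- x$deltas
  df
}

#' @rdname as.data.frame.scaling_series
#' @param series List of `scaling_series` on one grid.
#' @export
scaling_table <- function(series) {
  if (inherits(series, "scaling_series")) series <- list(series)
  check_shared_grid(series)
  df <- data.frame(time_sec = series[[1L]]$times)
  for (s in series) df[[s$label]] <- s$deltas
  df
}

#' Convert a window size in samples to seconds (and back)
#'
#' MDEA windows are specified in samples; recordings in seconds. E.g. a
#' 100-sample window at 512 Hz spans 100/512 = 0.195 s.
#'
#' @param w Window size in samples.
#' @param fs Sampling rate in Hz.
#' @return Duration in seconds.
#' @export
samples_to_sec <- function(w, fs) {
  stopifnot(fs > 0)
  w / fs
}

#' @rdname samples_to_sec
#' @param t_sec Duration in seconds.
#' @export
sec_to_samples <- function(t_sec, fs) {
  stopifnot(fs > 0)
  as.integer(round(t_sec * fs))
}

check_shared_grid <- function(series) {
  t0 <- series[[1L]]$times
  for (s in series)
    if (length(s$times) != length(t0) || any(abs(s$times - t0) > 1e-9))
      stop("scaling series do not share a window grid")
  invisible(TRUE)
}
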