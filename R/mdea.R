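# Modified diffusion entropy analysis (MDEA).
#
# A continuous signal is normalized to [0,1] and partitioned into equal
# horizontal stripes; a crossing from one stripe to another marks a crucial
# event. The cumulative event count is a diffusion trajectory; slicing it at
# every event origin and histogramming the displacement after w samples
# gives P(x, w), whose Shannon entropy grows as S(w) = S_ref + delta ln w
# for a self-similar process. The slope delta is the scaling index: 0.5 for
# ordinary diffusion, >0.5 for superdiffusive crucial-event dynamics.

#' Project a sequence onto the unit interval
#'
#' Subtracts the minimum and divides by the resulting maximum, so the output
#' spans exactly \[0, 1\]. A constant input cannot be normalized; it is
#' returned as-is with attribute `degenerate = TRUE`, which downstream MDEA
#' treats as "no events".
#'
#' @param values Numeric vector, length >= 2.
#' @return Numeric vector in \[0, 1\] with a logical `degenerate` attribute.
#' @export
normalize_unit <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values to normalize")
  y <- values - min(values)
  m <- max(y)
  if (m == 0) return(structure(y, degenerate = TRUE))
  structure(y / m, degenerate = FALSE)
}

n_stripes <- function(stripe_size) {
  if (stripe_size <= 0 || stripe_size >= 1)
    stop("'stripe_size' must lie in (0, 1)")
  k <- round(1 / stripe_size)
  if (abs(k * stripe_size - 1) > 1e-9) {
    warning("stripe_size does not divide 1; using ",
            floor(1 / stripe_size) + 1L, " stripes")
    k <- floor(1 / stripe_size) + 1L
  }
  as.integer(k)
}

#' Stripe index of normalized values
#'
#' Maps values in \[0, 1\] to 0-based stripe ids by `floor(x / stripe_size)`;
#' a value exactly on a boundary belongs to the upper stripe, and `x = 1` is
#' clamped into the top stripe.
#'
#' @param x Numeric vector in \[0, 1\].
#' @param stripe_size Stripe width in (0, 1); should divide 1 (else a warning
#'   is issued and one extra stripe covers the remainder).
#' @return Integer stripe ids in `0 .. round(1/stripe_size) - 1`.
#' @export
stripe_index <- function(x, stripe_size) {
  if (any(x < 0 | x > 1)) stop("values outside [0, 1]")
  k <- n_stripes(stripe_size)
  pmin.int(as.integer(floor(x / stripe_size)), k - 1L)
}

#' Extract crucial events as stripe crossings
#'
#' An event is recorded at sample `i` whenever the stripe of the normalized
#' signal differs from the stripe at sample `i - 1`. The first sample can
#' never carry an event.
#'
#' @param norm Normalized signal in \[0, 1\] (see [normalize_unit]); a
#'   degenerate input yields an all-zero event series.
#' @param stripe_size Stripe width in (0, 1).
#' @param fs Sampling rate in Hz (carried through for bookkeeping).
#' @return An object of class `event_series`: list with `indicator`
#'   (integer 0/1 per sample), `n_samples` and `fs`.
#' @export
extract_events <- function(norm, stripe_size, fs = 1) {
  n <- length(norm)
  ind <- integer(n)
  if (!isTRUE(attr(norm, "degenerate")) && n >= 2L) {
    id <- stripe_index(as.numeric(norm), stripe_size)
    ind[-1L] <- as.integer(id[-1L] != id[-n])
  }
  structure(list(indicator = ind, n_samples = n, fs = fs),
            class = "event_series")
}

#' Diffusion trajectory from an event series
#'
#' The trajectory is the running count of events; its value at the final
#' sample equals the total event count. Event origins are the sample indices
#' (1-based) carrying an event.
#'
#' @param ev An `event_series`.
#' @return An object of class `diffusion_trajectory`: list with `positions`,
#'   `event_origins`, `n_samples`.
#' @export
diffusion_trajectory <- function(ev) {
  stopifnot(inherits(ev, "event_series"))
  structure(list(positions = cumsum(ev$indicator),
                 event_origins = which(ev$indicator == 1L),
                 n_samples = ev$n_samples),
            class = "diffusion_trajectory")
}

#' Event-anchored displacements at window size w
#'
#' Every event origin whose window of `w` samples fits inside the record
#' contributes the trajectory displacement over that window. Displacements
#' are integers in `0..w` (at most one event per sample).
#'
#' @param traj A `diffusion_trajectory`.
#' @param w Window size in samples (>= 1).
#' @return Integer vector of displacements (possibly empty).
#' @export
displacement_ensemble <- function(traj, w) {
  stopifnot(inherits(traj, "diffusion_trajectory"), w >= 1)
  org <- traj$event_origins
  org <- org[org + w <= traj$n_samples]
  if (!length(org)) return(integer(0))
  traj$positions[org + w] - traj$positions[org]
}

#' Shannon entropy of a displacement ensemble
#'
#' Histogram over integer displacement values with unit bins; with the bin
#' width fixed at 1 the discretization offset is independent of the window
#' size, so it moves the entropy intercept, never the slope.
#'
#' @param displacements Non-empty integer vector.
#' @return Entropy in nats (>= 0).
#' @export
shannon_entropy <- function(displacements) {
  if (!length(displacements)) stop("empty displacement ensemble")
  p <- tabulate(displacements + 1L)
  p <- p[p > 0] / length(displacements)
  -sum(p * log(p))
}

#' Entropy as a function of window size
#'
#' Computes `S(w)` over a grid of window sizes; entries whose ensemble holds
#' fewer than `min_origins` usable origins are dropped (recorded in the
#' `dropped_w` attribute).
#'
#' @param traj A `diffusion_trajectory`.
#' @param ws Strictly increasing integer window sizes (each >= 1).
#' @param min_origins Minimum usable origins per window size.
#' @return Object of class `entropy_curve`: data frame with columns `w`, `S`
#'   (nats) and `n_origins`, attribute `dropped_w`.
#' @export
entropy_curve <- function(traj, ws, min_origins = 50L) {
  stopifnot(inherits(traj, "diffusion_trajectory"))
  ws <- as.integer(ws)
  if (any(ws < 1L) || is.unsorted(ws, strictly = TRUE))
    stop("'ws' must be strictly increasing window sizes >= 1")
  S <- n_org <- numeric(length(ws))
  for (i in seq_along(ws)) {
    d <- displacement_ensemble(traj, ws[i])
    n_org[i] <- length(d)
    S[i] <- if (length(d)) shannon_entropy(d) else NA_real_
  }
  keep <- n_org >= min_origins
  if (!any(keep)) stop("empty entropy curve: no window size retained enough origins")
  structure(data.frame(w = ws[keep], S = S[keep], n_origins = n_org[keep]),
            dropped_w = ws[!keep],
            class = c("entropy_curve", "data.frame"))
}

#' Fit the scaling index from an entropy curve
#'
#' Ordinary least squares of `S` on `ln w` over `[w_lo, w_hi]`; the slope is
#' the scaling index delta and the intercept estimates the reference entropy.
#' The fit is flagged invalid (never an error) when fewer than 4 usable
#' points fall in range, when `r2 < r2_min`, or when delta leaves (0, 1.5)
#' (ballistic/failed fits).
#'
#' @param curve An `entropy_curve`.
#' @param w_lo,w_hi Fit range in samples.
#' @param r2_min Minimum coefficient of determination for a valid fit.
#' @return Object of class `scaling_fit`: list with `delta`, `intercept`,
#'   `r2`, `w_lo`, `w_hi`, `n_points`, `valid`, `reason`.
#' @export
fit_delta <- function(curve, w_lo = 10, w_hi = 1000, r2_min = 0.9) {
  stopifnot(inherits(curve, "entropy_curve"))
  sel <- curve$w >= w_lo & curve$w <= w_hi & is.finite(curve$S)
  out <- list(delta = NA_real_, intercept = NA_real_, r2 = NA_real_,
              w_lo = w_lo, w_hi = w_hi, n_points = sum(sel),
              valid = FALSE, reason = "ok")
  class(out) <- "scaling_fit"
  if (sum(sel) < 4L) {
    out$reason <- "too-few-points"
    return(out)
  }
  lw <- log(curve$w[sel])
  S <- curve$S[sel]
  fit <- stats::lm.fit(cbind(1, lw), S)
  out$intercept <- fit$coefficients[[1L]]
  out$delta <- fit$coefficients[[2L]]
  ss_tot <- sum((S - mean(S))^2)
  out$r2 <- if (ss_tot > 0) 1 - sum(fit$residuals^2) / ss_tot else 1
  if (out$delta <= 0 || out$delta >= 1.5) {
    out$reason <- "delta-out-of-band"
  } else if (out$r2 < r2_min) {
    out$reason <- "poor-linearity"
  } else {
    out$valid <- TRUE
  }
  out
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf(
    "<scaling_fit> delta = %.4f (intercept %.3f, r2 %.4f, w in [%g, %g], %d pts)%s\n",
    x$delta, x$intercept, x$r2, x$w_lo, x$w_hi, x$n_points,
    if (x$valid) "" else paste0(" INVALID: ", x$reason)))
  invisible(x)
}

#' Default MDEA parameter set
#'
#' @param stripe_size Stripe width on the normalized signal (default 0.01,
#'   i.e. 100 stripes).
#' @param w_grid Window-size grid in samples; `NULL` (default) uses 30
#'   log-spaced integers from 10 to `min(3000, n/10)` per slice.
#' @param w_lo,w_hi Fit range in samples.
#' @param min_origins Minimum usable origins per window size.
#' @param min_events Minimum event count for a slice to be fitted.
#' @param r2_min Minimum r-squared for a valid fit.
#' @return Named list of parameters.
#' @export
mdea_params <- function(stripe_size = 0.01, w_grid = NULL, w_lo = 10,
                        w_hi = 1000, min_origins = 50L, min_events = 200L,
                        r2_min = 0.9) {
  list(stripe_size = stripe_size, w_grid = w_grid, w_lo = w_lo, w_hi = w_hi,
       min_origins = as.integer(min_origins),
       min_events = as.integer(min_events), r2_min = r2_min)
}

#' Default log-spaced window-size grid for a slice of n samples
#'
#' 30 log-spaced integers from 10 up to `min(w_max_cap, n/10)`.
#'
#' @param n Slice length in samples.
#' @param w_max_cap Upper cap on the largest window (default 3000).
#' @return Integer vector of window sizes.
#' @export
default_w_grid <- function(n, w_max_cap = 3000) {
  w_hi <- max(10, min(w_max_cap, floor(n / 10)))
  ws <- unique(round(exp(seq(log(10), log(w_hi), length.out = 30L))))
  as.integer(ws[ws >= 1])
}

#' Full MDEA on one data slice
#'
#' Composition of the MDEA chain: normalize to \[0, 1\], extract stripe
#' crossings, accumulate the diffusion trajectory, build the entropy curve
#' and fit the scaling index. Degenerate slices (constant signal) and slices
#' with fewer than `min_events` events return an invalid fit with a reason
#' code; invalidity is a value, not an exception.
#'
#' @param values Numeric vector (one slice of signal), length >= `w_hi + 2`
#'   recommended.
#' @param params Parameter list from [mdea_params].
#' @return A `scaling_fit` with an `n_events` element.
#' @export
mdea_slice <- function(values, params = mdea_params()) {
  invalid <- function(reason, n_events = 0L) {
    structure(list(delta = NA_real_, intercept = NA_real_, r2 = NA_real_,
                   w_lo = params$w_lo, w_hi = params$w_hi, n_points = 0L,
                   valid = FALSE, reason = reason, n_events = n_events),
              class = "scaling_fit")
  }
  norm <- normalize_unit(values)
  if (isTRUE(attr(norm, "degenerate")))
    return(invalid("degenerate-normalization"))
  ev <- extract_events(norm, params$stripe_size)
  n_events <- sum(ev$indicator)
  if (n_events < params$min_events)
    return(invalid("too-few-events", n_events))
  traj <- diffusion_trajectory(ev)
  ws <- if (is.null(params$w_grid)) default_w_grid(length(values))
        else as.integer(params$w_grid)
  curve <- tryCatch(entropy_curve(traj, ws, params$min_origins),
                    error = function(e) NULL)
  if (is.null(curve)) return(invalid("empty-entropy-curve", n_events))
  fit <- fit_delta(curve, params$w_lo, min(params$w_hi, max(curve$w)),
                   params$r2_min)
  fit$n_events <- n_events
  fit
}
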