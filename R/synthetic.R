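# Generators of renewal crucial-event processes with known scaling, plus
# Gaussian and fractional-Brownian controls. Every generator takes an
# explicit integer seed; no global RNG state is relied upon.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Sample inverse-power-law waiting times
#'
#' Draws from the regularized hyperbolic (Lomax/shifted-Pareto) density
#' `psi(tau) = (mu - 1) T^(mu-1) / (T + tau)^mu`, whose tail follows
#' `tau^-mu`. Inverse-transform sampling:
#' `tau = T (u^(-1/(mu-1)) - 1)`, `u ~ U(0, 1)`. The mean is `T/(mu - 2)`
#' for `mu > 2` and infinite for `mu <= 2` (non-ergodic regime).
#'
#' @param n Number of waiting times.
#' @param mu Power-law index (> 1); complexity regime is `1 < mu < 3`.
#' @param T_scale Scale parameter T, in samples (> 0).
#' @param seed Integer seed.
#' @return Numeric vector of waiting times in samples (real-valued).
#' @export
sample_waiting_times <- function(n, mu, T_scale = 5, seed = 1L) {
  if (mu <= 1) stop("'mu' must exceed 1")
  if (T_scale <= 0) stop("'T_scale' must be positive")
  stopifnot(n >= 1)
  with_seed(seed, {
    u <- stats::runif(n)
    T_scale * (u^(-1 / (mu - 1)) - 1)
  })
}

#' Place waiting times as events on a sample grid
#'
#' Events sit at cumulative waiting times rounded to integer sample indices
#' (0-based), truncated at the grid end; rounding collisions merge into a
#' single event. Index 0 never carries an event.
#'
#' @param taus Waiting times in samples.
#' @param n_samples Grid length (>= 2).
#' @param fs Sampling rate carried on the result.
#' @return An `event_series`.
#' @export
events_from_waiting_times <- function(taus, n_samples, fs = 1) {
  stopifnot(n_samples >= 2)
  t_ev <- round(cumsum(taus))
  t_ev <- unique(t_ev[t_ev >= 1 & t_ev <= n_samples - 1])
  ind <- integer(n_samples)
  ind[t_ev + 1L] <- 1L        # 0-based event index -> 1-based storage
  structure(list(indicator = ind, n_samples = as.integer(n_samples), fs = fs),
            class = "event_series")
}

#' Continuous signal whose stripe crossings reproduce a planted event train
#'
#' Builds a piecewise-constant signal sitting at stripe centers: at every
#' planted event the level jumps to a uniformly chosen different stripe's
#' center and holds until the next event. Because consecutive distinct
#' stripe centers stay more than one stripe width apart even after
#' re-normalization, `extract_events(normalize_unit(x), s)` recovers the
#' planted indicator exactly.
#'
#' @param ev An `event_series`.
#' @param stripe_size Stripe width (>= 2 stripes required).
#' @param seed Integer seed for the jump targets.
#' @return A [sampled_signal] with values in \[0, 1\].
#' @export
signal_from_events <- function(ev, stripe_size = 0.01, seed = 1L) {
  stopifnot(inherits(ev, "event_series"))
  k <- n_stripes(stripe_size)
  if (k < 2L) stop("need at least 2 stripes")
  n_ev <- sum(ev$indicator)
  lv <- with_seed(seed, {
    lev <- integer(n_ev + 1L)
    lev[1L] <- sample.int(k, 1L) - 1L
    if (n_ev > 0L) {
      # jump to a uniformly chosen stripe different from the current one
      step <- sample.int(k - 1L, n_ev, replace = TRUE)
      for (i in seq_len(n_ev))
        lev[i + 1L] <- (lev[i] + step[i]) %% k
    }
    lev
  })
  seg <- cumsum(ev$indicator) + 1L        # segment id per sample
  centers <- (seq_len(k) - 0.5) * stripe_size
  sampled_signal(centers[lv[seg] + 1L], fs = ev$fs, label = "renewal")
}

#' Renewal crucial-event channel with known waiting-time index
#'
#' Composition of [sample_waiting_times], [events_from_waiting_times] and
#' [signal_from_events]: a continuous signal whose MDEA scaling index should
#' follow the waiting-time branch relations (`delta = 1/(mu - 1)` for
#' `2 < mu < 3`, `delta = mu - 1` for `1 < mu < 2`, `delta = 0.5` for
#' `mu >= 3`).
#'
#' @param duration_sec Record duration in seconds.
#' @param fs Sampling rate in Hz.
#' @param mu Waiting-time power-law index.
#' @param T_scale Waiting-time scale in samples.
#' @param stripe_size Stripe width of the synthesized jumps.
#' @param seed Integer seed.
#' @return A [sampled_signal].
#' @export
generate_renewal_channel <- function(duration_sec, fs, mu, T_scale = 5,
                                     stripe_size = 0.01, seed = 1L) {
  n <- as.integer(round(duration_sec * fs))
  # draw enough waiting times to span the record, in batches
  taus <- numeric(0)
  total <- 0
  batch_seed <- seed
  mean_wait <- if (mu > 2.05) T_scale / (mu - 2) else T_scale * 10
  while (total < n) {
    batch_seed <- batch_seed + 1L
    need <- max(1000L, ceiling(1.5 * (n - total) / mean_wait))
    b <- sample_waiting_times(need, mu, T_scale, seed = batch_seed)
    taus <- c(taus, b)
    total <- total + sum(b)
  }
  ev <- events_from_waiting_times(taus, n, fs = fs)
  sig <- signal_from_events(ev, stripe_size, seed = seed)
  sig$label <- sprintf("renewal_mu%.2f", mu)
  sig
}

# Renewal event train whose waiting times are drawn with mu frozen at each
# draw's start time (piecewise-renewal approximation). Draws are batched in
# chunks of `chunk_sec` within which mu is treated as constant; valid while
# mu(t) varies slowly against the mean waiting time.
varying_mu_events <- function(n, fs, mu_fun, T_scale, seed, chunk_sec = 2) {
  chunk <- chunk_sec * fs
  with_seed(seed, {
    t_cur <- 0
    ev_times <- vector("list", ceiling(n / chunk) + 1L)
    i <- 0L
    while (t_cur < n - 1) {
      i <- i + 1L
      mu_c <- mu_fun(t_cur)
      mean_w <- if (mu_c > 2.05) T_scale / (mu_c - 2) else T_scale * 20
      k <- max(100L, ceiling(1.5 * chunk / max(mean_w, 0.5)))
      tau <- T_scale * (stats::runif(k)^(-1 / (mu_c - 1)) - 1)
      ends <- t_cur + cumsum(tau)
      starts <- c(t_cur, ends[-k])
      acc <- which(starts < t_cur + chunk)   # waits starting in this chunk
      ev_times[[i]] <- ends[acc]
      t_cur <- ends[acc[length(acc)]]
    }
    ev <- round(unlist(ev_times[seq_len(i)]))
    ev <- unique(ev[ev >= 1 & ev <= n - 1])
    ind <- integer(n)
    ind[ev + 1L] <- 1L
    structure(list(indicator = ind, n_samples = as.integer(n), fs = fs),
              class = "event_series")
  })
}

#' Multichannel ensemble with a shared slowly varying waiting-time index
#'
#' Every channel is a renewal stripe-jump signal whose waiting times are
#' drawn with the instantaneous index
#' `mu(t) = mu_base + mu_amplitude * sin(2 pi t / period_sec + phase)`
#' evaluated at the draw's start time (piecewise-renewal approximation,
#' valid while mu(t) varies slowly against the mean waiting time). With
#' `synchronized = TRUE` all channels share one driver (phase 0), so their
#' delta(t) series covary. With `synchronized = FALSE` each channel's driver
#' is made incoherent with the others: an independent random initial phase,
#' an independent period factor in \[0.3, 0.9\], and slow phase diffusion
#' (`phase_sd` rad per sqrt-second), so that even nearby periods drift
#' apart over the record.
#'
#' @param n_eeg,n_ecg,n_resp Channels per role.
#' @param duration_sec Record duration in seconds.
#' @param fs Sampling rate in Hz (default 512, the acquisition rate of the
#'   physiological recordings this emulates; the estimator works in samples,
#'   and 60 s windows need ~10^4 samples for delta(t) to resolve the
#'   modulation).
#' @param mu_base,mu_amplitude,period_sec The mu(t) modulation; requires
#'   `mu_base - mu_amplitude > 1`.
#' @param T_scale Waiting-time scale in samples (default 0.5, giving
#'   thousands of events per 60 s window at 512 Hz).
#' @param stripe_size Stripe width of the synthesized jumps.
#' @param synchronized Shared driver (`TRUE`) or independent per-channel
#'   drivers (`FALSE`).
#' @param phase_sd Phase-diffusion scale (rad/sqrt(s)) of desynchronized
#'   drivers; ignored when `synchronized = TRUE`.
#' @param seed Integer seed.
#' @return An [mc_recording] with `"EEG"`, `"ECG"`, `"RESP"` groups.
#' @export
generate_cs_ensemble <- function(n_eeg = 8L, n_ecg = 1L, n_resp = 1L,
                                 duration_sec = 3600, fs = 512,
                                 mu_base = 2.7, mu_amplitude = 0.5,
                                 period_sec = 400, T_scale = 0.5,
                                 stripe_size = 0.01, synchronized = TRUE,
                                 phase_sd = 0.1, seed = 1L) {
  if (mu_base - mu_amplitude <= 1)
    stop("mu(t) leaves the valid range: need mu_base - mu_amplitude > 1")
  n <- as.integer(round(duration_sec * fs))
  n_ch <- n_eeg + n_ecg + n_resp
  labels <- c(sprintf("EEG%02d", seq_len(n_eeg)),
              sprintf("ECG%d", seq_len(n_ecg)),
              sprintf("RESP%d", seq_len(n_resp)))
  phases <- rep(0, n_ch)
  pfac <- rep(1, n_ch)
  jitter <- vector("list", n_ch)
  if (!synchronized) {
    rnd <- with_seed(seed * 1009L + 7L, {
      list(ph = stats::runif(n_ch, 0, 2 * pi),
           pf = stats::runif(n_ch, 0.3, 0.9),
           jit = replicate(n_ch, cumsum(stats::rnorm(
             ceiling(duration_sec) + 2L, 0, phase_sd)), simplify = FALSE))
    })
    phases <- rnd$ph
    pfac <- rnd$pf
    jitter <- rnd$jit
  }
  channels <- vector("list", n_ch)
  for (j in seq_len(n_ch)) {
    omega <- 2 * pi / (period_sec * pfac[j] * fs)   # rad per sample
    jit_j <- jitter[[j]]
    mu_fun <- if (synchronized) {
      function(t) mu_base + mu_amplitude * sin(omega * t)
    } else {
      function(t) {
        ph_jit <- jit_j[min(length(jit_j), floor(t / fs) + 1L)]
        mu_base + mu_amplitude * sin(omega * t + phases[j] + ph_jit)
      }
    }
    ev <- varying_mu_events(n, fs, mu_fun, T_scale, seed = seed * 1000L + j)
    sig <- signal_from_events(ev, stripe_size, seed = seed * 1000L + j)
    sig$label <- labels[j]
    channels[[j]] <- sig
  }
  mc_recording(channels,
               groups = list(EEG = labels[seq_len(n_eeg)],
                             ECG = labels[n_eeg + seq_len(n_ecg)],
                             RESP = labels[n_eeg + n_ecg + seq_len(n_resp)]))
}

#' Instantaneous mu(t) of the synchronized ensemble driver
#'
#' Convenience for validation: the shared modulation evaluated at given
#' times, e.g. at the window centers of a `scaling_series`.
#'
#' @param t_sec Times in seconds.
#' @param mu_base,mu_amplitude,period_sec As in [generate_cs_ensemble]
#'   (note `t_sec` is in seconds here while the generator works in samples).
#' @return Numeric vector `mu(t)`.
#' @export
ensemble_mu_of_t <- function(t_sec, mu_base = 2.7, mu_amplitude = 0.5,
                             period_sec = 400) {
  mu_base + mu_amplitude * sin(2 * pi * t_sec / period_sec)
}

#' Gaussian random walk (ordinary diffusion control)
#'
#' Cumulative sum of iid standard normal increments; its MDEA scaling index
#' is 0.5 (the diffusive, Gaussian case).
#'
#' @param n_samples Length of the walk (>= 2).
#' @param fs Sampling rate carried on the result.
#' @param seed Integer seed.
#' @return A [sampled_signal].
#' @export
gaussian_random_walk <- function(n_samples, fs = 1, seed = 1L) {
  stopifnot(n_samples >= 2)
  vals <- with_seed(seed, cumsum(stats::rnorm(n_samples)))
  sampled_signal(vals, fs = fs, label = "gauss_walk")
}

#' Fractional Brownian motion control
#'
#' Exact-covariance synthesis of fractional Gaussian noise by circulant
#' embedding (Davies-Harte) of the increment autocovariance
#' `gamma(k) = (|k+1|^2H - 2|k|^2H + |k-1|^2H) / 2`, cumulatively summed.
#'
#' @param n_samples Path length (>= 2).
#' @param H Hurst exponent in (0, 1); `H = 0.5` reduces to Brownian motion.
#' @param fs Sampling rate carried on the result.
#' @param seed Integer seed.
#' @return A [sampled_signal].
#' @export
fbm_control <- function(n_samples, H, fs = 1, seed = 1L) {
  if (H <= 0 || H >= 1) stop("'H' must lie in (0, 1)")
  stopifnot(n_samples >= 2)
  n <- as.integer(n_samples)
  k <- 0:n
  gamma_k <- 0.5 * (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) +
                    abs(k - 1)^(2 * H))
  # first row of the 2n-circulant embedding; eigenvalues via FFT
  circ <- c(gamma_k[1:n], gamma_k[n + 1L], gamma_k[n:2])
  lambda <- Re(stats::fft(circ))
  lambda[lambda < 0] <- 0                  # clip tiny negative round-off
  m <- 2L * n
  z <- with_seed(seed, stats::rnorm(m) + 1i * stats::rnorm(m))
  w <- stats::fft(sqrt(lambda / (2 * m)) * z, inverse = FALSE)
  fgn <- Re(w)[1:n] * sqrt(2)
  sampled_signal(cumsum(fgn), fs = fs, label = sprintf("fbm_H%.2f", H))
}
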