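# Brute-force reference implementations of the event/diffusion chain,
# written as plain loops with no shared code with the package internals.

bf_stripe <- function(x, s) {
  k <- round(1 / s)
  id <- floor(x / s)
  if (id > k - 1) id <- k - 1
  id
}

bf_events <- function(norm, s) {
  n <- length(norm)
  ind <- integer(n)
  for (i in 2:n)
    if (bf_stripe(norm[i], s) != bf_stripe(norm[i - 1], s)) ind[i] <- 1L
  ind
}

bf_positions <- function(ind) {
  pos <- integer(length(ind))
  acc <- 0L
  for (i in seq_along(ind)) {
    acc <- acc + ind[i]
    pos[i] <- acc
  }
  pos
}

bf_displacements <- function(ind, w) {
  pos <- bf_positions(ind)
  n <- length(ind)
  out <- integer(0)
  for (i in seq_len(n))
    if (ind[i] == 1L && i + w <= n)
      out <- c(out, pos[i + w] - pos[i])
  out
}

bf_entropy <- function(d) {
  vals <- unique(d)
  s <- 0
  for (v in vals) {
    p <- sum(d == v) / length(d)
    s <- s - p * log(p)
  }
  s
}

# small library of test signals (all <= 200 samples)
oracle_test_signals <- function() {
  set.seed(404)
  sigs <- list(
    ramp = seq(0, 1, length.out = 120),
    sine = (sin(seq(0, 6 * pi, length.out = 150)) + 1) / 2,
    steps = rep(c(0.05, 0.55, 0.25, 0.95, 0.45), each = 30)
  )
  for (r in 1:6)
    sigs[[paste0("walk", r)]] <- {
      x <- cumsum(rnorm(180))
      (x - min(x)) / (max(x) - min(x))
    }
  for (r in 1:4)
    sigs[[paste0("unif", r)]] <- runif(60)
  sigs
}

# asymptotic-regime MDEA protocol used for scaling-index recovery studies
recovery_params <- function(w_lo = 100, w_hi = 10000) {
  mdea_params(
    w_grid = unique(round(exp(seq(log(10), log(50000), length.out = 40L)))),
    w_lo = w_lo, w_hi = w_hi, min_origins = 30
  )
}
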