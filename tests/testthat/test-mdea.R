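test_that("normalization projects onto [0,1] and flags constant input", {
  expect_equal(as.numeric(normalize_unit(c(2, 4, 6))), c(0, 0.5, 1))
  expect_equal(as.numeric(normalize_unit(c(-1, 0, 1))), c(0, 0.5, 1))
  deg <- normalize_unit(c(5, 5, 5))
  expect_true(attr(deg, "degenerate"))
  fit <- mdea_slice(rep(5, 5000))
  expect_false(fit$valid)
  expect_identical(fit$reason, "degenerate-normalization")
  expect_true(is.na(fit$delta))
})

test_that("stripe ids follow the floor convention with a clamped top stripe", {
  expect_identical(stripe_index(0, 0.01), 0L)
  expect_identical(stripe_index(0.999, 0.01), 99L)
  expect_identical(stripe_index(1.0, 0.1), 9L)
  expect_identical(stripe_index(c(0, 0.35, 0.30001, 1), 0.1),
                   c(0L, 3L, 3L, 9L))
  expect_error(stripe_index(1.2, 0.1), "outside")
  expect_warning(stripe_index(0.5, 0.03), "divide")
})

test_that("events are stripe crossings between consecutive samples", {
  ev <- extract_events(normalize_unit(rep(c(0.2, 0.2), 50) * c(1, 1)),
                       0.1)
  # constant after normalization -> degenerate -> no events
  expect_equal(sum(ev$indicator), 0)
  ev2 <- extract_events(structure(c(0.05, 0.15, 0.12, 0.31),
                                  degenerate = FALSE), 0.1)
  expect_identical(ev2$indicator, c(0L, 1L, 0L, 1L))
  ramp <- structure(seq(0, 1, length.out = 1000), degenerate = FALSE)
  expect_equal(sum(extract_events(ramp, 0.1)$indicator), 9)
  expect_identical(extract_events(ramp, 0.1)$indicator[1L], 0L)
})

test_that("the diffusion trajectory is the running event count", {
  ev <- structure(list(indicator = c(0L, 1L, 1L, 0L, 1L), n_samples = 5L,
                       fs = 1), class = "event_series")
  traj <- diffusion_trajectory(ev)
  expect_equal(traj$positions, c(0, 1, 2, 2, 3))
  expect_equal(traj$event_origins, c(2L, 3L, 5L))
  flat <- diffusion_trajectory(structure(
    list(indicator = integer(10), n_samples = 10L, fs = 1),
    class = "event_series"))
  expect_equal(flat$positions, rep(0L, 10))
  expect_length(flat$event_origins, 0)
  # conservation on random indicators
  set.seed(9)
  for (r in 1:10) {
    ind <- c(0L, rbinom(99, 1, 0.3))
    tr <- diffusion_trajectory(structure(
      list(indicator = ind, n_samples = 100L, fs = 1),
      class = "event_series"))
    expect_equal(tr$positions[100], sum(ind))
  }
})

test_that("displacement ensembles are event-anchored and bounded by w", {
  ind <- c(0L, 1L, 0L, 1L, 0L, 1L, 0L)
  traj <- diffusion_trajectory(structure(
    list(indicator = ind, n_samples = 7L, fs = 1), class = "event_series"))
  expect_equal(sort(displacement_ensemble(traj, 2)), c(1, 1))
  # single event near the end, window does not fit
  ind2 <- c(0L, 0L, 0L, 1L, 0L)
  traj2 <- diffusion_trajectory(structure(
    list(indicator = ind2, n_samples = 5L, fs = 1), class = "event_series"))
  expect_length(displacement_ensemble(traj2, 3), 0)
  set.seed(2)
  ind3 <- c(0L, rbinom(499, 1, 0.2))
  traj3 <- diffusion_trajectory(structure(
    list(indicator = ind3, n_samples = 500L, fs = 1),
    class = "event_series"))
  for (w in c(1, 7, 50))
    expect_true(all(displacement_ensemble(traj3, w) <= w))
})

test_that("entropy uses unit-bin histograms of integer displacements", {
  expect_equal(shannon_entropy(rep(3L, 40)), 0)
  expect_equal(shannon_entropy(c(0L, 1L, 2L, 3L)), log(4))
  expect_equal(shannon_entropy(c(0L, 0L, 1L, 1L)), log(2))
  expect_error(shannon_entropy(integer(0)), "empty")
})

test_that("entropy curves drop under-populated windows and flag flat input", {
  flat <- diffusion_trajectory(structure(
    list(indicator = integer(100), n_samples = 100L, fs = 1),
    class = "event_series"))
  expect_error(entropy_curve(flat, c(5L, 10L)), "empty entropy curve")
  # deterministic event every 2 samples: displacement at even w is constant
  ind <- rep(c(0L, 1L), 300)
  traj <- diffusion_trajectory(structure(
    list(indicator = ind, n_samples = 600L, fs = 1),
    class = "event_series"))
  cur <- entropy_curve(traj, c(2L, 4L, 8L, 16L), min_origins = 10)
  expect_true(all(cur$S == 0))
  expect_true(all(diff(cur$n_origins) <= 0))
  # Poisson train: S grows with w
  set.seed(31)
  evp <- events_from_waiting_times(rexp(5000, 1 / 6), 20000)
  curp <- entropy_curve(diffusion_trajectory(evp),
                        c(10L, 40L, 160L, 640L), min_origins = 30)
  expect_true(all(diff(curp$S) > 0))
})

test_that("the scaling fit recovers exact synthetic lines", {
  ws <- as.integer(round(exp(seq(log(10), log(1000), length.out = 20))))
  cur <- structure(data.frame(w = ws, S = 0.5 * log(ws) + 1,
                              n_origins = rep(100L, length(ws))),
                   class = c("entropy_curve", "data.frame"))
  fit <- fit_delta(cur, 10, 1000)
  expect_equal(fit$delta, 0.5, tolerance = 1e-12)
  expect_equal(fit$intercept, 1, tolerance = 1e-12)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  expect_true(fit$valid)
  cur$S <- rep(2, length(ws))
  flat <- fit_delta(cur, 10, 1000)
  expect_equal(flat$delta, 0)
  expect_false(flat$valid)           # zero slope is outside (0, 1.5)
  few <- fit_delta(cur[1:3, ], 10, 1000)
  expect_identical(few$reason, "too-few-points")
})

test_that("a Poisson event train scales diffusively (delta = 0.5)", {
  set.seed(77)
  ev <- events_from_waiting_times(rexp(80000, 1 / 6), 300000)
  cur <- entropy_curve(diffusion_trajectory(ev),
                       default_w_grid(300000), min_origins = 50)
  fit <- fit_delta(cur, 10, 1000)
  expect_true(fit$valid)
  expect_equal(fit$delta, 0.5, tolerance = 0.1)   # 0.5 +/- 0.05
})

test_that("mdea_slice is exactly invariant under affine transforms", {
  set.seed(12)
  x <- cumsum(rnorm(20000))
  f0 <- mdea_slice(x, mdea_params(min_events = 50))
  f1 <- mdea_slice(3.7 * x + 11, mdea_params(min_events = 50))
  expect_identical(f0$delta, f1$delta)
  expect_identical(f0$n_events, f1$n_events)
})

test_that("halving the stripe size never loses events", {
  set.seed(8)
  for (r in 1:6) {
    x <- cumsum(rnorm(2000))
    norm <- normalize_unit(x)
    for (s in c(0.2, 0.1, 0.05)) {
      n_coarse <- sum(extract_events(norm, s)$indicator)
      n_fine <- sum(extract_events(norm, s / 2)$indicator)
      expect_gte(n_fine, n_coarse)
    }
  }
})

test_that("entropy increments match the self-similarity relation S(lw) - S(w) = delta log(l)", {
  set.seed(21)
  ev <- events_from_waiting_times(rexp(150000, 1 / 5), 500000)
  traj <- diffusion_trajectory(ev)
  for (lam in c(2, 4)) {
    dS <- shannon_entropy(displacement_ensemble(traj, 200 * lam)) -
      shannon_entropy(displacement_ensemble(traj, 200))
    expect_equal(dS, 0.5 * log(lam), tolerance = 0.12)
  }
})
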