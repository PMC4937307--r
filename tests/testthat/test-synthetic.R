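# Properties of the stochastic trace generator: determinism, occupancy
# bounds, agreement of the event statistics with the rate model.

test_that("identical configuration gives an identical trace", {
  p <- stepping_params(22)
  cfg <- simulation_config(p, seed = 42,
                           force_schedule = data.frame(duration = 20,
                                                       force = 12))
  tr1 <- simulate_fork_trace(cfg)
  tr2 <- simulate_fork_trace(cfg)
  expect_identical(tr1$x, tr2$x)
  expect_identical(attr(tr1, "events"), attr(tr2, "events"))
  tr3 <- simulate_fork_trace(simulation_config(p, seed = 43,
    force_schedule = data.frame(duration = 20, force = 12)))
  expect_false(identical(tr1$x, tr3$x))
})

test_that("simulation does not disturb the caller's RNG stream", {
  set.seed(7); a <- runif(2)
  set.seed(7); runif(1)
  invisible(simulate_fork_trace(simulation_config(stepping_params(22),
    seed = 1, force_schedule = data.frame(duration = 2, force = 12))))
  expect_identical(runif(1), a[2])
})

test_that("occupancy stays within [0, hairpin_size]", {
  p <- kinetic_parameters(10, 15, 0, 0, 18.2, concentration = 2,
                          footprint = 30)
  tr <- simulate_fork_trace(simulation_config(p, seed = 9, hairpin_size = 100,
    noise_sd = 0, force_schedule = data.frame(duration = 120, force = 12)))
  ev <- attr(tr, "events")
  expect_true(all(ev$n_after >= 0 & ev$n_after <= 100))
  expect_true(all(ev$n_before >= 0 & ev$n_before <= 100))
  # both boundaries actually visited under these competing rates
  expect_true(any(ev$n_after == 0) || any(ev$n_before == 0))
  expect_true(any(ev$n_after == 100))
})

test_that("noiseless opening-only trace is a staircase of c(F)*footprint", {
  p <- kinetic_parameters(5, 0, 0, 0, 18.2, concentration = 2,
                          footprint = 20)
  tr <- simulate_fork_trace(simulation_config(p, seed = 5, noise_sd = 0,
    force_schedule = data.frame(duration = 30, force = 12)))
  jumps <- unique(round(diff(tr$x)[diff(tr$x) != 0], 9))
  step_nm <- conversion_factor(12, "hairpin") * 20
  expect_equal(jumps, rep(step_nm, length(jumps)), tolerance = 1e-9)
})

test_that("ensemble-mean opening slope matches net_rate within 3 SE", {
  m <- elasticity_model()
  sets <- list(
    kinetic_parameters(9, 50, 1.0, 0.5, 18.2, concentration = 20,
                       footprint = 23),
    kinetic_parameters(20, 10, 0, 0, 18.2, concentration = 5,
                       footprint = 15),
    kinetic_parameters(5, 100, 2.0, 1.0, 19.9, concentration = 40,
                       footprint = 23),
    kinetic_parameters(3, 5, 0.5, 0.2, 17.8, concentration = 30,
                       footprint = 30),
    kinetic_parameters(12, 80, 1.5, 1.5, 18.8, concentration = 10,
                       footprint = 20)
  )
  for (j in seq_along(sets)) {
    p <- sets[[j]]
    F <- 14
    target <- net_rate(F, p, m)
    T_end <- 4
    slopes <- vapply(1:30, function(i) {
      tr <- simulate_fork_trace(simulation_config(p, seed = 1000 * j + i,
        hairpin_size = 5000, noise_sd = 0, sample_rate = 20,
        force_schedule = data.frame(duration = T_end, force = F)))
      ev <- attr(tr, "events")
      if (nrow(ev) == 0) 0 else ev$n_after[nrow(ev)] / T_end
    }, numeric(1))
    se <- stats::sd(slopes) / sqrt(length(slopes))
    expect_lt(abs(mean(slopes) - target), 3 * se + 1e-9)
  }
})

test_that("event counts far from boundaries are Poisson-dispersed", {
  p <- kinetic_parameters(10, 0, 0, 0, 18.2, concentration = 1,
                          footprint = 20)   # 0.5 events/s, opening only
  counts <- unlist(lapply(1:3, function(i) {
    tr <- simulate_fork_trace(simulation_config(p, seed = 70 + i,
      hairpin_size = 1e5, noise_sd = 0, sample_rate = 10,
      force_schedule = data.frame(duration = 200, force = 12)))
    ev <- attr(tr, "events")
    tabulate(findInterval(ev$time, seq(0, 200, by = 10)), nbins = 20)
  }))
  disp <- stats::var(counts) / mean(counts)
  expect_gt(disp, 0.5)
  expect_lt(disp, 1.7)
  expect_equal(mean(counts), 5, tolerance = 0.25)  # 0.5/s * 10 s windows
})

test_that("rate dataset is exact without noise and reproducible", {
  p <- yrpa3()
  d0 <- simulate_rate_dataset(rate_design(), p, noise_cv = 0, seed = 3)
  expect_equal(d0$v, net_rate(rate_design(), p))
  d1 <- simulate_rate_dataset(rate_design(), p, noise_cv = 0.1, seed = 3)
  d2 <- simulate_rate_dataset(rate_design(), p, noise_cv = 0.1, seed = 3)
  expect_identical(d1, d2)
  # branch tags split at the equilibrium force
  F_equi <- equilibrium_force(p)
  expect_true(all(d1$branch[d1$F > F_equi] == "association"))
  expect_true(all(d1$branch[d1$F < F_equi] == "dissociation"))
  expect_error(simulate_rate_dataset(numeric(0), p, seed = 1), "empty")
})

test_that("sliding trace: gradual fraction and drift velocity", {
  tr <- simulate_sliding_trace(zeta = 0.005, F_low = 15.5, F_unz = 17.8,
                               seed = 21, n_cycles = 200, noise_sd = 3)
  ev <- attr(tr, "events")
  expect_equal(nrow(ev), 200)
  frac <- mean(ev$gradual)
  expect_lt(abs(frac - 0.1), 3 * sqrt(0.1 * 0.9 / 200))
  # drift velocity of gradual cycles is (F_unz - F_low)/zeta = 460 nt/s
  expect_equal(unique(ev$velocity_true[ev$gradual]), 460)
  # seed determinism
  tr2 <- simulate_sliding_trace(zeta = 0.005, F_low = 15.5, F_unz = 17.8,
                                seed = 21, n_cycles = 200, noise_sd = 3)
  expect_identical(tr$x, tr2$x)
})

test_that("sliding velocity scales inversely with friction", {
  tr <- simulate_sliding_trace(zeta = 0.05, F_low = 15.5, F_unz = 17.8,
                               seed = 4, n_cycles = 2,
                               sliding_probability = 1, noise_sd = 0)
  ev <- attr(tr, "events")
  expect_equal(unique(ev$velocity_true), 46)
  # gradual closure takes far longer than an abrupt one
  expect_gt(min(ev$t_close_end - ev$t_close_start), 10)
})

test_that("configuration validation", {
  p <- stepping_params(30)
  expect_error(simulation_config(p, hairpin_size = 20, seed = 1),
               "exceeds hairpin")
  expect_error(simulation_config(p, seed = 1,
    force_schedule = data.frame(duration = 10, force = -2)), "positive")
  expect_error(simulation_config(p), "seed")
  expect_error(simulate_sliding_trace(zeta = 0.005, F_low = 18, F_unz = 17.8,
                                      seed = 1), "below F_unz")
})
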