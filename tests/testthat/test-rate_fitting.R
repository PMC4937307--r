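# Trace-rate estimation and the weighted nonlinear fit of the two-term
# Arrhenius model.

test_that("trace rate: exact on a noiseless ramp, zero on a flat trace", {
  m <- elasticity_model()
  v <- 12.5; F <- 13
  t <- seq(0, 10, by = 1 / 300)
  cf <- conversion_factor(F, "hairpin", m)
  tr <- structure(data.frame(t = t, x = cf * v * t, F = F),
                  class = c("fork_trace", "data.frame"))
  attr(tr, "sample_rate") <- 300
  r <- estimate_trace_rate(tr)
  expect_equal(r$v, v, tolerance = 1e-9)
  expect_equal(r$branch, "association")
  tr$x <- rep(50, length(t))
  r0 <- estimate_trace_rate(tr)
  expect_equal(r0$v, 0, tolerance = 1e-12)
  # non-constant force on the window is refused
  tr$F <- rep(c(12, 14), length.out = nrow(tr))
  expect_error(estimate_trace_rate(tr), "not constant")
})

test_that("ensemble of Gillespie trace rates matches net_rate", {
  p <- yrpa3()
  m <- elasticity_model()
  target <- net_rate(13.2, p, m)
  rates <- vapply(1:40, function(i) {
    tr <- simulate_fork_trace(simulation_config(p, seed = 2000 + i,
      hairpin_size = 2000, noise_sd = 5, sample_rate = 60,
      initial_open_bp = 1000,   # start mid-hairpin: no boundary reflection
      force_schedule = data.frame(duration = 8, force = 13.2)))
    estimate_trace_rate(tr, model = m)$v
  }, numeric(1))
  se <- stats::sd(rates) / sqrt(length(rates))
  expect_lt(abs(mean(rates) - target), 3 * se)
})

test_that("noise-free synthetic data invert exactly", {
  p <- yrpa3()
  d <- simulate_rate_dataset(rate_design(), p, noise_cv = 0, seed = 1)
  fit <- fit_eq1(d, F_unz = 18.2, concentration = 20, n_boot = 0)
  truth <- c(9, 239, 3.3, 1.6)
  expect_equal(unname(fit$estimates), truth, tolerance = 1e-3)
  expect_lt(max(abs(fit$residuals)), 1e-4)
  expect_equal(fit$F_equi_derived, 13.42, tolerance = 0.02)
})

test_that("10% noise fit recovers the generating parameters", {
  p <- yrpa3()
  d <- simulate_rate_dataset(rate_design(), p, noise_cv = 0.1, seed = 5)
  fit <- fit_eq1(d, F_unz = 18.2, concentration = 20, n_boot = 200, seed = 5)
  # k_off within its bootstrap CI of the truth; dz_on near truth
  expect_gt(239, fit$ci[1, "k_off"])
  expect_lt(239, fit$ci[2, "k_off"])
  expect_lt(abs(fit$estimates[["dz_on"]] - 3.3), 0.6)
  expect_lt(abs(fit$estimates[["k_off"]] - 239) / 239, 0.15)
})

test_that("median recovery within 10% and CI coverage >= 80%", {
  p <- yrpa3()
  truth <- c(k_on_per_nM = 9, k_off = 239, dz_on = 3.3, dz_off = 1.6)
  est <- matrix(NA_real_, 20, 4, dimnames = list(NULL, names(truth)))
  covered <- 0; n_ci <- 0
  for (i in 1:20) {
    d <- simulate_rate_dataset(rate_design(), p, noise_cv = 0.1,
                               seed = 9000 + i)
    fit <- fit_eq1(d, F_unz = 18.2, concentration = 20, n_boot = 120,
                   seed = 9000 + i)
    est[i, ] <- fit$estimates[names(truth)]
    for (nm in names(truth)) {
      n_ci <- n_ci + 1
      if (truth[nm] >= fit$ci[1, nm] && truth[nm] <= fit$ci[2, nm]) {
        covered <- covered + 1
      }
    }
  }
  med <- apply(est, 2, stats::median)
  expect_true(all(abs(med - truth) / truth < 0.10))
  expect_gte(covered / n_ci, 0.8)
})

test_that("fit is equivariant under permutation and rate rescaling", {
  p <- yrpa3()
  d <- simulate_rate_dataset(rate_design(), p, noise_cv = 0.08, seed = 77)
  fit <- fit_eq1(d, 18.2, 20, n_boot = 0, seed = 2)
  perm <- d[sample(nrow(d)), ]
  fit_p <- fit_eq1(perm, 18.2, 20, n_boot = 0, seed = 2)
  expect_equal(fit_p$estimates, fit$estimates, tolerance = 1e-4)
  scaled <- d; scaled$v <- 3 * d$v; scaled$v_err <- 3 * d$v_err
  fit_s <- fit_eq1(scaled, 18.2, 20, n_boot = 0, seed = 2)
  expect_equal(fit_s$estimates[["k_on_per_nM"]],
               3 * fit$estimates[["k_on_per_nM"]], tolerance = 1e-3)
  expect_equal(fit_s$estimates[["k_off"]], 3 * fit$estimates[["k_off"]],
               tolerance = 1e-3)
  expect_equal(fit_s$estimates[["dz_on"]], fit$estimates[["dz_on"]],
               tolerance = 1e-3)
  expect_equal(fit_s$estimates[["dz_off"]], fit$estimates[["dz_off"]],
               tolerance = 1e-3)
})

test_that("duplex-geometry datasets are recovered equally well", {
  # plausible flap-duplex kinetics: equilibrium near 43 pN, toehold ~3 bp
  p <- kinetic_parameters(3.2, 564, 2.9, 1.6, 60, concentration = 20,
                          geometry = "duplex")
  forces <- c(seq(44, 58, length.out = 12), seq(15, 35, length.out = 12))
  d <- simulate_rate_dataset(forces, p, noise_cv = 0.1, seed = 31)
  fit <- fit_eq1(d, F_unz = 60, concentration = 20, geometry = "duplex",
                 n_boot = 0, seed = 31)
  truth <- c(3.2, 564, 2.9, 1.6)
  expect_true(all(abs(fit$estimates / truth - 1) < 0.25))
})

test_that("input validation and branch requirements", {
  p <- yrpa3()
  d <- simulate_rate_dataset(seq(14, 16, length.out = 6), p, noise_cv = 0,
                             seed = 1)
  expect_error(fit_eq1(d, 18.2, 20), "both branches")
  expect_error(fit_eq1(d[1:2, ], 18.2, 20), "at least 4")
})

test_that("k_on standardization", {
  expect_equal(standardize_kon(180, 20), 9)
  expect_equal(destandardize_kon(9, 20), 180)
  expect_equal(destandardize_kon(standardize_kon(63.8, 20), 20), 63.8)
  expect_equal(standardize_kon(0, 20), 0)
  expect_error(standardize_kon(180, 0), "positive")
})
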