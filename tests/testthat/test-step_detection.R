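# Step finder: exactness on clean staircases, false-positive control,
# recovery statistics on realistic noisy traces, invariances.

test_that("noiseless equal staircase is recovered exactly", {
  tr <- make_staircase(step_nm = 20, n_steps = 10, dwell_s = 2, noise_sd = 0)
  fit <- find_steps(tr)
  expect_equal(fit$n_steps, 10)
  expect_equal(fit$change_points, attr(tr, "true_cp"))
  expect_equal(fit$step_sizes_nm, rep(20, 10))
})

test_that("pure noise yields zero accepted steps", {
  set.seed(11)
  for (s in 1:3) {
    tr <- make_staircase(step_nm = 0, n_steps = 0, dwell_s = 30,
                         noise_sd = 5, seed = s)
    expect_equal(find_steps(tr)$n_steps, 0)
  }
  # degenerate flat and too-short traces return empty fits, no error
  flat <- make_staircase(step_nm = 0, n_steps = 0, dwell_s = 5, noise_sd = 0)
  expect_equal(find_steps(flat)$n_steps, 0)
  short <- make_staircase(step_nm = 20, n_steps = 1, dwell_s = 0.1,
                          noise_sd = 0)
  expect_equal(find_steps(short)$n_steps, 0)
})

test_that("noisy 21.8 bp staircase at 12 pN: >=90% recovery, <5% bias", {
  step_nm <- conversion_factor(12, "hairpin") * 21.8   # ~19 nm
  hits <- 0; total <- 0; sizes <- numeric(0)
  for (s in 1:5) {
    tr <- make_staircase(step_nm = step_nm, n_steps = 20, dwell_s = 2,
                         noise_sd = 5, seed = 100 + s)
    fit <- find_steps(tr)
    truth <- attr(tr, "true_cp")
    # a true step counts as recovered when a change point lies within 0.25 s
    hits <- hits + sum(vapply(truth, function(cp)
      any(abs(fit$change_points - cp) <= 75), logical(1)))
    total <- total + length(truth)
    sizes <- c(sizes, fit$step_sizes_bp)
  }
  expect_gte(hits / total, 0.9)
  expect_lt(abs(mean(sizes[sizes > 0]) - 21.8) / 21.8, 0.05)
})

test_that("recovered mean is robust to noise up to 25% of the step", {
  step_nm <- 20
  means <- vapply(c(1, 3, 5), function(sd) {
    tr <- make_staircase(step_nm = step_nm, n_steps = 15, dwell_s = 1.5,
                         noise_sd = sd, seed = 7)
    mean(find_steps(tr)$step_sizes_nm)
  }, numeric(1))
  expect_true(all(abs(means - step_nm) / step_nm < 0.05))
})

test_that("offset invariance and time reversal up to sign", {
  tr <- make_staircase(step_nm = 18, n_steps = 8, dwell_s = 1.5,
                       noise_sd = 4, seed = 3)
  fit <- find_steps(tr)
  tr_off <- tr; tr_off$x <- tr$x + 500
  fit_off <- find_steps(tr_off)
  expect_equal(fit_off$change_points, fit$change_points)
  expect_equal(fit_off$step_sizes_nm, fit$step_sizes_nm)
  tr_rev <- tr; tr_rev$x <- rev(tr$x)
  fit_rev <- find_steps(tr_rev)
  expect_equal(sort(abs(fit_rev$step_sizes_nm)),
               sort(abs(fit$step_sizes_nm)), tolerance = 1e-9)
  expect_equal(sum(fit_rev$step_sizes_nm), -sum(fit$step_sizes_nm),
               tolerance = 1e-9)
})

test_that("accepted fit never exceeds the single-plateau chi-square", {
  for (s in c(2, 9)) {
    tr <- make_staircase(step_nm = 15, n_steps = 6, dwell_s = 1,
                         noise_sd = 6, seed = s)
    fit <- find_steps(tr)
    bounds <- c(0, fit$change_points, nrow(tr))
    resid <- sum(vapply(seq_len(length(bounds) - 1), function(i) {
      seg <- tr$x[(bounds[i] + 1):bounds[i + 1]]
      sum((seg - mean(seg))^2)
    }, numeric(1)))
    expect_lte(resid, sum((tr$x - mean(tr$x))^2))
  }
})

test_that("steps in bp use the force at each step's time", {
  # two-phase schedule: same 20 nm physical steps read differently in bp
  p <- stepping_params(20, opening_bp_s = 20, closing_bp_s = 0)
  tr <- simulate_fork_trace(simulation_config(p, seed = 12, noise_sd = 2,
    force_schedule = data.frame(duration = c(15, 15), force = c(11, 14))))
  fit <- find_steps(tr)
  cf <- conversion_factor(fit$F_at_step, "hairpin")
  expect_equal(fit$step_sizes_bp, fit$step_sizes_nm / cf)
  expect_true(all(fit$F_at_step %in% c(11, 14)))
})

test_that("histogram fit: exact degenerate case and error on scarce data", {
  h <- fit_step_histogram(c(rep(21.8, 40), -rep(22, 5)), min_steps = 30)
  expect_equal(h$mean_bp, 21.8)
  expect_equal(h$sd_bp, 0)
  expect_equal(h$n_steps, 40)
  h2 <- fit_step_histogram(c(rep(21.8, 40), -rep(22, 31)), sign = "closing")
  expect_equal(h2$mean_bp, 22)
  expect_equal(h2$sign_class, "closing")
  expect_error(fit_step_histogram(rep(20, 10)), "10 < 30")
})

test_that("footprint recovery from stochastic stepping traces", {
  fits <- lapply(simulate_step_traces(21.8, n = 4, seed0 = 500), find_steps)
  h <- fit_step_histogram(fits)
  expect_lt(abs(h$mean_bp - 21.8), 1.5)
  expect_gt(h$n_steps, 30)
})
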