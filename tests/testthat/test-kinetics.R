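# Net-rate model, equilibrium force, energetics. Frozen values from the
# independent closed-form/grid-scan oracle script.

test_that("net rate reduces to the pre-factors when dz = 0", {
  p <- kinetic_parameters(2, 30, 0, 0, 18, concentration = 10)
  F <- c(2, 8, 15)
  expect_equal(net_rate(F, p), rep(2 * 10 - 30, 3))
})

test_that("opening branch equals k_on * conc at the unzipping force", {
  p <- yrpa3()
  expect_equal(opening_rate(18.2, p), 9.0 * 20)   # 180 bp/s
  expect_equal(net_rate(15.7, p), 16.6654, tolerance = 1e-4)
})

test_that("net rate is strictly increasing in force", {
  for (s in 1:5) {
    p <- random_kinetics(s)
    v <- net_rate(seq(1, p$F_unz + 5, by = 0.25), p)
    expect_true(all(diff(v) > 0))
  }
})

test_that("equilibrium force matches the dense-grid oracle", {
  p <- yrpa3()
  expect_equal(equilibrium_force(p), 13.4203, tolerance = 0.02)
  # 100 random parameter sets against a grid-scan sign-change oracle
  m <- elasticity_model()
  for (s in 1:100) {
    p <- random_kinetics(s)
    grid <- seq(1, p$F_unz + 5, by = 0.005)
    v <- net_rate(grid, p, m)
    oracle <- grid[which(diff(sign(v)) > 0)[1]]
    expect_equal(equilibrium_force(p, m), oracle, tolerance = 0.02)
  }
})

test_that("equilibrium force edge cases", {
  # no dissociation -> no sign change
  p <- kinetic_parameters(9, 0, 3.3, 1.6, 18.2, concentration = 20)
  expect_error(equilibrium_force(p), "no equilibrium")
  # balanced force-independent rates -> flagged degenerate
  p <- kinetic_parameters(1, 20, 0, 0, 18.2, concentration = 20)
  expect_error(equilibrium_force(p), "degenerate")
  # increasing k_off shifts the equilibrium to higher force
  base <- yrpa3()
  f <- vapply(c(150, 239, 400), function(k) {
    p <- kinetic_parameters(9, k, 3.3, 1.6, 18.2, concentration = 20)
    equilibrium_force(p)
  }, numeric(1))
  expect_true(all(diff(f) > 0))
})

test_that("binding free energy formula and properties", {
  expect_equal(binding_free_energy(18.2, 18.2), 0)
  expect_equal(binding_free_energy(18.2, 12.4), 46.531, tolerance = 1e-3)
  # linear in the footprint
  expect_equal(binding_free_energy(18.2, 12.4, footprint = 46),
               2 * binding_free_energy(18.2, 12.4, footprint = 23))
  expect_warning(binding_free_energy(12, 15), "negative")
})

test_that("free energy from the association constant", {
  expect_equal(free_energy_from_K(1), 0)
  expect_equal(free_energy_from_K(1e10), 57.05, tolerance = 1e-3)
  expect_equal(free_energy_from_K(1e5), free_energy_from_K(1e10) / 2)
  # additivity in log K
  expect_equal(free_energy_from_K(3e7 * 2e2),
               free_energy_from_K(3e7) + free_energy_from_K(2e2))
  expect_error(free_energy_from_K(-1), "positive")
})

test_that("passive unwinding model", {
  m <- elasticity_model()
  expect_equal(passive_unwinding_rate(18.2, 180, 23, 18.2, m), 180)
  v <- passive_unwinding_rate(seq(10, 18, by = 0.5), 180, 23, 18.2, m)
  expect_true(all(v < 180) && all(diff(v) > 0))
  # with n = 1 the model is the association branch with dz_on = 1
  p <- kinetic_parameters(9, 0, 1, 0, 18.2, concentration = 20)
  expect_equal(passive_unwinding_rate(15, 180, 1, 18.2, m),
               opening_rate(15, p, m))
})

test_that("Mg2+ extrapolation is the OLS x-intercept", {
  expect_equal(mg_extrapolation(c(3, 5), c(0, 100)), 3)
  # exactly collinear points: analytic -b/a
  mg <- c(2, 4, 8); ko <- 30 * mg - 45
  expect_equal(mg_extrapolation(mg, ko), 1.5)
  # the published hRPA triple gives ~0.58 mM by OLS (documented to differ
  # from the reported 2.5 mM; procedure there is unstated)
  expect_equal(mg_extrapolation(c(3, 5, 10), c(37, 109, 189)), 0.58333,
               tolerance = 1e-4)
  expect_error(mg_extrapolation(c(3, 5, 10), c(100, 50, 10)),
               "no zero crossing")
})

test_that("energetics summary combines the pieces", {
  p <- yrpa3()
  en <- binding_energetics(p)
  expect_s3_class(en, "energetics_result")
  expect_equal(en$F_equi, 13.42, tolerance = 0.02)
  expect_equal(en$dG_bp_per_bp, 17.709, tolerance = 1e-3)
  expect_equal(en$dG_bind,
               binding_free_energy(18.2, en$F_equi), tolerance = 1e-8)
})

test_that("reference parameter table is consistent", {
  tab <- rpa_reference_parameters()
  expect_equal(nrow(tab), 6)
  p <- rpa_condition("hRPA", 10)
  expect_equal(p$k_off, 189)
  expect_equal(p$concentration, 50)
  expect_error(rpa_condition("yRPA", 5), "no reference condition")
})
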