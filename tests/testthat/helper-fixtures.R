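# Shared fixture builders. All synthetic inputs are generated in code under
# fixed seeds; no stored data files.

# Force-independent stepping kinetics for resolved-step traces: dz = 0 makes
# both branch rates constant, so dwell times are set directly by the bp/s
# rates (opening 10.9 bp/s ~ one footprint event per ~2 s).
stepping_params <- function(footprint, opening_bp_s = 10.9,
                            closing_bp_s = 0.25, concentration = 2) {
  kinetic_parameters(opening_bp_s / concentration, closing_bp_s, 0, 0,
                     18.2, concentration, footprint = footprint)
}

simulate_step_traces <- function(footprint, n = 10, seed0 = 100,
                                 concentration = 2, duration = 70,
                                 force = 12, noise_sd = 5) {
  p <- stepping_params(footprint, concentration = concentration)
  lapply(seq_len(n), function(i) {
    simulate_fork_trace(simulation_config(
      p, seed = seed0 + i, noise_sd = noise_sd,
      force_schedule = data.frame(duration = duration, force = force)))
  })
}

# Deterministic staircase trace: n_steps equal steps of step_nm with equal
# dwells, optionally with Gaussian noise.
make_staircase <- function(step_nm = 20, n_steps = 10, dwell_s = 2,
                           sample_rate = 300, noise_sd = 0, force = 12,
                           seed = 1) {
  n_per <- round(dwell_s * sample_rate)
  lev <- rep(seq(0, n_steps) * step_nm, each = n_per)
  set.seed(seed)
  x <- lev + rnorm(length(lev), 0, noise_sd)
  t <- (seq_along(x) - 1) / sample_rate
  tr <- data.frame(t = t, x = x, F = force)
  attr(tr, "sample_rate") <- sample_rate
  attr(tr, "true_cp") <- n_per * seq_len(n_steps)
  class(tr) <- c("fork_trace", "data.frame")
  tr
}

# Random but physically sensible kinetic parameter sets with a guaranteed
# sign change of the net rate on (1, F_unz + 5).
random_kinetics <- function(seed) {
  set.seed(seed)
  repeat {
    p <- kinetic_parameters(
      k_on_per_nM = runif(1, 1, 40), k_off = runif(1, 30, 600),
      dz_on = runif(1, 0.5, 6), dz_off = runif(1, 0.3, 3),
      F_unz = runif(1, 16, 21), concentration = runif(1, 5, 60))
    v <- net_rate(c(1, p$F_unz + 5), p)
    if (v[1] < 0 && v[2] > 0) return(p)
  }
}

# Exact friction-law events (no noise): one gradual event per low force.
exact_sliding_events <- function(zeta, F_low, F_unz) {
  v <- (F_unz - F_low) / zeta
  out <- data.frame(cycle = seq_along(F_low), F_low = F_low, gradual = TRUE,
                    duration = 1, velocity = v, nt_closed = v)
  class(out) <- c("sliding_events", "data.frame")
  out
}

# Reference yRPA 3 mM condition used across tests.
yrpa3 <- function() rpa_condition("yRPA", 3)

# The standard synthetic rate-versus-force design: 15 association forces
# (11.5-16 pN) and 15 dissociation forces (2-7 pN).
rate_design <- function() c(seq(11.5, 16, length.out = 15),
                            seq(2, 7, length.out = 15))
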