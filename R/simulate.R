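# Stochastic simulator of magnetic-tweezers fork traces: Gillespie stepping
# under the two-term Arrhenius kinetics, bead noise, force schedules, and
# drift-diffusion sliding events. The test substrate for all downstream
# analysis stages.

# Run code with a temporary RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("a single finite numeric seed is required for reproducibility")
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Configuration of a synthetic fork trace
#'
#' Collects everything [simulate_fork_trace()] needs: the kinetic parameter
#' set, the elasticity model, the hairpin size, the bead-noise level, the
#' sampling rate, a mandatory seed and a force schedule. Defaults emulate the
#' instrument: 300 Hz camera-based bead tracking of a 488 bp hairpin with
#' about 5 nm of Gaussian position noise per sample.
#'
#' @param kinetic a [kinetic_parameters()] object.
#' @param elasticity an [elasticity_model()].
#' @param hairpin_size hairpin length (bp); default 488.
#' @param noise_sd Gaussian bead noise per sample (nm); default 5.
#' @param sample_rate sampling rate (Hz); default 300.
#' @param seed integer seed; mandatory.
#' @param force_schedule data.frame with columns `duration` (s) and
#'   `force` (pN); one row per constant-force phase.
#' @param drift_nm_per_s optional linear drift added to the extension (nm/s).
#' @param initial_open_bp opened base pairs at t = 0; default 0 (fully
#'   closed). Set to `hairpin_size` to start from the fully open state,
#'   e.g. for dissociation traces.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(kinetic, elasticity = elasticity_model(),
                              hairpin_size = 488, noise_sd = 5,
                              sample_rate = 300, seed,
                              force_schedule = data.frame(duration = 60,
                                                          force = 12),
                              drift_nm_per_s = 0, initial_open_bp = 0) {
  stopifnot(inherits(kinetic, "kinetic_parameters"),
            inherits(elasticity, "elasticity_model"))
  if (missing(seed)) stop("seed is mandatory for reproducibility")
  if (kinetic$footprint > hairpin_size) {
    stop("footprint (", kinetic$footprint, " bp) exceeds hairpin size (",
         hairpin_size, " bp)")
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (!all(c("duration", "force") %in% names(force_schedule))) {
    stop("force_schedule needs columns 'duration' and 'force'")
  }
  if (any(force_schedule$force <= 0) || any(force_schedule$duration <= 0)) {
    stop("force_schedule durations and forces must be positive")
  }
  if (initial_open_bp < 0 || initial_open_bp > hairpin_size) {
    stop("initial_open_bp must lie in [0, hairpin_size]")
  }
  structure(list(kinetic = kinetic, elasticity = elasticity,
                 hairpin_size = hairpin_size, noise_sd = noise_sd,
                 sample_rate = sample_rate, seed = seed,
                 force_schedule = force_schedule,
                 drift_nm_per_s = drift_nm_per_s,
                 initial_open_bp = initial_open_bp),
            class = "simulation_config")
}

# Assemble a fork_trace object from sampled columns and metadata.
.new_trace <- function(t, x, F, sample_rate, meta = list(), events = NULL) {
  tr <- data.frame(t = t, x = x, F = F)
  attr(tr, "sample_rate") <- sample_rate
  attr(tr, "meta") <- meta
  attr(tr, "events") <- events
  class(tr) <- c("fork_trace", "data.frame")
  tr
}

#' @export
print.fork_trace <- function(x, ...) {
  cat(sprintf("Fork trace: %d samples at %g Hz (%.1f s), force %s pN\n",
              nrow(x), attr(x, "sample_rate"),
              nrow(x) / attr(x, "sample_rate"),
              paste(unique(signif(x$F, 4)), collapse = "/")))
  ev <- attr(x, "events")
  if (!is.null(ev)) cat(sprintf("  %d recorded ground-truth events\n", nrow(ev)))
  invisible(x)
}

# Gillespie simulation of the opened-bp count on one constant-force phase.
# Events move n by +/- footprint (clamped at the boundaries); per-event
# rates are the bp/s branch rates divided by the footprint so that the
# ensemble-average bp/s slope reproduces net_rate().
.gillespie_phase <- function(n0, t0, t_end, F, kin, model, hairpin_size) {
  fp <- kin$footprint
  r_open_bp <- opening_rate(F, kin, model)
  r_close_bp <- closing_rate(F, kin, model)
  times <- numeric(0); n_after <- numeric(0)
  n <- n0; t <- t0
  repeat {
    ro <- if (n >= hairpin_size) 0 else r_open_bp / fp
    rc <- if (n <= 0) 0 else r_close_bp / fp
    rt <- ro + rc
    if (rt <= 0) break
    t <- t + stats::rexp(1, rt)
    if (t >= t_end) break
    if (stats::runif(1) < ro / rt) {
      n <- min(n + fp, hairpin_size)
    } else {
      n <- max(n - fp, 0)
    }
    times <- c(times, t); n_after <- c(n_after, n)
  }
  list(times = times, n_after = n_after, n_final = n)
}

#' Simulate a stochastic fork opening/closing trace
#'
#' Gillespie simulation of the number of opened base pairs `n` on
#' `[0, hairpin_size]`: opening events of one footprint occur at per-event
#' rate `opening_rate(F)/footprint` and closing events at
#' `closing_rate(F)/footprint`, with reflecting boundaries (events are
#' clamped at the fully-closed and fully-open states). One event covers both
#' strands of the fork, so each step changes the extension by
#' `c(F) * footprint` nm. The sampled extension is `c(F) * n` plus i.i.d.
#' Gaussian bead noise and an optional linear drift. Identical configuration
#' (including seed) gives an identical trace.
#'
#' @param config a [simulation_config()].
#' @return A `fork_trace`: a data.frame with columns `t` (s), `x` (nm),
#'   `F` (pN), with attributes `sample_rate`, `meta` (the generation
#'   parameters) and `events` (ground-truth event table with columns
#'   `time`, `n_before`, `n_after`, `size_bp`).
#' @examples
#' p <- kinetic_parameters(5, 0.2, 0, 0, 18.2, concentration = 2,
#'                         footprint = 22)
#' tr <- simulate_fork_trace(simulation_config(p, seed = 1,
#'   force_schedule = data.frame(duration = 10, force = 12)))
#' @export
simulate_fork_trace <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  .with_seed(config$seed, {
    sched <- config$force_schedule
    kin <- config$kinetic; m <- config$elasticity
    t_breaks <- cumsum(c(0, sched$duration))
    ev_time <- numeric(0); ev_n <- numeric(0)
    n <- config$initial_open_bp
    for (i in seq_len(nrow(sched))) {
      ph <- .gillespie_phase(n, t_breaks[i], t_breaks[i + 1], sched$force[i],
                             kin, m, config$hairpin_size)
      ev_time <- c(ev_time, ph$times)
      ev_n <- c(ev_n, ph$n_after)
      n <- ph$n_final
    }
    dt <- 1 / config$sample_rate
    t <- seq(0, t_breaks[length(t_breaks)] - dt, by = dt)
    # opened bp at each sample: last event before the sample time
    idx <- findInterval(t, ev_time)
    n_t <- c(config$initial_open_bp, ev_n)[idx + 1]
    F_t <- sched$force[pmin(findInterval(t, t_breaks,
                                         rightmost.closed = TRUE),
                            nrow(sched))]
    cf <- conversion_factor(F_t, kin$geometry, m)
    x <- cf * n_t + config$drift_nm_per_s * t +
      stats::rnorm(length(t), 0, config$noise_sd)
    n_before <- c(config$initial_open_bp, ev_n)[seq_along(ev_n)]
    events <- data.frame(time = ev_time, n_before = n_before,
                         n_after = ev_n, size_bp = ev_n - n_before)
    meta <- list(seed = config$seed, hairpin_size = config$hairpin_size,
                 noise_sd = config$noise_sd, sample_rate = config$sample_rate,
                 footprint = kin$footprint, geometry = kin$geometry,
                 concentration = kin$concentration)
    .new_trace(t, x, F_t, config$sample_rate, meta = meta, events = events)
  })
}

#' Simulate a rate-versus-force dataset
#'
#' Evaluates the net-rate model on a force grid and applies multiplicative
#' Gaussian noise, `v = v_net(F) * (1 + e)`, `e ~ N(0, noise_cv^2)`. The
#' reported per-point uncertainty is `|v_net| * noise_cv`, floored at
#' `1e-3 * max |v_net|` to keep weights finite near the zero crossing.
#' Points above the equilibrium force are tagged as the association branch,
#' points below as the dissociation branch.
#'
#' @param forces force grid (pN).
#' @param params a [kinetic_parameters()] object.
#' @param model an [elasticity_model()].
#' @param noise_cv multiplicative noise coefficient of variation.
#' @param seed integer seed.
#' @param condition free-text condition label.
#' @return A data.frame of class `rate_measurements` with columns `F`, `v`,
#'   `v_err`, `branch`, `condition`.
#' @export
simulate_rate_dataset <- function(forces, params, model = elasticity_model(),
                                  noise_cv = 0.1, seed, condition = "synthetic") {
  if (length(forces) == 0) stop("empty force grid")
  .check_force(forces)
  .with_seed(seed, {
    v_true <- net_rate(forces, params, model)
    v <- v_true * (1 + stats::rnorm(length(forces), 0, noise_cv))
    v_err <- pmax(abs(v_true) * noise_cv, 1e-3 * max(abs(v_true)))
    F_equi <- tryCatch(equilibrium_force(params, model),
                       error = function(e) NA_real_)
    branch <- if (is.na(F_equi)) {
      ifelse(v_true >= 0, "association", "dissociation")
    } else {
      ifelse(forces > F_equi, "association", "dissociation")
    }
    out <- data.frame(F = forces, v = v, v_err = v_err, branch = branch,
                      condition = condition, stringsAsFactors = FALSE)
    class(out) <- c("rate_measurements", "data.frame")
    attr(out, "seed") <- seed
    attr(out, "noise_cv") <- noise_cv
    out
  })
}

#' Simulate force-cycling traces with protein sliding events
#'
#' Emulates repeated hairpin unzip/rezip cycles used to probe protein
#' sliding: the force alternates between `F_high` (above the unzipping
#' force; the hairpin opens abruptly) and a low force `F_low` (below it; the
#' hairpin closes). With probability `sliding_probability` a closing cycle
#' is gradual -- a single protein is pushed along the ssDNA by the rezipping
#' fork, and the fork position (in nucleotides of released ssDNA, 2 per bp)
#' performs drift-diffusion with drift `(F_unz - F_low)/zeta` nt/s towards
#' closure and diffusion constant `D = kBT_nt/zeta`, absorbing at the
#' fully-closed state. All other cycles close in a single abrupt transition.
#'
#' @param zeta friction coefficient (pN s/nt).
#' @param F_low low-force bound(s) (pN); recycled over cycles, must be
#'   `< F_unz`.
#' @param F_unz characteristic unzipping force (pN).
#' @param hairpin_size hairpin length (bp); default 488.
#' @param sliding_probability probability that a closing cycle is gradual;
#'   default 0.1.
#' @param noise_sd Gaussian bead noise (nm); default 5.
#' @param seed integer seed.
#' @param n_cycles number of force cycles; default 10.
#' @param F_high high-force bound (pN); default `F_unz + 4.7`.
#' @param sample_rate sampling rate (Hz); default 300.
#' @param dwell_open time spent fully open at `F_high` (s); default 1.
#' @param dwell_closed time spent closed at `F_low` after closure (s);
#'   default 0.5.
#' @param model an [elasticity_model()].
#' @return A `fork_trace` whose `events` attribute is a cycle table with
#'   columns `cycle`, `F_low`, `gradual`, `t_close_start`, `t_close_end`,
#'   `velocity_true` (nt/s; drift velocity for gradual cycles, `NA`
#'   otherwise).
#' @export
simulate_sliding_trace <- function(zeta, F_low, F_unz, hairpin_size = 488,
                                   sliding_probability = 0.1, noise_sd = 5,
                                   seed, n_cycles = 10, F_high = F_unz + 4.7,
                                   sample_rate = 300, dwell_open = 1,
                                   dwell_closed = 0.5,
                                   model = elasticity_model()) {
  if (zeta <= 0) stop("zeta must be positive")
  if (any(F_low >= F_unz)) stop("F_low must be below F_unz")
  kBT_nt <- model$kBT / model$ss_contour_per_nt   # pN nt
  D <- kBT_nt / zeta                              # nt^2/s
  nt_total <- 2 * hairpin_size
  dt <- 1 / sample_rate
  F_low <- rep_len(F_low, n_cycles)
  .with_seed(seed, {
    t_list <- list(); n_list <- list(); F_list <- list()
    cyc <- vector("list", n_cycles)
    t_now <- 0
    for (k in seq_len(n_cycles)) {
      # open phase at F_high: hairpin fully open (abrupt opening at entry)
      n_open <- round(dwell_open * sample_rate)
      t_list[[length(t_list) + 1]] <- t_now + dt * (seq_len(n_open) - 1)
      n_list[[length(n_list) + 1]] <- rep(nt_total, n_open)
      F_list[[length(F_list) + 1]] <- rep(F_high, n_open)
      t_now <- t_now + n_open * dt

      gradual <- stats::runif(1) < sliding_probability
      v_drift <- (F_unz - F_low[k]) / zeta
      t_close_start <- t_now
      if (gradual) {
        # Euler-Maruyama drift-diffusion of the fork position, absorbing at 0
        s <- nt_total; s_path <- numeric(0)
        sd_step <- sqrt(2 * D * dt)
        while (s > 0) {
          s <- min(s - v_drift * dt + stats::rnorm(1, 0, sd_step), nt_total)
          s_path <- c(s_path, max(s, 0))
          if (length(s_path) > 100 * sample_rate) break  # safety stop
        }
        n_cl <- length(s_path)
        t_list[[length(t_list) + 1]] <- t_now + dt * (seq_len(n_cl) - 1)
        n_list[[length(n_list) + 1]] <- s_path
        F_list[[length(F_list) + 1]] <- rep(F_low[k], n_cl)
        t_now <- t_now + n_cl * dt
      }
      t_close_end <- if (gradual) t_now else t_now + dt
      # closed dwell at F_low (abrupt closure lands here directly)
      n_cl2 <- round(dwell_closed * sample_rate)
      t_list[[length(t_list) + 1]] <- t_now + dt * (seq_len(n_cl2) - 1)
      n_list[[length(n_list) + 1]] <- rep(0, n_cl2)
      F_list[[length(F_list) + 1]] <- rep(F_low[k], n_cl2)
      t_now <- t_now + n_cl2 * dt
      cyc[[k]] <- data.frame(cycle = k, F_low = F_low[k], gradual = gradual,
                             t_close_start = t_close_start,
                             t_close_end = t_close_end,
                             velocity_true = if (gradual) v_drift else NA_real_)
    }
    t <- unlist(t_list); n_nt <- unlist(n_list); F_t <- unlist(F_list)
    cf <- conversion_factor(F_t, "hairpin", model)
    x <- cf * n_nt / 2 + stats::rnorm(length(t), 0, noise_sd)
    events <- do.call(rbind, cyc)
    meta <- list(seed = seed, zeta = zeta, F_unz = F_unz, D = D,
                 hairpin_size = hairpin_size, noise_sd = noise_sd,
                 sample_rate = sample_rate,
                 sliding_probability = sliding_probability)
    .new_trace(t, x, F_t, sample_rate, meta = meta, events = events)
  })
}
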