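# Extraction of opening/closing rates from traces and weighted nonlinear
# fitting of the two-term Arrhenius model to rate-versus-force data.

#' Estimate the opening/closing rate of a trace window
#'
#' Converts the extension to opened base pairs with the conversion factor at
#' the (constant) window force and returns the ordinary least-squares slope
#' of opened bp versus time, with its standard error from the residuals.
#' Positive slopes are fork opening.
#'
#' @param trace a `fork_trace`.
#' @param window `c(t0, t1)` in seconds; default the whole trace. The force
#'   must be constant on the window.
#' @param geometry fork geometry; default `"hairpin"`.
#' @param model an [elasticity_model()].
#' @param condition label carried into the output.
#' @return A one-row `rate_measurements` data.frame (`F`, `v`, `v_err`,
#'   `branch`, `condition`).
#' @export
estimate_trace_rate <- function(trace, window = range(trace$t),
                                geometry = c("hairpin", "duplex"),
                                model = elasticity_model(),
                                condition = "trace") {
  geometry <- match.arg(geometry)
  sel <- trace$t >= window[1] & trace$t <= window[2]
  if (sum(sel) < 3) stop("window contains fewer than 3 samples")
  Fw <- unique(trace$F[sel])
  if (length(Fw) != 1L) {
    stop("force is not constant on the window (",
         paste(signif(Fw, 4), collapse = ", "), " pN)")
  }
  bp <- extension_to_bp(trace$x[sel], Fw, geometry, model)
  t <- trace$t[sel]
  fit <- stats::lm.fit(cbind(1, t - t[1]), bp)
  slope <- unname(fit$coefficients[2])
  dof <- length(t) - 2L
  se <- sqrt(sum(fit$residuals^2) / dof /
               sum((t - mean(t))^2))
  out <- data.frame(F = Fw, v = slope, v_err = se,
                    branch = if (slope >= 0) "association" else "dissociation",
                    condition = condition, stringsAsFactors = FALSE)
  class(out) <- c("rate_measurements", "data.frame")
  out
}

# Model prediction for the fit: theta = (log_kon, log_koff, dz_on, dz_off)
.eq_arrhenius <- function(theta, cFF, cuFu, conc, kBT) {
  exp(theta[1]) * conc * exp((cFF - cuFu) * theta[3] / kBT) -
    exp(theta[2]) * exp(-cFF * theta[4] / kBT)
}

#' Fit the two-term Arrhenius model to rate-versus-force data
#'
#' Weighted nonlinear least squares of the signed net rate over
#' `(k_on_per_nM, k_off, dz_on, dz_off)` with the unzipping force fixed at
#' its independently measured value. Rates are fitted on a log scale
#' internally (enforcing positivity); the transition-state distances are
#' bounded in `[0, 30]` bp. Weights are inverse-variance when `v_err` is
#' present, otherwise uniform; signed rates (not log rates) preserve the
#' sign change around the equilibrium force. Initialisation uses log-linear
#' regressions of each branch plus random multi-start perturbations.
#' Parameter uncertainties come from a seeded bootstrap over measurements.
#'
#' @param measurements a `rate_measurements` data.frame (columns `F`, `v`,
#'   optionally `v_err`), at least 4 points spanning both signs.
#' @param F_unz unzipping force (pN), held fixed.
#' @param concentration free protein concentration (nM).
#' @param model an [elasticity_model()].
#' @param geometry fork geometry; default `"hairpin"`.
#' @param n_starts number of optimisation starts; default 5.
#' @param n_boot bootstrap resamples for confidence intervals (0 disables);
#'   default 200.
#' @param seed seed for multi-start jitter and the bootstrap.
#' @return An object of class `fit_result`: list with `params` (a
#'   [kinetic_parameters()] with the fitted values), `estimates` (named
#'   vector), `ci` (bootstrap 95% intervals), `boot` (resample estimates),
#'   `F_equi_derived` (pN), `residuals`, `weighted_rss`, `at_bounds`,
#'   `convergence`.
#' @export
fit_eq1 <- function(measurements, F_unz, concentration,
                    model = elasticity_model(),
                    geometry = c("hairpin", "duplex"),
                    n_starts = 5, n_boot = 200, seed = 1) {
  geometry <- match.arg(geometry)
  F <- measurements$F; v <- measurements$v
  if (length(F) < 4) stop("need at least 4 rate measurements")
  if (all(v >= 0) || all(v <= 0)) {
    stop("measurements must span both branches (positive and negative ",
         "net rates)")
  }
  w <- if (!is.null(measurements$v_err) && any(measurements$v_err > 0)) {
    1 / pmax(measurements$v_err, 1e-6 * max(abs(v)))^2
  } else {
    rep(1, length(v))
  }
  kBT <- model$kBT
  cFF <- conversion_factor(F, geometry, model) * F
  cuFu <- conversion_factor(F_unz, geometry, model) * F_unz

  obj <- function(theta) {
    r <- v - .eq_arrhenius(theta, cFF, cuFu, concentration, kBT)
    sum(w * r^2)
  }
  lower <- c(-12, -12, 0, 0); upper <- c(15, 15, 30, 30)

  # branch-wise log-linear regressions for a starting point
  start0 <- local({
    dz_off0 <- 1; log_koff0 <- log(max(abs(v[v < 0]), 1))
    neg <- which(v < 0 & cFF < stats::median(cFF))
    if (length(neg) >= 2) {
      b <- stats::lm.fit(cbind(1, -cFF[neg] / kBT), log(-v[neg]))$coefficients
      if (is.finite(b[2]) && b[2] > 0) {
        log_koff0 <- b[1]; dz_off0 <- min(b[2], 29)
      }
    }
    dz_on0 <- 1; log_kon0 <- log(max(max(v), 1) / concentration)
    open_est <- v + exp(log_koff0) * exp(-cFF * dz_off0 / kBT)
    pos <- which(open_est > 0 & cFF > stats::median(cFF))
    if (length(pos) >= 2) {
      b <- stats::lm.fit(cbind(1, (cFF[pos] - cuFu) / kBT),
                         log(open_est[pos]))$coefficients
      if (is.finite(b[2]) && b[2] > 0) {
        log_kon0 <- b[1] - log(concentration); dz_on0 <- min(b[2], 29)
      }
    }
    unname(pmin(pmax(c(log_kon0, log_koff0, dz_on0, dz_off0), lower + 0.01),
                upper - 0.01))
  })

  run_fit <- function(starts) {
    best <- NULL
    for (s in starts) {
      fit <- tryCatch(
        stats::optim(s, obj, method = "L-BFGS-B", lower = lower,
                     upper = upper, control = list(maxit = 500)),
        error = function(e) NULL)
      if (!is.null(fit) && (is.null(best) || fit$value < best$value)) {
        best <- fit
      }
    }
    best
  }

  best <- .with_seed(seed, {
    starts <- c(list(start0), lapply(seq_len(max(n_starts - 1, 0)),
      function(i) {
        pmin(pmax(start0 + c(stats::rnorm(2, 0, 0.7),
                             stats::rnorm(2, 0, 0.8)),
                  lower + 0.01), upper - 0.01)
      }))
    run_fit(starts)
  })
  if (is.null(best)) stop("Arrhenius fit failed to converge from all starts")
  th <- unname(best$par)
  est <- c(k_on_per_nM = exp(th[1]), k_off = exp(th[2]),
           dz_on = th[3], dz_off = th[4])
  at_bounds <- any(abs(th - lower) < 1e-6) || any(abs(th - upper) < 1e-6)
  if (at_bounds) warning("fitted parameters lie at the box bounds")

  boot <- NULL; ci <- NULL
  if (n_boot > 0) {
    boot <- .with_seed(seed + 1L, {
      t(vapply(seq_len(n_boot), function(b) {
        idx <- sample(length(v), replace = TRUE)
        objb <- function(theta) {
          r <- v[idx] - .eq_arrhenius(theta, cFF[idx], cuFu, concentration, kBT)
          sum(w[idx] * r^2)
        }
        fb <- tryCatch(
          stats::optim(th, objb, method = "L-BFGS-B", lower = lower,
                       upper = upper, control = list(maxit = 300)),
          error = function(e) NULL)
        if (is.null(fb)) rep(NA_real_, 4) else fb$par
      }, numeric(4)))
    })
    boot <- cbind(k_on_per_nM = exp(boot[, 1]), k_off = exp(boot[, 2]),
                  dz_on = boot[, 3], dz_off = boot[, 4])
    ci <- apply(boot, 2, stats::quantile, probs = c(0.025, 0.975),
                na.rm = TRUE)
  }

  params <- kinetic_parameters(est[["k_on_per_nM"]], est[["k_off"]],
                               est[["dz_on"]], est[["dz_off"]], F_unz,
                               concentration, geometry = geometry)
  F_equi <- tryCatch(equilibrium_force(params, model),
                     error = function(e) NA_real_)
  structure(list(params = params, estimates = est, ci = ci, boot = boot,
                 F_equi_derived = F_equi,
                 residuals = v - .eq_arrhenius(th, cFF, cuFu, concentration,
                                               kBT),
                 weighted_rss = best$value, at_bounds = at_bounds,
                 convergence = best$convergence, n_boot = n_boot,
                 seed = seed),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Two-term Arrhenius fit (F_unz fixed at",
      sprintf("%.3g pN)\n", x$params$F_unz))
  e <- x$estimates
  lab <- c("k_on [bp/s/nM]", "k_off [bp/s]", "dz_on [bp]", "dz_off [bp]")
  for (i in seq_along(e)) {
    ci_txt <- if (!is.null(x$ci)) {
      sprintf("  [%.3g, %.3g]", x$ci[1, i], x$ci[2, i])
    } else ""
    cat(sprintf("  %-15s %.4g%s\n", lab[i], e[i], ci_txt))
  }
  cat(sprintf("  F_equi (derived): %.2f pN; weighted RSS %.4g\n",
              x$F_equi_derived, x$weighted_rss))
  invisible(x)
}

#' Standardize an association rate per nM of free protein
#'
#' The fork opening rate at the unzipping force grows linearly with the
#' protein concentration; dividing by the concentration gives the
#' standardized per-nM pre-factor. `destandardize_kon()` is the inverse.
#'
#' @param k_on association rate (bp/s) at the unzipping force.
#' @param concentration free protein concentration (nM).
#' @return Standardized rate (bp/s/nM), or its inverse.
#' @examples
#' standardize_kon(180, 20) # 9 bp/s/nM
#' @export
standardize_kon <- function(k_on, concentration) {
  if (any(concentration <= 0)) stop("concentration must be positive")
  k_on / concentration
}

#' @rdname standardize_kon
#' @export
destandardize_kon <- function(k_on, concentration) {
  if (any(concentration <= 0)) stop("concentration must be positive")
  k_on * concentration
}
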