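# Chi-square step detection (Kerssemakers-style) and footprint estimation
# from the step-size distribution.

# Residual sum of squares of plateau means over intervals delimited by
# sorted breakpoints (0-based right-closed boundaries), using cumsums.
.piecewise_ss <- function(cs, cs2, bounds) {
  a <- bounds[-length(bounds)] + 1L   # 1-based start
  b <- bounds[-1L]                    # 1-based end
  n <- b - a + 1L
  s <- cs[b + 1L] - cs[a]
  sum(cs2[b + 1L] - cs2[a] - s^2 / n)
}

# Best single split of segment [a, b] (1-based, inclusive) leaving at least
# w samples on each side. Returns NULL when no admissible split exists.
.best_split <- function(cs, cs2, a, b, w) {
  lo <- a + w - 1L; hi <- b - w
  if (lo > hi) return(NULL)
  i <- lo:hi
  nl <- i - a + 1L; nr <- b - i
  sl <- cs[i + 1L] - cs[a]
  sr <- cs[b + 1L] - cs[i + 1L]
  ss <- (cs2[b + 1L] - cs2[a]) - sl^2 / nl - sr^2 / nr
  k <- which.min(ss)
  seg_ss <- (cs2[b + 1L] - cs2[a]) -
    (cs[b + 1L] - cs[a])^2 / (b - a + 1L)
  list(at = i[k], gain = seg_ss - ss[k], ss_after = ss[k])
}

#' Detect steps in a trace by recursive chi-square fitting
#'
#' Piecewise-constant fit of the extension signal in the spirit of the
#' chi-square step fitter of Kerssemakers et al. Within a segment, change
#' points are placed greedily, each iteration adding the split that
#' maximally reduces the residual sum of squares over the current plateaus
#' (leaving at least one minimum dwell on either side). Every candidate
#' step count `k` is scored against a counter-fit whose change points sit
#' at the midpoints of the `k`-step fit's plateaus: genuine steps leave the
#' counter-fit with a large residual, whereas on pure noise it does at
#' least as well as the fit. The step count maximising the
#' counter-fit/fit chi-square ratio `S(k)` is accepted when the maximum
#' exceeds `acceptance_threshold`, and the procedure then recurses into
#' each accepted plateau until no further sub-segment passes -- this keeps
#' the detector sharp when dwell times are broadly distributed. On pure
#' noise the top-level ratio stays near 1 and nothing is accepted.
#' Deterministic for a given trace.
#'
#' Step sizes are converted to base pairs with the conversion factor at the
#' force recorded at each step's change point, so piecewise-constant force
#' schedules are handled per step.
#'
#' @param trace a `fork_trace` (or data.frame with columns `t`, `x`, `F`).
#' @param min_dwell minimum plateau duration (s); default 0.3.
#' @param acceptance_threshold minimum counter-fit/fit chi-square ratio;
#'   default 1.5.
#' @param max_steps cap on accepted steps; default
#'   `min(floor(n/w) - 1, 500)`.
#' @param geometry fork geometry for the bp conversion; default `"hairpin"`.
#' @param model an [elasticity_model()].
#' @return An object of class `step_fit`: list with `change_points` (sample
#'   indices of the last sample of each plateau), `levels` (nm),
#'   `step_sizes_nm`, `step_sizes_bp` (signed), `quality` (counter-fit/fit
#'   ratio per step), `t` (step times, s), `F_at_step`, `n_steps`.
#' @examples
#' p <- kinetic_parameters(5, 0.1, 0, 0, 18.2, concentration = 2,
#'                         footprint = 22)
#' tr <- simulate_fork_trace(simulation_config(p, seed = 7, noise_sd = 4,
#'   force_schedule = data.frame(duration = 30, force = 12)))
#' fit <- find_steps(tr)
#' fit$n_steps
#' @export
find_steps <- function(trace, min_dwell = 0.3, acceptance_threshold = 1.5,
                       max_steps = NULL, geometry = c("hairpin", "duplex"),
                       model = elasticity_model()) {
  geometry <- match.arg(geometry)
  x <- trace$x
  n <- length(x)
  sample_rate <- attr(trace, "sample_rate")
  if (is.null(sample_rate)) {
    sample_rate <- if (n > 1) 1 / stats::median(diff(trace$t)) else 1
  }
  w <- max(2L, as.integer(round(min_dwell * sample_rate)))
  empty <- structure(list(change_points = integer(0), levels = mean(x),
                          step_sizes_nm = numeric(0),
                          step_sizes_bp = numeric(0),
                          quality = numeric(0), t = numeric(0),
                          F_at_step = numeric(0), n_steps = 0L,
                          sample_rate = sample_rate),
                     class = "step_fit")
  if (n < 2L * w || stats::var(x) == 0) return(empty)
  if (is.null(max_steps)) max_steps <- min(n %/% w - 1L, 500L)

  cs <- c(0, cumsum(x))
  cs2 <- c(0, cumsum(x^2))

  # Greedy fit + counter-fit selection on one segment; returns the accepted
  # change points (with quality S at acceptance) or none.
  segment_fit <- function(a0, b0, budget) {
    segs <- list(list(a = a0, b = b0,
                      split = .best_split(cs, cs2, a0, b0, w)))
    cand <- integer(0); fit_chi2 <- numeric(0)
    chi2 <- .piecewise_ss(cs, cs2, c(a0 - 1L, b0))
    while (length(cand) < budget) {
      g <- vapply(segs, function(s) if (is.null(s$split)) -Inf
                                    else s$split$gain, numeric(1))
      j <- which.max(g)
      if (!is.finite(g[j]) || g[j] <= 0) break
      s <- segs[[j]]
      at <- s$split$at
      cand <- c(cand, at)
      chi2 <- chi2 - s$split$gain
      fit_chi2 <- c(fit_chi2, chi2)
      segs[[j]] <- list(a = s$a, b = at,
                        split = .best_split(cs, cs2, s$a, at, w))
      segs[[length(segs) + 1L]] <-
        list(a = at + 1L, b = s$b,
             split = .best_split(cs, cs2, at + 1L, s$b, w))
      if (chi2 <= 1e-12) break
    }
    if (length(cand) == 0L) return(NULL)
    S <- numeric(length(cand))
    for (k in seq_along(cand)) {
      bounds <- c(a0 - 1L, sort(cand[seq_len(k)]), b0)
      mids <- as.integer((bounds[-1L] + bounds[-length(bounds)]) %/% 2)
      mids <- unique(mids[mids > a0 - 1L & mids < b0])
      counter <- .piecewise_ss(cs, cs2, c(a0 - 1L, mids, b0))
      S[k] <- if (fit_chi2[k] <= 1e-12) Inf else counter / fit_chi2[k]
    }
    k_best <- which.max(S)
    if (S[k_best] < acceptance_threshold) return(NULL)
    list(cps = sort(cand[seq_len(k_best)]), S = S[k_best])
  }

  # recurse into accepted plateaus until nothing further passes
  cps <- integer(0); ratios <- numeric(0)
  stack <- list(c(1L, n))
  while (length(stack) > 0L && length(cps) < max_steps) {
    seg <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    a <- seg[1]; b <- seg[2]
    if (b - a + 1L < 2L * w) next
    res <- segment_fit(a, b, max_steps - length(cps))
    if (is.null(res)) next
    cps <- c(cps, res$cps)
    ratios <- c(ratios, rep(res$S, length(res$cps)))
    bounds <- c(a - 1L, res$cps, b)
    for (j in seq_len(length(bounds) - 1L)) {
      stack[[length(stack) + 1L]] <- c(bounds[j] + 1L, bounds[j + 1L])
    }
  }
  if (length(cps) == 0L) return(empty)

  ord <- order(cps)
  cp <- cps[ord]
  quality <- ratios[ord]
  bounds <- c(0L, cp, n)
  a <- bounds[-length(bounds)] + 1L; b <- bounds[-1L]
  levels <- (cs[b + 1L] - cs[a]) / (b - a + 1L)
  sizes_nm <- diff(levels)
  F_at <- trace$F[cp]
  cf <- conversion_factor(F_at, geometry, model)
  structure(list(change_points = cp, levels = levels,
                 step_sizes_nm = sizes_nm, step_sizes_bp = sizes_nm / cf,
                 quality = quality, t = trace$t[cp], F_at_step = F_at,
                 n_steps = length(cp),
                 sample_rate = sample_rate),
            class = "step_fit")
}

#' @export
print.step_fit <- function(x, ...) {
  cat(sprintf("Step fit: %d accepted steps", x$n_steps))
  if (x$n_steps > 0) {
    cat(sprintf(" (median |size| %.1f nm / %.1f bp)",
                stats::median(abs(x$step_sizes_nm)),
                stats::median(abs(x$step_sizes_bp))))
  }
  cat("\n")
  invisible(x)
}

#' Gaussian fit of the pooled step-size distribution
#'
#' Pools signed step sizes (in bp) from one or several [find_steps()] fits,
#' selects the opening (positive) or closing (negative) class, and fits a
#' Gaussian by maximum likelihood to the dominant mode. Because occasional
#' missed change points merge two protein binding events into one
#' double-sized step, the default trims the pooled sizes to a window of
#' (0.5, 1.5) times their median before fitting -- the histogram window
#' around the main peak.
#'
#' @param fits a `step_fit` or list of them (or a numeric vector of signed
#'   step sizes in bp).
#' @param sign `"opening"` (positive steps) or `"closing"` (negative steps;
#'   magnitudes are reported).
#' @param min_steps minimum number of pooled steps required; default 30.
#' @param trim trim to the dominant mode before fitting; default `TRUE`.
#' @return An object of class `step_histogram_fit`: list with `mean_bp`,
#'   `sd_bp`, `n_steps` (used in the fit), `n_pooled`, `sign_class`.
#' @export
fit_step_histogram <- function(fits, sign = c("opening", "closing"),
                               min_steps = 30, trim = TRUE) {
  sign <- match.arg(sign)
  sizes <- if (is.numeric(fits)) {
    fits
  } else {
    if (inherits(fits, "step_fit")) fits <- list(fits)
    unlist(lapply(fits, function(f) f$step_sizes_bp))
  }
  v <- if (sign == "opening") sizes[sizes > 0] else -sizes[sizes < 0]
  if (length(v) < min_steps) {
    stop("too few ", sign, " steps for a histogram fit: ", length(v),
         " < ", min_steps)
  }
  n_pooled <- length(v)
  if (trim) {
    med <- stats::median(v)
    keep <- v > 0.5 * med & v < 1.5 * med
    v <- v[keep]
  }
  structure(list(mean_bp = mean(v),
                 sd_bp = sqrt(mean((v - mean(v))^2)),
                 n_steps = length(v), n_pooled = n_pooled,
                 sign_class = sign),
            class = "step_histogram_fit")
}

#' @export
print.step_histogram_fit <- function(x, ...) {
  cat(sprintf("%s steps: mean %.1f bp, sd %.1f bp (n = %d of %d pooled)\n",
              x$sign_class, x$mean_bp, x$sd_bp, x$n_steps, x$n_pooled))
  invisible(x)
}
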