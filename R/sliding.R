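# Classification of hairpin closing cycles into abrupt versus gradual
# (protein-sliding) events and the friction fit F_push = zeta * v with the
# Einstein conversion to a diffusion coefficient.

#' Classify hairpin closing cycles as abrupt or gradual
#'
#' Scans a force-cycling trace for transitions from a high to a low force
#' and measures the closure duration of each cycle: the time taken for the
#' extension to fall from 90% to 10% of the fully-open level at the low
#' force. A cycle is gradual (a protein is sliding in front of the
#' rezipping fork) when this duration exceeds `threshold_multiple` times
#' the abrupt-closure reference time; unhindered rezipping completes within
#' a sample or two. The sliding velocity of a gradual cycle is the number
#' of nucleotides closed between the thresholds divided by the duration
#' (2 nt of ssDNA per rezipped bp).
#'
#' @param trace a `fork_trace` from [simulate_sliding_trace()] or read from
#'   file; the force column must encode the cycling schedule.
#' @param hairpin_size hairpin length (bp); taken from the trace metadata
#'   when present.
#' @param threshold_multiple gradual/abrupt duration ratio; default 10.
#' @param reference_time abrupt-closure reference time (s); default 0.05.
#' @param model an [elasticity_model()].
#' @return A data.frame of class `sliding_events` with one row per closing
#'   cycle: `cycle`, `F_low`, `gradual`, `duration` (s), `velocity` (nt/s;
#'   `NA` for abrupt cycles), `nt_closed`.
#' @export
classify_closing_cycles <- function(trace, hairpin_size = NULL,
                                    threshold_multiple = 10,
                                    reference_time = 0.05,
                                    model = elasticity_model()) {
  if (is.null(hairpin_size)) {
    hairpin_size <- attr(trace, "meta")$hairpin_size
    if (is.null(hairpin_size)) {
      stop("hairpin_size not given and absent from trace metadata")
    }
  }
  r <- rle(trace$F)
  ends <- cumsum(r$lengths)
  starts <- c(1, utils::head(ends, -1) + 1)
  # closing segments: force drops relative to the previous segment
  closing <- which(c(FALSE, diff(r$values) < 0))
  if (length(closing) == 0) {
    out <- data.frame(cycle = integer(0), F_low = numeric(0),
                      gradual = logical(0), duration = numeric(0),
                      velocity = numeric(0), nt_closed = numeric(0))
    class(out) <- c("sliding_events", "data.frame")
    return(out)
  }
  rows <- lapply(seq_along(closing), function(j) {
    i <- closing[j]
    idx <- starts[i]:ends[i]
    F_low <- r$values[i]
    x <- trace$x[idx]; t <- trace$t[idx]
    x_open <- conversion_factor(F_low, "hairpin", model) * hairpin_size
    i_hi <- which(x < 0.9 * x_open)[1]
    if (is.na(i_hi)) return(NULL)                 # never started closing
    i_lo <- which(x < 0.1 * x_open & seq_along(x) >= i_hi)[1]
    if (is.na(i_lo)) return(NULL)                 # stalled, incomplete
    duration <- max(t[i_lo] - t[i_hi], t[2] - t[1])
    nt_closed <- 0.8 * 2 * hairpin_size
    gradual <- duration > threshold_multiple * reference_time
    data.frame(cycle = j, F_low = F_low, gradual = gradual,
               duration = duration,
               velocity = if (gradual) nt_closed / duration else NA_real_,
               nt_closed = nt_closed)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(cycle = integer(0), F_low = numeric(0),
                      gradual = logical(0), duration = numeric(0),
                      velocity = numeric(0), nt_closed = numeric(0))
  }
  class(out) <- c("sliding_events", "data.frame")
  out
}

#' Fit the friction law of fork-driven protein sliding
#'
#' The pushing force exerted by the rezipping fork is the difference
#' between the characteristic unzipping force and the applied force,
#' `F_push = F_unz - F_low`, and balances friction: `F_push = zeta * v`.
#' The fit is an ordinary least-squares line of the mean gradual-cycle
#' velocity against `F_push` (one mean per distinct low force); the
#' friction coefficient is the reciprocal of its slope, and the Einstein
#' relation `D = kBT_nt / zeta` converts it into a diffusion coefficient.
#'
#' `kBT_nt` is the thermal energy expressed per nucleotide of ssDNA
#' contour, `kBT / ss_contour_per_nt`; the resulting `D` (nt^2/s) depends
#' on that length convention.
#'
#' @param events a `sliding_events` data.frame from
#'   [classify_closing_cycles()] with at least 3 gradual events spanning at
#'   least 2 distinct low forces.
#' @param F_unz characteristic unzipping force (pN).
#' @param model an [elasticity_model()].
#' @param kBT_nt thermal energy per nucleotide (pN nt); default
#'   `kBT / ss_contour_per_nt`.
#' @return An object of class `friction_fit`: list with `zeta` (pN s/nt),
#'   `zeta_err`, `slope` (nt/s/pN), `intercept` (nt/s at zero push),
#'   `r_squared`, `D` (nt^2/s), `n_events`, and the per-force mean table
#'   `means`.
#' @export
fit_friction <- function(events, F_unz, model = elasticity_model(),
                         kBT_nt = model$kBT / model$ss_contour_per_nt) {
  g <- events[events$gradual & is.finite(events$velocity), ]
  if (nrow(g) < 3) stop("need at least 3 gradual events, got ", nrow(g))
  if (length(unique(g$F_low)) < 2) {
    stop("need gradual events at >= 2 distinct low forces")
  }
  F_push <- F_unz - g$F_low
  means <- stats::aggregate(list(velocity = g$velocity),
                            by = list(F_push = F_push), FUN = mean)
  fit <- stats::lm.fit(cbind(1, means$F_push), means$velocity)
  slope <- unname(fit$coefficients[2])
  if (!is.finite(slope) || slope <= 0) {
    stop("invalid friction fit: velocity does not increase with the ",
         "pushing force")
  }
  rss <- sum(fit$residuals^2)
  tss <- sum((means$velocity - mean(means$velocity))^2)
  sxx <- sum((means$F_push - mean(means$F_push))^2)
  dof <- nrow(means) - 2L
  se_slope <- if (dof > 0) sqrt(rss / dof / sxx) else NA_real_
  zeta <- 1 / slope
  structure(list(zeta = zeta,
                 zeta_err = se_slope / slope^2,
                 slope = slope,
                 intercept = unname(fit$coefficients[1]),
                 r_squared = 1 - rss / tss,
                 D = kBT_nt / zeta,
                 n_events = nrow(g),
                 means = means),
            class = "friction_fit")
}

#' @export
print.friction_fit <- function(x, ...) {
  cat(sprintf("Friction fit over %d gradual events\n", x$n_events))
  cat(sprintf("  zeta = %.4g +/- %.2g pN s/nt (R^2 = %.2f)\n",
              x$zeta, x$zeta_err, x$r_squared))
  cat(sprintf("  D = %.3g nt^2/s (Einstein relation)\n", x$D))
  invisible(x)
}
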