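# Two-term Arrhenius model for the net fork opening rate, the equilibrium
# force, and the binding-energetics calculus derived from it.

#' Conversion between pN nm and kJ/mol
#' @keywords internal
.PNNM_TO_KJMOL <- 0.6022

#' Kinetic parameters of protein-mediated fork opening/closing
#'
#' Parameter set of the two-term Arrhenius rate model (see [net_rate()]):
#' association pre-factor `k_on_per_nM` (the per-nM fork opening rate
#' extrapolated to the unzipping force, in bp/s/nM), dissociation pre-factor
#' `k_off` (the fork closing rate extrapolated to zero force, bp/s), the
#' transition-state distances `dz_on` and `dz_off` (bp of transient helix
#' opening / rezipping needed to commit a full protein binding or release
#' event -- the "toehold"), the characteristic unzipping force `F_unz` (pN),
#' the free protein concentration (nM), the binding footprint (bp opened per
#' bound heterotrimer) and the fork geometry.
#'
#' @param k_on_per_nM standardized association pre-factor (bp/s/nM) at F_unz.
#' @param k_off dissociation pre-factor (bp/s) at zero force.
#' @param dz_on association transition-state distance (bp).
#' @param dz_off dissociation transition-state distance (bp).
#' @param F_unz characteristic unzipping force (pN).
#' @param concentration free protein concentration (nM).
#' @param footprint binding-site size (bp); default 23.
#' @param geometry `"hairpin"` or `"duplex"` (selects the conversion factor).
#' @return An object of class `kinetic_parameters`.
#' @examples
#' kinetic_parameters(9.0, 239, 3.3, 1.6, 18.2, concentration = 20)
#' @export
kinetic_parameters <- function(k_on_per_nM, k_off, dz_on, dz_off, F_unz,
                               concentration, footprint = 23,
                               geometry = c("hairpin", "duplex")) {
  geometry <- match.arg(geometry)
  p <- list(k_on_per_nM = k_on_per_nM, k_off = k_off,
            dz_on = dz_on, dz_off = dz_off, F_unz = F_unz,
            concentration = concentration, footprint = footprint,
            geometry = geometry)
  num <- p[setdiff(names(p), "geometry")]
  bad <- vapply(num, function(v) !is.numeric(v) || length(v) != 1L ||
                  !is.finite(v) || v < 0, logical(1))
  if (any(bad)) {
    stop("kinetic_parameters: numeric fields must be single non-negative ",
         "numbers; offending: ", paste(names(num)[bad], collapse = ", "))
  }
  if (F_unz <= 0) stop("F_unz must be positive")
  if (footprint < 1) stop("footprint must be >= 1 bp")
  structure(p, class = "kinetic_parameters")
}

#' @export
print.kinetic_parameters <- function(x, ...) {
  cat("Fork kinetic parameters (", x$geometry, " geometry)\n", sep = "")
  cat(sprintf("  k_on  %.3g bp/s/nM at F_unz (%.3g nM free protein)\n",
              x$k_on_per_nM, x$concentration))
  cat(sprintf("  k_off %.3g bp/s at zero force\n", x$k_off))
  cat(sprintf("  dz_on %.3g bp, dz_off %.3g bp, F_unz %.3g pN, footprint %.3g bp\n",
              x$dz_on, x$dz_off, x$F_unz, x$footprint))
  invisible(x)
}

#' Published rate parameters for yeast and human RPA
#'
#' Central values of the two-term Arrhenius fit parameters determined by
#' force spectroscopy of RPA on a 488 bp DNA hairpin, for yeast RPA (20 nM)
#' and human RPA (50 nM) at several Mg2+ concentrations. `F_equi` is the
#' reported equilibrium force at which net opening vanishes.
#'
#' @return A data.frame with one row per condition: `protein`, `mg_mM`,
#'   `k_on_per_nM`, `k_off`, `dz_on`, `dz_off`, `F_unz`, `concentration`,
#'   `F_equi`.
#' @examples
#' tab <- rpa_reference_parameters()
#' subset(tab, protein == "yRPA" & mg_mM == 3)
#' @export
rpa_reference_parameters <- function() {
  data.frame(
    protein = c("yRPA", "yRPA", "yRPA", "hRPA", "hRPA", "hRPA"),
    mg_mM = c(1, 3, 10, 3, 5, 10),
    k_on_per_nM = c(34.2, 9.0, 18.2, 2.1, 3.2, 6.2),
    k_off = c(233, 239, 336, 37, 109, 189),
    dz_on = c(5.0, 3.3, 2.4, 1.6, 2.1, 2.5),
    dz_off = c(1.8, 1.6, 1.8, 0.6, 1.1, 0.9),
    F_unz = c(17.8, 18.2, 19.9, 18.2, 18.8, 19.9),
    concentration = c(20, 20, 20, 50, 50, 50),
    F_equi = c(12.4, 12.4, 11.1, 11.8, 12.2, 14.5),
    stringsAsFactors = FALSE
  )
}

#' Kinetic parameters for one reference condition
#'
#' Convenience constructor pulling one row of [rpa_reference_parameters()]
#' into a [kinetic_parameters()] object.
#'
#' @param protein `"yRPA"` or `"hRPA"`.
#' @param mg_mM Mg2+ concentration in mM (1, 3 or 10 for yRPA; 3, 5 or 10
#'   for hRPA).
#' @param concentration free protein concentration (nM); defaults to the
#'   concentration at which the condition was measured.
#' @param footprint binding footprint (bp); default 23.
#' @return A [kinetic_parameters()] object.
#' @export
rpa_condition <- function(protein = c("yRPA", "hRPA"), mg_mM = 3,
                          concentration = NULL, footprint = 23) {
  protein <- match.arg(protein)
  tab <- rpa_reference_parameters()
  row <- tab[tab$protein == protein & tab$mg_mM == mg_mM, ]
  if (nrow(row) != 1L) {
    stop("no reference condition for ", protein, " at ", mg_mM, " mM Mg2+")
  }
  if (is.null(concentration)) concentration <- row$concentration
  kinetic_parameters(row$k_on_per_nM, row$k_off, row$dz_on, row$dz_off,
                     row$F_unz, concentration, footprint = footprint)
}

#' Force-dependent opening and closing branch rates
#'
#' The two Arrhenius terms of the net-rate model, individually:
#' \deqn{k_{open}(F) = k_{on} C \exp\left[\frac{(c(F) F -
#'   c(F_{unz}) F_{unz})\,\Delta z_{on}}{k_B T}\right]}
#' \deqn{k_{close}(F) = k_{off} \exp\left[-\frac{c(F) F\,
#'   \Delta z_{off}}{k_B T}\right]}
#' where `c(F)` is the geometry-dependent [conversion_factor()]. Both are in
#' bp/s and positive.
#'
#' @param F applied force (pN), vectorised.
#' @param params a [kinetic_parameters()] object.
#' @param model an [elasticity_model()].
#' @return Rate in bp/s.
#' @export
opening_rate <- function(F, params, model = elasticity_model()) {
  cf <- conversion_factor(F, params$geometry, model)
  cu <- conversion_factor(params$F_unz, params$geometry, model)
  params$k_on_per_nM * params$concentration *
    exp((cf * F - cu * params$F_unz) * params$dz_on / model$kBT)
}

#' @rdname opening_rate
#' @export
closing_rate <- function(F, params, model = elasticity_model()) {
  cf <- conversion_factor(F, params$geometry, model)
  params$k_off * exp(-cf * F * params$dz_off / model$kBT)
}

#' Net fork opening rate (two-term Arrhenius model)
#'
#' Net rate of protein-mediated fork opening, the difference between the
#' force-activated association branch and the force-suppressed dissociation
#' branch (see [opening_rate()]). Positive values mean the fork opens
#' (association dominates), negative values mean it closes.
#'
#' @inheritParams opening_rate
#' @return Signed net rate (bp/s), vectorised over `F`.
#' @examples
#' p <- rpa_condition("yRPA", 3)
#' net_rate(15.7, p) # ~ +17 bp/s, fork opening
#' net_rate(4.5, p)  # large negative, rapid rezipping
#' @export
net_rate <- function(F, params, model = elasticity_model()) {
  opening_rate(F, params, model) - closing_rate(F, params, model)
}

#' Equilibrium force of fork opening versus closing
#'
#' Force at which the net opening rate vanishes, found by bracketed
#' bisection of [net_rate()]. Both branch exponents are monotone in
#' `c(F) * F`, so the root is unique when it exists.
#'
#' @param params a [kinetic_parameters()] object.
#' @param model an [elasticity_model()].
#' @param bracket force bracket (pN); default `c(1, F_unz + 5)` for the
#'   hairpin geometry and `c(9, F_unz + 5)` for the duplex geometry (whose
#'   conversion factor is non-positive below ~8 pN).
#' @param tol force tolerance of the bisection (pN).
#' @return Equilibrium force (pN).
#' @examples
#' equilibrium_force(rpa_condition("yRPA", 3)) # ~13.4 pN
#' @export
equilibrium_force <- function(params, model = elasticity_model(),
                              bracket = c(if (params$geometry == "duplex") 9
                                          else 1, params$F_unz + 5),
                              tol = 0.01) {
  f <- function(F) net_rate(F, params, model)
  lo <- bracket[1]; hi <- bracket[2]
  vlo <- f(lo); vhi <- f(hi)
  if (vlo == 0 && vhi == 0) {
    stop("degenerate kinetics: net rate vanishes over the whole bracket")
  }
  if (sign(vlo) == sign(vhi)) {
    stop("no equilibrium: net rate does not change sign on (",
         lo, ", ", hi, ") pN")
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    vm <- f(mid)
    if (vm == 0) return(mid)
    if (sign(vm) == sign(vlo)) {
      lo <- mid; vlo <- vm
    } else {
      hi <- mid
    }
  }
  (lo + hi) / 2
}

#' Binding free energy per heterotrimer from the force balance
#'
#' At the equilibrium force, the base-pairing energy over one binding
#' footprint equals the mechanical work of opening plus twice the binding
#' free energy (one protein per strand):
#' \deqn{\Delta G_{bind} = \left(c_{unz} F_{unz} - c_{equi} F_{equi}\right)
#'   \cdot \mathrm{footprint} / 2}
#' evaluated with the hairpin conversion factor and converted to kJ/mol
#' (1 pN nm = 0.6022 kJ/mol).
#'
#' @param F_unz unzipping force (pN).
#' @param F_equi equilibrium force (pN); normally `<= F_unz`.
#' @param footprint binding footprint (bp); default 23.
#' @param model an [elasticity_model()].
#' @return Binding free energy per heterotrimer (kJ/mol). Negative values
#'   (when `F_equi > F_unz`) are returned with a warning.
#' @examples
#' binding_free_energy(18.2, 12.4) # ~46 kJ/mol
#' @export
binding_free_energy <- function(F_unz, F_equi, footprint = 23,
                                model = elasticity_model()) {
  if (any(F_unz <= 0) || any(F_equi <= 0)) stop("forces must be positive")
  work_unz <- conversion_factor(F_unz, "hairpin", model) * F_unz
  work_equi <- conversion_factor(F_equi, "hairpin", model) * F_equi
  dg <- (work_unz - work_equi) * footprint / 2 * .PNNM_TO_KJMOL
  if (any(dg < 0)) {
    warning("F_equi exceeds F_unz: negative binding free energy")
  }
  dg
}

#' Binding free energy from an equilibrium association constant
#'
#' `RT ln(K)` with `K` in 1/M, returned in kJ/mol. Serves as the
#' solution-based comparison value for [binding_free_energy()].
#'
#' @param K association equilibrium constant (1/M).
#' @param temperature absolute temperature (K); default 298.
#' @return Free energy (kJ/mol).
#' @examples
#' free_energy_from_K(1e10) # ~57 kJ/mol
#' @export
free_energy_from_K <- function(K, temperature = 298) {
  if (any(K <= 0)) stop("K must be positive")
  8.314462618 * temperature * log(K) / 1000
}

#' Passive fork-unwinding rate of a stepping motor
#'
#' Velocity of a passive helicase (or passively trapping binder) of step
#' size `n` bp on a hairpin under tension:
#' \deqn{v(F) = v_{max} \exp\left[\frac{\Delta G_F - \Delta G_{bp}}
#'   {k_B T}\right]}
#' with the mechanical work \eqn{\Delta G_F = c(F) F n} and the pairing
#' energy \eqn{\Delta G_{bp} = c(F_{unz}) F_{unz} n}; ssDNA entropic
#' stretching corrections are neglected. `v` equals `v_max` exactly at the
#' unzipping force and falls off exponentially below it.
#'
#' @param F applied force (pN), vectorised.
#' @param v_max maximum stepping rate (bp/s).
#' @param n step size (bp); must be >= 1.
#' @param F_unz unzipping force (pN).
#' @param model an [elasticity_model()].
#' @return Unwinding rate (bp/s).
#' @export
passive_unwinding_rate <- function(F, v_max, n, F_unz,
                                   model = elasticity_model()) {
  if (n < 1) stop("step size n must be >= 1 bp")
  dG_F <- conversion_factor(F, "hairpin", model) * F * n
  dG_bp <- conversion_factor(F_unz, "hairpin", model) * F_unz * n
  v_max * exp((dG_F - dG_bp) / model$kBT)
}

#' Zero-dissociation Mg2+ concentration by linear extrapolation
#'
#' Ordinary least-squares line through dissociation pre-factors `k_off`
#' measured at several Mg2+ concentrations; returns the concentration at
#' which the line crosses zero (below which no dissociation is expected).
#'
#' @param mg_mM Mg2+ concentrations (mM), length >= 2.
#' @param k_off dissociation pre-factors (bp/s), same length.
#' @return The x-intercept (mM).
#' @examples
#' mg_extrapolation(c(3, 5, 10), c(37, 109, 189)) # ~0.6 mM
#' @export
mg_extrapolation <- function(mg_mM, k_off) {
  if (length(mg_mM) < 2 || length(k_off) != length(mg_mM)) {
    stop("need at least two (mg, k_off) points of equal length")
  }
  fit <- stats::lm.fit(cbind(1, mg_mM), k_off)
  a <- fit$coefficients[1]; b <- fit$coefficients[2]
  if (!is.finite(b) || b <= 0) {
    stop("no zero crossing: extrapolation slope is not positive")
  }
  unname(-a / b)
}

#' Full binding-energetics summary for a parameter set
#'
#' Combines [equilibrium_force()], [basepair_energy_from_unzipping()] and
#' [binding_free_energy()] into one result: the equilibrium force, the
#' per-bp pairing energy at the unzipping force, and the binding free energy
#' per heterotrimer.
#'
#' @param params a [kinetic_parameters()] object.
#' @param model an [elasticity_model()].
#' @param F_equi optionally, an externally supplied equilibrium force (pN);
#'   when `NULL` it is computed from `params`.
#' @return A list of class `energetics_result` with elements `F_equi` (pN),
#'   `dG_bp_per_bp` (pN nm), `dG_bind` (kJ/mol) and `footprint` (bp).
#' @export
binding_energetics <- function(params, model = elasticity_model(),
                               F_equi = NULL) {
  if (is.null(F_equi)) F_equi <- equilibrium_force(params, model)
  structure(list(
    F_equi = F_equi,
    dG_bp_per_bp = basepair_energy_from_unzipping(params$F_unz, model),
    dG_bind = binding_free_energy(params$F_unz, F_equi,
                                  footprint = params$footprint, model = model),
    footprint = params$footprint
  ), class = "energetics_result")
}

#' @export
print.energetics_result <- function(x, ...) {
  cat(sprintf("F_equi: %.2f pN\n", x$F_equi))
  cat(sprintf("dG_bp:  %.2f pN nm per bp (%.2f kJ/mol)\n",
              x$dG_bp_per_bp, x$dG_bp_per_bp * .PNNM_TO_KJMOL))
  cat(sprintf("dG_bind: %.1f kJ/mol per heterotrimer (footprint %g bp)\n",
              x$dG_bind, x$footprint))
  invisible(x)
}
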