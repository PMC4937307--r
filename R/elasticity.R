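# Polymer elasticity of the two DNA species at the fork and the
# force-dependent conversion between opened base pairs and extension.

#' Polymer elasticity parameters for ssDNA and dsDNA
#'
#' Bundles the parameters of the extensible freely-jointed chain (FJC) used
#' for single-stranded DNA and of the extensible worm-like chain (WLC,
#' Marko-Siggia interpolation plus enthalpic stretching) used for B-form
#' double-stranded DNA, together with the thermal energy. These models define
#' the conversion factor `c(F)` between the number of opened base pairs at a
#' fork and the measured change in bead extension (see
#' [conversion_factor()]).
#'
#' Defaults are standard literature values for moderate ionic strength:
#' ssDNA contour 0.56 nm/nt, Kuhn length 1.5 nm, stretch modulus 800 pN;
#' dsDNA rise 0.34 nm/bp, persistence length 50 nm, stretch modulus 1000 pN;
#' kBT = 4.11 pN nm (298 K). With these values a 488 bp hairpin opens by
#' about 475 nm at its 18.2 pN unzipping force.
#'
#' @param ss_contour_per_nt ssDNA contour length per nucleotide (nm/nt).
#' @param ss_kuhn_length ssDNA FJC Kuhn length (nm).
#' @param ss_stretch_modulus ssDNA enthalpic stretch modulus (pN).
#' @param ds_rise_per_bp dsDNA helical rise (nm/bp).
#' @param ds_persistence_length dsDNA WLC persistence length (nm).
#' @param ds_stretch_modulus dsDNA enthalpic stretch modulus (pN).
#' @param kBT thermal energy (pN nm); 4.11 corresponds to 298 K.
#' @return An object of class `elasticity_model` (a named list).
#' @examples
#' m <- elasticity_model()
#' ssdna_extension_per_nt(18.2, m)
#' @export
elasticity_model <- function(ss_contour_per_nt = 0.56,
                             ss_kuhn_length = 1.5,
                             ss_stretch_modulus = 800,
                             ds_rise_per_bp = 0.34,
                             ds_persistence_length = 50,
                             ds_stretch_modulus = 1000,
                             kBT = 4.11) {
  m <- list(
    ss_contour_per_nt = ss_contour_per_nt,
    ss_kuhn_length = ss_kuhn_length,
    ss_stretch_modulus = ss_stretch_modulus,
    ds_rise_per_bp = ds_rise_per_bp,
    ds_persistence_length = ds_persistence_length,
    ds_stretch_modulus = ds_stretch_modulus,
    kBT = kBT
  )
  bad <- vapply(m, function(v) !is.numeric(v) || length(v) != 1L ||
                  !is.finite(v) || v <= 0, logical(1))
  if (any(bad)) {
    stop("elasticity_model: all parameters must be single positive numbers; ",
         "offending: ", paste(names(m)[bad], collapse = ", "))
  }
  structure(m, class = "elasticity_model")
}

#' @export
print.elasticity_model <- function(x, ...) {
  cat("Elasticity model (extensible FJC / extensible WLC)\n")
  cat(sprintf("  ssDNA: contour %.3g nm/nt, Kuhn %.3g nm, S %.4g pN\n",
              x$ss_contour_per_nt, x$ss_kuhn_length, x$ss_stretch_modulus))
  cat(sprintf("  dsDNA: rise %.3g nm/bp, P %.3g nm, S %.4g pN\n",
              x$ds_rise_per_bp, x$ds_persistence_length, x$ds_stretch_modulus))
  cat(sprintf("  kBT: %.3g pN nm\n", x$kBT))
  invisible(x)
}

.check_force <- function(F) {
  if (!is.numeric(F) || any(!is.finite(F)) || any(F <= 0)) {
    stop("force must be a finite positive number (pN)")
  }
  if (any(F > 65)) {
    warning("applied force exceeds 65 pN: outside the model range ",
            "(dsDNA overstretching)")
  }
  invisible(F)
}

#' ssDNA extension per nucleotide (extensible FJC)
#'
#' Evaluates the extensible freely-jointed chain
#' \deqn{x_{ss}(F) = L_c \left[\coth\left(\frac{F b}{k_B T}\right) -
#'   \frac{k_B T}{F b}\right]\left(1 + \frac{F}{S}\right)}
#' giving the equilibrium extension of one ssDNA nucleotide under force.
#' Strictly increasing in force and bounded by
#' `ss_contour_per_nt * (1 + F/S)`.
#'
#' @param F applied force (pN), vectorised; must be positive.
#' @param model an [elasticity_model()].
#' @return Extension per nucleotide (nm/nt).
#' @export
ssdna_extension_per_nt <- function(F, model = elasticity_model()) {
  .check_force(F)
  u <- F * model$ss_kuhn_length / model$kBT
  langevin <- 1 / tanh(u) - 1 / u
  model$ss_contour_per_nt * langevin * (1 + F / model$ss_stretch_modulus)
}

#' dsDNA extension per base pair (extensible WLC)
#'
#' Marko-Siggia high-force interpolation with an enthalpic stretching term:
#' \deqn{x_{ds}(F) = h \left[1 - \frac{1}{2}\sqrt{\frac{k_B T}{F P}} +
#'   \frac{F}{S}\right]}
#' with helical rise `h`, persistence length `P` and stretch modulus `S`.
#' Valid and strictly increasing over roughly 0.1-65 pN.
#'
#' @inheritParams ssdna_extension_per_nt
#' @return Extension per base pair (nm/bp).
#' @export
dsdna_extension_per_bp <- function(F, model = elasticity_model()) {
  .check_force(F)
  model$ds_rise_per_bp *
    (1 - 0.5 * sqrt(model$kBT / (F * model$ds_persistence_length)) +
       F / model$ds_stretch_modulus)
}

#' Conversion factor between opened base pairs and extension change
#'
#' At a fork held under force, opening one base pair changes the measured
#' extension by a force-dependent length `c(F)`:
#' \itemize{
#'   \item hairpin geometry: both released nucleotides carry the force, so
#'     `c(F) = 2 x_ss(F)`;
#'   \item (flapped) duplex geometry: only one strand is under tension and
#'     converts from dsDNA to ssDNA while the flap strand stays slack, so
#'     `c(F) = x_ss(F) - x_ds(F)`.
#' }
#' For the duplex geometry `c(F)` is non-positive below roughly 8 pN (ssDNA
#' is then shorter than dsDNA): the value is returned as-is with a warning,
#' because the melting signal vanishes there.
#'
#' @inheritParams ssdna_extension_per_nt
#' @param geometry `"hairpin"` or `"duplex"`.
#' @return Extension change per opened base pair (nm/bp).
#' @examples
#' conversion_factor(18.2, "hairpin")
#' conversion_factor(48.7, "duplex")
#' @export
conversion_factor <- function(F, geometry = c("hairpin", "duplex"),
                              model = elasticity_model()) {
  geometry <- match.arg(geometry)
  cf <- switch(geometry,
    hairpin = 2 * ssdna_extension_per_nt(F, model),
    duplex = ssdna_extension_per_nt(F, model) -
      dsdna_extension_per_bp(F, model)
  )
  if (geometry == "duplex" && any(cf <= 0)) {
    warning("duplex conversion factor is non-positive at ",
            paste(signif(F[cf <= 0], 3), collapse = ", "),
            " pN: no melting signal in this force range")
  }
  cf
}

#' Convert opened base pairs to extension change, and back
#'
#' `bp_to_extension()` multiplies by the conversion factor `c(F)`;
#' `extension_to_bp()` divides by it. The two round-trip exactly.
#' `extension_to_bp()` refuses the duplex low-force regime where `c(F) <= 0`.
#'
#' @param n_bp number of opened base pairs (real-valued).
#' @param dx extension change (nm).
#' @inheritParams conversion_factor
#' @return Extension change (nm), or opened base pairs.
#' @export
bp_to_extension <- function(n_bp, F, geometry = c("hairpin", "duplex"),
                            model = elasticity_model()) {
  n_bp * conversion_factor(F, geometry, model)
}

#' @rdname bp_to_extension
#' @export
extension_to_bp <- function(dx, F, geometry = c("hairpin", "duplex"),
                            model = elasticity_model()) {
  cf <- conversion_factor(F, geometry, model)
  if (any(cf <= 0)) {
    stop("conversion factor is non-positive: cannot convert extension to ",
         "base pairs in this regime")
  }
  dx / cf
}

#' Base-pairing energy from the mechanical unzipping force
#'
#' At the unzipping force the work performed while opening one base pair
#' exactly compensates its pairing free energy, so
#' `dG_bp = c(F_unz) * F_unz` per base pair (hairpin geometry).
#'
#' @param F_unz characteristic unzipping force (pN).
#' @param model an [elasticity_model()].
#' @return Energy per base pair (pN nm).
#' @examples
#' basepair_energy_from_unzipping(18.2) # ~17.7 pN nm ~ 4.3 kBT
#' @export
basepair_energy_from_unzipping <- function(F_unz, model = elasticity_model()) {
  conversion_factor(F_unz, "hairpin", model) * F_unz
}
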