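#' Donnan equilibrium concentrations inside the gel
#'
#' Closed-form equilibrium partitioning of a monovalent binary electrolyte
#' between the bath and a gel carrying a fixed charge. The gel concentrations
#' are the unique positive pair satisfying gel electroneutrality
#' `z+ c+ + z- c- + z_f c_f = 0` together with the ideal Donnan product
#' `c+ c- = c_sol^2`. For an anionic gel (z_f = -1) this gives
#' `c+- = -+ z_f c_f / 2 + sqrt((c_f/2)^2 + c_sol^2)`.
#'
#' @param fixed_charge [fixed_charge_field()]; `|valence|` must be 1.
#' @param bath [bath_composition()] with exactly two monovalent species of
#'   opposite sign and equal molarity `c_sol`.
#' @return Named numeric vector `c(gel_cation =, gel_anion =)` in mol m^-3.
#' @examples
#' b <- nacl_bath(1)
#' donnan_concentrations(fixed_charge_field(2, -1), b)
#' # gel_cation 2.4142, gel_anion 0.4142
#' @export
donnan_concentrations <- function(fixed_charge, bath) {
  check_monovalent_binary(bath)
  if (abs(fixed_charge$valence) != 1L) {
    stop("donnan_concentrations: only |z_f| = 1 is supported", call. = FALSE)
  }
  c_sol <- bath$molarity[[1L]]
  zc_f <- fixed_charge$valence * fixed_charge$concentration # signed
  disc <- sqrt((zc_f / 2)^2 + c_sol^2)
  # electroneutrality: c+ - c- = -z_f c_f ; product: c+ c- = c_sol^2
  c_cat <- -zc_f / 2 + disc
  c_an <- zc_f / 2 + disc
  c(gel_cation = c_cat, gel_anion = c_an)
}

#' Donnan potential of the gel relative to the bath
#'
#' The potential jump across the gel-solution interface implied by equality
#' of electrochemical potentials, `dphi = RT/(z_k F) log(c_sol,k / c_gel,k)`,
#' evaluated identically (to rounding) with either species. Negative for an
#' anionic gel.
#'
#' @param equilibrium Either a `donnan_equilibrium` object or the vector
#'   returned by [donnan_concentrations()].
#' @param bath [bath_composition()].
#' @param constants [physical_constants()].
#' @return Potential jump (gel minus bath) in volts.
#' @examples
#' b <- nacl_bath(1)
#' eq <- donnan_concentrations(fixed_charge_field(2, -1), b)
#' 1e3 * donnan_potential(eq, b) # -22.252 mV
#' @export
donnan_potential <- function(equilibrium, bath,
                             constants = physical_constants()) {
  check_monovalent_binary(bath)
  cg <- if (inherits(equilibrium, "donnan_equilibrium")) {
    c(equilibrium$gel_cation, equilibrium$gel_anion)
  } else {
    c(equilibrium[["gel_cation"]], equilibrium[["gel_anion"]])
  }
  z <- vapply(bath$species, `[[`, numeric(1), "valence")
  ord <- order(-z) # cation first
  cs <- bath$molarity[ord]
  z <- z[ord]
  if (any(!is.finite(cg)) || any(cg <= 0) || any(cs <= 0)) {
    stop("donnan_potential: concentrations must be positive", call. = FALSE)
  }
  vt <- thermal_voltage(constants)
  phi <- vt / z * log(cs / cg)
  if (abs(phi[1] - phi[2]) > 1e-12 * max(abs(phi), vt)) {
    warning("donnan_potential: cation- and anion-based evaluations disagree; ",
            "the supplied state is not a Donnan equilibrium", call. = FALSE)
  }
  unname(phi[1])
}

#' Full Donnan equilibrium (concentrations + potential)
#'
#' @inheritParams donnan_concentrations
#' @param constants [physical_constants()].
#' @return Object of class `donnan_equilibrium` with elements `gel_cation`,
#'   `gel_anion` (mol m^-3) and `potential_jump` (V, gel minus bath).
#' @export
donnan_equilibrium <- function(fixed_charge, bath,
                               constants = physical_constants()) {
  cc <- donnan_concentrations(fixed_charge, bath)
  phi <- donnan_potential(cc, bath, constants)
  structure(list(gel_cation = unname(cc[["gel_cation"]]),
                 gel_anion = unname(cc[["gel_anion"]]),
                 potential_jump = phi),
            class = "donnan_equilibrium")
}

#' @export
print.donnan_equilibrium <- function(x, ...) {
  cat("Donnan equilibrium (gel vs bath):\n")
  cat(sprintf("  gel cation      : %.6g mol/m^3\n", x$gel_cation))
  cat(sprintf("  gel anion       : %.6g mol/m^3\n", x$gel_anion))
  cat(sprintf("  potential jump  : %.6g mV\n", 1e3 * x$potential_jump))
  invisible(x)
}

#' NaCl bath shorthand
#'
#' A symmetric monovalent bath (Na+ / Cl-) at a single molarity, with both
#' diffusivities defaulting to the value used throughout the hydrogel
#' scenarios.
#'
#' @param molarity Bath concentration of each species, mol m^-3.
#' @param diffusivity Diffusivity of both species, m^2 s^-1.
#' @param constants [physical_constants()].
#' @return A [bath_composition()].
#' @export
nacl_bath <- function(molarity = 1, diffusivity = 1e-7,
                      constants = physical_constants()) {
  bath_composition(
    list(ion_species("Na+", 1L, diffusivity, constants = constants),
         ion_species("Cl-", -1L, diffusivity, constants = constants)),
    molarity = rep(molarity, 2L))
}

check_monovalent_binary <- function(bath) {
  z <- vapply(bath$species, `[[`, numeric(1), "valence")
  if (length(z) != 2L || !setequal(z, c(-1, 1)) ||
      abs(bath$molarity[1] - bath$molarity[2]) >
        1e-12 * max(bath$molarity)) {
    stop("unsupported configuration: a symmetric monovalent binary ",
         "electrolyte (z = +1/-1, equal molarity) is required",
         call. = FALSE)
  }
  invisible(TRUE)
}
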