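#' Physical constants for electrodiffusion problems
#'
#' Bundles the constants entering the Poisson and Nernst-Planck equations.
#' Defaults are the values conventionally used for hydrogel-in-NaCl-bath
#' simulations at room temperature; note that the relative permittivity of
#' 100 refers to the aqueous gel/bath medium.
#'
#' @param faraday Faraday constant, C mol^-1.
#' @param gas_constant Universal gas constant, J mol^-1 K^-1.
#' @param temperature Absolute temperature, K.
#' @param vacuum_permittivity Vacuum permittivity, A s V^-1 m^-1.
#' @param relative_permittivity Relative permittivity of the medium
#'   (dimensionless).
#'
#' @return An object of class `physical_constants`.
#' @examples
#' pc <- physical_constants()
#' thermal_voltage(pc) # ~0.02525 V
#' @export
physical_constants <- function(faraday = 9.6487e4,
                               gas_constant = 8.3143,
                               temperature = 293,
                               vacuum_permittivity = 8.854e-12,
                               relative_permittivity = 100) {
  vals <- c(faraday = faraday, gas_constant = gas_constant,
            temperature = temperature,
            vacuum_permittivity = vacuum_permittivity,
            relative_permittivity = relative_permittivity)
  bad <- !is.finite(vals) | vals <= 0
  if (any(bad)) {
    stop("physical_constants: all constants must be finite and strictly ",
         "positive; offending: ", paste(names(vals)[bad], collapse = ", "),
         call. = FALSE)
  }
  structure(as.list(vals), class = "physical_constants")
}

#' Thermal voltage RT/F
#'
#' @param constants A [physical_constants()] object.
#' @return Thermal voltage in volts (about 25.25 mV at the defaults).
#' @export
thermal_voltage <- function(constants) {
  with(constants, gas_constant * temperature / faraday)
}

#' @export
print.physical_constants <- function(x, ...) {
  cat("Physical constants:\n")
  cat(sprintf("  F      = %.6g C/mol\n", x$faraday))
  cat(sprintf("  R      = %.6g J/(mol K)\n", x$gas_constant))
  cat(sprintf("  T      = %.6g K\n", x$temperature))
  cat(sprintf("  eps0   = %.6g A s/(V m)\n", x$vacuum_permittivity))
  cat(sprintf("  eps_r  = %.6g\n", x$relative_permittivity))
  cat(sprintf("  RT/F   = %.6g mV (thermal voltage)\n",
              1e3 * thermal_voltage(x)))
  invisible(x)
}

#' Nernst-Einstein mobility
#'
#' Converts an ionic diffusivity to an ionic mobility via the Nernst-Einstein
#' relation mu = D F / (R T).
#'
#' @param diffusivity Diffusivity D, m^2 s^-1 (non-negative).
#' @param constants A [physical_constants()] object.
#' @return Mobility in m^2 s^-1 V^-1.
#' @examples
#' nernst_einstein_mobility(1e-7, physical_constants()) # 3.9607e-6
#' @export
nernst_einstein_mobility <- function(diffusivity, constants = physical_constants()) {
  if (!is.numeric(diffusivity) || any(!is.finite(diffusivity)) ||
      any(diffusivity < 0)) {
    stop("nernst_einstein_mobility: diffusivity must be finite and >= 0",
         call. = FALSE)
  }
  diffusivity * constants$faraday /
    (constants$gas_constant * constants$temperature)
}

#' Define a mobile ionic species
#'
#' @param name Species label (e.g. `"Na+"`).
#' @param valence Signed integer charge number z in -3..3, nonzero.
#' @param diffusivity Diffusivity, m^2 s^-1, strictly positive.
#' @param mobility Optional mobility, m^2 s^-1 V^-1. When omitted it is
#'   derived from the Nernst-Einstein relation. A stored value that deviates
#'   from Nernst-Einstein by more than 1e-4 relative triggers a warning (the
#'   value is kept).
#' @param constants Constants used for the Nernst-Einstein check/derivation.
#' @return An object of class `ion_species`.
#' @export
ion_species <- function(name, valence, diffusivity, mobility = NULL,
                        constants = physical_constants()) {
  if (!is.character(name) || length(name) != 1L) {
    stop("ion_species: name must be a single string", call. = FALSE)
  }
  if (!is.numeric(valence) || length(valence) != 1L ||
      valence != round(valence) || valence == 0 || abs(valence) > 3) {
    stop("ion_species: valence must be a nonzero integer in -3..3",
         call. = FALSE)
  }
  if (!is.numeric(diffusivity) || length(diffusivity) != 1L ||
      !is.finite(diffusivity) || diffusivity <= 0) {
    stop("ion_species: diffusivity must be finite and > 0", call. = FALSE)
  }
  mu_ne <- nernst_einstein_mobility(diffusivity, constants)
  if (is.null(mobility)) {
    mobility <- mu_ne
  } else if (abs(mobility - mu_ne) > 1e-4 * mu_ne) {
    warning(sprintf(paste0(
      "ion_species '%s': stored mobility %.6g differs from the ",
      "Nernst-Einstein value %.6g by more than 1e-4 relative"),
      name, mobility, mu_ne), call. = FALSE)
  }
  structure(list(name = name, valence = as.integer(valence),
                 diffusivity = diffusivity, mobility = mobility),
            class = "ion_species")
}

#' @export
print.ion_species <- function(x, ...) {
  cat(sprintf("Ion species '%s': z = %+d, D = %.4g m^2/s, mu = %.4g m^2/(V s)\n",
              x$name, x$valence, x$diffusivity, x$mobility))
  invisible(x)
}

#' Fixed (bound) charge of the gel network
#'
#' Concentration of ionizable groups bound to the polymer network, supported
#' only on the gel region. The concentration is stored as a magnitude; every
#' equation uses the signed product `valence * concentration`.
#'
#' @param concentration Magnitude of the bound-charge concentration,
#'   mol m^-3 (>= 0).
#' @param valence Signed integer valence z_f, nonzero (negative for an
#'   anionic gel such as a carboxylated hydrogel).
#' @param region Region tag carrying the charge, normally `"gel"`.
#' @return An object of class `fixed_charge_field`.
#' @export
fixed_charge_field <- function(concentration, valence = -1L, region = "gel") {
  if (!is.numeric(concentration) || length(concentration) != 1L ||
      !is.finite(concentration) || concentration < 0) {
    stop("fixed_charge_field: concentration must be finite and >= 0",
         call. = FALSE)
  }
  if (!is.numeric(valence) || length(valence) != 1L ||
      valence != round(valence) || valence == 0) {
    stop("fixed_charge_field: valence must be a nonzero integer",
         call. = FALSE)
  }
  structure(list(concentration = concentration, valence = as.integer(valence),
                 region = region), class = "fixed_charge_field")
}

#' Bath (external solution) composition
#'
#' The electrolyte bath that surrounds the gel and supplies the Dirichlet
#' concentration data at the electrode boundaries. The bath must be
#' electroneutral: sum(z_k * c_k) = 0.
#'
#' @param species List of [ion_species()] objects (two species, z = +1/-1,
#'   for the NaCl scenarios).
#' @param molarity Numeric vector of bath concentrations (mol m^-3; note
#'   1 mM = 1 mol m^-3), one per species, all > 0.
#' @return An object of class `bath_composition`.
#' @export
bath_composition <- function(species, molarity) {
  if (inherits(species, "ion_species")) species <- list(species)
  if (!length(species) || !all(vapply(species, inherits, TRUE, "ion_species"))) {
    stop("bath_composition: species must be a list of ion_species",
         call. = FALSE)
  }
  if (length(molarity) != length(species) || any(!is.finite(molarity)) ||
      any(molarity <= 0)) {
    stop("bath_composition: molarity must be positive, one value per species",
         call. = FALSE)
  }
  z <- vapply(species, `[[`, numeric(1), "valence")
  net <- sum(z * molarity)
  if (abs(net) > 1e-12 * max(abs(z) * molarity)) {
    stop(sprintf(paste0("bath_composition: bath is not electroneutral ",
                        "(sum z_k c_k = %.6g mol/m^3)"), net), call. = FALSE)
  }
  structure(list(species = species, molarity = as.numeric(molarity)),
            class = "bath_composition")
}

#' Validate a full electrodiffusion parameter set
#'
#' Checks every invariant of the parameter types jointly: positivity of the
#' constants, species valences and diffusivities, bath electroneutrality, and
#' the Nernst-Einstein consistency of any stored mobilities (a disagreement
#' beyond 1e-4 relative warns but does not fail).
#'
#' @param constants [physical_constants()].
#' @param species List of [ion_species()].
#' @param fixed_charge [fixed_charge_field()].
#' @param bath [bath_composition()].
#' @return Invisibly, a named list of the validated components (class
#'   `pnp_parameters`).
#' @export
validate_parameters <- function(constants, species, fixed_charge, bath) {
  if (!inherits(constants, "physical_constants")) {
    stop("validate_parameters: 'constants' is not a physical_constants object",
         call. = FALSE)
  }
  if (inherits(species, "ion_species")) species <- list(species)
  if (!all(vapply(species, inherits, TRUE, "ion_species"))) {
    stop("validate_parameters: 'species' must be ion_species objects",
         call. = FALSE)
  }
  if (!inherits(fixed_charge, "fixed_charge_field")) {
    stop("validate_parameters: 'fixed_charge' is not a fixed_charge_field",
         call. = FALSE)
  }
  if (!inherits(bath, "bath_composition")) {
    stop("validate_parameters: 'bath' is not a bath_composition", call. = FALSE)
  }
  for (sp in species) {
    mu_ne <- nernst_einstein_mobility(sp$diffusivity, constants)
    if (abs(sp$mobility - mu_ne) > 1e-4 * mu_ne) {
      warning(sprintf(paste0(
        "validate_parameters: species '%s' mobility %.6g deviates from ",
        "Nernst-Einstein %.6g (kept)"), sp$name, sp$mobility, mu_ne),
        call. = FALSE)
    }
  }
  # bath_composition() already enforced electroneutrality; re-check in case
  # the object was modified after construction
  z <- vapply(bath$species, `[[`, numeric(1), "valence")
  if (abs(sum(z * bath$molarity)) > 1e-12 * max(abs(z) * bath$molarity)) {
    stop("validate_parameters: bath electroneutrality violated", call. = FALSE)
  }
  invisible(structure(list(constants = constants, species = species,
                           fixed_charge = fixed_charge, bath = bath),
                      class = "pnp_parameters"))
}
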