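#' Boundary conditions for the coupled system
#'
#' Per boundary tag, either a Dirichlet value or natural zero-flux
#' (`NULL`/`NA`) for the potential, and per species a Dirichlet
#' concentration pair `(cation, anion)` or zero-flux. Electrical scenarios
#' require at least one potential Dirichlet datum (otherwise the solver pins
#' the potential at a single node to fix the gauge).
#'
#' @param potential Named list (by boundary tag) of potentials in V, or
#'   `NULL` entries for insulated (zero normal flux) boundaries.
#' @param concentration Named list (by tag) of length-2 numeric vectors
#'   (cation, anion) in mol m^-3, or `NULL` for zero-flux.
#' @return Object of class `boundary_conditions`.
#' @export
boundary_conditions <- function(potential = list(), concentration = list()) {
  known <- c("electrode_left", "electrode_right", "insulated")
  for (nm in union(names(potential), names(concentration))) {
    if (!nm %in% known) {
      stop("boundary_conditions: unknown boundary tag '", nm, "'",
           call. = FALSE)
    }
  }
  for (nm in names(concentration)) {
    v <- concentration[[nm]]
    if (!is.null(v) && (!is.numeric(v) || length(v) != 2L)) {
      stop("boundary_conditions: concentration data must be a ",
           "(cation, anion) pair", call. = FALSE)
    }
  }
  structure(list(potential = potential, concentration = concentration),
            class = "boundary_conditions")
}

#' @export
print.boundary_conditions <- function(x, ...) {
  cat("boundary_conditions:\n")
  for (tag in c("electrode_left", "electrode_right", "insulated")) {
    p <- x$potential[[tag]]
    cc <- x$concentration[[tag]]
    cat(sprintf("  %-15s psi: %s; c: %s\n", tag,
                if (is.null(p)) "zero-flux" else sprintf("%.4g V", p),
                if (is.null(cc)) "zero-flux" else
                  paste(signif(cc, 5), collapse = "/")))
  }
  invisible(x)
}

#' Chemical-stimulation protocol
#'
#' Gel equilibration against the bath with no applied field: the ion
#' concentrations are fixed at the bath values and the potential at 0 V on
#' both electrode boundaries; the remaining boundaries are insulated. The
#' initial state is the uniform bath state.
#'
#' @param bath A [bath_composition()].
#' @return List with `boundary_conditions` and `initial_state` (a function
#'   of an [fe_space()] returning the uniform [field_state()]).
#' @export
chemical_protocol <- function(bath) {
  stopifnot(inherits(bath, "bath_composition"))
  z <- vapply(bath$species, `[[`, numeric(1), "valence")
  mol <- bath$molarity[order(-z)]
  bc <- boundary_conditions(
    potential = list(electrode_left = 0, electrode_right = 0),
    concentration = list(electrode_left = mol, electrode_right = mol))
  list(boundary_conditions = bc,
       initial_state = function(fs) {
         field_state(0, cbind(cation = rep(mol[1L], fs$ndof),
                              anion = rep(mol[2L], fs$ndof)),
                     rep(0, fs$ndof))
       },
       protocol = "chemical")
}

#' Constant-voltage electrical-stimulation protocol
#'
#' Applies a constant potential difference across the bath: the anode
#' electrode is held at `applied_voltage`, the cathode at 0 V. Ion
#' concentrations stay fixed at the bath values on both electrodes
#' (well-stirred bath). The initial state must be the chemical-equilibrium
#' solution, which this protocol declares via `initial_requirement`.
#'
#' @param bath A [bath_composition()].
#' @param applied_voltage Applied potential, V (e.g. 0.05 for 50 mV).
#' @param anode Which electrode is the anode: `"left"` (default) or
#'   `"right"`.
#' @return List with `boundary_conditions`, `initial_requirement =
#'   "chemical_equilibrium"`, and the scenario metadata.
#' @export
electrical_protocol <- function(bath, applied_voltage, anode = "left") {
  stopifnot(inherits(bath, "bath_composition"))
  if (!is.numeric(applied_voltage) || !is.finite(applied_voltage)) {
    stop("electrical_protocol: applied_voltage must be finite",
         call. = FALSE)
  }
  if (!anode %in% c("left", "right")) {
    stop("electrical_protocol: anode must be 'left' or 'right'",
         call. = FALSE)
  }
  z <- vapply(bath$species, `[[`, numeric(1), "valence")
  mol <- bath$molarity[order(-z)]
  pot <- if (anode == "left") {
    list(electrode_left = applied_voltage, electrode_right = 0)
  } else {
    list(electrode_left = 0, electrode_right = applied_voltage)
  }
  bc <- boundary_conditions(
    potential = pot,
    concentration = list(electrode_left = mol, electrode_right = mol))
  list(boundary_conditions = bc,
       initial_requirement = "chemical_equilibrium",
       applied_voltage = applied_voltage, anode = anode,
       cathode = setdiff(c("left", "right"), anode),
       protocol = "electrical")
}
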