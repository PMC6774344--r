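# JSON configuration layer: schema validation, presets, scenario runner.

config_known_keys <- list(
  top = c("name", "geometry", "constants", "species", "fixed_charge",
          "bath", "protocol", "solver", "output", "seed"),
  geometry = c("dimension", "bath_extent", "gel_shape", "gel_extent",
               "gel_center", "refinement_band", "base_resolution",
               "refined_resolution"),
  constants = c("faraday", "gas_constant", "temperature",
                "vacuum_permittivity", "relative_permittivity"),
  species = c("name", "valence", "diffusivity", "mobility"),
  fixed_charge = c("concentration", "valence", "region"),
  bath = c("molarity"),
  protocol = c("type", "applied_mV", "anode_side"),
  solver = c("order", "dt", "t_end", "newton_rel_tol", "newton_abs_tol",
             "newton_step_tol", "linear_solver",
             "max_newton_iterations", "damping", "nondimensionalize",
             "strategy", "steady_tolerance", "stop_at_steady",
             "store_every", "max_dt_halvings"),
  output = c("dir", "vtk", "profile", "checkpoint"))

check_keys <- function(block, known, path) {
  unknown <- setdiff(names(block), known)
  if (length(unknown)) {
    stop(sprintf("load_config: unknown key '%s' under '%s'", unknown[1L],
                 path), call. = FALSE)
  }
  invisible(TRUE)
}

require_key <- function(block, key, path) {
  if (is.null(block[[key]])) {
    stop(sprintf("load_config: required key '%s' missing under '%s'", key,
                 path), call. = FALSE)
  }
  block[[key]]
}

#' Load and validate a run configuration
#'
#' Reads a JSON configuration describing geometry, physical constants,
#' species, fixed charge, bath, stimulation protocol and solver settings;
#' fills defaults, rejects unknown keys (typo safety) and constructs the
#' validated parameter objects.
#'
#' @param path Path to a JSON configuration file, or the name of a bundled
#'   preset (see [preset_names()]).
#' @return Object of class `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    preset <- preset_path(path)
    if (is.na(preset)) {
      stop("load_config: no such file or preset: ", path, call. = FALSE)
    }
    path <- preset
  }
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE,
                            simplifyMatrix = FALSE)
  check_keys(raw, config_known_keys$top, "(top level)")

  geo <- require_key(raw, "geometry", "(top level)")
  check_keys(geo, config_known_keys$geometry, "geometry")
  geometry <- geometry_spec(
    dimension = require_key(geo, "dimension", "geometry"),
    bath_extent = require_key(geo, "bath_extent", "geometry"),
    gel_shape = require_key(geo, "gel_shape", "geometry"),
    gel_extent = require_key(geo, "gel_extent", "geometry"),
    gel_center = geo$gel_center,
    refinement_band = require_key(geo, "refinement_band", "geometry"),
    base_resolution = require_key(geo, "base_resolution", "geometry"),
    refined_resolution = require_key(geo, "refined_resolution", "geometry"))

  cns <- raw$constants
  check_keys(cns, config_known_keys$constants, "constants")
  constants <- do.call(physical_constants, as.list(cns))

  sp_raw <- require_key(raw, "species", "(top level)")
  if (!length(sp_raw)) {
    stop("load_config: 'species' must list at least one species",
         call. = FALSE)
  }
  species <- lapply(sp_raw, function(s) {
    check_keys(s, config_known_keys$species, "species[]")
    ion_species(require_key(s, "name", "species[]"),
                require_key(s, "valence", "species[]"),
                require_key(s, "diffusivity", "species[]"),
                mobility = s$mobility, constants = constants)
  })

  fc <- require_key(raw, "fixed_charge", "(top level)")
  check_keys(fc, config_known_keys$fixed_charge, "fixed_charge")
  fixed_charge <- fixed_charge_field(
    require_key(fc, "concentration", "fixed_charge"),
    require_key(fc, "valence", "fixed_charge"),
    region = if (is.null(fc$region)) "gel" else fc$region)

  bt <- require_key(raw, "bath", "(top level)")
  check_keys(bt, config_known_keys$bath, "bath")
  mol <- rep_len(as.numeric(require_key(bt, "molarity", "bath")),
                 length(species))
  bath <- bath_composition(species, mol)

  params <- validate_parameters(constants, species, fixed_charge, bath)

  pr <- raw$protocol
  if (is.null(pr)) pr <- list(type = "chemical")
  check_keys(pr, config_known_keys$protocol, "protocol")
  if (!pr$type %in% c("chemical", "electrical")) {
    stop("load_config: protocol type must be 'chemical' or 'electrical'",
         call. = FALSE)
  }
  protocol <- list(type = pr$type,
                   applied_mV = if (is.null(pr$applied_mV)) 0 else
                     pr$applied_mV,
                   anode_side = if (is.null(pr$anode_side)) "left" else
                     pr$anode_side)

  sv <- raw$solver
  check_keys(sv, config_known_keys$solver, "solver")
  solver <- do.call(solver_options, as.list(sv))

  out <- raw$output
  check_keys(out, config_known_keys$output, "output")

  structure(list(name = if (is.null(raw$name)) "run" else raw$name,
                 geometry = geometry, params = params, protocol = protocol,
                 solver = solver, output = out,
                 seed = if (is.null(raw$seed)) 1L else as.integer(raw$seed)),
            class = "run_config")
}

#' Normalized list form of a configuration (for dumping)
#'
#' `load_config(write_config(cfg, f))` is idempotent: dumping and reloading
#' reproduces the same normalized configuration.
#'
#' @param config A `run_config`.
#' @return A plain list mirroring the JSON schema with defaults filled.
#' @export
config_as_list <- function(config) {
  g <- config$geometry
  p <- config$params
  sp <- lapply(p$species, function(s) {
    list(name = s$name, valence = s$valence, diffusivity = s$diffusivity,
         mobility = s$mobility)
  })
  sv <- config$solver
  list(name = config$name,
       geometry = list(dimension = g$dimension,
                       bath_extent = g$bath_extent,
                       gel_shape = g$gel_shape, gel_extent = g$gel_extent,
                       gel_center = g$gel_center,
                       refinement_band = g$refinement_band,
                       base_resolution = g$base_resolution,
                       refined_resolution = g$refined_resolution),
       constants = unclass(p$constants),
       species = sp,
       fixed_charge = list(concentration = p$fixed_charge$concentration,
                           valence = p$fixed_charge$valence,
                           region = p$fixed_charge$region),
       bath = list(molarity = p$bath$molarity),
       protocol = config$protocol,
       solver = Filter(Negate(is.null), unclass(sv)),
       output = config$output,
       seed = config$seed)
}

#' Write a configuration as JSON
#'
#' @param config A `run_config`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(config_as_list(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("run_config '%s': %s protocol, %dD %s gel\n", x$name,
              x$protocol$type, x$geometry$dimension, x$geometry$gel_shape))
  invisible(x)
}

#' Bundled preset configurations
#'
#' Presets encode the standard scenarios: `paper_table1_chemical` and
#' `paper_table1_electrical` at bench scale (0.015 m bath; expressible but
#' not resolvable on a desk machine), their `_scaled` variants shrunk 1e4x
#' so Debye layers are mesh-resolved, and `circular_scaffold_scaled` (2D
#' disc scaffold).
#'
#' @return Character vector of preset names.
#' @export
preset_names <- function() {
  sub("\\.json$", "",
      list.files(system.file("extdata", "presets", package = "pnpgel"),
                 pattern = "\\.json$"))
}

preset_path <- function(name) {
  p <- system.file("extdata", "presets", paste0(name, ".json"),
                   package = "pnpgel")
  if (identical(p, "")) NA_character_ else p
}

#' Run a full simulation scenario
#'
#' Orchestrates mesh generation, protocol translation, the stationary or
#' transient solve, and postprocessing. For the electrical protocol the
#' chemical-equilibrium solution is computed first and used as the initial
#' condition. Identical configurations produce identical summaries (no
#' unseeded randomness, no timestamps).
#'
#' @param config A `run_config` from [load_config()], or a preset name.
#' @param output_dir Optional directory for artifacts (summary JSON, VTK
#'   fields, centre-line profile CSV, final-state checkpoint); overrides
#'   `config$output$dir`.
#' @param quiet Suppress progress messages.
#' @return Object of class `scenario_result`: `summary` (list), `state`
#'   (final [field_state()]), `result` (transient result or `NULL`),
#'   `fe_space`, `mesh`, `config`.
#' @export
run_scenario <- function(config, output_dir = NULL, quiet = FALSE) {
  if (is.character(config)) config <- load_config(config)
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  say <- function(...) if (!quiet) message(sprintf(...))
  params <- config$params
  say("[mesh] building %s mesh", config$geometry$gel_shape)
  mesh <- build_mesh(config$geometry)
  fs <- fe_space(mesh, config$solver$order)
  say("[mesh] %d cells, %d scalar DOFs", nrow(mesh$cells), fs$ndof)

  say("[solve] chemical equilibrium (stationary)")
  chem <- solve_chemical_equilibrium(params, fs, options = config$solver)
  result <- NULL
  final <- chem
  if (config$protocol$type == "electrical") {
    proto <- electrical_protocol(params$bath,
                                 config$protocol$applied_mV * 1e-3,
                                 anode = config$protocol$anode_side)
    say("[solve] electrical stimulation: %g mV, anode %s",
        config$protocol$applied_mV, config$protocol$anode_side)
    result <- run_transient(chem, params, fs, proto$boundary_conditions,
                            config$solver)
    final <- result$states[[length(result$states)]]
  }

  summary <- scenario_summary(config, fs, chem, final, result)
  out <- structure(list(summary = summary, state = final, result = result,
                        fe_space = fs, mesh = mesh, config = config),
                   class = "scenario_result")
  dir <- if (!is.null(output_dir)) output_dir else config$output$dir
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    jsonlite::write_json(summary, file.path(dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (isTRUE(config$output$vtk) || is.null(config$output$vtk)) {
      export_fields(if (is.null(result)) final else result, fs,
                    file.path(dir, "fields"))
    }
    if (isTRUE(config$output$profile) || is.null(config$output$profile)) {
      prof <- extract_line_profile(final, fs)
      write_profile_csv(prof, file.path(dir, "profile_center.csv"))
    }
    if (isTRUE(config$output$checkpoint) ||
        is.null(config$output$checkpoint)) {
      write_checkpoint(final, file.path(dir, "state_final.txt"))
    }
    say("[output] written to %s", dir)
  }
  out
}

scenario_summary <- function(config, fs, chem, final, result) {
  params <- config$params
  g <- config$geometry
  ctr <- matrix(g$gel_center, ncol = g$dimension)
  # bath probe halfway between the left electrode and the gel
  probe_x <- (g$gel_center[1L] - g$gel_extent) / 2
  probe <- ctr
  probe[1L] <- probe_x
  vc <- evaluate_state(final, fs, ctr)
  vp <- evaluate_state(final, fs, probe)
  don <- donnan_equilibrium(params$fixed_charge, params$bath,
                            params$constants)
  list(
    name = config$name,
    protocol = config$protocol$type,
    n_cells = nrow(fs$mesh$cells),
    n_dofs = fs$ndof,
    element_order = fs$order,
    gel_center = list(cation_mol_m3 = unname(vc[1L, "cation"]),
                      anion_mol_m3 = unname(vc[1L, "anion"]),
                      potential_V = unname(vc[1L, "potential"])),
    bath_probe = list(cation_mol_m3 = unname(vp[1L, "cation"]),
                      anion_mol_m3 = unname(vp[1L, "anion"]),
                      potential_V = unname(vp[1L, "potential"])),
    potential_jump_V = unname(vc[1L, "potential"] - vp[1L, "potential"]),
    donnan_oracle = list(cation_mol_m3 = don$gel_cation,
                         anion_mol_m3 = don$gel_anion,
                         potential_V = don$potential_jump),
    newton = if (is.null(result)) {
      list(iterations = attr(chem, "newton")$iterations)
    } else {
      list(steps = length(result$newton_iterations),
           total_iterations = sum(result$newton_iterations),
           max_iterations_per_step = max(result$newton_iterations))
    },
    steady_state_time_s = if (is.null(result)) NULL else
      result$steady_state_time,
    end_time_s = if (is.null(result)) NULL else
      result$times[length(result$times)])
}

#' @export
print.scenario_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("scenario_result '%s' (%s): %d DOFs\n", s$name, s$protocol,
              s$n_dofs))
  cat(sprintf("  gel centre: c+ = %.5g, c- = %.5g mol/m^3, psi = %.5g mV\n",
              s$gel_center$cation_mol_m3, s$gel_center$anion_mol_m3,
              1e3 * s$gel_center$potential_V))
  cat(sprintf("  Donnan oracle: c+ = %.5g, c- = %.5g mol/m^3, dphi = %.5g mV\n",
              s$donnan_oracle$cation_mol_m3, s$donnan_oracle$anion_mol_m3,
              1e3 * s$donnan_oracle$potential_V))
  if (!is.null(s$steady_state_time_s)) {
    cat(sprintf("  steady state at t = %.5g s\n", s$steady_state_time_s))
  }
  invisible(x)
}
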