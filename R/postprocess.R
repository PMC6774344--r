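# Field evaluation, line profiles, steady-state detection, diagnostics and
# export.

# Locate points in the mesh and return per-point cell index and reference
# coordinates; points outside the domain give NA.
locate_points <- function(fs, pts) {
  mesh <- fs$mesh
  pts <- matrix(pts, ncol = fs$dim)
  npts <- nrow(pts)
  cell <- rep(NA_integer_, npts)
  ref <- matrix(NA_real_, npts, fs$dim)
  cl <- mesh$cells
  x <- mesh$nodes
  tol <- 1e-10 * max(abs(x))
  if (fs$dim == 1L) {
    xa <- x[cl[, 1L], 1L]; xb <- x[cl[, 2L], 1L]
    lo <- pmin(xa, xb); hi <- pmax(xa, xb)
    for (p in seq_len(npts)) {
      px <- pts[p, 1L]
      k <- which(px >= lo - tol & px <= hi + tol)
      if (length(k)) {
        k <- k[1L]
        cell[p] <- k
        ref[p, 1L] <- (px - xa[k]) / (xb[k] - xa[k])
      }
    }
  } else {
    v1 <- x[cl[, 1L], , drop = FALSE]
    d21 <- x[cl[, 2L], , drop = FALSE] - v1
    d31 <- x[cl[, 3L], , drop = FALSE] - v1
    det <- d21[, 1L] * d31[, 2L] - d31[, 1L] * d21[, 2L]
    rtol <- 1e-10
    for (p in seq_len(npts)) {
      rx <- pts[p, 1L] - v1[, 1L]
      ry <- pts[p, 2L] - v1[, 2L]
      xi <- (rx * d31[, 2L] - ry * d31[, 1L]) / det
      eta <- (ry * d21[, 1L] - rx * d21[, 2L]) / det
      k <- which(xi >= -rtol & eta >= -rtol & xi + eta <= 1 + rtol)
      if (length(k)) {
        k <- k[1L]
        cell[p] <- k
        ref[p, ] <- c(xi[k], eta[k])
      }
    }
  }
  list(cell = cell, ref = ref)
}

# Evaluate the three fields of a state at arbitrary physical points using
# the discretization's own basis (no extrapolation).
evaluate_state <- function(state, fs, pts) {
  pts <- matrix(pts, ncol = fs$dim)
  loc <- locate_points(fs, pts)
  if (anyNA(loc$cell)) {
    bad <- which(is.na(loc$cell))[1L]
    stop(sprintf(paste0("evaluate_state: point (%s) lies outside the ",
                        "domain; extrapolation is not performed"),
                 paste(signif(pts[bad, ], 6), collapse = ", ")),
         call. = FALSE)
  }
  expo <- mono_exponents(fs$elem, fs$order)
  nodes <- ref_nodes(fs$elem, fs$order)
  Vinv <- solve(mono_eval(expo, nodes))
  Bpts <- mono_eval(expo, matrix(loc$ref, ncol = fs$dim)) %*% Vinv
  out <- matrix(0, nrow(pts), 3L)
  colnames(out) <- c("cation", "anion", "potential")
  for (p in seq_len(nrow(pts))) {
    dofs <- fs$cell_dofs[loc$cell[p], ]
    phi <- Bpts[p, ]
    out[p, 1L] <- sum(state$concentrations[dofs, 1L] * phi)
    out[p, 2L] <- sum(state$concentrations[dofs, 2L] * phi)
    out[p, 3L] <- sum(state$potential[dofs] * phi)
  }
  out
}

#' Extract a 1D line profile through the fields
#'
#' Samples concentrations and potential along an axis-parallel line using
#' the finite-element basis itself (polynomials up to the element order are
#' reproduced exactly). Sample points outside the domain raise an error
#' rather than being extrapolated.
#'
#' @param state A [field_state()].
#' @param fs The [fe_space()] the state lives on.
#' @param axis `"x"` (default) or `"y"`: the coordinate that varies.
#' @param offset Fixed value of the other coordinate (2D only; e.g. the
#'   mid-bath height 0.0075 m).
#' @param range Length-2 sampling interval along the axis; defaults to the
#'   full bath extent.
#' @param n Number of samples (>= 2).
#' @return A `line_profile`: data frame with columns `coord` (m), `cation`,
#'   `anion` (mol m^-3) and `potential` (V).
#' @export
extract_line_profile <- function(state, fs, axis = c("x", "y"),
                                 offset = NULL, range = NULL, n = 200L) {
  axis <- match.arg(axis)
  if (n < 2L) stop("extract_line_profile: need at least 2 samples",
                   call. = FALSE)
  mesh <- fs$mesh
  ext <- apply(mesh$nodes, 2L, range)
  ax <- if (axis == "x") 1L else 2L
  if (fs$dim == 1L && axis != "x") {
    stop("extract_line_profile: 1D meshes only have an x axis",
         call. = FALSE)
  }
  if (is.null(range)) range <- ext[, ax]
  coord <- seq(range[1L], range[2L], length.out = n)
  if (fs$dim == 1L) {
    pts <- matrix(coord, ncol = 1L)
  } else {
    if (is.null(offset)) offset <- mean(ext[, 3L - ax])
    pts <- if (ax == 1L) cbind(coord, offset) else cbind(offset, coord)
  }
  vals <- evaluate_state(state, fs, pts)
  out <- data.frame(coord = coord, cation = vals[, 1L], anion = vals[, 2L],
                    potential = vals[, 3L])
  attr(out, "axis") <- axis
  attr(out, "offset") <- if (fs$dim == 2L) offset else NA_real_
  class(out) <- c("line_profile", class(out))
  out
}

#' Detect the steady state of a transient run
#'
#' Finds the earliest time `t*` such that for every later pair of
#' consecutive stored states the relative inter-step change rate
#' `max_field( max|delta| / max|field| ) / dt` stays below `tolerance`.
#'
#' @param result A [run_transient()] result.
#' @param tolerance Relative change rate threshold, s^-1 (default 1e-8).
#' @return The steady time in seconds, or `NA` if the criterion is never
#'   met. Larger tolerances never give a later time.
#' @export
detect_steady_state <- function(result, tolerance = 1e-8) {
  stopifnot(inherits(result, "transient_result"))
  m <- length(result$states)
  if (m < 2L) stop("detect_steady_state: need at least 2 states",
                   call. = FALSE)
  rates <- numeric(m - 1L)
  for (s in seq_len(m - 1L)) {
    s1 <- result$states[[s]]; s2 <- result$states[[s + 1L]]
    dt <- result$times[s + 1L] - result$times[s]
    fields <- list(cbind(s1$concentrations[, 1L], s2$concentrations[, 1L]),
                   cbind(s1$concentrations[, 2L], s2$concentrations[, 2L]),
                   cbind(s1$potential, s2$potential))
    rel <- vapply(fields, function(f) {
      max(abs(f[, 2L] - f[, 1L])) /
        max(max(abs(f[, 2L])), .Machine$double.eps)
    }, numeric(1))
    rates[s] <- max(rel) / dt
  }
  ok <- rates <= tolerance
  # earliest k with all pairs from k onwards quiet
  idx <- which(rev(cumprod(rev(ok))) == 1)
  if (!length(idx)) return(NA_real_)
  result$times[idx[1L]]
}

#' Deviation from electroneutrality
#'
#' Computes the net charge concentration `z+ c+ + z- c- + z_f c_f` per DOF
#' (the fixed charge counted on DOFs interior to the gel) and its norms.
#' Because mobile ions screen the fixed charge everywhere except in thin
#' space-charge layers, the metric is also reported with DOFs within
#' `exclude_debye` Debye lengths of the gel-solution interface masked out.
#'
#' @param state A [field_state()].
#' @param params A [validate_parameters()] result.
#' @param fs The [fe_space()] of the state.
#' @param exclude_debye Width of the interface exclusion zone in Debye
#'   lengths (default 5).
#' @return List with `field` (mol m^-3 per DOF), `norm_inf`, `norm_l2`,
#'   `interior_norm_inf` (interface zone excluded), `mask` (logical,
#'   TRUE = kept), and `debye_length` (m).
#' @export
electroneutrality_metric <- function(state, params, fs, exclude_debye = 5) {
  stopifnot(inherits(state, "field_state"),
            inherits(params, "pnp_parameters"))
  z <- vapply(params$bath$species, `[[`, numeric(1), "valence")
  z <- z[order(-z)]
  zc_f <- params$fixed_charge$valence * params$fixed_charge$concentration
  cf_dof <- ifelse(dof_in_gel(fs), zc_f, 0)
  field <- z[1L] * state$concentrations[, 1L] +
    z[2L] * state$concentrations[, 2L] + cf_dof
  cn <- params$constants
  eps <- cn$relative_permittivity * cn$vacuum_permittivity
  debye <- sqrt(eps * cn$gas_constant * cn$temperature /
                (2 * cn$faraday^2 * params$bath$molarity[1L]))
  ifc <- interface_dofs(fs)
  if (length(ifc)) {
    dmin <- rep(Inf, fs$ndof)
    xi <- fs$dof_coords[ifc, , drop = FALSE]
    for (k in seq_along(ifc)) {
      dd <- sqrt(rowSums((fs$dof_coords -
                          matrix(xi[k, ], fs$ndof, fs$dim,
                                 byrow = TRUE))^2))
      dmin <- pmin(dmin, dd)
    }
    mask <- dmin > exclude_debye * debye
  } else {
    mask <- rep(TRUE, fs$ndof)
  }
  list(field = field,
       norm_inf = max(abs(field)),
       norm_l2 = sqrt(sum(field^2) / fs$ndof),
       interior_norm_inf = if (any(mask)) max(abs(field[mask])) else NA_real_,
       mask = mask, debye_length = debye)
}

#' Per-step diagnostics of a transient run
#'
#' @param result A [run_transient()] result.
#' @param params A [validate_parameters()] result.
#' @return A `diagnostic_series` data frame: time, total ion content per
#'   species (mol, via the assembly quadrature), relative inter-step change,
#'   electroneutrality interior norm and minimum concentration.
#' @export
diagnostic_series <- function(result, params) {
  stopifnot(inherits(result, "transient_result"))
  fs <- result$fe_space
  m <- length(result$states)
  total_cat <- total_an <- en <- minc <- numeric(m)
  for (s in seq_len(m)) {
    st <- result$states[[s]]
    total_cat[s] <- integrate_field(fs, st$concentrations[, 1L])
    total_an[s] <- integrate_field(fs, st$concentrations[, 2L])
    en[s] <- electroneutrality_metric(st, params, fs)$interior_norm_inf
    minc[s] <- min(st$concentrations)
  }
  change <- c(NA_real_, vapply(seq_len(m - 1L), function(s) {
    a <- result$states[[s]]; b <- result$states[[s + 1L]]
    max(abs(b$concentrations - a$concentrations)) /
      max(abs(b$concentrations))
  }, numeric(1)))
  out <- data.frame(time = result$times, total_cation = total_cat,
                    total_anion = total_an, relative_change = change,
                    electroneutrality_interior = en,
                    min_concentration = minc)
  class(out) <- c("diagnostic_series", class(out))
  out
}

# --- export ---------------------------------------------------------------

fmt_num <- function(x) sprintf("%.10e", x)

write_vtk_state <- function(state, mesh, path) {
  nv <- nrow(mesh$nodes)
  coords <- cbind(mesh$nodes, matrix(0, nv, 3L - ncol(mesh$nodes)))
  ne <- nrow(mesh$cells)
  npc <- ncol(mesh$cells)
  vtk_type <- if (mesh$dim == 1L) 3L else 5L # line / triangle
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "pnpgel fields (cation, anion, potential)",
               "ASCII", "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", nv)), con)
  writeLines(paste(fmt_num(coords[, 1L]), fmt_num(coords[, 2L]),
                   fmt_num(coords[, 3L])), con)
  writeLines(sprintf("CELLS %d %d", ne, ne * (npc + 1L)), con)
  writeLines(do.call(paste, c(list(npc),
                              lapply(seq_len(npc),
                                     function(k) mesh$cells[, k] - 1L))),
             con)
  writeLines(sprintf("CELL_TYPES %d", ne), con)
  writeLines(as.character(rep(vtk_type, ne)), con)
  writeLines(sprintf("POINT_DATA %d", nv), con)
  for (fld in c("cation", "anion", "potential")) {
    vals <- if (fld == "potential") state$potential[seq_len(nv)] else
      state$concentrations[seq_len(nv), fld]
    writeLines(c(sprintf("SCALARS %s double 1", fld),
                 "LOOKUP_TABLE default", fmt_num(vals)), con)
  }
  invisible(path)
}

#' Export fields for visualization
#'
#' Writes a state (or every stored state of a transient result) as legacy
#' ASCII VTK unstructured-grid files with point data `cation`, `anion` and
#' `potential` at the mesh vertices, plus a plain-text index listing file
#' names and times. Output is deterministic: identical inputs give
#' byte-identical files (no timestamps inside the data).
#'
#' @param x A [field_state()] or [run_transient()] result.
#' @param fs The [fe_space()] (or [pnp_mesh()]) the fields live on.
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix (default `"field"`).
#' @return Invisibly, the written file paths.
#' @export
export_fields <- function(x, fs, dir, prefix = "field") {
  mesh <- if (inherits(fs, "fe_space")) fs$mesh else fs
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE)) {
    stop("export_fields: cannot create directory: ", dir, call. = FALSE)
  }
  states <- if (inherits(x, "transient_result")) x$states else list(x)
  times <- if (inherits(x, "transient_result")) x$times else x$time
  paths <- character(length(states))
  for (s in seq_along(states)) {
    paths[s] <- file.path(dir, sprintf("%s_%04d.vtk", prefix, s - 1L))
    write_vtk_state(states[[s]], mesh, paths[s])
  }
  idx <- file.path(dir, sprintf("%s_index.txt", prefix))
  writeLines(c("# file time_s",
               paste(basename(paths), fmt_num(times))), idx)
  invisible(c(paths, idx))
}

#' Write a line profile as CSV
#'
#' Plain tabular text with a header naming fields and units; deterministic
#' byte-identical output for identical input.
#'
#' @param profile A [extract_line_profile()] result.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_profile_csv <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# pnpgel line profile",
               sprintf("# axis=%s offset_m=%s", attr(profile, "axis"),
                       fmt_num(attr(profile, "offset"))),
               "coord_m,cation_mol_m3,anion_mol_m3,potential_V"), con)
  writeLines(paste(fmt_num(profile$coord), fmt_num(profile$cation),
                   fmt_num(profile$anion), fmt_num(profile$potential),
                   sep = ","), con)
  invisible(path)
}

#' Read back a profile CSV written by [write_profile_csv()]
#'
#' @param path CSV path.
#' @return Data frame with the profile columns.
#' @export
read_profile_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  names(df) <- c("coord", "cation", "anion", "potential")
  df
}

#' Write a diagnostics table as CSV
#'
#' @param diag A [diagnostic_series()] result.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_diagnostics_csv <- function(diag, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# pnpgel transient diagnostics",
               paste0("# time_s,total_cation_mol,total_anion_mol,",
                      "relative_change,electroneutrality_mol_m3,",
                      "min_concentration_mol_m3")), con)
  writeLines(paste(fmt_num(diag$time), fmt_num(diag$total_cation),
                   fmt_num(diag$total_anion),
                   fmt_num(diag$relative_change),
                   fmt_num(diag$electroneutrality_interior),
                   fmt_num(diag$min_concentration), sep = ","), con)
  invisible(path)
}
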