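test_that("line profiles reproduce constants and linear fields exactly", {
  fs <- fe_space(build_interval_mesh(scaled_1d_geometry(refined = 4e-8)), 2)
  x <- fs$dof_coords[, 1]
  st <- field_state(0, cbind(cation = rep(2, fs$ndof),
                             anion = rep(2, fs$ndof)),
                    0.01 + 3e3 * x) # linear potential
  pr <- extract_line_profile(st, fs, n = 57)
  expect_equal(pr$cation, rep(2, 57))
  expect_equal(pr$potential, 0.01 + 3e3 * pr$coord, tolerance = 1e-12)
  expect_true(all(diff(pr$coord) > 0))
  # profile of a scaled field is the scaled profile
  st2 <- field_state(0, 3 * st$concentrations, 3 * st$potential)
  pr2 <- extract_line_profile(st2, fs, n = 57)
  expect_equal(pr2$cation, 3 * pr$cation)
  expect_equal(pr2$potential, 3 * pr$potential)
  # sampling outside the domain is refused
  expect_error(extract_line_profile(st, fs, range = c(0, 2e-6)),
               "outside the domain")
})

test_that("the chemical-equilibrium profile shows a Donnan plateau", {
  cs <- cached_chemical_solution()
  don <- donnan_equilibrium(cs$params$fixed_charge, cs$params$bath)
  pr <- extract_line_profile(cs$state, cs$fs, range = c(6.5e-7, 8.5e-7),
                             n = 41)
  expect_lt(max(abs(pr$cation - don$gel_cation)), 5e-3 * don$gel_cation)
  expect_lt(diff(range(pr$cation)), 1e-3)
})

test_that("2D profiles follow the interpolated fields", {
  spec <- geometry_spec(2, 1.5e-6, "square", 2.5e-7,
                        refinement_band = 1.5e-7,
                        base_resolution = 2e-7, refined_resolution = 1e-7)
  fs <- fe_space(build_square_gel_mesh(spec), 2)
  st <- field_state(0, cbind(cation = rep(1, fs$ndof),
                             anion = rep(1, fs$ndof)),
                    fs$dof_coords[, 1] * 1e3 + fs$dof_coords[, 2] * 2e3)
  pr <- extract_line_profile(st, fs, axis = "x", offset = 7.5e-7, n = 33)
  expect_equal(pr$potential, pr$coord * 1e3 + 7.5e-7 * 2e3,
               tolerance = 1e-10)
})

test_that("steady-state detection finds the quiet tail", {
  mk_state <- function(v) {
    field_state(0, cbind(cation = rep(v, 4), anion = rep(v, 4)), rep(0, 4))
  }
  mk_result <- function(vals, dt = 1) {
    structure(list(states = lapply(vals, mk_state),
                   times = dt * (seq_along(vals) - 1)),
              class = "transient_result")
  }
  # constant sequence: steady from the first time
  expect_equal(detect_steady_state(mk_result(rep(2, 5)), 1e-8), 0)
  # strict oscillation never settles
  expect_true(is.na(detect_steady_state(mk_result(rep(c(1, 2), 4)), 1e-3)))
  # decaying sequence settles once changes drop below tolerance
  vals <- 1 + 2^-(0:12)
  r <- mk_result(vals)
  t_small <- detect_steady_state(r, 1e-3)
  t_large <- detect_steady_state(r, 1e-1)
  expect_true(t_large <= t_small) # monotone in tolerance
  expect_error(detect_steady_state(mk_result(1), 1), "at least 2")
})

test_that("electroneutrality metric isolates the unscreened fixed charge", {
  params <- table1_params()
  fs <- fe_space(build_interval_mesh(scaled_1d_geometry(refined = 1.6e-8)), 2)
  # uniform c+ = c-: the net charge equals z_f c_f on gel-interior DOFs
  st <- pnpgel:::uniform_bath_state(fs, params)
  m <- electroneutrality_metric(st, params, fs, exclude_debye = 0)
  gel_dofs <- pnpgel:::dof_in_gel(fs)
  expect_true(all(m$field[gel_dofs] == -2))
  expect_true(all(m$field[!gel_dofs] == 0))
  expect_equal(m$debye_length, 1.0764e-8, tolerance = 1e-4)
  # the converged equilibrium is electroneutral away from the interface
  cs <- cached_chemical_solution()
  m2 <- electroneutrality_metric(cs$state, cs$params, cs$fs,
                                 exclude_debye = 5)
  expect_lt(m2$interior_norm_inf, 0.01)
  expect_gt(m2$norm_inf, m2$interior_norm_inf) # layers do carry charge
})

test_that("profile CSV, checkpoint and VTK exports round-trip", {
  cs <- cached_chemical_solution()
  pr <- extract_line_profile(cs$state, cs$fs, n = 40)
  f <- tempfile(fileext = ".csv")
  write_profile_csv(pr, f)
  back <- read_profile_csv(f)
  expect_equal(back$cation, pr$cation, tolerance = 1e-9)
  expect_equal(back$potential, pr$potential, tolerance = 1e-9)
  # deterministic bytes on rewrite
  f2 <- tempfile(fileext = ".csv")
  write_profile_csv(pr, f2)
  expect_identical(readLines(f), readLines(f2))
  unlink(c(f, f2))

  cp <- tempfile(fileext = ".txt")
  write_checkpoint(cs$state, cp)
  st2 <- read_checkpoint(cp)
  expect_identical(st2$concentrations[, 1], unname(cs$state$concentrations[, 1]))
  expect_identical(st2$potential, cs$state$potential)
  unlink(cp)

  dir <- tempfile()
  paths <- export_fields(cs$state, cs$fs, dir)
  vtk <- grep("\\.vtk$", paths, value = TRUE)
  expect_length(vtk, 1)
  txt <- readLines(vtk)
  # all three fields present
  for (fld in c("cation", "anion", "potential")) {
    expect_true(any(grepl(paste0("SCALARS ", fld), txt)))
  }
  # cell count in the header matches the mesh (independent parse)
  cells_line <- grep("^CELLS ", txt, value = TRUE)
  expect_equal(as.integer(strsplit(cells_line, " ")[[1]][2]),
               nrow(cs$fs$mesh$cells))
  unlink(dir, recursive = TRUE)
})

test_that("transient diagnostics align with the stored states", {
  cs <- cached_chemical_solution()
  proto <- electrical_protocol(cs$params$bath, 0.05)
  res <- run_transient(cs$state, cs$params, cs$fs,
                       proto$boundary_conditions,
                       solver_options(dt = 8e-7, t_end = 4e-6,
                                      steady_tolerance = NULL))
  dg <- diagnostic_series(res, cs$params)
  expect_equal(nrow(dg), length(res$states))
  expect_true(all(diff(dg$time) > 0))
  expect_true(all(is.finite(dg$total_cation)))
  f <- tempfile(fileext = ".csv")
  write_diagnostics_csv(dg, f)
  expect_true(any(grepl("total_cation", readLines(f))))
  unlink(f)
})
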