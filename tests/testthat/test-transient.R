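# Backward-Euler transient behaviour: fixed points, conservation,
# diffusion oracle, polarity symmetry, first-order accuracy.

test_that("pure diffusion matches the dense backward-Euler oracle", {
  params <- table1_params(cf = 0)
  mesh <- uniform_1d_mesh(2.5e-8)
  fs <- fe_space(mesh, 1)
  x <- fs$dof_coords[, 1]
  L <- 1.5e-6
  c0 <- 1 + 0.5 * cos(pi * x / L) # no-flux compatible initial bump
  init <- field_state(0, cbind(cation = c0, anion = c0), rep(0, fs$ndof))
  bc <- boundary_conditions(potential = list(electrode_left = 0,
                                             electrode_right = 0))
  dt <- 2e-6
  nsteps <- 5
  res <- run_transient(init, params, fs, bc,
                       solver_options(dt = dt, t_end = nsteps * dt,
                                      order = 1L,
                                      steady_tolerance = NULL))
  fin <- res$states[[length(res$states)]]
  oracle <- fd_heat_be(c0, 2.5e-8, 1e-7, dt, nsteps)
  expect_lt(max(abs(fin$concentrations[, 1] - oracle)), 1e-8)
  expect_lt(max(abs(fin$concentrations[, 2] - oracle)), 1e-8)
  # equal-diffusivity symmetric electrolyte develops no potential
  expect_lt(max(abs(fin$potential)), 1e-10)
})

test_that("total ion content is conserved with no-flux ion boundaries", {
  cs <- cached_chemical_solution()
  params <- cs$params
  fs <- cs$fs
  # electroneutral multiplicative perturbation of the equilibrium
  bump <- 1 + 0.1 * cos(pi * fs$dof_coords[, 1] / 1.5e-6)
  init <- field_state(0, cs$state$concentrations * bump, cs$state$potential)
  bc <- boundary_conditions(potential = list(electrode_left = 0,
                                             electrode_right = 0))
  res <- run_transient(init, params, fs, bc,
                       solver_options(dt = 5e-7, t_end = 5e-6,
                                      steady_tolerance = NULL))
  dg <- diagnostic_series(res, params)
  for (col in c("total_cation", "total_anion")) {
    drift <- abs(dg[[col]] - dg[[col]][1]) / dg[[col]][1]
    expect_lt(max(drift), 1e-9)
  }
})

test_that("the chemical equilibrium is a fixed point at zero applied voltage", {
  cs <- cached_chemical_solution()
  proto <- electrical_protocol(cs$params$bath, 0)
  res <- run_transient(cs$state, cs$params, cs$fs,
                       proto$boundary_conditions,
                       solver_options(dt = 4e-7, t_end = 2e-6,
                                      steady_tolerance = NULL))
  for (st in res$states) {
    expect_lt(max(abs(st$concentrations - cs$state$concentrations)), 1e-10)
    expect_lt(max(abs(st$potential - cs$state$potential)), 1e-12)
  }
  # a constant-in-time sequence is steady from the first stored time
  # (tolerance above the round-off change rate ~1e-12/dt)
  expect_equal(detect_steady_state(res, 1e-3), res$times[1])
})

test_that("swapping electrode polarity mirrors the transient solution", {
  cs <- cached_chemical_solution()
  run_side <- function(anode) {
    proto <- electrical_protocol(cs$params$bath, 0.05, anode = anode)
    run_transient(cs$state, cs$params, cs$fs, proto$boundary_conditions,
                  solver_options(dt = 4e-7, t_end = 2.4e-6,
                                 steady_tolerance = NULL))
  }
  rl <- run_side("left")
  rr <- run_side("right")
  fl <- rl$states[[length(rl$states)]]
  fr <- rr$states[[length(rr$states)]]
  xs <- seq(5e-8, 1.45e-6, length.out = 31)
  vl <- eval_at(fl, cs$fs, xs)
  vr <- eval_at(fr, cs$fs, 1.5e-6 - xs)
  expect_equal(vl[, "cation"], vr[, "cation"], tolerance = 1e-8)
  expect_equal(vl[, "anion"], vr[, "anion"], tolerance = 1e-8)
  expect_equal(vl[, "potential"], vr[, "potential"], tolerance = 1e-8)
})

test_that("without fixed charge the potential is odd about the mid-level", {
  # charge conjugation + mirror symmetry: psi(x) + psi(L - x) = V when the
  # gel carries no fixed charge (the anionic gel breaks this, the mirror
  # relation above is what survives)
  params <- table1_params(cf = 0)
  fs <- fe_space(build_interval_mesh(scaled_1d_geometry(refined = 1.6e-8)), 2)
  init <- pnpgel:::uniform_bath_state(fs, params)
  proto <- electrical_protocol(params$bath, 0.05)
  res <- run_transient(init, params, fs, proto$boundary_conditions,
                       solver_options(dt = 4e-7, t_end = 2e-6,
                                      steady_tolerance = NULL))
  fin <- res$states[[length(res$states)]]
  xs <- seq(5e-8, 1.45e-6, length.out = 31)
  v1 <- eval_at(fin, fs, xs)
  v2 <- eval_at(fin, fs, 1.5e-6 - xs)
  expect_equal(v1[, "potential"] + v2[, "potential"],
               rep(0.05, length(xs)), tolerance = 1e-8)
})

test_that("backward Euler is first-order accurate in the time step", {
  cs <- cached_chemical_solution()
  proto <- electrical_protocol(cs$params$bath, 0.05)
  t_end <- 3.2e-6
  final_at <- function(dt) {
    r <- run_transient(cs$state, cs$params, cs$fs,
                       proto$boundary_conditions,
                       solver_options(dt = dt, t_end = t_end,
                                      steady_tolerance = NULL,
                                      store_every = 1000L))
    r$states[[length(r$states)]]
  }
  ref <- final_at(t_end / 64)
  err <- function(st) max(abs(st$concentrations - ref$concentrations))
  e1 <- err(final_at(t_end / 4))
  e2 <- err(final_at(t_end / 8))
  rate <- log2(e1 / e2)
  expect_gt(rate, 0.7)
  expect_lt(rate, 1.4)
})

test_that("a strict iteration cap surfaces as a transient failure", {
  cs <- cached_chemical_solution()
  proto <- electrical_protocol(cs$params$bath, 0.05)
  expect_error(
    run_transient(cs$state, cs$params, cs$fs, proto$boundary_conditions,
                  solver_options(dt = 4e-6, t_end = 8e-6,
                                 max_newton_iterations = 1L,
                                 max_dt_halvings = 2L)),
    class = "pnpgel_convergence_error")
})

test_that("transient runs record times, states and iteration counts", {
  cs <- cached_chemical_solution()
  proto <- electrical_protocol(cs$params$bath, 0.05)
  res <- run_transient(cs$state, cs$params, cs$fs,
                       proto$boundary_conditions,
                       solver_options(dt = 4e-7, t_end = 2e-6,
                                      steady_tolerance = NULL))
  expect_true(all(diff(res$times) > 0))
  # first stored state is the supplied initial condition
  expect_identical(res$states[[1]]$concentrations, cs$state$concentrations)
  expect_equal(length(res$newton_iterations), 5)
  expect_output(print(res), "transient_result")
})
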