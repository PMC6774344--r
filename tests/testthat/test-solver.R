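test_that("solver options validate their invariants", {
  expect_error(solver_options(dt = -1), "dt")
  expect_error(solver_options(newton_rel_tol = 0), "tolerances")
  expect_error(solver_options(max_newton_iterations = 0), "iterations")
  expect_error(solver_options(damping = 0), "damping")
  expect_error(solver_options(strategy = "secant"), "arg")
})

test_that("Newton converges in one iteration on a linear system", {
  set.seed(42)
  n <- 30
  A <- Matrix::Diagonal(n, 4) +
    Matrix::sparseMatrix(i = 1:(n - 1), j = 2:n, x = rep(1, n - 1),
                         dims = c(n, n))
  b <- rnorm(n)
  resfn <- function(u) list(res = as.numeric(A %*% u - b), jac = A)
  sol <- newton_solve(resfn, rep(0, n))
  expect_equal(sol$iterations, 1L)
  expect_lt(max(abs(as.numeric(A %*% sol$u - b))), 1e-10)
})

test_that("iteration cap raises a convergence error on the nonlinear solve", {
  params <- table1_params()
  fs <- fe_space(build_interval_mesh(scaled_1d_geometry(refined = 1.6e-8)), 2)
  expect_error(
    solve_chemical_equilibrium(params, fs,
                               options = solver_options(
                                 max_newton_iterations = 1L)),
    class = "pnpgel_convergence_error")
})

test_that("chemical equilibrium recovers the Donnan solution in the bulk", {
  cs <- cached_chemical_solution()
  don <- donnan_equilibrium(cs$params$fixed_charge, cs$params$bath)
  v <- eval_at(cs$state, cs$fs, 7.5e-7)
  expect_equal(unname(v[1, "cation"]), don$gel_cation, tolerance = 5e-3)
  expect_equal(unname(v[1, "anion"]), don$gel_anion, tolerance = 5e-3)
  vb <- eval_at(cs$state, cs$fs, 1.25e-7)
  expect_equal(unname(v[1, "potential"] - vb[1, "potential"]),
               don$potential_jump, tolerance = 5e-3)
  # bath far from the gel stays at bath conditions
  expect_equal(unname(vb[1, "cation"]), 1, tolerance = 1e-3)
})

test_that("zero fixed charge leaves the bath state untouched", {
  params <- table1_params(cf = 0)
  fs <- fe_space(build_interval_mesh(scaled_1d_geometry(refined = 1.6e-8)), 2)
  st <- solve_chemical_equilibrium(params, fs)
  expect_lt(max(abs(st$concentrations - 1)), 1e-9)
  expect_lt(max(abs(st$potential)), 1e-12)
})

test_that("chemical equilibrium is mirror-symmetric about the gel centre", {
  cs <- cached_chemical_solution()
  xs <- seq(1e-7, 7.4e-7, length.out = 23)
  va <- eval_at(cs$state, cs$fs, xs)
  vb <- eval_at(cs$state, cs$fs, 1.5e-6 - xs)
  expect_equal(va, vb, tolerance = 1e-8)
})

test_that("Gummel strategy agrees with monolithic Newton", {
  params <- table1_params()
  fs <- fe_space(build_interval_mesh(scaled_1d_geometry(refined = 1.6e-8)), 2)
  st_n <- solve_chemical_equilibrium(params, fs)
  st_g <- solve_chemical_equilibrium(params, fs,
                                     options = solver_options(
                                       strategy = "gummel"))
  expect_equal(st_g$concentrations, st_n$concentrations, tolerance = 1e-7)
  expect_equal(st_g$potential, st_n$potential, tolerance = 1e-6)
})

test_that("dimensional (unscaled) solve matches the nondimensional one", {
  params <- table1_params()
  fs <- fe_space(build_interval_mesh(scaled_1d_geometry(refined = 1.6e-8)), 2)
  st_s <- solve_chemical_equilibrium(params, fs)
  st_d <- solve_chemical_equilibrium(params, fs,
                                     options = solver_options(
                                       nondimensionalize = FALSE))
  expect_equal(st_d$concentrations, st_s$concentrations, tolerance = 1e-3)
  expect_equal(st_d$potential, st_s$potential, tolerance = 1e-3)
})

test_that("1D steady solve matches the dense finite-difference oracle", {
  params <- table1_params()
  mesh <- uniform_1d_mesh(2.5e-8)
  fs <- fe_space(mesh, 1)
  st <- solve_chemical_equilibrium(params, fs,
                                   options = solver_options(
                                     order = 1L, newton_step_tol = 1e-12))
  x <- mesh$nodes[, 1]
  or <- fd_pnp_steady(x, gel_interval = c(5e-7, 1e-6), cf_signed = -2,
                      constants = params$constants)
  vt <- thermal_voltage(params$constants)
  nv <- nrow(mesh$nodes)
  expect_lt(max(abs(st$concentrations[seq_len(nv), 1] - or$cation)) /
              max(or$cation), 1e-6)
  expect_lt(max(abs(st$concentrations[seq_len(nv), 2] - or$anion)) /
              max(or$anion), 1e-6)
  expect_lt(max(abs(st$potential[seq_len(nv)] / vt - or$potential)) /
              max(abs(or$potential)), 1e-6)
})

test_that("bulk error against the Donnan oracle decreases with refinement", {
  params <- table1_params()
  don <- donnan_equilibrium(params$fixed_charge, params$bath)
  err <- vapply(c(3.2e-8, 8e-9), function(rr) {
    fs <- fe_space(build_interval_mesh(scaled_1d_geometry(refined = rr)), 2)
    st <- solve_chemical_equilibrium(params, fs)
    abs(eval_at(st, fs, 7.5e-7)[1, "cation"] - don$gel_cation)
  }, numeric(1))
  expect_lt(err[2], err[1] / 4)
})

test_that("nondimensionalization round trip and derived scales are exact", {
  params <- table1_params()
  geo <- scaled_1d_geometry()
  sc <- nondimensionalize(params, geo)
  st <- cached_chemical_solution()$state
  back <- sc$unscale(sc$scale(st))
  expect_equal(back$concentrations, st$concentrations, tolerance = 1e-12)
  expect_equal(back$potential, st$potential, tolerance = 1e-12)
  # thermal voltage is the potential scale by construction
  expect_equal(sc$potential, thermal_voltage(params$constants))
  # dimensionless Debye coefficient, independent arithmetic
  cn <- params$constants
  expect_equal(sc$poisson_coefficient,
               100 * 8.854e-12 * 8.3143 * 293 /
                 (9.6487e4^2 * 1 * 1.5e-6^2),
               tolerance = 1e-12)
  expect_equal(sc$debye_length, 1.0764e-8, tolerance = 1e-4)
})
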