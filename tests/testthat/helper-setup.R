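# Shared fixtures: the standard NaCl/hydrogel parameter set, scaled
# geometries, and independent numerical oracles (dense finite-difference
# PNP solve, closed-form helpers). Everything is built in code.

table1_params <- function(molarity = 1, cf = 2) {
  bath <- nacl_bath(molarity)
  validate_parameters(physical_constants(), bath$species,
                      fixed_charge_field(cf, -1L), bath)
}

# Debye-resolved scaled 1D geometry (bath 1.5 um, gel 0.5 um)
scaled_1d_geometry <- function(refined = 8e-9, base = 8e-8) {
  geometry_spec(1, 1.5e-6, "interval", 2.5e-7, gel_center = 7.5e-7,
                refinement_band = 2e-7, base_resolution = base,
                refined_resolution = refined)
}

# Uniform scaled 1D mesh (interfaces and band edges on the grid) for
# oracle comparisons on matched grids
uniform_1d_mesh <- function(h = 2.5e-8) {
  build_interval_mesh(scaled_1d_geometry(refined = h, base = h))
}

# cached chemical-equilibrium solve on the standard scaled mesh
chem_cache <- new.env()
cached_chemical_solution <- function() {
  if (is.null(chem_cache$sol)) {
    params <- table1_params()
    fs <- fe_space(build_interval_mesh(scaled_1d_geometry()), 2)
    chem_cache$sol <- solve_chemical_equilibrium(params, fs)
    chem_cache$fs <- fs
    chem_cache$params <- params
  }
  list(state = chem_cache$sol, fs = chem_cache$fs,
       params = chem_cache$params)
}

eval_at <- function(state, fs, x, y = NULL) {
  pts <- if (is.null(y)) matrix(x, ncol = 1L) else cbind(x, y)
  pnpgel:::evaluate_state(state, fs, pts)
}

# ---- independent dense finite-difference PNP oracle ----------------------
#
# Steady coupled PNP on a uniform 1D grid, written from explicit per-node
# formulas (midpoint fluxes, Simpson charge weights) and solved by dense
# Newton with a numerically differentiated Jacobian. Shares no code with
# the package assembly pipeline.
fd_pnp_steady <- function(x, gel_interval, cf_signed, constants,
                          D = c(1e-7, 1e-7), z = c(1, -1),
                          c_bc = c(1, 1), psi_bc = c(0, 0),
                          tol = 1e-12, maxit = 40) {
  n <- length(x)
  h <- diff(x)
  stopifnot(max(abs(h - h[1])) < 1e-9 * h[1])
  h <- h[1]
  vt <- constants$gas_constant * constants$temperature / constants$faraday
  eps <- constants$relative_permittivity * constants$vacuum_permittivity
  kappa <- eps * vt / constants$faraday # c_ref = 1 mol/m^3
  mid <- (x[-1] + x[-n]) / 2
  cf_cell <- ifelse(mid > gel_interval[1] & mid < gel_interval[2],
                    cf_signed, 0)

  residual <- function(U) {
    c1 <- U[1:n]; c2 <- U[n + 1:n]; p <- U[2 * n + 1:n]
    r <- numeric(3 * n)
    G <- function(cc, zk) {
      diff(cc) / h + zk * (cc[-n] + cc[-1]) / 2 * diff(p) / h
    }
    g1 <- D[1] * G(c1, z[1])
    g2 <- D[2] * G(c2, z[2])
    for (i in 2:(n - 1)) {
      r[i] <- g1[i - 1] - g1[i]
      r[n + i] <- g2[i - 1] - g2[i]
      rho <- z[1] * c1 + z[2] * c2
      charge <- h / 6 * (rho[i - 1] + 4 * rho[i] + rho[i + 1]) +
        h / 2 * (cf_cell[i - 1] + cf_cell[i])
      r[2 * n + i] <- kappa * ((p[i] - p[i - 1]) / h -
                               (p[i + 1] - p[i]) / h) - charge
    }
    r[1] <- c1[1] - c_bc[1]; r[n] <- c1[n] - c_bc[1]
    r[n + 1] <- c2[1] - c_bc[2]; r[2 * n] <- c2[n] - c_bc[2]
    r[2 * n + 1] <- p[1] - psi_bc[1]; r[3 * n] <- p[n] - psi_bc[2]
    r
  }

  U <- c(rep(c_bc[1], n), rep(c_bc[2], n), rep(0, n))
  for (it in seq_len(maxit)) {
    r0 <- residual(U)
    if (max(abs(r0)) < tol) break
    J <- matrix(0, 3 * n, 3 * n)
    dh <- 1e-7
    for (k in seq_len(3 * n)) {
      Up <- U; Up[k] <- Up[k] + dh
      Um <- U; Um[k] <- Um[k] - dh
      J[, k] <- (residual(Up) - residual(Um)) / (2 * dh)
    }
    U <- U + solve(J, -r0)
  }
  list(cation = U[1:n], anion = U[n + 1:n], potential = U[2 * n + 1:n],
       residual = max(abs(residual(U))))
}

# Dense backward-Euler heat-equation step oracle for P1 elements on a
# uniform grid (consistent mass, explicit tridiagonal formulas).
fd_heat_be <- function(c0, h, D, dt, nsteps) {
  n <- length(c0)
  M <- matrix(0, n, n); K <- matrix(0, n, n)
  for (e in seq_len(n - 1)) {
    idx <- c(e, e + 1)
    M[idx, idx] <- M[idx, idx] + h / 6 * matrix(c(2, 1, 1, 2), 2)
    K[idx, idx] <- K[idx, idx] + D / h * matrix(c(1, -1, -1, 1), 2)
  }
  A <- M / dt + K
  cc <- c0
  for (s in seq_len(nsteps)) cc <- solve(A, M %*% cc / dt)
  as.numeric(cc)
}

# L2 norm of a nodal field via the package quadrature
l2_norm <- function(fs, v) sqrt(pnpgel:::integrate_field(fs, v^2))

# ---- shared assembly helpers ---------------------------------------------

# coefficient set isolating the Poisson block with unit constants
unit_coef <- function() {
  list(D = c(0, 0), z = c(1, -1), drift = c(1, -1), kappa = 1, beta = 1,
       zc_f = 0, c_ref = 1, phi_ref = 1, molarity = c(1, 1),
       species_names = c("c1", "c2"), nondim = TRUE, thermal_voltage = 1)
}

two_cell_mesh <- function() {
  pnp_mesh(matrix(c(0, 0.5, 1), ncol = 1), rbind(c(1L, 2L), c(2L, 3L)),
           c("solution", "gel"), matrix(c(1L, 3L), ncol = 1),
           c("electrode_left", "electrode_right"))
}

extract_blocks <- function(fs, coef) {
  n <- fs$ndof
  sys <- pnpgel:::assemble_pnp(fs, coef, rep(0, 3 * n))
  J <- Matrix::sparseMatrix(i = sys$i, j = sys$j, x = sys$x,
                            dims = c(3 * n, 3 * n))
  K <- as.matrix(J[2 * n + 1:n, 2 * n + 1:n]) / coef$kappa
  M <- -as.matrix(J[2 * n + 1:n, 1:n]) / (coef$beta * coef$z[1])
  list(K = K, M = M, J = J)
}


manufactured_poisson_error <- function(order, h) {
  spec <- geometry_spec(1, 1, "interval", 0.25, gel_center = 0.5,
                        refinement_band = 0.1, base_resolution = h,
                        refined_resolution = h)
  fs <- fe_space(build_interval_mesh(spec), order)
  bl <- extract_blocks(fs, unit_coef())
  x <- fs$dof_coords[, 1]
  f <- pi^2 * sin(pi * x)
  rhs <- as.numeric(bl$M %*% f)
  K <- bl$K
  bdofs <- unique(unlist(fs$facet_tag_dofs))
  K[bdofs, ] <- 0
  K[cbind(bdofs, bdofs)] <- 1
  rhs[bdofs] <- 0
  psi <- solve(K, rhs)
  l2_norm(fs, psi - sin(pi * x))
}

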