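# Weak-form assembly of the coupled Poisson-Nernst-Planck system.
#
# Unknown layout: u = (c_cation, c_anion, psi), each of length ndof, in
# solver units (by default concentrations scaled by the bath molarity and
# the potential by the thermal voltage RT/F; see pnp_coefficients()).
#
# Residuals (weak form, zero-flux boundaries natural, Dirichlet rows
# replaced afterwards):
#   species k: int [ (c_k - c_k_old)/dt v + D_k (grad c_k
#                     + drift_k c_k grad psi) . grad v ] dx
#   potential: int [ kappa grad psi . grad v
#                     - beta (z1 c1 + z2 c2 + cf) v ] dx
# with drift_k = z_k (scaled) or z_k F/(RT) (unscaled), cf the signed fixed
# charge supported on gel cells.

# Coefficient set for the assembler, in scaled or physical units
pnp_coefficients <- function(params, nondimensionalize = TRUE) {
  stopifnot(inherits(params, "pnp_parameters"))
  cn <- params$constants
  vt <- thermal_voltage(cn)
  z <- vapply(params$bath$species, `[[`, numeric(1), "valence")
  ord <- order(-z) # cation block first
  species <- params$bath$species[ord]
  z <- z[ord]
  D <- vapply(species, `[[`, numeric(1), "diffusivity")
  molarity <- params$bath$molarity[ord]
  c_ref <- if (nondimensionalize) molarity[1L] else 1
  phi_ref <- if (nondimensionalize) vt else 1
  zc_f <- params$fixed_charge$valence * params$fixed_charge$concentration
  eps <- cn$relative_permittivity * cn$vacuum_permittivity
  if (nondimensionalize) {
    kappa <- eps * vt / (cn$faraday * c_ref) # m^2
    beta <- 1
    drift <- z
  } else {
    kappa <- 1
    beta <- cn$faraday / eps
    drift <- z / vt
  }
  structure(list(D = D, z = z, drift = drift, kappa = kappa, beta = beta,
                 zc_f = zc_f / c_ref, c_ref = c_ref, phi_ref = phi_ref,
                 molarity = molarity, species_names =
                   vapply(species, `[[`, character(1), "name"),
                 nondim = nondimensionalize, thermal_voltage = vt),
            class = "pnp_coefficients")
}

#' Nondimensionalization of the PNP system
#'
#' Returns the scales used internally by the solver (concentration scaled by
#' the bath molarity, potential by the thermal voltage RT/F, length by the
#' bath extent, time by L^2/D) together with forward and backward transforms
#' for a state vector. The raw Poisson coupling F/(eps_r eps0) is of order
#' 1e14 V m / mol, which makes the unscaled system numerically hostile; in
#' scaled variables the dimensionless squared Debye-length ratio
#' eps_r eps0 R T / (F^2 c_ref L^2) multiplies the Poisson stiffness instead.
#'
#' @param params A [validate_parameters()] result.
#' @param geometry A [geometry_spec()] (supplies the length scale).
#' @return Object of class `pnp_scaling` with elements `length`,
#'   `concentration`, `potential`, `time`, `debye_length`,
#'   `poisson_coefficient` (the dimensionless Debye ratio), and functions
#'   `scale(state)` / `unscale(state)` operating on `(c+, c-, psi)` lists.
#' @export
nondimensionalize <- function(params, geometry) {
  stopifnot(inherits(params, "pnp_parameters"),
            inherits(geometry, "geometry_spec"))
  cn <- params$constants
  vt <- thermal_voltage(cn)
  c_ref <- params$bath$molarity[1L]
  if (c_ref <= 0) stop("nondimensionalize: zero reference concentration",
                       call. = FALSE)
  L <- max(geometry$bath_extent)
  D_ref <- max(vapply(params$bath$species, `[[`, numeric(1), "diffusivity"))
  eps <- cn$relative_permittivity * cn$vacuum_permittivity
  debye <- sqrt(eps * cn$gas_constant * cn$temperature /
                (2 * cn$faraday^2 * c_ref))
  coefficient <- eps * cn$gas_constant * cn$temperature /
    (cn$faraday^2 * c_ref * L^2)
  sc <- list(length = L, concentration = c_ref, potential = vt,
             time = L^2 / D_ref, diffusivity = D_ref,
             debye_length = debye, poisson_coefficient = coefficient)
  sc$scale <- function(state) {
    list(concentrations = state$concentrations / c_ref,
         potential = state$potential / vt,
         time = state$time / sc$time)
  }
  sc$unscale <- function(state) {
    list(concentrations = state$concentrations * c_ref,
         potential = state$potential * vt,
         time = state$time * sc$time)
  }
  structure(sc, class = "pnp_scaling")
}

#' @export
print.pnp_scaling <- function(x, ...) {
  cat("PNP scaling:\n")
  cat(sprintf("  length        : %.4g m\n", x$length))
  cat(sprintf("  concentration : %.4g mol/m^3\n", x$concentration))
  cat(sprintf("  potential     : %.4g V (thermal voltage)\n", x$potential))
  cat(sprintf("  time          : %.4g s\n", x$time))
  cat(sprintf("  Debye length  : %.4g m\n", x$debye_length))
  cat(sprintf("  Poisson coeff : %.4g (dimensionless)\n",
              x$poisson_coefficient))
  invisible(x)
}

# Signed fixed charge per cell in solver units
cf_cell_values <- function(fs, coef) {
  ifelse(fs$gel_cell, coef$zc_f, 0)
}

scatter_add <- function(vec, idx, vals) {
  s <- rowsum(vals, idx)
  at <- as.integer(rownames(s))
  vec[at] <- vec[at] + s[, 1L]
  vec
}

#' Assemble the coupled PNP residual and Jacobian
#'
#' Low-level assembler for the mixed system. With `inv_dt = 0` the
#' stationary residual is assembled (chemical equilibrium / steady state);
#' with `inv_dt = 1/dt` and `u_old` supplied, the backward-Euler residual of
#' one implicit step. Dirichlet rows are not yet replaced (see
#' [apply_dirichlet()]).
#'
#' @param fs An [fe_space()].
#' @param coef Coefficients from `pnp_coefficients()` (internal).
#' @param u Current state vector, length `3 * ndof`, layout
#'   `(c+, c-, psi)`.
#' @param u_old Previous-step state vector (transient only).
#' @param inv_dt Reciprocal time step, s^-1 (0 for stationary).
#' @return List with `res` (numeric, `3 ndof`) and Jacobian triplets `i`,
#'   `j`, `x`.
#' @keywords internal
assemble_pnp <- function(fs, coef, u, u_old = NULL, inv_dt = 0) {
  n <- fs$ndof
  if (length(u) != 3L * n) stop("assemble_pnp: state has wrong length",
                                call. = FALSE)
  nb <- fs$nb
  cd <- fs$cell_dofs
  ne <- nrow(cd)
  nq <- length(fs$quad_w)
  B <- fs$B
  wdet <- outer(fs$detJ, fs$quad_w) # ne x nq
  two_d <- fs$dim == 2L

  A1 <- matrix(u[cd], ne, nb)
  A2 <- matrix(u[n + cd], ne, nb)
  P <- matrix(u[2L * n + cd], ne, nb)
  transient <- inv_dt > 0
  if (transient) {
    O1 <- matrix(u_old[cd], ne, nb)
    O2 <- matrix(u_old[n + cd], ne, nb)
  }
  cf <- cf_cell_values(fs, coef)
  D <- coef$D; drift <- coef$drift; z <- coef$z

  aq <- bq <- gax <- gay <- gbx <- gby <- gpx <- gpy <- vector("list", nq)
  daq <- dbq <- vector("list", nq)
  for (q in seq_len(nq)) {
    Gx <- fs$Gphys[[q]]$x
    aq[[q]] <- drop(A1 %*% B[q, ])
    bq[[q]] <- drop(A2 %*% B[q, ])
    gax[[q]] <- rowSums(A1 * Gx)
    gbx[[q]] <- rowSums(A2 * Gx)
    gpx[[q]] <- rowSums(P * Gx)
    if (two_d) {
      Gy <- fs$Gphys[[q]]$y
      gay[[q]] <- rowSums(A1 * Gy)
      gby[[q]] <- rowSums(A2 * Gy)
      gpy[[q]] <- rowSums(P * Gy)
    }
    if (transient) {
      daq[[q]] <- aq[[q]] - drop(O1 %*% B[q, ])
      dbq[[q]] <- bq[[q]] - drop(O2 %*% B[q, ])
    }
  }

  res <- numeric(3L * n)
  for (i in seq_len(nb)) {
    r1 <- r2 <- r3 <- numeric(ne)
    for (q in seq_len(nq)) {
      w <- wdet[, q]
      Gxi <- fs$Gphys[[q]]$x[, i]
      Bi <- B[q, i]
      f1 <- D[1L] * (gax[[q]] + drift[1L] * aq[[q]] * gpx[[q]])
      f2 <- D[2L] * (gbx[[q]] + drift[2L] * bq[[q]] * gpx[[q]])
      r1 <- r1 + w * f1 * Gxi
      r2 <- r2 + w * f2 * Gxi
      r3 <- r3 + w * (coef$kappa * gpx[[q]] * Gxi -
                      coef$beta * (z[1L] * aq[[q]] + z[2L] * bq[[q]] + cf) *
                        Bi)
      if (two_d) {
        Gyi <- fs$Gphys[[q]]$y[, i]
        r1 <- r1 + w * D[1L] * (gay[[q]] + drift[1L] * aq[[q]] * gpy[[q]]) *
          Gyi
        r2 <- r2 + w * D[2L] * (gby[[q]] + drift[2L] * bq[[q]] * gpy[[q]]) *
          Gyi
        r3 <- r3 + w * coef$kappa * gpy[[q]] * Gyi
      }
      if (transient) {
        r1 <- r1 + w * inv_dt * daq[[q]] * Bi
        r2 <- r2 + w * inv_dt * dbq[[q]] * Bi
      }
    }
    idx <- cd[, i]
    res <- scatter_add(res, idx, r1)
    res <- scatter_add(res, n + idx, r2)
    res <- scatter_add(res, 2L * n + idx, r3)
  }

  # Jacobian triplets, block by block, accumulated over quadrature points
  nblk <- nb * nb
  ti <- tj <- tx <- vector("list", 7L * nblk)
  slot <- 0L
  for (i in seq_len(nb)) {
    for (j in seq_len(nb)) {
      j11 <- j22 <- j13 <- j23 <- j31 <- j32 <- j33 <- numeric(ne)
      for (q in seq_len(nq)) {
        w <- wdet[, q]
        Gxi <- fs$Gphys[[q]]$x[, i]; Gxj <- fs$Gphys[[q]]$x[, j]
        Bi <- B[q, i]; Bj <- B[q, j]
        gg <- Gxj * Gxi
        if (two_d) {
          Gyi <- fs$Gphys[[q]]$y[, i]; Gyj <- fs$Gphys[[q]]$y[, j]
          gg <- gg + Gyj * Gyi
        }
        # d(species)/d(species)
        adv1 <- drift[1L] * Bj * (gpx[[q]] * Gxi)
        adv2 <- drift[2L] * Bj * (gpx[[q]] * Gxi)
        if (two_d) {
          adv1 <- adv1 + drift[1L] * Bj * (gpy[[q]] * Gyi)
          adv2 <- adv2 + drift[2L] * Bj * (gpy[[q]] * Gyi)
        }
        j11 <- j11 + w * (D[1L] * (gg + adv1))
        j22 <- j22 + w * (D[2L] * (gg + adv2))
        if (transient) {
          j11 <- j11 + w * inv_dt * Bi * Bj
          j22 <- j22 + w * inv_dt * Bi * Bj
        }
        # d(species)/d(psi)
        j13 <- j13 + w * D[1L] * drift[1L] * aq[[q]] * gg
        j23 <- j23 + w * D[2L] * drift[2L] * bq[[q]] * gg
        # d(poisson)/d(...)
        j31 <- j31 - w * coef$beta * z[1L] * Bi * Bj
        j32 <- j32 - w * coef$beta * z[2L] * Bi * Bj
        j33 <- j33 + w * coef$kappa * gg
      }
      ri <- cd[, i]; rj <- cd[, j]
      blocks <- list(list(0L, 0L, j11), list(n, n, j22),
                     list(0L, 2L * n, j13), list(n, 2L * n, j23),
                     list(2L * n, 0L, j31), list(2L * n, n, j32),
                     list(2L * n, 2L * n, j33))
      for (bkl in blocks) {
        slot <- slot + 1L
        ti[[slot]] <- ri + bkl[[1L]]
        tj[[slot]] <- rj + bkl[[2L]]
        tx[[slot]] <- bkl[[3L]]
      }
    }
  }
  list(res = res, i = unlist(ti), j = unlist(tj), x = unlist(tx))
}

#' Replace Dirichlet rows in an assembled system
#'
#' @param sys Output of [assemble_pnp()].
#' @param u Current state vector.
#' @param dirichlet List with integer `idx` (global row indices) and numeric
#'   `values` (solver units).
#' @param ndof_total Total system size.
#' @return List with `res` and sparse Jacobian `jac` (`dgCMatrix`).
#' @keywords internal
apply_dirichlet <- function(sys, u, dirichlet, ndof_total) {
  res <- sys$res
  isdir <- logical(ndof_total)
  isdir[dirichlet$idx] <- TRUE
  keep <- !isdir[sys$i]
  i <- c(sys$i[keep], dirichlet$idx)
  j <- c(sys$j[keep], dirichlet$idx)
  x <- c(sys$x[keep], rep(1, length(dirichlet$idx)))
  res[dirichlet$idx] <- u[dirichlet$idx] - dirichlet$values
  jac <- Matrix::sparseMatrix(i = i, j = j, x = x,
                              dims = c(ndof_total, ndof_total))
  list(res = res, jac = jac)
}

# Integral of a nodal field over the domain (or a region subset)
integrate_field <- function(fs, vals, cells = NULL) {
  cd <- fs$cell_dofs
  if (!is.null(cells)) cd <- cd[cells, , drop = FALSE]
  U <- matrix(vals[cd], nrow(cd), fs$nb)
  detJ <- if (is.null(cells)) fs$detJ else fs$detJ[cells]
  tot <- 0
  for (q in seq_along(fs$quad_w)) {
    tot <- tot + fs$quad_w[q] * sum(detJ * drop(U %*% fs$B[q, ]))
  }
  tot
}
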