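#' Nodal field state (concentrations + potential)
#'
#' Holds the nodal values of both ion concentrations and the electric
#' potential at one time, in physical units.
#'
#' @param time Time, s.
#' @param concentrations Matrix `ndof x 2` (cation, anion), mol m^-3.
#' @param potential Numeric vector `ndof`, V.
#' @return Object of class `field_state`.
#' @export
field_state <- function(time, concentrations, potential) {
  concentrations <- as.matrix(concentrations)
  if (ncol(concentrations) != 2L) {
    stop("field_state: two concentration columns (cation, anion) expected",
         call. = FALSE)
  }
  if (nrow(concentrations) != length(potential)) {
    stop("field_state: concentration and potential layouts disagree",
         call. = FALSE)
  }
  cmax <- max(concentrations, 1e-300)
  if (min(concentrations) < -1e-12 * cmax) {
    stop("field_state: negative concentrations beyond solver tolerance",
         call. = FALSE)
  }
  if (is.null(colnames(concentrations))) {
    colnames(concentrations) <- c("cation", "anion")
  }
  structure(list(time = time, concentrations = concentrations,
                 potential = as.numeric(potential)),
            class = "field_state")
}

#' @export
print.field_state <- function(x, ...) {
  cat(sprintf("field_state at t = %.6g s (%d DOFs)\n", x$time,
              length(x$potential)))
  rng <- function(v) sprintf("[%.5g, %.5g]", min(v), max(v))
  cat(sprintf("  cation    : %s mol/m^3\n", rng(x$concentrations[, 1L])))
  cat(sprintf("  anion     : %s mol/m^3\n", rng(x$concentrations[, 2L])))
  cat(sprintf("  potential : %s V\n", rng(x$potential)))
  invisible(x)
}

#' Solver options
#'
#' @param dt Time step, s (transient runs; > 0).
#' @param t_end End time, s (transient runs).
#' @param newton_rel_tol Relative residual reduction for convergence.
#' @param newton_abs_tol Absolute residual norm for convergence (solver
#'   units).
#' @param newton_step_tol Relative simplified-Newton-correction norm below
#'   which the iteration is converged (solver units; the workhorse
#'   criterion for stationary solves, where the residual norm scales with
#'   the element volumes).
#' @param max_newton_iterations Maximum Newton iterations per solve.
#' @param damping Initial step-length factor in (0, 1]; backtracking halves
#'   it further when the residual does not decrease.
#' @param linear_solver Sparse linear solver (`"lu"`, the Matrix default).
#' @param nondimensionalize Scale concentrations by the bath molarity and
#'   the potential by the thermal voltage before solving (recommended; the
#'   raw Poisson coupling is of order 1e14).
#' @param order Lagrange element order, 1..3 (default 2).
#' @param strategy `"newton"` (damped monolithic Newton, default) or
#'   `"gummel"` (alternating linearized Poisson / Nernst-Planck fixed
#'   point).
#' @param steady_tolerance Relative inter-step change rate (s^-1) below
#'   which a transient run is considered steady; `NULL` disables early
#'   stopping.
#' @param stop_at_steady Stop a transient run once `steady_tolerance` is
#'   met.
#' @param store_every Store every k-th transient state (the initial and
#'   final states are always stored).
#' @param max_dt_halvings Retry limit for time-step halving after a failed
#'   or negative-concentration step.
#' @return Object of class `solver_options`.
#' @export
solver_options <- function(dt = NULL, t_end = NULL,
                           newton_rel_tol = 1e-10, newton_abs_tol = 1e-12,
                           newton_step_tol = 1e-9,
                           max_newton_iterations = 25L, damping = 1,
                           linear_solver = "lu", nondimensionalize = TRUE,
                           order = 2L, strategy = c("newton", "gummel"),
                           steady_tolerance = NULL, stop_at_steady = TRUE,
                           store_every = 1L, max_dt_halvings = 6L) {
  strategy <- match.arg(strategy)
  if (!is.null(dt) && (!is.finite(dt) || dt <= 0)) {
    stop("solver_options: dt must be > 0", call. = FALSE)
  }
  if (newton_rel_tol <= 0 || newton_abs_tol <= 0) {
    stop("solver_options: tolerances must be > 0", call. = FALSE)
  }
  if (max_newton_iterations < 1L) {
    stop("solver_options: max_newton_iterations must be >= 1", call. = FALSE)
  }
  if (damping <= 0 || damping > 1) {
    stop("solver_options: damping must be in (0, 1]", call. = FALSE)
  }
  structure(list(dt = dt, t_end = t_end, newton_rel_tol = newton_rel_tol,
                 newton_abs_tol = newton_abs_tol,
                 newton_step_tol = newton_step_tol,
                 max_newton_iterations = as.integer(max_newton_iterations),
                 damping = damping, linear_solver = linear_solver,
                 nondimensionalize = nondimensionalize,
                 order = as.integer(order), strategy = strategy,
                 steady_tolerance = steady_tolerance,
                 stop_at_steady = stop_at_steady,
                 store_every = as.integer(store_every),
                 max_dt_halvings = as.integer(max_dt_halvings)),
            class = "solver_options")
}

#' Damped Newton iteration on a residual system
#'
#' Solves `F(u) = 0` for a residual function returning the residual vector
#' and sparse Jacobian. Step acceptance uses the affine-covariant (natural)
#' monotonicity test: a damped step `u + lambda du` is accepted when the
#' simplified Newton correction `J(u)^{-1} F(u + lambda du)` is shorter than
#' `(1 - lambda/2) |du|`; this is robust for stiff drift-diffusion systems,
#' where the raw residual norm is dominated by the tiny element volumes
#' while the correction is order one. Convergence is declared when the
#' residual norm falls below `newton_abs_tol`, is reduced by
#' `newton_rel_tol` relative to the first iterate, or the simplified
#' correction norm falls below `newton_step_tol`. Failure to accept a step
#' or exhausting `max_newton_iterations` raises a condition of class
#' `pnpgel_convergence_error` carrying the residual history.
#'
#' @param residual_fn Function `u -> list(res, jac)`.
#' @param u0 Initial guess (must satisfy any Dirichlet constraints; the
#'   residual function is expected to encode them as `u - g` rows).
#' @param options [solver_options()].
#' @param accept Optional predicate on a trial iterate; the line search
#'   halves the step until it holds (used to keep concentrations out of
#'   strongly negative territory without clipping accepted states).
#' @return List with `u`, `iterations`, `residual_norms`.
#' @export
newton_solve <- function(residual_fn, u0, options = solver_options(),
                         accept = NULL) {
  u <- u0
  sys <- residual_fn(u)
  rnorm <- function(sys) {
    r <- if (is.null(sys$norm_scale)) sys$res else sys$res / sys$norm_scale
    sqrt(sum(r^2))
  }
  rn <- rnorm(sys)
  rn0 <- max(rn, .Machine$double.xmin)
  history <- rn
  fail <- function(msg) {
    cond <- structure(class = c("pnpgel_convergence_error", "error",
                                "condition"),
                      list(message = paste0(msg, " (residual history: ",
                                            paste(signif(history, 4),
                                                  collapse = ", "), ")"),
                           call = sys.call(-1), history = history))
    stop(cond)
  }
  if (rn <= options$newton_abs_tol) {
    return(list(u = u, iterations = 0L, residual_norms = history))
  }
  scale <- function(v) max(sqrt(sum(v^2)), .Machine$double.xmin)
  for (it in seq_len(options$max_newton_iterations)) {
    fac <- tryCatch(Matrix::lu(sys$jac),
                    error = function(e) fail(paste0(
                      "linear factorization failed: ", conditionMessage(e))))
    du <- as.numeric(Matrix::solve(fac, -sys$res))
    ndu <- scale(du)
    lambda <- options$damping
    accepted <- FALSE
    for (ls in 1:12) {
      u_try <- u + lambda * du
      if (!is.null(accept) && !accept(u_try)) {
        lambda <- lambda / 2
        next
      }
      sys_try <- residual_fn(u_try)
      rn_try <- rnorm(sys_try)
      if (!is.finite(rn_try)) {
        lambda <- lambda / 2
        next
      }
      dub <- as.numeric(Matrix::solve(fac, -sys_try$res))
      ndub <- scale(dub)
      if (rn_try <= options$newton_abs_tol ||
          ndub <= (1 - lambda / 2) * ndu) {
        accepted <- TRUE
        break
      }
      lambda <- lambda / 2
    }
    if (!accepted) fail("Newton damping stagnated")
    u <- u_try
    sys <- sys_try
    rn <- rn_try
    history <- c(history, rn)
    unorm <- max(sqrt(sum(u^2)), 1)
    if (rn <= options$newton_abs_tol ||
        rn / rn0 <= options$newton_rel_tol ||
        ndub <= options$newton_step_tol * unorm) {
      return(list(u = u, iterations = it, residual_norms = history))
    }
  }
  fail(sprintf("no convergence in %d Newton iterations",
               options$max_newton_iterations))
}

# --- internal helpers ------------------------------------------------------

# Global Dirichlet rows for the 3-field system, in solver units.
# bc: boundary_conditions object; pins psi at one dof if no potential
# Dirichlet data exist (pure-Neumann Poisson is singular).
dirichlet_rows <- function(fs, bc, coef) {
  n <- fs$ndof
  idx <- integer(0)
  val <- numeric(0)
  for (tag in names(fs$facet_tag_dofs)) {
    dofs <- fs$facet_tag_dofs[[tag]]
    pot <- bc$potential[[tag]]
    if (!is.null(pot) && !is.na(pot)) {
      idx <- c(idx, 2L * n + dofs)
      val <- c(val, rep(pot / coef$phi_ref, length(dofs)))
    }
    conc <- bc$concentration[[tag]]
    if (!is.null(conc) && !anyNA(conc)) {
      for (k in 1:2) {
        idx <- c(idx, (k - 1L) * n + dofs)
        val <- c(val, rep(conc[k] / coef$c_ref, length(dofs)))
      }
    }
  }
  pinned <- FALSE
  if (!any(idx > 2L * n)) {
    idx <- c(idx, 2L * n + 1L)
    val <- c(val, 0)
    pinned <- TRUE
  }
  dup <- duplicated(idx)
  list(idx = idx[!dup], values = val[!dup], pinned = pinned)
}

state_to_vector <- function(state, coef) {
  c(state$concentrations[, 1L] / coef$c_ref,
    state$concentrations[, 2L] / coef$c_ref,
    state$potential / coef$phi_ref)
}

vector_to_state <- function(u, coef, time = 0) {
  n <- length(u) / 3L
  conc <- cbind(u[seq_len(n)], u[n + seq_len(n)]) * coef$c_ref
  colnames(conc) <- c("cation", "anion")
  # clamp solver-level round-off so the state invariant holds exactly
  conc[conc < 0 & conc > -1e-12 * coef$c_ref] <- 0
  field_state(time, conc, u[2L * n + seq_len(n)] * coef$phi_ref)
}

uniform_bath_state <- function(fs, params, time = 0) {
  z <- vapply(params$bath$species, `[[`, numeric(1), "valence")
  mol <- params$bath$molarity[order(-z)]
  field_state(time,
              cbind(cation = rep(mol[1L], fs$ndof),
                    anion = rep(mol[2L], fs$ndof)),
              rep(0, fs$ndof))
}

pnp_residual_fn <- function(fs, coef, dirichlet, u_old = NULL, inv_dt = 0) {
  ntot <- 3L * fs$ndof
  nscale <- residual_norm_scale(fs, dirichlet)
  function(u) {
    sys <- assemble_pnp(fs, coef, u, u_old = u_old, inv_dt = inv_dt)
    out <- apply_dirichlet(sys, u, dirichlet, ntot)
    out$norm_scale <- nscale
    out
  }
}

# Per-row normalization for residual norms: the weak residual of an O(1)
# field scales with the DOF patch volume, which varies over ~16 orders of
# magnitude between bench-scale and Debye-resolved meshes. Dirichlet rows
# (u - g) stay O(1) and keep scale 1.
residual_norm_scale <- function(fs, dirichlet) {
  vol <- numeric(fs$ndof)
  meas <- if (fs$dim == 1L) fs$detJ else fs$detJ / 2
  for (l in seq_len(fs$nb)) {
    vol <- scatter_add(vol, fs$cell_dofs[, l], meas / fs$nb)
  }
  nscale <- rep(vol, 3L)
  nscale[dirichlet$idx] <- 1
  nscale
}

impose_dirichlet_values <- function(u, dirichlet) {
  u[dirichlet$idx] <- dirichlet$values
  u
}

# Gummel fixed point (quasi-Fermi form): each sweep solves the *nonlinear*
# Poisson equation with the concentrations slaved to the potential through
# Boltzmann factors frozen at the current state,
#   c_k(psi) = c_k_cur exp(-z_k (psi - psi_cur)),
# then the two linear Nernst-Planck solves with the potential frozen. The
# Boltzmann coupling is what keeps the potential step bounded when the
# fixed charge is still unscreened (a plain linear Poisson step produces
# potentials of hundreds of thermal volts and destroys the species solves).
gummel_solve <- function(fs, coef, dirichlet, u0, options,
                         u_old = NULL, inv_dt = 0, max_sweeps = 100L) {
  n <- fs$ndof
  ntot <- 3L * n
  u <- impose_dirichlet_values(u0, dirichlet)
  blocks <- list(seq_len(n), n + seq_len(n), 2L * n + seq_len(n))
  resfn <- pnp_residual_fn(fs, coef, dirichlet, u_old, inv_dt)
  psi_dirichlet <- dirichlet$idx > 2L * n
  pd <- list(idx = dirichlet$idx[psi_dirichlet] - 2L * n,
             values = dirichlet$values[psi_dirichlet])
  rn0 <- NULL
  history <- numeric(0)
  for (sweep in seq_len(max_sweeps)) {
    # nonlinear Poisson step (inner Newton, monotone problem)
    psi <- u[blocks[[3L]]]
    for (inner in 1:30) {
      pb <- assemble_poisson_boltzmann(fs, coef, psi, u)
      pbs <- apply_dirichlet(pb, psi, pd, n)
      dpsi <- as.numeric(Matrix::solve(pbs$jac, -pbs$res))
      # cap the potential update at a few thermal voltages per inner step
      cap <- max(abs(dpsi))
      if (cap > 2) dpsi <- dpsi * (2 / cap)
      psi <- psi + dpsi
      if (max(abs(dpsi)) < 1e-12 * max(1, max(abs(psi)))) break
    }
    u[blocks[[3L]]] <- psi
    # linear transport solves with the potential frozen
    for (b in c(1L, 2L)) {
      sys <- resfn(u)
      sel <- blocks[[b]]
      J <- sys$jac[sel, sel, drop = FALSE]
      du <- as.numeric(Matrix::solve(J, -sys$res[sel]))
      u[sel] <- u[sel] + du
    }
    sys <- resfn(u)
    r <- if (is.null(sys$norm_scale)) sys$res else sys$res / sys$norm_scale
    rn <- sqrt(sum(r^2))
    history <- c(history, rn)
    if (is.null(rn0)) rn0 <- max(rn, .Machine$double.xmin)
    if (rn <= options$newton_abs_tol ||
        rn / rn0 <= options$newton_rel_tol) {
      return(list(u = u, iterations = sweep, residual_norms = history,
                  stalled = FALSE))
    }
    # the alternation stalls at the interpolation-level mismatch between
    # the pointwise Boltzmann slaving and the FE transport solution; hand
    # over to Newton once progress stops
    if (sweep >= 3L && rn > 0.5 * min(history[seq_len(sweep - 1L)])) {
      return(list(u = u, iterations = sweep, residual_norms = history,
                  stalled = TRUE))
    }
  }
  list(u = u, iterations = max_sweeps, residual_norms = history,
       stalled = TRUE)
}

# Residual/Jacobian of the Poisson equation with Boltzmann-slaved
# concentrations c_k = c_k_cur exp(-z_k (psi - psi_cur)); solver units.
assemble_poisson_boltzmann <- function(fs, coef, psi, u_cur) {
  n <- fs$ndof
  nb <- fs$nb
  cd <- fs$cell_dofs
  ne <- nrow(cd)
  nq <- length(fs$quad_w)
  B <- fs$B
  wdet <- outer(fs$detJ, fs$quad_w)
  two_d <- fs$dim == 2L
  P <- matrix(psi[cd], ne, nb)
  C1 <- matrix(u_cur[cd], ne, nb)
  C2 <- matrix(u_cur[n + cd], ne, nb)
  P0 <- matrix(u_cur[2L * n + cd], ne, nb)
  cf <- cf_cell_values(fs, coef)
  z <- coef$z
  res <- numeric(n)
  ti <- tj <- tx <- vector("list", nb * nb)
  acc <- vector("list", nb * nb)
  for (k in seq_len(nb * nb)) acc[[k]] <- numeric(ne)
  racc <- vector("list", nb)
  for (i in seq_len(nb)) racc[[i]] <- numeric(ne)
  for (q in seq_len(nq)) {
    w <- wdet[, q]
    pq <- drop(P %*% B[q, ])
    p0q <- drop(P0 %*% B[q, ])
    dpsi <- pmin(pmax(pq - p0q, -40), 40) # overflow guard
    c1 <- pmax(drop(C1 %*% B[q, ]), 0) * exp(-z[1L] * dpsi)
    c2 <- pmax(drop(C2 %*% B[q, ]), 0) * exp(-z[2L] * dpsi)
    rho <- z[1L] * c1 + z[2L] * c2 + cf
    drho <- z[1L]^2 * c1 + z[2L]^2 * c2
    gpx <- rowSums(P * fs$Gphys[[q]]$x)
    if (two_d) gpy <- rowSums(P * fs$Gphys[[q]]$y)
    for (i in seq_len(nb)) {
      Gxi <- fs$Gphys[[q]]$x[, i]
      r <- coef$kappa * gpx * Gxi - coef$beta * rho * B[q, i]
      if (two_d) r <- r + coef$kappa * gpy * fs$Gphys[[q]]$y[, i]
      racc[[i]] <- racc[[i]] + w * r
      for (j in seq_len(nb)) {
        gg <- fs$Gphys[[q]]$x[, j] * Gxi
        if (two_d) gg <- gg + fs$Gphys[[q]]$y[, j] * fs$Gphys[[q]]$y[, i]
        acc[[(i - 1L) * nb + j]] <- acc[[(i - 1L) * nb + j]] +
          w * (coef$kappa * gg +
               coef$beta * drho * B[q, i] * B[q, j])
      }
    }
  }
  for (i in seq_len(nb)) res <- scatter_add(res, cd[, i], racc[[i]])
  for (i in seq_len(nb)) {
    for (j in seq_len(nb)) {
      k <- (i - 1L) * nb + j
      ti[[k]] <- cd[, i]
      tj[[k]] <- cd[, j]
      tx[[k]] <- acc[[k]]
    }
  }
  list(res = res, i = unlist(ti), j = unlist(tj), x = unlist(tx))
}

solve_stationary <- function(fs, coef, dirichlet, u0, options,
                             u_old = NULL, inv_dt = 0) {
  u0 <- impose_dirichlet_values(u0, dirichlet)
  resfn <- pnp_residual_fn(fs, coef, dirichlet, u_old, inv_dt)
  # keep trial concentrations out of strongly negative territory; accepted
  # states are never clipped, so conservation is untouched
  floor_c <- -0.2 * max(coef$molarity) / coef$c_ref
  n2 <- 2L * fs$ndof
  accept <- function(u) min(u[seq_len(n2)]) > floor_c
  if (options$strategy == "gummel") {
    gum <- gummel_solve(fs, coef, dirichlet, u0, options, u_old, inv_dt)
    if (!gum$stalled) return(gum)
    fin <- newton_solve(resfn, gum$u, options, accept = accept)
    return(list(u = fin$u, iterations = gum$iterations + fin$iterations,
                residual_norms = c(gum$residual_norms,
                                   fin$residual_norms)))
  }
  newton_solve(resfn, u0, options, accept = accept)
}

#' Steady-state solve of the chemical-stimulation scenario
#'
#' Solves the stationary coupled PNP system (time-derivative terms dropped)
#' for a gel equilibrating against the bath with no applied potential. In
#' the bulk of the gel the solution reproduces the closed-form Donnan
#' concentrations and potential jump; thin space-charge layers of a few
#' Debye lengths form at the gel-solution interface.
#'
#' If the damped Newton iteration fails from the uniform initial guess, the
#' fixed charge is ramped up in four continuation steps before giving up.
#'
#' @param params A [validate_parameters()] result.
#' @param mesh A [pnp_mesh()] (or an [fe_space()], reused as-is).
#' @param bc Boundary conditions; defaults to [chemical_protocol()] of the
#'   bath.
#' @param options [solver_options()].
#' @return A [field_state()] with attributes `fe_space` and `newton` (the
#'   iteration record).
#' @export
solve_chemical_equilibrium <- function(params, mesh, bc = NULL,
                                       options = solver_options()) {
  stopifnot(inherits(params, "pnp_parameters"))
  fs <- if (inherits(mesh, "fe_space")) mesh else fe_space(mesh, options$order)
  coef <- pnp_coefficients(params, options$nondimensionalize)
  if (is.null(bc)) bc <- chemical_protocol(params$bath)$boundary_conditions
  dirichlet <- dirichlet_rows(fs, bc, coef)
  u0 <- state_to_vector(uniform_bath_state(fs, params), coef)
  fractions <- 1
  sol <- NULL
  for (attempt in 1:2) {
    ok <- TRUE
    u <- u0
    for (f in fractions) {
      coef_f <- coef
      coef_f$zc_f <- coef$zc_f * f
      sol <- tryCatch(solve_stationary(fs, coef_f, dirichlet, u, options),
                      pnpgel_convergence_error = function(e) e)
      if (inherits(sol, "error")) {
        ok <- FALSE
        break
      }
      u <- sol$u
    }
    if (ok) break
    if (attempt == 1L) {
      fractions <- c(0.25, 0.5, 0.75, 1) # fixed-charge continuation ramp
    } else {
      stop(sol)
    }
  }
  out <- vector_to_state(sol$u, coef, time = 0)
  attr(out, "fe_space") <- fs
  attr(out, "newton") <- sol[c("iterations", "residual_norms")]
  out
}

#' Backward-Euler transient PNP run
#'
#' Advances the coupled system from an initial state with implicit Euler
#' steps, each solved by damped Newton (or Gummel sweeps). A step that fails
#' to converge, or that produces concentrations below `-1e-12` of the
#' reference concentration, is rejected and retried with a halved time step
#' (up to `max_dt_halvings`; the step size recovers gradually afterwards).
#'
#' @param initial A [field_state()] (e.g. the chemical equilibrium).
#' @param params A [validate_parameters()] result.
#' @param mesh A [pnp_mesh()] or [fe_space()].
#' @param bc Boundary conditions, e.g. from [electrical_protocol()].
#' @param options [solver_options()] with `dt` and `t_end` set.
#' @return Object of class `transient_result`: time-ordered states (the
#'   first equals `initial`), per-step Newton counts, a convergence flag and
#'   the first time at which the steady criterion held (`NA` if never).
#' @export
run_transient <- function(initial, params, mesh, bc,
                          options = solver_options()) {
  stopifnot(inherits(initial, "field_state"),
            inherits(params, "pnp_parameters"))
  if (is.null(options$dt) || is.null(options$t_end)) {
    stop("run_transient: options must set dt and t_end", call. = FALSE)
  }
  fs <- if (inherits(mesh, "fe_space")) mesh else fe_space(mesh, options$order)
  coef <- pnp_coefficients(params, options$nondimensionalize)
  dirichlet <- dirichlet_rows(fs, bc, coef)
  u <- state_to_vector(initial, coef)
  # the initial state keeps its own boundary values; Dirichlet data apply
  # from the first implicit step onwards
  t <- initial$time
  dt0 <- options$dt
  dt <- dt0
  states <- list(initial)
  times <- t
  newton_iters <- integer(0)
  steady_time <- NA_real_
  step <- 0L
  neg_tol <- -1e-12 # solver units (concentration scale)
  while (t < options$t_end - 1e-12 * options$t_end) {
    dt_try <- min(dt, options$t_end - t)
    halvings <- 0L
    repeat {
      sol <- tryCatch(
        solve_stationary(fs, coef, dirichlet,
                         impose_dirichlet_values(u, dirichlet), options,
                         u_old = u, inv_dt = 1 / dt_try),
        pnpgel_convergence_error = function(e) e)
      bad <- inherits(sol, "error") ||
        min(sol$u[seq_len(2L * fs$ndof)]) < neg_tol
      if (!bad) break
      halvings <- halvings + 1L
      if (halvings > options$max_dt_halvings) {
        if (inherits(sol, "error")) stop(sol)
        stop("run_transient: negative concentrations persist after ",
             options$max_dt_halvings, " time-step halvings", call. = FALSE)
      }
      dt_try <- dt_try / 2
    }
    u_new <- sol$u
    step <- step + 1L
    # inter-step relative change rate, per field, in 1/s
    rate <- step_change_rate(u_new, u, fs$ndof) / dt_try
    t <- t + dt_try
    newton_iters <- c(newton_iters, sol$iterations)
    if (step %% options$store_every == 0L ||
        t >= options$t_end - 1e-12 * options$t_end) {
      states <- c(states, list(vector_to_state(u_new, coef, time = t)))
      times <- c(times, t)
    }
    u <- u_new
    if (!is.null(options$steady_tolerance) &&
        rate <= options$steady_tolerance) {
      if (is.na(steady_time)) steady_time <- t
      if (options$stop_at_steady) break
    }
    dt <- min(dt_try * 2, dt0)
  }
  if (!identical(times[length(times)], t)) {
    states <- c(states, list(vector_to_state(u, coef, time = t)))
    times <- c(times, t)
  }
  structure(list(states = states, times = times,
                 newton_iterations = newton_iters,
                 converged = TRUE, steady_state_time = steady_time,
                 fe_space = fs, options = options),
            class = "transient_result")
}

step_change_rate <- function(u_new, u_old, n) {
  blocks <- list(seq_len(n), n + seq_len(n), 2L * n + seq_len(n))
  rates <- vapply(blocks, function(sel) {
    denom <- max(max(abs(u_new[sel])), .Machine$double.eps)
    max(abs(u_new[sel] - u_old[sel])) / denom
  }, numeric(1))
  max(rates)
}

#' @export
print.transient_result <- function(x, ...) {
  cat(sprintf("transient_result: %d stored states, t in [%.4g, %.4g] s\n",
              length(x$states), x$times[1L], x$times[length(x$times)]))
  cat(sprintf("  Newton iterations/step: %s\n",
              paste(range(x$newton_iterations), collapse = "-")))
  if (is.na(x$steady_state_time)) {
    cat("  steady state: not reached\n")
  } else {
    cat(sprintf("  steady state at t = %.6g s\n", x$steady_state_time))
  }
  invisible(x)
}
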