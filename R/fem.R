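# Lagrange reference elements (interval [0,1], unit triangle), quadrature,
# and the scalar finite-element space with global DOF numbering.
#
# Reference node ordering: vertices first, then edge nodes walking each edge
# from its first to its second vertex (edges (1,2), (2,3), (3,1) on the
# triangle), then interior nodes. This matches the global numbering built in
# fe_space(), where shared edge DOFs are oriented from the lower to the
# higher global vertex index.

ref_nodes <- function(elem, order) {
  p <- order
  if (elem == "interval") {
    xs <- c(0, 1, if (p > 1) seq_len(p - 1) / p)
    return(matrix(xs, ncol = 1L))
  }
  v <- rbind(c(0, 0), c(1, 0), c(0, 1))
  nodes <- v
  edges <- rbind(c(1L, 2L), c(2L, 3L), c(3L, 1L))
  if (p > 1) {
    for (e in 1:3) {
      t <- seq_len(p - 1) / p
      nodes <- rbind(nodes,
                     outer(1 - t, v[edges[e, 1L], ]) +
                     outer(t, v[edges[e, 2L], ]))
    }
  }
  if (p == 3) nodes <- rbind(nodes, c(1 / 3, 1 / 3))
  nodes
}

mono_exponents <- function(elem, order) {
  if (elem == "interval") {
    cbind(0:order)
  } else {
    ex <- expand.grid(a = 0:order, b = 0:order)
    ex <- ex[ex$a + ex$b <= order, , drop = FALSE]
    as.matrix(ex)
  }
}

mono_eval <- function(expo, pts) {
  # values (npts x nmono) of monomials prod(x^a) at pts
  npts <- nrow(pts)
  sapply(seq_len(nrow(expo)), function(j) {
    val <- rep(1, npts)
    for (d in seq_len(ncol(pts))) val <- val * pts[, d]^expo[j, d]
    val
  })
}

mono_grad <- function(expo, pts, d) {
  npts <- nrow(pts)
  sapply(seq_len(nrow(expo)), function(j) {
    a <- expo[j, d]
    if (a == 0) return(rep(0, npts))
    val <- rep(a, npts) * pts[, d]^(a - 1)
    for (dd in seq_len(ncol(pts))) {
      if (dd != d) val <- val * pts[, dd]^expo[j, dd]
    }
    val
  })
}

# Nodal Lagrange basis: coefficients from the Vandermonde inverse
ref_basis <- function(elem, order, pts) {
  nodes <- ref_nodes(elem, order)
  expo <- mono_exponents(elem, order)
  V <- mono_eval(expo, nodes)
  Vinv <- solve(V)
  pts <- matrix(pts, ncol = ncol(nodes))
  B <- mono_eval(expo, pts) %*% Vinv
  G <- lapply(seq_len(ncol(nodes)),
              function(d) mono_grad(expo, pts, d) %*% Vinv)
  list(B = B, G = G, nodes = nodes)
}

# Quadrature on the reference element, exact to the given polynomial degree.
# Weights sum to the reference measure (1 for the interval, 1/2 triangle).
ref_quadrature <- function(elem, degree) {
  if (elem == "interval") {
    n <- max(1L, ceiling((degree + 1) / 2))
    gl <- pracma::gaussLegendre(max(n, 2L), 0, 1)
    return(list(points = matrix(gl$x, ncol = 1L), weights = gl$w))
  }
  perm3 <- function(a) {
    rbind(c(a, a), c(1 - 2 * a, a), c(a, 1 - 2 * a))
  }
  perm6 <- function(a, b) {
    cc <- 1 - a - b
    rbind(c(a, b), c(b, a), c(a, cc), c(cc, a), c(b, cc), c(cc, b))
  }
  if (degree <= 2) {
    pts <- perm3(1 / 6)
    w <- rep(1 / 3, 3)
  } else if (degree <= 4) {
    pts <- rbind(perm3(0.445948490915965), perm3(0.091576213509771))
    w <- c(rep(0.223381589678011, 3), rep(0.109951743655322, 3))
  } else if (degree <= 6) {
    pts <- rbind(perm3(0.063089014491502), perm3(0.249286745170910),
                 perm6(0.310352451033785, 0.053145049844816))
    w <- c(rep(0.050844906370207, 3), rep(0.116786275726379, 3),
           rep(0.082851075618374, 6))
  } else {
    stop("triangle quadrature implemented up to degree 6", call. = FALSE)
  }
  list(points = pts, weights = w / 2)
}

#' Scalar Lagrange finite-element space on a mesh
#'
#' Builds the global degree-of-freedom numbering (vertices, then edge nodes,
#' then cell-interior nodes), DOF coordinates, the boundary-facet DOF lists
#' per tag, and the precomputed reference/physical quadrature data used by
#' the assembly routines.
#'
#' @param mesh A [pnp_mesh()].
#' @param order Polynomial order of the Lagrange elements, 1, 2 or 3
#'   (default 2).
#' @param quadrature_degree Polynomial degree the quadrature must integrate
#'   exactly; defaults to `2 * order`.
#' @return An object of class `fe_space`.
#' @export
fe_space <- function(mesh, order = 2L, quadrature_degree = 2L * order) {
  stopifnot(inherits(mesh, "pnp_mesh"))
  if (!order %in% 1:3) {
    stop("fe_space: order must be 1, 2 or 3", call. = FALSE)
  }
  p <- as.integer(order)
  dim <- mesh$dim
  elem <- if (dim == 1L) "interval" else "triangle"
  nv <- nrow(mesh$nodes)
  ne <- nrow(mesh$cells)
  cl <- mesh$cells

  if (dim == 1L) {
    nb <- p + 1L
    cell_dofs <- matrix(0L, ne, nb)
    cell_dofs[, 1:2] <- cl
    if (p > 1) {
      cell_dofs[, 3:nb] <- nv + matrix(seq_len(ne * (p - 1L)), ne,
                                       p - 1L, byrow = TRUE)
    }
    ndof <- nv + ne * (p - 1L)
    facet_tag_dofs <- split(mesh$boundary_facets[, 1L], mesh$boundary_tag)
  } else {
    # local edges (1,2), (2,3), (3,1)
    ea <- cbind(cl[, 1L], cl[, 2L], cl[, 3L])
    eb <- cbind(cl[, 2L], cl[, 3L], cl[, 1L])
    lo <- pmin(ea, eb); hi <- pmax(ea, eb)
    key <- as.numeric(lo) * (nv + 1) + as.numeric(hi)
    ukey <- unique(key)
    edge_id <- matrix(match(key, ukey), ne, 3L)
    n_edge <- length(ukey)
    forward <- ea < eb # cell walks the edge in global (lo -> hi) direction
    nb <- (p + 1L) * (p + 2L) / 2L
    cell_dofs <- matrix(0L, ne, nb)
    cell_dofs[, 1:3] <- cl
    if (p > 1) {
      npe <- p - 1L
      for (e in 1:3) {
        base <- nv + (edge_id[, e] - 1L) * npe
        for (j in seq_len(npe)) {
          jj <- ifelse(forward[, e], j, npe + 1L - j)
          cell_dofs[, 3L + (e - 1L) * npe + j] <- base + jj
        }
      }
    }
    ndof <- nv + n_edge * (p - 1L)
    if (p == 3) {
      cell_dofs[, nb] <- ndof + seq_len(ne)
      ndof <- ndof + ne
    }
    # boundary facet DOFs: endpoint vertices plus the facet edge's nodes
    bf <- mesh$boundary_facets
    fkey <- as.numeric(pmin(bf[, 1L], bf[, 2L])) * (nv + 1) +
      as.numeric(pmax(bf[, 1L], bf[, 2L]))
    fedge <- match(fkey, ukey)
    fdofs <- cbind(bf[, 1L], bf[, 2L])
    if (p > 1) {
      npe <- p - 1L
      for (j in seq_len(npe)) {
        fdofs <- cbind(fdofs, nv + (fedge - 1L) * npe + j)
      }
    }
    facet_tag_dofs <- lapply(split(seq_len(nrow(bf)), mesh$boundary_tag),
                             function(i) sort(unique(as.integer(fdofs[i, ]))))
  }
  if (dim == 1L) {
    facet_tag_dofs <- lapply(facet_tag_dofs, as.integer)
  }

  # DOF coordinates via the affine map of the reference nodes
  rb <- ref_basis(elem, p, ref_nodes(elem, p)) # identity basis eval
  rn <- rb$nodes
  dof_coords <- matrix(0, ndof, dim)
  v1 <- mesh$nodes[cl[, 1L], , drop = FALSE]
  if (dim == 1L) {
    h <- mesh$nodes[cl[, 2L], 1L] - v1[, 1L]
    for (l in seq_len(nrow(rn))) {
      dof_coords[cell_dofs[, l], 1L] <- v1[, 1L] + rn[l, 1L] * h
    }
  } else {
    d21 <- mesh$nodes[cl[, 2L], , drop = FALSE] - v1
    d31 <- mesh$nodes[cl[, 3L], , drop = FALSE] - v1
    for (l in seq_len(nrow(rn))) {
      xy <- v1 + rn[l, 1L] * d21 + rn[l, 2L] * d31
      dof_coords[cell_dofs[, l], ] <- xy
    }
  }

  # quadrature and per-cell geometric factors
  qr <- ref_quadrature(elem, quadrature_degree)
  basis <- ref_basis(elem, p, qr$points)
  nq <- length(qr$weights)
  if (dim == 1L) {
    h <- mesh$nodes[cl[, 2L], 1L] - mesh$nodes[cl[, 1L], 1L]
    detJ <- abs(h)
    Gphys <- lapply(seq_len(nq), function(q) {
      list(x = outer(1 / h, basis$G[[1L]][q, ]))
    })
  } else {
    d21 <- mesh$nodes[cl[, 2L], , drop = FALSE] - v1
    d31 <- mesh$nodes[cl[, 3L], , drop = FALSE] - v1
    det <- d21[, 1L] * d31[, 2L] - d31[, 1L] * d21[, 2L]
    detJ <- abs(det)
    # inv(J)^T rows: d(xi)/dx etc.
    ixx <- d31[, 2L] / det;  ixy <- -d31[, 1L] / det
    iyx <- -d21[, 2L] / det; iyy <- d21[, 1L] / det
    Gphys <- lapply(seq_len(nq), function(q) {
      g1 <- basis$G[[1L]][q, ]; g2 <- basis$G[[2L]][q, ]
      list(x = outer(ixx, g1) + outer(iyx, g2),
           y = outer(ixy, g1) + outer(iyy, g2))
    })
  }

  structure(list(mesh = mesh, order = p, elem = elem, dim = dim,
                 ndof = ndof, nb = if (dim == 1L) p + 1L else nb,
                 cell_dofs = cell_dofs, dof_coords = dof_coords,
                 facet_tag_dofs = facet_tag_dofs,
                 quad_w = qr$weights, quad_pts = qr$points,
                 B = basis$B, Gphys = Gphys, detJ = detJ,
                 gel_cell = mesh$region == "gel"),
            class = "fe_space")
}

#' @export
print.fe_space <- function(x, ...) {
  cat(sprintf("fe_space: order-%d Lagrange on %dD mesh, %d DOFs (%d cells)\n",
              x$order, x$dim, x$ndof, nrow(x$cell_dofs)))
  invisible(x)
}

# DOFs whose every adjacent cell is a gel cell (interface DOFs count as
# solution); used for region-wise nodal fields
dof_in_gel <- function(fs) {
  ingel <- rep(TRUE, fs$ndof)
  touched <- rep(FALSE, fs$ndof)
  gel <- fs$gel_cell
  for (l in seq_len(ncol(fs$cell_dofs))) {
    idx <- fs$cell_dofs[, l]
    touched[idx] <- TRUE
    ingel[idx[!gel]] <- FALSE
  }
  ingel & touched
}

# DOFs adjacent to both gel and solution cells
interface_dofs <- function(fs) {
  ingel <- rep(FALSE, fs$ndof)
  insol <- rep(FALSE, fs$ndof)
  gel <- fs$gel_cell
  for (l in seq_len(ncol(fs$cell_dofs))) {
    idx <- fs$cell_dofs[, l]
    ingel[idx[gel]] <- TRUE
    insol[idx[!gel]] <- TRUE
  }
  which(ingel & insol)
}
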