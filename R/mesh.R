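#' Construct a tagged simplicial mesh
#'
#' Low-level constructor for the discretized bath-gel domain. Most users
#' should call [build_interval_mesh()], [build_square_gel_mesh()] or
#' [build_disc_gel_mesh()] instead. The constructor validates the mesh
#' invariants (see [check_mesh()]).
#'
#' @param nodes Numeric matrix (n x dim) of vertex coordinates in metres.
#' @param cells Integer matrix (ne x (dim+1)) of vertex indices (intervals
#'   in 1D, triangles in 2D).
#' @param region Character vector per cell, each `"gel"` or `"solution"`.
#' @param boundary_facets Integer matrix (nf x dim): boundary vertices in 1D,
#'   boundary edges (vertex pairs) in 2D.
#' @param boundary_tag Character per facet: `"electrode_left"`,
#'   `"electrode_right"` or `"insulated"`.
#' @param geometry Optional [geometry_spec()] the mesh was built from.
#' @return An object of class `pnp_mesh`.
#' @export
pnp_mesh <- function(nodes, cells, region, boundary_facets, boundary_tag,
                     geometry = NULL) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  cells <- as.matrix(cells)
  storage.mode(cells) <- "integer"
  boundary_facets <- as.matrix(boundary_facets)
  storage.mode(boundary_facets) <- "integer"
  dimnames(nodes) <- dimnames(cells) <- dimnames(boundary_facets) <- NULL
  dim <- ncol(nodes)
  m <- structure(list(dim = dim, nodes = nodes, cells = cells,
                      region = as.character(region),
                      boundary_facets = boundary_facets,
                      boundary_tag = as.character(boundary_tag),
                      geometry = geometry),
                 class = "pnp_mesh")
  check_mesh(m)
  m
}

#' Validate mesh invariants
#'
#' Checks that region tags partition the cells into `gel` and `solution`,
#' that all cell measures are positive, and that every exterior facet
#' carries exactly one boundary tag from the recognized set.
#'
#' @param mesh A [pnp_mesh()].
#' @return Invisibly `TRUE`; errors describe the violated invariant.
#' @export
check_mesh <- function(mesh) {
  stopifnot(inherits(mesh, "pnp_mesh"))
  if (!mesh$dim %in% c(1L, 2L)) stop("check_mesh: dim must be 1 or 2")
  if (ncol(mesh$cells) != mesh$dim + 1L) {
    stop("check_mesh: cells must have dim+1 vertices", call. = FALSE)
  }
  if (length(mesh$region) != nrow(mesh$cells)) {
    stop("check_mesh: one region tag per cell required", call. = FALSE)
  }
  bad_region <- setdiff(unique(mesh$region), c("gel", "solution"))
  if (length(bad_region)) {
    stop("check_mesh: unknown region tag(s): ",
         paste(bad_region, collapse = ", "), call. = FALSE)
  }
  if (any(cell_measures(mesh) <= 0)) {
    stop("check_mesh: all cell measures must be positive", call. = FALSE)
  }
  bad_tag <- setdiff(unique(mesh$boundary_tag),
                     c("electrode_left", "electrode_right", "insulated"))
  if (length(bad_tag)) {
    stop("check_mesh: unknown boundary tag(s): ",
         paste(bad_tag, collapse = ", "), call. = FALSE)
  }
  ext <- exterior_facets(mesh)
  got <- facet_key(mesh$boundary_facets)
  if (length(mesh$boundary_tag) != nrow(mesh$boundary_facets)) {
    stop("check_mesh: one tag per boundary facet required", call. = FALSE)
  }
  if (anyDuplicated(got)) {
    stop("check_mesh: duplicate boundary facets", call. = FALSE)
  }
  if (!setequal(got, facet_key(ext))) {
    stop("check_mesh: boundary facets must coincide with the exterior ",
         "facets of the cell complex", call. = FALSE)
  }
  invisible(TRUE)
}

#' Cell measures (lengths or areas)
#'
#' @param mesh A [pnp_mesh()].
#' @return Numeric vector of element lengths (1D) or triangle areas (2D).
#' @export
cell_measures <- function(mesh) {
  x <- mesh$nodes
  cl <- mesh$cells
  if (mesh$dim == 1L) {
    abs(x[cl[, 2L], 1L] - x[cl[, 1L], 1L])
  } else {
    x1 <- x[cl[, 1L], , drop = FALSE]
    x2 <- x[cl[, 2L], , drop = FALSE]
    x3 <- x[cl[, 3L], , drop = FALSE]
    0.5 * abs((x2[, 1] - x1[, 1]) * (x3[, 2] - x1[, 2]) -
              (x3[, 1] - x1[, 1]) * (x2[, 2] - x1[, 2]))
  }
}

# Canonical string key for a facet matrix (order-independent)
facet_key <- function(f) {
  f <- as.matrix(f)
  if (ncol(f) == 1L) return(as.character(f[, 1L]))
  paste(pmin(f[, 1L], f[, 2L]), pmax(f[, 1L], f[, 2L]), sep = "-")
}

# Facets of the cell complex that belong to exactly one cell
exterior_facets <- function(mesh) {
  cl <- mesh$cells
  if (mesh$dim == 1L) {
    ids <- c(cl[, 1L], cl[, 2L])
    tab <- table(ids)
    matrix(as.integer(names(tab)[tab == 1L]), ncol = 1L)
  } else {
    ed <- rbind(cl[, c(1L, 2L)], cl[, c(2L, 3L)], cl[, c(3L, 1L)])
    key <- facet_key(ed)
    tab <- table(key)
    ones <- names(tab)[tab == 1L]
    ed[match(ones, key), , drop = FALSE]
  }
}

#' @export
print.pnp_mesh <- function(x, ...) {
  cat(sprintf("pnp_mesh: %dD, %d nodes, %d cells (%d gel / %d solution)\n",
              x$dim, nrow(x$nodes), nrow(x$cells),
              sum(x$region == "gel"), sum(x$region == "solution")))
  tags <- table(x$boundary_tag)
  cat("  boundary facets:",
      paste(sprintf("%s=%d", names(tags), tags), collapse = ", "), "\n")
  invisible(x)
}

#' Build a 1D bath-gel-bath interval mesh
#'
#' Nodes cover `[0, bath_extent]`; the two gel-solution interfaces are mesh
#' nodes and the element size does not exceed `refined_resolution` within
#' `refinement_band` of either interface. The left domain end is tagged
#' `electrode_left` and the right end `electrode_right`.
#'
#' @param spec A 1D [geometry_spec()].
#' @return A [pnp_mesh()].
#' @export
build_interval_mesh <- function(spec) {
  stopifnot(inherits(spec, "geometry_spec"))
  if (spec$dimension != 1L) {
    stop("build_interval_mesh: spec must be 1D", call. = FALSE)
  }
  ifc <- spec$gel_center + c(-1, 1) * spec$gel_extent
  x <- graded_points(0, spec$bath_extent[1L], ifc, spec$refinement_band,
                     spec$base_resolution, spec$refined_resolution)
  n <- length(x)
  cells <- cbind(seq_len(n - 1L), seq.int(2L, n))
  mid <- (x[cells[, 1L]] + x[cells[, 2L]]) / 2
  region <- ifelse(mid > ifc[1L] & mid < ifc[2L], "gel", "solution")
  pnp_mesh(matrix(x, ncol = 1L), cells, region,
           matrix(c(1L, n), ncol = 1L),
           c("electrode_left", "electrode_right"), geometry = spec)
}

# Tensor-product graded triangulation helpers ------------------------------

# Split the structured quad grid (nx x ny points) into triangles.
grid_triangles <- function(nx, ny) {
  ix <- rep(seq_len(nx - 1L), ny - 1L)
  iy <- rep(seq_len(ny - 1L), each = nx - 1L)
  v00 <- (iy - 1L) * nx + ix
  v10 <- v00 + 1L
  v01 <- v00 + nx
  v11 <- v01 + 1L
  rbind(cbind(v00, v10, v11), cbind(v00, v11, v01))
}

#' Build a 2D mesh with a centred square gel
#'
#' Tensor-product graded triangulation of a rectangular bath containing an
#' axis-aligned square gel; the gel boundary coincides with grid lines, so
#' the mesh conforms to the interface. Left/right exterior edges are tagged
#' `electrode_left`/`electrode_right`, top and bottom `insulated`.
#'
#' @param spec A 2D [geometry_spec()] with `gel_shape = "square"`.
#' @return A [pnp_mesh()].
#' @export
build_square_gel_mesh <- function(spec) {
  stopifnot(inherits(spec, "geometry_spec"))
  if (spec$dimension != 2L || spec$gel_shape != "square") {
    stop("build_square_gel_mesh: spec must be 2D with gel_shape 'square'",
         call. = FALSE)
  }
  lo <- spec$gel_center - spec$gel_extent
  hi <- spec$gel_center + spec$gel_extent
  xs <- graded_points(0, spec$bath_extent[1L], c(lo[1L], hi[1L]),
                      spec$refinement_band, spec$base_resolution,
                      spec$refined_resolution)
  ys <- graded_points(0, spec$bath_extent[2L], c(lo[2L], hi[2L]),
                      spec$refinement_band, spec$base_resolution,
                      spec$refined_resolution)
  nx <- length(xs); ny <- length(ys)
  nodes <- cbind(rep(xs, ny), rep(ys, each = nx))
  cells <- grid_triangles(nx, ny)
  cent <- (nodes[cells[, 1L], ] + nodes[cells[, 2L], ] +
           nodes[cells[, 3L], ]) / 3
  region <- ifelse(cent[, 1L] > lo[1L] & cent[, 1L] < hi[1L] &
                   cent[, 2L] > lo[2L] & cent[, 2L] < hi[2L],
                   "gel", "solution")
  bf <- exterior_facets_from_cells(cells)
  tag <- classify_boundary_edges(nodes, bf, spec$bath_extent)
  pnp_mesh(nodes, cells, region, bf, tag, geometry = spec)
}

exterior_facets_from_cells <- function(cells) {
  ed <- rbind(cells[, c(1L, 2L)], cells[, c(2L, 3L)], cells[, c(3L, 1L)])
  key <- paste(pmin(ed[, 1L], ed[, 2L]), pmax(ed[, 1L], ed[, 2L]), sep = "-")
  tab <- table(key)
  ones <- names(tab)[tab == 1L]
  ed[match(ones, key), , drop = FALSE]
}

classify_boundary_edges <- function(nodes, edges, bath_extent) {
  tol <- 1e-9 * max(bath_extent)
  mx <- (nodes[edges[, 1L], 1L] + nodes[edges[, 2L], 1L]) / 2
  my <- (nodes[edges[, 1L], 2L] + nodes[edges[, 2L], 2L]) / 2
  tag <- rep(NA_character_, nrow(edges))
  tag[abs(mx) < tol] <- "electrode_left"
  tag[abs(mx - bath_extent[1L]) < tol] <- "electrode_right"
  tag[is.na(tag) & (abs(my) < tol | abs(my - bath_extent[2L]) < tol)] <-
    "insulated"
  if (anyNA(tag)) {
    stop("boundary edge not on any side of the bath rectangle",
         call. = FALSE)
  }
  tag
}

#' Build a 2D mesh with a circular gel scaffold
#'
#' Boundary-fitted O-grid mesh for a disc-shaped gel (2D approximation of a
#' cylindrical scaffold) inside a rectangular bath. The disc interface is a
#' polygon whose vertex count scales with `radius / refined_resolution`;
#' inside the disc a radially graded fan/ring mesh is used, outside it the
#' annular region blends radially onto the bath rectangle. Radial spacing is
#' at most `refined_resolution` within `refinement_band` of the interface.
#'
#' The angular grid always contains the directions of the four bath corners
#' so each exterior facet lies on exactly one side; when the gel is centred
#' the node set is mirror-symmetric about both axes.
#'
#' @param spec A 2D [geometry_spec()] with `gel_shape = "disc"`;
#'   `gel_extent` is the disc radius.
#' @return A [pnp_mesh()].
#' @export
build_disc_gel_mesh <- function(spec) {
  stopifnot(inherits(spec, "geometry_spec"))
  if (spec$dimension != 2L || spec$gel_shape != "disc") {
    stop("build_disc_gel_mesh: spec must be 2D with gel_shape 'disc'",
         call. = FALSE)
  }
  r <- spec$gel_extent
  ctr <- spec$gel_center
  L <- spec$bath_extent
  # angular grid: uniform, multiple of 8, spacing ~ refined_resolution at the
  # interface, plus the exact corner directions
  ntheta <- max(32L, 8L * as.integer(ceiling(2 * pi * r /
                                             spec$refined_resolution / 8)))
  theta <- 2 * pi * seq.int(0L, ntheta - 1L) / ntheta
  corners <- rbind(c(0, 0), c(L[1L], 0), c(L[1L], L[2L]), c(0, L[2L]))
  th_c <- atan2(corners[, 2L] - ctr[2L], corners[, 1L] - ctr[1L]) %% (2 * pi)
  theta <- sort(unique(round(c(theta, th_c), 12)))
  nth <- length(theta)
  ux <- cos(theta); uy <- sin(theta)

  # ray lengths from the centre to the bath rectangle
  tx <- ifelse(ux > 0, (L[1L] - ctr[1L]) / ux,
               ifelse(ux < 0, -ctr[1L] / ux, Inf))
  ty <- ifelse(uy > 0, (L[2L] - ctr[2L]) / uy,
               ifelse(uy < 0, -ctr[2L] / uy, Inf))
  raylen <- pmin(tx, ty)
  Tk <- raylen - r # circle-to-boundary distance per ray
  if (any(Tk <= spec$refinement_band)) {
    stop("build_disc_gel_mesh: gel too close to the bath boundary for the ",
         "requested refinement band", call. = FALSE)
  }

  # radial template inside the disc (refined towards the interface)
  r_in <- graded_points(0, r, r, spec$refinement_band,
                        spec$base_resolution, spec$refined_resolution)
  n_in <- length(r_in) - 1L # rings excluding the centre point
  # outward template distances: refined band absolute, coarse part stretched
  Tmax <- max(Tk)
  d_out <- graded_points(0, Tmax, 0, spec$refinement_band,
                         spec$base_resolution, spec$refined_resolution)
  d_out <- d_out[-1L]
  n_out <- length(d_out)
  b <- spec$refinement_band

  # nodes: centre, then rings of nth points
  nring <- n_in + n_out
  xs <- matrix(0, nth, nring)
  ys <- matrix(0, nth, nring)
  for (j in seq_len(n_in)) {
    xs[, j] <- ctr[1L] + r_in[j + 1L] * ux
    ys[, j] <- ctr[2L] + r_in[j + 1L] * uy
  }
  for (j in seq_len(n_out)) {
    d <- d_out[j]
    dk <- ifelse(rep(d <= b, nth), d, b + (d - b) * (Tk - b) / (Tmax - b))
    xs[, n_in + j] <- ctr[1L] + (r + dk) * ux
    ys[, n_in + j] <- ctr[2L] + (r + dk) * uy
  }
  # snap the outermost ring exactly onto the rectangle
  tol <- 1e-9 * max(L)
  xo <- xs[, nring]; yo <- ys[, nring]
  xo[abs(xo) < tol] <- 0; xo[abs(xo - L[1L]) < tol] <- L[1L]
  yo[abs(yo) < tol] <- 0; yo[abs(yo - L[2L]) < tol] <- L[2L]
  xs[, nring] <- xo; ys[, nring] <- yo

  nodes <- rbind(ctr, cbind(as.vector(xs), as.vector(ys)))
  ring_id <- function(j, k) 1L + (j - 1L) * nth + ((k - 1L) %% nth) + 1L
  k <- seq_len(nth)
  kp <- k %% nth + 1L
  # centre fan (gel)
  cells <- cbind(1L, ring_id(1L, k), ring_id(1L, kp))
  for (j in seq.int(2L, nring)) {
    v00 <- ring_id(j - 1L, k); v10 <- ring_id(j, k)
    v11 <- ring_id(j, kp); v01 <- ring_id(j - 1L, kp)
    cells <- rbind(cells, cbind(v00, v10, v11), cbind(v00, v11, v01))
  }
  ngel_cells <- nth + 2L * nth * (n_in - 1L)
  region <- c(rep("gel", ngel_cells),
              rep("solution", nrow(cells) - ngel_cells))
  bf <- exterior_facets_from_cells(cells)
  tag <- classify_boundary_edges(nodes, bf, L)
  pnp_mesh(nodes, cells, region, bf, tag, geometry = spec)
}

#' Build the mesh described by a geometry spec
#'
#' Dispatches to the interval, square-gel or disc-gel builder.
#'
#' @param spec A [geometry_spec()].
#' @return A [pnp_mesh()].
#' @export
build_mesh <- function(spec) {
  switch(spec$gel_shape,
         interval = build_interval_mesh(spec),
         square = build_square_gel_mesh(spec),
         disc = build_disc_gel_mesh(spec))
}
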