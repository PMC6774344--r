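# Gmsh MSH 2.2 ASCII import/export with physical-group tags.
#
# Physical groups used:
#   dim  id name
#   d    1  gel            (cells)
#   d    2  solution       (cells)
#   d-1  3  electrode_left (boundary facets)
#   d-1  4  electrode_right
#   d-1  5  insulated
# Element types: 15 = point, 1 = 2-node line, 2 = 3-node triangle.

msh_region_ids <- c(gel = 1L, solution = 2L)
msh_boundary_ids <- c(electrode_left = 3L, electrode_right = 4L,
                      insulated = 5L)

#' Export a mesh to Gmsh MSH 2.2 format
#'
#' Writes nodes, cells and boundary facets together with the `gel` /
#' `solution` region tags and the electrode/insulated boundary tags as Gmsh
#' physical groups. Coordinates are written with 17 significant digits so a
#' round trip reproduces them exactly.
#'
#' @param mesh A [pnp_mesh()].
#' @param path Output file path (conventionally `.msh`).
#' @return Invisibly, `path`.
#' @seealso [read_mesh_msh()]
#' @export
write_mesh_msh <- function(mesh, path) {
  stopifnot(inherits(mesh, "pnp_mesh"))
  n <- nrow(mesh$nodes)
  coords <- cbind(mesh$nodes,
                  matrix(0, n, 3L - ncol(mesh$nodes)))
  lines <- c("$MeshFormat", "2.2 0 8", "$EndMeshFormat", "$PhysicalNames")
  pn <- c(sprintf("%d %d \"%s\"", mesh$dim, msh_region_ids,
                  names(msh_region_ids)),
          sprintf("%d %d \"%s\"", mesh$dim - 1L,
                  msh_boundary_ids[unique(mesh$boundary_tag)],
                  unique(mesh$boundary_tag)))
  lines <- c(lines, length(pn), pn, "$EndPhysicalNames", "$Nodes", n,
             sprintf("%d %.17g %.17g %.17g", seq_len(n),
                     coords[, 1L], coords[, 2L], coords[, 3L]),
             "$EndNodes", "$Elements")
  facet_type <- if (mesh$dim == 1L) 15L else 1L
  cell_type <- if (mesh$dim == 1L) 1L else 2L
  nf <- nrow(mesh$boundary_facets)
  ne <- nrow(mesh$cells)
  fac <- apply(mesh$boundary_facets, 1L, paste, collapse = " ")
  cel <- apply(mesh$cells, 1L, paste, collapse = " ")
  btag <- msh_boundary_ids[mesh$boundary_tag]
  rtag <- msh_region_ids[mesh$region]
  el <- c(sprintf("%d %d 2 %d %d %s", seq_len(nf), facet_type, btag, btag,
                  fac),
          sprintf("%d %d 2 %d %d %s", nf + seq_len(ne), cell_type, rtag,
                  rtag, cel))
  lines <- c(lines, nf + ne, el, "$EndElements")
  writeLines(lines, path)
  invisible(path)
}

#' Import a mesh from Gmsh MSH 2.2 format
#'
#' Reads an ASCII MSH 2.2 file carrying physical-group tags, reconstructs a
#' [pnp_mesh()] and validates its invariants. Region names must include
#' `gel` and `solution` (matched by physical name, falling back to the
#' conventional ids written by [write_mesh_msh()]); boundary facets must be
#' tagged `electrode_left`, `electrode_right` or `insulated`.
#'
#' @param path Path to a `.msh` file.
#' @return A [pnp_mesh()].
#' @export
read_mesh_msh <- function(path) {
  if (!file.exists(path)) {
    stop("read_mesh_msh: file not found: ", path, call. = FALSE)
  }
  txt <- readLines(path)
  section <- function(name) {
    i0 <- match(paste0("$", name), txt)
    i1 <- match(paste0("$End", name), txt)
    if (is.na(i0) || is.na(i1)) {
      stop("read_mesh_msh: missing $", name, " section", call. = FALSE)
    }
    txt[(i0 + 1L):(i1 - 1L)]
  }
  # physical names -> tag ids
  phys <- tryCatch(section("PhysicalNames"), error = function(e) NULL)
  name_of <- c()
  if (!is.null(phys)) {
    for (ln in phys[-1L]) {
      m <- regmatches(ln, regexec("^\\s*(\\d+)\\s+(\\d+)\\s+\"(.*)\"", ln))[[1]]
      if (length(m) == 4L) name_of[m[4L]] <- as.integer(m[3L])
    }
  }
  id_to_name <- function(id, fallback) {
    nm <- names(name_of)[match(id, name_of)]
    ifelse(is.na(nm), fallback[as.character(id)], nm)
  }

  nd <- section("Nodes")
  nn <- as.integer(nd[1L])
  ndat <- matrix(scan(text = nd[-1L], quiet = TRUE), nrow = nn, byrow = TRUE)
  ord <- order(ndat[, 1L])
  coords3 <- ndat[ord, 2:4, drop = FALSE]

  el <- section("Elements")
  vv <- lapply(strsplit(trimws(el[-1L]), "\\s+"), as.integer)
  type <- vapply(vv, `[`, integer(1), 2L)
  phys <- vapply(vv, function(v) if (v[3L] >= 1L) v[4L] else NA_integer_,
                 integer(1))
  conn_of <- function(sel, k) {
    if (!any(sel)) return(NULL)
    vals <- vapply(vv[sel], function(v) v[(length(v) - k + 1L):length(v)],
                   integer(k))
    if (k == 1L) matrix(vals, ncol = 1L) else t(vals)
  }
  tri <- conn_of(type == 2L, 3L)
  lin <- conn_of(type == 1L, 2L)
  pts <- conn_of(type == 15L, 1L)
  if (!is.null(tri)) {
    # 2D: triangles are cells, lines are boundary facets
    dim <- 2L
    cells <- tri; region_id <- phys[type == 2L]
    facets <- lin; facet_id <- phys[type == 1L]
  } else if (!is.null(lin)) {
    # 1D: lines are cells, points are boundary facets
    dim <- 1L
    cells <- lin; region_id <- phys[type == 1L]
    facets <- pts; facet_id <- phys[type == 15L]
  } else {
    stop("read_mesh_msh: no cells found", call. = FALSE)
  }
  coords <- coords3[, seq_len(dim), drop = FALSE]
  region <- id_to_name(region_id, c(`1` = "gel", `2` = "solution"))
  btag <- id_to_name(facet_id, c(`3` = "electrode_left",
                                 `4` = "electrode_right",
                                 `5` = "insulated"))
  if (anyNA(region) || !all(region %in% c("gel", "solution"))) {
    stop("read_mesh_msh: cells without a recognizable region tag",
         call. = FALSE)
  }
  for (req in c("gel", "solution")) {
    if (!req %in% region) {
      stop("read_mesh_msh: mesh lacks a '", req, "' region", call. = FALSE)
    }
  }
  if (is.null(facets) || anyNA(btag)) {
    stop("read_mesh_msh: boundary facets missing or untagged", call. = FALSE)
  }
  pnp_mesh(coords, cells, region, facets, btag)
}
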