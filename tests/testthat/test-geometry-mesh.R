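test_that("geometry spec enforces its invariants", {
  expect_error(geometry_spec(1, 0.015, "interval", 0.008), "strictly inside")
  expect_error(geometry_spec(1, 0.015, "interval", 0.0025,
                             refinement_band = 0), "refinement_band")
  expect_error(geometry_spec(1, 0.015, "interval", 0.0025,
                             base_resolution = 1e-4,
                             refined_resolution = 2e-4),
               "refined_resolution")
  expect_error(geometry_spec(2, 0.015, "interval", 0.0025), "1D only")
  sc <- scale_geometry(geometry_spec(1, 0.015, "interval", 0.0025), 1e-4)
  expect_equal(sc$bath_extent, 1.5e-6)
  expect_equal(sc$gel_extent, 2.5e-7)
})

test_that("interval mesh has interface nodes, graded bands and exact gel length", {
  spec <- geometry_spec(1, 0.015, "interval", 0.0025,
                        refinement_band = 0.002,
                        base_resolution = 5e-4, refined_resolution = 1e-4)
  m <- build_interval_mesh(spec)
  x <- m$nodes[, 1]
  # interfaces at 0.005 and 0.010 are mesh nodes
  expect_true(any(abs(x - 0.005) < 1e-12))
  expect_true(any(abs(x - 0.010) < 1e-12))
  h <- cell_measures(m)
  mid <- (x[m$cells[, 1]] + x[m$cells[, 2]]) / 2
  in_band <- (abs(mid - 0.005) <= 0.002) | (abs(mid - 0.010) <= 0.002)
  expect_lte(max(h[in_band]), 1e-4 * (1 + 1e-9))
  expect_lte(max(h), 5e-4 * (1 + 1e-9))
  # gel cells sum exactly to the gel length
  expect_equal(sum(h[m$region == "gel"]), 0.005, tolerance = 1e-12)
  # conformity: every cell lies wholly inside or outside the gel
  lo <- pmin(x[m$cells[, 1]], x[m$cells[, 2]])
  hi <- pmax(x[m$cells[, 1]], x[m$cells[, 2]])
  straddle <- (lo < 0.005 - 1e-12 & hi > 0.005 + 1e-12) |
    (lo < 0.010 - 1e-12 & hi > 0.010 + 1e-12)
  expect_false(any(straddle))
})

test_that("equal resolutions give a uniform interval mesh", {
  spec <- geometry_spec(1, 0.015, "interval", 0.0025,
                        refinement_band = 0.002,
                        base_resolution = 2.5e-4,
                        refined_resolution = 2.5e-4)
  m <- build_interval_mesh(spec)
  expect_lt(diff(range(cell_measures(m))), 1e-12)
})

test_that("halving the refined resolution at least doubles band nodes", {
  count_band_nodes <- function(rr) {
    m <- build_interval_mesh(geometry_spec(1, 0.015, "interval", 0.0025,
                                           refinement_band = 0.002,
                                           base_resolution = 5e-4,
                                           refined_resolution = rr))
    x <- m$nodes[, 1]
    sum(abs(x - 0.005) <= 0.002 | abs(x - 0.010) <= 0.002)
  }
  expect_gte(count_band_nodes(5e-5), 2 * count_band_nodes(1e-4) - 4)
})

test_that("square-gel mesh partitions the bath with tagged boundary", {
  spec <- geometry_spec(2, 0.015, "square", 0.0025,
                        refinement_band = 0.002,
                        base_resolution = 1.5e-3, refined_resolution = 5e-4)
  m <- build_square_gel_mesh(spec)
  a <- cell_measures(m)
  expect_equal(sum(a), 0.015^2, tolerance = 1e-12)
  expect_equal(sum(a[m$region == "gel"]), 0.005^2, tolerance = 1e-12)
  # regions partition the cells
  expect_setequal(unique(m$region), c("gel", "solution"))
  # every exterior facet carries exactly one tag
  ext <- pnpgel:::exterior_facets(m)
  expect_equal(nrow(m$boundary_facets), nrow(ext))
  expect_setequal(unique(m$boundary_tag),
                  c("electrode_left", "electrode_right", "insulated"))
  # electrodes on x = 0 / x = L, insulated top and bottom
  for (f in seq_len(nrow(m$boundary_facets))) {
    xy <- m$nodes[m$boundary_facets[f, ], , drop = FALSE]
    tag <- m$boundary_tag[f]
    if (tag == "electrode_left") expect_true(all(abs(xy[, 1]) < 1e-12))
    if (tag == "electrode_right") {
      expect_true(all(abs(xy[, 1] - 0.015) < 1e-12))
    }
  }
  expect_output(print(m), "pnp_mesh")
})

test_that("disc-gel mesh approximates the disc and refines the annulus", {
  r <- 0.0025
  spec <- geometry_spec(2, 0.015, "disc", r,
                        refinement_band = 0.002,
                        base_resolution = 1.5e-3, refined_resolution = 4e-4)
  m <- build_disc_gel_mesh(spec)
  a <- cell_measures(m)
  expect_equal(sum(a), 0.015^2, tolerance = 1e-9 * 0.015^2)
  gel_area <- sum(a[m$region == "gel"])
  expect_lt(abs(gel_area - pi * r^2) / (pi * r^2), 0.01)
  # conformity at the circular interface: gel vertices inside radius r,
  # solution cells outside the inscribed polygon
  ctr <- c(0.0075, 0.0075)
  rad <- sqrt((m$nodes[, 1] - ctr[1])^2 + (m$nodes[, 2] - ctr[2])^2)
  gel_vertices <- unique(as.vector(m$cells[m$region == "gel", ]))
  expect_lte(max(rad[gel_vertices]), r * (1 + 1e-12))
  # radial spacing within the refinement annulus
  band_cells <- which(vapply(seq_len(nrow(m$cells)), function(e) {
    rc <- mean(rad[m$cells[e, ]])
    abs(rc - r) <= 0.002
  }, logical(1)))
  expect_lte(max(a[band_cells]), 0.5 * 4e-4^2 * (1 + 1e-6) * 2)
  # mirror symmetry of the node set for a centred gel
  refl <- cbind(m$nodes[, 1], 0.015 - m$nodes[, 2])
  key <- function(p) paste(round(p[, 1], 12), round(p[, 2], 12))
  expect_setequal(key(m$nodes), key(refl))
  # gel too close to the wall
  expect_error(build_disc_gel_mesh(
    geometry_spec(2, 0.015, "disc", 0.0056, refinement_band = 0.002,
                  base_resolution = 1.5e-3, refined_resolution = 4e-4)),
    "too close")
})

test_that("mesh invariants are checked by the constructor", {
  nodes <- matrix(c(0, 0.5, 1), ncol = 1)
  cells <- rbind(c(1L, 2L), c(2L, 3L))
  expect_silent(pnp_mesh(nodes, cells, c("solution", "gel"),
                         matrix(c(1L, 3L), ncol = 1),
                         c("electrode_left", "electrode_right")))
  expect_error(pnp_mesh(nodes, cells, c("solution", "plasma"),
                        matrix(c(1L, 3L), ncol = 1),
                        c("electrode_left", "electrode_right")),
               "unknown region")
  expect_error(pnp_mesh(nodes, cells, c("solution", "gel"),
                        matrix(1L, ncol = 1), "electrode_left"),
               "exterior")
  expect_error(pnp_mesh(nodes, rbind(c(1L, 1L), c(2L, 3L)),
                        c("solution", "gel"),
                        matrix(c(1L, 3L), ncol = 1),
                        c("electrode_left", "electrode_right")),
               "positive")
})
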