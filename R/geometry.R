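#' Geometry specification for the bath-gel domain
#'
#' Describes a rectangular solution bath with an embedded gel (interval,
#' square or disc) plus the mesh-grading parameters: a locally refined band
#' around the gel-solution interface where the electric double layers live,
#' and a coarser base resolution elsewhere.
#'
#' The default lengths follow the usual bench-top configuration: a 0.015 m
#' bath with a gel of half-width 0.0025 m at its centre and a refinement
#' band extending 0.002 m to either side of the interface.
#'
#' @param dimension 1 or 2.
#' @param bath_extent Bath size per axis, m (scalar, or length 2 in 2D).
#' @param gel_shape `"interval"` (1D), `"square"` or `"disc"` (2D).
#' @param gel_extent Gel half-width (interval/square) or radius (disc), m.
#' @param gel_center Gel centre coordinates, m; defaults to the bath centre.
#' @param refinement_band Half-width of the refined zone around the
#'   interface, m (> 0).
#' @param base_resolution Target element size away from the interface, m.
#' @param refined_resolution Target element size inside the band, m
#'   (<= base_resolution).
#' @return An object of class `geometry_spec`.
#' @examples
#' geometry_spec(1, 0.015, "interval", 0.0025)
#' @export
geometry_spec <- function(dimension,
                          bath_extent = 0.015,
                          gel_shape = c("interval", "square", "disc"),
                          gel_extent = 0.0025,
                          gel_center = NULL,
                          refinement_band = 0.002,
                          base_resolution = max(bath_extent) / 30,
                          refined_resolution = base_resolution / 5) {
  gel_shape <- match.arg(gel_shape)
  if (!dimension %in% c(1L, 2L)) {
    stop("geometry_spec: dimension must be 1 or 2", call. = FALSE)
  }
  if (dimension == 1L && gel_shape != "interval") {
    stop("geometry_spec: 1D geometry requires gel_shape = 'interval'",
         call. = FALSE)
  }
  if (dimension == 2L && gel_shape == "interval") {
    stop("geometry_spec: gel_shape 'interval' is 1D only", call. = FALSE)
  }
  bath_extent <- rep_len(as.numeric(bath_extent), dimension)
  if (any(bath_extent <= 0)) {
    stop("geometry_spec: bath_extent must be positive", call. = FALSE)
  }
  if (is.null(gel_center)) gel_center <- bath_extent / 2
  gel_center <- rep_len(as.numeric(gel_center), dimension)
  if (gel_extent <= 0) {
    stop("geometry_spec: gel_extent must be positive", call. = FALSE)
  }
  if (refinement_band <= 0) {
    stop("geometry_spec: refinement_band must be > 0", call. = FALSE)
  }
  if (refined_resolution > base_resolution || refined_resolution <= 0) {
    stop("geometry_spec: need 0 < refined_resolution <= base_resolution",
         call. = FALSE)
  }
  clearance <- pmin(gel_center, bath_extent - gel_center) - gel_extent
  if (any(clearance <= 0)) {
    stop("geometry_spec: gel must lie strictly inside the bath ",
         "(clearance must be positive on every side)", call. = FALSE)
  }
  structure(list(dimension = as.integer(dimension),
                 bath_extent = bath_extent, gel_shape = gel_shape,
                 gel_extent = gel_extent, gel_center = gel_center,
                 refinement_band = refinement_band,
                 base_resolution = base_resolution,
                 refined_resolution = refined_resolution),
            class = "geometry_spec")
}

#' @export
print.geometry_spec <- function(x, ...) {
  cat(sprintf("Geometry: %dD %s gel (extent %.4g m) in bath %s m\n",
              x$dimension, x$gel_shape, x$gel_extent,
              paste(signif(x$bath_extent, 4), collapse = " x ")))
  cat(sprintf("  centre %s m; refinement band %.4g m; h = %.4g / %.4g m\n",
              paste(signif(x$gel_center, 4), collapse = ", "),
              x$refinement_band, x$base_resolution, x$refined_resolution))
  invisible(x)
}

#' Shrink a geometry to Debye-resolvable scale
#'
#' Multiplies every length of a [geometry_spec()] by `factor` (default
#' 1e-4, i.e. a 0.015 m bath becomes 1.5 um). Bulk Donnan values are
#' geometry-independent, so the scaled domain supports quantitative
#' validation with electric double layers (about 10 nm at 1 mM, eps_r = 100)
#' that the mesh can actually resolve.
#'
#' @param spec A [geometry_spec()].
#' @param factor Length scale factor (default 1e-4).
#' @return A rescaled `geometry_spec`.
#' @export
scale_geometry <- function(spec, factor = 1e-4) {
  stopifnot(inherits(spec, "geometry_spec"), factor > 0)
  geometry_spec(spec$dimension, spec$bath_extent * factor, spec$gel_shape,
                spec$gel_extent * factor, spec$gel_center * factor,
                spec$refinement_band * factor,
                spec$base_resolution * factor,
                spec$refined_resolution * factor)
}

# Graded 1D point set on [a, b]: spacing <= h_ref within `band` of any
# interface position, <= h_base elsewhere; all interfaces become points.
graded_points <- function(a, b, interfaces, band, h_base, h_ref) {
  stopifnot(b > a, h_ref <= h_base, h_ref > 0)
  len <- b - a
  brk <- c(a, b, vapply(interfaces, function(p) p, numeric(1)),
           unlist(lapply(interfaces, function(p) c(p - band, p + band))))
  brk <- pmin(pmax(brk, a), b)
  brk <- sort(unique(round(brk / len, 14) * len))
  pts <- brk[1]
  for (s in seq_len(length(brk) - 1L)) {
    s0 <- brk[s]; s1 <- brk[s + 1L]
    if (s1 - s0 <= 1e-14 * len) next
    mid <- (s0 + s1) / 2
    h <- if (length(interfaces) &&
             min(abs(mid - interfaces)) <= band * (1 + 1e-12)) h_ref else h_base
    n <- max(1L, ceiling((s1 - s0) / h - 1e-9))
    pts <- c(pts, s0 + (s1 - s0) * seq_len(n) / n)
  }
  pts
}
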