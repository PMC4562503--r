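#' Display geometry: pixel/degree scale
#'
#' The stimulus matrix is square; `matrix_px` pixels subtend `matrix_deg`
#' degrees of visual angle, so lengths convert at a single scale
#' `matrix_deg / matrix_px`.  Defaults reproduce a 600 x 600 px matrix
#' subtending 19.15 x 19.15 deg.
#'
#' @param matrix_px Pixels per matrix side (positive integer).
#' @param matrix_deg Degrees of visual angle per matrix side (positive).
#' @return An object of class `display_geometry`.
#' @examples
#' geom <- display_geometry()
#' px_to_deg(100, geom)  # 3.19 deg
#' @export
display_geometry <- function(matrix_px = 600, matrix_deg = 19.15) {
  if (length(matrix_px) != 1L || !is.finite(matrix_px) || matrix_px <= 0)
    stop("matrix_px must be a single positive number")
  if (length(matrix_deg) != 1L || !is.finite(matrix_deg) || matrix_deg <= 0)
    stop("matrix_deg must be a single positive number")
  structure(
    list(matrix_px = as.integer(matrix_px),
         matrix_deg = as.numeric(matrix_deg),
         deg_per_px = as.numeric(matrix_deg) / as.integer(matrix_px)),
    class = "display_geometry")
}

#' @export
print.display_geometry <- function(x, ...) {
  cat(sprintf("display geometry: %d px ~ %.4g deg (%.5f deg/px)\n",
              x$matrix_px, x$matrix_deg, x$deg_per_px))
  invisible(x)
}

#' Convert pixel lengths to degrees of visual angle (and back)
#'
#' @param n_px,deg Non-negative lengths (vectorised).
#' @param geom A [display_geometry()].
#' @return Numeric vector of converted lengths.
#' @export
px_to_deg <- function(n_px, geom = display_geometry()) {
  stopifnot(inherits(geom, "display_geometry"))
  if (any(n_px < 0)) stop("pixel lengths must be non-negative")
  n_px * geom$matrix_deg / geom$matrix_px
}

#' @rdname px_to_deg
#' @export
deg_to_px <- function(deg, geom = display_geometry()) {
  stopifnot(inherits(geom, "display_geometry"))
  if (any(deg < 0)) stop("degree lengths must be non-negative")
  deg * geom$matrix_px / geom$matrix_deg
}

#' Annulus specification
#'
#' The printed stimulus numbers (size 100 or 200, thickness 25 or 75, both in
#' pixels) are ambiguous: read naively as outer diameter plus ring width the
#' small/thick annulus is geometrically impossible (inner radius would be
#' negative).  Two self-consistent conventions are supported, both of which
#' make the small/thick and large/thin annuli equal in area:
#'
#' * `"diameter_diff"` (default): size = outer diameter, thickness = outer
#'   minus inner diameter, so the ring width is `thickness / 2`.  The only
#'   reading under which all four annuli also fit a central 300 x 300 px
#'   region.
#' * `"radius_width"`: size = outer radius, thickness = ring width.
#' * `"diameter_width"`: the naive reading (outer diameter + ring width as
#'   printed); constructing an impossible annulus under it raises an error.
#'
#' @param size_px Printed size value in pixels (e.g. 100 or 200).
#' @param thickness_px Printed thickness value in pixels (e.g. 25 or 75).
#' @param convention One of `"diameter_diff"`, `"radius_width"`,
#'   `"diameter_width"`.
#' @param center Optional shape centre in continuous 0-based pixel
#'   coordinates `c(x, y)`; default is the matrix centre.
#' @return Object of class `annulus_spec` with derived `outer_r` and
#'   `inner_r` (pixels).
#' @export
annulus_spec <- function(size_px, thickness_px,
                         convention = c("diameter_diff", "radius_width",
                                        "diameter_width"),
                         center = NULL) {
  convention <- match.arg(convention)
  stopifnot(size_px > 0, thickness_px > 0)
  dims <- switch(convention,
    diameter_diff = c(outer = size_px / 2, inner = (size_px - thickness_px) / 2),
    radius_width  = c(outer = size_px, inner = size_px - thickness_px),
    diameter_width = c(outer = size_px / 2, inner = size_px / 2 - thickness_px))
  if (dims["inner"] < 0)
    stop(sprintf(paste0("impossible annulus under convention '%s': size %g px",
                        " with thickness %g px gives inner radius %g px"),
                 convention, size_px, thickness_px, dims["inner"]))
  if (dims["outer"] <= dims["inner"])
    stop("outer radius must exceed inner radius")
  structure(
    list(size_value_px = size_px, thickness_value_px = thickness_px,
         convention = convention, center = center,
         outer_r = unname(dims["outer"]), inner_r = unname(dims["inner"])),
    class = c("annulus_spec", "shape_spec"))
}

#' Disk specification
#'
#' @param diameter_deg Disk diameter in degrees of visual angle (positive).
#' @param eccentricity_deg Displacement of the disk centre from the matrix
#'   centre, degrees (non-negative).
#' @param direction Direction of the displacement, radians.
#' @return Object of class `disk_spec`.
#' @export
disk_spec <- function(diameter_deg, eccentricity_deg = 0, direction = 0) {
  stopifnot(diameter_deg > 0, eccentricity_deg >= 0)
  structure(
    list(diameter_deg = diameter_deg, eccentricity_deg = eccentricity_deg,
         direction = direction),
    class = c("disk_spec", "shape_spec"))
}

# Continuous outer/inner radii and centre of a shape, in pixels.
shape_radii_px <- function(spec, geom) {
  if (inherits(spec, "annulus_spec")) {
    list(outer = spec$outer_r, inner = spec$inner_r)
  } else {
    list(outer = deg_to_px(spec$diameter_deg / 2, geom), inner = 0)
  }
}

shape_center_px <- function(spec, geom) {
  c0 <- (geom$matrix_px - 1) / 2
  if (inherits(spec, "annulus_spec")) {
    if (!is.null(spec$center)) spec$center else c(c0, c0)
  } else {
    ecc <- deg_to_px(spec$eccentricity_deg, geom)
    c(c0 + ecc * cos(spec$direction), c0 + ecc * sin(spec$direction))
  }
}

#' Rasterise a shape as a binary pixel mask
#'
#' A pixel belongs to the mask iff its centre lies at radial distance `d`
#' from the shape centre with `inner <= d < outer` (half-open outer
#' boundary; a disk is the inner-radius-zero case).  Pixel centres sit on the
#' integer grid `0 .. N-1` with the matrix centre at `(N-1)/2`.
#'
#' @param spec An [annulus_spec()] or [disk_spec()].
#' @param geom A [display_geometry()].
#' @return Logical `N x N` matrix (`TRUE` inside the shape).
#' @export
shape_mask <- function(spec, geom = display_geometry()) {
  stopifnot(inherits(spec, "shape_spec"), inherits(geom, "display_geometry"))
  n <- geom$matrix_px
  rr <- shape_radii_px(spec, geom)
  ctr <- shape_center_px(spec, geom)
  over <- max(ctr[1] + rr$outer - (n - 1), ctr[2] + rr$outer - (n - 1),
              -(ctr[1] - rr$outer), -(ctr[2] - rr$outer))
  if (over > 0)
    stop(sprintf("shape extends %.2f px beyond the %d x %d matrix", over, n, n))
  x <- matrix(0:(n - 1), n, n, byrow = TRUE)  # column index = x
  y <- matrix(0:(n - 1), n, n)                # row index = y
  d <- sqrt((x - ctr[1])^2 + (y - ctr[2])^2)
  d >= rr$inner & d < rr$outer
}

#' Contour-length and fill-distance features of a shape
#'
#' Features entering the filling-in regression: the summed contour length
#' `C` (inner plus outer circumference for an annulus, the circumference for
#' a disk) and the filling-in distance `D_fill` (the ring width for an
#' annulus, the radius for a disk), both in pixels.  For an annulus
#' `fill_dist = "width"` uses the physical ring width `R - r`;
#' `fill_dist = "printed"` uses the printed thickness value instead.
#'
#' @param spec An [annulus_spec()] or [disk_spec()].
#' @param geom A [display_geometry()].
#' @param fill_dist `"width"` (default) or `"printed"`.
#' @return A list with `contour_len_px` and `fill_dist_px`.
#' @export
fillin_features <- function(spec, geom = display_geometry(),
                            fill_dist = c("width", "printed")) {
  fill_dist <- match.arg(fill_dist)
  rr <- shape_radii_px(spec, geom)
  if (inherits(spec, "annulus_spec")) {
    d <- if (fill_dist == "printed") spec$thickness_value_px else rr$outer - rr$inner
    list(contour_len_px = 2 * pi * (rr$outer + rr$inner), fill_dist_px = d)
  } else {
    list(contour_len_px = 2 * pi * rr$outer, fill_dist_px = rr$outer)
  }
}

#' Continuous area of a shape in square pixels
#'
#' `pi * (R^2 - r^2)`; used for the equal-stimulus-energy checks.
#'
#' @inheritParams fillin_features
#' @return Area in px^2.
#' @export
shape_area_px <- function(spec, geom = display_geometry()) {
  rr <- shape_radii_px(spec, geom)
  pi * (rr$outer^2 - rr$inner^2)
}
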