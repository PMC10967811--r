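#' Equivalent-duct description of a nasal passage
#'
#' The nasal passage is modelled as a straight duct characterised by a
#' hydraulic diameter, an effective channel length and a relative wall
#' roughness. The hydraulic diameter of a non-circular cross-section is
#' \eqn{D_h = 4A/O}, with \eqn{A} the cross-sectional area and \eqn{O} its
#' perimeter.
#'
#' @param hydraulic_diameter Hydraulic diameter \eqn{D_h} in m. Positive.
#' @param length Channel length \eqn{L} in m. Non-negative (zero collapses
#'   the duct to a resistance-free element, useful in limits).
#' @param relative_roughness Dimensionless relative wall roughness
#'   \eqn{\epsilon_r \ge 0}; 0 for a smooth duct.
#'
#' @return An object of class `duct_model`.
#' @seealso [duct_from_cross_section()], [hydraulic_diameter()]
#' @examples
#' duct_model(hydraulic_diameter = 0.01, length = 0.1)
#' @export
duct_model <- function(hydraulic_diameter, length, relative_roughness = 0) {
  stop_if_not_positive_scalar(hydraulic_diameter, "hydraulic_diameter")
  stop_if_not_nonnegative_scalar(length, "length")
  stop_if_not_nonnegative_scalar(relative_roughness, "relative_roughness")
  structure(
    list(
      hydraulic_diameter = hydraulic_diameter,
      length = length,
      relative_roughness = relative_roughness
    ),
    class = "duct_model"
  )
}

#' Build a duct model from a cross-section
#'
#' @param area Cross-sectional area \eqn{A} in m^2.
#' @param perimeter Cross-section perimeter \eqn{O} in m.
#' @inheritParams duct_model
#' @return A [duct_model()] with `hydraulic_diameter = 4 * area / perimeter`;
#'   the generating `area` and `perimeter` are kept as elements.
#' @examples
#' # a circular pipe of radius r has Dh = 2 r
#' duct_from_cross_section(area = pi * 0.005^2, perimeter = 2 * pi * 0.005,
#'                         length = 0.1)$hydraulic_diameter
#' @export
duct_from_cross_section <- function(area, perimeter, length,
                                    relative_roughness = 0) {
  duct <- duct_model(
    hydraulic_diameter = hydraulic_diameter(area, perimeter),
    length = length,
    relative_roughness = relative_roughness
  )
  duct$area <- area
  duct$perimeter <- perimeter
  duct
}

#' Hydraulic diameter of a cross-section
#'
#' \eqn{D_h = 4A/O}. Reduces to the geometric diameter for a circle and to
#' the side length for a square.
#'
#' @param area Cross-sectional area in m^2, positive.
#' @param perimeter Cross-section perimeter in m, positive.
#' @return Hydraulic diameter in m.
#' @examples
#' hydraulic_diameter(1e-4, 0.05) # 8 mm
#' @export
hydraulic_diameter <- function(area, perimeter) {
  stop_if_not_positive_scalar(area, "area")
  stop_if_not_positive_scalar(perimeter, "perimeter")
  4 * area / perimeter
}

#' @export
print.duct_model <- function(x, ...) {
  cat("Duct model\n")
  cat(sprintf("  hydraulic diameter: %g mm\n", x$hydraulic_diameter * 1e3))
  cat(sprintf("  length:             %g m\n", x$length))
  cat(sprintf("  relative roughness: %g\n", x$relative_roughness))
  invisible(x)
}

as_duct <- function(duct) {
  if (!inherits(duct, "duct_model")) {
    stop("`duct` must be a duct_model object; see duct_model()", call. = FALSE)
  }
  duct
}
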