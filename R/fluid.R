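#' Fluid properties for nasal airflow modelling
#'
#' Bundles the constant air properties used by every pressure-drop and
#' dimensionless-number computation: mass density \eqn{\rho}, dynamic
#' viscosity \eqn{\mu}, and the derived kinematic viscosity
#' \eqn{\nu = \mu / \rho}.
#'
#' @param density Mass density \eqn{\rho} in kg m^-3. Must be positive.
#' @param dynamic_viscosity Dynamic viscosity \eqn{\mu} in Pa s. Must be
#'   positive.
#'
#' @return An object of class `fluid_properties`: a list with elements
#'   `density`, `dynamic_viscosity` and `kinematic_viscosity` (m^2 s^-1).
#'
#' @seealso [air_properties()] for the two standard air presets.
#' @examples
#' air <- fluid_properties(density = 1.225, dynamic_viscosity = 1.7894e-5)
#' air$kinematic_viscosity
#' @export
fluid_properties <- function(density, dynamic_viscosity) {
  stop_if_not_positive_scalar(density, "density")
  stop_if_not_positive_scalar(dynamic_viscosity, "dynamic_viscosity")
  structure(
    list(
      density = density,
      dynamic_viscosity = dynamic_viscosity,
      kinematic_viscosity = dynamic_viscosity / density
    ),
    class = "fluid_properties"
  )
}

#' Standard air presets
#'
#' Two constant-property descriptions of air at ambient conditions are in
#' common use for nasal airflow work, differing only in rounding:
#'
#' * `"cfd"`: \eqn{\rho = 1.225} kg m^-3, \eqn{\mu = 1.7894 \times 10^{-5}}
#'   Pa s (giving \eqn{\nu \approx 1.4607 \times 10^{-5}} m^2 s^-1) -- the
#'   values typically used in isothermal CFD set-ups.
#' * `"rounded"`: the same density with the kinematic viscosity rounded to
#'   \eqn{\nu = 1.5 \times 10^{-5}} m^2 s^-1, the convention for quick
#'   order-of-magnitude estimates (Womersley numbers, relative hysteresis
#'   widths).
#'
#' @param preset Either `"cfd"` or `"rounded"`.
#' @return A [fluid_properties()] object.
#' @examples
#' air_properties("rounded")$kinematic_viscosity # 1.5e-5
#' @export
air_properties <- function(preset = c("cfd", "rounded")) {
  preset <- match.arg(preset)
  switch(preset,
    cfd = fluid_properties(density = 1.225, dynamic_viscosity = 1.7894e-5),
    rounded = fluid_properties(density = 1.225, dynamic_viscosity = 1.5e-5 * 1.225)
  )
}

#' @export
print.fluid_properties <- function(x, ...) {
  cat("Fluid properties\n")
  cat(sprintf("  density:             %g kg/m^3\n", x$density))
  cat(sprintf("  dynamic viscosity:   %g Pa s\n", x$dynamic_viscosity))
  cat(sprintf("  kinematic viscosity: %g m^2/s\n", x$kinematic_viscosity))
  invisible(x)
}

is_fluid_properties <- function(x) inherits(x, "fluid_properties")

as_fluid <- function(fluid) {
  if (!is_fluid_properties(fluid)) {
    stop("`fluid` must be a fluid_properties object; see fluid_properties() or air_properties()",
      call. = FALSE
    )
  }
  fluid
}
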