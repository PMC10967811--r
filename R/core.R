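#' Reynolds number for internal duct flow
#'
#' \eqn{Re = 4|Q| / (\pi \nu D_h)}, the ratio of inertial to viscous forces
#' expressed in terms of volumetric flowrate and hydraulic diameter.
#'
#' @param flowrate Volumetric flowrate(s) \eqn{Q} in m^3 s^-1 (sign is
#'   ignored). Vectorised.
#' @param duct A [duct_model()].
#' @param fluid A [fluid_properties()].
#' @return Reynolds number(s), dimensionless and non-negative.
#' @examples
#' reynolds_number(600e-6, duct_model(0.01, 0.1), air_properties("rounded"))
#' @export
reynolds_number <- function(flowrate, duct, fluid) {
  duct <- as_duct(duct)
  fluid <- as_fluid(fluid)
  stop_if_not_numeric(flowrate, "flowrate")
  4 * abs(flowrate) / (pi * fluid$kinematic_viscosity * duct$hydraulic_diameter)
}

#' Hagen-Poiseuille flow resistance
#'
#' Resistance of fully developed, steady, laminar flow in a straight duct:
#' \eqn{R = 128 L \mu / (\pi D_h^4)}. The strong (fourth-power) dependence on
#' hydraulic diameter is what makes nasal resistance so sensitive to small
#' anatomical changes.
#'
#' @inheritParams reynolds_number
#' @return Resistance in Pa s m^-3; zero iff the duct length is zero.
#' @examples
#' hagen_poiseuille_resistance(duct_model(0.01, 0.1), air_properties("cfd"))
#' @export
hagen_poiseuille_resistance <- function(duct, fluid) {
  duct <- as_duct(duct)
  fluid <- as_fluid(fluid)
  128 * duct$length * fluid$dynamic_viscosity / (pi * duct$hydraulic_diameter^4)
}

#' Combine unilateral nasal resistances
#'
#' The two nasal passages act as parallel flow channels, so the reciprocal
#' bilateral resistance is the sum of the reciprocal unilateral resistances:
#' \eqn{1/R_{bi} = 1/R_{left} + 1/R_{right}}. An occluded (unmeasured) side
#' is passed as `NA`, in which case the other side's resistance is returned
#' unchanged; zero or infinite sentinels are rejected.
#'
#' @param left,right Unilateral resistances in Pa s m^-3, each either a
#'   positive finite number or `NA` for an occluded side.
#' @return Bilateral resistance in Pa s m^-3; never exceeds the smaller of
#'   the two sides.
#' @examples
#' combine_unilateral_resistances(3, 6) # 2
#' combine_unilateral_resistances(5, NA) # 5
#' @export
combine_unilateral_resistances <- function(left, right) {
  check_side <- function(x, name) {
    if (length(x) != 1L) {
      stop(sprintf("`%s` must be a single value", name), call. = FALSE)
    }
    if (is.na(x)) {
      return(NA_real_)
    }
    if (!is.numeric(x) || !is.finite(x) || x <= 0) {
      stop(sprintf(
        "`%s` must be a positive finite resistance, or NA for an occluded side",
        name
      ), call. = FALSE)
    }
    as.numeric(x)
  }
  left <- check_side(left, "left")
  right <- check_side(right, "right")
  if (is.na(left) && is.na(right)) {
    stop("at least one side must carry a resistance", call. = FALSE)
  }
  if (is.na(left)) {
    return(right)
  }
  if (is.na(right)) {
    return(left)
  }
  1 / (1 / left + 1 / right)
}

#' Unsteady Bernoulli pressure drop through a duct
#'
#' Pressure drop of unsteady, fully developed, incompressible flow through a
#' straight rigid duct, as the sum of a friction term and an unsteady
#' inertial term:
#' \deqn{\Delta P = L\left[\frac{8\rho f_D\, Q|Q|}{\pi^2 D_h^5}
#'   + \frac{4\rho}{\pi D_h^2}\frac{\partial Q}{\partial t}\right].}
#' The friction term is written with \eqn{Q|Q|} so that friction opposes the
#' flow in both breathing directions. For the laminar (and blended) regimes
#' the laminar contribution is evaluated in its exact linear form
#' \eqn{128 L \mu Q / (\pi D_h^4)}, which is algebraically identical to the
#' \eqn{64/Re} friction factor but avoids the 0/0 evaluation at \eqn{Q = 0};
#' the steady laminar pressure-flow curve is therefore exactly the
#' Hagen-Poiseuille line through the origin.
#'
#' @param flowrate Volumetric flowrate(s) \eqn{Q} in m^3 s^-1 (signed).
#'   Vectorised.
#' @param dflow_dt Flow derivative(s) \eqn{\partial Q/\partial t} in
#'   m^3 s^-2. Recycled against `flowrate`.
#' @param duct A [duct_model()].
#' @param fluid A [fluid_properties()].
#' @param policy A [friction_policy()].
#' @return Pressure drop(s) \eqn{\Delta P} in Pa.
#' @examples
#' duct <- duct_model(0.01, 0.1)
#' air <- air_properties("cfd")
#' pressure_drop(100e-6, 0, duct, air, friction_policy("laminar"))
#' @export
pressure_drop <- function(flowrate, dflow_dt = 0, duct, fluid,
                          policy = friction_policy()) {
  duct <- as_duct(duct)
  fluid <- as_fluid(fluid)
  policy <- as_policy(policy)
  stop_if_not_numeric(flowrate, "flowrate")
  stop_if_not_numeric(dflow_dt, "dflow_dt")
  n <- max(length(flowrate), length(dflow_dt))
  q <- rep_len(flowrate, n)
  dq <- rep_len(dflow_dt, n)
  dh <- duct$hydraulic_diameter
  len <- duct$length

  # exact laminar linear law (finite at Q = 0)
  lam <- 128 * len * fluid$dynamic_viscosity * q / (pi * dh^4)
  turb <- function(q) {
    out <- numeric(length(q))
    nz <- q != 0
    if (any(nz)) {
      re <- reynolds_number(q[nz], duct, fluid)
      fd <- haaland_friction_factor(re, duct$relative_roughness)
      out[nz] <- 8 * fluid$density * len * fd * q[nz] * abs(q[nz]) / (pi^2 * dh^5)
    }
    out
  }
  friction <- switch(policy$regime,
    laminar = lam,
    turbulent = turb(q),
    blended = {
      wt <- transition_weight(reynolds_number(q, duct, fluid), policy)
      wt * lam + (1 - wt) * turb(q)
    }
  )
  unsteady <- 4 * fluid$density * len * dq / (pi * dh^2)
  friction + unsteady
}

#' Analytic hysteresis width of a sinusoidal pressure-flow loop
#'
#' For sinusoidal breathing the unsteady inertial term opens the
#' pressure-flow curve into a loop. Its width at zero flow, where the
#' friction term vanishes, is
#' \eqn{W = 8 \rho L \omega Q_{max} / (\pi D_h^2)} with
#' \eqn{\omega = 2\pi/\tau}.
#'
#' @param duct A [duct_model()].
#' @param fluid A [fluid_properties()].
#' @param protocol A [breathing_protocol()] supplying \eqn{Q_{max}} and
#'   \eqn{\tau}.
#' @return Hysteresis width in Pa (non-negative; zero iff \eqn{Q_{max} = 0}
#'   or \eqn{L = 0}).
#' @seealso [relative_hysteresis_width()], [measure_hysteresis_width()] for
#'   the empirical counterpart measured from a sampled loop.
#' @examples
#' hysteresis_width(duct_model(0.01, 0.1), air_properties("cfd"),
#'                  breathing_protocol(peak_flowrate = 600e-6, period = 5))
#' @export
hysteresis_width <- function(duct, fluid, protocol) {
  duct <- as_duct(duct)
  fluid <- as_fluid(fluid)
  protocol <- as_protocol(protocol)
  8 * fluid$density * duct$length * protocol$angular_frequency *
    protocol$peak_flowrate / (pi * duct$hydraulic_diameter^2)
}

#' Relative hysteresis width
#'
#' The hysteresis width normalised by the maximum laminar pressure drop
#' \eqn{R_{HP} Q_{max}} is independent of both channel length and peak
#' flowrate: \eqn{W_{rel} = \omega D_h^2 / (16\nu)}. It depends only on the
#' hydraulic diameter and the period of the respiratory cycle.
#'
#' @param duct A [duct_model()] or a bare hydraulic diameter in m.
#' @param protocol A [breathing_protocol()] or a bare period \eqn{\tau} in s.
#' @param fluid A [fluid_properties()].
#' @return Dimensionless relative width.
#' @examples
#' relative_hysteresis_width(0.01, 5, air_properties("rounded"))
#' @export
relative_hysteresis_width <- function(duct, protocol, fluid) {
  dh <- if (inherits(duct, "duct_model")) duct$hydraulic_diameter else duct
  stop_if_not_positive_scalar(dh, "hydraulic diameter")
  tau <- if (inherits(protocol, "breathing_protocol")) protocol$period else protocol
  stop_if_not_positive_scalar(tau, "period")
  fluid <- as_fluid(fluid)
  omega <- 2 * pi / tau
  omega * dh^2 / (16 * fluid$kinematic_viscosity)
}

#' Womersley number
#'
#' \eqn{Wo = D_h \sqrt{\pi f / (2\nu)}}, the ratio of transient inertial to
#' viscous forces in pulsatile duct flow. Flows with \eqn{Wo < 1} are
#' commonly treated as quasi-steady; restful unilateral nasal airflow sits
#' near \eqn{Wo \approx 1}, where oscillatory effects are present but not
#' dominant.
#'
#' @param hydraulic_diameter Hydraulic diameter in m, or a [duct_model()].
#' @param frequency Pulsation frequency \eqn{f} in Hz, non-negative.
#' @param fluid A [fluid_properties()].
#' @return Dimensionless Womersley number (0 iff `frequency` is 0).
#' @examples
#' womersley_number(0.005, 0.2, air_properties("rounded")) # ~0.72
#' @export
womersley_number <- function(hydraulic_diameter, frequency, fluid) {
  dh <- if (inherits(hydraulic_diameter, "duct_model")) {
    hydraulic_diameter$hydraulic_diameter
  } else {
    hydraulic_diameter
  }
  stop_if_not_positive_scalar(dh, "hydraulic_diameter")
  stop_if_not_nonnegative_scalar(frequency, "frequency")
  fluid <- as_fluid(fluid)
  dh * sqrt(pi * frequency / (2 * fluid$kinematic_viscosity))
}

#' Dimensionless characterisation of a breathing/duct configuration
#'
#' Convenience summary of the dimensionless numbers governing an RMM
#' configuration: peak Reynolds number, Womersley number at the breathing
#' frequency \eqn{f = 1/\tau}, and the relative hysteresis width.
#'
#' @param duct A [duct_model()].
#' @param fluid A [fluid_properties()].
#' @param protocol A [breathing_protocol()].
#' @return A list of class `dimensionless_numbers` with elements
#'   `reynolds_peak`, `womersley`, `relative_hysteresis_width` and
#'   `frequency`.
#' @export
dimensionless_numbers <- function(duct, fluid, protocol) {
  duct <- as_duct(duct)
  fluid <- as_fluid(fluid)
  protocol <- as_protocol(protocol)
  f <- 1 / protocol$period
  structure(
    list(
      reynolds_peak = reynolds_number(protocol$peak_flowrate, duct, fluid),
      womersley = womersley_number(duct, f, fluid),
      relative_hysteresis_width =
        relative_hysteresis_width(duct, protocol, fluid),
      frequency = f
    ),
    class = "dimensionless_numbers"
  )
}

#' @export
print.dimensionless_numbers <- function(x, ...) {
  cat("Dimensionless numbers\n")
  cat(sprintf("  peak Reynolds number:      %.4g\n", x$reynolds_peak))
  cat(sprintf("  Womersley number (f=%.3g): %.4g\n", x$frequency, x$womersley))
  cat(sprintf("  relative hysteresis width: %.4g\n", x$relative_hysteresis_width))
  invisible(x)
}
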