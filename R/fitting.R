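#' Measure the hysteresis width of a pressure-flow loop
#'
#' The hysteresis width is the separation of the two branches of the
#' pressure-flow loop at zero flow. Each zero crossing of the flowrate is
#' located and the pressure there is obtained by linear interpolation
#' between the bracketing samples; the width of a cycle is the absolute
#' difference between its two crossing pressures, and multi-cycle series
#' report the per-cycle mean.
#'
#' @param series An `rmm_series`.
#' @return An object of class `hysteresis_measurement` with elements
#'   `width` (Pa, mean over cycles), `widths` (per-cycle), and `crossings`
#'   (data frame of crossing times and interpolated pressures).
#' @seealso [hysteresis_width()] for the analytic width of a sinusoidal
#'   protocol.
#' @examples
#' ser <- generate_rmm_timeseries(
#'   duct_model(0.01, 0.1), air_properties("cfd"),
#'   protocol_preset("illustrative"), friction_policy("laminar")
#' )
#' measure_hysteresis_width(ser)$width
#' @export
measure_hysteresis_width <- function(series) {
  series <- as_rmm_series(series)
  q <- series$flow
  p <- series$pressure
  t <- series$time
  n <- length(q)

  ct <- numeric(0)
  cp <- numeric(0)
  i <- 1L
  while (i <= n) {
    if (q[i] == 0) {
      ct <- c(ct, t[i])
      cp <- c(cp, p[i])
      # skip any adjacent exact zeros (flat rest phase)
      while (i < n && q[i + 1L] == 0) i <- i + 1L
    } else if (i < n && q[i] * q[i + 1L] < 0) {
      w <- -q[i] / (q[i + 1L] - q[i])
      ct <- c(ct, t[i] + w * (t[i + 1L] - t[i]))
      cp <- c(cp, p[i] + w * (p[i + 1L] - p[i]))
    }
    i <- i + 1L
  }

  if (length(ct) < 2L) {
    stop("hysteresis width is undefined: the series has fewer than two ",
      "zero crossings of the flowrate (unidirectional or steady data)",
      call. = FALSE
    )
  }
  n_pairs <- length(ct) %/% 2L
  widths <- abs(cp[2L * seq_len(n_pairs) - 1L] - cp[2L * seq_len(n_pairs)])
  structure(
    list(
      width = mean(widths),
      widths = widths,
      crossings = data.frame(time = ct, pressure = cp)
    ),
    class = "hysteresis_measurement"
  )
}

#' @export
print.hysteresis_measurement <- function(x, ...) {
  cat(sprintf(
    "Hysteresis width: %.4g Pa (%d cycle%s, %d zero crossings)\n",
    x$width, length(x$widths), if (length(x$widths) == 1) "" else "s",
    nrow(x$crossings)
  ))
  invisible(x)
}

as_width <- function(width) {
  if (inherits(width, "hysteresis_measurement")) {
    return(width$width)
  }
  stop_if_not_nonnegative_scalar(width, "width")
  width
}

new_fit_result <- function(hydraulic_diameter, length, length_source, policy,
                           phase_scope, residual_rms, convergence, n_eval,
                           n_samples) {
  structure(
    list(
      hydraulic_diameter = hydraulic_diameter,
      length = length,
      length_source = length_source,
      policy = policy,
      phase_scope = phase_scope,
      residual_rms = residual_rms,
      convergence = convergence,
      n_eval = n_eval,
      n_samples = n_samples
    ),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat("RMM curve fit\n")
  cat(sprintf("  hydraulic diameter: %.4g mm\n", x$hydraulic_diameter * 1e3))
  cat(sprintf("  channel length:     %.4g m (%s)\n", x$length, x$length_source))
  cat(sprintf("  phase scope:        %s\n", x$phase_scope))
  cat(sprintf("  residual RMS:       %.4g Pa over %d samples\n",
              x$residual_rms, x$n_samples))
  cat(sprintf("  friction policy:    %s\n", x$policy$regime))
  invisible(x)
}

scope_samples <- function(series, phase_scope) {
  if (phase_scope == "both") {
    return(series)
  }
  series[series$phase == phase_scope, , drop = FALSE]
}

series_fluid <- function(series, fluid) {
  if (!is.null(fluid)) {
    return(as_fluid(fluid))
  }
  f <- attr(series, "fluid")
  if (is.null(f)) {
    stop("series carries no fluid properties; pass `fluid` explicitly",
      call. = FALSE
    )
  }
  f
}

# deterministic bounded scalar least squares on Dh, with an evaluation counter
minimise_dh <- function(objective, bounds, tol) {
  n_eval <- 0L
  wrapped <- function(dh) {
    n_eval <<- n_eval + 1L
    objective(dh)
  }
  opt <- stats::optimize(wrapped, interval = bounds, tol = tol)
  interior <- opt$minimum > bounds[1] + 10 * tol &&
    opt$minimum < bounds[2] - 10 * tol
  list(dh = opt$minimum, rss = opt$objective, n_eval = n_eval,
       convergence = interior)
}

#' Fit a hydraulic diameter at fixed channel length
#'
#' Fits the steady (quasi-steady) duct model to pressure-flow data by
#' adjusting the hydraulic diameter: the unsteady term is neglected and
#' \eqn{D_h} minimises the unweighted sum of squared pressure residuals of
#' [pressure_drop()] with `dflow_dt = 0` at the assumed channel length.
#' Inspiration and expiration may be fitted separately.
#'
#' @param series An `rmm_series`.
#' @param length Assumed channel length \eqn{L} in m (commonly 0.1 m).
#' @param fluid A [fluid_properties()]; defaults to the series' own.
#' @param policy A [friction_policy()].
#' @param phase_scope `"both"` (default), `"inspiration"` or `"expiration"`.
#' @param weight_by_flow If `TRUE`, residuals are weighted by \eqn{|Q|}.
#' @param bounds Search interval for \eqn{D_h} in m. Default 1-30 mm.
#' @param tol Absolute convergence tolerance on \eqn{D_h} in m.
#' @return A `fit_result` with the fitted diameter, the (fixed) length, the
#'   root-mean-square residual in Pa, a convergence flag and the number of
#'   model evaluations. Deterministic for fixed inputs.
#' @export
fit_dh_fixed_length <- function(series, length, fluid = NULL,
                                policy = friction_policy(),
                                phase_scope = c("both", "inspiration", "expiration"),
                                weight_by_flow = FALSE,
                                bounds = c(1e-3, 30e-3), tol = 1e-6) {
  series <- as_rmm_series(series)
  phase_scope <- match.arg(phase_scope)
  stop_if_not_positive_scalar(length, "length")
  policy <- as_policy(policy)
  fluid <- series_fluid(series, fluid)

  data <- scope_samples(series, phase_scope)
  if (nrow(data) < 10L) {
    stop("need at least 10 samples in the selected phase scope", call. = FALSE)
  }
  if (all(data$flow == 0)) {
    stop("degenerate input: all flowrates are zero", call. = FALSE)
  }
  w <- if (weight_by_flow) abs(data$flow) else rep(1, nrow(data))

  objective <- function(dh) {
    duct <- duct_model(dh, length)
    sum(w * (pressure_drop(data$flow, 0, duct, fluid, policy) - data$pressure)^2)
  }
  fit <- minimise_dh(objective, bounds, tol)
  new_fit_result(
    hydraulic_diameter = fit$dh, length = length, length_source = "fixed",
    policy = policy, phase_scope = phase_scope,
    residual_rms = sqrt(fit$rss / sum(w)), convergence = fit$convergence,
    n_eval = fit$n_eval, n_samples = nrow(data)
  )
}

#' Fit a hydraulic diameter constrained by the measured hysteresis width
#'
#' Eliminates the unknown channel length by combining the unsteady duct
#' model with the analytic hysteresis width: substituting
#' \eqn{L = W \pi D_h^2 / (8 \rho \omega Q_{max})} into the pressure-drop
#' model gives
#' \deqn{\Delta P = \frac{W}{\omega Q_{max}}
#'   \left(\frac{f_D\, Q|Q|}{\pi D_h^3} + \frac{1}{2}
#'   \frac{\partial Q}{\partial t}\right),}
#' which is fitted for \eqn{D_h} by least squares; the channel length is
#' then recovered from the width relation. Pass
#' `policy = friction_policy("turbulent")` to use the Haaland friction
#' factor across all flowrates (the published fitting variant).
#'
#' @param series An `rmm_series`.
#' @param protocol A [breathing_protocol()]; defaults to the series' own.
#' @param width A `hysteresis_measurement` (or a width in Pa); defaults to
#'   measuring it from the series. Must be positive.
#' @inheritParams fit_dh_fixed_length
#' @return A `fit_result`; `length` holds the recovered channel length.
#' @export
fit_dh_hysteresis_constrained <- function(series, protocol = NULL, width = NULL,
                                          fluid = NULL,
                                          policy = friction_policy(),
                                          phase_scope = c("both", "inspiration", "expiration"),
                                          weight_by_flow = FALSE,
                                          bounds = c(1e-3, 30e-3), tol = 1e-6) {
  series <- as_rmm_series(series)
  phase_scope <- match.arg(phase_scope)
  policy <- as_policy(policy)
  fluid <- series_fluid(series, fluid)
  if (is.null(protocol)) protocol <- attr(series, "protocol")
  protocol <- as_protocol(protocol)
  if (protocol$peak_flowrate <= 0) {
    stop("the protocol peak flowrate must be positive", call. = FALSE)
  }
  if (is.null(width)) width <- measure_hysteresis_width(series)
  w_pa <- as_width(width)
  if (w_pa <= 0) {
    stop("constraint is degenerate: the hysteresis width must be positive",
      call. = FALSE
    )
  }

  data <- scope_samples(series, phase_scope)
  if (nrow(data) < 10L) {
    stop("need at least 10 samples in the selected phase scope", call. = FALSE)
  }
  wts <- if (weight_by_flow) abs(data$flow) else rep(1, nrow(data))
  omega <- protocol$angular_frequency
  qmax <- protocol$peak_flowrate
  scale <- w_pa / (omega * qmax)
  nu <- fluid$kinematic_viscosity

  friction_term <- function(dh) {
    q <- data$flow
    # laminar part in its exact linear form: (64/Re) |Q| = 16 pi nu Dh
    lam <- 16 * nu * q / dh^2
    turb <- numeric(length(q))
    nz <- q != 0
    if (any(nz) && policy$regime != "laminar") {
      re <- 4 * abs(q[nz]) / (pi * nu * dh)
      fd <- haaland_friction_factor(re, 0)
      turb[nz] <- fd * q[nz] * abs(q[nz]) / (pi * dh^3)
    }
    switch(policy$regime,
      laminar = lam,
      turbulent = turb,
      blended = {
        wt <- transition_weight(4 * abs(q) / (pi * nu * dh), policy)
        wt * lam + (1 - wt) * turb
      }
    )
  }
  objective <- function(dh) {
    model <- scale * (friction_term(dh) + 0.5 * data$dflow_dt)
    sum(wts * (model - data$pressure)^2)
  }
  fit <- minimise_dh(objective, bounds, tol)
  len <- channel_length_from_width(w_pa, fit$dh, protocol, fluid)
  new_fit_result(
    hydraulic_diameter = fit$dh, length = len, length_source = "recovered",
    policy = policy, phase_scope = phase_scope,
    residual_rms = sqrt(fit$rss / sum(wts)), convergence = fit$convergence,
    n_eval = fit$n_eval, n_samples = nrow(data)
  )
}

#' Channel length implied by a hysteresis width
#'
#' Inverts the analytic width relation:
#' \eqn{L = W \pi D_h^2 / (8 \rho \omega Q_{max})}. Round-trips with
#' [hysteresis_width()] to machine precision.
#'
#' @param width Hysteresis width in Pa (or a `hysteresis_measurement`).
#' @param hydraulic_diameter Hydraulic diameter in m.
#' @param protocol A [breathing_protocol()] (supplies \eqn{\omega} and
#'   \eqn{Q_{max}}; the peak flowrate must be positive).
#' @param fluid A [fluid_properties()].
#' @return Channel length in m.
#' @examples
#' air <- air_properties("cfd")
#' pr <- protocol_preset("illustrative")
#' w <- hysteresis_width(duct_model(0.01, 0.1), air, pr)
#' channel_length_from_width(w, 0.01, pr, air) # 0.1
#' @export
channel_length_from_width <- function(width, hydraulic_diameter, protocol,
                                      fluid) {
  w_pa <- as_width(width)
  stop_if_not_positive_scalar(hydraulic_diameter, "hydraulic_diameter")
  protocol <- as_protocol(protocol)
  fluid <- as_fluid(fluid)
  if (protocol$peak_flowrate <= 0) {
    stop("channel length is undefined for a zero peak flowrate", call. = FALSE)
  }
  w_pa * pi * hydraulic_diameter^2 /
    (8 * fluid$density * protocol$angular_frequency * protocol$peak_flowrate)
}

#' Flow resistance at a reference flowrate
#'
#' \eqn{R = \Delta P(Q_{ref}) / Q_{ref}}, with the pressure read off the
#' selected branch of the sampled curve by linear interpolation in flow.
#' For a steady laminar curve the result is independent of the reference
#' flowrate.
#'
#' @param series An `rmm_series`.
#' @param flowrate_ref Reference flowrate in m^3 s^-1; nonzero, same sign as
#'   the sampled branch, and within the sampled flow range.
#' @param branch Which loop branch to interpolate along: `"accelerating"`
#'   (default) or `"decelerating"`.
#' @return Resistance in Pa s m^-3.
#' @export
resistance_at <- function(series, flowrate_ref,
                          branch = c("accelerating", "decelerating")) {
  series <- as_rmm_series(series)
  branch <- match.arg(branch)
  if (!is.numeric(flowrate_ref) || length(flowrate_ref) != 1L ||
    !is.finite(flowrate_ref) || flowrate_ref == 0) {
    stop("resistance is undefined at zero flow; `flowrate_ref` must be a ",
      "single nonzero flowrate",
      call. = FALSE
    )
  }
  sel <- series$subphase == branch & sign(series$flow) == sign(flowrate_ref)
  data <- series[sel, , drop = FALSE]
  if (nrow(data) < 2L) {
    stop("the selected branch holds fewer than two samples of that flow sign",
      call. = FALSE
    )
  }
  if (abs(flowrate_ref) > max(abs(data$flow))) {
    stop(sprintf(
      "`flowrate_ref` (%g mL/s) lies outside the sampled flow range (max %g mL/s)",
      flowrate_ref * 1e6, max(abs(data$flow)) * 1e6
    ), call. = FALSE)
  }
  p_ref <- stats::approx(data$flow, data$pressure,
    xout = flowrate_ref,
    ties = mean, rule = 1
  )$y
  if (is.na(p_ref)) {
    stop("`flowrate_ref` lies outside the sampled flow range", call. = FALSE)
  }
  p_ref / flowrate_ref
}
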