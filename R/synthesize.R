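#' Measurement-noise model for synthetic RMM data
#'
#' Emulates the scatter seen in clinical rhinomanometry recordings with two
#' mechanisms: additive Gaussian noise on each pressure sample (transducer
#' noise), and a breath-to-breath multiplicative jitter of the hydraulic
#' diameter (a crude stand-in for the nasal cycle and posture/mucosal
#' variability between breaths; the diameter is resampled once per cycle).
#'
#' @param pressure_sd Standard deviation of additive pressure noise in Pa,
#'   non-negative. Default 0 (off).
#' @param dh_jitter_cv Coefficient of variation of the per-breath hydraulic
#'   diameter, non-negative. Each cycle uses
#'   \eqn{D_h (1 + cv \cdot z)} with \eqn{z \sim N(0,1)}, truncated to stay
#'   positive. Default 0 (off).
#' @param seed Integer RNG seed; identical seed and parameters give
#'   identical output. Required whenever either noise source is active.
#' @return An object of class `noise_model`.
#' @examples
#' noise_model(pressure_sd = 0.05, seed = 42)
#' @export
noise_model <- function(pressure_sd = 0, dh_jitter_cv = 0, seed = NULL) {
  stop_if_not_nonnegative_scalar(pressure_sd, "pressure_sd")
  stop_if_not_nonnegative_scalar(dh_jitter_cv, "dh_jitter_cv")
  active <- pressure_sd > 0 || dh_jitter_cv > 0
  if (active && is.null(seed)) {
    stop("a `seed` is required when any noise source is active", call. = FALSE)
  }
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || seed != round(seed)) {
      stop("`seed` must be a single integer", call. = FALSE)
    }
    seed <- as.integer(seed)
  }
  structure(
    list(pressure_sd = pressure_sd, dh_jitter_cv = dh_jitter_cv, seed = seed),
    class = "noise_model"
  )
}

noise_is_active <- function(noise) {
  !is.null(noise) && (noise$pressure_sd > 0 || noise$dh_jitter_cv > 0)
}

new_rmm_series <- function(samples, side, duct = NULL, fluid = NULL,
                           protocol = NULL, policy = NULL, noise = NULL,
                           sampling_rate = NULL, inspiration_sign = -1) {
  structure(samples,
    side = side, duct = duct, fluid = fluid, protocol = protocol,
    policy = policy, noise = noise, sampling_rate = sampling_rate,
    inspiration_sign = inspiration_sign,
    class = c("rmm_series", "data.frame")
  )
}

#' @export
print.rmm_series <- function(x, ...) {
  cat(sprintf(
    "RMM time series: %d samples, side = %s, t in [%g, %g] s\n",
    nrow(x), attr(x, "side"), min(x$time), max(x$time)
  ))
  cat(sprintf(
    "  flow in [%g, %g] mL/s, pressure in [%g, %g] Pa\n",
    min(x$flow) * 1e6, max(x$flow) * 1e6, min(x$pressure), max(x$pressure)
  ))
  invisible(x)
}

label_phase <- function(flow, dflow_dt, inspiration_sign) {
  s <- sign(flow)
  # zero-flow samples belong to the phase the flow is entering
  s[s == 0] <- sign(dflow_dt[s == 0])
  ifelse(s == inspiration_sign, "inspiration", "expiration")
}

label_subphase <- function(flow, dflow_dt) {
  # |Q| increasing = accelerating branch; Q = 0 turns are accelerating
  ifelse(flow * dflow_dt >= 0, "accelerating", "decelerating")
}

#' Generate a synthetic RMM time series
#'
#' Samples the protocol waveform on a uniform time grid and computes each
#' sample's differential pressure with the unsteady Bernoulli duct model
#' ([pressure_drop()]), using the analytic flow derivative. With noise off,
#' the (Q, dP) trajectory over each full period is a closed loop; with noise
#' on, the output is reproducible from the noise model's seed.
#'
#' @param duct A [duct_model()].
#' @param fluid A [fluid_properties()].
#' @param protocol A [breathing_protocol()].
#' @param policy A [friction_policy()].
#' @param sampling_rate Samples per second; must give at least 50 samples
#'   per cycle. Default 1000 samples per cycle, which keeps interpolation
#'   error in width measurement far below 1%.
#' @param noise A [noise_model()] or `NULL` for a noise-free series.
#' @param side `"right"` or `"left"` nasal passage label.
#' @param include_unsteady Set `FALSE` to drop the unsteady inertial term;
#'   the loop then collapses to a single-valued steady curve through the
#'   origin (useful as a quasi-steady reference).
#' @return An `rmm_series`: a data frame with columns `time` (s), `flow`
#'   (m^3 s^-1), `dflow_dt` (m^3 s^-2), `pressure` (Pa), `phase`
#'   (inspiration/expiration) and `subphase` (accelerating/decelerating),
#'   carrying the generating objects as attributes.
#' @examples
#' ser <- generate_rmm_timeseries(
#'   duct_model(0.01, 0.1), air_properties("cfd"),
#'   protocol_preset("illustrative")
#' )
#' head(ser)
#' @export
generate_rmm_timeseries <- function(duct, fluid, protocol,
                                    policy = friction_policy(),
                                    sampling_rate = NULL, noise = NULL,
                                    side = c("right", "left"),
                                    include_unsteady = TRUE) {
  duct <- as_duct(duct)
  fluid <- as_fluid(fluid)
  protocol <- as_protocol(protocol)
  policy <- as_policy(policy)
  side <- match.arg(side)
  if (!is.null(noise) && !inherits(noise, "noise_model")) {
    stop("`noise` must be a noise_model object or NULL", call. = FALSE)
  }
  if (is.null(sampling_rate)) sampling_rate <- 1000 / protocol$period
  stop_if_not_positive_scalar(sampling_rate, "sampling_rate")
  if (sampling_rate * protocol$period < 50) {
    stop("insufficient sampling resolution: need at least 50 samples per cycle",
      call. = FALSE
    )
  }

  n_per_cycle <- round(sampling_rate * protocol$period)
  n <- n_per_cycle * protocol$n_cycles + 1L
  t <- protocol$phase_offset +
    (seq_len(n) - 1L) / sampling_rate
  wf <- waveform_flow(t, protocol)
  dq <- if (include_unsteady) wf$dflow_dt else rep(0, n)

  gen <- function() {
    cycle <- pmin(
      floor((t - protocol$phase_offset) / protocol$period),
      protocol$n_cycles - 1L
    )
    dh_cycle <- rep(duct$hydraulic_diameter, protocol$n_cycles)
    if (!is.null(noise) && noise$dh_jitter_cv > 0) {
      z <- stats::rnorm(protocol$n_cycles)
      dh_cycle <- duct$hydraulic_diameter *
        pmax(1 + noise$dh_jitter_cv * z, 0.05)
    }
    p <- numeric(n)
    for (k in seq_len(protocol$n_cycles)) {
      sel <- cycle == (k - 1L)
      duct_k <- duct_model(dh_cycle[k], duct$length, duct$relative_roughness)
      p[sel] <- pressure_drop(wf$flow[sel], dq[sel], duct_k, fluid, policy)
    }
    if (!is.null(noise) && noise$pressure_sd > 0) {
      p <- p + stats::rnorm(n, sd = noise$pressure_sd)
    }
    p
  }
  p <- if (noise_is_active(noise)) with_seed(noise$seed, gen()) else gen()

  samples <- data.frame(
    time = t, flow = wf$flow, dflow_dt = dq, pressure = p,
    phase = label_phase(wf$flow, wf$dflow_dt, protocol$inspiration_sign),
    subphase = label_subphase(wf$flow, wf$dflow_dt),
    stringsAsFactors = FALSE
  )
  new_rmm_series(samples,
    side = side, duct = duct, fluid = fluid,
    protocol = protocol, policy = policy, noise = noise,
    sampling_rate = sampling_rate,
    inspiration_sign = protocol$inspiration_sign
  )
}

#' Map an RMM series to the clinical four-quadrant chart
#'
#' Clinical pressure-flow charts place each (side, phase) combination in its
#' own quadrant: right-side inspiration upper-right, left-side inspiration
#' lower-right, right-side expiration lower-left, left-side expiration
#' upper-left. This is implemented as
#' `x = phase_sign * |dP|` (inspiration +, expiration -) and
#' `y = side_sign * phase_sign * |Q|` (right +, left -), so magnitudes of
#' pressure and flow are preserved and the (side, phase) to quadrant mapping
#' is a bijection.
#'
#' @param series An `rmm_series` (see [generate_rmm_timeseries()] or
#'   [read_rmm_csv()]) with a side label.
#' @return A data frame of class `pressure_flow_curve` with columns `x`
#'   (signed pressure, Pa), `y` (signed flow, m^3 s^-1), `phase`, `subphase`
#'   and `side`.
#' @export
to_clinical_quadrants <- function(series) {
  series <- as_rmm_series(series)
  side <- attr(series, "side")
  if (is.null(side) || !side %in% c("left", "right")) {
    stop("series carries no side label; set side to \"left\" or \"right\"",
      call. = FALSE
    )
  }
  phase_sign <- ifelse(series$phase == "inspiration", 1, -1)
  side_sign <- if (side == "right") 1 else -1
  structure(
    data.frame(
      x = phase_sign * abs(series$pressure),
      y = side_sign * phase_sign * abs(series$flow),
      phase = series$phase,
      subphase = series$subphase,
      side = side,
      stringsAsFactors = FALSE
    ),
    class = c("pressure_flow_curve", "data.frame")
  )
}

as_rmm_series <- function(series) {
  if (!inherits(series, "rmm_series")) {
    stop("expected an rmm_series object; see generate_rmm_timeseries() or read_rmm_csv()",
      call. = FALSE
    )
  }
  required <- c("time", "flow", "dflow_dt", "pressure", "phase", "subphase")
  missing <- setdiff(required, names(series))
  if (length(missing)) {
    stop(
      "rmm_series is missing columns: ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  if (nrow(series) < 2L) {
    stop("rmm_series must contain at least two samples", call. = FALSE)
  }
  series
}
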