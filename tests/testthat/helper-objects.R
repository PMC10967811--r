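# shared fixtures, built in code

air_cfd <- air_properties("cfd")
air_rounded <- air_properties("rounded")
duct_10mm <- duct_model(hydraulic_diameter = 0.01, length = 0.1)
proto_sine <- protocol_preset("illustrative")
laminar <- friction_policy("laminar")
turbulent <- friction_policy("turbulent")
blended <- friction_policy()

# hand-assemble an rmm_series from raw sample vectors (bypasses the
# generator so interpolation logic can be tested against hand arithmetic)
manual_series <- function(time, flow, pressure, side = "right",
                          phase = NULL, subphase = NULL) {
  dq <- rep(0, length(flow))
  if (is.null(phase)) {
    phase <- ifelse(flow <= 0, "inspiration", "expiration")
  }
  if (is.null(subphase)) subphase <- rep("accelerating", length(flow))
  structure(
    data.frame(
      time = time, flow = flow, dflow_dt = dq, pressure = pressure,
      phase = phase, subphase = subphase, stringsAsFactors = FALSE
    ),
    side = side, fluid = air_cfd, inspiration_sign = -1,
    class = c("rmm_series", "data.frame")
  )
}

sine_loop <- function(dh = 0.01, len = 0.1, qmax = 600e-6, tau = 5,
                      policy = laminar, fluid = air_cfd, ...) {
  generate_rmm_timeseries(
    duct_model(dh, len), fluid,
    breathing_protocol("sine", qmax, tau),
    policy, ...
  )
}
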