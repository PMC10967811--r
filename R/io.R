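#' Write an RMM time series to CSV
#'
#' Plain comma-separated UTF-8 with a mandatory header whose flow column
#' token declares the unit: `time_s, flow_mL_s (or flow_m3_s), pressure_Pa,
#' side, phase`. Numbers are written in the shortest representation that
#' round-trips a double (R's default `format(..., digits = 17)` trimmed), so
#' written and re-read values are bit-identical.
#'
#' @param series An `rmm_series`.
#' @param path Output file path.
#' @param flow_unit `"mL_s"` (default, the clinical convention) or `"m3_s"`.
#' @return The path, invisibly.
#' @export
write_rmm_csv <- function(series, path, flow_unit = c("mL_s", "m3_s")) {
  series <- as_rmm_series(series)
  flow_unit <- match.arg(flow_unit)
  scale <- if (flow_unit == "mL_s") 1e6 else 1
  fmt <- function(x) vapply(x, format, "", digits = 17)
  out <- data.frame(
    time_s = fmt(series$time),
    flow = fmt(series$flow * scale),
    pressure_Pa = fmt(series$pressure),
    side = attr(series, "side"),
    phase = series$phase,
    stringsAsFactors = FALSE
  )
  names(out)[2] <- paste0("flow_", flow_unit)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

central_differences <- function(t, x) {
  n <- length(x)
  d <- numeric(n)
  if (n >= 3L) {
    d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
  }
  d[1] <- (x[2] - x[1]) / (t[2] - t[1])
  d[n] <- (x[n] - x[n - 1]) / (t[n] - t[n - 1])
  d
}

#' Read an RMM time series from CSV
#'
#' Reads the schema written by [write_rmm_csv()]: columns `time_s`, `flow`
#' with its unit declared in the header token (`flow_mL_s` or `flow_m3_s`),
#' `pressure_Pa`, `side`, and `phase`. Flow is normalised to SI
#' (m^3 s^-1). The flow derivative is reconstructed by central finite
#' differences (one-sided at the edges). Rows whose `phase` is `"auto"` are
#' labelled from the flow sign using `inspiration_sign`. Malformed numeric
#' fields and non-increasing time stamps are reported with their line
#' numbers.
#'
#' @param path CSV file path.
#' @param inspiration_sign Flow sign treated as inspiration when phase is
#'   `"auto"`: `-1` (default, the convention in which negative flowrates
#'   indicate inhalation) or `+1`.
#' @return An `rmm_series`.
#' @export
read_rmm_csv <- function(path, inspiration_sign = -1) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  if (!inspiration_sign %in% c(-1, 1)) {
    stop("`inspiration_sign` must be +1 or -1", call. = FALSE)
  }
  raw <- utils::read.csv(path,
    stringsAsFactors = FALSE, colClasses = "character",
    fileEncoding = "UTF-8"
  )
  flow_col <- grep("^flow_", names(raw), value = TRUE)
  if (!"time_s" %in% names(raw) || length(flow_col) != 1L ||
    !"pressure_Pa" %in% names(raw)) {
    stop("schema error: header must contain time_s, flow_<unit> ",
      "(flow_mL_s or flow_m3_s) and pressure_Pa",
      call. = FALSE
    )
  }
  unit <- sub("^flow_", "", flow_col)
  if (!unit %in% c("mL_s", "m3_s")) {
    stop(sprintf("schema error: unknown flow unit token '%s'", flow_col),
      call. = FALSE
    )
  }
  if (!"side" %in% names(raw)) {
    stop("schema error: missing 'side' column", call. = FALSE)
  }
  if (!"phase" %in% names(raw)) raw$phase <- "auto"

  parse_num <- function(col, name) {
    x <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(x))
    if (length(bad)) {
      stop(sprintf(
        "malformed value in column '%s' at line %d: '%s'",
        name, bad[1] + 1L, col[bad[1]]
      ), call. = FALSE)
    }
    x
  }
  t <- parse_num(raw$time_s, "time_s")
  q <- parse_num(raw[[flow_col]], flow_col)
  p <- parse_num(raw$pressure_Pa, "pressure_Pa")
  if (unit == "mL_s") q <- q / 1e6

  side <- unique(raw$side)
  if (length(side) != 1L || !side %in% c("left", "right")) {
    stop("side column must hold a single value, 'left' or 'right'",
      call. = FALSE
    )
  }
  if (length(t) < 2L) {
    stop("need at least two samples", call. = FALSE)
  }
  non_mono <- which(diff(t) <= 0)
  if (length(non_mono)) {
    stop(sprintf(
      "ordering error: time is not strictly increasing at line %d",
      non_mono[1] + 2L
    ), call. = FALSE)
  }

  dq <- central_differences(t, q)
  phase <- raw$phase
  auto <- phase == "auto"
  if (any(auto)) {
    phase[auto] <- label_phase(q[auto], dq[auto], inspiration_sign)
  }
  bad_phase <- which(!phase %in% c("inspiration", "expiration"))
  if (length(bad_phase)) {
    stop(sprintf(
      "labelling error: invalid phase '%s' at line %d",
      phase[bad_phase[1]], bad_phase[1] + 1L
    ), call. = FALSE)
  }

  samples <- data.frame(
    time = t, flow = q, dflow_dt = dq, pressure = p,
    phase = phase, subphase = label_subphase(q, dq),
    stringsAsFactors = FALSE
  )
  new_rmm_series(samples, side = side, inspiration_sign = inspiration_sign)
}

#' Read per-cell CFD summaries from CSV
#'
#' Expects columns `y` (wall distance, m), `epsilon` (turbulent dissipation
#' rate, m^2 s^-3) and either `cell_volume` (m^3) or `dx` (characteristic
#' cell size, m; converted as `cell_volume = dx^3`); optional columns `u`
#' (velocity magnitude, m s^-1) and `tau_w` (wall shear stress, Pa) are
#' passed through.
#'
#' @param path CSV file path.
#' @return A data frame suitable for [resolution_report()].
#' @export
read_cell_csv <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  cells <- utils::read.csv(path, stringsAsFactors = FALSE,
                           fileEncoding = "UTF-8")
  if (!"cell_volume" %in% names(cells)) {
    if (!"dx" %in% names(cells)) {
      stop("schema error: need a 'cell_volume' or 'dx' column", call. = FALSE)
    }
    cells$cell_volume <- cells$dx^3
  }
  missing <- setdiff(c("y", "epsilon"), names(cells))
  if (length(missing)) {
    stop("schema error: missing columns ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  cells
}

#' Run configuration
#'
#' A reproducible description of a simulate/measure/fit run: fluid preset
#' (or explicit properties), duct geometry, breathing protocol, friction
#' policy, sampling rate, noise, and fit/diagnostics options. Serialises
#' losslessly to YAML via [write_run_config()] / [read_run_config()].
#'
#' @param fluid_preset `"cfd"` or `"rounded"`; ignored if `density` and
#'   `dynamic_viscosity` are both given.
#' @param density,dynamic_viscosity Optional explicit fluid properties (SI).
#' @param hydraulic_diameter,length,relative_roughness Duct geometry (SI).
#' @param waveform,peak_flowrate,period,phase_offset,n_cycles Breathing
#'   protocol (SI units; see [breathing_protocol()]).
#' @param friction `"blended"`, `"laminar"` or `"turbulent"`.
#' @param sampling_rate Samples per second, or `NULL` for 1000 per cycle.
#' @param pressure_noise_sd,dh_jitter_cv,seed Noise model (see
#'   [noise_model()]).
#' @param side `"right"` or `"left"`.
#' @param fit_mode `"fixed_length"` or `"hysteresis_constrained"`.
#' @param fit_length Assumed channel length for the fixed-length fit, m.
#' @param phase_scope `"both"`, `"inspiration"` or `"expiration"`.
#' @param dt Diagnostics time step, s.
#' @param bin_width Diagnostics histogram bin width.
#' @return A list of class `run_config`.
#' @export
run_config <- function(fluid_preset = "cfd", density = NULL,
                       dynamic_viscosity = NULL,
                       hydraulic_diameter = 0.01, length = 0.1,
                       relative_roughness = 0,
                       waveform = "sine", peak_flowrate = 600e-6, period = 5,
                       phase_offset = 0, n_cycles = 1,
                       friction = "blended", sampling_rate = NULL,
                       pressure_noise_sd = 0, dh_jitter_cv = 0, seed = NULL,
                       side = "right",
                       fit_mode = "fixed_length", fit_length = 0.1,
                       phase_scope = "both",
                       dt = 1e-5, bin_width = 0.1) {
  cfg <- list(
    fluid_preset = fluid_preset, density = density,
    dynamic_viscosity = dynamic_viscosity,
    hydraulic_diameter = hydraulic_diameter, length = length,
    relative_roughness = relative_roughness,
    waveform = waveform, peak_flowrate = peak_flowrate, period = period,
    phase_offset = phase_offset, n_cycles = n_cycles,
    friction = friction, sampling_rate = sampling_rate,
    pressure_noise_sd = pressure_noise_sd, dh_jitter_cv = dh_jitter_cv,
    seed = seed, side = side,
    fit_mode = fit_mode, fit_length = fit_length, phase_scope = phase_scope,
    dt = dt, bin_width = bin_width
  )
  # validate eagerly by building the objects once
  config_objects(structure(cfg, class = "run_config"))
  structure(cfg, class = "run_config")
}

#' Materialise the model objects described by a run configuration
#'
#' @param config A [run_config()].
#' @return A list with elements `fluid`, `duct`, `protocol`, `policy`,
#'   `noise`, `side` and `sampling_rate`.
#' @export
config_objects <- function(config) {
  if (!inherits(config, "run_config")) {
    stop("`config` must be a run_config object", call. = FALSE)
  }
  fluid <- if (!is.null(config$density) && !is.null(config$dynamic_viscosity)) {
    fluid_properties(config$density, config$dynamic_viscosity)
  } else {
    air_properties(config$fluid_preset)
  }
  list(
    fluid = fluid,
    duct = duct_model(
      config$hydraulic_diameter, config$length,
      config$relative_roughness
    ),
    protocol = breathing_protocol(
      config$waveform, config$peak_flowrate,
      config$period, config$phase_offset, config$n_cycles
    ),
    policy = friction_policy(config$friction),
    noise = noise_model(config$pressure_noise_sd, config$dh_jitter_cv,
      seed = config$seed
    ),
    side = config$side,
    sampling_rate = config$sampling_rate
  )
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  if (!inherits(config, "run_config")) {
    stop("`config` must be a run_config object", call. = FALSE)
  }
  yaml::write_yaml(unclass(config), path, precision = 17)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw[!vapply(raw, is.null, logical(1))])
}
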