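#' Dimensionless wall distance (wall units)
#'
#' \eqn{y^+ = u_\tau y / \nu} with the shear velocity
#' \eqn{u_\tau = \sqrt{\tau_w / \rho}}. Used to judge whether near-wall grid
#' cells sit in the viscous sublayer, buffer layer or log layer.
#'
#' @param wall_shear_stress Wall shear stress(es) \eqn{\tau_w} in Pa,
#'   non-negative. Vectorised.
#' @param wall_distance Wall distance(s) \eqn{y} in m, non-negative.
#'   Recycled against `wall_shear_stress`.
#' @param fluid A [fluid_properties()].
#' @return Dimensionless \eqn{y^+} value(s); 0 where \eqn{\tau_w} or
#'   \eqn{y} is 0.
#' @examples
#' y_plus(0.049, 5e-5, air_properties("cfd"))
#' @export
y_plus <- function(wall_shear_stress, wall_distance, fluid) {
  fluid <- as_fluid(fluid)
  stop_if_not_numeric(wall_shear_stress, "wall_shear_stress")
  stop_if_not_numeric(wall_distance, "wall_distance")
  if (any(wall_shear_stress < 0)) {
    stop("`wall_shear_stress` must be non-negative", call. = FALSE)
  }
  if (any(wall_distance < 0)) {
    stop("`wall_distance` must be non-negative", call. = FALSE)
  }
  sqrt(wall_shear_stress / fluid$density) * wall_distance /
    fluid$kinematic_viscosity
}

#' Law of the wall
#'
#' The universal near-wall velocity profile: \eqn{u^+ = y^+} in the viscous
#' sublayer (\eqn{y^+ \le 5}) and
#' \eqn{u^+ = (1/0.41)\ln y^+ + 5} in the log layer (\eqn{y^+ \ge 35}). The
#' buffer layer in between follows neither law; here it is filled by linear
#' interpolation in \eqn{\ln y^+} between the two laws' values at the layer
#' bounds, and flagged explicitly -- near-wall cells in this range
#' misrepresent wall shear stress and should be avoided.
#'
#' @param y_plus Dimensionless wall distance(s), non-negative. Vectorised.
#' @return A data frame with columns `y_plus`, `u_plus` and `layer`
#'   (`"viscous"`, `"buffer"` or `"log"`).
#' @examples
#' law_of_wall(c(1, 5, 20, 100))
#' @export
law_of_wall <- function(y_plus) {
  stop_if_not_numeric(y_plus, "y_plus")
  if (any(y_plus < 0)) {
    stop("`y_plus` must be non-negative", call. = FALSE)
  }
  kappa <- 0.41
  b <- 5
  log_law <- function(yp) log(yp) / kappa + b
  u_lo <- 5                 # linear law at y+ = 5
  u_hi <- log_law(35)       # log law at y+ = 35
  u_plus <- ifelse(y_plus <= 5, y_plus,
    ifelse(y_plus >= 35, log_law(pmax(y_plus, 35)),
      u_lo + (u_hi - u_lo) * (log(y_plus) - log(5)) / (log(35) - log(5))
    )
  )
  layer <- ifelse(y_plus <= 5, "viscous",
    ifelse(y_plus >= 35, "log", "buffer")
  )
  data.frame(y_plus = y_plus, u_plus = u_plus, layer = layer,
             stringsAsFactors = FALSE)
}

#' Courant-Friedrichs-Lewy (CFL) number
#'
#' \eqn{CFL = u \Delta t / \Delta x}: the distance advected during one time
#' step relative to the grid size. Values near or below 1 are the usual
#' target for scale-resolving transient simulation.
#'
#' @param velocity Flow speed(s) \eqn{u} in m s^-1, non-negative. Vectorised.
#' @param dt Time step \eqn{\Delta t} in s, positive.
#' @param dx Characteristic grid size(s) \eqn{\Delta x} in m, positive.
#' @return Dimensionless CFL number(s).
#' @examples
#' cfl_number(2, 1e-5, 2e-4) # 0.1
#' @export
cfl_number <- function(velocity, dt, dx) {
  stop_if_not_numeric(velocity, "velocity")
  if (any(velocity < 0)) stop("`velocity` must be non-negative", call. = FALSE)
  stop_if_not_positive_scalar(dt, "dt")
  stop_if_not_numeric(dx, "dx")
  if (any(dx <= 0)) stop("`dx` must be positive", call. = FALSE)
  velocity * dt / dx
}

#' Kolmogorov microscales
#'
#' The smallest turbulent length and time scales,
#' \eqn{\eta = (\nu^3/\epsilon)^{1/4}} and
#' \eqn{\tau_\eta = (\nu/\epsilon)^{1/2}}, computed from the kinematic
#' viscosity and the turbulent dissipation rate. The identity
#' \eqn{\tau_\eta = \eta^2/\nu} holds exactly. Cells with
#' \eqn{\epsilon = 0} are laminar and the scales are undefined there; such
#' entries are returned as `NA` (an explicit laminar marker), and negative
#' dissipation rates are rejected.
#'
#' @param dissipation_rate Turbulent dissipation rate(s) \eqn{\epsilon} in
#'   m^2 s^-3, non-negative. Vectorised.
#' @param fluid A [fluid_properties()].
#' @return A data frame with columns `eta` (m) and `tau_eta` (s); `NA` rows
#'   mark laminar (\eqn{\epsilon = 0}) input.
#' @examples
#' kolmogorov_scales(1, air_properties("rounded"))
#' @export
kolmogorov_scales <- function(dissipation_rate, fluid) {
  fluid <- as_fluid(fluid)
  stop_if_not_numeric(dissipation_rate, "dissipation_rate")
  if (any(dissipation_rate < 0)) {
    stop("Kolmogorov scales are undefined for negative dissipation rates",
      call. = FALSE
    )
  }
  nu <- fluid$kinematic_viscosity
  eta <- ifelse(dissipation_rate > 0, (nu^3 / dissipation_rate)^0.25, NA_real_)
  tau_eta <- ifelse(dissipation_rate > 0, sqrt(nu / dissipation_rate), NA_real_)
  data.frame(eta = eta, tau_eta = tau_eta)
}

#' WALE subgrid mixing length
#'
#' The subgrid length scale of the wall-adapting local eddy-viscosity LES
#' closure: \eqn{l_{LES} = \min(\kappa y,\ 0.325\,\Delta)}, where
#' \eqn{\kappa = 0.4187} is the von Karman constant, \eqn{y} the wall
#' distance and \eqn{\Delta} the cube root of the grid-cell volume.
#'
#' @param wall_distance Wall distance(s) \eqn{y} in m, non-negative.
#'   Vectorised.
#' @param cell_volume Grid cell volume(s) in m^3, positive. Recycled.
#' @param kappa Von Karman constant. Default 0.4187.
#' @return Mixing length(s) in m.
#' @examples
#' les_mixing_length(1e-4, 1e-9) # capped by kappa * y here
#' @export
les_mixing_length <- function(wall_distance, cell_volume, kappa = 0.4187) {
  stop_if_not_numeric(wall_distance, "wall_distance")
  stop_if_not_numeric(cell_volume, "cell_volume")
  if (any(wall_distance < 0)) {
    stop("`wall_distance` must be non-negative", call. = FALSE)
  }
  if (any(cell_volume <= 0)) {
    stop("`cell_volume` must be positive", call. = FALSE)
  }
  pmin(kappa * wall_distance, 0.325 * cell_volume^(1 / 3))
}

ratio_histogram <- function(ratios, bin_width) {
  top <- max(ratios, 1)
  breaks <- seq(0, (floor(top / bin_width) + 1) * bin_width, by = bin_width)
  counts <- as.vector(table(cut(ratios, breaks,
    include.lowest = TRUE,
    right = FALSE
  )))
  data.frame(
    bin_lower = breaks[-length(breaks)],
    bin_upper = breaks[-1],
    count = counts
  )
}

#' LES resolution report from per-cell summaries
#'
#' Audits the spatial and temporal resolution of a scale-resolving
#' simulation by comparing, cell by cell, the WALE subgrid mixing length to
#' the Kolmogorov length scale (\eqn{l_{LES}/\eta}) and the time step to the
#' Kolmogorov time scale (\eqn{\Delta t/\tau_\eta}). Ratios at or below 1
#' indicate near-DNS resolution. The report holds histograms of both ratios
#' and the fraction of cells exceeding 1 (the under-resolution metric).
#' Cells with zero dissipation rate are laminar: they are excluded from the
#' ratios and reported as a separate count, never treated as ratio 0.
#'
#' @param cells A data frame with columns `y` (wall distance, m),
#'   `cell_volume` (m^3) and `epsilon` (turbulent dissipation rate,
#'   m^2 s^-3); a `u` (velocity) column is accepted and ignored here.
#' @param dt Simulation time step in s, positive.
#' @param fluid A [fluid_properties()].
#' @param bin_width Histogram bin width for the ratios. 0.1 by default;
#'   0.01 gives the finer view.
#' @return An object of class `resolution_report`: a list with
#'   `length_hist` and `time_hist` (bin edges and counts),
#'   `length_exceedance` and `time_exceedance` (fractions of included cells
#'   with ratio > 1), `n_included`, `n_laminar`, and the per-cell `ratios`.
#' @examples
#' cells <- data.frame(y = 1e-4, cell_volume = 1e-12, epsilon = c(0.5, 2, 0))
#' resolution_report(cells, dt = 1e-5, air_properties("cfd"))
#' @export
resolution_report <- function(cells, dt, fluid, bin_width = 0.1) {
  if (!is.data.frame(cells) || nrow(cells) == 0L) {
    stop("`cells` must be a non-empty data frame of per-cell summaries",
      call. = FALSE
    )
  }
  required <- c("y", "cell_volume", "epsilon")
  missing <- setdiff(required, names(cells))
  if (length(missing)) {
    stop("`cells` is missing columns: ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  stop_if_not_positive_scalar(dt, "dt")
  stop_if_not_positive_scalar(bin_width, "bin_width")
  fluid <- as_fluid(fluid)
  if (any(cells$epsilon < 0)) {
    stop("`epsilon` must be non-negative", call. = FALSE)
  }

  turb <- cells[cells$epsilon > 0, , drop = FALSE]
  n_laminar <- nrow(cells) - nrow(turb)
  if (nrow(turb) == 0L) {
    stop("no cells with positive dissipation rate: resolution ratios are ",
      "undefined for fully laminar input",
      call. = FALSE
    )
  }
  scales <- kolmogorov_scales(turb$epsilon, fluid)
  l_les <- les_mixing_length(turb$y, turb$cell_volume)
  length_ratio <- l_les / scales$eta
  time_ratio <- dt / scales$tau_eta

  structure(
    list(
      length_hist = ratio_histogram(length_ratio, bin_width),
      time_hist = ratio_histogram(time_ratio, bin_width),
      length_exceedance = mean(length_ratio > 1),
      time_exceedance = mean(time_ratio > 1),
      n_included = nrow(turb),
      n_laminar = n_laminar,
      bin_width = bin_width,
      ratios = data.frame(length_ratio = length_ratio, time_ratio = time_ratio)
    ),
    class = "resolution_report"
  )
}

#' @export
print.resolution_report <- function(x, ...) {
  cat("LES resolution report\n")
  cat(sprintf("  cells included: %d (laminar, excluded: %d)\n",
              x$n_included, x$n_laminar))
  cat(sprintf("  l_LES/eta > 1:  %.3g%% of cells\n",
              100 * x$length_exceedance))
  cat(sprintf("  dt/tau_eta > 1: %.3g%% of cells\n", 100 * x$time_exceedance))
  cat(sprintf("  bin width:      %g\n", x$bin_width))
  invisible(x)
}
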