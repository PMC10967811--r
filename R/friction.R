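#' Darcy friction-factor policy
#'
#' Internal duct flow is laminar below a Reynolds number of about 2000 and
#' turbulent above about 4000; in between it is transitional. The policy
#' object selects how the Darcy friction factor \eqn{f_D} is evaluated:
#'
#' * `"laminar"`: \eqn{f_D = 64/Re} everywhere.
#' * `"turbulent"`: the Haaland correlation everywhere
#'   (\eqn{1/\sqrt{f_D} = -1.8 \log_{10}[(\epsilon_r/3.7)^{1.11} + 6.9/Re]}).
#' * `"blended"` (default): a smooth weighted average
#'   \eqn{f_D = w\,f_{D,lam} + (1-w)\,f_{D,turb}} with a weight that is 1 at
#'   or below `blend_lower`, 0 at or above `blend_upper`, and tapers
#'   monotonically in between. The default taper is a half-cosine, which is
#'   continuous and introduces no extra parameters.
#'
#' @param regime One of `"blended"`, `"laminar"`, `"turbulent"`.
#' @param blend_lower Reynolds number below which the flow is treated as
#'   fully laminar (default 2000).
#' @param blend_upper Reynolds number above which the flow is treated as
#'   fully turbulent (default 4000). Must exceed `blend_lower`.
#' @param weight Taper shape for the transitional weight: `"cosine"`
#'   (half-cosine, default) or `"linear"`.
#'
#' @return An object of class `friction_policy`.
#' @examples
#' friction_policy()             # blended, thresholds 2000/4000
#' friction_policy("turbulent")  # Haaland across all flowrates
#' @export
friction_policy <- function(regime = c("blended", "laminar", "turbulent"),
                            blend_lower = 2000, blend_upper = 4000,
                            weight = c("cosine", "linear")) {
  regime <- match.arg(regime)
  weight <- match.arg(weight)
  stop_if_not_positive_scalar(blend_lower, "blend_lower")
  stop_if_not_positive_scalar(blend_upper, "blend_upper")
  if (blend_lower >= blend_upper) {
    stop("`blend_lower` must be strictly less than `blend_upper`", call. = FALSE)
  }
  structure(
    list(
      regime = regime, blend_lower = blend_lower,
      blend_upper = blend_upper, weight = weight
    ),
    class = "friction_policy"
  )
}

#' @export
print.friction_policy <- function(x, ...) {
  cat(sprintf(
    "Friction policy: %s (blend %g-%g, %s taper)\n",
    x$regime, x$blend_lower, x$blend_upper, x$weight
  ))
  invisible(x)
}

as_policy <- function(policy) {
  if (!inherits(policy, "friction_policy")) {
    stop("`policy` must be a friction_policy object; see friction_policy()",
      call. = FALSE
    )
  }
  policy
}

#' Transitional blending weight
#'
#' Weight applied to the laminar friction factor in the blended regime:
#' 1 at or below `blend_lower`, 0 at or above `blend_upper`, continuous and
#' monotonically non-increasing in between.
#'
#' @param reynolds Reynolds number(s), non-negative. Vectorised.
#' @param policy A [friction_policy()].
#' @return Numeric weight(s) in \[0, 1\].
#' @export
transition_weight <- function(reynolds, policy = friction_policy()) {
  policy <- as_policy(policy)
  stop_if_not_numeric(reynolds, "reynolds")
  s <- (reynolds - policy$blend_lower) / (policy$blend_upper - policy$blend_lower)
  s <- pmin(pmax(s, 0), 1)
  switch(policy$weight,
    cosine = 0.5 * (1 + cos(pi * s)),
    linear = 1 - s
  )
}

haaland_friction_factor <- function(reynolds, relative_roughness = 0) {
  (-1.8 * log10((relative_roughness / 3.7)^1.11 + 6.9 / reynolds))^-2
}

#' Darcy friction factor
#'
#' Evaluates the Darcy friction factor for internal duct flow under the
#' selected regime policy: laminar \eqn{64/Re}, the turbulent Haaland
#' correlation, or their smooth transitional blend (see
#' [friction_policy()]).
#'
#' @param reynolds Reynolds number(s), positive. Vectorised.
#' @param relative_roughness Dimensionless relative roughness
#'   \eqn{\epsilon_r \ge 0} (used by the turbulent branch only).
#' @param policy A [friction_policy()].
#' @return Friction factor(s) \eqn{f_D}, dimensionless.
#' @examples
#' friction_factor(2000, policy = friction_policy("laminar")) # 64/2000 = 0.032
#' friction_factor(1e5, policy = friction_policy("turbulent")) # ~0.0178
#' @export
friction_factor <- function(reynolds, relative_roughness = 0,
                            policy = friction_policy()) {
  policy <- as_policy(policy)
  stop_if_not_numeric(reynolds, "reynolds")
  stop_if_not_nonnegative_scalar(relative_roughness, "relative_roughness")
  if (any(reynolds < 0)) {
    stop("`reynolds` must be non-negative", call. = FALSE)
  }
  if (policy$regime %in% c("laminar", "blended") && any(reynolds == 0)) {
    stop("friction factor is undefined at Re = 0 for the laminar branch; ",
      "the friction *term* of the pressure drop has a finite Q -> 0 limit, ",
      "see pressure_drop()",
      call. = FALSE
    )
  }
  switch(policy$regime,
    laminar = 64 / reynolds,
    turbulent = haaland_friction_factor(reynolds, relative_roughness),
    blended = {
      wt <- transition_weight(reynolds, policy)
      f_lam <- ifelse(wt > 0, 64 / reynolds, 0)
      f_turb <- ifelse(wt < 1,
        haaland_friction_factor(reynolds, relative_roughness), 0
      )
      wt * f_lam + (1 - wt) * f_turb
    }
  )
}
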