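#' Power-law blood rheology parameters
#'
#' Blood in the dissected aorta is modelled as a shear-thinning power-law
#' fluid, \eqn{\eta(\dot\gamma) = K \dot\gamma^{\,n-1}}, where \eqn{K} is the
#' consistency index and \eqn{n} the flow-behaviour exponent. For \eqn{n < 1}
#' the apparent viscosity diverges as the shear rate approaches zero, so a
#' low-shear floor clamps the viscosity (the floor applies to the viscosity
#' only; the wall shear stress \eqn{\tau = \eta\dot\gamma} still vanishes at
#' zero shear).
#'
#' @param consistency_index_K Consistency index, Pa s^n. Default 0.08.
#' @param exponent_n Dimensionless power-law exponent, in (0, 1.2].
#'   Default 0.55; `n = 1` recovers a Newtonian fluid of viscosity `K`.
#' @param shear_rate_floor Shear rate (1/s) below which the viscosity is held
#'   constant at its floor value. Default 0.01.
#' @return An object of class `power_law_params`.
#' @examples
#' pl <- power_law_params()
#' apparent_viscosity(pl, 1)    # == K
#' apparent_viscosity(pl, 100)  # shear thinning
#' @export
power_law_params <- function(consistency_index_K = 0.08,
                             exponent_n = 0.55,
                             shear_rate_floor = 0.01) {
  stopifnot(is.numeric(consistency_index_K), length(consistency_index_K) == 1,
            is.finite(consistency_index_K), consistency_index_K > 0)
  stopifnot(is.numeric(exponent_n), length(exponent_n) == 1,
            is.finite(exponent_n), exponent_n > 0, exponent_n <= 1.2)
  stopifnot(is.numeric(shear_rate_floor), length(shear_rate_floor) == 1,
            is.finite(shear_rate_floor), shear_rate_floor > 0)
  structure(list(K = consistency_index_K, n = exponent_n,
                 shear_rate_floor = shear_rate_floor),
            class = "power_law_params")
}

#' @export
print.power_law_params <- function(x, ...) {
  cat("Power-law rheology: K =", x$K, "Pa.s^n, n =", x$n,
      "(shear-rate floor", x$shear_rate_floor, "1/s)\n")
  invisible(x)
}

#' Fluid properties: density plus rheology
#'
#' @param density Mass density in kg/m^3. Default 1022 (blood).
#' @param rheology A [power_law_params()] object.
#' @return An object of class `fluid_properties`.
#' @export
fluid_properties <- function(density = 1022, rheology = power_law_params()) {
  stopifnot(is.numeric(density), length(density) == 1,
            is.finite(density), density > 0)
  stopifnot(inherits(rheology, "power_law_params"))
  structure(list(density = density, rheology = rheology),
            class = "fluid_properties")
}

#' @export
print.fluid_properties <- function(x, ...) {
  cat("Fluid: density =", x$density, "kg/m^3\n")
  print(x$rheology)
  invisible(x)
}

#' Apparent viscosity of a power-law fluid
#'
#' Evaluates \eqn{\eta = K \max(\dot\gamma, \dot\gamma_{floor})^{\,n-1}}.
#' Vectorised over `shear_rate`.
#'
#' @param params A [power_law_params()] object.
#' @param shear_rate Shear rate(s), 1/s; must be finite and non-negative.
#' @return Apparent viscosity in Pa s, same length as `shear_rate`.
#' @export
apparent_viscosity <- function(params, shear_rate) {
  stopifnot(inherits(params, "power_law_params"))
  if (!is.numeric(shear_rate) || any(!is.finite(shear_rate)))
    stop("shear_rate must be finite numeric")
  if (any(shear_rate < 0)) stop("shear_rate must be >= 0")
  g <- pmax(shear_rate, params$shear_rate_floor)
  params$K * g^(params$n - 1)
}

#' Wall shear stress from a wall shear rate
#'
#' \eqn{\tau = \eta(\dot\gamma)\,\dot\gamma}; above the viscosity floor this is
#' \eqn{K \dot\gamma^{\,n}}. The floor applies only inside
#' [apparent_viscosity()], so \eqn{\tau(0) = 0} exactly.
#'
#' @inheritParams apparent_viscosity
#' @param wall_shear_rate Wall shear rate(s), 1/s, non-negative.
#' @return Wall shear stress in Pa.
#' @export
wall_shear_stress <- function(params, wall_shear_rate) {
  apparent_viscosity(params, wall_shear_rate) * wall_shear_rate
}

# Pa per mmHg; single source of truth for all unit conversions in the package.
MMHG_PA <- 133.322
# m^3/s per L/min
LMIN_M3S <- 1 / 60000
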