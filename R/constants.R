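#' Physical constants for electrodiffusion computations
#'
#' Returns the set of physical constants used throughout the solver, in the
#' package's canonical unit system (length nm, time ms, concentration mM,
#' potential mV).  In this system the Poisson equation
#' \eqn{\nabla\cdot(\varepsilon_r\varepsilon_0\nabla\phi) = -\rho} yields a
#' charge density directly in C/m^3 when \eqn{\varepsilon_0} is expressed in
#' fF/m, \eqn{\phi} in mV and lengths in nm, so no per-term conversion
#' factors appear in the discretization.
#'
#' @param temperature Absolute temperature in K.
#' @return An object of class \code{pnp_constants}: a list with elements
#'   \code{F} (Faraday constant, C/mol), \code{eps0} (vacuum permittivity,
#'   fF/m), \code{e} (elementary charge, C), \code{kB} (Boltzmann constant,
#'   mJ/K) and \code{T} (temperature, K).
#' @examples
#' pnp_constants()$F
#' @export
pnp_constants <- function(temperature = 310) {
  stopifnot(is.numeric(temperature), length(temperature) == 1L, temperature >= 0)
  out <- list(
    F    = 96485.3365,     # C/mol
    eps0 = 8854,           # fF/m
    e    = 1.60217662e-19, # C
    kB   = 1.380649e-20,   # mJ/K
    T    = temperature     # K
  )
  class(out) <- "pnp_constants"
  out
}

#' Thermal voltage kB*T/e
#'
#' @param constants A \code{\link{pnp_constants}} object.
#' @return The thermal voltage in mV (about 26.7 mV at 310 K).
#' @export
thermal_voltage <- function(constants = pnp_constants()) {
  stopifnot(constants$T >= 0)
  constants$kB * constants$T / constants$e
}

#' Nernst equilibrium potential
#'
#' The transmembrane voltage at which the net electrodiffusive flux of one
#' ion species through an open channel vanishes,
#' \eqn{v_0 = (k_B T / z e)\,\ln(c_e/c_i)}.
#'
#' @param z Integer valence of the ion (nonzero).
#' @param ce Extracellular-side concentration (mM), positive.
#' @param ci Intracellular-side concentration (mM), positive.
#' @param constants A \code{\link{pnp_constants}} object.
#' @return Potential in mV.
#' @examples
#' nernst_potential(1, 5, 125)   # K+ at rest, about -86 mV
#' nernst_potential(2, 1.4, 1e-4) # Ca2+, about +128 mV
#' @export
nernst_potential <- function(z, ce, ci, constants = pnp_constants()) {
  if (any(z == 0)) stop("valence must be nonzero")
  if (any(ce <= 0) || any(ci <= 0)) {
    stop("concentrations must be positive for a Nernst potential")
  }
  thermal_voltage(constants) / z * log(ce / ci)
}

#' Canonical unit system and SI conversion factors
#'
#' The solver works in nm / ms / mM / mV.  Derived units follow: conductance
#' zS (1e-21 S), current yA (1e-24 A), capacitance yF/nm^2, amount ymol
#' (1e-24 mol), and flux density mM nm/ms, which equals ymol/(nm^2 s) by
#' construction.  Charge density comes out of the Poisson discretization
#' directly in C/m^3.  The returned factors multiply a value in canonical
#' units to give SI.
#'
#' @return A named list of multiplicative conversion factors to SI.
#' @export
pnp_units <- function() {
  list(
    length_m            = 1e-9,   # nm -> m
    time_s              = 1e-3,   # ms -> s
    concentration_mol_m3 = 1,     # mM == mol/m^3
    potential_V         = 1e-3,   # mV -> V
    conductance_S       = 1e-21,  # zS -> S
    current_A           = 1e-24,  # yA -> A
    capacitance_F_m2    = 1e-6,   # yF/nm^2 -> F/m^2
    amount_mol          = 1e-24,  # ymol -> mol
    flux_mol_m2_s       = 1e-6,   # mM nm/ms -> mol/(m^2 s)
    charge_density_C_m3 = 1       # already C/m^3
  )
}
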