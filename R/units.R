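#' Gating schedule of a membrane unit
#'
#' Deterministic, instantaneous gating: the unit is open at time t iff t
#' falls inside one of the (open, close) intervals.
#'
#' @param open,close Numeric vectors of equal length: interval start and end
#'   times (ms).  Use \code{close = Inf} for "stays open".
#' @return An object of class \code{gating_schedule}.
#' @export
gating_schedule <- function(open = numeric(0), close = numeric(0)) {
  stopifnot(length(open) == length(close), all(close > open))
  if (length(open) > 1L) {
    o <- order(open); open <- open[o]; close <- close[o]
    if (any(open[-1] < close[-length(close)])) stop("gating intervals overlap")
  }
  structure(list(open = open, close = close), class = "gating_schedule")
}

#' Always-open / always-closed schedules
#' @rdname gating_schedule
#' @export
always_open <- function() gating_schedule(0, Inf)

#' @rdname gating_schedule
#' @export
always_closed <- function() gating_schedule()

#' Is the unit open at time t?
#' @param schedule A \code{gating_schedule}.
#' @param t Time (ms).
#' @return Logical.
#' @export
is_open <- function(schedule, t) {
  any(t >= schedule$open & t < schedule$close)
}

#' Single ion channel specification
#'
#' A linear single-channel model: current \eqn{i = g (v - v_0)} with
#' \eqn{v_0} the Nernst equilibrium potential evaluated at the channel
#' mouths, converted to a flux density over the wc x wc membrane patch,
#' \eqn{J = g (v - v_0) / (z F w_c^2)} in mM nm/ms, positive for
#' intracellular-to-extracellular flow.
#'
#' @param ion Species name ("K", "Na", "Ca").
#' @param g Single-channel conductance (zS); defaults: K 5e9, Na 20e9,
#'   Ca 8e9 (i.e. 5, 20 and 8 pS).
#' @param placement A \code{\link{unit_placement}}.
#' @param schedule A \code{\link{gating_schedule}}.
#' @return An object of class \code{channel_spec} (also \code{membrane_unit}).
#' @export
channel_spec <- function(ion, g = NULL, placement, schedule = always_open()) {
  if (is.null(g)) {
    g <- switch(ion, K = 5e9, Na = 20e9, Ca = 8e9,
                stop("no default conductance for ion '", ion, "'"))
  }
  stopifnot(g > 0, inherits(placement, "unit_placement"),
            inherits(schedule, "gating_schedule"))
  structure(list(kind = "channel", id = placement$id, ion = ion, g = g,
                 placement = placement, schedule = schedule),
            class = c("channel_spec", "membrane_unit"))
}

#' Sodium-calcium exchanger specification
#'
#' Electrogenic 3 Na+ : 1 Ca2+ exchange with the standard
#' allosterically-regulated current-density formulation (in A/F), converted
#' to per-channel flux densities via the specific membrane capacitance
#' \code{Cm} and the NCX surface density \code{delta}.
#'
#' @param placement A \code{\link{unit_placement}}.
#' @param schedule A \code{\link{gating_schedule}}.
#' @param Ibar Scaling current density (A/F).
#' @param delta NCX surface density (nm^-2).
#' @param Cm Specific membrane capacitance (yF/nm^2).
#' @param nu Energy barrier position (dimensionless).
#' @param ksat Saturation factor at negative potentials.
#' @param Kact Ca2+ activation constant (mM).
#' @param KCai,KCae,KNai,KNae Half-saturation constants (mM).
#' @return An object of class \code{ncx_spec} (also \code{membrane_unit}).
#' @export
ncx_spec <- function(placement, schedule = always_open(), Ibar = 4.9,
                     delta = 4e-4, Cm = 1e4, nu = 0.3, ksat = 0.3,
                     Kact = 1.5e-4, KCai = 3.6e-3, KCae = 1.3,
                     KNai = 12.3, KNae = 87.5) {
  stopifnot(Ibar > 0, delta > 0, Cm > 0, nu > 0, ksat > 0, Kact > 0,
            KCai > 0, KCae > 0, KNai > 0, KNae > 0,
            inherits(placement, "unit_placement"),
            inherits(schedule, "gating_schedule"))
  structure(list(kind = "ncx", id = placement$id, Ibar = Ibar, delta = delta,
                 Cm = Cm, nu = nu, ksat = ksat, Kact = Kact, KCai = KCai,
                 KCae = KCae, KNai = KNai, KNae = KNae,
                 placement = placement, schedule = schedule),
            class = c("ncx_spec", "membrane_unit"))
}

#' Area-averaged state at the two mouths of a membrane unit
#'
#' Averages the electrical potential and the free concentrations over the
#' first layer of non-membrane cells adjacent to the unit's membrane patch,
#' area-weighted; the transmembrane potential of the unit is
#' \code{v = phii - phie}.
#'
#' @param state A \code{pnp_state} (see \code{\link{init_state}}).
#' @param faces A unit face set from \code{\link{locate_unit_faces}} (an
#'   element of \code{mesh$unit_faces}).
#' @return A list with \code{phii}, \code{phie}, \code{v} (mV) and matrices
#'   \code{ci}, \code{ce} (named per-species mouth concentrations, mM).
#' @export
mouth_state <- function(state, faces) {
  if (is.null(faces) || !length(faces$i$cells) || !length(faces$e$cells)) {
    stop("empty mouth face set")
  }
  phii <- sum(faces$i$w * state$phi[faces$i$cells])
  phie <- sum(faces$e$w * state$phi[faces$e$cells])
  ci <- drop(faces$i$w %*% state$conc[faces$i$cells, , drop = FALSE])
  ce <- drop(faces$e$w %*% state$conc[faces$e$cells, , drop = FALSE])
  names(ci) <- names(ce) <- colnames(state$conc)
  list(phii = phii, phie = phie, v = phii - phie, ci = ci, ce = ce)
}

#' Affine (linearized) channel flux for the implicit coupled step
#'
#' The channel flux is taken implicitly in the coupled
#' Poisson/Nernst-Planck solve.  The logarithm in the Nernst potential is
#' linearized by a first-order expansion around the interim concentrations
#' \eqn{\tilde c} from the buffering step, giving the affine form
#' \deqn{J = K\left(\phi_i - \phi_e - V_z\left[\ln(\tilde c_e/\tilde c_i)
#'   + c_e/\tilde c_e - c_i/\tilde c_i\right]\right),}
#' with \eqn{K = g/(z F w_c^2)} and \eqn{V_z = k_BT/(z e)}, where
#' \eqn{\phi_i, \phi_e, c_i, c_e} are current-step unknowns (mouth
#' averages).  At \eqn{v = v_0(\tilde c)} and \eqn{c = \tilde c} the flux
#' is zero.  (A consistent expansion of \eqn{\ln c_e - \ln c_i} makes the
#' two constant terms cancel and puts \eqn{c_e} over \eqn{\tilde c_e};
#' published statements of this scheme sometimes carry a typo here.)
#'
#' @param spec A \code{\link{channel_spec}}.
#' @param mouth_interim Mouth state evaluated on the interim concentrations
#'   (from \code{\link{mouth_state}}).
#' @param constants A \code{\link{pnp_constants}}.
#' @param wc Channel patch edge (nm).
#' @return List of affine coefficients: \code{a_v} (on \code{phii - phie}),
#'   \code{a_ci}, \code{a_ce} (on the mouth concentrations of the channel's
#'   ion) and \code{const}, such that
#'   \code{J = a_v*(phii - phie) + a_ci*ci + a_ce*ce + const} (mM nm/ms).
#' @export
channel_flux_affine <- function(spec, mouth_interim, constants = pnp_constants(),
                                wc = 4) {
  sp <- default_species()
  z <- sp$z[match(spec$ion, sp$name)]
  cti <- mouth_interim$ci[[spec$ion]]
  cte <- mouth_interim$ce[[spec$ion]]
  if (!is.finite(cti) || !is.finite(cte) || cti <= 0 || cte <= 0) {
    stop("nonpositive interim mouth concentration for ", spec$ion)
  }
  K <- spec$g / (z * constants$F * wc^2)
  Vz <- thermal_voltage(constants) / z
  list(a_v = K,
       a_ci = K * Vz / cti,
       a_ce = -K * Vz / cte,
       const = -K * Vz * log(cte / cti),
       z = z, ion = spec$ion)
}

#' Evaluate the linearized channel flux at given mouth values
#'
#' @param aff Output of \code{\link{channel_flux_affine}}.
#' @param v Transmembrane potential (mV).
#' @param ci,ce Current-step mouth concentrations (mM).
#' @return Flux density J (mM nm/ms), positive intracellular-to-extracellular.
#' @export
channel_flux_eval <- function(aff, v, ci, ce) {
  aff$a_v * v + aff$a_ci * ci + aff$a_ce * ce + aff$const
}

#' Nonlinear single-channel flux density
#'
#' The unlinearized flux \eqn{J = g (v - v_0)/(z F w_c^2)} with
#' \eqn{v_0} the Nernst potential at the given mouth concentrations.
#'
#' @inheritParams channel_flux_affine
#' @param v Transmembrane potential (mV).
#' @param ci,ce Mouth concentrations (mM).
#' @return Flux density (mM nm/ms).
#' @export
channel_flux <- function(spec, v, ci, ce, constants = pnp_constants(), wc = 4) {
  sp <- default_species()
  z <- sp$z[match(spec$ion, sp$name)]
  v0 <- nernst_potential(z, ce, ci, constants)
  spec$g * (v - v0) / (z * constants$F * wc^2)
}

#' NCX current density
#'
#' Evaluates the exchanger current density (A/F) from the transmembrane
#' potential and the four mouth concentrations.  Positive current
#' corresponds to net positive charge moving out of the cell (reverse mode:
#' Ca2+ entry); at the reversal potential \eqn{3 v_{Na} - 2 v_{Ca}} the
#' current is zero, and at the resting potential (slightly below reversal)
#' it is negative, i.e. forward-mode Ca2+ extrusion.
#'
#' @param v Transmembrane potential (mV).
#' @param cNai,cNae,cCai,cCae Mouth concentrations (mM), positive.
#' @param spec An \code{\link{ncx_spec}}.
#' @param constants A \code{\link{pnp_constants}}.
#' @return Current density in A/F.
#' @export
ncx_current_density <- function(v, cNai, cNae, cCai, cCae, spec,
                                constants = pnp_constants()) {
  if (any(c(cNai, cNae, cCai, cCae) <= 0)) {
    stop("nonpositive mouth concentration in NCX evaluation")
  }
  f <- v / thermal_voltage(constants)   # e*v/(kB*T)
  s <- spec$KCai * cNae^3 * (1 + (cNai / spec$KNai)^3) +
    spec$KNae^3 * cCai * (1 + cCai / spec$KCai) +
    spec$KCae * cNai^3 + cNai^3 * cCae + cNae^3 * cCai
  num <- exp(spec$nu * f) * cNai^3 * cCae -
    exp((spec$nu - 1) * f) * cNae^3 * cCai
  den <- s * (1 + (spec$Kact / cCai)^2) *
    (1 + spec$ksat * exp((spec$nu - 1) * f))
  spec$Ibar * num / den
}

#' Convert NCX current density to Na+ and Ca2+ flux densities
#'
#' One exchange cycle moves 3 Na+ one way and 1 Ca2+ the other; the single
#' exchanger current is \code{(Cm/delta) * INCX} and the flux densities over
#' the wc x wc patch follow by dividing by \code{z F wc^2} per species:
#' \code{JNa = 3 Cm INCX / (F wc^2 delta)},
#' \code{JCa = -Cm INCX / (F wc^2 delta)} (mM nm/ms, positive out of the
#' cell), so \code{JNa / JCa = -3} whenever the current is nonzero.
#'
#' @param INCX Current density (A/F).
#' @param spec An \code{\link{ncx_spec}}.
#' @param constants A \code{\link{pnp_constants}}.
#' @param wc Patch edge (nm).
#' @return Named numeric vector \code{c(Na = JNa, Ca = JCa)}.
#' @export
ncx_flux_densities <- function(INCX, spec, constants = pnp_constants(), wc = 4) {
  base <- spec$Cm * INCX / (constants$F * wc^2 * spec$delta)
  c(Na = 3 * base, Ca = -base)
}
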