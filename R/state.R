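#' Initialize the field state
#'
#' Concentrations are set per subdomain (extracellular / intracellular
#' columns of the species table, zero in the membrane where there are no
#' concentration unknowns), bound buffer pools are set to binding
#' equilibrium so the buffering flux is exactly zero at t = 0, the
#' potential is zero, and the background charge density is chosen so the
#' total charge density vanishes in every cell: the initial state is
#' electroneutral by construction.  Inside the membrane the background
#' charge is zero.
#'
#' @param mesh A \code{tensor_mesh}.
#' @param species Species table (see \code{\link{default_species}}).
#' @param buffers Buffer table or NULL.
#' @param constants A \code{\link{pnp_constants}}.
#' @param conc_init Optional ncell x nspecies matrix (or function of
#'   \code{(mesh, species)} returning one) overriding the default
#'   concentrations, used by the perturbation presets.
#' @return An object of class \code{pnp_state}: list with \code{phi} (mV),
#'   \code{conc} (mM, ncell x K), \code{bound} (mM, ncell x nbuf),
#'   \code{rho0} (C/m^3), \code{t} (ms).
#' @export
init_state <- function(mesh, species = default_species(),
                       buffers = default_buffers(),
                       constants = pnp_constants(), conc_init = NULL) {
  validate_species(species)
  validate_buffers(buffers)
  K <- nrow(species)
  conc <- matrix(0, mesh$ncell, K, dimnames = list(NULL, species$name))
  for (k in seq_len(K)) {
    conc[mesh$label == 1L, k] <- species$c0e[k]
    conc[mesh$label == 3L, k] <- species$c0i[k]
  }
  if (!is.null(conc_init)) {
    m <- if (is.function(conc_init)) conc_init(mesh, species) else conc_init
    stopifnot(is.matrix(m), nrow(m) == mesh$ncell, ncol(m) == K)
    conc <- m
    colnames(conc) <- species$name
    conc[mesh$label == 2L, ] <- 0
  }
  nb <- if (is.null(buffers)) 0L else nrow(buffers)
  bound <- matrix(0, mesh$ncell, max(nb, 0L),
                  dimnames = list(NULL, if (nb) buffers$name))
  if (nb) {
    ii <- mesh$label == 3L
    for (j in seq_len(nb)) {
      k <- match(buffers$target[j], species$name)
      bound[ii, j] <- buffer_equilibrium(conc[ii, k], buffers$Btot[j],
                                         buffers$kon[j], buffers$koff[j])
    }
  }
  st <- structure(list(phi = rep(0, mesh$ncell), conc = conc, bound = bound,
                       rho0 = rep(0, mesh$ncell), t = 0),
                  class = "pnp_state")
  mobile <- mobile_charge(st, mesh, species, buffers, constants)
  st$rho0 <- -mobile
  st$rho0[mesh$label == 2L] <- 0
  st
}

# F * sum_k z_k (c_k + sum_j b_{k,j}) per cell, in C/m^3; zero in the membrane
mobile_charge <- function(state, mesh, species, buffers, constants) {
  rho <- drop(state$conc %*% species$z)
  if (!is.null(buffers) && nrow(buffers)) {
    zt <- species$z[match(buffers$target, species$name)]
    rho <- rho + drop(state$bound %*% zt)
  }
  rho <- rho * constants$F
  rho[mesh$label == 2L] <- 0
  rho
}

#' Total charge density per cell
#'
#' \eqn{\rho = \rho_0 + F \sum_k z_k (c_k + \sum_j b_{k,j})} in C/m^3; in
#' the membrane only the background charge contributes.
#'
#' @param state A \code{pnp_state}.
#' @param mesh A \code{tensor_mesh}.
#' @param species Species table.
#' @param buffers Buffer table or NULL.
#' @param constants A \code{\link{pnp_constants}}.
#' @return Numeric vector, C/m^3 per cell.
#' @export
charge_density <- function(state, mesh, species = default_species(),
                           buffers = default_buffers(),
                           constants = pnp_constants()) {
  state$rho0 + mobile_charge(state, mesh, species, buffers, constants)
}

#' Explicit buffering step of the operator splitting
#'
#' Forward-Euler update of the buffer reaction over one time step: for each
#' buffer the binding flux \eqn{J_B = k_{on} c (B_{tot} - b) - k_{off} b}
#' is evaluated at the previous-step values, the bound pool gains
#' \eqn{\Delta t\, J_B} and the free pool loses it, so free + bound is
#' conserved exactly per cell.  The result \code{ctilde} is the interim
#' concentration used by the coupled implicit step.
#'
#' @param state A \code{pnp_state}.
#' @param mesh A \code{tensor_mesh}.
#' @param species Species table.
#' @param buffers Buffer table (may be NULL / empty).
#' @param dt Time step (ms).
#' @return List with \code{ctilde} (full concentration matrix) and
#'   \code{bound} (updated bound pools).
#' @export
buffering_step <- function(state, mesh, species, buffers, dt) {
  stopifnot(dt > 0)
  ctilde <- state$conc
  bound <- state$bound
  if (is.null(buffers) || nrow(buffers) == 0L) {
    return(list(ctilde = ctilde, bound = bound))
  }
  ii <- mesh$label == 3L
  for (j in seq_len(nrow(buffers))) {
    k <- match(buffers$target[j], species$name)
    JB <- buffer_flux(state$conc[ii, k], state$bound[ii, j],
                      buffers$Btot[j], buffers$kon[j], buffers$koff[j])
    ctilde[ii, k] <- ctilde[ii, k] - dt * JB
    bound[ii, j] <- bound[ii, j] + dt * JB
    if (any(bound[ii, j] < -1e-9) ||
        any(bound[ii, j] > buffers$Btot[j] + 1e-9)) {
      stop("buffering step left bound pool of '", buffers$name[j],
           "' outside [0, Btot]; reduce dt")
    }
  }
  list(ctilde = ctilde, bound = bound)
}
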