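#' Default ion species table
#'
#' Valences, diffusion coefficients and initial concentrations for the four
#' ion species carried in the full dyad simulations.  Extracellular and
#' intracellular diffusion coefficients differ; inside the membrane the
#' diffusion coefficient is zero for every species (transport through the
#' membrane happens only through channel/exchanger fluxes).
#'
#' @param names Optional character vector to subset/reorder the table,
#'   e.g. \code{c("K", "Cl")} for the simple two-ion examples.
#' @return A data.frame with columns \code{name}, \code{z} (valence),
#'   \code{De}, \code{Di} (diffusion coefficients, nm^2/ms), \code{c0e},
#'   \code{c0i} (initial concentrations, mM).
#' @export
default_species <- function(names = NULL) {
  tab <- data.frame(
    name = c("Na", "K", "Ca", "Cl"),
    z    = c(1L, 1L, 2L, -1L),
    De   = c(1.33e6, 1.96e6, 0.71e6, 2.03e6),
    Di   = c(0.37e6, 0.55e6, 0.20e6, 0.57e6),
    c0e  = c(100, 5, 1.4, 107.8),
    c0i  = c(12, 125, 1e-4, 15),
    stringsAsFactors = FALSE
  )
  if (!is.null(names)) {
    miss <- setdiff(names, tab$name)
    if (length(miss)) stop("unknown species: ", paste(miss, collapse = ", "))
    tab <- tab[match(names, tab$name), , drop = FALSE]
    rownames(tab) <- NULL
  }
  validate_species(tab)
  tab
}

validate_species <- function(species) {
  stopifnot(
    is.data.frame(species),
    all(c("name", "z", "De", "Di", "c0e", "c0i") %in% names(species)),
    all(species$De >= 0), all(species$Di >= 0),
    all(species$z != 0), !anyDuplicated(species$name)
  )
  invisible(species)
}

#' Default stationary calcium buffer table
#'
#' Two stationary (non-diffusing) intracellular Ca2+ binding proteins, one
#' high-affinity and one low-affinity.  Buffers exist only in the
#' intracellular subdomain and bind only Ca2+.
#'
#' @return A data.frame with columns \code{name}, \code{target} (ion name),
#'   \code{Btot} (total buffer concentration, mM), \code{kon}
#'   (ms^-1 mM^-1) and \code{koff} (ms^-1).
#' @export
default_buffers <- function() {
  tab <- data.frame(
    name   = c("high_affinity", "low_affinity"),
    target = c("Ca", "Ca"),
    Btot   = c(0.20, 0.56),
    kon    = c(100, 100),
    koff   = c(0.03, 1.3),
    stringsAsFactors = FALSE
  )
  validate_buffers(tab)
  tab
}

validate_buffers <- function(buffers) {
  if (is.null(buffers) || nrow(buffers) == 0L) return(invisible(buffers))
  stopifnot(
    is.data.frame(buffers),
    all(c("name", "target", "Btot", "kon", "koff") %in% names(buffers)),
    all(buffers$Btot > 0), all(buffers$kon > 0), all(buffers$koff > 0)
  )
  invisible(buffers)
}

#' Equilibrium bound concentration of a stationary buffer
#'
#' Bound concentration at which the mass-action binding flux
#' \eqn{J_B = k_{on} c (B_{tot} - b) - k_{off} b} vanishes:
#' \eqn{b^* = B_{tot}\, k_{on} c / (k_{on} c + k_{off})}.  Used to
#' initialize the bound pools so the buffering term is exactly zero at t=0.
#'
#' @param c Free ion concentration (mM), nonnegative; vectorized.
#' @param Btot,kon,koff Buffer parameters (see \code{\link{default_buffers}}).
#' @return Bound concentration in mM, in \code{[0, Btot]}.
#' @export
buffer_equilibrium <- function(c, Btot, kon, koff) {
  stopifnot(all(c >= 0), Btot > 0, kon > 0, koff > 0)
  Btot * kon * c / (kon * c + koff)
}

#' Mass-action buffer binding flux
#'
#' @param c Free ion concentration (mM).
#' @param b Bound concentration (mM).
#' @param Btot,kon,koff Buffer parameters.
#' @return Binding flux in mM/ms (positive: free ion being bound).
#' @export
buffer_flux <- function(c, b, Btot, kon, koff) {
  kon * c * (Btot - b) - koff * b
}

#' Load the shipped default parameter file
#'
#' The file \code{inst/extdata/default_parameters.yaml} mirrors the default
#' constants, species, buffers, geometry and membrane-unit parameters in a
#' single human-readable place.
#'
#' @return A nested list of parameter values.
#' @export
default_parameters <- function() {
  path <- system.file("extdata", "default_parameters.yaml", package = "dyadPNP",
                      mustWork = TRUE)
  yaml::read_yaml(path)
}
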