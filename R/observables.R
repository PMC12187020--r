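#' Transmembrane potential of a membrane unit
#'
#' \code{v = phii - phie}: the difference between the area-averaged
#' potentials over the intracellular and extracellular mouths of the unit.
#'
#' @param state A \code{pnp_state}.
#' @param mesh A \code{tensor_mesh}.
#' @param id Unit id.
#' @return Potential in mV.
#' @export
transmembrane_potential <- function(state, mesh, id) {
  uf <- mesh$unit_faces[[id]]
  if (is.null(uf)) stop("unknown unit '", id, "'")
  mouth_state(state, uf)$v
}

#' Per-term magnitudes of the transport equation at a point
#'
#' Evaluates the three discrete operators of the buffered transport
#' equation at one cell, using exactly the solver's stencils: the diffusion
#' term \eqn{B_d = \nabla\cdot D\nabla c} (at the new concentrations), the
#' electrical drift term \eqn{B_e = \nabla\cdot(D z e/(k_BT)\,\tilde c\,
#' \nabla\phi)} (interim concentrations, new potential) and the buffering
#' term \eqn{B_b = \sum_j J_{B,j}} (previous-step values).  With the
#' operator splitting used here, \eqn{B_d + B_e - B_b} equals the discrete
#' time derivative of c at every cell that receives no membrane flux.
#'
#' @param prev,cur States at consecutive steps (prev at t, cur at t + dt).
#' @param mesh A \code{tensor_mesh}.
#' @param ion Species name.
#' @param cell Cell index (must not lie in the membrane).
#' @param dt Time step between the two states (ms).
#' @param species,buffers,constants,config Model tables and configuration.
#' @return List with \code{Bd}, \code{Be}, \code{Bb} (mM/ms) and
#'   \code{dcdt} (discrete time derivative, mM/ms).
#' @export
term_breakdown <- function(prev, cur, mesh, ion, cell, dt,
                           species = default_species(),
                           buffers = default_buffers(),
                           constants = pnp_constants(),
                           config = solver_config()) {
  if (mesh$label[cell] == 2L) stop("point lies in the membrane")
  k <- match(ion, species$name)
  if (is.na(k)) stop("unknown species '", ion, "'")
  fc <- mesh$faces
  Dc <- ifelse(mesh$label == 1L, species$De[k],
               ifelse(mesh$label == 3L, species$Di[k], 0))
  Df <- dw_harmonic(fc$da, fc$db, Dc[fc$a], Dc[fc$b])
  sel <- which(Df > 0 & (fc$a == cell | fc$b == cell))
  gd <- Df[sel] * fc$area[sel] / (fc$da[sel] + fc$db[sel])
  sgn <- ifelse(fc$a[sel] == cell, 1, -1)   # +: neighbour is b
  other <- ifelse(fc$a[sel] == cell, fc$b[sel], fc$a[sel])

  # interim concentrations reproduced from the previous state
  bs <- buffering_step(prev, mesh, species, buffers, dt)
  ct <- bs$ctilde
  Vt <- thermal_voltage(constants)
  ctf <- 0.5 * (ct[fc$a[sel], k] + ct[fc$b[sel], k])
  w <- gd * species$z[k] / Vt * ctf

  V <- mesh$vol[cell]
  Bd <- sum(gd * (cur$conc[other, k] - cur$conc[cell, k])) / V
  Be <- if (isTRUE(config$drift_off)) 0 else
    sum(w * (cur$phi[other] - cur$phi[cell])) / V
  Bb <- 0
  if (!is.null(buffers) && nrow(buffers) && mesh$label[cell] == 3L) {
    for (j in seq_len(nrow(buffers))) {
      if (buffers$target[j] == ion) {
        Bb <- Bb + buffer_flux(prev$conc[cell, k], prev$bound[cell, j],
                               buffers$Btot[j], buffers$kon[j],
                               buffers$koff[j])
      }
    }
  }
  list(Bd = unname(Bd), Be = unname(Be), Bb = unname(Bb),
       dcdt = unname((cur$conc[cell, k] - prev$conc[cell, k]) / dt))
}

#' RyR activation time from a trajectory
#'
#' Time from the opening of the dyadic Ca2+ source until the area-averaged
#' Ca2+ concentration over the RyR patch on the SR boundary (recorded in
#' the trajectory as \code{ryr_ca}) first exceeds the threshold, with
#' linear interpolation between output samples.
#'
#' @param trajectory A \code{pnp_trajectory} whose scenario declared an
#'   \code{observe$ryr} block.
#' @param open_time Time at which the source opened (ms).
#' @param threshold Activation threshold (mM); default 5e-4 (0.5 uM).
#' @return Activation delay in ms, or \code{NA} ("not activated") if the
#'   threshold is never reached.
#' @export
ryr_activation_time <- function(trajectory, open_time = 0,
                                threshold = 5e-4) {
  d <- trajectory$data
  if (is.null(d$ryr_ca)) stop("trajectory has no RyR patch record")
  tt <- d$time
  cc <- d$ryr_ca
  sel <- tt >= open_time - 1e-12
  tt <- tt[sel]; cc <- cc[sel]
  if (!length(cc)) stop("trajectory does not cover the opening time")
  if (cc[1] >= threshold) return(0)
  ab <- which(cc >= threshold)
  if (!length(ab)) return(NA_real_)
  i <- ab[1]
  frac <- (threshold - cc[i - 1]) / (cc[i] - cc[i - 1])
  (tt[i - 1] + frac * (tt[i] - tt[i - 1])) - open_time
}

#' Profile of the solution along a mesh line in x
#'
#' Extracts potential, concentrations and charge density along the row of
#' cells nearest to the given transverse position; used for Debye-layer
#' inspection.
#'
#' @param state A \code{pnp_state}.
#' @param mesh A \code{tensor_mesh}.
#' @param y,z Transverse anchor (nm); defaults to the domain center.
#' @param species,buffers,constants Model tables.
#' @return A data.frame with x, subdomain label, phi, one column per
#'   species, and rho.
#' @export
line_profile <- function(state, mesh, y = NULL, z = NULL,
                         species = default_species(),
                         buffers = default_buffers(),
                         constants = pnp_constants()) {
  j <- if (is.null(y)) which.min(abs(mesh$yc - mesh$geometry$Ly / 2)) else
    which.min(abs(mesh$yc - y))
  k <- if (mesh$dims == 3) {
    if (is.null(z)) which.min(abs(mesh$zc - mesh$geometry$Lz / 2)) else
      which.min(abs(mesh$zc - z))
  } else 1L
  cells <- cell_index(mesh, seq_len(mesh$nx), j, k)
  rho <- charge_density(state, mesh, species, buffers, constants)
  out <- data.frame(x = mesh$xc, label = mesh$label[cells],
                    phi = state$phi[cells])
  for (s in colnames(state$conc)) out[[s]] <- state$conc[cells, s]
  out$rho <- rho[cells]
  out
}

#' Time for a charge perturbation to decay to a fraction of its start
#'
#' Reads the recorded center-point charge density of a trajectory and
#' returns the first time |rho| falls below \code{frac} of its initial
#' magnitude, log-linearly interpolated between output samples (the decay
#' is near-exponential on the Debye relaxation time scale).
#'
#' @param trajectory A \code{pnp_trajectory} recording \code{rho_center}.
#' @param frac Decay fraction (default 0.05).
#' @return Time in ms, or \code{NA} if the threshold is not reached.
#' @export
electroneutrality_decay_time <- function(trajectory, frac = 0.05) {
  d <- trajectory$data
  if (is.null(d$rho_center)) stop("trajectory has no center charge record")
  rho <- abs(d$rho_center)
  tt <- d$time
  target <- frac * rho[1]
  ab <- which(rho <= target)
  if (!length(ab)) return(NA_real_)
  i <- ab[1]
  if (i == 1) return(0)
  r1 <- rho[i - 1]; r2 <- rho[i]
  f <- if (r2 > 0 && r1 > target) {
    (log(r1) - log(target)) / (log(r1) - log(r2))
  } else {
    (r1 - target) / (r1 - r2)
  }
  tt[i - 1] + f * (tt[i] - tt[i - 1])
}

#' Analytic Debye length
#'
#' \eqn{\lambda_D = \sqrt{\varepsilon_r\varepsilon_0\,(k_BT/e) / (F \sum_k
#' z_k^2 c_k)}} for the given mobile-ion composition, in nm.
#'
#' @param conc Named concentrations (mM).
#' @param z Valences in matching order.
#' @param eps_r Relative permittivity.
#' @param constants A \code{\link{pnp_constants}}.
#' @return Debye length in nm.
#' @export
debye_length <- function(conc, z, eps_r = 80, constants = pnp_constants()) {
  sqrt(eps_r * constants$eps0 * thermal_voltage(constants) /
         (constants$F * sum(z^2 * conc)))
}

#' Fit an exponential decay length to a charge-density profile
#'
#' Log-linear least squares on \code{|rho|} over the given distance window
#' from the membrane face; used to compare the simulated Debye layer with
#' the analytic Debye length.
#'
#' @param dist Distance from the membrane face (nm).
#' @param rho Charge density values.
#' @param window Distances (nm) to include in the fit.
#' @return Fitted e-folding length (nm).
#' @export
fit_decay_length <- function(dist, rho, window = c(0.2, 4)) {
  sel <- dist >= window[1] & dist <= window[2] & abs(rho) > 0
  if (sum(sel) < 3) stop("too few points in the fit window")
  fit <- stats::lm(log(abs(rho[sel])) ~ dist[sel])
  -1 / unname(stats::coef(fit)[2])
}

#' Extract the mouth-potential trace of a PNP run
#'
#' Collects the recorded per-unit mouth potentials (phii, phie) from a
#' trajectory into an interpolable trace object, used to drive the
#' reaction-diffusion and compartment models with a potential they cannot
#' compute themselves.
#'
#' @param trajectory A \code{pnp_trajectory} from a PNP run.
#' @return A \code{potential_trace}: list with \code{times} and a per-unit
#'   matrix of (phii, phie).
#' @export
potential_trace <- function(trajectory) {
  d <- trajectory$data
  ids <- vapply(trajectory$scenario$units, `[[`, "", "id")
  units <- lapply(ids, function(id) {
    cbind(phii = d[[paste0("phii_", id)]], phie = d[[paste0("phie_", id)]])
  })
  names(units) <- ids
  structure(list(times = d$time, units = units), class = "potential_trace")
}

trace_lookup <- function(trace) {
  stopifnot(inherits(trace, "potential_trace"))
  function(id, t) {
    m <- trace$units[[id]]
    if (is.null(m)) stop("potential trace has no unit '", id, "'")
    tt <- trace$times
    if (t < tt[1] - 1e-9 || t > tt[length(tt)] + 1e-9) {
      stop("potential trace does not cover t = ", t, " ms")
    }
    c(stats::approx(tt, m[, 1], t, rule = 2)$y,
      stats::approx(tt, m[, 2], t, rule = 2)$y)
  }
}
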