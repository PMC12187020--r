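# Assembly of the coupled implicit Poisson/Nernst-Planck step.
#
# Spatial discretization: conservative two-point-flux finite volumes on the
# tensor mesh.  Face diffusion coefficients are distance-weighted harmonic
# means of the adjacent cell values (so the D = 0 membrane yields exactly
# zero flux); the drift coefficient uses the arithmetic mean of the interim
# concentrations.  Permittivity at material interfaces is likewise the
# distance-weighted harmonic mean.  Unknowns: phi at every cell, one
# concentration per species at every non-membrane cell.
#
# The sparsity pattern is fixed for a given scenario, so the plan
# precomputes the CSC structure once and each step only refills the value
# vector (drift terms, channel linearization, time terms) and the RHS.
#
# Concentration unknowns are deviations from the per-subdomain reference
# concentrations (the species table's c0e/c0i).  The charge density a
# Poisson row senses is the difference of O(100 mM) charge sums that
# cancel to O(uM) resolution; solving for the deviations keeps that
# cancellation analytic instead of numerical, so the electroneutral
# uniform state is an exact fixed point in floating point and conservation
# audits are not polluted by catastrophic cancellation.  The reference is
# constant within each connected (membrane-separated) subdomain, so
# diffusive fluxes of deviations equal fluxes of full concentrations
# exactly.

dw_harmonic <- function(da, db, va, vb) {
  out <- numeric(length(va))
  ok <- va > 0 & vb > 0
  out[ok] <- (da[ok] + db[ok]) / (da[ok] / va[ok] + db[ok] / vb[ok])
  out
}

side_names_all <- c("xmin", "xmax", "ymin", "ymax", "zmin", "zmax")

resolve_sides <- function(sides) {
  if (is.null(sides) || identical(sides, "none")) return(character(0))
  if (identical(sides, "all")) return(side_names_all)
  stopifnot(all(sides %in% side_names_all))
  sides
}

#' Solver configuration
#'
#' @param tol Linear-solver relative residual tolerance.
#' @param maxit Maximum BiCGSTAB iterations before falling back to a direct
#'   sparse solve.
#' @param eps1 Relative permittivity in the aqueous subdomains.
#' @param epsm Relative permittivity in the membrane.
#' @param phi_dirichlet Sides with phi = 0 Dirichlet conditions ("xmin" by
#'   default: the left, T-tubule-lumen boundary anchors the potential);
#'   "all", "none", or a character vector of sides.
#' @param conc_dirichlet NULL for the default no-flux boundaries, or a list
#'   \code{list(sides =, values = c(species = mM))} fixing boundary
#'   concentrations (used by the 2D perturbation example).
#' @param method "iterative" (ILUT-preconditioned BiCGSTAB, the default)
#'   or "direct" (sparse LU; exact to machine precision, used for
#'   conservation audits on small meshes where Krylov accuracy is limited
#'   by the conditioning of the coupled system).
#' @param lfil Maximum retained entries per row and part in the ILUT
#'   preconditioner.
#' @param droptol Relative drop tolerance of the ILUT preconditioner.
#' @param reuse_factor Reuse the incomplete factorization across steps
#'   (refreshed when convergence degrades).  Disable for bitwise
#'   reproducibility across checkpoint restarts: with reuse, the iterate
#'   sequence depends on when the factorization was last rebuilt, so a
#'   resumed run agrees with the uninterrupted one only to the solver
#'   tolerance.
#' @param drift_off Zero the electrical drift term in the transport
#'   equations (equivalence switch used to cross-check the
#'   reaction-diffusion model; the potential is still solved but no longer
#'   moves ions in the bulk).
#' @param neg_tol Most negative concentration (mM) tolerated before the
#'   step aborts with a diagnostic.
#' @return A list of class \code{solver_config}.
#' @export
solver_config <- function(tol = 1e-10, maxit = 300, eps1 = 80, epsm = 2,
                          phi_dirichlet = "xmin", conc_dirichlet = NULL,
                          method = "iterative", lfil = 40, droptol = 1e-3,
                          reuse_factor = TRUE, drift_off = FALSE,
                          neg_tol = 1e-6) {
  stopifnot(tol > 0, tol < 1, maxit >= 1, eps1 > 0, epsm > 0, lfil >= 1,
            method %in% c("iterative", "direct"))
  structure(list(tol = tol, maxit = maxit, eps1 = eps1, epsm = epsm,
                 phi_dirichlet = phi_dirichlet,
                 conc_dirichlet = conc_dirichlet,
                 method = method, lfil = lfil, droptol = droptol,
                 reuse_factor = reuse_factor,
                 drift_off = drift_off, neg_tol = neg_tol),
            class = "solver_config")
}

# Build the per-scenario assembly plan: fixed CSC structure plus the index
# arrays needed to refill values quickly.  `model` is "pnp", "diffusion" or
# "reaction_diffusion".
build_assembly_plan <- function(mesh, species, units, config, constants,
                                model = "pnp", buffers = NULL) {
  zt <- if (!is.null(buffers) && nrow(buffers)) {
    species$z[match(buffers$target, species$name)]
  } else numeric(0)
  K <- nrow(species)
  ncell <- mesh$ncell
  notm <- mesh$label != 2L
  ncc <- sum(notm)
  n <- ncell + K * ncc
  # interleaved unknown ordering: per cell phi, then its K concentrations
  # (membrane cells carry only phi); keeps strongly coupled unknowns close,
  # which the incomplete factorization needs
  width <- ifelse(notm, 1L + K, 1L)
  phi_idx <- cumsum(c(1L, width[-ncell]))
  cidx <- function(k, cells) phi_idx[cells] + k
  Vt <- thermal_voltage(constants)
  fc <- mesh$faces
  epsc <- ifelse(mesh$label == 2L, config$epsm, config$eps1)
  use_poisson <- model == "pnp"
  use_drift <- use_poisson && !isTRUE(config$drift_off)
  use_units <- model != "diffusion"

  # per-subdomain reference concentrations (0 in the membrane)
  cref <- matrix(0, ncell, K, dimnames = list(NULL, species$name))
  for (k in seq_len(K)) {
    cref[mesh$label == 1L, k] <- species$c0e[k]
    cref[mesh$label == 3L, k] <- species$c0i[k]
  }
  qref <- constants$F * drop(cref %*% species$z)   # C/m^3 per cell

  ti <- list(); tj <- list(); tx <- list()   # triplets; tx NA marks dynamic
  seg <- list()                              # name -> index range
  pos <- 0L
  push <- function(name, i, j, x) {
    m <- length(i)
    ti[[length(ti) + 1L]] <<- i
    tj[[length(tj) + 1L]] <<- j
    tx[[length(tx) + 1L]] <<- x
    seg[[name]] <<- pos + seq_len(m)
    pos <<- pos + m
  }

  if (use_poisson) {
    s <- constants$eps0 * dw_harmonic(fc$da, fc$db, epsc[fc$a], epsc[fc$b]) *
      fc$area / (fc$da + fc$db)
    push("P_face",
         phi_idx[c(fc$a, fc$a, fc$b, fc$b)], phi_idx[c(fc$a, fc$b, fc$b, fc$a)],
         c(s, -s, s, -s))
    psides <- resolve_sides(config$phi_dirichlet)
    if (length(psides)) {
      bd <- mesh$bnd[mesh$bnd$side %in% psides, , drop = FALSE]
      sb <- constants$eps0 * epsc[bd$cell] * bd$area / bd$dhalf
      push("P_dir", phi_idx[bd$cell], phi_idx[bd$cell], sb)
    } else {
      stop("no Dirichlet anchor for the potential; the Poisson system ",
           "would be singular")
    }
    nm <- which(notm)
    push("P_c",
         rep(phi_idx[nm], K),
         unlist(lapply(seq_len(K), function(k) cidx(k, nm))),
         -constants$F * rep(species$z, each = length(nm)) * rep(mesh$vol[nm], K))
  } else {
    push("P_ident", phi_idx, phi_idx, rep(1, ncell))
  }

  csides <- if (!is.null(config$conc_dirichlet))
    resolve_sides(config$conc_dirichlet$sides) else character(0)
  bdc <- if (length(csides))
    mesh$bnd[mesh$bnd$side %in% csides, , drop = FALSE] else NULL

  sp_face <- vector("list", K)
  sp_bdir <- vector("list", K)
  for (k in seq_len(K)) {
    Dc <- ifelse(mesh$label == 1L, species$De[k],
                 ifelse(mesh$label == 3L, species$Di[k], 0))
    Df <- dw_harmonic(fc$da, fc$db, Dc[fc$a], Dc[fc$b])
    sel <- which(Df > 0)
    fa <- fc$a[sel]; fb <- fc$b[sel]
    gd <- Df[sel] * fc$area[sel] / (fc$da[sel] + fc$db[sel])
    pf <- gd * species$z[k] / Vt
    ra <- cidx(k, fa); rb <- cidx(k, fb)
    nm <- which(notm)
    rows <- cidx(k, nm)
    push(paste0("time_", k), rows, rows, rep(NA_real_, length(rows)))
    push(paste0("diff_", k),
         c(ra, ra, rb, rb), c(ra, rb, rb, ra), c(gd, -gd, gd, -gd))
    sp_face[[k]] <- list(fa = fa, fb = fb, pf = pf, gd = gd,
                         ra = ra, rb = rb)
    if (!is.null(bdc)) {
      bcell <- bdc$cell
      keep <- Dc[bcell] > 0
      bcell <- bcell[keep]
      gb <- Dc[bcell] * bdc$area[keep] / bdc$dhalf[keep]
      pb <- gb * species$z[k] / Vt
      rc <- cidx(k, bcell)
      push(paste0("cdir_", k), rc, rc, gb)
      cbc <- unname(config$conc_dirichlet$values[species$name[k]])
      # a corner cell sits on several boundary faces: aggregate its RHS
      agg <- rowsum(gb * (cbc - cref[bcell, k]), rc)
      sp_bdir[[k]] <- list(cells = bcell, gb = gb, pb = pb, rc = rc,
                           cbc = cbc,
                           rhs_idx = as.integer(rownames(agg)),
                           rhs_val = as.vector(agg))
      if (use_drift) {
        push(paste0("bdrift_", k), rc, phi_idx[bcell],
             rep(NA_real_, length(rc)))
      }
    }
    if (use_drift) {
      push(paste0("drift_", k),
           c(ra, ra, rb, rb), phi_idx[c(fa, fb, fb, fa)],
           rep(NA_real_, 4L * length(fa)))
    }
  }

  chans <- list()
  if (use_units) {
    for (u in units) {
      uf <- mesh$unit_faces[[u$id]]
      if (is.null(uf)) stop("unit '", u$id, "' has no registered mouth faces")
      if (u$kind == "channel") {
        k <- match(u$ion, species$name)
        Ic <- uf$i$cells; Ec <- uf$e$cells
        fi <- uf$i$scale * uf$i$areas       # amount/ms per unit of J, i-side
        fe <- uf$e$scale * uf$e$areas
        rows <- c(cidx(k, Ic), cidx(k, Ec))
        rowfac <- c(fi, -fe)                # +J leaves i-side, enters e-side
        if (model == "pnp") {
          cols <- c(phi_idx[Ic], phi_idx[Ec], cidx(k, Ic), cidx(k, Ec))
        } else {
          cols <- c(cidx(k, Ic), cidx(k, Ec))
        }
        nrw <- length(rows); ncl <- length(cols)
        push(paste0("chan_", u$id),
             rep(rows, times = ncl), rep(cols, each = nrw),
             rep(NA_real_, nrw * ncl))
        chans[[u$id]] <- list(k = k, rows = rows, rowfac = rowfac,
                              wi = uf$i$w, we = uf$e$w, nI = length(Ic),
                              nE = length(Ec), spec = u)
      }
    }
  }

  i <- unlist(ti, use.names = FALSE)
  j <- unlist(tj, use.names = FALSE)
  x0 <- unlist(tx, use.names = FALSE)
  key <- (j - 1) * n + i
  uk <- sort(unique(key))
  slot <- findInterval(key, uk)
  nnz <- length(uk)
  acc_ord <- order(slot)
  acc_ends <- cumsum(tabulate(slot, nbins = nnz))
  col0 <- (uk - 1) %/% n            # 0-based columns
  Ap <- c(0L, cumsum(tabulate(col0 + 1L, nbins = n)))
  Ai <- as.integer((uk - 1) %% n)   # 0-based rows

  list(model = model, n = n, ncell = ncell, ncc = ncc, K = K,
       phi_idx = phi_idx, notm = notm, cidx = cidx, species = species,
       constants = constants, config = config, Vt = Vt, zt = zt,
       cref = cref, qref = qref,
       trip_i = i, trip_j = j, x0 = x0, slot = slot, nnz = nnz,
       acc_ord = acc_ord, acc_ends = acc_ends,
       Ai = Ai, Ap = as.integer(Ap), seg = seg,
       sp_face = sp_face, sp_bdir = sp_bdir, chans = chans,
       use_poisson = use_poisson, use_drift = use_drift,
       use_units = use_units, mesh = mesh, units = units)
}

# Fill triplet values and RHS for one step.
#  state  : previous-step state (phi used by Poisson rhs via rho0/bound)
#  ctilde : interim concentrations from the buffering step
#  bound  : updated bound pools (enter the Poisson right-hand side)
#  t      : time at the start of the step (gating is evaluated here)
#  trace  : potential-trace lookup function(id, t) -> c(phii, phie), for the
#           reaction-diffusion model
fill_system <- function(plan, state, ctilde, bound, dt, t, trace = NULL) {
  mesh <- plan$mesh
  species <- plan$species
  constants <- plan$constants
  x <- plan$x0
  rhs <- numeric(plan$n)
  vols <- mesh$vol
  notm <- plan$notm

  if (plan$use_poisson) {
    # rho = (rho0 + qref + F sum z b) + F sum z (c - cref); the bracket is
    # the small residual charge, the deviation part sits on the LHS
    rb <- (state$rho0 + plan$qref) * vols
    if (length(plan$zt) && ncol(bound)) {
      rb <- rb + constants$F * drop(bound %*% plan$zt) * vols
    }
    rhs[plan$phi_idx] <- rb
  }

  for (k in seq_len(plan$K)) {
    sf <- plan$sp_face[[k]]
    rows <- plan$seg[[paste0("time_", k)]]
    nmv <- vols[notm] / dt
    x[rows] <- nmv
    rhs[plan$cidx(k, which(notm))] <-
      nmv * (ctilde[notm, k] - plan$cref[notm, k])
    if (plan$use_drift && length(sf$fa)) {
      ctf <- 0.5 * (ctilde[sf$fa, k] + ctilde[sf$fb, k])
      w <- sf$pf * ctf
      x[plan$seg[[paste0("drift_", k)]]] <- c(w, -w, w, -w)
    }
    bd <- plan$sp_bdir[[k]]
    if (!is.null(bd) && length(bd$cells)) {
      rhs[bd$rhs_idx] <- rhs[bd$rhs_idx] + bd$rhs_val
      if (plan$use_drift) {
        wb <- bd$pb * 0.5 * (ctilde[bd$cells, k] + bd$cbc)
        x[plan$seg[[paste0("bdrift_", k)]]] <- wb
        # phi_bc = 0 on concentration-Dirichlet boundaries
      }
    }
  }

  if (plan$use_units) {
    for (u in plan$units) {
      uf <- mesh$unit_faces[[u$id]]
      open <- is_open(u$schedule, t)
      if (u$kind == "channel") {
        ch <- plan$chans[[u$id]]
        m <- length(plan$seg[[paste0("chan_", u$id)]])
        if (!open) {
          x[plan$seg[[paste0("chan_", u$id)]]] <- rep(0, m)
          next
        }
        mt <- mouth_values(ctilde, state$phi, uf)
        aff <- channel_flux_affine(u, mt, constants, mesh$geometry$wc)
        # mouth concentrations are cref + deviation; cref is uniform on
        # each side, so its contribution folds into the constant term
        crefi <- plan$cref[uf$i$cells[1], ch$k]
        crefe <- plan$cref[uf$e$cells[1], ch$k]
        cref_const <- aff$a_ci * crefi + aff$a_ce * crefe
        if (plan$model == "pnp") {
          coefs <- c(aff$a_v * ch$wi, -aff$a_v * ch$we,
                     aff$a_ci * ch$wi, aff$a_ce * ch$we)
          const <- aff$const + cref_const
        } else {
          vtr <- trace(u$id, state$t + dt)
          coefs <- c(aff$a_ci * ch$wi, aff$a_ce * ch$we)
          const <- aff$const + cref_const + aff$a_v * (vtr[1] - vtr[2])
        }
        x[plan$seg[[paste0("chan_", u$id)]]] <- outer(ch$rowfac, coefs)
        rhs[ch$rows] <- rhs[ch$rows] - ch$rowfac * const
      } else if (u$kind == "ncx") {
        if (!open) next
        mt <- mouth_values(ctilde, state$phi, uf)
        v <- if (plan$model == "pnp") mt$v else {
          vtr <- trace(u$id, state$t)
          vtr[1] - vtr[2]
        }
        INCX <- ncx_current_density(v, mt$ci[["Na"]], mt$ce[["Na"]],
                                    mt$ci[["Ca"]], mt$ce[["Ca"]], u, constants)
        Jd <- ncx_flux_densities(INCX, u, constants, mesh$geometry$wc)
        for (ion in c("Na", "Ca")) {
          k <- match(ion, species$name)
          ri <- plan$cidx(k, uf$i$cells)
          re <- plan$cidx(k, uf$e$cells)
          rhs[ri] <- rhs[ri] - uf$i$scale * uf$i$areas * Jd[[ion]]
          rhs[re] <- rhs[re] + uf$e$scale * uf$e$areas * Jd[[ion]]
        }
      }
    }
  }

  cx <- cumsum(x[plan$acc_ord])[plan$acc_ends]
  xacc <- c(cx[1], diff(cx))
  list(Ai = plan$Ai, Ap = plan$Ap, Ax = xacc, rhs = rhs, n = plan$n)
}

# area-weighted mouth averages on interim concentrations / previous phi
mouth_values <- function(conc, phi, uf) {
  phii <- sum(uf$i$w * phi[uf$i$cells])
  phie <- sum(uf$e$w * phi[uf$e$cells])
  ci <- drop(uf$i$w %*% conc[uf$i$cells, , drop = FALSE])
  ce <- drop(uf$e$w %*% conc[uf$e$cells, , drop = FALSE])
  names(ci) <- names(ce) <- colnames(conc)
  list(phii = phii, phie = phie, v = phii - phie, ci = ci, ce = ce)
}

#' Assemble the coupled implicit system for one time step
#'
#' Discretizes the Poisson equation (with subdomain permittivities and the
#' bound-buffer charge) and the backward-Euler Nernst-Planck equations
#' (with the drift coefficient frozen at the interim concentrations) as one
#' sparse linear system over (phi at all cells, concentrations at
#' non-membrane cells), including the implicit affine channel fluxes and
#' the explicit exchanger fluxes on the mouth faces.
#'
#' @param state A \code{pnp_state} (previous step).
#' @param ctilde Interim concentrations from \code{\link{buffering_step}}.
#' @param mesh A \code{tensor_mesh}.
#' @param units List of membrane units.
#' @param config A \code{\link{solver_config}}.
#' @param dt Time step (ms).
#' @param species Species table.
#' @param constants Physical constants.
#' @param model "pnp", "diffusion" or "reaction_diffusion".
#' @param bound Updated bound pools (defaults to \code{state$bound}).
#' @param trace Potential-trace function for the reaction-diffusion model.
#' @param plan Optional precomputed assembly plan (rebuilt if NULL).
#' @return A list with the CSC matrix slots (\code{Ai}, \code{Ap},
#'   \code{Ax}, 0-based), \code{rhs}, \code{n} and the \code{plan}.
#' @export
assemble_coupled_system <- function(state, ctilde, mesh, units, config,
                                    dt, species = default_species(),
                                    constants = pnp_constants(),
                                    model = "pnp", bound = state$bound,
                                    buffers = NULL, trace = NULL, plan = NULL) {
  if (is.null(plan)) {
    plan <- build_assembly_plan(mesh, species, units, config, constants,
                                model, buffers)
  }
  sys <- fill_system(plan, state, ctilde, bound, dt, state$t, trace)
  sys$plan <- plan
  sys
}

#' Solve one assembled step
#'
#' Solves the coupled sparse system with an ILU(0)-preconditioned BiCGSTAB
#' (after max-norm equilibration); if the iteration does not reach the
#' configured relative residual it falls back to a direct sparse LU.
#'
#' @param sys Output of \code{\link{assemble_coupled_system}} (or of the
#'   internal fast path).
#' @param config A \code{\link{solver_config}}.
#' @param cache Optional environment reusing the incomplete factorization
#'   across consecutive steps (the matrix changes slowly within a phase);
#'   the factorization is refreshed whenever the iteration count degrades
#'   or the solve stops converging.
#' @return The solution vector (length \code{sys$n}).
#' @export
solve_step <- function(sys, config, cache = NULL) {
  if (identical(config$method, "direct")) {
    A <- Matrix::sparseMatrix(i = sys$Ai + 1L, p = sys$Ap, x = sys$Ax,
                              dims = c(sys$n, sys$n))
    return(as.vector(Matrix::solve(A, sys$rhs)))
  }
  if (is.null(cache) || isFALSE(config$reuse_factor)) {
    cache <- new.env(parent = emptyenv())
  }
  refactor <- is.null(cache$pc)
  if (!refactor) {
    res <- .cpp_bicgstab_pc(cache$pc, sys$Ai, sys$Ap, sys$Ax, sys$rhs,
                            config$tol, config$maxit)
    if (!res$converged || res$iter > max(80, 3 * cache$base_iters)) {
      refactor <- TRUE
    }
  }
  if (refactor) {
    cache$pc <- .cpp_ilut_factor(sys$Ai, sys$Ap, sys$Ax, sys$n,
                                 config$lfil, config$droptol)
    res <- .cpp_bicgstab_pc(cache$pc, sys$Ai, sys$Ap, sys$Ax, sys$rhs,
                            config$tol, config$maxit)
    cache$base_iters <- res$iter
  }
  if (!res$converged) {
    A <- Matrix::sparseMatrix(i = sys$Ai + 1L, p = sys$Ap, x = sys$Ax,
                              dims = c(sys$n, sys$n))
    sol <- try(as.vector(Matrix::solve(A, sys$rhs)), silent = TRUE)
    if (inherits(sol, "try-error")) {
      stop("linear solver did not converge (relative residual ",
           format(res$resid), " after ", res$iter, " iterations) and the ",
           "direct fallback failed")
    }
    return(sol)
  }
  res$x
}

# unpack a solution vector into phi / conc
unpack_solution <- function(plan, sol) {
  phi <- sol[plan$phi_idx]
  conc <- plan$cref
  nm <- which(plan$notm)
  for (k in seq_len(plan$K)) {
    conc[nm, k] <- conc[nm, k] + sol[plan$cidx(k, nm)]
  }
  list(phi = phi, conc = conc)
}
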