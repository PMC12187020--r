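# Time stepping: first-order operator splitting per step
#   1. explicit forward-Euler buffering update  (c -> ctilde, b -> b^n)
#   2. fully coupled implicit Poisson/Nernst-Planck solve (phi^n, c^n)
# Channel fluxes enter step 2 implicitly through their affine
# linearization; exchanger fluxes are explicit (previous-step potential,
# interim concentrations).

#' Run a scenario
#'
#' Advances the configured model (\code{pnp}, \code{diffusion},
#' \code{reaction_diffusion}) over the scenario's phase table, applying
#' gating schedules and recording observables at the requested cadence.
#'
#' @param scenario A scenario list (see \code{\link{pnp_scenario}} and
#'   \code{\link{preset}}).
#' @param state Optional initial \code{pnp_state} (e.g. a relaxed resting
#'   state from a previous run or checkpoint); defaults to the scenario's
#'   electroneutral initial condition.
#' @param mesh Optional prebuilt mesh (must match the scenario geometry).
#' @param verbose Print per-phase progress.
#' @return A \code{pnp_trajectory}: list with \code{times} (ms),
#'   \code{data} (data.frame of observables), \code{state} (final state),
#'   \code{mesh}, \code{scenario}, and \code{snapshots} (list of saved
#'   states, if requested).
#' @export
run_scenario <- function(scenario, state = NULL, mesh = NULL, verbose = FALSE) {
  sc <- validate_scenario(scenario)
  constants <- sc$constants
  species <- sc$species
  buffers <- sc$buffers
  if (is.null(mesh)) {
    mesh <- build_mesh(sc$geometry,
                       placements = lapply(sc$units, `[[`, "placement"),
                       fine_dx = sc$mesh$fine_dx, fine_dyz = sc$mesh$fine_dyz,
                       max_h = sc$mesh$max_h, uniform = isTRUE(sc$mesh$uniform))
  }
  if (is.null(state)) {
    state <- init_state(mesh, species, buffers, constants,
                        conc_init = sc$init)
    if (identical(sc$rho0_mode, "zero")) state$rho0[] <- 0
  }
  zt <- if (!is.null(buffers) && nrow(buffers)) {
    species$z[match(buffers$target, species$name)]
  } else numeric(0)

  config <- sc$solver
  plan <- build_assembly_plan(mesh, species, sc$units, config, constants,
                              model = sc$model, buffers = buffers)
  trace_fun <- if (!is.null(sc$potential_trace)) {
    trace_lookup(sc$potential_trace)
  } else if (sc$model == "reaction_diffusion") {
    stop("the reaction-diffusion model needs a potential trace")
  } else NULL

  obs_plan <- prepare_observables(sc, mesh)
  solver_cache <- new.env(parent = emptyenv())
  rows <- list()
  snaps <- list()
  snap_times <- sort(sc$snapshots)
  rows[[1]] <- observe_row(state, mesh, sc, obs_plan, zt)

  for (ph in seq_len(nrow(sc$phases))) {
    dt <- sc$phases$dt[ph]
    t_end <- sc$phases$t_end[ph]
    rec <- sc$phases$record_every[ph]
    nstep <- max(0L, round((t_end - state$t) / dt))
    if (verbose) {
      message(sprintf("phase %d: %d steps of dt = %g ms to t = %g ms",
                      ph, nstep, dt, t_end))
    }
    for (s in seq_len(nstep)) {
      state <- advance_step(state, plan, mesh, sc, dt, zt, trace_fun,
                            solver_cache)
      if (s %% rec == 0L || s == nstep) {
        rows[[length(rows) + 1L]] <- observe_row(state, mesh, sc, obs_plan, zt)
      }
      while (length(snap_times) &&
             state$t >= snap_times[1] - 1e-12) {
        snaps[[length(snaps) + 1L]] <- state
        snap_times <- snap_times[-1]
      }
    }
  }

  data <- do.call(rbind, lapply(rows, as.data.frame))
  structure(list(times = data$time, data = data, state = state,
                 mesh = mesh, scenario = sc, snapshots = snaps),
            class = "pnp_trajectory")
}

advance_step <- function(state, plan, mesh, sc, dt, zt, trace_fun,
                         solver_cache = NULL) {
  if (sc$model == "diffusion") {
    ctilde <- state$conc
    bound <- state$bound
  } else {
    bs <- buffering_step(state, mesh, sc$species, sc$buffers, dt)
    ctilde <- bs$ctilde
    bound <- bs$bound
  }
  sys <- fill_system(plan, state, ctilde, bound, dt, state$t, trace_fun)
  sol <- solve_step(sys, sc$solver, solver_cache)
  up <- unpack_solution(plan, sol)
  if (min(up$conc[plan$notm, ]) < -sc$solver$neg_tol) {
    stop(sprintf(
      "negative concentration (%.3g mM) at t = %g ms; reduce dt",
      min(up$conc[plan$notm, ]), state$t + dt))
  }
  state$phi <- up$phi
  state$conc <- up$conc
  state$bound <- bound
  state$t <- state$t + dt
  state
}

prepare_observables <- function(sc, mesh) {
  pts <- list()
  if (!is.null(sc$observe$points)) {
    for (nm in names(sc$observe$points)) {
      p <- sc$observe$points[[nm]]
      cell <- if (is.numeric(p)) {
        as.integer(p)
      } else if (!is.null(p$unit)) {
        u <- sc$units[[match(p$unit, vapply(sc$units, `[[`, "", "id"))]]
        observation_point(mesh, u$placement,
                          if (is.null(p$x_fraction)) 0.5 else p$x_fraction)
      } else {
        i <- which.min(abs(mesh$xc - p$x))
        j <- which.min(abs(mesh$yc - p$y))
        k <- if (mesh$dims == 3) which.min(abs(mesh$zc - p$z)) else 1L
        cell_index(mesh, i, j, k)
      }
      pts[[nm]] <- cell
    }
  }
  ryr <- NULL
  if (!is.null(sc$observe$ryr)) {
    r <- sc$observe$ryr
    u <- sc$units[[match(r$unit, vapply(sc$units, `[[`, "", "id"))]]
    ryr <- c(sr_patch_cells(mesh, u$placement,
                            if (is.null(r$patch)) 30 else r$patch),
             list(threshold = if (is.null(r$threshold)) 5e-4 else r$threshold))
  }
  list(points = pts, ryr = ryr)
}

observe_row <- function(state, mesh, sc, obs_plan, zt) {
  row <- list(time = state$t)
  for (u in sc$units) {
    uf <- mesh$unit_faces[[u$id]]
    mt <- mouth_values(state$conc, state$phi, uf)
    row[[paste0("v_", u$id)]] <- mt$v
    row[[paste0("phii_", u$id)]] <- mt$phii
    row[[paste0("phie_", u$id)]] <- mt$phie
    if (u$kind == "ncx") {
      row[[paste0("INCX_", u$id)]] <-
        ncx_current_density(mt$v, mt$ci[["Na"]], mt$ce[["Na"]],
                            mt$ci[["Ca"]], mt$ce[["Ca"]], u, sc$constants)
    } else {
      row[[paste0("ci_", u$id)]] <- mt$ci[[u$ion]]
      row[[paste0("ce_", u$id)]] <- mt$ce[[u$ion]]
    }
  }
  for (nm in names(obs_plan$points)) {
    cell <- obs_plan$points[[nm]]
    for (k in seq_len(ncol(state$conc))) {
      row[[paste0(nm, "_", colnames(state$conc)[k])]] <- state$conc[cell, k]
    }
    row[[paste0(nm, "_phi")]] <- state$phi[cell]
  }
  if (!is.null(obs_plan$ryr)) {
    row$ryr_ca <- sum(obs_plan$ryr$w *
                        state$conc[obs_plan$ryr$cells, "Ca"])
  }
  # per-species total amount (free + bound), for conservation audits
  for (k in seq_len(ncol(state$conc))) {
    tot <- sum(state$conc[, k] * mesh$vol)
    if (ncol(state$bound)) {
      bt <- sc$buffers$target == colnames(state$conc)[k]
      if (any(bt)) {
        tot <- tot + sum(state$bound[, bt, drop = FALSE] %*%
                           rep(1, sum(bt)) * mesh$vol)
      }
    }
    row[[paste0("mass_", colnames(state$conc)[k])]] <- tot
  }
  rho <- charge_density(state, mesh, sc$species, sc$buffers, sc$constants)
  row$rho_max <- max(abs(rho))
  if (length(obs_plan$points)) {
    row$rho_center <- rho[obs_plan$points[[1]]]
  }
  row
}

#' Save / load a restartable checkpoint
#'
#' A checkpoint stores the state, mesh and a hash of the scenario
#' configuration; \code{load_checkpoint} refuses to resume under a
#' different configuration unless \code{force = TRUE}.
#'
#' @param trajectory A \code{pnp_trajectory} (or list with \code{state},
#'   \code{mesh}, \code{scenario}).
#' @param path File path.
#' @export
save_checkpoint <- function(trajectory, path) {
  obj <- list(state = trajectory$state, mesh = trajectory$mesh,
              scenario_hash = scenario_hash(trajectory$scenario),
              scenario_name = trajectory$scenario$name)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @param scenario Scenario the checkpoint is resumed under.
#' @param force Skip the configuration-hash check.
#' @export
load_checkpoint <- function(path, scenario = NULL, force = FALSE) {
  obj <- readRDS(path)
  if (!is.null(scenario) && !force &&
      !identical(obj$scenario_hash, scenario_hash(scenario))) {
    stop("checkpoint was written under a different configuration; ",
         "use force = TRUE to resume anyway")
  }
  obj
}

scenario_hash <- function(sc) {
  keep <- sc[setdiff(names(sc), c("phases", "snapshots", "observe"))]
  paste(utils::capture.output(utils::str(keep, digits.d = 12)),
        collapse = "\n")
}

#' @export
print.pnp_trajectory <- function(x, ...) {
  cat("<pnp_trajectory> scenario '", x$scenario$name, "' (",
      x$scenario$model, "), ", length(x$times), " samples to t = ",
      max(x$times), " ms\n", sep = "")
  invisible(x)
}
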