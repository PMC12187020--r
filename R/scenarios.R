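#' Construct a scenario
#'
#' A scenario bundles everything one run needs: the model switch, the
#' geometry, species/buffer tables, membrane units with gating schedules,
#' mesh and solver settings, the phase table (end time, dt and output
#' cadence per phase) and the observables.  Unknown fields are rejected.
#'
#' @param name Scenario name.
#' @param model One of "pnp", "diffusion", "reaction_diffusion".
#' @param geometry A \code{\link{dyad_geometry}}.
#' @param species Species table.
#' @param buffers Buffer table or NULL.
#' @param constants Physical constants.
#' @param units List of membrane units (may be empty).
#' @param mesh List: \code{fine_dx}, \code{fine_dyz}, \code{max_h},
#'   \code{uniform}.
#' @param solver A \code{\link{solver_config}}.
#' @param phases data.frame with columns \code{t_end}, \code{dt},
#'   \code{record_every}.
#' @param init Optional initial-concentration override (matrix or
#'   function(mesh, species)).
#' @param rho0_mode "electroneutral" (background charge cancels the initial
#'   mobile charge) or "zero".
#' @param observe List: \code{points} (named list of cell indices, unit
#'   references or coordinates) and \code{ryr} (unit, patch, threshold).
#' @param potential_trace A \code{potential_trace} for the
#'   reaction-diffusion model.
#' @param snapshots Times (ms) at which to keep full state snapshots.
#' @param marks Named numeric vector of reference times (e.g. channel
#'   opening) carried along for analysis.
#' @param seed Unused; reserved for stochastic gating extensions.
#' @return A validated scenario list (class \code{pnp_scenario}).
#' @export
pnp_scenario <- function(name, model = "pnp", geometry = dyad_geometry(),
                         species = default_species(),
                         buffers = default_buffers(),
                         constants = pnp_constants(), units = list(),
                         mesh = list(), solver = solver_config(),
                         phases, init = NULL,
                         rho0_mode = c("electroneutral", "zero"),
                         observe = list(), potential_trace = NULL,
                         snapshots = numeric(0), marks = numeric(0),
                         seed = NULL) {
  sc <- list(name = name, model = model, geometry = geometry,
             species = species, buffers = buffers, constants = constants,
             units = units,
             mesh = utils::modifyList(
               list(fine_dx = 0.5, fine_dyz = 2, max_h = 64,
                    uniform = FALSE), mesh),
             solver = solver, phases = phases, init = init,
             rho0_mode = match.arg(rho0_mode), observe = observe,
             potential_trace = potential_trace, snapshots = snapshots,
             marks = marks, seed = seed)
  class(sc) <- "pnp_scenario"
  validate_scenario(sc)
}

scenario_fields <- c("name", "model", "geometry", "species", "buffers",
                     "constants", "units", "mesh", "solver", "phases",
                     "init", "rho0_mode", "observe", "potential_trace",
                     "snapshots", "marks", "seed")

#' Validate a scenario
#' @param sc A scenario list.
#' @return The scenario, invisibly checked.
#' @export
validate_scenario <- function(sc) {
  unknown <- setdiff(names(sc), scenario_fields)
  if (length(unknown)) {
    stop("unknown scenario fields: ", paste(unknown, collapse = ", "))
  }
  stopifnot(sc$model %in% c("pnp", "diffusion", "reaction_diffusion"),
            inherits(sc$geometry, "dyad_geometry"),
            is.data.frame(sc$phases),
            all(c("t_end", "dt", "record_every") %in% names(sc$phases)),
            all(sc$phases$dt > 0), all(diff(c(0, sc$phases$t_end)) > 0))
  validate_species(sc$species)
  validate_buffers(sc$buffers)
  ids <- vapply(sc$units, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("duplicate unit ids")
  sc
}

# standard four-unit layout: K+/Na+ pair on the main membrane, Ca2+/NCX
# pair in the dyad region; all at z = Lz/2, separations in y.  Positions
# scale with the transverse extent so reduced-domain runs stay valid.
standard_placements <- function(geometry, pair_sep = 20) {
  zc <- if (geometry$dims == 3) geometry$Lz / 2 else NA_real_
  y0 <- 0.20 * geometry$Ly
  y1 <- 0.48 * geometry$Ly
  list(K   = unit_placement("K", y0, zc, "main"),
       Na  = unit_placement("Na", y0 + pair_sep, zc, "main"),
       Ca  = unit_placement("Ca", y1, zc, "dyad"),
       NCX = unit_placement("NCX", y1 + pair_sep, zc, "dyad"))
}

dyad_units <- function(geometry, kK = always_open(),
                       kNa = always_closed(), kCa = always_closed(),
                       kNCX = always_closed(), na_by_ncx = FALSE,
                       pair_sep = 20) {
  pl <- standard_placements(geometry, pair_sep)
  if (na_by_ncx) {
    pl$Na <- unit_placement("Na", pl$NCX$y - pair_sep, pl$NCX$z, "dyad")
    pl$Ca <- unit_placement("Ca", pl$NCX$y - 2 * pair_sep, pl$NCX$z, "dyad")
  }
  list(channel_spec("K", placement = pl$K, schedule = kK),
       channel_spec("Na", placement = pl$Na, schedule = kNa),
       channel_spec("Ca", placement = pl$Ca, schedule = kCa),
       ncx_spec(placement = pl$NCX, schedule = kNCX))
}

#' Scenario presets
#'
#' Returns one of the named scenario presets.  Each preset carries two
#' resolutions: \code{"paper"} uses the reference time steps and mesh
#' spacings of the corresponding published simulation setups, while
#' \code{"smoke"} (the default) coarsens the transverse mesh and the time
#' step so the scenario runs at desk scale; the physics configuration
#' (geometry, gating, parameters) is identical.  Additional arguments are
#' forwarded to the preset builder (e.g. \code{Ly}, \code{Lz} for reduced
#' transverse domains, \code{Li}, \code{DCa} for the sweep presets).
#'
#' Available presets: \code{perturbation2d} (2D two-ion relaxation after a
#' local K+ perturbation, Dirichlet 100 mM boundaries),
#' \code{debye2d} (Debye-layer formation at a sealed membrane, 100.1/99.9
#' mM split), \code{rest3d} (open K+ channel relaxing to the resting
#' state), \code{upstroke3d} (Na+ channel opening after a settling phase),
#' \code{ca_open} (dyadic Ca2+ channel opening, NCX closed),
#' \code{ca_ncx} (as ca_open with the NCX open), \code{ncx_only} (NCX open,
#' Ca2+ channel closed), \code{ncx_enhanced} (narrow dyad, halved
#' intracellular diffusion, Na+ channel adjacent to the NCX), and
#' \code{ryr_sweep} (one grid point of the activation-time sweep over dyad
#' width and Ca2+ diffusion coefficient).
#'
#' @param name Preset name.
#' @param resolution "smoke" or "paper".
#' @param ... Builder-specific parameters.
#' @return A \code{pnp_scenario}.
#' @export
preset <- function(name, resolution = c("smoke", "paper"), ...) {
  resolution <- match.arg(resolution)
  reg <- preset_registry()
  if (!name %in% names(reg)) {
    stop("unknown preset '", name, "'; available: ",
         paste(names(reg), collapse = ", "))
  }
  reg[[name]](resolution = resolution, ...)
}

#' @rdname preset
#' @export
list_presets <- function() names(preset_registry())

preset_registry <- function() {
  list(
    perturbation2d = preset_perturbation2d,
    debye2d = preset_debye2d,
    rest3d = preset_rest3d,
    upstroke3d = preset_upstroke3d,
    ca_open = preset_ca_open,
    ca_ncx = preset_ca_ncx,
    ncx_only = preset_ncx_only,
    ncx_enhanced = preset_ncx_enhanced,
    ryr_sweep = preset_ryr_sweep
  )
}

two_ion_species <- function(c0K_left = 100, c0K_right = 100) {
  data.frame(name = c("K", "Cl"), z = c(1L, -1L),
             De = c(2.03e6, 2.03e6), Di = c(2.03e6, 2.03e6),
             c0e = c(c0K_left, 100), c0i = c(c0K_right, 100),
             stringsAsFactors = FALSE)
}

# 2D relaxation of a localized K+ perturbation with fixed (100 mM, phi = 0)
# boundaries.  The domain size is not part of the reference setup; the
# default is a 50 nm box with a Gaussian bump (amplitude 10 mM, sd box/10)
# at the center.
preset_perturbation2d <- function(resolution = "smoke", box = 50, amp = 10,
                                  sigma = NULL, t_end = 6e-6,
                                  fine_dx = NULL) {
  if (is.null(sigma)) sigma <- box / 10
  if (is.null(fine_dx)) fine_dx <- if (resolution == "paper") 0.25 else 1
  geom <- dyad_geometry(Le = 0, Lm = 0, Li = box, Ly = box, dims = 2)
  init <- function(mesh, species) {
    conc <- matrix(100, mesh$ncell, nrow(species),
                   dimnames = list(NULL, species$name))
    xy <- expand.grid(x = mesh$xc, y = mesh$yc)
    r2 <- (xy$x - box / 2)^2 + (xy$y - box / 2)^2
    conc[, "K"] <- 100 + amp * exp(-r2 / (2 * sigma^2))
    conc
  }
  pnp_scenario(
    name = "perturbation2d", geometry = geom,
    species = two_ion_species(), buffers = NULL,
    mesh = list(fine_dx = fine_dx, uniform = TRUE),
    solver = solver_config(phi_dirichlet = "all",
                           conc_dirichlet = list(sides = "all",
                                                 values = c(K = 100, Cl = 100))),
    phases = data.frame(t_end = t_end, dt = 1e-7, record_every = 1),
    init = init, rho0_mode = "zero",
    observe = list(points = list(center = list(x = box / 2, y = box / 2))))
}

# 2D Debye-layer formation at a sealed membrane separating a slightly
# positive and a slightly negative region.
preset_debye2d <- function(resolution = "smoke", t_end = 1e-5) {
  geom <- dyad_geometry(Le = 22.5, Lm = 5, Li = 22.5, Ly = 50, dims = 2)
  mesh <- if (resolution == "paper") {
    list(fine_dx = 0.1, uniform = TRUE)
  } else {
    list(fine_dx = 0.1, fine_dyz = 25, max_h = 64)
  }
  pnp_scenario(
    name = "debye2d", geometry = geom,
    species = two_ion_species(c0K_left = 100.1, c0K_right = 99.9),
    buffers = NULL, mesh = mesh,
    phases = data.frame(t_end = t_end, dt = 1e-7, record_every = 10),
    rho0_mode = "zero",
    observe = list(points = list(
      x1 = list(x = 27.6, y = 25),     # 0.1 nm right of the membrane
      x2 = list(x = 47.5, y = 25))))   # 20 nm right of the membrane
}

dyad_observe <- function() {
  list(points = list(mid_ca = list(unit = "Ca", x_fraction = 0.5),
                     mid_ncx = list(unit = "NCX", x_fraction = 0.5)),
       ryr = list(unit = "Ca", patch = 30, threshold = 5e-4))
}

smoke_mesh <- function() list(fine_dyz = 8, max_h = 256)
paper_mesh <- function() list(fine_dyz = 2, max_h = 64)

# Open K+ channel relaxing the electroneutral initial state to the cell's
# resting state (Debye layer + K+ Nernst-level transmembrane potential).
preset_rest3d <- function(resolution = "smoke", Ly = 1000, Lz = 1000,
                          t_end = NULL) {
  geom <- dyad_geometry(Ly = Ly, Lz = Lz)
  units <- dyad_units(geom)
  if (is.null(t_end)) t_end <- if (resolution == "paper") 5 else 3
  mesh <- if (resolution == "paper") paper_mesh() else smoke_mesh()
  dt <- if (resolution == "paper") 1e-2 else 2e-2
  pnp_scenario(
    name = "rest3d", geometry = geom, units = units, mesh = mesh,
    phases = data.frame(t_end = t_end, dt = dt, record_every = 5),
    observe = dyad_observe(),
    marks = c(k_open = 0))
}

# Na+ channel opening 0.05 ms after a settling phase: the action-potential
# upstroke.  The settling phase replaces restarting from a stored resting
# state; the Na+ opening time is carried in `marks`.
preset_upstroke3d <- function(resolution = "smoke", Ly = 1000, Lz = 1000,
                              rest_t = 2, run_t = 0.8) {
  geom <- dyad_geometry(Ly = Ly, Lz = Lz)
  units <- dyad_units(geom, kNa = gating_schedule(rest_t + 0.05, Inf))
  mesh <- if (resolution == "paper") paper_mesh() else smoke_mesh()
  dt_active <- if (resolution == "paper") 1e-3 else 4e-3
  pnp_scenario(
    name = "upstroke3d", geometry = geom, units = units, mesh = mesh,
    phases = data.frame(t_end = c(rest_t, rest_t + run_t),
                        dt = c(2e-2, dt_active),
                        record_every = c(10, 5)),
    observe = dyad_observe(),
    marks = c(rest_end = rest_t, na_open = rest_t + 0.05))
}

dyad_preset <- function(name, resolution, Ly, Lz, rest_t, run_t, kCa, kNCX,
                        na_by_ncx = FALSE, Li = 7, Di_scale = 1,
                        DCa = NULL, fine_dx = NULL, dt_active = NULL) {
  geom <- dyad_geometry(Li = Li, Ly = Ly, Lz = Lz)
  species <- default_species()
  species$Di <- species$Di * Di_scale
  if (!is.null(DCa)) {
    f <- DCa / 2e5
    species$Di <- default_species()$Di * f
  }
  units <- dyad_units(geom, kNa = gating_schedule(rest_t + 0.05, Inf),
                      kCa = kCa, kNCX = kNCX, na_by_ncx = na_by_ncx)
  mesh <- if (resolution == "paper") paper_mesh() else smoke_mesh()
  if (is.null(fine_dx)) fine_dx <- if (Li < 5) 0.25 else 0.5
  mesh$fine_dx <- fine_dx
  if (is.null(dt_active)) {
    dt_active <- if (resolution == "paper") 1e-3 else 5e-3
  }
  pnp_scenario(
    name = name, geometry = geom, species = species, units = units,
    mesh = mesh,
    phases = data.frame(t_end = c(rest_t, rest_t + run_t),
                        dt = c(2e-2, dt_active),
                        record_every = c(10, 2)),
    observe = dyad_observe(),
    marks = c(rest_end = rest_t, na_open = rest_t + 0.05,
              ca_open = rest_t + 0.1))
}

# Dyadic Ca2+ channel opening (0.1 ms after the settling phase), NCX closed.
preset_ca_open <- function(resolution = "smoke", Ly = 1000, Lz = 1000,
                           rest_t = 2, run_t = 1) {
  dyad_preset("ca_open", resolution, Ly, Lz, rest_t, run_t,
              kCa = gating_schedule(rest_t + 0.1, Inf),
              kNCX = always_closed())
}

# As ca_open, with the NCX open throughout.
preset_ca_ncx <- function(resolution = "smoke", Ly = 1000, Lz = 1000,
                          rest_t = 2, run_t = 1) {
  dyad_preset("ca_ncx", resolution, Ly, Lz, rest_t, run_t,
              kCa = gating_schedule(rest_t + 0.1, Inf),
              kNCX = always_open())
}

# NCX open, Ca2+ channel never opens: reverse-mode Ca2+ entry after the
# Na+ channel opening.
preset_ncx_only <- function(resolution = "smoke", Ly = 1000, Lz = 1000,
                            rest_t = 2, run_t = 1) {
  dyad_preset("ncx_only", resolution, Ly, Lz, rest_t, run_t,
              kCa = always_closed(), kNCX = always_open())
}

# Enhanced-NCX variant: narrow dyad (Li = 5 nm), intracellular diffusion
# halved, Na+ channel adjacent to the NCX.
preset_ncx_enhanced <- function(resolution = "smoke", Ly = 1000, Lz = 1000,
                                rest_t = 2, run_t = 1) {
  dyad_preset("ncx_enhanced", resolution, Ly, Lz, rest_t, run_t,
              kCa = always_closed(), kNCX = always_open(),
              na_by_ncx = TRUE, Li = 5, Di_scale = 0.5)
}

# One grid point of the RyR activation-time sweep over (Li, DCa).  The
# "smoke" resolution runs the sweep in 2D (x-y plane, per-nm depth), which
# preserves the diffusion/buffering physics the sweep probes at a fraction
# of the cost; "paper" is the full 3D configuration.
preset_ryr_sweep <- function(resolution = "smoke", Li = 7, DCa = 2e5,
                             Ly = NULL, rest_t = NULL, run_t = NULL,
                             model = "pnp", potential_trace = NULL) {
  f <- DCa / 2e5
  species <- default_species()
  species$Di <- species$Di * f
  fine_dx <- if (Li < 5) 0.25 else 0.5
  if (resolution == "paper") {
    if (is.null(Ly)) Ly <- 1000
    if (is.null(rest_t)) rest_t <- 2
    if (is.null(run_t)) run_t <- 0.5
    geom <- dyad_geometry(Li = Li, Ly = Ly, Lz = Ly)
    units <- dyad_units(geom, kNa = gating_schedule(rest_t + 0.05, Inf),
                        kCa = gating_schedule(rest_t + 0.1, Inf),
                        kNCX = always_open())
    phases <- data.frame(t_end = c(rest_t, rest_t + run_t),
                         dt = c(2e-2, 1e-6), record_every = c(10, 50))
    mesh <- c(paper_mesh(), list(fine_dx = fine_dx))
    marks <- c(rest_end = rest_t, na_open = rest_t + 0.05,
               ca_open = rest_t + 0.1)
  } else {
    if (is.null(Ly)) Ly <- 150
    if (is.null(rest_t)) rest_t <- 0.01
    if (is.null(run_t)) run_t <- 0.012
    geom <- dyad_geometry(Li = Li, Ly = Ly, dims = 2)
    units <- dyad_units(geom, kNa = gating_schedule(rest_t + 0.002, Inf),
                        kCa = gating_schedule(rest_t + 0.004, Inf),
                        kNCX = always_open())
    phases <- data.frame(t_end = c(rest_t, rest_t + run_t),
                         dt = c(5e-4, 1e-5), record_every = c(5, 1))
    mesh <- list(fine_dx = fine_dx, fine_dyz = 4, max_h = 64)
    marks <- c(rest_end = rest_t, na_open = rest_t + 0.002,
               ca_open = rest_t + 0.004)
  }
  pnp_scenario(
    name = "ryr_sweep", model = model, geometry = geom, species = species,
    units = units, mesh = mesh, phases = phases,
    observe = dyad_observe(), potential_trace = potential_trace,
    marks = marks)
}
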