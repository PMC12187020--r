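test_that("transmembrane potential reads zero on a uniform state", {
  sc <- tiny_1d_scenario()
  mesh <- build_mesh(sc$geometry, lapply(sc$units, `[[`, "placement"),
                     fine_dx = 0.5, uniform = TRUE)
  st <- init_state(mesh, sc$species, NULL)
  expect_equal(transmembrane_potential(st, mesh, "K"), 0)
  expect_error(transmembrane_potential(st, mesh, "nope"), "unknown unit")
})

test_that("term breakdown satisfies the discrete balance away from
           membrane fluxes", {
  sc <- preset("perturbation2d", box = 20, amp = 5, sigma = 2, t_end = 1e-6)
  mesh <- build_mesh(sc$geometry, list(), fine_dx = 1, uniform = TRUE)
  st <- init_state(mesh, sc$species, NULL, conc_init = sc$init)
  st$rho0[] <- 0
  plan <- dyadPNP:::build_assembly_plan(mesh, sc$species, list(), sc$solver,
                                        pnp_constants(), "pnp", NULL)
  dt <- 1e-7
  st2 <- dyadPNP:::advance_step(st, plan, mesh, sc, dt, numeric(0), NULL)
  # at an interior cell: Bd + Be - Bb equals dc/dt for both species
  cell <- dyadPNP:::cell_index(mesh, 8L, 8L)
  for (s in c("K", "Cl")) {
    tb <- term_breakdown(st, st2, mesh, s, cell, dt, sc$species, NULL,
                         config = sc$solver)
    scale <- max(abs(c(tb$Bd, tb$Be, 1)))
    expect_equal(tb$Bd + tb$Be - tb$Bb, tb$dcdt,
                 tolerance = 1e-6 * scale)
  }
  # before electroneutrality is restored the electrical term dominates
  center <- dyadPNP:::cell_index(mesh, which.min(abs(mesh$xc - 10)),
                                 which.min(abs(mesh$yc - 10)))
  tb <- term_breakdown(st, st2, mesh, "K", center, dt, sc$species, NULL,
                       config = sc$solver)
  expect_gt(abs(tb$Be), abs(tb$Bd))
  # membrane points are rejected
  g2 <- dyad_geometry(Le = 3, Lm = 2, Li = 3, Ly = 1, dims = 2)
  m2 <- build_mesh(g2, list(), fine_dx = 0.5, uniform = TRUE)
  mcell <- which(m2$label == 2L)[1]
  expect_error(term_breakdown(st, st2, m2, "K", mcell, dt), "membrane")
})

test_that("uniform neutral states have vanishing transport terms", {
  sc <- tiny_1d_scenario(with_channel = FALSE)
  mesh <- build_mesh(sc$geometry, list(), fine_dx = 0.5, uniform = TRUE)
  st <- init_state(mesh, sc$species, NULL)
  plan <- dyadPNP:::build_assembly_plan(mesh, sc$species, list(), sc$solver,
                                        pnp_constants(), "pnp", NULL)
  st2 <- dyadPNP:::advance_step(st, plan, mesh, sc, 1e-5, numeric(0), NULL)
  tb <- term_breakdown(st, st2, mesh, "K", 2L, 1e-5, sc$species, NULL)
  expect_equal(tb$Bd, 0, tolerance = 1e-6)
  expect_equal(tb$Be, 0, tolerance = 1e-6)
  expect_equal(tb$Bb, 0)
})

test_that("RyR activation time interpolates and handles edge cases", {
  traj <- structure(list(data = data.frame(
    time = c(0, 0.1, 0.2, 0.3),
    ryr_ca = c(1e-4, 2e-4, 6e-4, 9e-4))), class = "pnp_trajectory")
  # crosses 5e-4 between 0.1 and 0.2: linear interpolation
  expect_equal(ryr_activation_time(traj, 0, 5e-4), 0.175)
  # measured from a later opening time
  expect_equal(ryr_activation_time(traj, 0.1, 5e-4), 0.075)
  # threshold at or below the start: immediate
  expect_equal(ryr_activation_time(traj, 0, 1e-4), 0)
  # threshold above the peak: not activated
  expect_true(is.na(ryr_activation_time(traj, 0, 1e-2)))
  expect_error(ryr_activation_time(structure(list(data = data.frame(time = 1)),
                                             class = "pnp_trajectory")),
               "no RyR patch")
})

test_that("activation time is invariant to output cadence refinement", {
  sc1 <- preset("ryr_sweep", Li = 7, DCa = 2e5)
  tr1 <- run_scenario(sc1)
  a1 <- ryr_activation_time(tr1, sc1$marks[["ca_open"]])
  sc2 <- preset("ryr_sweep", Li = 7, DCa = 2e5)
  sc2$phases$record_every <- c(5, 4)
  tr2 <- run_scenario(sc2)
  a2 <- ryr_activation_time(tr2, sc2$marks[["ca_open"]])
  expect_equal(a1, a2, tolerance = 0.05)
})

test_that("line profiles are flat initially and expose the Debye layer at
           rest", {
  sd <- preset("debye2d", t_end = 4e-6)
  tr <- run_scenario(sd)
  st0 <- init_state(tr$mesh, sd$species, NULL)
  st0$rho0[] <- 0
  lp0 <- line_profile(st0, tr$mesh, species = sd$species, buffers = NULL)
  expect_equal(unique(lp0$phi), 0)
  expect_lt(diff(range(lp0$K[lp0$label == 3L])), 1e-12)
  lp <- line_profile(tr$state, tr$mesh, species = sd$species, buffers = NULL)
  # opposite-signed charge layers on the two membrane faces
  rho_left <- lp$rho[max(which(lp$label == 1L))]
  rho_right <- lp$rho[min(which(lp$label == 3L))]
  expect_gt(rho_left, 0)
  expect_lt(rho_right, 0)
  # the layer decays with the analytic Debye length (20% band)
  xi <- lp$x[lp$label == 3L] - (sd$geometry$Le + sd$geometry$Lm)
  lam_fit <- fit_decay_length(xi, lp$rho[lp$label == 3L], window = c(0.1, 3))
  lam_an <- debye_length(c(K = 100, Cl = 100), c(1, -1))
  expect_equal(lam_fit, lam_an, tolerance = 0.2)
})

test_that("potential traces interpolate the recorded mouth potentials", {
  sc <- tiny_1d_scenario()
  tr <- run_scenario(sc)
  trc <- potential_trace(tr)
  lk <- dyadPNP:::trace_lookup(trc)
  tmid <- mean(tr$times[2:3])
  v <- lk("K", tmid)
  expect_length(v, 2)
  expect_true(all(is.finite(v)))
  expect_error(lk("K", max(tr$times) + 1), "does not cover")
  expect_error(lk("nope", 0), "no unit")
})
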