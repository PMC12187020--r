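test_that("pure diffusion leaves the co-ion untouched and forms no Debye
           layer", {
  # localized K+ perturbation: Cl- must stay exactly uniform
  sc <- preset("perturbation2d", box = 20, amp = 5, sigma = 2, t_end = 1e-6)
  sc$model <- "diffusion"
  tr <- run_scenario(sc)
  expect_lt(max(abs(tr$state$conc[, "Cl"] - 100)), 1e-6)
  expect_lt(max(abs(tr$state$phi)), 1e-12)
  # sealed membrane with piecewise-constant start: exactly stationary
  sd <- preset("debye2d", t_end = 2e-6)
  sd$model <- "diffusion"
  trd <- run_scenario(sd)
  st0 <- init_state(trd$mesh, sd$species, NULL)
  expect_lt(max(abs(trd$state$conc - st0$conc)), 1e-9)
})

test_that("diffusion alone decays a perturbation more slowly than
           electrodiffusion", {
  scp <- preset("perturbation2d", box = 20, amp = 5, sigma = 2, t_end = 2e-6)
  trp <- run_scenario(scp)
  scd <- scp; scd$model <- "diffusion"
  trd <- run_scenario(scd)
  dp <- trp$data; dd <- trd$data
  exc_p <- dp$center_K[nrow(dp)] - 100
  exc_d <- dd$center_K[nrow(dd)] - 100
  expect_gt(exc_d, exc_p * 1.5)
})

test_that("with zero imported potential and closed units the
           reaction-diffusion model is buffered diffusion", {
  sc <- preset("ryr_sweep", Li = 7, DCa = 2e5)
  sc$phases <- data.frame(t_end = 5e-3, dt = 5e-4, record_every = 1)
  sc$units <- lapply(sc$units, function(u) { u$schedule <- always_closed(); u })
  zero_trace <- structure(list(
    times = c(0, 1),
    units = stats::setNames(
      lapply(sc$units, function(u) cbind(phii = c(0, 0), phie = c(0, 0))),
      vapply(sc$units, `[[`, "", "id"))), class = "potential_trace")
  scr <- sc; scr$model <- "reaction_diffusion"; scr$potential_trace <- zero_trace
  trr <- run_scenario(scr)
  scd <- sc; scd$model <- "diffusion"
  trd <- run_scenario(scd)
  # all species identical except Ca2+ (buffered in the RD model)
  for (s in c("Na", "K", "Cl")) {
    expect_equal(trr$state$conc[, s], trd$state$conc[, s], tolerance = 1e-10)
  }
})

test_that("species without a transport pathway stay uniform in the dyad
           under reaction-diffusion but not under electrodiffusion", {
  sc <- preset("ryr_sweep", Li = 7, DCa = 2e5)
  tr <- run_scenario(sc)
  scr <- preset("ryr_sweep", Li = 7, DCa = 2e5, model = "reaction_diffusion",
                potential_trace = potential_trace(tr))
  trr <- run_scenario(scr)
  m <- trr$mesh
  ids <- vapply(sc$units, `[[`, "", "id")
  yca <- sc$units[[match("Ca", ids)]]$placement$y
  yncx <- sc$units[[match("NCX", ids)]]$placement$y
  yy <- rep(m$yc, each = m$nx)
  win <- m$label == 3L & yy > yca - 10 & yy < yncx + 10
  spread <- function(state, s) diff(range(state$conc[win, s])) /
    mean(state$conc[win, s])
  # chloride crosses no channel or exchanger: without the electrical
  # coupling it stays exactly uniform; the PNP run shows its Debye layer
  expect_lt(spread(trr$state, "Cl"), 1e-9)
  expect_gt(spread(tr$state, "Cl"), 1e-3)
  # potassium (channel far from the dyad): flatter under RD than PNP
  expect_lt(spread(trr$state, "K"), spread(tr$state, "K"))
  # calcium is the species being released: strongly non-uniform in both
  expect_gt(spread(trr$state, "Ca"), 0.1)
})

test_that("compartment models conserve calcium up to the membrane influx", {
  g <- dyad_geometry(Li = 7, Ly = 150, dims = 2)
  chan <- channel_spec("Ca", placement = unit_placement("Ca", 72, NA),
                       schedule = gating_schedule(0.002, Inf))
  v_fun <- function(t) -60
  for (variant in c("ode1", "ode2")) {
    m0 <- compartment_model(variant, geometry = g, dyad_area = 2e4,
                            k_dl = 1e8, k_cr = 6e3)
    m <- m0
    dt <- 1e-5
    influx_tot <- 0
    for (s in 1:400) {
      first <- if (variant == "ode1") "d" else "c"
      if (is_open(chan$schedule, m$t)) {
        influx_tot <- influx_tot + dt *
          dyadPNP:::ode_channel_influx(m, chan, v_fun(m$t), m$comp[[first]]$c)
      }
      m <- ode_model_step(m, chan, v_fun, dt)
    }
    tot <- function(mm) sum(vapply(mm$comp, function(cp)
      cp$vol * (cp$c + sum(cp$b)), numeric(1)))
    expect_equal(tot(m) - tot(m0), influx_tot,
                 tolerance = 1e-10 * abs(tot(m0)))
  }
})

test_that("zero influx with equal concentrations is stationary", {
  g <- dyad_geometry()
  m <- compartment_model("ode2", geometry = g, k_dl = 1e6, k_cr = 1e4)
  m2 <- ode_model_step(m, NULL, function(t) 0, 1e-3)
  for (nm in names(m$comp)) {
    expect_equal(m2$comp[[nm]]$c, m$comp[[nm]]$c, tolerance = 1e-14)
  }
})

# Calibrated behavior of both variants against a spatially resolved
# reference (shared across the expectations below).
ref_env <- new.env()

get_ref <- function() {
  if (is.null(ref_env$ref)) {
    sc <- preset("ryr_sweep", Li = 7, DCa = 2e5)
    tr <- run_scenario(sc)
    ref_env$sc <- sc
    ref_env$tr <- tr
    ref_env$ref <- ryr_activation_time(tr, sc$marks[["ca_open"]])
    lk <- dyadPNP:::trace_lookup(potential_trace(tr))
    tmax <- max(tr$times)
    ref_env$v_fun <- function(t) {
      p <- lk("Ca", min(t, tmax)); p[1] - p[2]
    }
    ref_env$chan <- sc$units[[3]]
    ref_env$t_end <- tmax
  }
  ref_env
}

test_that("calibration matches the reference activation time by
           construction", {
  e <- get_ref()
  m1 <- calibrate_ode_model(
    compartment_model("ode1", geometry = e$sc$geometry, dyad_area = 2e4),
    e$chan, e$v_fun, e$ref, e$t_end, dt = 1e-5)
  a1 <- ode_run(m1, e$chan, e$v_fun, e$t_end, 1e-5)$activation
  expect_equal(a1, e$ref, tolerance = 0.01)
  ref_env$m1 <- m1
  m2 <- calibrate_ode_model(
    compartment_model("ode2", geometry = e$sc$geometry, dyad_area = 2e4,
                      k_dl = m1$k_dl / 2),
    e$chan, e$v_fun, e$ref, e$t_end, dt = 1e-5)
  a2 <- ode_run(m2, e$chan, e$v_fun, e$t_end, 1e-5)$activation
  expect_equal(a2, e$ref, tolerance = 0.01)
  ref_env$m2 <- m2
  expect_error(
    calibrate_ode_model(
      compartment_model("ode1", geometry = e$sc$geometry, dyad_area = 2e4),
      e$chan, e$v_fun, e$ref * 1e-4, e$t_end, dt = 1e-5),
    "no root")
})

test_that("the single-compartment activation time is insensitive to the
           diffusion coefficient while the two-compartment one is
           monotone", {
  e <- get_ref()
  a1 <- vapply(c(1.5e5, 2e5, 2.5e5, 3e5), function(D) {
    m <- ref_env$m1; m$DCa <- D
    ode_run(m, e$chan, e$v_fun, e$t_end, 1e-5)$activation
  }, numeric(1))
  expect_lt(diff(range(a1)) / mean(a1), 0.01)
  a2 <- vapply(c(1.5e5, 2e5, 2.5e5, 3e5), function(D) {
    m <- ref_env$m2; m$DCa <- D
    ode_run(m, e$chan, e$v_fun, e$t_end, 1e-5)$activation
  }, numeric(1))
  expect_true(all(diff(a2) < 0))   # slower diffusion -> later activation
})

test_that("activation time grows with dyad width in both compartment
           variants", {
  e <- get_ref()
  for (variant in c("ode1", "ode2")) {
    base <- if (variant == "ode1") ref_env$m1 else ref_env$m2
    acts <- vapply(c(7, 10, 14), function(L) {
      g <- dyad_geometry(Li = L, Ly = 150, dims = 2)
      m <- compartment_model(variant, geometry = g, dyad_area = 2e4,
                             k_dl = base$k_dl, k_cr = base$k_cr)
      ode_run(m, e$chan, e$v_fun, e$t_end, 1e-5)$activation
    }, numeric(1))
    expect_true(all(diff(acts) > 0))
  }
})
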