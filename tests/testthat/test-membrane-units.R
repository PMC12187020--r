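mk_mouth <- function(phii = 0, phie = 0, ci = NULL, ce = NULL) {
  sp <- default_species()
  if (is.null(ci)) ci <- stats::setNames(sp$c0i, sp$name)
  if (is.null(ce)) ce <- stats::setNames(sp$c0e, sp$name)
  list(phii = phii, phie = phie, v = phii - phie, ci = ci, ce = ce)
}

test_that("gating schedules open and close deterministically", {
  s <- gating_schedule(c(0.05, 0.5), c(0.2, Inf))
  expect_false(is_open(s, 0))
  expect_true(is_open(s, 0.05))
  expect_true(is_open(s, 0.1))
  expect_false(is_open(s, 0.3))
  expect_true(is_open(s, 10))
  expect_false(is_open(always_closed(), 1))
  expect_true(is_open(always_open(), 1e6))
  expect_error(gating_schedule(c(0, 0.1), c(0.2, 0.3)), "overlap")
})

test_that("mouth averages are area-weighted convex combinations", {
  sc <- tiny_1d_scenario()
  mesh <- build_mesh(sc$geometry, lapply(sc$units, `[[`, "placement"),
                     fine_dx = 0.5, uniform = TRUE)
  st <- init_state(mesh, sc$species, NULL)
  ms <- mouth_state(st, mesh$unit_faces[["K"]])
  expect_equal(ms$v, 0)
  expect_equal(unname(ms$ci[["K"]]), 125)
  expect_equal(unname(ms$ce[["K"]]), 5)
  # constant shift in the intracellular potential shifts v one-to-one
  st$phi[mesh$label == 3L] <- -80
  expect_equal(mouth_state(st, mesh$unit_faces[["K"]])$v, -80)
  expect_error(mouth_state(st, list(i = list(cells = integer(0)),
                                    e = list(cells = integer(0)))),
               "empty")
})

test_that("channel flux density reproduces the single-channel arithmetic", {
  # 5 pS K+ channel, 10 mV above equilibrium: i = 0.05 pA,
  # J = i/(z F wc^2) = 3.24e4 mM nm/ms
  ch <- channel_spec("K", placement = unit_placement("K", 500, 500))
  m <- mk_mouth()
  v0 <- nernst_potential(1, m$ce[["K"]], m$ci[["K"]])
  J <- channel_flux(ch, v0 + 10, m$ci[["K"]], m$ce[["K"]], wc = 4)
  i_yA <- J * 1 * pnp_constants()$F * 16
  expect_equal(i_yA, 5e10, tolerance = 1e-10)   # 0.05 pA in yA
  expect_equal(J, 3.239e4, tolerance = 1e-3)
  # sign convention: v above the Nernst level drives K+ efflux
  expect_gt(J, 0)
  expect_equal(channel_flux(ch, v0, m$ci[["K"]], m$ce[["K"]]), 0,
               tolerance = 1e-12)
})

test_that("channel flux is antisymmetric under swapping the two sides", {
  ch <- channel_spec("Na", placement = unit_placement("Na", 500, 500))
  set.seed(7)
  for (i in 1:20) {
    v <- runif(1, -120, 120)
    ci <- runif(1, 0.1, 150)
    ce <- runif(1, 0.1, 150)
    expect_equal(channel_flux(ch, v, ci, ce),
                 -channel_flux(ch, -v, ce, ci), tolerance = 1e-10)
  }
})

test_that("the affine linearization is exact at the expansion point", {
  ch <- channel_spec("Ca", placement = unit_placement("Ca", 500, 500))
  m <- mk_mouth()
  aff <- channel_flux_affine(ch, m, wc = 4)
  v0 <- nernst_potential(2, m$ce[["Ca"]], m$ci[["Ca"]])
  # at v = v0 and current-step concentrations = interim ones: J = 0
  expect_equal(channel_flux_eval(aff, v0, m$ci[["Ca"]], m$ce[["Ca"]]), 0,
               tolerance = 1e-12)
  # the affine slope in v is the full conductance factor
  expect_equal(aff$a_v, ch$g / (2 * pnp_constants()$F * 16))
  # linearization agrees with the nonlinear flux to first order
  Jlin <- channel_flux_eval(aff, v0 + 1, m$ci[["Ca"]] * 1.01,
                            m$ce[["Ca"]] * 1.01)
  Jnl <- channel_flux(ch, v0 + 1, m$ci[["Ca"]] * 1.01, m$ce[["Ca"]] * 1.01)
  expect_equal(Jlin, Jnl, tolerance = 1e-3)
  bad <- m; bad$ci[["Ca"]] <- -1
  expect_error(channel_flux_affine(ch, bad), "nonpositive")
})

test_that("NCX current vanishes at its reversal potential and is
           forward-mode (Ca2+ extruding) at rest", {
  spec <- ncx_spec(unit_placement("NCX", 500, 500))
  m <- mk_mouth()
  vrev <- 3 * nernst_potential(1, m$ce[["Na"]], m$ci[["Na"]]) -
    2 * nernst_potential(2, m$ce[["Ca"]], m$ci[["Ca"]])
  expect_equal(vrev, -85.11, tolerance = 1e-3)
  at <- function(v) ncx_current_density(v, m$ci[["Na"]], m$ce[["Na"]],
                                        m$ci[["Ca"]], m$ce[["Ca"]], spec)
  expect_equal(at(vrev), 0, tolerance = 1e-12)
  # at rest (below reversal): forward mode, inward current, Ca2+ out
  expect_lt(at(-86), 0)
  expect_gt(unname(ncx_flux_densities(at(-86), spec)[["Ca"]]), 0)
  # after depolarization with unchanged concentrations the sign flips
  expect_gt(at(20), 0)
  expect_lt(unname(ncx_flux_densities(at(20), spec)[["Ca"]]), 0)
  expect_error(at <- ncx_current_density(0, -1, 100, 1e-4, 1.4, spec),
               "nonpositive")
})

test_that("NCX flux densities honour the 3:1 stoichiometry and current
           scale", {
  spec <- ncx_spec(unit_placement("NCX", 500, 500))
  expect_equal(unname(ncx_flux_densities(0, spec)), c(0, 0))
  for (I in c(-2, -0.1, 0.5, 4.9)) {
    Jd <- ncx_flux_densities(I, spec)
    expect_equal(unname(Jd[["Na"]] / Jd[["Ca"]]), -3)
    # single-exchanger current (Cm/delta) * INCX = 2.5e7 yA per (A/F)
    i_yA <- -Jd[["Ca"]] * pnp_constants()$F * 16
    expect_equal(unname(i_yA / I), 2.5e7, tolerance = 1e-9)
  }
})
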