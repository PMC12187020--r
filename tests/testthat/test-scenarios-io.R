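test_that("the preset registry is complete and rejects unknown names", {
  expect_setequal(list_presets(),
                  c("perturbation2d", "debye2d", "rest3d", "upstroke3d",
                    "ca_open", "ca_ncx", "ncx_only", "ncx_enhanced",
                    "ryr_sweep"))
  expect_error(preset("nope"), "available")
})

test_that("presets encode the documented initial states and schedules", {
  sd <- preset("debye2d")
  expect_equal(sd$species$c0e[sd$species$name == "K"], 100.1)
  expect_equal(sd$species$c0i[sd$species$name == "K"], 99.9)
  expect_identical(sd$rho0_mode, "zero")

  sc <- preset("ca_open")
  ids <- vapply(sc$units, `[[`, "", "id")
  sch <- function(id) sc$units[[match(id, ids)]]$schedule
  t0 <- sc$marks[["rest_end"]]
  expect_true(is_open(sch("K"), 0))                     # K+ always open
  expect_false(is_open(sch("Na"), t0 + 0.049))
  expect_true(is_open(sch("Na"), t0 + 0.051))           # Na+ at +0.05 ms
  expect_false(is_open(sch("Ca"), t0 + 0.099))
  expect_true(is_open(sch("Ca"), t0 + 0.101))           # Ca2+ at +0.1 ms
  expect_false(is_open(sch("NCX"), t0 + 0.5))           # NCX closed

  expect_true(is_open(preset("ca_ncx")$units[[4]]$schedule, 0))
  en <- preset("ncx_enhanced")
  expect_equal(en$geometry$Li, 5)
  expect_equal(en$species$Di, default_species()$Di / 2)

  # narrow-dyad sweep points refine the near-membrane spacing
  expect_equal(preset("ryr_sweep", Li = 3)$mesh$fine_dx, 0.25)
  expect_equal(preset("ryr_sweep", Li = 7)$mesh$fine_dx, 0.5)
  rs <- preset("ryr_sweep", DCa = 1.5e5)
  expect_equal(rs$species$Di, default_species()$Di * 1.5e5 / 2e5)
})

test_that("scenario validation rejects unknown fields and bad phases", {
  sc <- preset("perturbation2d")
  sc$bogus <- 1
  expect_error(validate_scenario(sc), "unknown scenario fields")
  sc2 <- preset("perturbation2d")
  sc2$phases <- data.frame(t_end = c(2, 1), dt = c(1e-3, 1e-3),
                           record_every = c(1, 1))
  expect_error(validate_scenario(sc2))
})

test_that("trajectory outputs round-trip through the run directory", {
  sc <- tiny_1d_scenario()
  tr <- run_scenario(sc)
  out <- file.path(tempdir(), "dyadpnp-io-test")
  unlink(out, recursive = TRUE)
  paths <- write_outputs(tr, out)
  expect_true(file.exists(file.path(out, "trajectory.csv")))
  d <- utils::read.csv(file.path(out, "trajectory.csv"), comment.char = "#")
  expect_equal(nrow(d), nrow(tr$data))
  expect_equal(d$v_K, tr$data$v_K, tolerance = 1e-9)
  man <- jsonlite::read_json(file.path(out, "manifest.json"))
  expect_equal(man$scenario, "tiny1d")
  expect_equal(man$geometry$Li, 3)
  expect_equal(length(man$units), 1)
  expect_equal(man$units[[1]]$id, "K")
})

test_that("VTK rectilinear snapshots round-trip", {
  sc <- tiny_1d_scenario()
  mesh <- build_mesh(sc$geometry, lapply(sc$units, `[[`, "placement"),
                     fine_dx = 0.5, uniform = TRUE)
  st <- init_state(mesh, sc$species, NULL)
  st$phi <- seq_len(mesh$ncell) * 0.1
  f <- tempfile(fileext = ".vtr")
  write_vtr(mesh, st, f, species = sc$species, buffers = NULL)
  back <- read_vtr(f)
  expect_equal(back$xf, mesh$xf, tolerance = 1e-6)
  expect_equal(back$arrays$phi, st$phi, tolerance = 1e-6)
  # membrane cells masked in concentration arrays
  expect_true(all(is.nan(back$arrays$c_K[mesh$label == 2L])))
  expect_equal(back$arrays$c_K[mesh$label == 3L],
               st$conc[mesh$label == 3L, "K"], tolerance = 1e-6)
})

test_that("checkpoint restart reproduces the uninterrupted run", {
  sc <- tiny_1d_scenario()
  # bitwise reproducibility across a restart needs the solve to be a pure
  # function of the current system (no cross-step factor reuse)
  sc$solver$reuse_factor <- FALSE
  tr_full <- run_scenario(sc)
  sc_half <- sc
  sc_half$phases$t_end <- 5e-5
  tr_half <- run_scenario(sc_half)
  ck <- tempfile(fileext = ".rds")
  save_checkpoint(tr_half, ck)
  res <- load_checkpoint(ck, sc_half)
  tr_rest <- run_scenario(sc, state = res$state, mesh = res$mesh)
  expect_identical(tr_rest$state$phi, tr_full$state$phi)
  expect_identical(tr_rest$state$conc, tr_full$state$conc)
  # mismatched configuration is refused
  sc_alt <- sc
  sc_alt$units[[1]]$g <- 1e9
  expect_error(load_checkpoint(ck, sc_alt), "different configuration")
  expect_silent(load_checkpoint(ck, sc_alt, force = TRUE))
})

test_that("runs are deterministic", {
  sc <- tiny_1d_scenario()
  tr1 <- run_scenario(sc)
  tr2 <- run_scenario(sc)
  expect_identical(tr1$state$phi, tr2$state$phi)
  expect_identical(tr1$data, tr2$data)
})

test_that("YAML scenario configs build presets and reject unknown keys", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c("preset: perturbation2d",
               "params:",
               "  box: 20",
               "  amp: 5",
               "  t_end: 1.0e-6"), f)
  sc <- read_scenario(f)
  expect_equal(sc$name, "perturbation2d")
  expect_equal(sc$geometry$Li, 20)
  writeLines(c("preset: perturbation2d", "bogus: 1"), f)
  expect_error(read_scenario(f), "unknown configuration keys")
})

test_that("the command line interface runs, summarizes and resumes", {
  out <- file.path(tempdir(), "dyadpnp-cli-test")
  unlink(out, recursive = TRUE)
  expect_equal(run_cli(c("list-presets")), 0L)
  st <- run_cli(c("run", "perturbation2d", "--param", "box=20",
                  "--param", "amp=5", "--param", "t_end=1e-6",
                  "--out", out, "--checkpoint"))
  expect_equal(st, 0L)
  expect_true(file.exists(file.path(out, "trajectory.csv")))
  expect_true(file.exists(file.path(out, "metrics.json")))
  expect_true(file.exists(file.path(out, "checkpoint.rds")))
  expect_equal(run_cli(c("summarize", file.path(out, "trajectory.csv"))), 0L)
  out2 <- file.path(out, "resumed")
  st2 <- run_cli(c("resume", file.path(out, "checkpoint.rds"),
                   "perturbation2d", "--param", "box=20",
                   "--param", "amp=5", "--param", "t_end=2e-6",
                   "--out", out2))
  expect_equal(st2, 0L)
  expect_true(file.exists(file.path(out2, "trajectory.csv")))
  # invalid input: nonzero status, no crash
  expect_equal(run_cli(c("run", "nope")), 1L)
  expect_equal(run_cli(c("frobnicate")), 1L)
})
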