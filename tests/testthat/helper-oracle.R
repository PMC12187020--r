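# Shared fixtures: tiny scenarios built in code, and an independent dense
# brute-force assembly of one coupled implicit step used as an oracle for
# the sparse solver path.

# 16-cell quasi-1D two-ion domain with a membrane and one K+ channel.
tiny_1d_scenario <- function(with_channel = TRUE) {
  geom <- dyad_geometry(Le = 3, Lm = 2, Li = 3, Ly = 0.5, wc = 0.4, dims = 2)
  species <- data.frame(
    name = c("K", "Cl"), z = c(1L, -1L),
    De = c(1.96e6, 2.03e6), Di = c(0.55e6, 0.57e6),
    c0e = c(5, 107.8), c0i = c(125, 15), stringsAsFactors = FALSE)
  units <- if (with_channel) {
    list(channel_spec("K", placement = unit_placement("K", 0.25, NA),
                      schedule = always_open()))
  } else list()
  pnp_scenario(
    name = "tiny1d", geometry = geom, species = species, buffers = NULL,
    units = units, mesh = list(fine_dx = 0.5, uniform = TRUE),
    phases = data.frame(t_end = 1e-4, dt = 1e-5, record_every = 1))
}

# Independent dense assembly of the coupled implicit step: plain loops
# over cells and neighbour pairs, own unknown numbering (phi block first,
# then one block per species over non-membrane cells).
dense_coupled_solve <- function(mesh, species, state, ctilde, units, config,
                                constants, dt) {
  nc <- mesh$ncell
  K <- nrow(species)
  notm <- mesh$label != 2L
  cmap <- integer(nc)
  cmap[notm] <- seq_len(sum(notm))
  ncc <- sum(notm)
  n <- nc + K * ncc
  cix <- function(k, cell) nc + (k - 1L) * ncc + cmap[cell]
  Vt <- thermal_voltage(constants)
  epsc <- ifelse(mesh$label == 2L, config$epsm, config$eps1)
  Dk <- function(k, cell) {
    if (mesh$label[cell] == 1L) species$De[k]
    else if (mesh$label[cell] == 3L) species$Di[k]
    else 0
  }
  A <- matrix(0, n, n)
  b <- numeric(n)
  cellat <- function(i, j) i + mesh$nx * (j - 1L)

  for (j in seq_len(mesh$ny)) {
    for (i in seq_len(mesh$nx)) {
      p <- cellat(i, j)
      V <- mesh$dx[i] * mesh$dy[j]
      nbrs <- list()
      if (i > 1) nbrs <- c(nbrs, list(list(q = cellat(i - 1, j),
                                           dpp = mesh$dx[i] / 2,
                                           dqq = mesh$dx[i - 1] / 2,
                                           area = mesh$dy[j])))
      if (i < mesh$nx) nbrs <- c(nbrs, list(list(q = cellat(i + 1, j),
                                                 dpp = mesh$dx[i] / 2,
                                                 dqq = mesh$dx[i + 1] / 2,
                                                 area = mesh$dy[j])))
      if (j > 1) nbrs <- c(nbrs, list(list(q = cellat(i, j - 1),
                                           dpp = mesh$dy[j] / 2,
                                           dqq = mesh$dy[j - 1] / 2,
                                           area = mesh$dx[i])))
      if (j < mesh$ny) nbrs <- c(nbrs, list(list(q = cellat(i, j + 1),
                                                 dpp = mesh$dy[j] / 2,
                                                 dqq = mesh$dy[j + 1] / 2,
                                                 area = mesh$dx[i])))
      # Poisson row
      for (nb in nbrs) {
        s <- constants$eps0 * nb$area /
          (nb$dpp / epsc[p] + nb$dqq / epsc[nb$q])
        A[p, p] <- A[p, p] + s
        A[p, nb$q] <- A[p, nb$q] - s
      }
      if (i == 1) {  # phi = 0 Dirichlet on xmin
        sb <- constants$eps0 * epsc[p] * mesh$dy[j] / (mesh$dx[1] / 2)
        A[p, p] <- A[p, p] + sb
      }
      rho_rhs <- state$rho0[p]
      if (notm[p]) {
        for (k in seq_len(K)) {
          A[p, cix(k, p)] <- A[p, cix(k, p)] - constants$F * species$z[k] * V
        }
      }
      b[p] <- rho_rhs * V
      # transport rows
      if (notm[p]) {
        for (k in seq_len(K)) {
          r <- cix(k, p)
          A[r, r] <- A[r, r] + V / dt
          b[r] <- b[r] + V / dt * ctilde[p, k]
          for (nb in nbrs) {
            Dp <- Dk(k, p); Dq <- Dk(k, nb$q)
            if (Dp > 0 && Dq > 0) {
              gd <- nb$area / (nb$dpp / Dp + nb$dqq / Dq)
              A[r, r] <- A[r, r] + gd
              A[r, cix(k, nb$q)] <- A[r, cix(k, nb$q)] - gd
              w <- gd * species$z[k] / Vt *
                0.5 * (ctilde[p, k] + ctilde[nb$q, k])
              A[r, p] <- A[r, p] + w
              A[r, nb$q] <- A[r, nb$q] - w
            }
          }
        }
      }
    }
  }
  # channel fluxes (implicit affine form)
  for (u in units) {
    if (u$kind != "channel" || !is_open(u$schedule, state$t)) next
    uf <- mesh$unit_faces[[u$id]]
    k <- match(u$ion, species$name)
    z <- species$z[k]
    cti <- sum(uf$i$w * ctilde[uf$i$cells, k])
    cte <- sum(uf$e$w * ctilde[uf$e$cells, k])
    Kc <- u$g / (z * constants$F * mesh$geometry$wc^2)
    Vz <- Vt / z
    # J = Kc*(phii - phie - Vz*(log(cte/cti) + ce/cte - ci/cti))
    sides <- list(list(cells = uf$i$cells, fac = uf$i$scale * uf$i$areas),
                  list(cells = uf$e$cells, fac = -uf$e$scale * uf$e$areas))
    for (sd in sides) {
      for (m in seq_along(sd$cells)) {
        r <- cix(k, sd$cells[m])
        f <- sd$fac[m]
        for (q in seq_along(uf$i$cells)) {
          A[r, uf$i$cells[q]] <- A[r, uf$i$cells[q]] + f * Kc * uf$i$w[q]
          A[r, cix(k, uf$i$cells[q])] <-
            A[r, cix(k, uf$i$cells[q])] + f * Kc * Vz / cti * uf$i$w[q]
        }
        for (q in seq_along(uf$e$cells)) {
          A[r, uf$e$cells[q]] <- A[r, uf$e$cells[q]] - f * Kc * uf$e$w[q]
          A[r, cix(k, uf$e$cells[q])] <-
            A[r, cix(k, uf$e$cells[q])] - f * Kc * Vz / cte * uf$e$w[q]
        }
        b[r] <- b[r] + f * Kc * Vz * log(cte / cti)
      }
    }
  }
  sol <- solve(A, b)
  phi <- sol[seq_len(nc)]
  conc <- matrix(0, nc, K, dimnames = list(NULL, species$name))
  for (k in seq_len(K)) conc[notm, k] <- sol[nc + (k - 1L) * ncc + seq_len(ncc)]
  # pack a (phi, conc) field pair into this system's unknown ordering
  pack <- function(phi_in, conc_in) {
    x <- numeric(n)
    x[seq_len(nc)] <- phi_in
    for (k in seq_len(K)) {
      x[nc + (k - 1L) * ncc + seq_len(ncc)] <- conc_in[notm, k]
    }
    x
  }
  list(phi = phi, conc = conc, A = A, b = b, pack = pack)
}

# Compare one package-assembled implicit step against the dense oracle:
# the package solution must satisfy the brute-force equations to the
# stated relative residual, and the two solutions must agree to the
# (conditioning-limited) solve accuracy of the dense systems.
expect_matches_dense_oracle <- function(sc, perturb) {
  mesh <- build_mesh(sc$geometry, lapply(sc$units, `[[`, "placement"),
                     fine_dx = 0.5, uniform = TRUE)
  st <- init_state(mesh, sc$species, NULL)
  st <- perturb(st)
  dt <- 1e-5
  sys <- assemble_coupled_system(st, st$conc, mesh, sc$units, sc$solver,
                                 dt, sc$species)
  A <- Matrix::sparseMatrix(i = sys$Ai + 1L, p = sys$Ap, x = sys$Ax,
                            dims = c(sys$n, sys$n))
  up <- dyadPNP:::unpack_solution(sys$plan, solve(as.matrix(A), sys$rhs))
  oracle <- dense_coupled_solve(mesh, sc$species, st, st$conc, sc$units,
                                sc$solver, pnp_constants(), dt)
  # residual of the package solution in the independently assembled
  # dense system
  x_pkg <- oracle$pack(up$phi, up$conc)
  res <- sqrt(sum((oracle$A %*% x_pkg - oracle$b)^2)) /
    sqrt(sum(oracle$b^2))
  expect_lt(res, 1e-10)
  # solution agreement (both dense solves carry conditioning-limited
  # noise of order kappa * eps)
  expect_equal(up$phi, oracle$phi, tolerance = 1e-7)
  expect_equal(up$conc, oracle$conc, tolerance = 1e-9)
  invisible(list(up = up, oracle = oracle, mesh = mesh, st = st))
}

# small closed 3D dyad scenario for conservation/stationarity checks
tiny_3d_scenario <- function(open_k = FALSE, perturb = FALSE) {
  geom <- dyad_geometry(Ly = 100, Lz = 100)
  units <- list(
    channel_spec("K", placement = unit_placement("K", 30, 50),
                 schedule = if (open_k) always_open() else always_closed()),
    ncx_spec(placement = unit_placement("NCX", 70, 50),
             schedule = always_closed()))
  init <- if (perturb) {
    function(mesh, species) {
      conc <- matrix(0, mesh$ncell, nrow(species),
                     dimnames = list(NULL, species$name))
      for (k in seq_len(nrow(species))) {
        conc[mesh$label == 1L, k] <- species$c0e[k]
        conc[mesh$label == 3L, k] <- species$c0i[k]
      }
      yy <- rep(rep(mesh$yc, each = mesh$nx), mesh$nz)
      ii <- mesh$label == 3L & yy < 50
      conc[ii, "K"] <- conc[ii, "K"] + 2
      conc[ii, "Cl"] <- conc[ii, "Cl"] + 2   # keep it electroneutral-ish
      conc
    }
  } else NULL
  pnp_scenario(
    name = "tiny3d", geometry = geom, units = units,
    mesh = list(fine_dx = 1, fine_dyz = 8, max_h = 64),
    phases = data.frame(t_end = 1e-1, dt = 2e-2, record_every = 1),
    init = init)
}
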