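#' Domain geometry for dyad simulations
#'
#' The computational domain is a rectangular cuboid split along x into an
#' extracellular slab (T-tubule lumen, thickness \code{Le}), the cell
#' membrane (\code{Lm}) and the intracellular dyadic cleft (\code{Li}) whose
#' right boundary represents the closed SR membrane.  \code{Ly}, \code{Lz}
#' are the transverse extents; \code{wc} is the edge length of the square
#' membrane patch occupied by one channel or exchanger.  Setting
#' \code{Lm = 0} gives a membrane-free box (used by the simple 2D
#' perturbation example); \code{dims = 2} drops the z axis and interprets
#' quantities per nm of depth.
#'
#' @param Le,Lm,Li Extracellular, membrane, intracellular thickness (nm).
#' @param Ly,Lz Transverse extents (nm); \code{Lz} ignored when
#'   \code{dims = 2}.
#' @param wc Channel patch edge length (nm).
#' @param dims 2 or 3.
#' @return An object of class \code{dyad_geometry}.
#' @export
dyad_geometry <- function(Le = 100, Lm = 5, Li = 7, Ly = 1000, Lz = 1000,
                          wc = 4, dims = 3) {
  stopifnot(Le >= 0, Lm >= 0, Li > 0, Ly > 0, wc > 0, dims %in% c(2, 3))
  if (dims == 3) stopifnot(Lz > 0) else Lz <- 1
  out <- list(Le = Le, Lm = Lm, Li = Li, Ly = Ly, Lz = Lz, wc = wc,
              dims = dims, Lx = Le + Lm + Li)
  class(out) <- "dyad_geometry"
  out
}

#' Membrane unit placement
#'
#' @param id Unit identifier (character).
#' @param y,z Center of the wc x wc membrane patch (nm); \code{z} ignored in
#'   2D.
#' @param region Free-form tag ("dyad" or "main").
#' @return An object of class \code{unit_placement}.
#' @export
unit_placement <- function(id, y, z = NA_real_, region = "main") {
  stopifnot(is.character(id), length(id) == 1L, is.numeric(y))
  structure(list(id = id, y = y, z = z, region = region),
            class = "unit_placement")
}

# Graded interval widths covering a segment of length L exactly.
# hl/hr: fine spacing required at the left/right end (NA = free end);
# widths double away from fine ends and are capped at hmax.  The remainder
# is placed as a middle interval when it keeps the neighbour ratio sane,
# otherwise absorbed into the adjacent coarsest interval.
graded_intervals <- function(L, hl = NA, hr = NA, hmax = 64) {
  eps <- 1e-9
  stopifnot(L > 0)
  if (is.na(hl) && is.na(hr)) {
    n <- max(1L, ceiling(L / hmax - eps))
    return(rep(L / n, n))
  }
  if (is.na(hl)) return(rev(graded_intervals(L, hl = hr, hr = NA, hmax = hmax)))
  if (is.na(hr)) {
    iv <- numeric(0); h <- min(hl, L); rem <- L
    repeat {
      if (rem <= h + eps) {
        if (length(iv) == 0L) return(rem)
        if (rem >= 0.5 * iv[length(iv)] - eps) return(c(iv, rem))
        iv[length(iv)] <- iv[length(iv)] + rem
        return(iv)
      }
      iv <- c(iv, h); rem <- rem - h; h <- min(2 * h, hmax)
    }
  }
  # two fine ends
  if (L < hl + hr + eps) {
    n <- max(1L, round(L / min(hl, hr)))
    return(rep(L / n, n))
  }
  left <- hl; right <- hr; rem <- L - hl - hr
  while (rem > eps) {
    ll <- left[length(left)]; lr <- right[length(right)]
    if (ll <= lr) {
      p <- min(2 * ll, hmax)
      if (rem <= p + eps) break
      left <- c(left, p)
    } else {
      p <- min(2 * lr, hmax)
      if (rem <= p + eps) break
      right <- c(right, p)
    }
    rem <- rem - p
  }
  if (rem > eps) {
    ll <- left[length(left)]; lr <- right[length(right)]
    if (rem >= 0.5 * min(ll, lr) - eps) {
      return(c(left, rem, rev(right)))
    }
    if (ll >= lr) left[length(left)] <- ll + rem
    else right[length(right)] <- lr + rem
  }
  c(left, rev(right))
}

# Transverse axis: uniform fine spacing across each (merged) patch span,
# graded in between and toward the boundaries.
transverse_intervals <- function(L, spans, fine, hmax) {
  if (length(spans) == 0L) return(graded_intervals(L, hmax = hmax))
  spans <- spans[order(vapply(spans, `[`, numeric(1), 1L))]
  merged <- list(spans[[1]])
  for (s in spans[-1]) {
    last <- merged[[length(merged)]]
    if (s[1] <= last[2] + 1e-9) merged[[length(merged)]] <- c(last[1], max(last[2], s[2]))
    else merged <- c(merged, list(s))
  }
  iv <- numeric(0); pos <- 0
  for (m in merged) {
    if (m[1] > pos + 1e-9) {
      hl <- if (pos > 1e-9) fine else NA   # previous patch ended at pos
      iv <- c(iv, graded_intervals(m[1] - pos, hl = hl, hr = fine, hmax = hmax))
    }
    n <- max(1L, round((m[2] - m[1]) / fine))
    iv <- c(iv, rep((m[2] - m[1]) / n, n))
    pos <- m[2]
  }
  if (L > pos + 1e-9) iv <- c(iv, graded_intervals(L - pos, hl = fine, hmax = hmax))
  iv
}

#' Build the adaptive tensor-product mesh
#'
#' Finite-volume mesh with unknowns at cell centers.  Along x the spacing is
#' \code{fine_dx} adjacent to both membrane faces and to the right (SR)
#' boundary and doubles away from them (capped at \code{max_h}); along y and
#' z it is \code{fine_dyz} across each unit's membrane patch, doubling away.
#' \code{uniform = TRUE} requests a uniform mesh with spacing \code{fine_dx}
#' in every direction (used by the simple 2D examples).
#'
#' @param geometry A \code{\link{dyad_geometry}}.
#' @param placements List of \code{\link{unit_placement}} objects.
#' @param fine_dx Fine x spacing (nm).
#' @param fine_dyz Fine transverse spacing (nm).
#' @param max_h Coarsening cap (nm).
#' @param uniform Logical; uniform mesh at \code{fine_dx}.
#' @return An object of class \code{tensor_mesh}.
#' @export
build_mesh <- function(geometry, placements = list(), fine_dx = 0.5,
                       fine_dyz = 2, max_h = 64, uniform = FALSE) {
  stopifnot(inherits(geometry, "dyad_geometry"))
  g <- geometry
  if (g$Lm == 0 && length(placements) > 0L) {
    stop("membrane units require a membrane (Lm > 0)")
  }
  for (p in placements) {
    if (p$y - g$wc / 2 < -1e-9 || p$y + g$wc / 2 > g$Ly + 1e-9) {
      stop("unit '", p$id, "' patch outside the membrane cross-section (y)")
    }
    if (g$dims == 3 && (p$z - g$wc / 2 < -1e-9 || p$z + g$wc / 2 > g$Lz + 1e-9)) {
      stop("unit '", p$id, "' patch outside the membrane cross-section (z)")
    }
  }
  if (length(placements) > 1L) {
    for (i in seq_len(length(placements) - 1L)) {
      for (j in seq(i + 1L, length(placements))) {
        a <- placements[[i]]; b <- placements[[j]]
        dy <- abs(a$y - b$y)
        dz <- if (g$dims == 3) abs(a$z - b$z) else Inf
        if (dy < g$wc - 1e-9 && (g$dims == 2 || dz < g$wc - 1e-9)) {
          stop("unit patches '", a$id, "' and '", b$id, "' overlap")
        }
      }
    }
  }

  if (uniform) {
    nx_ <- max(1L, round(g$Lx / fine_dx))
    dx <- rep(g$Lx / nx_, nx_)
    dy <- rep(g$Ly / max(1L, round(g$Ly / fine_dx)), max(1L, round(g$Ly / fine_dx)))
    dz <- if (g$dims == 3) {
      rep(g$Lz / max(1L, round(g$Lz / fine_dx)), max(1L, round(g$Lz / fine_dx)))
    } else 1
  } else {
    dx <- c(
      if (g$Le > 0) graded_intervals(g$Le, hl = NA, hr = fine_dx, hmax = max_h),
      if (g$Lm > 0) graded_intervals(g$Lm, hl = fine_dx, hr = fine_dx, hmax = max_h),
      graded_intervals(g$Li, hl = if (g$Lm > 0) fine_dx else NA, hr = fine_dx,
                       hmax = max_h)
    )
    yspans <- lapply(placements, function(p) c(p$y - g$wc / 2, p$y + g$wc / 2))
    dy <- transverse_intervals(g$Ly, yspans, fine_dyz, max_h)
    dz <- if (g$dims == 3) {
      zspans <- lapply(placements, function(p) c(p$z - g$wc / 2, p$z + g$wc / 2))
      transverse_intervals(g$Lz, zspans, fine_dyz, max_h)
    } else 1
  }

  xf <- c(0, cumsum(dx)); yf <- c(0, cumsum(dy)); zf <- c(0, cumsum(dz))
  xc <- (xf[-1] + xf[-length(xf)]) / 2
  yc <- (yf[-1] + yf[-length(yf)]) / 2
  zc <- (zf[-1] + zf[-length(zf)]) / 2
  nx <- length(xc); ny <- length(yc); nz <- length(zc)
  ncell <- nx * ny * nz

  # subdomain label by x center: 1 = extracellular, 2 = membrane, 3 = intracellular
  lab_x <- ifelse(xc < g$Le, 1L, ifelse(xc < g$Le + g$Lm, 2L, 3L))
  if (g$Le == 0 && g$Lm == 0) lab_x <- rep(3L, nx)
  label <- rep(lab_x, times = ny * nz)

  vol <- as.vector(outer(outer(dx, dy), dz))

  mesh <- structure(list(
    geometry = g, dims = g$dims,
    xf = xf, yf = yf, zf = zf, xc = xc, yc = yc, zc = zc,
    dx = dx, dy = dy, dz = dz, nx = nx, ny = ny, nz = nz,
    ncell = ncell, label = label, vol = vol,
    placements = placements
  ), class = "tensor_mesh")
  mesh$faces <- interior_faces(mesh)
  mesh$bnd <- boundary_faces(mesh)
  mesh$unit_faces <- lapply(placements, function(p)
    locate_unit_faces(mesh, p, g$wc))
  names(mesh$unit_faces) <- vapply(placements, `[[`, character(1), "id")
  mesh
}

cell_index <- function(mesh, i, j, k = 1L) {
  i + mesh$nx * (j - 1L) + mesh$nx * mesh$ny * (k - 1L)
}

interior_faces <- function(mesh) {
  nx <- mesh$nx; ny <- mesh$ny; nz <- mesh$nz
  gidx <- expand.grid(i = seq_len(nx), j = seq_len(ny), k = seq_len(nz))
  out <- list()
  if (nx > 1L) {
    sel <- gidx$i < nx
    a <- cell_index(mesh, gidx$i[sel], gidx$j[sel], gidx$k[sel])
    out$x <- data.frame(
      a = a, b = a + 1L,
      area = mesh$dy[gidx$j[sel]] * mesh$dz[gidx$k[sel]],
      da = mesh$dx[gidx$i[sel]] / 2, db = mesh$dx[gidx$i[sel] + 1L] / 2,
      axis = 1L)
  }
  if (ny > 1L) {
    sel <- gidx$j < ny
    a <- cell_index(mesh, gidx$i[sel], gidx$j[sel], gidx$k[sel])
    out$y <- data.frame(
      a = a, b = a + nx,
      area = mesh$dx[gidx$i[sel]] * mesh$dz[gidx$k[sel]],
      da = mesh$dy[gidx$j[sel]] / 2, db = mesh$dy[gidx$j[sel] + 1L] / 2,
      axis = 2L)
  }
  if (nz > 1L) {
    sel <- gidx$k < nz
    a <- cell_index(mesh, gidx$i[sel], gidx$j[sel], gidx$k[sel])
    out$z <- data.frame(
      a = a, b = a + nx * ny,
      area = mesh$dx[gidx$i[sel]] * mesh$dy[gidx$j[sel]],
      da = mesh$dz[gidx$k[sel]] / 2, db = mesh$dz[gidx$k[sel] + 1L] / 2,
      axis = 3L)
  }
  do.call(rbind, out)
}

boundary_faces <- function(mesh) {
  nx <- mesh$nx; ny <- mesh$ny; nz <- mesh$nz
  jk <- expand.grid(j = seq_len(ny), k = seq_len(nz))
  ik <- expand.grid(i = seq_len(nx), k = seq_len(nz))
  ij <- expand.grid(i = seq_len(nx), j = seq_len(ny))
  out <- list(
    data.frame(cell = cell_index(mesh, 1L, jk$j, jk$k),
               area = mesh$dy[jk$j] * mesh$dz[jk$k],
               dhalf = mesh$dx[1] / 2, side = "xmin"),
    data.frame(cell = cell_index(mesh, nx, jk$j, jk$k),
               area = mesh$dy[jk$j] * mesh$dz[jk$k],
               dhalf = mesh$dx[nx] / 2, side = "xmax"),
    data.frame(cell = cell_index(mesh, ik$i, 1L, ik$k),
               area = mesh$dx[ik$i] * mesh$dz[ik$k],
               dhalf = mesh$dy[1] / 2, side = "ymin"),
    data.frame(cell = cell_index(mesh, ik$i, ny, ik$k),
               area = mesh$dx[ik$i] * mesh$dz[ik$k],
               dhalf = mesh$dy[ny] / 2, side = "ymax")
  )
  if (mesh$dims == 3) {
    out <- c(out, list(
      data.frame(cell = cell_index(mesh, ij$i, ij$j, 1L),
                 area = mesh$dx[ij$i] * mesh$dy[ij$j],
                 dhalf = mesh$dz[1] / 2, side = "zmin"),
      data.frame(cell = cell_index(mesh, ij$i, ij$j, nz),
                 area = mesh$dx[ij$i] * mesh$dy[ij$j],
                 dhalf = mesh$dz[nz] / 2, side = "zmax")))
  }
  do.call(rbind, out)
}

# overlap length of [a1,a2] with [b1,b2]
overlap1 <- function(a1, a2, b1, b2) pmax(0, pmin(a2, b2) - pmax(a1, b1))

#' Locate the mouth faces of a membrane unit
#'
#' Returns, for each side of the membrane, the first layer of non-membrane
#' cells adjacent to the unit's wc x wc membrane patch, together with the
#' face areas, normalized area weights used for mouth averaging, and the
#' scale factor that makes the surface-integrated flux equal
#' \code{J * wc^2} (in 2D: \code{J * wc} per nm of depth) regardless of how
#' the mesh quantizes the patch.
#'
#' @param mesh A \code{tensor_mesh}.
#' @param placement A \code{\link{unit_placement}}.
#' @param wc Patch edge length (nm).
#' @return List with elements \code{i} and \code{e} (intracellular and
#'   extracellular mouths), each a list \code{(cells, areas, w, scale)}.
#' @export
locate_unit_faces <- function(mesh, placement, wc = mesh$geometry$wc) {
  g <- mesh$geometry
  if (g$Lm <= 0) stop("mesh has no membrane")
  ie <- max(which(mesh$xc < g$Le))            # last extracellular x-column
  ii <- min(which(mesh$xc > g$Le + g$Lm))     # first intracellular x-column
  y1 <- placement$y - wc / 2; y2 <- placement$y + wc / 2
  wy <- overlap1(mesh$yf[-length(mesh$yf)], mesh$yf[-1], y1, y2)
  jy <- which(wy > 1e-12)
  if (mesh$dims == 3) {
    z1 <- placement$z - wc / 2; z2 <- placement$z + wc / 2
    wz <- overlap1(mesh$zf[-length(mesh$zf)], mesh$zf[-1], z1, z2)
    kz <- which(wz > 1e-12)
    if (!length(jy) || !length(kz)) stop("unit patch not resolvable by mesh")
    grid <- expand.grid(j = jy, k = kz)
    areas <- wy[grid$j] * wz[grid$k]
    target <- wc^2
    side <- function(icol) list(
      cells = cell_index(mesh, icol, grid$j, grid$k),
      areas = areas, w = areas / sum(areas), scale = target / sum(areas))
  } else {
    if (!length(jy)) stop("unit patch not resolvable by mesh")
    areas <- wy[jy]
    target <- wc
    side <- function(icol) list(
      cells = cell_index(mesh, icol, jy, 1L),
      areas = areas, w = areas / sum(areas), scale = target / sum(areas))
  }
  list(i = side(ii), e = side(ie))
}

#' Mesh node nearest a point across the dyad from a unit
#'
#' Returns the index of the cell whose center is nearest to
#' \code{x = Le + Lm + x_fraction * Li} at the unit's (y, z) center: the
#' standard observation points are \code{x_fraction = 0.5} (halfway across
#' the dyad) and \code{x_fraction = 1} (at the SR boundary).
#'
#' @param mesh A \code{tensor_mesh}.
#' @param placement A \code{\link{unit_placement}}.
#' @param x_fraction Position across the intracellular width, in [0, 1].
#' @return A cell index.
#' @export
observation_point <- function(mesh, placement, x_fraction = 0.5) {
  stopifnot(x_fraction >= 0, x_fraction <= 1)
  g <- mesh$geometry
  xt <- g$Le + g$Lm + x_fraction * g$Li
  ix <- which(mesh$xc > g$Le + g$Lm)       # intracellular columns only
  i <- ix[which.min(abs(mesh$xc[ix] - xt))]
  j <- which.min(abs(mesh$yc - placement$y))
  k <- if (mesh$dims == 3) which.min(abs(mesh$zc - placement$z)) else 1L
  cell_index(mesh, i, j, k)
}

# Intracellular cells adjacent to the SR boundary within a square patch
# centered across the dyad from `placement`; used for the RyR activation
# average.  Returns cells and area weights.
sr_patch_cells <- function(mesh, placement, patch = 30) {
  g <- mesh$geometry
  i <- mesh$nx                               # SR boundary column
  y1 <- placement$y - patch / 2; y2 <- placement$y + patch / 2
  wy <- overlap1(mesh$yf[-length(mesh$yf)], mesh$yf[-1], y1, y2)
  jy <- which(wy > 1e-12)
  if (mesh$dims == 3) {
    z1 <- placement$z - patch / 2; z2 <- placement$z + patch / 2
    wz <- overlap1(mesh$zf[-length(mesh$zf)], mesh$zf[-1], z1, z2)
    kz <- which(wz > 1e-12)
    grid <- expand.grid(j = jy, k = kz)
    areas <- wy[grid$j] * wz[grid$k]
    cells <- cell_index(mesh, i, grid$j, grid$k)
  } else {
    areas <- wy[jy]
    cells <- cell_index(mesh, i, jy, 1L)
  }
  list(cells = cells, w = areas / sum(areas))
}

#' @export
print.tensor_mesh <- function(x, ...) {
  cat("<tensor_mesh> ", x$nx, " x ", x$ny, " x ", x$nz, " = ", x$ncell,
      " cells (", sum(x$label == 1L), " extracellular, ",
      sum(x$label == 2L), " membrane, ", sum(x$label == 3L),
      " intracellular)\n", sep = "")
  invisible(x)
}
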