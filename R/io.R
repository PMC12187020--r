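#' Write trajectory and run metadata to a directory
#'
#' Writes \code{trajectory.csv} (time series of all recorded observables,
#' with a commented unit header), \code{manifest.json} (scenario summary,
#' package version, configuration hash) and, if the trajectory holds
#' snapshots, one VTK rectilinear file per snapshot.
#'
#' @param trajectory A \code{pnp_trajectory}.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_outputs <- function(trajectory, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    trajectory = write_trajectory_csv(trajectory,
                                      file.path(dir, "trajectory.csv")),
    manifest = write_manifest(trajectory, file.path(dir, "manifest.json")))
  if (length(trajectory$snapshots)) {
    for (i in seq_along(trajectory$snapshots)) {
      st <- trajectory$snapshots[[i]]
      p <- file.path(dir, sprintf("snapshot_%03d.vtr", i))
      write_vtr(trajectory$mesh, st, p,
                species = trajectory$scenario$species,
                buffers = trajectory$scenario$buffers,
                constants = trajectory$scenario$constants)
      paths[paste0("snapshot_", i)] <- p
    }
  }
  invisible(paths)
}

#' @rdname write_outputs
#' @param file Output CSV path.
#' @export
write_trajectory_csv <- function(trajectory, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# scenario: ", trajectory$scenario$name,
           " (model: ", trajectory$scenario$model, ")"),
    "# units: time ms; v/phi mV; concentrations mM; mass mM*nm^3; rho C/m^3; INCX A/F"),
    con)
  utils::write.csv(trajectory$data, con, row.names = FALSE)
  file
}

write_manifest <- function(trajectory, file) {
  sc <- trajectory$scenario
  man <- list(
    scenario = sc$name,
    model = sc$model,
    package_version = as.character(utils::packageVersion("dyadPNP")),
    geometry = sc$geometry[c("Le", "Lm", "Li", "Ly", "Lz", "wc", "dims")],
    mesh = c(sc$mesh, list(nx = trajectory$mesh$nx, ny = trajectory$mesh$ny,
                           nz = trajectory$mesh$nz)),
    phases = sc$phases,
    units = lapply(sc$units, function(u)
      list(id = u$id, kind = u$kind,
           y = u$placement$y, z = u$placement$z,
           open = u$schedule$open, close = u$schedule$close)),
    species = sc$species,
    marks = as.list(sc$marks),
    config_hash = scenario_hash(sc),
    final_time = trajectory$state$t)
  jsonlite::write_json(man, file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "columns")
  file
}

#' Write a state snapshot as a VTK rectilinear grid file
#'
#' ASCII .vtr (XML rectilinear grid) with cell data: potential, per-species
#' concentration, bound pools, and charge density.  Concentrations are
#' written as NaN inside the membrane, where there are no concentration
#' unknowns.
#'
#' @param mesh A \code{tensor_mesh}.
#' @param state A \code{pnp_state}.
#' @param file Output path.
#' @param species,buffers,constants Model tables (for the charge density).
#' @return The file path, invisibly.
#' @export
write_vtr <- function(mesh, state, file, species = default_species(),
                      buffers = default_buffers(),
                      constants = pnp_constants()) {
  num <- function(v) paste(formatC(v, format = "g", digits = 9),
                           collapse = " ")
  nxf <- mesh$nx; nyf <- mesh$ny
  nzf <- if (mesh$dims == 3) mesh$nz else 1L
  ext <- sprintf("0 %d 0 %d 0 %d", nxf, nyf, nzf)
  zf <- if (mesh$dims == 3) mesh$zf else c(0, 1)
  rho <- charge_density(state, mesh, species, buffers, constants)
  conc <- state$conc
  conc[mesh$label == 2L, ] <- NaN
  arrays <- c(list(phi = state$phi, rho = rho),
              stats::setNames(lapply(colnames(conc), function(s) conc[, s]),
                              paste0("c_", colnames(conc))))
  if (ncol(state$bound)) {
    arrays <- c(arrays, stats::setNames(
      lapply(seq_len(ncol(state$bound)), function(j) state$bound[, j]),
      paste0("b_", colnames(state$bound))))
  }
  con <- file(file, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w('<?xml version="1.0"?>')
  w('<VTKFile type="RectilinearGrid" version="0.1" byte_order="LittleEndian">')
  w('  <RectilinearGrid WholeExtent="', ext, '">')
  w('    <Piece Extent="', ext, '">')
  w('      <Coordinates>')
  for (cc in list(mesh$xf, mesh$yf, zf)) {
    w('        <DataArray type="Float64" format="ascii">')
    w('          ', num(cc))
    w('        </DataArray>')
  }
  w('      </Coordinates>')
  w('      <CellData>')
  for (nm in names(arrays)) {
    w('        <DataArray type="Float64" Name="', nm, '" format="ascii">')
    w('          ', num(arrays[[nm]]))
    w('        </DataArray>')
  }
  w('      </CellData>')
  w('    </Piece>')
  w('  </RectilinearGrid>')
  w('</VTKFile>')
  invisible(file)
}

#' Read back a .vtr file written by \code{\link{write_vtr}}
#'
#' @param file Path to a .vtr file.
#' @return List with \code{xf}, \code{yf}, \code{zf} coordinate vectors and
#'   a named list \code{arrays} of cell-data vectors.
#' @export
read_vtr <- function(file) {
  doc <- readLines(file)
  parse_after <- function(i) as.numeric(strsplit(trimws(doc[i + 1]),
                                                 "\\s+")[[1]])
  coord_idx <- grep("<DataArray type=\"Float64\" format=\"ascii\">", doc)
  coords <- lapply(coord_idx[1:3], parse_after)
  arr_idx <- grep("Name=", doc)
  arrays <- lapply(arr_idx, parse_after)
  names(arrays) <- sub('.*Name="([^"]+)".*', "\\1", doc[arr_idx])
  list(xf = coords[[1]], yf = coords[[2]], zf = coords[[3]],
       arrays = arrays)
}

#' Read a scenario from a YAML configuration file
#'
#' The supported schema is preset-based: \code{preset:} names a registered
#' preset, \code{resolution:} selects "smoke" or "paper", and
#' \code{params:} holds builder parameters (e.g. \code{Ly}, \code{Li}).
#' Unknown top-level keys are rejected.
#'
#' @param file Path to a YAML file.
#' @return A \code{pnp_scenario}.
#' @export
read_scenario <- function(file) {
  cfg <- yaml::read_yaml(file)
  allowed <- c("preset", "resolution", "params")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown)) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  }
  if (is.null(cfg$preset)) stop("configuration must name a preset")
  args <- c(list(name = cfg$preset), cfg$params)
  if (!is.null(cfg$resolution)) args$resolution <- cfg$resolution
  do.call(preset, args)
}

#' Summary metrics of a trajectory
#'
#' Final transmembrane potentials per unit, 10-90\% rise time of the first
#' channel-driven depolarization (if any), final observation-point
#' concentrations, and the RyR activation time when the trajectory records
#' an RyR patch and the scenario marks a Ca2+ opening time.
#'
#' @param trajectory A \code{pnp_trajectory} (or path to a trajectory CSV
#'   written by \code{\link{write_outputs}}).
#' @param marks Optional named reference times; defaults to the scenario's.
#' @return A named list of metrics.
#' @export
summarize_trajectory <- function(trajectory, marks = NULL) {
  if (is.character(trajectory)) {
    d <- utils::read.csv(trajectory, comment.char = "#")
    sc <- NULL
  } else {
    d <- trajectory$data
    sc <- trajectory$scenario
  }
  if (is.null(marks) && !is.null(sc)) marks <- sc$marks
  out <- list()
  for (col in grep("^v_", names(d), value = TRUE)) {
    out[[paste0("final_", col)]] <- d[[col]][nrow(d)]
  }
  if ("v_K" %in% names(d) && !is.null(marks) && "na_open" %in% names(marks)) {
    out$upstroke <- rise_time(d$time, d$v_K, after = marks[["na_open"]])
  }
  for (col in grep("^(mid_|ryr_ca)", names(d), value = TRUE)) {
    out[[paste0("final_", col)]] <- d[[col]][nrow(d)]
  }
  if ("ryr_ca" %in% names(d) && !is.null(marks) &&
      "ca_open" %in% names(marks)) {
    tr <- list(data = d)
    out$ryr_activation <- ryr_activation_time(
      structure(tr, class = "pnp_trajectory"), marks[["ca_open"]])
  }
  out
}

# 10-90% rise time of a monotone-ish upstroke starting after `after` (ms)
rise_time <- function(time, v, after = 0) {
  sel <- time >= after
  tt <- time[sel]; vv <- v[sel]
  if (length(vv) < 3) return(NA_real_)
  v0 <- vv[1]; v1 <- max(vv)
  if (v1 - v0 < 1) return(NA_real_)
  lo <- v0 + 0.1 * (v1 - v0)
  hi <- v0 + 0.9 * (v1 - v0)
  t_lo <- stats::approx(vv, tt, lo, ties = "ordered")$y
  t_hi <- stats::approx(vv, tt, hi, ties = "ordered")$y
  t_hi - t_lo
}
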