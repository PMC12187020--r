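# Compartment (ODE) representations of the dyad Ca2+ dynamics, of the kind
# used in whole-cell action potential models: the dyad is one well-mixed
# compartment (or two, split halfway between the cell membrane and the SR),
# coupled to a large cytosolic compartment by linear exchange.  The
# published variants of these models leave the exchange geometry
# unspecified, so the formulation here is an explicit reconstruction:
#  - the dyad <-> cytosol exchange is a lumped conductance,
#    J = k_dl * (c_l - c_d) in mM nm^3/ms, fixed by calibrating the RyR
#    activation time against a spatially resolved reference; it absorbs
#    the (unresolved) escape geometry, so the one-compartment model has no
#    explicit diffusion-coefficient dependence;
#  - the membrane-side <-> SR-side flux of the two-compartment variant is
#    explicitly diffusive, J = DCa * k_cr * (c_c - c_r) with k_cr in nm,
#    because transport across the resolved dyad gap is the mechanism this
#    variant exists to represent.

#' Construct a compartment model of the dyad
#'
#' @param variant "ode1" (one dyad compartment plus cytosol) or "ode2"
#'   (membrane-side and SR-side dyad halves plus cytosol).
#' @param geometry A \code{\link{dyad_geometry}}; the dyad compartment
#'   volume is \code{Li * dyad_area}.
#' @param dyad_area Lateral area of the dyad region (nm^2); the default is
#'   a 300 nm x 300 nm dyad footprint, a typical dyad size.
#' @param DCa Intracellular Ca2+ diffusion coefficient (nm^2/ms).
#' @param k_dl Cytosol exchange conductance (nm^3/ms; amount flux =
#'   \code{k_dl * (c_l - c_d)}).
#' @param k_cr Inter-dyad exchange coefficient for "ode2" (nm; amount flux
#'   = \code{DCa * k_cr * (c_c - c_r)}).
#' @param cytosol_factor Cytosol volume as a multiple of the dyad volume.
#' @param species,buffers,constants Model tables.
#' @return An object of class \code{compartment_model}.
#' @export
compartment_model <- function(variant = c("ode1", "ode2"),
                              geometry = dyad_geometry(),
                              dyad_area = 300^2, DCa = 2e5,
                              k_dl = 1, k_cr = 1, cytosol_factor = 2000,
                              species = default_species(),
                              buffers = default_buffers(),
                              constants = pnp_constants()) {
  variant <- match.arg(variant)
  Vd <- geometry$Li * dyad_area
  c0 <- species$c0i[match("Ca", species$name)]
  nb <- if (is.null(buffers)) 0L else nrow(buffers)
  b0 <- if (nb) vapply(seq_len(nb), function(j)
    buffer_equilibrium(c0, buffers$Btot[j], buffers$kon[j], buffers$koff[j]),
    numeric(1)) else numeric(0)
  comp <- if (variant == "ode1") {
    list(d = list(vol = Vd, c = c0, b = b0),
         l = list(vol = cytosol_factor * Vd, c = c0, b = b0))
  } else {
    list(c = list(vol = Vd / 2, c = c0, b = b0),
         r = list(vol = Vd / 2, c = c0, b = b0),
         l = list(vol = cytosol_factor * Vd, c = c0, b = b0))
  }
  structure(list(variant = variant, geometry = geometry,
                 dyad_area = dyad_area, DCa = DCa, k_dl = k_dl,
                 k_cr = k_cr, comp = comp, species = species,
                 buffers = buffers, constants = constants, t = 0),
            class = "compartment_model")
}

# Ca2+ influx (amount/ms, positive into the dyad) through the membrane
# channel at transmembrane potential v, extracellular mouth concentration
# ce (bulk) and intracellular mouth concentration ci (first dyad
# compartment).
ode_channel_influx <- function(model, chan, v, ci,
                               ce = model$species$c0e[match("Ca", model$species$name)]) {
  J <- channel_flux(chan, v, ci, ce, model$constants, model$geometry$wc)
  -J * model$geometry$wc^2    # J > 0 means efflux
}

#' Advance a compartment model by one operator-split Euler step
#'
#' The same splitting as the PDE solver: an explicit buffering update
#' followed by a backward-Euler update of the (linear) inter-compartment
#' exchange with the membrane influx taken explicitly.  The implicit
#' exchange keeps the step stable for arbitrarily large exchange
#' coefficients, which the calibration bracket explores.
#'
#' @param model A \code{compartment_model}.
#' @param chan The dyadic Ca2+ \code{\link{channel_spec}} (or NULL for no
#'   influx).
#' @param v_fun Function of time returning the transmembrane potential (mV)
#'   used for the channel flux.
#' @param dt Time step (ms).
#' @return The updated model.
#' @export
ode_model_step <- function(model, chan, v_fun, dt) {
  m <- model$comp
  buffers <- model$buffers
  nb <- if (is.null(buffers)) 0L else nrow(buffers)
  # buffering (explicit, per compartment)
  for (nm in names(m)) {
    if (nb) {
      for (j in seq_len(nb)) {
        JB <- buffer_flux(m[[nm]]$c, m[[nm]]$b[j], buffers$Btot[j],
                          buffers$kon[j], buffers$koff[j])
        m[[nm]]$c <- m[[nm]]$c - dt * JB
        m[[nm]]$b[j] <- m[[nm]]$b[j] + dt * JB
      }
    }
  }
  # exchange + membrane influx
  influx <- if (!is.null(chan) && is_open(chan$schedule, model$t)) {
    first <- if (model$variant == "ode1") "d" else "c"
    ode_channel_influx(model, chan, v_fun(model$t), m[[first]]$c)
  } else 0
  D <- model$DCa
  if (model$variant == "ode1") {
    a <- dt * model$k_dl / m$d$vol
    b <- dt * model$k_dl / m$l$vol
    A <- matrix(c(1 + a, -a,
                  -b, 1 + b), 2, 2, byrow = TRUE)
    rhs <- c(m$d$c + dt * influx / m$d$vol, m$l$c)
    sol <- solve(A, rhs)
    m$d$c <- sol[1]; m$l$c <- sol[2]
  } else {
    kcr <- D * model$k_cr
    khl <- model$k_dl / 2
    Vc <- m$c$vol; Vr <- m$r$vol; Vl <- m$l$vol
    A <- matrix(c(
      1 + dt * (kcr + khl) / Vc, -dt * kcr / Vc,        -dt * khl / Vc,
      -dt * kcr / Vr,            1 + dt * (kcr + khl) / Vr, -dt * khl / Vr,
      -dt * khl / Vl,            -dt * khl / Vl,        1 + 2 * dt * khl / Vl),
      3, 3, byrow = TRUE)
    rhs <- c(m$c$c + dt * influx / Vc, m$r$c, m$l$c)
    sol <- solve(A, rhs)
    m$c$c <- sol[1]; m$r$c <- sol[2]; m$l$c <- sol[3]
  }
  model$comp <- m
  model$t <- model$t + dt
  model
}

#' Run a compartment model and report the RyR activation time
#'
#' The RyR-side concentration (the single dyad compartment for "ode1", the
#' SR-side half for "ode2") is tracked from the channel opening until it
#' exceeds the threshold, with linear interpolation.
#'
#' @param model A \code{compartment_model}.
#' @param chan The dyadic Ca2+ channel spec.
#' @param v_fun Potential source, function(t) -> mV.
#' @param t_end End time (ms).
#' @param dt Time step (ms).
#' @param threshold Activation threshold (mM).
#' @return List with \code{activation} (ms after opening, NA if never),
#'   \code{trace} (data.frame of compartment concentrations), and the
#'   final \code{model}.
#' @export
ode_run <- function(model, chan, v_fun, t_end, dt = 1e-3,
                    threshold = 5e-4) {
  nstep <- round(t_end / dt)
  watch <- if (model$variant == "ode1") "d" else "r"
  times <- numeric(nstep + 1)
  cw <- numeric(nstep + 1)
  recs <- vector("list", nstep + 1)
  recs[[1]] <- vapply(model$comp, `[[`, numeric(1), "c")
  cw[1] <- model$comp[[watch]]$c
  for (s in seq_len(nstep)) {
    model <- ode_model_step(model, chan, v_fun, dt)
    times[s + 1] <- model$t
    recs[[s + 1]] <- vapply(model$comp, `[[`, numeric(1), "c")
    cw[s + 1] <- model$comp[[watch]]$c
  }
  open_t <- if (!is.null(chan) && length(chan$schedule$open))
    chan$schedule$open[1] else 0
  act <- NA_real_
  sel <- times >= open_t
  tt <- times[sel]; cc <- cw[sel]
  ab <- which(cc >= threshold)
  if (length(ab)) {
    i <- ab[1]
    act <- if (i == 1) 0 else {
      frac <- (threshold - cc[i - 1]) / (cc[i] - cc[i - 1])
      tt[i - 1] + frac * (tt[i] - tt[i - 1]) - open_t
    }
  }
  trace <- cbind(data.frame(time = times), do.call(rbind, recs))
  list(activation = act, trace = trace, model = model)
}

#' Calibrate a compartment model's exchange coefficient
#'
#' Root-finds the exchange coefficient (\code{k_dl} for "ode1",
#' \code{k_cr} for "ode2") so that the model's RyR activation time matches
#' a reference value (from a spatially resolved run) at the calibration
#' point.  The activation time is monotone in the coefficient (a larger
#' cytosol leak delays activation of the single compartment; a larger
#' inter-compartment conductance speeds activation of the SR-side
#' compartment), which makes the scalar root-find well posed whenever a
#' root is bracketed.
#'
#' @param model A \code{compartment_model} at the calibration parameters.
#' @param chan Dyadic Ca2+ channel spec.
#' @param v_fun Potential source.
#' @param reference_time Target activation time (ms).
#' @param t_end,dt Integration horizon and step for each evaluation.
#' @param interval Log10 search interval for the coefficient.
#' @return The calibrated model (with the coefficient set).
#' @export
calibrate_ode_model <- function(model, chan, v_fun, reference_time,
                                t_end, dt = 1e-3,
                                interval = c(-2, 14)) {
  act_of <- function(logk) {
    m <- model
    if (m$variant == "ode1") m$k_dl <- 10^logk else m$k_cr <- 10^logk
    a <- ode_run(m, chan, v_fun, t_end, dt)$activation
    if (is.na(a)) t_end else a
  }
  f <- function(logk) act_of(logk) - reference_time
  lo <- f(interval[1]); hi <- f(interval[2])
  if (is.na(lo) || is.na(hi) || lo * hi > 0) {
    stop("no root in bracket: activation time range [",
         signif(min(lo, hi) + reference_time, 4), ", ",
         signif(max(lo, hi) + reference_time, 4),
         "] ms does not contain the reference ", reference_time, " ms")
  }
  r <- stats::uniroot(f, interval, tol = 1e-4)
  if (model$variant == "ode1") model$k_dl <- 10^r$root else
    model$k_cr <- 10^r$root
  model
}
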