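# dyadPNP

Nano-scale electrodiffusion in the cardiomyocyte dyad: a finite-volume
solver for the Poisson–Nernst–Planck (PNP) equations with stationary
Ca²⁺ buffers, single-channel and Na⁺/Ca²⁺-exchanger flux boundary
conditions, and an adaptive tensor-product mesh — together with the
reduced models the field usually uses instead (pure diffusion,
reaction–diffusion with an imported potential, one- and two-compartment
ODE models) and the diagnostics needed to compare them (Debye-layer
profiles, per-term magnitudes of the transport equation, ryanodine
receptor activation times).

It is written for computational physiologists who want to know *when the
full electrodiffusion problem matters* in the 5–20 nm dyadic cleft
between the T-tubule membrane and the sarcoplasmic reticulum (SR), where
Ca²⁺ entering through membrane channels triggers Ca²⁺-induced Ca²⁺
release.

## The model

For ion species *k* with valence *z_k*, diffusivity *D_k* and stationary
buffers *j*:

```
∇·(ε_r ε_0 ∇φ) = −ρ,          ρ = ρ0 + F Σ_k z_k (c_k + Σ_j b_kj)
∂c_k/∂t = ∇·D_k∇c_k + ∇·( (D_k z_k e / k_B T) c_k ∇φ ) − Σ_j J_B^kj
∂b_kj/∂t = J_B^kj = k_on c_k (B_tot − b_kj) − k_off b_kj
```

The domain is extracellular slab | membrane | dyadic cleft, with the SR
as a closed right boundary. Channels (K⁺ 5 pS, Na⁺ 20 pS, Ca²⁺ 8 pS)
obey `i = g (v − v0)` with the Nernst potential `v0` at area-averaged
channel-mouth concentrations; the NCX uses the standard allosteric 3:1
current-density formulation. Each step is an operator split: explicit
buffering, then one *fully coupled* implicit Poisson/Nernst–Planck solve
(channels linearized implicitly, NCX explicit) — the coupling is what
allows 1000 ns time steps instead of the ~0.5 ns Debye-relaxation limit
of split schemes. Details and all numerical choices are in the methods
vignette (`vignettes/electrodiffusion-methods.Rmd`).

## A worked example

Relax an electroneutral dyad to the cell's resting state through a
single open K⁺ channel on a reduced transverse domain:

```r
library(dyadPNP)

sc   <- preset("rest3d", Ly = 250, Lz = 250, t_end = 1.5)
traj <- run_scenario(sc)
traj
#> <pnp_trajectory> scenario 'rest3d' (pnp), 16 samples to t = 1.5 ms

m <- mouth_state(traj$state, traj$mesh$unit_faces[["K"]])
sprintf("resting potential: %.2f mV", tail(traj$data$v_K, 1))
#> "resting potential: -85.07 mV"
sprintf("K+ Nernst potential at the channel mouths: %.2f mV",
        nernst_potential(1, m$ce[["K"]], m$ci[["K"]]))
#> "K+ Nernst potential at the channel mouths: -85.07 mV"

lp <- line_profile(traj$state, traj$mesh, y = 200, z = 125)
ii <- lp$label == 3L   # intracellular cells
sprintf("Debye decay length (fit): %.2f nm, analytic: %.2f nm",
        fit_decay_length(lp$x[ii] - 105, lp$rho[ii], c(0.1, 3.2)),
        debye_length(default_species()$c0i, default_species()$z))
#> "Debye decay length (fit): 1.11 nm, analytic: 1.14 nm"
```

The transmembrane potential settles exactly at the Nernst level of the
K⁺ concentrations *at the channel mouths* (inside the Debye layers, not
the bulk values), and the charge-density profile decays away from the
membrane with the analytic Debye length — the two signatures of a
correctly resolved electric double layer.

Other presets reproduce the package's standard experiments:
`perturbation2d` (nanosecond relaxation to electroneutrality),
`debye2d` (double-layer formation at a sealed membrane), `upstroke3d`
(Na⁺-driven action-potential upstroke), `ca_open` / `ca_ncx` /
`ncx_only` / `ncx_enhanced` (dyadic Ca²⁺ dynamics with channel and
exchanger combinations), `ryr_sweep` (RyR activation time vs dyad width
and Ca²⁺ diffusivity). `list_presets()` lists them; every preset also
runs under `model = "diffusion"` or `"reaction_diffusion"`, and
`compartment_model()` / `calibrate_ode_model()` provide the ODE
reductions.

A command-line entry point is installed at `inst/cli/dyadpnp`:

```sh
Rscript inst/cli/dyadpnp run rest3d --param Ly=250 --param Lz=250 --out runs/rest
Rscript inst/cli/dyadpnp summarize runs/rest/trajectory.csv
```

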