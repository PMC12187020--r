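---
title: "Electrodiffusion in the cardiac dyad: model and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Electrodiffusion in the cardiac dyad: model and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The physical problem

The cardiac dyad is the 5–20 nm cytosolic cleft between a T-tubule
invagination of the cardiomyocyte membrane and the sarcoplasmic reticulum
(SR). Ca²⁺ entering through L-type channels in the T-tubule membrane must
cross this cleft to activate ryanodine receptors (RyRs) on the SR and
trigger Ca²⁺-induced Ca²⁺ release. At nanometer and nanosecond scales the
usual reaction–diffusion picture is incomplete: ion concentrations near
charged membranes deviate from electroneutrality over the Debye length
(≈1 nm at physiological ionic strength), and the electric field these
deviations generate feeds back on every ionic species.

`dyadPNP` solves the electrodiffusion problem in this geometry with the
Poisson–Nernst–Planck (PNP) system,

$$\nabla\cdot(\varepsilon_r\varepsilon_0\nabla\phi) = -\rho, \qquad
\frac{\partial c_k}{\partial t} =
\nabla\cdot D_k\nabla c_k +
\nabla\cdot\Bigl(\frac{D_k z_k e}{k_B T}\, c_k \nabla\phi\Bigr)
 - \sum_{j} J_{B}^{k,j},$$

with stationary Ca²⁺ buffers obeying mass-action kinetics
$\partial b_{k,j}/\partial t = J_B^{k,j} = k_{on} c_k (B_{tot} - b_{k,j})
- k_{off} b_{k,j}$ and the charge density
$\rho = \rho_0 + F\sum_k z_k (c_k + \sum_j b_{k,j})$. The background
charge $\rho_0$ is fixed so the initial state is exactly electroneutral;
it lumps all immobile charge, including that of the buffer proteins.
Buffer-bound Ca²⁺ carries the valence of the free ion; all other protein
charge is in $\rho_0$.

Four species are carried (Na⁺, K⁺, Ca²⁺, Cl⁻) with separate
extracellular and intracellular diffusion coefficients and zero diffusion
inside the membrane. The two simple 2D illustrations use only K⁺ and Cl⁻.

## Units

Everything internal is nm / ms / mM / mV. With the vacuum permittivity in
fF/m, the Poisson discretization then produces charge density directly in
C/m³, and a single-channel flux density in mM·nm/ms equals
ymol/(nm²·s); no per-term conversion factors appear anywhere in the
solver. `pnp_units()` documents the conversion factors to SI used at the
reporting boundary.

## Geometry and mesh

The domain is a rectangular cuboid: extracellular slab (`Le` = 100 nm),
membrane (`Lm` = 5 nm), intracellular cleft (`Li` = 7 nm, the control
parameter of the width sweeps), transverse extents `Ly`, `Lz` (1000 nm by
default — with one channel of each type this membrane area gives a
realistic ≈0.5 ms upstroke). The right boundary is the closed SR
membrane.

The finite-volume tensor mesh places unknowns at cell centers. Along x
the spacing is 0.5 nm adjacent to both membrane faces and to the SR
boundary and doubles per interval away from them (0.25 nm for dyads
narrower than 5 nm); transversely it is 2 nm across each wc × wc = 4 × 4
nm channel patch, doubling away. The doubling is capped (default 64 nm;
coarse desk-scale meshes use 256 nm) and remainder intervals are placed
mid-segment when they keep the neighbour ratio near 2, otherwise absorbed
into the adjacent coarsest interval. Where refinement zones of the
membrane and the SR boundary meet (narrow dyads), the finer spacing wins
by construction since grading starts from both ends.

Boundary conditions: homogeneous Neumann for all concentrations
everywhere (the SR is closed; the far boundaries are remote), homogeneous
Neumann for the potential except φ = 0 on the leftmost (T-tubule lumen)
boundary, which anchors the otherwise singular Poisson problem. The 2D
perturbation example instead fixes φ = 0 and c = 100 mM on all
boundaries.

## Membrane units

Channels and the Na⁺/Ca²⁺ exchanger (NCX) are internal flux boundary
conditions on the first non-membrane cell layers ("mouths") adjacent to
their membrane patch; the membrane itself is impermeable (D = 0, which
the distance-weighted harmonic face mean enforces exactly).

* **Channels.** Linear single-channel model $i = g\,(v - v_0)$ with the
  Nernst equilibrium potential $v_0$ evaluated at area-averaged mouth
  concentrations and $v = \phi_i - \phi_e$ from area-averaged mouth
  potentials; converted to a flux density $J = g (v - v_0)/(z F w_c^2)$,
  positive outward. In the implicit step the logarithm is linearized
  around the buffering-step concentrations:
  $\ln(c_e/c_i) \approx \ln(\tilde c_e/\tilde c_i) + c_e/\tilde c_e -
  c_i/\tilde c_i$ (the consistent first-order expansion; the two
  constant terms cancel). The flux is applied uniformly over the mouth
  faces, scaled so its surface integral is exactly $J\,w_c^2$ regardless
  of mesh quantization, and identically (with opposite sign) on both
  sides, which makes conservation exact.
* **NCX.** The standard allosterically regulated 3:1 exchanger
  current-density formulation (A/F), converted to per-unit fluxes via the
  specific membrane capacitance and exchanger surface density:
  $J_{Na} = 3 C_m I_{NCX}/(F w_c^2 \delta_{NCX})$,
  $J_{Ca} = -C_m I_{NCX}/(F w_c^2 \delta_{NCX})$. The current is zero at
  the reversal potential $3v_{Na} - 2v_{Ca} \approx -85$ mV, negative
  (forward mode, Ca²⁺ extrusion) at rest just below it, positive
  (reverse mode, Ca²⁺ entry) after depolarization. The NCX flux is
  explicit: previous-step potential, buffering-step concentrations.
* **Gating** is deterministic and instantaneous: a unit is open iff the
  step-start time lies in one of its (open, close) intervals.

Unit placements follow a fixed layout: a K⁺/Na⁺ pair on the "main"
membrane and a Ca²⁺/NCX pair in the dyad region, all at mid-depth, with
20 nm center-to-center separation within each pair. The separation is not
a published number; it was inferred from the published lateral
concentration drop between the point opposite the Ca²⁺ channel (≈0.7 mM)
and the point opposite the NCX (≈0.3 mM), which the simulated
$c \sim \ln(R/r)$ lateral profile reproduces at r ≈ 20 nm. It is exposed
as a preset parameter (`pair_sep`).

## Time stepping

First-order operator splitting per step:

1. **Buffering** — forward Euler on the mass-action kinetics, giving
   interim concentrations $\tilde c$ and the step's bound pools; free +
   bound is conserved exactly per cell. A bound pool leaving
   $[0, B_{tot}]$ aborts with a step-size diagnostic.
2. **Coupled implicit step** — backward Euler on the Poisson and
   transport equations *simultaneously*, with the drift coefficient
   frozen at $\tilde c$ and channel fluxes included implicitly through
   the affine form above. Solving potential and concentrations together
   is what permits 1000 ns steps; splitting them would reintroduce the
   Debye-relaxation stability limit (≈0.5 ns).

The spatial scheme is conservative two-point-flux finite volumes: face
diffusivities and permittivities are distance-weighted harmonic means
(zero across the membrane, flux-continuous at the ε = 80 / ε = 2
interfaces), drift face concentrations are arithmetic means of $\tilde
c$. Mass conservation is exact to solver precision by construction.

### The deviation formulation

Concentration unknowns are stored as deviations from the per-subdomain
reference concentrations (the initial-condition table). The charge a
Poisson row senses is a difference of O(F · 100 mM) terms that cancel to
μM-scale resolution; with full concentrations as unknowns that
cancellation happens in floating point and leaves noise no solver
tolerance can remove. With deviations the cancellation is analytic: the
uniform electroneutral state is an exact fixed point (observed ≈1e-14)
and closed-system mass drift sits at the solver tolerance (≈1e-12
relative). Because the reference is constant within each
membrane-separated subdomain, deviation fluxes equal full-concentration
fluxes exactly.

### Linear solver

Unknowns are interleaved per cell (φ, then the cell's concentrations) to
keep coupled entries close. Each step solves one sparse nonsymmetric
system (assembled once into a fixed sparsity pattern; only drift, channel
and time entries are refilled). The solver is BiCGSTAB preconditioned
with a threshold incomplete LU (ILUT, fill limit 40/row·part, drop
tolerance 1e-3 after max-norm row/column equilibration), converging to a
relative residual of 1e-10; the factorization is reused across steps and
refreshed when the iteration count degrades. A plain ILU(0) is *not*
sufficient here — the Poisson/drift coupling carries the Debye screening
response, orders of magnitude stiffer than transport at 1000 ns steps. A
sparse-LU `method = "direct"` option exists for machine-precision
conservation audits on small meshes; a non-convergent iterative solve
falls back to it automatically.

Concentrations are never clipped; any concentration below −1e-6 mM
aborts with a diagnostic recommending a smaller time step.

## Reduced comparison models

* **Pure diffusion** (`model = "diffusion"`): buffers, drift, potential
  and membrane fluxes all off. Used to show that a K⁺ perturbation
  leaves Cl⁻ exactly untouched, decays more slowly than under
  electrodiffusion, and that no Debye layer can form.
* **Reaction–diffusion** (`model = "reaction_diffusion"`): buffered
  diffusion plus membrane fluxes evaluated with an *imported* potential
  trace recorded from a PNP run (the RD system generates no potential of
  its own). Channel concentrations remain implicit and local. Setting
  `drift_off = TRUE` in a PNP run and feeding its trace to the RD model
  reproduces it exactly — the equivalence switch used in the tests.
* **Compartment (ODE) models**: the dyad as one well-mixed compartment
  (plus a large cytosol), or two half-slab compartments. The published
  compartment equations for this configuration are not available, so the
  formulation here is an explicit reconstruction: dyad↔cytosol exchange
  is a lumped conductance $J = k_{dl}(c_l - c_d)$ fixed by calibrating
  the RyR activation time against a spatially resolved reference at one
  parameter point (so the one-compartment activation time is exactly
  independent of $D_{Ca}$ — the "curves overlap" behaviour); the
  membrane-side↔SR-side flux of the two-compartment variant is
  explicitly diffusive, $J = D_{Ca} k_{cr}(c_c - c_r)$, because
  transport across the resolved gap is the mechanism that variant
  exists to represent. The two-compartment model uses half the
  one-compartment leak (reusing it in full makes the calibration
  degenerate: the infinite-transfer limit then reproduces the reference
  exactly and the root-find diverges) and calibrates $k_{cr}$.
  Exchange is integrated backward-Euler (2×2/3×3 solves) so the
  calibration bracket can explore arbitrarily stiff coefficients. The
  default dyad footprint is 300 × 300 nm (a typical dyad); the tests
  use a smaller footprint consistent with their 2D reference.

## Observables

`transmembrane_potential` (mouth-averaged φ difference), `line_profile`
(x-profiles of φ, c, ρ for Debye-layer inspection), `term_breakdown`
(the discrete diffusion, drift and buffering operators at a point, using
the solver's own stencils, so $B_d + B_e - B_b$ equals the discrete time
derivative wherever no membrane flux lands), `ryr_activation_time` (time
from channel opening until the area-averaged Ca²⁺ over a 30 × 30 nm
patch on the SR boundary opposite the channel first exceeds 0.5 μM,
linearly interpolated; the patch is snapped to mesh faces and averaged
area-weighted over the boundary-adjacent cell layer),
`electroneutrality_decay_time`, and the analytic `debye_length` with a
log-linear `fit_decay_length` for profile comparisons.

## Scenario presets and problem sizes

Each preset exists at two resolutions. `"paper"` uses the reference time
steps and fine meshes of the corresponding published setups (0.1 ns / 1
μs / 10 μs steps; 0.25–2 nm spacings). `"smoke"` (the default) keeps the
physics configuration — geometry, parameters, gating — and coarsens only
the numerics; these are the problem sizes this package runs routinely:

* `perturbation2d`, `debye2d`: 2D boxes (the published examples do not
  state a domain size; 50 nm is used and the perturbation is a Gaussian
  of amplitude 10 mM, s.d. box/10). Decay-time measurements are
  insensitive to both choices, which only set the slow diffusive tail.
* `rest3d`, `upstroke3d`, `ca_open`, `ca_ncx`, `ncx_only`,
  `ncx_enhanced`: full 1 μm² membrane, transverse patch spacing 8 nm
  with a 256 nm cap (≈19 × 31 × 13 cells, ≈30k unknowns), a 2 ms
  settling phase at 20 μs steps replacing a stored resting state, then
  2–5 μs active-phase steps. Mid-dyad Ca²⁺ values are read as the
  maximum reached after opening: with the linear channel model the mouth
  equilibrates as the potential settles near +20 mV, so the mid-dyad
  concentration peaks and then relaxes.
* `ryr_sweep`: the activation-time sweep over (`Li`, `DCa`) runs in 2D
  (x–y, per-nm depth) at smoke scale — the sweep's comparisons
  (reaction–diffusion vs PNP, compartment models) are model-internal,
  and 2D preserves the diffusion/buffering physics they probe at ≈10 s
  per point; `"paper"` keeps the 3D configuration with 1 ns steps.

## What the desk-scale runs do and do not show

Passing tests at smoke scale demonstrate the scheme's structural
properties (exact conservation, stationarity, Debye-layer physics,
model-comparison behaviour) and reproduce the published headline values
within generous bands (resting potential at the mouth-Nernst level,
≈+20 mV upstroke of ≈0.3–0.5 ms, mid-dyad Ca²⁺ levels within ±40%).
They do not establish fine-mesh converged values: transverse 8 nm cells
smear the lateral Ca²⁺ profile around its sources, and the coarse
settling phase leaves the resting state a few mV short of fully relaxed.
The 2D sweep preserves mechanisms, not absolute 3D activation times.
Real dyads additionally have irregular geometry, channel clusters,
stochastic gating, mobile buffers and an explicit SR — all outside this
model, which treats a single deterministic unit of each type in a
rectangular cleft, stopping before RyR feedback (no SR release flux).

## Known numerical limitations

The Krylov solver's attainable accuracy is conditioning-limited; audits
needing machine precision should use `method = "direct"` (small meshes
only). The explicit buffering step bounds the usable time step at high
free-Ca²⁺ transients (the bound-pool guard aborts rather than silently
clipping). The mid-dyad residual charge cannot fall below the
cosh-profile floor set by the Debye layer overlapping the closed SR
boundary in a 7 nm cleft — a physical feature, not a solver artifact.
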