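# Default parameter values for the dyad electrodiffusion model.
# Canonical units: length nm, time ms, concentration mM, potential mV,
# conductance zS, capacitance yF/nm^2.  Charge density reported in C/m^3.
constants:
  F: 96485.3365        # Faraday constant, C/mol
  eps0: 8854           # vacuum permittivity, fF/m
  eps_water: 80        # relative permittivity in extracellular/intracellular space
  eps_membrane: 2      # relative permittivity in the membrane
  e: 1.60217662e-19    # elementary charge, C
  kB: 1.380649e-20     # Boltzmann constant, mJ/K
  T: 310               # temperature, K
species:
  Na: {z: 1,  De: 1.33e+6, Di: 0.37e+6, c0e: 100,   c0i: 12}
  K:  {z: 1,  De: 1.96e+6, Di: 0.55e+6, c0e: 5,     c0i: 125}
  Ca: {z: 2,  De: 0.71e+6, Di: 0.20e+6, c0e: 1.4,   c0i: 1.0e-4}
  Cl: {z: -1, De: 2.03e+6, Di: 0.57e+6, c0e: 107.8, c0i: 15}
buffers:
  high_affinity: {target: Ca, Btot: 0.20, kon: 100, koff: 0.03}
  low_affinity:  {target: Ca, Btot: 0.56, kon: 100, koff: 1.3}
geometry:
  Le: 100              # extracellular thickness, nm
  Lm: 5                # membrane thickness, nm
  Li: 7                # intracellular (dyad) width, nm
  Ly: 1000             # transverse extent, nm
  Lz: 1000             # transverse extent, nm
  wc: 4                # channel patch edge length, nm
channels:
  gK: 5.0e+9            # single K+ channel conductance, zS (= 5 pS)
  gNa: 20.0e+9          # single Na+ channel conductance, zS (= 20 pS)
  gCa: 8.0e+9           # single Ca2+ channel conductance, zS (= 8 pS)
ncx:
  Ibar: 4.9            # scaling current density, A/F
  delta: 4.0e-4        # NCX surface density, nm^-2
  Cm: 10000            # specific membrane capacitance, yF/nm^2
  nu: 0.3              # energy barrier position
  ksat: 0.3            # saturation factor
  Kact: 1.5e-4         # Ca2+ activation constant, mM
  KCai: 3.6e-3         # half-saturation, intracellular Ca2+, mM
  KCae: 1.3            # half-saturation, extracellular Ca2+, mM
  KNai: 12.3           # half-saturation, intracellular Na+, mM
  KNae: 87.5           # half-saturation, extracellular Na+, mM
mesh:
  fine_dx: 0.5         # near-membrane/near-SR x spacing, nm
  fine_dyz: 2          # transverse spacing over channel patches, nm
  max_h: 64            # cap on the geometric coarsening, nm
solver:
  dt: 1.0e-3           # default time step, ms (= 1000 ns)
  tol: 1.0e-10         # linear solver relative residual tolerance
ryr:
  threshold: 5.0e-4    # RyR activation threshold, mM (= 0.5 uM)
  patch: 30            # RyR patch edge length on the SR boundary, nm
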