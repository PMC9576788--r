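# Default model constants for the confined-cell osmotic-engine steady state.
#
# Units: length um, time s, pressure Pa, concentration mM (= mol/m^3, so
# RT * c is a pressure in Pa), potential V, energy per mole J/mol.
# Membrane ion fluxes carry mM um/s; ion permeabilities are pre-scaled to
# (mM um/s) per (J/mol); water permeability is um/(s Pa).
#
# Extracellular composition, temperature and pH are standard physiological
# values. Transport coefficients were calibrated once, as a set, so that the
# baseline polarized cell (Cl conductance enriched at the rear, Na+/H+
# exchange modestly enriched at the front, front actin polymerization)
# migrates forward at tens of nm/s, reverses direction when the Cl
# polarization is inverted, and keeps migrating when actin polymerization is
# disabled -- the regime the osmotic-engine mechanism describes. Effective
# ion diffusivities are aqueous values reduced 50x for the crowded,
# organelle-filled cytoplasm of a confined cell (a lumped 1D choice).

cell_length: 50.0            # um, confined cell length
cross_section: 30.0          # um^2, channel cross-section (3 x 10 um)
interfacial_friction: 1.0e+4 # Pa s / (um^2 mM), actin-cytosol drag
adhesion_strength: 500.0     # Pa s / (um^2 mM), focal-adhesion coupling (weak in confinement)
wall_friction: 1.0e+4        # Pa s / um, channel-wall friction on the cell
depolymerization_rate: 2.0e-3  # 1/s, bulk F-actin depolymerization
gactin_diffusivity: 10.0     # um^2/s, G-actin diffusion
actin_stiffness: 1.0e+3      # Pa/mM, network stress per F-actin concentration
mean_actin: 0.3              # mM, prescribed mean total actin
polymerization_saturation: 0.2  # mM, G-actin half-saturation of polymerization
membrane_thickness_factor: 4.0e-3  # um, tension prefactor b in tau_m = b/2 (...)
gas_constant: 8.314          # J/(mol K)
temperature: 310.0           # K
faraday: 96485.0             # C/mol
henry_constant: 29.41        # mmHg/mM (pco2/henry_constant = dissolved CO2, mM)
pco2: 35.3                   # mmHg (5% CO2 incubator; 1.2 mM dissolved)
pK_c: 6.1                    # effective pK, CO2/bicarbonate
pK_B: 7.0                    # pK, intracellular buffer
extracellular_pH: 7.4
extracellular_potential: 0.0 # V, reference potential of the bath
symmetric_resistance_in_force_balance: no  # cell force balance as printed (front water flux only)

gating_constants:
  beta1: 0.02    # 1/(Pa um), mechanosensitive gate steepness
  beta2: 80.0    # Pa um, mechanosensitive gate midpoint tension
  beta3: 30.0    # 1/V, pump voltage-gate steepness
  beta4: -0.15   # V, pump voltage-gate midpoint
  beta5: 5.0     # 1/pH, NHE gate steepness (quiescent at alkaline pH)
  beta6: 7.2     # pH, NHE gate midpoint
  beta7: 5.0     # 1/pH, AE2 gate steepness (quiescent at acidic pH)
  beta8: 7.1     # pH, AE2 gate midpoint

nke_scalings:
  Na: 0.05       # scales Gamma_Na inside the Na Hill factor
  K: 0.01        # scales 1/Gamma_K inside the K Hill factor

impermeant_totals:
  N_A: 150000.0        # attomol; mean c_A = N_A / (S L) = 100 mM
  N_Buf_total: 60000.0 # attomol; mean buffer (Buf + HBuf) = 40 mM

front:
  water_permeability: 2.0e-5   # um/(s Pa), aquaporin-rich membrane
  hydraulic_resistance: 1.0e+5 # Pa s/um, confining-channel resistance
  external_pressure: 0.0       # Pa
  passive_permeability:        # (mM um/s) per (J/mol)
    Na: 1.0e-4
    K: 0.1
    Cl: 1.0e-4                 # SWELL1, rear-enriched: back/front = 4 at baseline
  nke_permeability: 10.0       # mM um/s at saturation
  nhe_permeability: 1.0901e-2  # NHE1, front-enriched: front/back = 1.5
  ae2_permeability: 1.0e-3
  actin_polymerization_rate: 3.0e-3  # mM um/s, front polymerization J_actin^f

back:
  water_permeability: 2.0e-5
  hydraulic_resistance: 1.0e+5
  external_pressure: 0.0
  passive_permeability:
    Na: 1.0e-4
    K: 0.1
    Cl: 4.0e-4
  nke_permeability: 10.0
  nhe_permeability: 7.2671e-3
  ae2_permeability: 1.0e-3
  actin_polymerization_rate: 0.0   # no polymerization at the rear

species:
  # diffusivities: aqueous values / 50 (effective axial diffusion in a
  # crowded confined cytoplasm); extracellular bath is fixed
  Na:   {valence: 1,  diffusivity: 26.6, extracellular_concentration: 140.0}
  K:    {valence: 1,  diffusivity: 39.2, extracellular_concentration: 5.0}
  Cl:   {valence: -1, diffusivity: 40.6, extracellular_concentration: 110.0}
  H:    {valence: 1,  diffusivity: 186.2}
  HCO3: {valence: -1, diffusivity: 23.6}
  A:    {valence: -1, diffusivity: 1.0, extracellular_concentration: 21.0}
  Buf:  {valence: -1, diffusivity: 10.0}
  HBuf: {valence: 0,  diffusivity: 10.0}
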