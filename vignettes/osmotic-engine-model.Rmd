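---
title: "The osmotic engine model of confined cell migration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The osmotic engine model of confined cell migration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

A tumor cell migrating through a confining microchannel can move without a
functional actin cytoskeleton: polarized ion transport drives water influx at
the leading edge and efflux at the trailing edge, so the cell effectively
pumps itself forward — the osmotic engine. `osmigrate` implements a
steady-state, one-dimensional, multi-phase model of this mechanism that
couples:

* **Two-phase mechanics.** The cytoplasm is cytosol plus an F-actin network.
  On the moving-frame domain $x \in [0, L]$ (back at $x = 0$, front at
  $x = L$), cytosol momentum balances pressure against interfacial drag,
  $-p' - \eta\,\theta_n (v_c - v_n) = 0$, with spatially constant cytosol
  velocity; network momentum balances the swelling stress
  $\sigma_n = k_{\sigma_n}\theta_n$ against interfacial drag and
  focal-adhesion traction $-\eta_{st}\,\theta_n v_n$.

* **Actin turnover.** Polymerization occurs only at the front membrane at the
  saturating rate $J_{actin} = J^f_{actin}\,\theta_c/(\theta_{c,c}+\theta_c)$,
  depolymerization at rate $\gamma$ throughout; F-actin is advected, G-actin
  advects and diffuses, and the mean total actin over the cell is prescribed.

* **Electrodiffusive ion transport.** Eight species (Na⁺, K⁺, Cl⁻, H⁺,
  HCO₃⁻, impermeant protein A⁻, and a Buf⁻/HBuf buffer pair) move by
  diffusion, advection and electromigration (Nernst–Planck). The potential
  $\phi$ is closed algebraically by electroneutrality $\sum_n z_n c_n = 0$;
  protons, bicarbonate and protonated buffer are never independent unknowns
  but algebraic functions of pH through the CO₂/bicarbonate and buffer
  equilibria (CO₂ equilibrates freely across the membrane).

* **Pump-leak membrane fluxes** at each end: osmotic water flux against
  external hydraulic resistance; passive Na⁺/K⁺/Cl⁻ channels gated by one
  mechanosensitive Boltzmann function of the local membrane tension
  $\tau_m = \tfrac{b}{2}(\sigma_n + p - p_*)$ (the volume-regulated anion
  channel SWELL1 is the Cl⁻ pathway); a 3:2 Na⁺/K⁺ ATPase with a voltage
  gate and cubic/quadratic Hill saturation; a 1:1 Na⁺/H⁺ exchanger (NHE1)
  quiescent at alkaline pH; and a 1:1 Cl⁻/HCO₃⁻ exchanger (AE2) quiescent
  at acidic pH. All boundary fluxes are positive-inward at their own end.

* **A whole-cell force balance** — far-field pressure difference, external
  hydraulic drag, focal-adhesion traction, and wall friction $\xi v_0$ —
  which determines the migration velocity $v_0$.

Channel *polarization* enters purely through front/back asymmetry of the
permeability coefficients: the baseline cell has the Cl⁻ conductance
enriched at the rear (back/front ratio 4) and the Na⁺/H⁺ exchanger modestly
enriched at the front (front/back ratio 1.5).

### Frame convention

The steady state is posed in the frame moving with the cell, so every bulk
advection term uses the relative velocity $v - v_0$, and membrane boundary
fluxes are fluxes relative to the moving membrane. The printed form of such
models sometimes leaves the $v_0$ shift implicit; the relative-velocity form
is the one under which the boundary conditions conserve total actin and
solute exactly, and it is what the conservation test suite asserts. For the
same reason the front G-actin boundary flux includes its diffusive part.

## Units

Lengths in µm, time in s, pressure in Pa, concentrations in mM
(1 mM ≡ 1 mol/m³, so $RT\,c$ with $RT$ in J/mol is a pressure in Pa),
potential in V (reported in mV), ion fluxes in mM µm/s. Permeabilities are
pre-scaled: water in µm/(s Pa), ion pathways in (mM µm/s) per (J/mol) of
electrochemical driving force. This is the single conversion layer; no other
module rescales units.

## Default parameters and how they were chosen

Defaults live in `inst/extdata/default_parameters.yaml` (load with
`default_parameters()`; the loader rejects unknown keys so typos cannot
silently become defaults). Extracellular composition, temperature and pH are
standard physiology: Na⁺ 140, K⁺ 5, Cl⁻ 110 mM, pH 7.4, T 310 K, 5% CO₂
(1.2 mM dissolved), plus 21 mM impermeant extracellular osmolytes bringing
the bath to 300 mOsm. Geometry is a 50 µm cell in a 3 × 10 µm channel.

The transport and mechanical coefficients are lumped effective constants
that no single measurement pins down. They were calibrated **once, as a
set**, so that the model sits in the regime the osmotic-engine mechanism
describes, and then frozen:

* the baseline polarized cell migrates forward at tens of nm/s with a
  resting potential near −90 mV;
* migration reverses sign when the Cl⁻ polarization ratio is swept from
  rear-enriched to front-enriched (total conductance held fixed);
* migration persists when actin polymerization is removed (the
  latrunculin-A condition) — i.e. the engine, not the cytoskeleton, carries
  most of the velocity (actin contributes roughly 10% at baseline, which is
  also why a weak focal-adhesion coupling $\eta_{st}$ = 500 Pa s/(µm² mM)
  was chosen: confined migration is largely adhesion-independent);
* knocking the Cl⁻ conductance down 10× at both ends largely halts the cell,
  with or without actin.

Three calibration choices deserve explanation. First, effective ion
diffusivities are aqueous values divided by 50: the 1D model lumps
cytoplasmic crowding, organelles and tortuosity of a confined cell into the
axial diffusivity, and the osmotic engine's speed is set by how large a
front/back osmolarity difference a given solute throughput can sustain
against diffusive smoothing. Second, the Na⁺/K⁺-pump capacity (10 mM µm/s)
is at the high end of plausible surface densities; the engine's throughput
is pump-limited, so this constant, together with the exchanger capacities,
sets the velocity scale. Third, the Cl⁻ conductance is deliberately *not*
saturating: with a very large conductance the channel equilibrates chloride
and its spatial distribution stops mattering, whereas knockdown experiments
require the channel to be rate-limiting. A structural property worth knowing
when exploring parameters: with the Na⁺/H⁺ exchanger disabled the system
relaxes to a genuine rest state in which chloride sits at its Nernst
potential and the cell velocity is exactly zero regardless of Cl⁻
polarization — the engine is fundamentally the NHE/AE2 acid-base cycle, and
SWELL1 polarization steers the resulting circulation.

## Numerical method

The unknowns are nodal values of $p$, $q_n$, $\theta_n$, $\theta_c$,
$c_{Na}$, $c_K$, $c_{Cl}$, pH, $c_A$, $c_{Buf}$, $\phi$ on a uniform grid of
$N$ nodes plus the scalars $u_c = v_c - v_0$ and $v_0$ (11N + 2 unknowns).
Two reformulations keep the system well-posed everywhere:

* the network-phase unknown is the relative F-actin flux
  $q_n = \theta_n (v_n - v_0)$ rather than $v_n$: momentum and mass balances
  are linear in $q_n$, so the equations do not degenerate when the network
  vanishes (latrunculin-type conditions with zero polymerization);
* pH is the acid-base unknown; $c_H$, $c_{HCO_3}$, $c_{HBuf}$ are
  substituted inside every residual so derived fields can never drift out of
  sync.

Discretization is second order: midpoint fluxes with central differences,
three-point one-sided end derivatives, trapezoidal quadrature for the
integral constraints (conserved total actin, impermeant protein, buffer).
Each conserved family contributes one constraint row in place of a redundant
zero-flux boundary row. Species with no membrane pathway at either end (they
arise in limiting scenarios such as the single-permeant-ion Nernst check)
get a conserved-content row instead of their redundant boundary row, with
the content fixed by the canonical initial guess; with no water pathway the
pressure level is pinned at the back instead of the duplicate cytosol
closure. The advective terms are not upwinded: in every regime the model
describes, the cell Péclet number $u_c h / D$ is far below one, and a
central scheme is both stable and unbiased there.

The nonlinear system is scaled (concentrations by 100 mM, pressure by
$RT \cdot 100$ mM, velocities by 10 nm/s, potential by $RT/F$; residual rows
by family-specific magnitudes) and solved by damped Newton iteration with
Armijo backtracking and up to three seeded perturbed restarts. The Jacobian
is assembled by finite differences with graph coloring: the sparsity pattern
is detected numerically once per problem structure at a jittered reference
point (two jitters, union), columns are greedily colored so no residual row
sees two perturbed columns, and the few dense rows — the integral
constraints (analytic entries) and the global force balance (single-row
differencing) — are handled exactly. Linear solves use a sparse LU
(`Matrix`). Newton is declared converged at a scaled residual max-norm of
1e-10, or when it stalls below 3e-9 — the rounding floor of the flux
differences, far below every conservation tolerance the diagnostics check.

The initial guess is spatially uniform and satisfies the algebraic structure
exactly: impermeants spread to their conserved totals, pH at the bath value,
Na/K/Cl at Donnan-adjusted bath values (exact nodal electroneutrality),
pressure at osmotic equilibrium, everything at rest. Strongly perturbed
regimes (scenario knockdowns, sweep extremes) are reached by warm-started
parameter continuation with geometric ramps and automatic step halving;
direct and continued solves agree to solver tolerance whenever both
converge, and when multiple steady states might exist the one continuously
connected to the rest state is the one reported.

`check_solution()` recomputes all diagnostics from the stored profiles:
spatial constancy of every transported family flux (relative to the
solution's largest mean family flux — a family whose net flux happens to
vanish would otherwise divide rounding noise by zero), back-influx =
front-efflux per conserved family (H⁺ and HCO₃⁻ are checked through the
combined acid-base flux, since the equilibria interconvert them along the
cell), nodal electroneutrality relative to ionic strength, conservation of
actin and impermeant totals, and the whole-cell force balance. Because the
constancy check uses the same midpoint flux the solver enforces, it measures
solver convergence, not discretization error; discretization accuracy is
established separately by grid refinement of $v_0$ (the default $N = 128$ is
converged to well under 1%) and by manufactured-solution convergence tests
(observed order ≥ 2 on all bulk operators).

## Scenarios, sweeps and fitting

`oem_scenarios()` encodes the standard manipulations: polarization reversal
and equalization of the Cl⁻ channel at fixed total conductance,
latrunculin A ($J^f_{actin} = 0$), and knockdowns as 0.1× multiplicative
scalings of a permeability at both ends (shRNA depletes the protein
everywhere; the polarization pattern is a separate axis).
`sweep_polarization()` sweeps the back/front Cl⁻ ratio holding the geometric
mean fixed, so total conductance is ratio-independent; a `hold_front` mode
is provided since the normalization convention is itself a modeling choice.
Non-converged sweep points are explicit `NA`s, never zeros and never
interpolated. In the calibrated defaults the velocity crosses zero at a
back/front ratio of about 0.27 rather than exactly 1: the front-polarized
Na⁺/H⁺ exchanger and the actin term keep a modest forward bias at symmetric
Cl⁻, so equalizing the Cl⁻ channel roughly halves the speed and pushing it
to the front reverses the direction. The crossing location is a
parameter-dependent quantity; the robust, tested statements are
monotonicity and the single sign change.

`fit_parameters()` does bounded least squares of model velocity against
observed per-cell velocities (Brent search for one free parameter, seeded
multi-start L-BFGS-B otherwise), with solves memoized and warm-started, and
reports Gauss–Newton confidence intervals from the residual curvature.

## Synthetic data and what the tests do (and do not) show

`gen_velocity_observations()` draws per-cell velocities as the model's
steady-state velocity plus Gaussian noise (default SD 30% of the baseline
speed, resembling the cell-to-cell spread of confined-migration data; the
recovery study uses the 10% figure of its protocol with 11 cells per
condition). `gen_polarized_cell_image()` builds rectangular intensity
phantoms with bright pole bands, a dim interior and truncated Gaussian
noise; they are fixtures for the polarity quantifier, not renderings of the
transport model, and contain no optics (no PSF, no shot noise).
`gen_trajectory()` samples drift-diffusion tracks at uniform intervals.
Every generator records its full provenance (parameters and seed) and
regenerates bit-identically; none touches the caller's RNG stream.

Passing the recovery and round-trip tests therefore shows that the pipeline
is self-consistent — the estimator recovers what the generator put in, at
the stated noise — not that real micrographs or real cell tracks obey the
generators' simple noise models. Real intensity backgrounds are structured,
real tracks have measurement error and finite sampling, and real velocity
distributions are skewed; the quantifiers expose the knobs (zero threshold,
window geometry, lag fraction) that such data would require, and the pole
windows are always explicit inputs because window placement was a manual
step in the workflows this mirrors.

Problem sizes used by the shipped studies: $N = 128$ for headline solves and
scenario panels (grid-converged to <0.01% in $v_0$), $N = 64$ for the
25-point polarization sweep, $N = 32$ for the 50-replicate recovery study
(generator and fit share the grid, so discretization cancels in the
recovery).

## Known limitations

* Steady state only; no transient dynamics, no bifurcation tracking.
* One spatial dimension; the channel cross-section enters only through
  conserved totals and the force balance.
* Myosin contraction is not modeled; network stress is passive swelling.
* No Na⁺/K⁺/2Cl⁻ cotransporter and no separate aquaporin state — water
  permeability is one lumped coefficient per end.
* The whole-cell force balance uses the front water flux in the
  hydraulic-resistance term, as the model is usually written; a symmetrized
  variant is available via `symmetric_resistance_in_force_balance` and
  changes baseline results negligibly.
* Absolute velocities are calibration-dependent; the robust outputs are
  signs, orderings, and ratios across scenarios.
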