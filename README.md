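# osmigrate

Steady-state modeling of **osmotic-engine cell migration**: how polarized
ion transport lets a confined cell pump itself through a narrow channel by
taking water in at the front and expelling it at the rear, with or without
a functional actin cytoskeleton.

Cells in confining microchannels (e.g. breast cancer cells in 3 × 10 µm
PDMS channels) polarize their transport machinery: the Na⁺/H⁺ exchanger
NHE1 at the leading edge and the volume-regulated Cl⁻ channel SWELL1
(LRRC8A) at the trailing edge. Local swelling at the front and shrinkage at
the rear then produce net locomotion. `osmigrate` implements a multi-phase,
steady-state, one-dimensional model of this mechanism and the analysis
around it, for cell biophysicists who want to explore which polarization
patterns move a cell, in which direction, and how fast.

## The model in brief

On the moving-frame domain $x\in[0,L]$ (back at 0, front at $L$) the
package solves, as one coupled nonlinear system:

* two-phase cytosol/actin-network mechanics,
  $-p' - \eta\,\theta_n(v_c - v_n) = 0$ and
  $-(k_{\sigma_n}\theta_n)' + \eta\,\theta_n(v_c - v_n) - \eta_{st}\theta_n v_n = 0$,
  with front-only actin polymerization
  $J_{actin} = J^f_{actin}\,\theta_c/(\theta_{c,c}+\theta_c)$ and bulk
  depolymerization at rate $\gamma$;
* electroneutral Nernst–Planck transport of Na⁺, K⁺, Cl⁻, H⁺, HCO₃⁻, an
  impermeant protein and a buffer pair,
  $J_n = -D_n c_n' + v_c c_n - D_n \tfrac{z_n F}{RT} c_n \phi'$, with
  $\sum_n z_n c_n = 0$ closing the potential and pH slaving the acid-base
  species;
* pump-leak membrane fluxes at each end: osmotic water flux against
  hydraulic resistance, tension-gated passive channels
  $J_{n,p} = \alpha_{n,p} G_m (RT\ln\Gamma_n - z_n F V_m)$ with
  $\Gamma_n = c_n^0/c_n$, a 3:2 Na⁺/K⁺ ATPase with voltage gating and Hill
  saturation, and pH-gated 1:1 NHE and AE2 exchangers;
* a whole-cell force balance yielding the migration velocity $v_0$.

Channel polarization is encoded purely as front/back asymmetry of the
permeability coefficients. The numerical core is a damped Newton solver
with a colored sparse finite-difference Jacobian and warm-started parameter
continuation; the methods vignette
(`vignettes/osmotic-engine-model.Rmd`) documents the discretization,
scaling, and the calibration of the default constants.

Alongside the solver, the package ships the surrounding workflow: scenario
presets (knockdowns, latrunculin A, polarization reversal), polarization
sweeps and two-parameter sensitivity contours, least-squares fitting of
model parameters to single-cell velocities, synthetic-data generators with
recorded ground truth (noisy velocity observations, polarized-cell
intensity phantoms, drift-diffusion trajectories), and the matching
quantification tools (front/rear intensity polarity ratio, instantaneous
velocity, mean squared displacement, spheroid shape metrics).

## Worked example

```r
library(osmigrate)

params <- default_parameters()  # calibrated baseline: rear SWELL1, front NHE1
st <- solve_steady(params, solver_options(grid_size = 128))
st
#> <oem_state> steady-state confined-cell solution
#>   v0 = 0.0004617 um/s (0.0277 um/min), N = 128 nodes, 11 Newton iterations
#>   V_m front/back = -92.4 / -92.4 mV, residual max = 4.30e-11
#>   checks: flux constancy 4.0e-11, electroneutrality 1.7e-15
```

The baseline cell migrates toward its front at 0.028 µm/min with a resting
membrane potential near −92 mV; the diagnostics confirm that every species
flux is spatially constant and every node electroneutral to solver
precision. `tidy(st)` returns the nodal profiles as a tibble, `glance(st)`
the scalar summary, and `autoplot(st)` a faceted profile figure.

Sweeping the SWELL1 polarization ratio (back/front Cl⁻ permeability, total
conductance fixed) reproduces the model's central prediction — rear
enrichment drives forward migration, front enrichment reverses it:

```r
sw <- sweep_polarization(params, ratios = 10^seq(-1, 1, length.out = 9),
                         options = solver_options(grid_size = 64))
tidy(sw)[, 1:3]
#>    ratio         v0 converged
#>  1 0.1   -0.000133  TRUE          # front-enriched: cell moves backward
#>  ...
#>  5 1      0.000205  TRUE
#>  9 10     0.000644  TRUE          # rear-enriched: fastest forward migration
glance(sw)$ratio_at_sign_change
#> [1] 0.267
```

Velocity is monotone in rear enrichment and crosses zero once. Disabling
actin polymerization (the latrunculin-A condition) barely slows the
baseline cell — migration here is water-driven:

```r
lat <- run_scenario("lat_a", params, solver_options(grid_size = 64),
                    base_state = st)
60 * lat$v0
#> [1] 0.02551   # um/min, ~92% of baseline
```

whereas additionally knocking down SWELL1 (`"lat_a_swell1_kd"`) drops the
speed to ~15% of baseline. Synthetic observations and parameter recovery:

```r
obs <- gen_velocity_observations(params,
  conditions = list(cells = list(swell1_ratio = 4)),
  n_per = 11, seed = 1, options = solver_options(grid_size = 32))
fit <- fit_parameters(obs, params, free = list(swell1_ratio = c(0.5, 20)),
                      options = solver_options(grid_size = 32))
tidy(fit)  # estimate with Gauss-Newton 95% CI covering the true ratio 4
```

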