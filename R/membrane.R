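#' Membrane flux laws and gating functions
#'
#' Everything that happens at the two cell ends lives here: osmotic water
#' flux against external hydraulic resistance, the mechanosensitive Boltzmann
#' gate shared by the passive channels, the voltage gate of the Na+/K+ pump,
#' the pH gates of the Na+/H+ (NHE) and Cl-/HCO3- (AE2) exchangers, and the
#' per-mechanism ion fluxes. All boundary fluxes are signed positive-inward
#' at their own end; the bulk equations apply the end-specific sign flips.
#'
#' Ion fluxes carry mM um/s; permeability coefficients are pre-scaled so that
#' multiplying the electrochemical driving force (J/mol) gives that unit.
#'
#' @name membrane-fluxes
NULL

#' Hydraulic pressure felt just outside a cell end
#'
#' External hydraulic resistance makes the pressure at the membrane differ
#' from the far-field pressure when the cell moves or pumps water:
#' front `p* = p0 + d_g (v0 - J_water)`, back `p* = p0 - d_g (v0 + J_water)`.
#'
#' @param end `"front"` or `"back"`.
#' @param v0 Cell velocity, um/s (positive toward the front).
#' @param J_water Water influx at that end, um/s (positive inward).
#' @param d_g External hydraulic resistance, Pa s/um; >= 0.
#' @param p0 Far-field pressure, Pa.
#' @return Pressure at the membrane, Pa.
#' @export
external_pressure <- function(end, v0, J_water, d_g, p0) {
  if (any(d_g < 0)) abort("`d_g` must be >= 0.", class = "osmigrate_invalid_parameter")
  switch(end,
    front = p0 + d_g * (v0 - J_water),
    back = p0 - d_g * (v0 + J_water),
    abort(sprintf("Unknown end `%s`", end), class = "osmigrate_invalid_input")
  )
}

#' Osmotic water flux across a cell end
#'
#' `J_water = -alpha * ((p - p*) - RT (c_total - c0_total))`, positive inward.
#' Water leaves where the outside is hypertonic or the inside pressurized.
#'
#' @param p Intracellular pressure at the end, Pa.
#' @param p_star External pressure at the membrane, Pa (see
#'   [external_pressure()]; the pair is mutually implicit and can be resolved
#'   with [resolve_water_flux()]).
#' @param c_total,c0_total Total intra/extracellular solute concentration, mM.
#' @param alpha Membrane water permeability, um/(s Pa); >= 0.
#' @param RT Thermal energy scale, J/mol (Pa per mM).
#' @return Water flux, um/s.
#' @export
water_flux <- function(p, p_star, c_total, c0_total, alpha, RT) {
  if (any(alpha < 0)) abort("`alpha` must be >= 0.", class = "osmigrate_invalid_parameter")
  -alpha * ((p - p_star) - RT * (c_total - c0_total))
}

#' @rdname water_flux
#' @description `resolve_water_flux()` eliminates the linear implicitness
#'   between the water flux and the resistance-corrected external pressure and
#'   returns both consistently.
#' @inheritParams external_pressure
#' @export
resolve_water_flux <- function(end, p, c_total, c0_total, v0, alpha, d_g, p0, RT) {
  if (any(d_g < 0)) abort("`d_g` must be >= 0.", class = "osmigrate_invalid_parameter")
  osm <- RT * (c_total - c0_total)
  J <- switch(end,
    front = -alpha * ((p - p0 - d_g * v0) - osm) / (1 + alpha * d_g),
    back = -alpha * ((p - p0 + d_g * v0) - osm) / (1 + alpha * d_g),
    abort(sprintf("Unknown end `%s`", end), class = "osmigrate_invalid_input")
  )
  list(J_water = J, p_star = external_pressure(end, v0, J, d_g, p0))
}

#' Membrane tension from the local force balance
#'
#' `tau_m = (b/2) (sigma_n + p_c - p*)`: cortical network stress plus excess
#' cytosol pressure, converted to a tension by the length prefactor `b`.
#'
#' @param sigma_n Actin network stress at the end, Pa.
#' @param p_c Cytosol pressure at the end, Pa.
#' @param p_star External pressure at the membrane, Pa.
#' @param b Length prefactor, um; > 0.
#' @return Membrane tension, Pa um.
#' @export
membrane_tension <- function(sigma_n, p_c, p_star, b) {
  if (any(b <= 0)) abort("`b` must be > 0.", class = "osmigrate_invalid_parameter")
  (b / 2) * (sigma_n + p_c - p_star)
}

#' Gating functions
#'
#' Boltzmann-type open probabilities: the mechanosensitive gate rises with
#' membrane tension, the pump voltage gate is odd around its midpoint (range
#' (-1, 1)), the NHE gate closes and the AE2 gate opens with rising
#' intracellular pH.
#'
#' @param tau_m Membrane tension, Pa um.
#' @param beta1,beta3,beta5,beta7 Gate steepness constants.
#' @param beta2,beta4,beta6,beta8 Gate midpoints.
#' @return Open fraction in (0, 1) (or (-1, 1) for the voltage gate).
#' @export
gate_mechanosensitive <- function(tau_m, beta1, beta2) {
  1 / (1 + exp(-beta1 * (tau_m - beta2)))
}

#' @rdname gate_mechanosensitive
#' @param V_m Membrane potential jump phi - phi0, V.
#' @export
gate_nke_voltage <- function(V_m, beta3, beta4) {
  2 / (1 + exp(-beta3 * (V_m - beta4))) - 1
}

#' @rdname gate_mechanosensitive
#' @param pH Intracellular pH at the end.
#' @export
gate_nhe <- function(pH, beta5, beta6) {
  1 / (1 + exp(beta5 * (pH - beta6)))
}

#' @rdname gate_mechanosensitive
#' @export
gate_ae2 <- function(pH, beta7, beta8) {
  1 / (1 + exp(-beta7 * (pH - beta8)))
}

check_gamma <- function(Gamma, what) {
  if (any(!is.finite(Gamma)) || any(Gamma <= 0)) {
    abort(sprintf("Concentration ratio %s must be positive and finite.", what),
      class = "osmigrate_invalid_input"
    )
  }
}

#' Passive electrodiffusive channel flux
#'
#' `J = alpha G_m (RT ln Gamma - z F V_m)`, zero exactly at the Nernst
#' potential of the species. One mechanosensitive gate `G_m` (from the local
#' end's tension) multiplies all passive species at that end; channel
#' specificity (e.g. the volume-regulated anion channel SWELL1 for Cl-)
#' enters through the per-species permeability `alpha`.
#'
#' @param z Valence of the species.
#' @param Gamma Extracellular / intracellular concentration ratio; > 0.
#' @param V_m Membrane potential jump, V.
#' @param G_m Mechanosensitive gate value in (0, 1).
#' @param alpha Channel permeability, (mM um/s) per (J/mol); >= 0.
#' @param RT Thermal energy, J/mol.
#' @param faraday Faraday constant, C/mol.
#' @return Flux, mM um/s, positive inward.
#' @export
passive_ion_flux <- function(z, Gamma, V_m, G_m, alpha, RT, faraday) {
  check_gamma(Gamma, "Gamma")
  alpha * G_m * (RT * log(Gamma) - z * faraday * V_m)
}

#' Na+/K+ pump flux (3 Na+ out : 2 K+ in)
#'
#' Voltage-gated, saturating in both substrate ratios through cubed/squared
#' Hill factors. Returns the Na and K fluxes; the Na flux is negative
#' (outward) when the pump runs forward and `J_K = -(2/3) J_Na`.
#'
#' @param Gamma_Na,Gamma_K Extra/intracellular concentration ratios; > 0.
#' @param V_m Membrane potential jump, V.
#' @param alpha_NKE Pump permeability (density x ATP availability), mM um/s.
#' @param beta_Na,beta_K Hill-factor scalings of `Gamma_Na` and `1/Gamma_K`.
#' @param beta3,beta4 Voltage-gate constants.
#' @return List with elements `Na` and `K`, mM um/s, positive inward.
#' @export
nke_flux <- function(Gamma_Na, Gamma_K, V_m, alpha_NKE, beta_Na, beta_K, beta3, beta4) {
  check_gamma(Gamma_Na, "Gamma_Na")
  check_gamma(Gamma_K, "Gamma_K")
  G_V <- gate_nke_voltage(V_m, beta3, beta4)
  J_Na <- -alpha_NKE * G_V * (1 + beta_Na * Gamma_Na)^-3 * (1 + beta_K / Gamma_K)^-2
  list(Na = J_Na, K = -(2 / 3) * J_Na)
}

#' Na+/H+ exchanger flux (1:1 antiport)
#'
#' `J_Na = alpha G_NHE(pH) RT (ln Gamma_Na - ln Gamma_H)`, `J_H = -J_Na`.
#' The pH gate makes the exchanger quiescent at alkaline intracellular pH.
#'
#' @inheritParams nke_flux
#' @param Gamma_H Proton concentration ratio; > 0.
#' @param pH Intracellular pH at the end.
#' @param alpha_NHE Exchanger permeability, (mM um/s) per (J/mol).
#' @param beta5,beta6 pH-gate constants.
#' @param RT Thermal energy, J/mol.
#' @return List with elements `Na` and `H`, mM um/s, positive inward.
#' @export
nhe_flux <- function(Gamma_Na, Gamma_H, pH, alpha_NHE, beta5, beta6, RT) {
  check_gamma(Gamma_Na, "Gamma_Na")
  check_gamma(Gamma_H, "Gamma_H")
  J <- alpha_NHE * gate_nhe(pH, beta5, beta6) * RT * (log(Gamma_Na) - log(Gamma_H))
  list(Na = J, H = -J)
}

#' Cl-/HCO3- exchanger flux (1:1 antiport)
#'
#' `J_Cl = alpha G_AE2(pH) RT (ln Gamma_Cl - ln Gamma_HCO3)`,
#' `J_HCO3 = -J_Cl`; quiescent at acidic intracellular pH.
#'
#' @inheritParams nhe_flux
#' @param Gamma_Cl,Gamma_HCO3 Concentration ratios; > 0.
#' @param alpha_AE2 Exchanger permeability, (mM um/s) per (J/mol).
#' @param beta7,beta8 pH-gate constants.
#' @return List with elements `Cl` and `HCO3`, mM um/s, positive inward.
#' @export
ae2_flux <- function(Gamma_Cl, Gamma_HCO3, pH, alpha_AE2, beta7, beta8, RT) {
  check_gamma(Gamma_Cl, "Gamma_Cl")
  check_gamma(Gamma_HCO3, "Gamma_HCO3")
  J <- alpha_AE2 * gate_ae2(pH, beta7, beta8) * RT * (log(Gamma_Cl) - log(Gamma_HCO3))
  list(Cl = J, HCO3 = -J)
}

#' Actin polymerization flux at the cell front
#'
#' Saturating (Michaelis-Menten) dependence on the local G-actin pool:
#' `J_actin = J_actin^f * theta_c / (theta_cc + theta_c)`.
#'
#' @param theta_c Front G-actin concentration, mM; >= 0.
#' @param J_actin_f Maximal polymerization rate, mM um/s.
#' @param theta_cc Half-saturation G-actin concentration, mM; > 0.
#' @return Polymerization flux, mM um/s, in `[0, J_actin_f)`.
#' @export
actin_polymerization_flux <- function(theta_c, J_actin_f, theta_cc) {
  if (any(theta_cc <= 0)) abort("`theta_cc` must be > 0.", class = "osmigrate_invalid_parameter")
  if (any(theta_c < 0)) abort("`theta_c` must be >= 0.", class = "osmigrate_invalid_input")
  J_actin_f * theta_c / (theta_cc + theta_c)
}

#' Assemble every membrane flux at one cell end
#'
#' Evaluates the full pump-leak flux set from the end-local state: resolves
#' the water-flux/external-pressure pair, computes tension and all gates,
#' then the per-mechanism ion fluxes and their per-species totals
#' (`J_Na = J_Na,p + J_NKE,Na + J_NHE,Na`, `J_K = J_K,p + J_NKE,K`,
#' `J_Cl = J_Cl,p + J_AE2,Cl`, `J_H = J_NHE,H`, `J_HCO3 = J_AE2,HCO3`).
#' Buffer and impermeant-protein fluxes are identically zero.
#'
#' @param end_state List with `end`, `p_c` (Pa), `theta_n`, `theta_c` (mM),
#'   `c_Na`, `c_K`, `c_Cl`, `c_A`, `c_Buf` (mM), `pH`, `phi` (V), `v0`
#'   (um/s), all evaluated at that end's boundary node.
#' @param end_params The `front` or `back` component of the parameter set.
#' @param params A validated `oem_parameters` object.
#' @return A `membrane_fluxes` list: `water`, `p_star`, `tau_m`, `V_m`,
#'   gates, `total` (named species flux vector, mM um/s, positive inward),
#'   `passive`, `nke`, `nhe`, `ae2` decompositions, and `actin`.
#' @export
assemble_boundary_fluxes <- function(end_state, end_params, params) {
  d <- params$derived
  g <- params$gating_constants
  es <- end_state
  c_H <- proton_from_ph(es$pH)
  c_HCO3 <- bicarbonate_from_ph(es$pH, params$pco2, params$henry_constant, params$pK_c)
  c_HBuf <- buffer_partition(es$pH, es$c_Buf, params$pK_B)
  c_in <- c(
    Na = es$c_Na, K = es$c_K, Cl = es$c_Cl, H = c_H, HCO3 = c_HCO3,
    A = es$c_A, Buf = es$c_Buf, HBuf = c_HBuf
  )
  c_total <- sum(c_in)

  wf <- resolve_water_flux(
    es$end, es$p_c, c_total, d$c0_total, es$v0,
    end_params$water_permeability, end_params$hydraulic_resistance,
    end_params$external_pressure, d$RT
  )
  sigma_n <- params$actin_stiffness * es$theta_n
  tau_m <- membrane_tension(sigma_n, es$p_c, wf$p_star, params$membrane_thickness_factor)
  V_m <- es$phi - params$extracellular_potential
  G_m <- gate_mechanosensitive(tau_m, g$beta1, g$beta2)

  Gamma <- d$c0[passive_species] / c_in[passive_species]
  passive <- setNames(numeric(3), passive_species)
  for (sp in passive_species) {
    passive[[sp]] <- passive_ion_flux(
      d$z[[sp]], Gamma[[sp]], V_m, G_m,
      end_params$passive_permeability[[sp]], d$RT, params$faraday
    )
  }
  nke <- nke_flux(
    Gamma[["Na"]], Gamma[["K"]], V_m, end_params$nke_permeability,
    params$nke_scalings$Na, params$nke_scalings$K, g$beta3, g$beta4
  )
  nhe <- nhe_flux(
    Gamma[["Na"]], d$c_H0 / c_H, es$pH, end_params$nhe_permeability,
    g$beta5, g$beta6, d$RT
  )
  ae2 <- ae2_flux(
    Gamma[["Cl"]], d$c_HCO3_0 / c_HCO3, es$pH, end_params$ae2_permeability,
    g$beta7, g$beta8, d$RT
  )
  actin <- if (identical(es$end, "front")) {
    actin_polymerization_flux(
      es$theta_c, end_params$actin_polymerization_rate,
      params$polymerization_saturation
    )
  } else {
    0
  }
  total <- c(
    Na = passive[["Na"]] + nke$Na + nhe$Na,
    K = passive[["K"]] + nke$K,
    Cl = passive[["Cl"]] + ae2$Cl,
    H = nhe$H,
    HCO3 = ae2$HCO3,
    A = 0, Buf = 0, HBuf = 0
  )
  structure(
    list(
      end = es$end, water = wf$J_water, p_star = wf$p_star, tau_m = tau_m,
      V_m = V_m, G_m = G_m,
      G_V = gate_nke_voltage(V_m, g$beta3, g$beta4),
      G_NHE = gate_nhe(es$pH, g$beta5, g$beta6),
      G_AE2 = gate_ae2(es$pH, g$beta7, g$beta8),
      total = total, passive = passive,
      nke = unlist(nke), nhe = unlist(nhe), ae2 = unlist(ae2),
      actin = actin
    ),
    class = "membrane_fluxes"
  )
}
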