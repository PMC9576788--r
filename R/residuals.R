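#' Bulk residual equations on the moving-frame domain
#'
#' The steady state is posed on a uniform grid of `N` nodes over `x` in
#' `[0, L]`, back of the cell at `x = 0`, front at `x = L`, positive cell
#' velocity `v0` meaning migration toward the front. The model is steady in
#' the frame moving with the cell, so every bulk advection term uses the
#' velocity relative to the cell (`v - v0`); membrane boundary fluxes are
#' fluxes relative to the moving membrane, positive inward.
#'
#' Discretization: fluxes and first-order balances are evaluated at cell
#' midpoints with central differences (second order); end derivatives use
#' three-point one-sided stencils; integral constraints use trapezoidal
#' quadrature. Residuals returned by these functions are in physical units;
#' the solver applies its own row scaling.
#'
#' A `profiles` argument is a list (or data frame) with the nodal fields
#' `x, p, v_c, v_n, theta_n, theta_c, c_Na, c_K, c_Cl, pH, c_A, c_Buf, phi`
#' (where `v_c` is the spatially constant cytosol velocity, lab frame) and
#' the scalar `v0`.
#'
#' @name bulk-residuals
NULL

av <- function(y) (y[-1] + y[-length(y)]) / 2

trapz <- function(y, h) h * (sum(y) - (y[1] + y[length(y)]) / 2)

onesided_deriv <- function(y, h, at = c("first", "last")) {
  n <- length(y)
  switch(match.arg(at),
    first = (-3 * y[1] + 4 * y[2] - y[3]) / (2 * h),
    last = (3 * y[n] - 4 * y[n - 1] + y[n - 2]) / (2 * h)
  )
}

central_deriv <- function(y, h) {
  n <- length(y)
  c(
    onesided_deriv(y, h, "first"),
    (y[-(1:2)] - y[1:(n - 2)]) / (2 * h),
    onesided_deriv(y, h, "last")
  )
}

# Convert a user-facing profiles list into the internal field set (relative
# velocities, grid metadata).
fields_from_profiles <- function(profiles, v0 = NULL) {
  f <- as.list(profiles)
  if (is.null(v0)) v0 <- f$v0[1]
  stopifnot(!is.null(v0), !is.null(f$x))
  N <- length(f$x)
  h <- f$x[2] - f$x[1]
  list(
    x = f$x, N = N, h = h,
    p = f$p,
    # the network unknown is the relative F-actin flux q_n = theta_n (v_n -
    # v0): the momentum and mass balances are linear in it and stay
    # well-posed when the network vanishes (latrunculin-type conditions)
    q_n = f$theta_n * (f$v_n - v0),
    theta_n = f$theta_n, theta_c = f$theta_c,
    c_Na = f$c_Na, c_K = f$c_K, c_Cl = f$c_Cl,
    pH = f$pH, c_A = f$c_A, c_Buf = f$c_Buf, phi = f$phi,
    u_c = f$v_c[1] - v0, v0 = v0
  )
}

derived_concentrations <- function(pH, c_Buf, params) {
  list(
    c_H = proton_from_ph(pH),
    c_HCO3 = bicarbonate_from_ph(pH, params$pco2, params$henry_constant, params$pK_c),
    c_HBuf = buffer_partition(pH, c_Buf, params$pK_B)
  )
}

end_state_from_fields <- function(fields, end) {
  i <- if (end == "front") fields$N else 1L
  list(
    end = end, p_c = fields$p[i], theta_n = fields$theta_n[i],
    theta_c = fields$theta_c[i], c_Na = fields$c_Na[i], c_K = fields$c_K[i],
    c_Cl = fields$c_Cl[i], c_A = fields$c_A[i], c_Buf = fields$c_Buf[i],
    pH = fields$pH[i], phi = fields$phi[i], v0 = fields$v0
  )
}

boundary_fluxes_from_fields <- function(fields, params) {
  list(
    front = assemble_boundary_fluxes(
      end_state_from_fields(fields, "front"), params$front, params
    ),
    back = assemble_boundary_fluxes(
      end_state_from_fields(fields, "back"), params$back, params
    )
  )
}

# Electrodiffusive species flux relative to the cell at midpoints:
# J = -D dc/dx + u_c c - D z (F/RT) c dphi/dx
species_flux_mid <- function(cc, D, z, phi, u_c, h, F_over_RT) {
  cbar <- av(cc)
  -D * diff(cc) / h + u_c * cbar - D * z * F_over_RT * cbar * diff(phi) / h
}

#' @rdname bulk-residuals
#' @param profiles See Details.
#' @param params A validated `oem_parameters` object.
#' @return `cytosol_residuals()`: midpoint residuals of the cytosol momentum
#'   balance `-dp/dx - eta theta_n (v_c - v_n) = 0` (length `N - 1`).
#' @export
cytosol_residuals <- function(profiles, params) {
  f <- fields_from_profiles(profiles)
  -diff(f$p) / f$h -
    params$interfacial_friction * (av(f$theta_n) * f$u_c - av(f$q_n))
}

#' @rdname bulk-residuals
#' @return `network_residuals()`: nodal residuals of the actin-network
#'   momentum balance
#'   `-d(k theta_n)/dx + eta theta_n (v_c - v_n) - eta_st theta_n v_n = 0`
#'   (length `N`; focal-adhesion drag acts on the lab-frame network velocity).
#' @export
network_residuals <- function(profiles, params) {
  f <- fields_from_profiles(profiles)
  dsig <- params$actin_stiffness * central_deriv(f$theta_n, f$h)
  -dsig + params$interfacial_friction * (f$theta_n * f$u_c - f$q_n) -
    params$adhesion_strength * (f$q_n + f$theta_n * f$v0)
}

#' @rdname bulk-residuals
#' @return `actin_mass_residuals()`: list with `factin` (interior balances,
#'   back zero-flux row, front polymerization row), `gactin` (interior
#'   balances, front consumption row) and `total_constraint` (the conserved
#'   mean-actin row `integral(theta_n + theta_c) - L theta*`).
#' @export
actin_mass_residuals <- function(profiles, params) {
  f <- fields_from_profiles(profiles)
  h <- f$h
  J_actin <- actin_polymerization_flux(
    f$theta_c[f$N], params$front$actin_polymerization_rate,
    params$polymerization_saturation
  )
  # F-actin: d(q_n)/dx = -gamma theta_n with q_n = theta_n (v_n - v0)
  Fmid <- av(f$q_n)
  factin_interior <- diff(Fmid) / h + params$depolymerization_rate * f$theta_n[2:(f$N - 1)]
  factin <- c(
    back_bc = f$q_n[1],
    interior = factin_interior,
    front_bc = f$q_n[f$N] + J_actin
  )
  # G-actin: d(u_c theta_c - D dtheta_c/dx)/dx = +gamma theta_n
  Gmid <- f$u_c * av(f$theta_c) - params$gactin_diffusivity * diff(f$theta_c) / h
  gactin_interior <- diff(Gmid) / h - params$depolymerization_rate * f$theta_n[2:(f$N - 1)]
  gactin <- c(
    interior = gactin_interior,
    front_bc = f$u_c * f$theta_c[f$N] -
      params$gactin_diffusivity * onesided_deriv(f$theta_c, h, "last") - J_actin
  )
  list(
    factin = factin,
    gactin = gactin,
    total_constraint = trapz(f$theta_n + f$theta_c, h) -
      params$cell_length * params$mean_actin
  )
}

#' @rdname bulk-residuals
#' @return `species_transport_residuals()`: list of residual blocks, one per
#'   transported family (`Na`, `K`, `Cl`, the combined `pH` balance, the
#'   impermeant protein `A` and the buffer total), each ordered back-boundary
#'   row, interior flux-constancy rows, front-boundary (or constraint) row.
#'   Boundary rows equate the domain-edge flux to the membrane flux
#'   (`J(0) = J^b`, `J(L) = -J^f`).
#' @export
species_transport_residuals <- function(profiles, params) {
  f <- fields_from_profiles(profiles)
  d <- params$derived
  h <- f$h
  bf <- boundary_fluxes_from_fields(f, params)
  der <- derived_concentrations(f$pH, f$c_Buf, params)

  mid <- function(cc, sp) species_flux_mid(cc, d$D[[sp]], d$z[[sp]], f$phi, f$u_c, h, d$F_over_RT)
  block <- function(Jmid, Jb, Jf) {
    c(back_bc = Jmid[1] - Jb, interior = diff(Jmid), front_bc = Jmid[f$N - 1] + Jf)
  }

  out <- list()
  for (sp in c("Na", "K", "Cl")) {
    Jmid <- mid(f[[paste0("c_", sp)]], sp)
    out[[sp]] <- block(Jmid, bf$back$total[[sp]], bf$front$total[[sp]])
  }
  # combined acid-base balance, paired with unknown pH:
  # J_HCO3 + J_Buf - J_H spatially constant
  Jc <- mid(der$c_HCO3, "HCO3") + mid(f$c_Buf, "Buf") - mid(der$c_H, "H")
  out$pH <- block(
    Jc,
    bf$back$total[["HCO3"]] - bf$back$total[["H"]],
    bf$front$total[["HCO3"]] - bf$front$total[["H"]]
  )
  # impermeant protein: zero boundary flux, conserved total
  JA <- mid(f$c_A, "A")
  out$A <- c(
    back_bc = JA[1],
    interior = diff(JA),
    constraint = params$cross_section * trapz(f$c_A, h) - params$impermeant_totals$N_A
  )
  # buffer total (Buf + HBuf): zero boundary flux, conserved total
  JB <- mid(f$c_Buf, "Buf") + mid(der$c_HBuf, "HBuf")
  out$Buf <- c(
    back_bc = JB[1],
    interior = diff(JB),
    constraint = params$cross_section * trapz(f$c_Buf + der$c_HBuf, h) -
      params$impermeant_totals$N_Buf_total
  )
  out
}

#' @rdname bulk-residuals
#' @return `electroneutrality_residuals()`: nodal net charge
#'   `sum_n z_n c_n` in mM (length `N`); the equation family paired with the
#'   electric potential.
#' @export
electroneutrality_residuals <- function(profiles, params) {
  f <- fields_from_profiles(profiles)
  d <- params$derived
  der <- derived_concentrations(f$pH, f$c_Buf, params)
  d$z[["Na"]] * f$c_Na + d$z[["K"]] * f$c_K + d$z[["Cl"]] * f$c_Cl +
    d$z[["H"]] * der$c_H + d$z[["HCO3"]] * der$c_HCO3 +
    d$z[["A"]] * f$c_A + d$z[["Buf"]] * f$c_Buf + d$z[["HBuf"]] * der$c_HBuf
}

#' @rdname bulk-residuals
#' @return `impermeant_constraints()`: the two conserved-total rows for the
#'   impermeant protein and the buffer pair, in attomol.
#' @export
impermeant_constraints <- function(profiles, params) {
  f <- fields_from_profiles(profiles)
  der <- derived_concentrations(f$pH, f$c_Buf, params)
  c(
    A = params$cross_section * trapz(f$c_A, f$h) - params$impermeant_totals$N_A,
    Buf = params$cross_section * trapz(f$c_Buf + der$c_HBuf, f$h) -
      params$impermeant_totals$N_Buf_total
  )
}

#' @rdname bulk-residuals
#' @param v0 Cell velocity override (defaults to `profiles$v0`).
#' @return `global_force_balance()`: the scalar whole-cell force balance
#'   residual (Pa): far-field pressure difference, external hydraulic
#'   resistance, focal-adhesion traction `eta_st integral(theta_n v_n)` and
#'   wall friction `xi v0`. With
#'   `symmetric_resistance_in_force_balance: yes` the hydraulic-resistance
#'   term uses each end's own water flux instead of the front flux only.
#' @export
global_force_balance <- function(profiles, params, v0 = NULL) {
  f <- fields_from_profiles(profiles, v0)
  bf <- boundary_fluxes_from_fields(f, params)
  drag <- if (isTRUE(params$symmetric_resistance_in_force_balance)) {
    params$front$hydraulic_resistance * (f$v0 - bf$front$water) +
      params$back$hydraulic_resistance * (f$v0 + bf$back$water)
  } else {
    (params$front$hydraulic_resistance + params$back$hydraulic_resistance) *
      (f$v0 - bf$front$water)
  }
  -(params$front$external_pressure - params$back$external_pressure) - drag -
    params$adhesion_strength * trapz(f$q_n + f$theta_n * f$v0, f$h) -
    params$wall_friction * f$v0
}

# Full physical-unit residual evaluation used by the solver.
# Returns the named blocks plus the boundary fluxes (reused by callers).
eval_residual_blocks <- function(fields, params) {
  f <- fields
  d <- params$derived
  h <- f$h
  bf <- boundary_fluxes_from_fields(f, params)
  der <- derived_concentrations(f$pH, f$c_Buf, params)

  cytosol <- -diff(f$p) / h -
    params$interfacial_friction * (av(f$theta_n) * f$u_c - av(f$q_n))
  cytosol_bc <- c(front = f$u_c + bf$front$water, back = f$u_c - bf$back$water)

  dsig <- params$actin_stiffness * central_deriv(f$theta_n, h)
  network <- -dsig + params$interfacial_friction * (f$theta_n * f$u_c - f$q_n) -
    params$adhesion_strength * (f$q_n + f$theta_n * f$v0)

  J_actin <- bf$front$actin
  Fmid <- av(f$q_n)
  factin <- c(
    f$q_n[1],
    diff(Fmid) / h + params$depolymerization_rate * f$theta_n[2:(f$N - 1)],
    f$q_n[f$N] + J_actin
  )
  Gmid <- f$u_c * av(f$theta_c) - params$gactin_diffusivity * diff(f$theta_c) / h
  gactin <- c(
    diff(Gmid) / h - params$depolymerization_rate * f$theta_n[2:(f$N - 1)],
    f$u_c * f$theta_c[f$N] -
      params$gactin_diffusivity * onesided_deriv(f$theta_c, h, "last") - J_actin,
    trapz(f$theta_n + f$theta_c, h) - params$cell_length * params$mean_actin
  )

  mid <- function(cc, sp) species_flux_mid(cc, d$D[[sp]], d$z[[sp]], f$phi, f$u_c, h, d$F_over_RT)
  block <- function(Jmid, Jb, Jf) c(Jmid[1] - Jb, diff(Jmid), Jmid[f$N - 1] + Jf)

  sp_blocks <- list()
  for (sp in c("Na", "K", "Cl")) {
    sp_blocks[[sp]] <- block(
      mid(f[[paste0("c_", sp)]], sp),
      bf$back$total[[sp]], bf$front$total[[sp]]
    )
  }
  Jc <- mid(der$c_HCO3, "HCO3") + mid(f$c_Buf, "Buf") - mid(der$c_H, "H")
  sp_blocks$pH <- block(
    Jc, bf$back$total[["HCO3"]] - bf$back$total[["H"]],
    bf$front$total[["HCO3"]] - bf$front$total[["H"]]
  )
  JA <- mid(f$c_A, "A")
  sp_blocks$A <- c(
    JA[1], diff(JA),
    params$cross_section * trapz(f$c_A, h) - params$impermeant_totals$N_A
  )
  JB <- mid(f$c_Buf, "Buf") + mid(der$c_HBuf, "HBuf")
  sp_blocks$Buf <- c(
    JB[1], diff(JB),
    params$cross_section * trapz(f$c_Buf + der$c_HBuf, h) -
      params$impermeant_totals$N_Buf_total
  )

  electro <- d$z[["Na"]] * f$c_Na + d$z[["K"]] * f$c_K + d$z[["Cl"]] * f$c_Cl +
    d$z[["H"]] * der$c_H + d$z[["HCO3"]] * der$c_HCO3 +
    d$z[["A"]] * f$c_A + d$z[["Buf"]] * f$c_Buf + d$z[["HBuf"]] * der$c_HBuf

  drag <- if (isTRUE(params$symmetric_resistance_in_force_balance)) {
    params$front$hydraulic_resistance * (f$v0 - bf$front$water) +
      params$back$hydraulic_resistance * (f$v0 + bf$back$water)
  } else {
    (params$front$hydraulic_resistance + params$back$hydraulic_resistance) *
      (f$v0 - bf$front$water)
  }
  force <- -(params$front$external_pressure - params$back$external_pressure) - drag -
    params$adhesion_strength * trapz(f$q_n + f$theta_n * f$v0, h) -
    params$wall_friction * f$v0

  list(
    blocks = list(
      cytosol = cytosol, cytosol_bc = cytosol_bc, network = network,
      factin = factin, gactin = gactin,
      Na = sp_blocks$Na, K = sp_blocks$K, Cl = sp_blocks$Cl,
      pH = sp_blocks$pH, A = sp_blocks$A, Buf = sp_blocks$Buf,
      electroneutrality = electro, force = force
    ),
    fluxes = bf
  )
}
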