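test_that("external pressure follows the end-specific resistance law", {
  expect_equal(external_pressure("front", v0 = 3, J_water = 1, d_g = 0, p0 = 7), 7)
  expect_equal(external_pressure("front", v0 = 1, J_water = 0, d_g = 2, p0 = 0), 2)
  expect_equal(external_pressure("back", v0 = 1, J_water = 0, d_g = 2, p0 = 0), -2)
  expect_error(external_pressure("middle", 0, 0, 1, 0), class = "osmigrate_invalid_input")
})

test_that("water flux follows the chemical-potential difference", {
  expect_equal(water_flux(5, 5, 300, 300, alpha = 1, RT = 2577), 0)
  expect_equal(water_flux(2, 0, 300, 300 - 5 / 2577, alpha = 1, RT = 2577), 3)
  expect_lt(water_flux(1, 1, 290, 310, alpha = 1e-4, RT = 2577), 0) # hypertonic outside
  expect_error(water_flux(0, 0, 1, 1, alpha = -1, RT = 1), class = "osmigrate_invalid_parameter")
})

test_that("resolved water flux is consistent with the implicit flux/pressure pair", {
  # Eliminating p* analytically must satisfy both original relations
  for (end in c("front", "back")) {
    r <- resolve_water_flux(end,
      p = 1000, c_total = 305, c0_total = 300, v0 = 0.01,
      alpha = 2e-5, d_g = 1e5, p0 = 50, RT = 2577
    )
    expect_equal(r$p_star, external_pressure(end, 0.01, r$J_water, 1e5, 50))
    expect_equal(r$J_water, water_flux(1000, r$p_star, 305, 300, 2e-5, 2577))
  }
})

test_that("membrane tension is the linear force balance at the membrane", {
  expect_equal(membrane_tension(2, 3, 5, b = 1), 0)
  expect_equal(membrane_tension(1, 1, 0, b = 2), 2)
  expect_equal(membrane_tension(4, 2, 1, b = 4), 2 * membrane_tension(4, 2, 1, b = 2))
  expect_error(membrane_tension(1, 1, 1, b = 0), class = "osmigrate_invalid_parameter")
})

test_that("gates hit their midpoints, saturate, and are monotone", {
  expect_equal(gate_mechanosensitive(80, 0.02, 80), 0.5)
  expect_equal(gate_mechanosensitive(1e9, 0.02, 80), 1)
  expect_equal(gate_mechanosensitive(-1e9, 0.02, 80), 0)
  expect_equal(gate_nke_voltage(-0.15, 30, -0.15), 0)
  expect_equal(gate_nke_voltage(1e3, 30, -0.15), 1)
  expect_equal(gate_nke_voltage(-1e3, 30, -0.15), -1)
  expect_equal(gate_nhe(7.2, 5, 7.2), 0.5)
  expect_equal(gate_ae2(7.1, 5, 7.1), 0.5)
  # quiescence directions: NHE shuts and AE2 opens at alkaline pH
  expect_lt(gate_nhe(9, 5, 7.2), 1e-3)
  expect_gt(gate_ae2(9, 5, 7.1), 1 - 1e-3)

  grid <- seq(-200, 200, length.out = 101)
  gm <- gate_mechanosensitive(grid, 0.05, 10)
  expect_true(all(gm > 0 & gm < 1) && !is.unsorted(gm))
  gv <- gate_nke_voltage(grid / 1e3, 30, -0.15)
  expect_true(all(gv > -1 & gv < 1) && !is.unsorted(gv))
  ph <- seq(5, 9, length.out = 81)
  expect_true(!is.unsorted(rev(gate_nhe(ph, 5, 7.2))))
  expect_true(!is.unsorted(gate_ae2(ph, 5, 7.1)))
})

test_that("passive flux vanishes at the Nernst potential and changes sign once", {
  RT <- 2577
  Fd <- 96485
  V <- 0.05
  gamma_eq <- exp(1 * Fd * V / RT)
  expect_equal(passive_ion_flux(1, gamma_eq, V, G_m = 0.7, alpha = 2, RT = RT, faraday = Fd), 0)
  expect_equal(passive_ion_flux(-1, 3, 0.1, G_m = 0, alpha = 5, RT = RT, faraday = Fd), 0)
  expect_equal(passive_ion_flux(1, exp(1), 0, G_m = 1, alpha = 1, RT = RT, faraday = Fd), RT)
  expect_error(passive_ion_flux(1, -1, 0, 1, 1, RT, Fd), class = "osmigrate_invalid_input")

  Vs <- seq(-0.1, 0.1, length.out = 201)
  J <- passive_ion_flux(1, gamma_eq, Vs, 1, 1, RT, Fd)
  expect_equal(sum(diff(sign(J)) != 0), 1)
  expect_lt(max(abs(Vs[which(diff(sign(J)) != 0)] - V)), 2e-3)
})

test_that("pump and exchanger fluxes respect their stoichiometries", {
  # pump: off at the voltage midpoint, off without K, 3:2 stoichiometry
  z <- nke_flux(10, 0.03, V_m = -0.15, alpha_NKE = 1, beta_Na = 0.1, beta_K = 0.01,
    beta3 = 30, beta4 = -0.15)
  expect_equal(unlist(z), c(Na = 0, K = 0))
  z <- nke_flux(10, 1e-12, V_m = 1, alpha_NKE = 1, beta_Na = 0.1, beta_K = 0.01,
    beta3 = 30, beta4 = -0.15)
  expect_equal(z$Na, 0, tolerance = 1e-15)
  z <- nke_flux(1, 1, V_m = 10, alpha_NKE = 1, beta_Na = 0, beta_K = 0,
    beta3 = 30, beta4 = -0.15)
  expect_equal(z$Na, -1)
  expect_equal(z$K, 2 / 3)
  # net charge per cycle: J_Na + J_K = J_Na / 3, nonzero when running
  zs <- nke_flux(11, 0.04, -0.05, 3, 0.05, 0.01, 30, -0.15)
  expect_equal(zs$Na + zs$K, zs$Na / 3)
  expect_true(zs$Na != 0)
  expect_error(nke_flux(-1, 1, 0, 1, 1, 1, 1, 0), class = "osmigrate_invalid_input")

  # NHE: equal driving -> 0, alkaline quiescence, 1:1 antiport
  expect_equal(unlist(nhe_flux(2, 2, 7, 1, 5, 7.2, 2577)), c(Na = 0, H = 0))
  expect_lt(abs(nhe_flux(5, 1, 12, 1, 5, 7.2, 2577)$Na), 1e-6)
  g <- gate_nhe(7.2, 5, 7.2)
  z <- nhe_flux(exp(1), 1, 7.2, 1 / (g * 2577), 5, 7.2, 2577)
  expect_equal(z$Na, 1)
  expect_equal(z$H, -1)

  # AE2: equal driving -> 0, acidic quiescence, 1:1 antiport
  expect_equal(unlist(ae2_flux(3, 3, 7.4, 1, 5, 7.1, 2577)), c(Cl = 0, HCO3 = 0))
  expect_lt(abs(ae2_flux(5, 1, 2, 1, 5, 7.1, 2577)$Cl), 1e-6)
  g <- gate_ae2(7.4, 5, 7.1)
  z <- ae2_flux(exp(2), exp(1), 7.4, 1 / (g * 2577), 5, 7.1, 2577)
  expect_equal(z$Cl, 1)
  expect_equal(z$HCO3, -1)
})

test_that("actin polymerization saturates in the G-actin pool", {
  expect_equal(actin_polymerization_flux(0, 2, 0.2), 0)
  expect_equal(actin_polymerization_flux(0.2, 2, 0.2), 1)
  expect_equal(actin_polymerization_flux(1e9, 2, 0.2), 2, tolerance = 1e-8)
  expect_error(actin_polymerization_flux(1, 1, 0), class = "osmigrate_invalid_parameter")
})

test_that("assembled boundary fluxes decompose into their mechanisms", {
  params <- test_params()
  es <- list(
    end = "front", p_c = 500, theta_n = 0.2, theta_c = 0.12,
    c_Na = 15, c_K = 140, c_Cl = 9, c_A = 100, c_Buf = 26,
    pH = 7.15, phi = -0.06, v0 = 3e-4
  )
  fx <- assemble_boundary_fluxes(es, params$front, params)

  # totals are the sums of the independently computed mechanisms
  expect_equal(fx$total[["Na"]], fx$passive[["Na"]] + fx$nke[["Na"]] + fx$nhe[["Na"]])
  expect_equal(fx$total[["K"]], fx$passive[["K"]] + fx$nke[["K"]])
  expect_equal(fx$total[["Cl"]], fx$passive[["Cl"]] + fx$ae2[["Cl"]])
  expect_equal(fx$total[["H"]], fx$nhe[["H"]])
  expect_equal(fx$total[["HCO3"]], fx$ae2[["HCO3"]])
  expect_equal(fx$total[["A"]], 0)
  expect_equal(fx$total[["Buf"]], 0)
  expect_equal(fx$total[["HBuf"]], 0)
  # antiporters are electroneutral, the pump is not
  expect_equal(fx$nhe[["Na"]] + fx$nhe[["H"]], 0)
  expect_equal(fx$ae2[["Cl"]] + fx$ae2[["HCO3"]], 0)
  expect_true(fx$nke[["Na"]] + fx$nke[["K"]] != 0)

  # recompute one mechanism independently from the same end state
  d <- params$derived
  g <- params$gating_constants
  nhe_direct <- nhe_flux(
    d$c0[["Na"]] / es$c_Na, d$c_H0 / proton_from_ph(es$pH), es$pH,
    params$front$nhe_permeability, g$beta5, g$beta6, d$RT
  )
  expect_equal(fx$nhe[["Na"]], nhe_direct$Na)

  # all permeabilities zero -> all ion fluxes zero
  p0 <- params
  for (end in c("front", "back")) {
    p0[[end]]$passive_permeability <- list(Na = 0, K = 0, Cl = 0)
    p0[[end]]$nke_permeability <- 0
    p0[[end]]$nhe_permeability <- 0
    p0[[end]]$ae2_permeability <- 0
  }
  p0 <- validate_parameters(p0)
  fx0 <- assemble_boundary_fluxes(es, p0$front, p0)
  expect_equal(unname(fx0$total), rep(0, 8))
})
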