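test_that("cytosol momentum residuals match trivial and manufactured cases", {
  params <- test_params()
  N <- 41
  prof <- smooth_profiles(params, N)
  # no network, uniform pressure: identically zero
  prof0 <- prof
  prof0$theta_n <- rep(0, N)
  prof0$p <- rep(123, N)
  expect_equal(cytosol_residuals(prof0, params), rep(0, N - 1))

  # constant theta, v_n: p(x) = eta * theta * (v_n - v_c) * x solves the balance
  profm <- prof
  profm$theta_n <- rep(0.2, N)
  profm$v_n <- rep(1e-3, N)
  profm$v_c <- rep(2e-3, N)
  profm$v0 <- 0
  profm$p <- params$interfacial_friction * 0.2 * (1e-3 - 2e-3) * profm$x
  expect_equal(cytosol_residuals(profm, params), rep(0, N - 1), tolerance = 1e-10)

  # independent loop-coded oracle on a generic profile
  r <- cytosol_residuals(prof, params)
  h <- prof$x[2] - prof$x[1]
  u_c <- prof$v_c[1] - prof$v0
  q <- prof$theta_n * (prof$v_n - prof$v0)
  oracle <- numeric(N - 1)
  for (i in seq_len(N - 1)) {
    thbar <- (prof$theta_n[i] + prof$theta_n[i + 1]) / 2
    qbar <- (q[i] + q[i + 1]) / 2
    oracle[i] <- -(prof$p[i + 1] - prof$p[i]) / h -
      params$interfacial_friction * (thbar * u_c - qbar)
  }
  expect_equal(r, oracle)
})

test_that("network momentum residuals match trivial cases and an oracle", {
  params <- test_params()
  N <- 41
  prof <- smooth_profiles(params, N)
  prof0 <- prof
  prof0$theta_n <- rep(0.2, N)
  prof0$v_n <- rep(0, N)
  prof0$v_c <- rep(0, N)
  prof0$v0 <- 0
  expect_equal(network_residuals(prof0, params), rep(0, N), tolerance = 1e-12)

  r <- network_residuals(prof, params)
  h <- prof$x[2] - prof$x[1]
  u_c <- prof$v_c[1] - prof$v0
  q <- prof$theta_n * (prof$v_n - prof$v0)
  th <- prof$theta_n
  k <- params$actin_stiffness
  dth <- numeric(N)
  dth[1] <- (-3 * th[1] + 4 * th[2] - th[3]) / (2 * h)
  dth[N] <- (3 * th[N] - 4 * th[N - 1] + th[N - 2]) / (2 * h)
  for (i in 2:(N - 1)) dth[i] <- (th[i + 1] - th[i - 1]) / (2 * h)
  oracle <- -k * dth + params$interfacial_friction * (th * u_c - q) -
    params$adhesion_strength * (q + th * prof$v0)
  expect_equal(r, oracle)
})

test_that("actin mass residuals satisfy the conservation structure", {
  params <- test_params()
  N <- 41
  prof <- smooth_profiles(params, N)
  # gamma = 0, static network and uniform monomer: bulk residuals vanish
  p0 <- param_set(params, "depolymerization_rate", 0)
  prof0 <- prof
  prof0$v_n <- rep(0, N)
  prof0$v_c <- rep(0, N)
  prof0$v0 <- 0
  prof0$theta_c <- rep(0.1, N)
  r0 <- actin_mass_residuals(prof0, p0)
  expect_equal(unname(r0$factin[2:(N - 1)]), rep(0, N - 2))
  expect_equal(unname(r0$gactin[1:(N - 2)]), rep(0, N - 2))

  # the conserved-total row is exactly zero when theta_n + theta_c == theta*
  profc <- prof
  profc$theta_c <- params$mean_actin - profc$theta_n
  rc <- actin_mass_residuals(profc, params)
  expect_equal(unname(rc$total_constraint), 0, tolerance = 1e-12)

  # exponential F-actin profile with constant relative velocity solves
  # d(q)/dx = -gamma theta_n exactly; discrete residual converges at order 2
  gamma <- params$depolymerization_rate
  u <- -0.05 # decay length |u|/gamma = 25 um, resolved on the 50 um domain
  errs <- vapply(c(41, 81, 161), function(Nk) {
    profe <- smooth_profiles(params, Nk)
    x <- profe$x
    profe$v0 <- 0
    profe$v_n <- rep(u, Nk)
    profe$theta_n <- 0.2 * exp(gamma * x / abs(u))
    re <- actin_mass_residuals(profe, params)
    max(abs(re$factin[2:(Nk - 1)]))
  }, numeric(1))
  orders <- log2(errs[-length(errs)] / errs[-1])
  expect_true(all(orders > 1.8))
})

test_that("species transport residuals vanish for equilibrium profiles", {
  params <- test_params()
  N <- 41
  prof <- smooth_profiles(params, N)
  # uniform concentrations and potential with no cytosol flow: zero interior flux
  prof0 <- prof
  for (f in c("c_Na", "c_K", "c_Cl", "c_A", "c_Buf")) prof0[[f]] <- rep(prof0[[f]][1], N)
  prof0$pH <- rep(7.2, N)
  prof0$phi <- rep(0, N)
  prof0$v_c <- rep(0, N)
  prof0$v0 <- 0
  r0 <- species_transport_residuals(prof0, params)
  for (sp in c("Na", "K", "Cl", "pH", "A", "Buf")) {
    expect_equal(unname(r0[[sp]][2:(N - 1)]), rep(0, N - 2),
      tolerance = 1e-12, label = sp
    )
  }
  # linear profile, pure diffusion: flux is spatially constant
  prof1 <- prof0
  prof1$c_Na <- seq(10, 20, length.out = N)
  r1 <- species_transport_residuals(prof1, params)
  expect_equal(unname(r1$Na[2:(N - 1)]), rep(0, N - 2), tolerance = 1e-12)

  # independently coded Nernst-Planck midpoint evaluator on a generic profile
  r <- species_transport_residuals(prof, params)
  h <- prof$x[2] - prof$x[1]
  u_c <- prof$v_c[1] - prof$v0
  d <- params$derived
  J <- numeric(N - 1)
  for (i in seq_len(N - 1)) {
    cbar <- (prof$c_Na[i] + prof$c_Na[i + 1]) / 2
    J[i] <- -d$D[["Na"]] * (prof$c_Na[i + 1] - prof$c_Na[i]) / h + u_c * cbar -
      d$D[["Na"]] * d$z[["Na"]] * d$F_over_RT * cbar * (prof$phi[i + 1] - prof$phi[i]) / h
  }
  expect_equal(unname(r$Na[2:(N - 1)]), diff(J))
})

test_that("electroneutrality residuals are the nodal charge sums", {
  params <- test_params()
  N <- 11
  prof <- smooth_profiles(params, N)
  # derived proton/bicarbonate contributions at fixed pH
  c_H <- proton_from_ph(7)
  c_HCO3 <- bicarbonate_from_ph(7, params$pco2, params$henry_constant, params$pK_c)
  prof0 <- prof
  prof0$c_Na <- rep(100, N)
  prof0$c_Cl <- rep(100, N)
  prof0$c_K <- rep(0, N)
  prof0$c_A <- rep(0, N)
  prof0$c_Buf <- rep(0, N)
  prof0$pH <- rep(7, N)
  expect_equal(
    electroneutrality_residuals(prof0, params),
    rep(c_H - c_HCO3, N)
  )
  # 100 Na = 90 Cl + 10 A (z_A = -1) once the derived charge is balanced out
  prof0$c_Cl <- rep(90 + c_H - c_HCO3, N)
  prof0$c_A <- rep(10, N)
  expect_equal(electroneutrality_residuals(prof0, params), rep(0, N), tolerance = 1e-12)
  # adding 1 mM K at one node adds +1 mM charge there
  prof1 <- prof0
  prof1$c_K[3] <- 1
  expect_equal(
    electroneutrality_residuals(prof1, params) - electroneutrality_residuals(prof0, params),
    replace(rep(0, N), 3, 1)
  )
})

test_that("impermeant constraints use trapezoidal totals", {
  params <- test_params()
  N <- 41
  prof <- smooth_profiles(params, N)
  S <- params$cross_section
  L <- params$cell_length
  prof$c_A <- rep(params$impermeant_totals$N_A / (S * L), N)
  r <- impermeant_constraints(prof, params)
  expect_equal(unname(r[["A"]]), 0, tolerance = 1e-9)
  prof2 <- prof
  prof2$c_A <- 2 * prof$c_A
  expect_equal(
    unname(impermeant_constraints(prof2, params)[["A"]]),
    params$impermeant_totals$N_A
  )
  # nonuniform profile against an independently coded quadrature
  prof3 <- prof
  prof3$c_A <- 100 + 5 * sin(2 * pi * prof$x / L)
  target <- 0
  for (i in seq_len(N - 1)) {
    target <- target + (prof3$x[i + 1] - prof3$x[i]) *
      (prof3$c_A[i] + prof3$c_A[i + 1]) / 2
  }
  expect_equal(
    unname(impermeant_constraints(prof3, params)[["A"]]),
    S * target - params$impermeant_totals$N_A
  )
})

test_that("the whole-cell force balance matches a term-by-term oracle", {
  params <- test_params()
  N <- 41
  # no water pathway, no actin motion: residual reduces to -(dg_f+dg_b+xi) v0
  p0 <- params
  for (end in c("front", "back")) p0[[end]]$water_permeability <- 0
  p0 <- validate_parameters(p0)
  prof <- smooth_profiles(p0, N)
  prof$v_n <- rep(0, N) # stationary network: no adhesion traction
  r <- global_force_balance(prof, p0)
  dgs <- p0$front$hydraulic_resistance + p0$back$hydraulic_resistance
  expect_equal(r, -(dgs + p0$wall_friction) * prof$v0, tolerance = 1e-10)
  # static symmetric cell: zero
  prof0 <- prof
  prof0$v0 <- 0
  expect_equal(global_force_balance(prof0, p0), 0)

  # generic state: quadrature of the adhesion term recomputed independently
  prof <- smooth_profiles(params, N)
  r <- global_force_balance(prof, params)
  h <- prof$x[2] - prof$x[1]
  q <- prof$theta_n * (prof$v_n - prof$v0)
  integrand <- q + prof$theta_n * prof$v0
  quad <- h * (sum(integrand) - (integrand[1] + integrand[N]) / 2)
  es <- list(
    end = "front", p_c = prof$p[N], theta_n = prof$theta_n[N],
    theta_c = prof$theta_c[N], c_Na = prof$c_Na[N], c_K = prof$c_K[N],
    c_Cl = prof$c_Cl[N], c_A = prof$c_A[N], c_Buf = prof$c_Buf[N],
    pH = prof$pH[N], phi = prof$phi[N], v0 = prof$v0
  )
  Jwf <- assemble_boundary_fluxes(es, params$front, params)$water
  oracle <- -(params$front$external_pressure - params$back$external_pressure) -
    (params$front$hydraulic_resistance + params$back$hydraulic_resistance) *
      (prof$v0 - Jwf) -
    params$adhesion_strength * quad - params$wall_friction * prof$v0
  expect_equal(r, oracle)
})

test_that("bulk discretizations converge at second order on manufactured fields", {
  params <- test_params()
  m <- mms_fields(params)
  eta <- params$interfacial_friction
  eta_st <- params$adhesion_strength
  k <- params$actin_stiffness
  gamma <- params$depolymerization_rate
  Dg <- params$gactin_diffusivity
  d <- params$derived
  q <- function(x) m$theta_n(x) * m$vn_rel(x)
  dq <- function(x) m$dtheta_n(x) * m$vn_rel(x) + m$theta_n(x) * m$dvn_rel(x)

  errs <- sapply(c(41, 81, 161), function(N) {
    prof <- mms_profiles(params, N)
    x <- prof$x
    h <- x[2] - x[1]
    xmid <- (x[-1] + x[-N]) / 2
    interior <- 2:(N - 1)

    # cytosol rows live at midpoints
    exact_cyt <- -m$dp(xmid) - eta * (m$theta_n(xmid) * m$u_c - q(xmid))
    e_cyt <- max(abs(cytosol_residuals(prof, params) - exact_cyt))

    exact_net <- -k * m$dtheta_n(x) + eta * (m$theta_n(x) * m$u_c - q(x)) -
      eta_st * (q(x) + m$theta_n(x) * m$v0)
    e_net <- max(abs(network_residuals(prof, params)[interior] - exact_net[interior]))

    am <- actin_mass_residuals(prof, params)
    exact_fa <- dq(x) + gamma * m$theta_n(x)
    e_fa <- max(abs(am$factin[interior] / 1 - exact_fa[interior]))
    exact_ga <- m$u_c * m$dtheta_c(x) - Dg * m$d2theta_c(x) - gamma * m$theta_n(x)
    e_ga <- max(abs(am$gactin[1:(N - 2)] - exact_ga[interior]))

    sp <- species_transport_residuals(prof, params)
    DN <- d$D[["Na"]]
    zF <- d$z[["Na"]] * d$F_over_RT
    exact_dJ <- -DN * m$d2c_Na(x) + m$u_c * m$dc_Na(x) -
      DN * zF * (m$dc_Na(x) * m$dphi(x) + m$c_Na(x) * m$d2phi(x))
    e_sp <- max(abs(sp$Na[interior] / h - exact_dJ[interior]))

    c(cyt = e_cyt, net = e_net, fa = e_fa, ga = e_ga, sp = e_sp)
  })
  orders <- log2(errs[, -ncol(errs), drop = FALSE] / errs[, -1, drop = FALSE])
  expect_true(all(orders > 1.8),
    info = paste(capture.output(print(orders)), collapse = "\n")
  )
})
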