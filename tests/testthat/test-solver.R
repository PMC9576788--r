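test_that("the initial guess satisfies the algebraic structure exactly", {
  params <- test_params()
  g <- initial_guess(params, 32)
  expect_equal(max(abs(electroneutrality_residuals(g, params))), 0, tolerance = 1e-10)
  expect_equal(unname(impermeant_constraints(g, params)), c(0, 0), tolerance = 1e-8)
  expect_true(all(g$c_Na > 0 & g$c_K > 0 & g$c_Cl > 0))

  pA0 <- params
  pA0$impermeant_totals$N_A <- 0
  pA0 <- validate_parameters(pA0)
  expect_equal(initial_guess(pA0, 16)$c_A, rep(0, 16))
})

test_that("a fully symmetric cell does not move", {
  st <- solve_steady(symmetric_params(), solver_options(grid_size = 48))
  expect_true(st$converged)
  expect_lt(abs(st$v0), 1e-8)
})

test_that("solves are deterministic given parameters and options", {
  st1 <- solve_steady(test_params(), solver_options(grid_size = 32))
  st2 <- solve_steady(test_params(), solver_options(grid_size = 32))
  expect_identical(st1$v0, st2$v0)
  expect_identical(st1$profiles$c_Na, st2$profiles$c_Na)
})

test_that("baseline polarization drives forward migration with clean diagnostics", {
  st <- baseline_state(48)
  expect_gt(st$v0, 0)
  d <- st$diagnostics
  expect_lt(d$flux_constancy_rel, 1e-6)
  expect_lt(d$electroneutrality_rel, 1e-9)
  expect_lt(d$actin_conservation_rel, 1e-8)
  expect_lt(d$impermeant_conservation_rel, 1e-8)
  expect_lt(max(abs(d$cytosol_closure)), 1e-10)
})

test_that("swapping front and back parameters mirrors the solution", {
  base <- test_params()
  draws <- matrix(
    c(
      1.2, 0.8, 1.1, 0.7, 1.3, 0.9,
      0.9, 1.4, 0.8, 1.2, 1.1, 0.8
    ),
    nrow = 3, byrow = TRUE
  )
  for (k in seq_len(3)) {
    p <- base
    p$front$passive_permeability$Cl <- p$front$passive_permeability$Cl * draws[k, 1]
    p$back$passive_permeability$Cl <- p$back$passive_permeability$Cl * draws[k, 2]
    p$front$nhe_permeability <- p$front$nhe_permeability * draws[k, 3]
    p$back$nhe_permeability <- p$back$nhe_permeability * draws[k, 4]
    p$front$actin_polymerization_rate <- 0 # mirror requires no front-only source
    p <- validate_parameters(p)
    pm <- p
    pm$front <- p$back
    pm$back <- p$front
    pm$front$actin_polymerization_rate <- 0
    pm$back$actin_polymerization_rate <- 0
    pm <- validate_parameters(pm)
    st <- solve_steady(p, solver_options(grid_size = 32))
    stm <- solve_steady(pm, solver_options(grid_size = 32))
    expect_equal(stm$v0, -st$v0, tolerance = 1e-6)
    expect_equal(stm$profiles$c_Na, rev(st$profiles$c_Na), tolerance = 1e-6)
    expect_equal(stm$profiles$pH, rev(st$profiles$pH), tolerance = 1e-6)
  }
})

test_that("a single permeant ion equilibrates at its Nernst potential", {
  params <- test_params()
  for (end in c("front", "back")) {
    params[[end]]$passive_permeability$Na <- 0
    params[[end]]$passive_permeability$Cl <- 0
    params[[end]]$nke_permeability <- 0
    params[[end]]$nhe_permeability <- 0
    params[[end]]$ae2_permeability <- 0
  }
  params$front$actin_polymerization_rate <- 0
  params$gating_constants$beta2 <- -1e6 # mechanosensitive gate pinned open
  params <- validate_parameters(params)
  st <- solve_steady(params, solver_options(grid_size = 32))
  RTF <- params$derived$RT / params$faraday
  for (i in c(1, nrow(st$profiles))) {
    V_nernst <- RTF * log(params$derived$c0[["K"]] / st$profiles$c_K[i])
    V_m <- st$profiles$phi[i] - params$extracellular_potential
    expect_equal(V_m, V_nernst, tolerance = 1e-6)
  }
})

test_that("non-convergence raises a structured error with block residuals", {
  params <- test_params()
  opts <- solver_options(grid_size = 32, max_iter = 1, n_restarts = 0)
  err <- tryCatch(solve_steady(params, opts), error = function(e) e)
  expect_s3_class(err, "osmigrate_no_convergence")
  expect_true(!is.null(err$data$block_residuals))
  expect_true("electroneutrality" %in% names(err$data$block_residuals))
})

test_that("check_solution flags a post-hoc perturbed state", {
  st <- baseline_state(48)
  bad <- st
  bad$profiles$c_K[10] <- bad$profiles$c_K[10] + 1
  d <- check_solution(bad, st$params)
  expect_gt(d$electroneutrality_rel, 1e-4)
})

test_that("continuation agrees with direct solves and handles ramps", {
  params <- test_params()
  opts <- solver_options(grid_size = 32)
  base_state <- solve_steady(params, opts)

  # zero-length ramp behaves exactly like solve_steady
  st0 <- continuation_solve(params, opts, list(), base_state = base_state)
  expect_equal(st0$v0, base_state$v0)

  # direct vs continuation at the same target agree to solver tolerance
  target <- list("front.passive_permeability.Cl" = list(mul = 10))
  stc <- continuation_solve(params, opts, target, steps = 4, base_state = base_state)
  pt <- apply_overrides(params, target)
  od <- opts
  od$init <- base_state
  std <- solve_steady(pt, od)
  expect_equal(stc$v0, std$v0, tolerance = 1e-6)
  # enriching the front Cl pathway slows (or reverses) migration
  expect_lt(stc$v0, base_state$v0)
})

test_that("tidiers expose the state as tables and plots build", {
  st <- baseline_state(48)
  td <- tidy(st)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("x", "p", "v_n", "c_Na", "pH", "phi", "c_H") %in% names(td)))
  gl <- glance(st)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$v0, st$v0)
  pl <- autoplot(st)
  expect_s3_class(pl, "ggplot")
})
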