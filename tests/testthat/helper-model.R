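# Shared fixtures: parameter sets and memoized steady-state solves so the
# suite does not repeat identical baseline solves across test files.

.test_cache <- new.env(parent = emptyenv())

test_params <- function() {
  if (is.null(.test_cache$params)) .test_cache$params <- default_parameters()
  .test_cache$params
}

# baseline solve at a given grid size, solved once per run
baseline_state <- function(N = 48) {
  key <- paste0("base", N)
  if (is.null(.test_cache[[key]])) {
    .test_cache[[key]] <- solve_steady(test_params(), solver_options(grid_size = N))
  }
  .test_cache[[key]]
}

# fully front/back-symmetric parameters with no actin polymerization
symmetric_params <- function(base = test_params()) {
  base$front <- base$back
  base$front$actin_polymerization_rate <- 0
  base$back$actin_polymerization_rate <- 0
  validate_parameters(base)
}

# a smooth, structurally valid profile set for residual-level tests
smooth_profiles <- function(params, N = 41) {
  L <- params$cell_length
  x <- seq(0, L, length.out = N)
  s <- function(k, a, b) a + b * sin(k * pi * x / L)
  list(
    x = x,
    p = 200 * cos(pi * x / L),
    v_c = rep(2e-3, N),
    v_n = -1e-3 + 5e-4 * sin(pi * x / L),
    theta_n = s(2, 0.15, 0.03),
    theta_c = s(1, 0.15, -0.02),
    c_Na = s(1, 15, 0.5),
    c_K = s(2, 140, 1),
    c_Cl = s(1, 10, 0.4),
    pH = s(1, 7.2, 0.02),
    c_A = s(2, 100, 2),
    c_Buf = s(1, 25, 0.5),
    phi = -0.06 + 0.002 * sin(pi * x / L),
    v0 = 5e-4
  )
}

# Analytic field set used for manufactured-solution checks: every field is a
# smooth closed form whose derivatives are written out by hand, so discrete
# residuals can be compared against the exact continuous operators.
mms_fields <- function(params) {
  L <- params$cell_length
  w1 <- pi / L
  w2 <- 2 * pi / L
  list(
    L = L,
    v0 = 5e-4, u_c = 2e-3 - 5e-4,
    p = function(x) 200 * cos(w1 * x),
    dp = function(x) -200 * w1 * sin(w1 * x),
    theta_n = function(x) 0.15 + 0.03 * sin(w2 * x),
    dtheta_n = function(x) 0.03 * w2 * cos(w2 * x),
    vn_rel = function(x) -1.5e-3 + 5e-4 * sin(w1 * x), # v_n - v0
    dvn_rel = function(x) 5e-4 * w1 * cos(w1 * x),
    theta_c = function(x) 0.15 - 0.02 * sin(w1 * x),
    dtheta_c = function(x) -0.02 * w1 * cos(w1 * x),
    d2theta_c = function(x) 0.02 * w1^2 * sin(w1 * x),
    c_Na = function(x) 15 + 0.5 * sin(w1 * x),
    dc_Na = function(x) 0.5 * w1 * cos(w1 * x),
    d2c_Na = function(x) -0.5 * w1^2 * sin(w1 * x),
    phi = function(x) -0.06 + 0.002 * sin(w1 * x),
    dphi = function(x) 0.002 * w1 * cos(w1 * x),
    d2phi = function(x) -0.002 * w1^2 * sin(w1 * x)
  )
}

mms_profiles <- function(params, N) {
  m <- mms_fields(params)
  x <- seq(0, m$L, length.out = N)
  prof <- smooth_profiles(params, N)
  prof$p <- m$p(x)
  prof$theta_n <- m$theta_n(x)
  prof$v_n <- m$vn_rel(x) + m$v0
  prof$theta_c <- m$theta_c(x)
  prof$c_Na <- m$c_Na(x)
  prof$phi <- m$phi(x)
  prof$v_c <- rep(m$u_c + m$v0, N)
  prof$v0 <- m$v0
  prof
}

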