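#' Solver options
#'
#' Options controlling the damped Newton solve of the steady-state system.
#'
#' @param grid_size Number of grid nodes `N` (>= 16). 128 resolves the
#'   default cell to well under 1% in the migration velocity.
#' @param newton_tol Target max-norm of the scaled residual.
#' @param stall_tol Residual level still accepted as converged when Newton
#'   stalls at the rounding floor of the discretized fluxes.
#' @param max_iter Maximum Newton iterations.
#' @param n_restarts Perturbed restarts (seeded) attempted after a failed
#'   solve before giving up.
#' @param seed Integer seed used for perturbed restarts.
#' @param init Optional warm-start: an `oem_state` or a profiles list from a
#'   previous solve (interpolated onto the requested grid if needed).
#' @param verbose Print per-iteration residual norms.
#' @return A `solver_options` list.
#' @export
solver_options <- function(grid_size = 128, newton_tol = 1e-10, stall_tol = 3e-9,
                           max_iter = 60, n_restarts = 3, seed = 1L,
                           init = NULL, verbose = FALSE) {
  stopifnot(grid_size >= 16, newton_tol > 0, stall_tol >= newton_tol, max_iter >= 1)
  structure(
    list(
      grid_size = as.integer(grid_size), newton_tol = newton_tol,
      stall_tol = stall_tol, max_iter = as.integer(max_iter),
      n_restarts = as.integer(n_restarts), seed = as.integer(seed),
      init = init, verbose = isTRUE(verbose)
    ),
    class = "solver_options"
  )
}

grid_fields <- c(
  "p", "q_n", "theta_n", "theta_c", "c_Na", "c_K", "c_Cl", "pH",
  "c_A", "c_Buf", "phi"
)

# package-level cache for sparsity patterns / colorings
.osm_cache <- new.env(parent = emptyenv())

# Characteristic scales used to nondimensionalize unknowns and residual rows.
solver_scales <- function(params) {
  RT <- params$derived$RT
  list(
    c = 100, # mM
    v = 1e-2, # um/s (10 nm/s)
    p = RT * 100, # Pa
    th = params$mean_actin, # mM
    phi = RT / params$faraday, # V
    flux = 100 * 1e-2 # mM um/s
  )
}

# Structural flags: which equation families degenerate for this parameter set
# (species with no membrane pathway at either end get a conserved-content row
# instead of a redundant zero-flux boundary row; with no water pathway the
# pressure level is pinned at the back instead).
structure_flags <- function(params) {
  f <- params$front
  b <- params$back
  list(
    zero_Na = all(c(
      f$passive_permeability$Na, b$passive_permeability$Na,
      f$nke_permeability, b$nke_permeability,
      f$nhe_permeability, b$nhe_permeability
    ) == 0),
    zero_K = all(c(
      f$passive_permeability$K, b$passive_permeability$K,
      f$nke_permeability, b$nke_permeability
    ) == 0),
    zero_Cl = all(c(
      f$passive_permeability$Cl, b$passive_permeability$Cl,
      f$ae2_permeability, b$ae2_permeability
    ) == 0),
    zero_pH = all(c(
      f$nhe_permeability, b$nhe_permeability,
      f$ae2_permeability, b$ae2_permeability
    ) == 0),
    zero_water = all(c(f$water_permeability, b$water_permeability) == 0),
    symm = isTRUE(params$symmetric_resistance_in_force_balance)
  )
}

structure_signature <- function(params, N) {
  fl <- structure_flags(params)
  zeros <- vapply(
    c(
      params$front$actin_polymerization_rate, params$depolymerization_rate,
      params$gating_constants$beta1, params$wall_friction,
      params$adhesion_strength, params$interfacial_friction,
      params$front$hydraulic_resistance, params$back$hydraulic_resistance,
      unlist(params$front$passive_permeability),
      unlist(params$back$passive_permeability),
      params$front$nke_permeability, params$back$nke_permeability,
      params$front$nhe_permeability, params$back$nhe_permeability,
      params$front$ae2_permeability, params$back$ae2_permeability
    ),
    function(v) v == 0, logical(1)
  )
  paste(N, paste(as.integer(unlist(fl)), collapse = ""),
    paste(as.integer(zeros), collapse = ""),
    sep = "-"
  )
}

#' Initial guess for the steady-state solve
#'
#' Spatially uniform profiles that satisfy the algebraic structure exactly:
#' impermeants spread uniformly to meet their conserved totals, pH at the
#' extracellular value, Na/K/Cl at Donnan-adjusted extracellular values so
#' every node is exactly electroneutral, potential at the bath reference,
#' all velocities zero, and pressure at the osmotic-equilibrium value so the
#' initial water flux vanishes.
#'
#' @param params A validated `oem_parameters` object.
#' @param N Number of grid nodes.
#' @return A profiles list (`x`, nodal fields, `v0 = 0`).
#' @export
initial_guess <- function(params, N) {
  d <- params$derived
  L <- params$cell_length
  x <- seq(0, L, length.out = N)
  c_A <- params$impermeant_totals$N_A / (params$cross_section * L)
  buf_tot <- params$impermeant_totals$N_Buf_total / (params$cross_section * L)
  c_Buf <- buf_tot / (1 + 10^(params$pK_B - params$extracellular_pH))
  pH <- params$extracellular_pH
  der <- derived_concentrations(pH, c_Buf, params)
  # Donnan factor lambda: cations scaled by lambda, Cl by 1/lambda, such that
  # the node is electroneutral given the fixed impermeant/derived charge.
  fixed_charge <- d$z[["H"]] * der$c_H + d$z[["HCO3"]] * der$c_HCO3 +
    d$z[["A"]] * c_A + d$z[["Buf"]] * c_Buf
  cat0 <- d$c0[["Na"]] + d$c0[["K"]]
  if (cat0 <= 0 || d$c0[["Cl"]] <= 0) {
    abort("Initial guess requires positive extracellular Na/K and Cl.",
      class = "osmigrate_infeasible"
    )
  }
  disc <- fixed_charge^2 + 4 * cat0 * d$c0[["Cl"]]
  lambda <- (-fixed_charge + sqrt(disc)) / (2 * cat0)
  if (lambda <= 0) {
    abort("Impermeant totals admit no positive Donnan-adjusted ion balance.",
      class = "osmigrate_infeasible"
    )
  }
  c_Na <- lambda * d$c0[["Na"]]
  c_K <- lambda * d$c0[["K"]]
  c_Cl <- d$c0[["Cl"]] / lambda
  c_tot <- c_Na + c_K + c_Cl + der$c_H + der$c_HCO3 + c_A + c_Buf + der$c_HBuf
  p0m <- (params$front$external_pressure + params$back$external_pressure) / 2
  p <- p0m + d$RT * (c_tot - d$c0_total)
  ones <- rep(1, N)
  list(
    x = x, p = p * ones, v_c = 0 * ones, v_n = 0 * ones,
    theta_n = params$mean_actin / 2 * ones, theta_c = params$mean_actin / 2 * ones,
    c_Na = c_Na * ones, c_K = c_K * ones, c_Cl = c_Cl * ones,
    pH = pH * ones, c_A = c_A * ones, c_Buf = c_Buf * ones,
    phi = params$extracellular_potential * ones, v0 = 0
  )
}

# Conserved-content targets for species with no membrane pathway, evaluated
# from the canonical initial guess so they are deterministic in the
# parameters alone (warm starts do not change them).
impermeable_targets <- function(params, N) {
  g <- initial_guess(params, N)
  S <- params$cross_section
  h <- g$x[2] - g$x[1]
  der <- derived_concentrations(g$pH, g$c_Buf, params)
  list(
    Na = S * trapz(g$c_Na, h), K = S * trapz(g$c_K, h), Cl = S * trapz(g$c_Cl, h),
    pH = S * trapz(der$c_HCO3 + g$c_Buf - der$c_H, h)
  )
}

pack_fields <- function(fields) {
  c(unlist(fields[grid_fields], use.names = FALSE), fields$u_c, fields$v0)
}

unpack_fields <- function(x, N, grid) {
  out <- list(x = grid, N = N, h = grid[2] - grid[1])
  for (k in seq_along(grid_fields)) {
    out[[grid_fields[k]]] <- x[((k - 1) * N + 1):(k * N)]
  }
  out$u_c <- x[11 * N + 1]
  out$v0 <- x[11 * N + 2]
  out
}

# Column scale vector (order matches pack_fields).
column_scales <- function(params, N) {
  s <- solver_scales(params)
  per_field <- c(
    p = s$p, q_n = s$th * s$v, theta_n = s$th, theta_c = s$th,
    c_Na = s$c, c_K = s$c, c_Cl = s$c, pH = 1,
    c_A = s$c, c_Buf = s$c, phi = s$phi
  )
  unname(c(rep(per_field[grid_fields], each = N), s$v, s$v))
}

# Row scale vector (order matches the residual assembly).
row_scales <- function(params, N, flags) {
  s <- solver_scales(params)
  L <- params$cell_length
  cons_c <- params$cross_section * L * s$c
  actin_int <- s$th * (s$v / L + params$depolymerization_rate)
  species_block <- function(zero) {
    bc <- if (zero) c(s$flux, rep(s$flux, N - 2), cons_c) else rep(s$flux, N)
    bc
  }
  c(
    rep(s$p / L, N - 1), # cytosol momentum
    if (flags$zero_water) c(s$v, s$p) else c(s$v, s$v), # cytosol bc
    rep(params$actin_stiffness * s$th / L +
      (params$interfacial_friction + params$adhesion_strength) * s$th * s$v, N), # network
    c(s$th * s$v, rep(actin_int, N - 2), s$th * s$v), # factin
    c(rep(actin_int, N - 2), s$th * s$v, L * s$th), # gactin
    species_block(flags$zero_Na),
    species_block(flags$zero_K),
    species_block(flags$zero_Cl),
    species_block(flags$zero_pH),
    c(s$flux, rep(s$flux, N - 2), cons_c), # A
    c(s$flux, rep(s$flux, N - 2), cons_c), # Buf
    rep(s$c, N), # electroneutrality
    max(
      1,
      (params$front$hydraulic_resistance + params$back$hydraulic_resistance +
        params$wall_friction) * s$v
    ) # force balance
  )
}

# Scaled residual closure. The network-phase unknown is the relative F-actin
# flux q_n = theta_n (v_n - v0), in which the momentum and mass balances are
# linear, so the system stays well-posed when the network vanishes
# (latrunculin-type conditions with no polymerization).
make_residual <- function(params, N) {
  flags <- structure_flags(params)
  s <- solver_scales(params)
  L <- params$cell_length
  grid <- seq(0, L, length.out = N)
  colsc <- column_scales(params, N)
  rowsc <- row_scales(params, N, flags)
  targets <- impermeable_targets(params, N)
  S <- params$cross_section

  eval_phys <- function(x) {
    f <- unpack_fields(x, N, grid)
    out <- eval_residual_blocks(f, params)
    b <- out$blocks
    h <- f$h
    # species with no membrane pathway: conserved-content row replaces the
    # (redundant) front boundary row
    if (flags$zero_Na) b$Na[N] <- S * trapz(f$c_Na, h) - targets$Na
    if (flags$zero_K) b$K[N] <- S * trapz(f$c_K, h) - targets$K
    if (flags$zero_Cl) b$Cl[N] <- S * trapz(f$c_Cl, h) - targets$Cl
    if (flags$zero_pH) {
      der <- derived_concentrations(f$pH, f$c_Buf, params)
      b$pH[N] <- S * trapz(der$c_HCO3 + f$c_Buf - der$c_H, h) - targets$pH
    }
    # no water pathway: pin the pressure level instead of the duplicate
    # cytosol closure
    if (flags$zero_water) {
      b$cytosol_bc[2] <- f$p[1] - params$back$external_pressure
    }
    list(r = unlist(b, use.names = FALSE), fluxes = out$fluxes, fields = f)
  }

  fn <- function(xs) {
    res <- tryCatch(eval_phys(xs * colsc), error = function(e) NULL)
    if (is.null(res) || anyNA(res$r) || any(!is.finite(res$r))) {
      return(NULL)
    }
    res$r_scaled <- res$r / rowsc
    res
  }

  lay <- block_layout(N)
  colof <- function(field, i) (match(field, grid_fields) - 1L) * N + i
  w <- rep(grid[2] - grid[1], N)
  w[c(1, N)] <- w[1] / 2
  ln10 <- log(10)

  # Analytic Jacobian rows for the integral-constraint equations (they are
  # dense in the unknowns, so colored differencing cannot resolve them).
  dense_exact <- function(fields) {
    f <- fields
    der <- derived_concentrations(f$pH, f$c_Buf, params)
    rows <- list()
    add <- function(row, cols, vals) {
      rows[[length(rows) + 1]] <<- list(
        row = row, cols = cols,
        vals = vals * colsc[cols] / rowsc[row]
      )
    }
    add(
      lay$ends[["gactin"]],
      c(colof("theta_n", 1:N), colof("theta_c", 1:N)), c(w, w)
    )
    add(lay$ends[["A"]], colof("c_A", 1:N), S * w)
    add(
      lay$ends[["Buf"]],
      c(colof("c_Buf", 1:N), colof("pH", 1:N)),
      c(S * w * (1 + 10^(params$pK_B - f$pH)), -ln10 * S * w * der$c_HBuf)
    )
    if (flags$zero_Na) add(lay$ends[["Na"]], colof("c_Na", 1:N), S * w)
    if (flags$zero_K) add(lay$ends[["K"]], colof("c_K", 1:N), S * w)
    if (flags$zero_Cl) add(lay$ends[["Cl"]], colof("c_Cl", 1:N), S * w)
    if (flags$zero_pH) {
      add(
        lay$ends[["pH"]],
        c(colof("c_Buf", 1:N), colof("pH", 1:N)),
        c(S * w, S * w * ln10 * (der$c_HCO3 + der$c_H))
      )
    }
    rows
  }

  # Cheap standalone evaluator of the (scaled) global force-balance row,
  # used to difference that single dense row column-wise.
  force_fn <- function(xs) {
    f <- unpack_fields(xs * colsc, N, grid)
    bf_front <- assemble_boundary_fluxes(
      end_state_from_fields(f, "front"), params$front, params
    )
    drag <- if (flags$symm) {
      bf_back <- assemble_boundary_fluxes(
        end_state_from_fields(f, "back"), params$back, params
      )
      params$front$hydraulic_resistance * (f$v0 - bf_front$water) +
        params$back$hydraulic_resistance * (f$v0 + bf_back$water)
    } else {
      (params$front$hydraulic_resistance + params$back$hydraulic_resistance) *
        (f$v0 - bf_front$water)
    }
    r <- -(params$front$external_pressure - params$back$external_pressure) - drag -
      params$adhesion_strength * trapz(f$q_n + f$theta_n * f$v0, f$h) -
      params$wall_friction * f$v0
    r / rowsc[lay$ends[["force"]]]
  }

  list(
    fn = fn, colsc = colsc, rowsc = rowsc, grid = grid, N = N,
    flags = flags, n = 11 * N + 2,
    dense_exact = dense_exact, force_fn = force_fn,
    force_row = lay$ends[["force"]],
    known_dense_rows = c(
      lay$ends[["gactin"]], lay$ends[["A"]], lay$ends[["Buf"]],
      if (flags$zero_Na) lay$ends[["Na"]], if (flags$zero_K) lay$ends[["K"]],
      if (flags$zero_Cl) lay$ends[["Cl"]], if (flags$zero_pH) lay$ends[["pH"]],
      lay$ends[["force"]]
    ),
    sig = structure_signature(params, N)
  )
}

# deterministic low-discrepancy jitter (no RNG state touched)
det_jitter <- function(n, k) 0.02 * sin(seq_len(n) * 12.9898 * k + 78.233 * k)

# seeded normal draws that leave the caller's RNG state alone
local_rnorm <- function(n, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  )
  set.seed(seed)
  rnorm(n)
}

# Numeric sparsity pattern + greedy coloring, cached per structure signature.
jacobian_plan <- function(res, xs_ref) {
  key <- res$sig
  if (!is.null(.osm_cache[[key]])) {
    return(.osm_cache[[key]])
  }
  n <- res$n
  h <- 1e-6
  pattern <- vector("list", n)
  for (jit in 1:2) {
    xs <- xs_ref + det_jitter(n, jit)
    base <- res$fn(xs)
    if (is.null(base)) {
      xs <- xs_ref + 0.1 * det_jitter(n, jit)
      base <- res$fn(xs)
    }
    if (is.null(base)) next
    r0 <- base$r_scaled
    for (j in seq_len(n)) {
      xp <- xs
      xp[j] <- xp[j] + h
      rp <- res$fn(xp)
      if (is.null(rp)) next
      hit <- which(abs(rp$r_scaled - r0) > h * 1e-8)
      pattern[[j]] <- union(pattern[[j]], hit)
    }
  }
  nrows <- length(r0)
  row_ncols <- tabulate(unlist(pattern), nbins = nrows)
  dense_rows <- sort(union(which(row_ncols > 25), res$known_dense_rows))
  sparse_pattern <- lapply(pattern, function(p) setdiff(p, dense_rows))

  # greedy coloring: columns sharing any (sparse) row get different colors
  colors <- integer(n)
  color_rows <- list()
  for (j in seq_len(n)) {
    rows_j <- sparse_pattern[[j]]
    assigned <- FALSE
    for (cc in seq_along(color_rows)) {
      if (!any(color_rows[[cc]][rows_j])) {
        colors[j] <- cc
        color_rows[[cc]][rows_j] <- TRUE
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      colors[j] <- length(color_rows) + 1L
      v <- logical(nrows)
      v[rows_j] <- TRUE
      color_rows[[length(color_rows) + 1L]] <- v
    }
  }
  plan <- list(
    pattern = sparse_pattern, colors = colors, n_colors = length(color_rows),
    dense_rows = dense_rows,
    dense_cols = lapply(dense_rows, function(i) {
      which(vapply(pattern, function(p) i %in% p, logical(1)))
    })
  )
  .osm_cache[[key]] <- plan
  plan
}

# Sparse finite-difference Jacobian of the scaled residual using the colored
# plan; dense rows (integral constraints, global force balance) are re-done
# column-wise so simultaneous perturbations cannot alias into them.
fd_jacobian <- function(res, plan, xs, r0, fields) {
  n <- res$n
  hstep <- 1e-7
  ii <- vector("list", plan$n_colors)
  jj <- vector("list", plan$n_colors)
  vv <- vector("list", plan$n_colors)
  for (cc in seq_len(plan$n_colors)) {
    cols <- which(plan$colors == cc)
    xp <- xs
    xp[cols] <- xp[cols] + hstep
    rp <- res$fn(xp)
    if (is.null(rp)) {
      return(NULL)
    }
    delta <- (rp$r_scaled - r0) / hstep
    rows_c <- unlist(plan$pattern[cols], use.names = FALSE)
    cols_c <- rep.int(cols, lengths(plan$pattern[cols]))
    ii[[cc]] <- rows_c
    jj[[cc]] <- cols_c
    vv[[cc]] <- delta[rows_c]
  }
  i_all <- unlist(ii)
  j_all <- unlist(jj)
  v_all <- unlist(vv)
  # dense rows (integral constraints, force balance): analytic where the row
  # is an integral of the unknowns, single-row differencing for the force
  # balance, full-residual differencing as a safety net otherwise
  exact <- res$dense_exact(fields)
  exact_rows <- vapply(exact, function(e) e$row, numeric(1))
  for (e in exact) {
    i_all <- c(i_all, rep.int(e$row, length(e$cols)))
    j_all <- c(j_all, e$cols)
    v_all <- c(v_all, e$vals)
  }
  for (k in seq_along(plan$dense_rows)) {
    row <- plan$dense_rows[k]
    if (row %in% exact_rows) next
    cols <- plan$dense_cols[[k]]
    vals <- numeric(length(cols))
    if (row == res$force_row) {
      f0 <- res$force_fn(xs)
      for (m in seq_along(cols)) {
        xp <- xs
        xp[cols[m]] <- xp[cols[m]] + hstep
        vals[m] <- (res$force_fn(xp) - f0) / hstep
      }
    } else {
      for (m in seq_along(cols)) {
        xp <- xs
        xp[cols[m]] <- xp[cols[m]] + hstep
        rp <- res$fn(xp)
        if (is.null(rp)) {
          return(NULL)
        }
        vals[m] <- (rp$r_scaled[row] - r0[row]) / hstep
      }
    }
    i_all <- c(i_all, rep.int(row, length(cols)))
    j_all <- c(j_all, cols)
    v_all <- c(v_all, vals)
  }
  Matrix::sparseMatrix(
    i = i_all, j = j_all, x = v_all, dims = c(length(r0), n),
    repr = "C"
  )
}

newton_solve <- function(res, xs0, options) {
  xs <- xs0
  ev <- res$fn(xs)
  if (is.null(ev)) {
    return(list(ok = FALSE, reason = "initial residual not finite", xs = xs))
  }
  plan <- jacobian_plan(res, xs0)
  rnorm_ <- function(e) max(abs(e$r_scaled))
  best <- ev
  best_xs <- xs
  history <- numeric(0)
  for (it in seq_len(options$max_iter)) {
    rn <- rnorm_(ev)
    history <- c(history, rn)
    if (options$verbose) message(sprintf("  newton iter %d: max|r| = %.3e", it - 1, rn))
    if (rn <= options$newton_tol) {
      return(list(ok = TRUE, xs = xs, ev = ev, iterations = it - 1L, residual_norm = rn))
    }
    # stalled at rounding floor?
    if (it > 3 && rn <= options$stall_tol) {
      recent <- tail(history, 3)
      if (max(recent) / min(recent) < 1.5) {
        return(list(ok = TRUE, xs = xs, ev = ev, iterations = it - 1L, residual_norm = rn))
      }
    }
    J <- fd_jacobian(res, plan, xs, ev$r_scaled, ev$fields)
    if (is.null(J)) {
      return(list(ok = FALSE, reason = "non-finite residual in Jacobian", xs = best_xs, ev = best))
    }
    dx <- tryCatch(
      as.numeric(Matrix::solve(J, -ev$r_scaled)),
      error = function(e) NULL
    )
    if (is.null(dx) || anyNA(dx)) {
      return(list(ok = FALSE, reason = "singular Jacobian", xs = best_xs, ev = best))
    }
    # Armijo backtracking on the residual norm
    t <- 1
    accepted <- FALSE
    for (ls in 1:30) {
      ev_new <- res$fn(xs + t * dx)
      if (!is.null(ev_new) && rnorm_(ev_new) < (1 - 1e-4 * t) * rn) {
        xs <- xs + t * dx
        ev <- ev_new
        accepted <- TRUE
        break
      }
      t <- t / 2
    }
    if (!accepted) {
      rn_final <- rnorm_(ev)
      if (rn_final <= options$stall_tol) {
        return(list(ok = TRUE, xs = xs, ev = ev, iterations = it, residual_norm = rn_final))
      }
      return(list(
        ok = FALSE, reason = "line search failed", xs = xs, ev = ev,
        residual_norm = rn_final
      ))
    }
    if (rnorm_(ev) < rnorm_(best)) {
      best <- ev
      best_xs <- xs
    }
  }
  rn <- rnorm_(ev)
  if (rn <= options$stall_tol) {
    return(list(ok = TRUE, xs = xs, ev = ev, iterations = options$max_iter, residual_norm = rn))
  }
  list(
    ok = FALSE, reason = "max iterations reached", xs = best_xs, ev = best,
    residual_norm = rnorm_(best)
  )
}

profiles_to_xs <- function(init, params, N, grid, colsc) {
  prof <- if (inherits(init, "oem_state")) as.list(init$profiles) else as.list(init)
  v0 <- if (inherits(init, "oem_state")) init$v0 else prof$v0[1]
  interp <- function(y) {
    if (length(y) == N) y else stats::approx(prof$x, y, xout = grid)$y
  }
  fields <- list(x = grid)
  fields$p <- interp(prof$p)
  fields$q_n <- interp(prof$theta_n) * (interp(prof$v_n) - v0)
  for (fn in c(
    "theta_n", "theta_c", "c_Na", "c_K", "c_Cl", "pH", "c_A",
    "c_Buf", "phi"
  )) {
    fields[[fn]] <- interp(prof[[fn]])
  }
  fields$u_c <- prof$v_c[1] - v0
  fields$v0 <- v0
  pack_fields(fields) / colsc
}

#' Solve the steady-state migration problem
#'
#' Assembles the full square nonlinear system (two-phase mechanics, actin
#' turnover, electrodiffusive ion transport with electroneutrality closure,
#' membrane boundary fluxes, conserved totals and the whole-cell force
#' balance) and solves it by damped Newton iteration with a colored sparse
#' finite-difference Jacobian. The solve is deterministic given
#' `(params, options)`; perturbed restarts use the options seed.
#'
#' @param params A validated `oem_parameters` object.
#' @param options A [solver_options()] list.
#' @return An `oem_state`: `profiles` (tibble of nodal fields, lab-frame
#'   velocities and derived concentrations), scalar `v0` (um/s), per-end
#'   `fluxes` ([assemble_boundary_fluxes()] output), `converged`,
#'   `iterations`, `residual_norm`, and `diagnostics` from
#'   [check_solution()]. On non-convergence an error of class
#'   `osmigrate_no_convergence` carries the best iterate and per-block
#'   residual summary in its `data` field.
#' @examples
#' \donttest{
#' p <- default_parameters()
#' st <- solve_steady(p, solver_options(grid_size = 64))
#' st$v0
#' }
#' @export
solve_steady <- function(params, options = solver_options()) {
  params <- validate_parameters(params)
  N <- options$grid_size
  res <- make_residual(params, N)
  starts <- list()
  if (!is.null(options$init)) {
    starts <- c(starts, list(profiles_to_xs(options$init, params, N, res$grid, res$colsc)))
  }
  xs_guess <- pack_fields(fields_from_profiles(initial_guess(params, N))) / res$colsc
  starts <- c(starts, list(xs_guess))
  # perturbed restarts, deterministic in the seed; global RNG state untouched
  for (k in seq_len(options$n_restarts)) {
    noise <- local_rnorm(res$n, options$seed + 1000L * k)
    starts <- c(starts, list(xs_guess * (1 + 0.02 * noise)))
  }
  last <- NULL
  for (xs0 in starts) {
    out <- newton_solve(res, xs0, options)
    last <- out
    if (out$ok) {
      return(build_state(out, res, params, options))
    }
  }
  blocks <- if (!is.null(last$ev)) {
    summarize_block_residuals(last$ev$r_scaled, N, res$flags)
  } else {
    NULL
  }
  abort(
    sprintf(
      "Steady-state solve did not converge (%s); best max|r| = %.3e",
      last$reason, if (!is.null(last$ev)) max(abs(last$ev$r_scaled)) else NA_real_
    ),
    class = "osmigrate_no_convergence",
    data = list(best = last, block_residuals = blocks)
  )
}

block_layout <- function(N) {
  sizes <- c(
    cytosol = N - 1, cytosol_bc = 2, network = N, factin = N, gactin = N,
    Na = N, K = N, Cl = N, pH = N, A = N, Buf = N,
    electroneutrality = N, force = 1
  )
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1
  list(sizes = sizes, starts = starts, ends = ends)
}

summarize_block_residuals <- function(r, N, flags) {
  lay <- block_layout(N)
  vapply(
    seq_along(lay$sizes),
    function(i) max(abs(r[lay$starts[i]:lay$ends[i]])),
    numeric(1)
  ) |> setNames(names(lay$sizes))
}

build_state <- function(out, res, params, options) {
  f <- out$ev$fields
  der <- derived_concentrations(f$pH, f$c_Buf, params)
  profiles <- tibble::tibble(
    x = f$x,
    p = f$p,
    v_c = f$u_c + f$v0,
    v_n = f$v0 + ifelse(f$theta_n > 1e-9, f$q_n / f$theta_n, 0),
    theta_n = f$theta_n,
    theta_c = f$theta_c,
    c_Na = f$c_Na, c_K = f$c_K, c_Cl = f$c_Cl,
    pH = f$pH, c_A = f$c_A, c_Buf = f$c_Buf,
    phi = f$phi,
    c_H = der$c_H, c_HCO3 = der$c_HCO3, c_HBuf = der$c_HBuf,
    sigma_n = params$actin_stiffness * f$theta_n
  )
  state <- structure(
    list(
      profiles = profiles, v0 = f$v0, u_c = f$u_c,
      fluxes = out$ev$fluxes,
      converged = TRUE, iterations = out$iterations,
      residual_norm = out$residual_norm,
      params = params, options = options[c("grid_size", "newton_tol", "seed")]
    ),
    class = "oem_state"
  )
  state$diagnostics <- check_solution(state, params)
  state
}

#' @export
print.oem_state <- function(x, ...) {
  cat("<oem_state> steady-state confined-cell solution\n")
  cat(sprintf(
    "  v0 = %.4g um/s (%.4g um/min), N = %d nodes, %d Newton iterations\n",
    x$v0, x$v0 * 60, nrow(x$profiles), x$iterations
  ))
  cat(sprintf(
    "  V_m front/back = %.1f / %.1f mV, residual max = %.2e\n",
    1e3 * x$fluxes$front$V_m, 1e3 * x$fluxes$back$V_m, x$residual_norm
  ))
  cat(sprintf(
    "  checks: flux constancy %.1e, electroneutrality %.1e\n",
    x$diagnostics$flux_constancy_rel, x$diagnostics$electroneutrality_rel
  ))
  invisible(x)
}

#' Recompute solution diagnostics from the profiles
#'
#' Everything is recomputed from the stored profiles, never cached from the
#' solve: spatial constancy of every transported family flux (relative to
#' the solution's largest mean family flux, floored at 1e-6 mM um/s), the
#' back-influx/front-efflux balance per conserved family, nodal
#' electroneutrality relative to the total ionic strength, actin and
#' impermeant conservation errors, the cytosol velocity closure and the
#' whole-cell force balance residual.
#'
#' @param state An `oem_state`.
#' @param params Parameter set (defaults to the one stored in the state).
#' @return Named list of diagnostic errors (all dimensionless except
#'   `force_balance` in Pa).
#' @export
check_solution <- function(state, params = state$params) {
  prof <- c(as.list(state$profiles), list(v0 = state$v0))
  f <- fields_from_profiles(prof, state$v0)
  d <- params$derived
  h <- f$h
  bf <- boundary_fluxes_from_fields(f, params)
  der <- derived_concentrations(f$pH, f$c_Buf, params)
  floor_flux <- 1e-6

  mid <- function(cc, sp) species_flux_mid(cc, d$D[[sp]], d$z[[sp]], f$phi, f$u_c, h, d$F_over_RT)
  Jmids <- list(
    Na = mid(f$c_Na, "Na"), K = mid(f$c_K, "K"), Cl = mid(f$c_Cl, "Cl"),
    pH = mid(der$c_HCO3, "HCO3") + mid(f$c_Buf, "Buf") - mid(der$c_H, "H"),
    A = mid(f$c_A, "A"),
    Buf = mid(f$c_Buf, "Buf") + mid(der$c_HBuf, "HBuf")
  )
  # relative to the solution's own flux scale (largest transported mean flux):
  # families whose net flux happens to vanish would otherwise divide rounding
  # noise by zero
  flux_scale <- max(vapply(Jmids, function(J) abs(mean(J)), numeric(1)), floor_flux)
  constancy <- vapply(Jmids, function(J) (max(J) - min(J)) / flux_scale, numeric(1))

  # back influx must equal front efflux per conserved transported family
  # (H and HCO3 are checked through the combined acid-base flux since the
  # equilibria interconvert them along the cell)
  memb <- function(end) {
    tot <- bf[[end]]$total
    c(
      Na = tot[["Na"]], K = tot[["K"]], Cl = tot[["Cl"]],
      pH = tot[["HCO3"]] - tot[["H"]]
    )
  }
  jb <- memb("back")
  jf <- memb("front")
  balance <- abs(jb + jf) / pmax(abs(jb), abs(jf), flux_scale)

  charge <- electroneutrality_residuals(prof, params)
  strength <- abs(d$z[["Na"]]) * f$c_Na + abs(d$z[["K"]]) * f$c_K +
    abs(d$z[["Cl"]]) * f$c_Cl + abs(d$z[["A"]]) * f$c_A + f$c_Buf +
    der$c_H + der$c_HCO3
  actin_rel <- abs(trapz(f$theta_n + f$theta_c, h) -
    params$cell_length * params$mean_actin) /
    (params$cell_length * params$mean_actin)
  imp <- impermeant_constraints(prof, params)
  imp_rel <- abs(imp) / c(
    params$impermeant_totals$N_A,
    params$impermeant_totals$N_Buf_total
  )
  list(
    flux_constancy = constancy,
    flux_constancy_rel = max(constancy),
    flux_balance = balance,
    flux_balance_rel = max(balance),
    electroneutrality_rel = max(abs(charge) / strength),
    actin_conservation_rel = actin_rel,
    impermeant_conservation_rel = max(imp_rel),
    cytosol_closure = c(
      front = f$u_c + bf$front$water,
      back = f$u_c - bf$back$water
    ),
    force_balance = global_force_balance(prof, params, state$v0)
  )
}

#' Continuation solve along a parameter ramp
#'
#' Ramps the named parameters from their base values to the targets in
#' `steps` warm-started increments, halving the step on failure (down to a
#' floor of 1/64 of the ramp). The final state matches a direct solve to
#' solver tolerance whenever both converge; continuation exists to reach
#' strongly polarized or knocked-down regimes for which the cold start is
#' outside Newton's basin.
#'
#' @param params Base parameter set.
#' @param options A [solver_options()] list.
#' @param target_overrides Named list of dotted parameter paths to target
#'   values (see [apply_overrides()]; multiplier entries are resolved against
#'   the base before ramping).
#' @param steps Number of ramp increments (0 = direct solve at the target).
#' @param base_state Optional converged state at the base parameters.
#' @return The `oem_state` at the target parameters.
#' @export
continuation_solve <- function(params, options = solver_options(),
                               target_overrides = list(), steps = 4,
                               base_state = NULL) {
  params <- validate_parameters(params)
  paths <- names(target_overrides)
  base_vals <- vapply(paths, function(p) param_get(params, p), numeric(1))
  target_vals <- vapply(paths, function(p) {
    ov <- target_overrides[[p]]
    if (is.list(ov) && identical(names(ov), "mul")) param_get(params, p) * ov$mul else ov
  }, numeric(1))
  if (length(paths) == 0 || steps == 0) {
    opts <- options
    opts$init <- base_state %||% options$init
    target <- params
    for (i in seq_along(paths)) target <- param_set(target, paths[i], target_vals[i])
    return(solve_steady(target, opts))
  }
  state <- base_state
  frac_done <- 0
  dfrac <- 1 / steps
  min_dfrac <- 1 / 64
  while (frac_done < 1 - 1e-12) {
    frac <- min(1, frac_done + dfrac)
    pk <- params
    for (i in seq_along(paths)) {
      # geometric ramp for positive multiplicative parameters, linear otherwise
      val <- if (base_vals[i] > 0 && target_vals[i] > 0) {
        base_vals[i] * (target_vals[i] / base_vals[i])^frac
      } else {
        base_vals[i] + frac * (target_vals[i] - base_vals[i])
      }
      pk <- param_set(pk, paths[i], val)
    }
    opts <- options
    opts$init <- state %||% options$init
    ok <- tryCatch(solve_steady(pk, opts), osmigrate_no_convergence = function(e) NULL)
    if (is.null(ok)) {
      if (dfrac <= min_dfrac) {
        abort(
          sprintf("Continuation failed at ramp fraction %.3f", frac),
          class = "osmigrate_no_convergence"
        )
      }
      dfrac <- dfrac / 2
    } else {
      state <- ok
      frac_done <- frac
    }
  }
  state
}

`%||%` <- function(a, b) if (is.null(a)) b else a
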