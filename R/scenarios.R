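#' Built-in scenario library
#'
#' Named perturbations of the baseline parameter set that map onto the
#' standard experimental manipulations: polarization reversal and
#' equalization of the rear Cl channel (SWELL1), latrunculin-A treatment
#' (no actin polymerization), and shRNA-style knockdowns modeled as a 0.1x
#' multiplicative scaling of the corresponding permeability at both ends
#' (depletion everywhere, polarization ratio preserved).
#'
#' @return Named list of `oem_scenario` objects (`name`, `overrides`,
#'   `description`).
#' @export
oem_scenarios <- function() {
  sc <- function(name, overrides, description) {
    structure(list(name = name, overrides = overrides, description = description),
      class = "oem_scenario"
    )
  }
  mul <- function(m) list(mul = m)
  kd_swell1 <- list(
    "front.passive_permeability.Cl" = mul(0.1),
    "back.passive_permeability.Cl" = mul(0.1)
  )
  kd_nhe1 <- list(
    "front.nhe_permeability" = mul(0.1),
    "back.nhe_permeability" = mul(0.1)
  )
  list(
    baseline = sc("baseline", list(),
      "rear-polarized Cl conductance, front-polarized Na+/H+ exchange"),
    swell1_front = sc("swell1_front", list(
      "front.passive_permeability.Cl" = mul(4),
      "back.passive_permeability.Cl" = mul(0.25)
    ), "Cl polarization inverted to the front (ratio 1/4), total conductance fixed"),
    swell1_symmetric = sc("swell1_symmetric", list(
      "front.passive_permeability.Cl" = mul(2),
      "back.passive_permeability.Cl" = mul(0.5)
    ), "Cl conductance equalized between the poles, total conductance fixed"),
    lat_a = sc("lat_a", list("front.actin_polymerization_rate" = 0),
      "latrunculin A: actin polymerization disabled"),
    nhe1_kd = sc("nhe1_kd", kd_nhe1, "NHE1 knockdown (0.1x at both ends)"),
    swell1_kd = sc("swell1_kd", kd_swell1, "SWELL1 knockdown (0.1x at both ends)"),
    dual_kd = sc("dual_kd", c(kd_swell1, kd_nhe1),
      "dual NHE1 + SWELL1 knockdown"),
    lat_a_swell1_kd = sc("lat_a_swell1_kd",
      c(list("front.actin_polymerization_rate" = 0), kd_swell1),
      "latrunculin A on SWELL1-knockdown cells")
  )
}

#' @export
print.oem_scenario <- function(x, ...) {
  cat(sprintf("<oem_scenario> %s: %s\n", x$name, x$description))
  invisible(x)
}

#' Solve a scenario
#'
#' Applies a scenario's parameter overrides to the base parameter set and
#' solves the steady state, using parameter continuation from the solved
#' baseline so that strongly perturbed regimes are reached from within
#' Newton's basin of attraction.
#'
#' @param scenario An `oem_scenario` (see [oem_scenarios()]) or the name of a
#'   built-in one.
#' @param base Base parameter set (default [default_parameters()]).
#' @param options [solver_options()].
#' @param base_state Optional pre-solved baseline `oem_state` (saves one
#'   solve when running several scenarios).
#' @return An `oem_state` with a `scenario` field naming the scenario.
#' @export
run_scenario <- function(scenario, base = default_parameters(),
                         options = solver_options(), base_state = NULL) {
  if (is.character(scenario)) {
    lib <- oem_scenarios()
    if (!scenario %in% names(lib)) {
      abort(sprintf("Unknown scenario `%s`", scenario), class = "osmigrate_invalid_input")
    }
    scenario <- lib[[scenario]]
  }
  base <- validate_parameters(base)
  if (length(scenario$overrides) == 0) {
    st <- base_state %||% solve_steady(base, options)
  } else {
    if (is.null(base_state)) {
      base_state <- tryCatch(solve_steady(base, options), error = function(e) NULL)
    }
    st <- withCallingHandlers(
      continuation_solve(base, options,
        target_overrides = scenario$overrides,
        steps = 4, base_state = base_state
      ),
      osmigrate_no_convergence = function(e) {
        abort(sprintf("Scenario `%s` failed to converge", scenario$name),
          class = "osmigrate_no_convergence", parent = e
        )
      }
    )
  }
  st$scenario <- scenario$name
  st
}

#' Set a channel polarization ratio
#'
#' Rewrites the front/back permeabilities of the Cl channel (SWELL1) or the
#' Na+/H+ exchanger (NHE1) to a prescribed polarization ratio. For
#' `mode = "geometric_mean"` (default) the geometric mean of the two ends is
#' held fixed, so total conductance is ratio-independent; `mode =
#' "hold_front"` keeps the front value and moves only the back.
#'
#' The Cl ratio is back/front (rear enrichment > 1); the NHE ratio is
#' front/back (front enrichment > 1), matching each protein's polarized end.
#'
#' @param params Parameter set.
#' @param ratio Positive polarization ratio.
#' @param channel `"Cl"` or `"NHE"`.
#' @param mode Normalization convention (see Details).
#' @return Modified, revalidated parameter set.
#' @export
set_polarization_ratio <- function(params, ratio, channel = c("Cl", "NHE"),
                                   mode = c("geometric_mean", "hold_front")) {
  channel <- match.arg(channel)
  mode <- match.arg(mode)
  if (!is.numeric(ratio) || ratio <= 0) {
    abort("`ratio` must be positive.", class = "osmigrate_invalid_input")
  }
  get2 <- function(end) {
    if (channel == "Cl") params[[end]]$passive_permeability$Cl else params[[end]]$nhe_permeability
  }
  set2 <- function(end, v) {
    if (channel == "Cl") {
      params[[end]]$passive_permeability$Cl <<- v
    } else {
      params[[end]]$nhe_permeability <<- v
    }
  }
  f <- get2("front")
  b <- get2("back")
  # enriched end: back for Cl, front for NHE
  if (mode == "geometric_mean") {
    gm <- sqrt(f * b)
    if (channel == "Cl") {
      set2("front", gm / sqrt(ratio))
      set2("back", gm * sqrt(ratio))
    } else {
      set2("front", gm * sqrt(ratio))
      set2("back", gm / sqrt(ratio))
    }
  } else {
    if (channel == "Cl") set2("back", f * ratio) else set2("back", f / ratio)
  }
  validate_parameters(params)
}

#' Sweep the Cl (SWELL1) polarization ratio
#'
#' Solves the steady state along a grid of back/front Cl-permeability ratios,
#' warm-starting outward from the most symmetric point. Non-converged points
#' carry `NA` velocity (never zero) and are reported, not interpolated.
#'
#' @param base Base parameter set.
#' @param ratios Positive, sorted vector of back/front ratios.
#' @param options [solver_options()].
#' @param mode Ratio normalization, see [set_polarization_ratio()].
#' @param channel Channel whose polarization is swept (`"Cl"` or `"NHE"`).
#' @return An `oem_sweep` tibble: `ratio`, `v0` (um/s), `converged`,
#'   `iterations`, `residual_norm`, `V_m_front_mV`, `J_water_front`.
#'   Provenance (base parameters, options, mode) is attached as attributes.
#' @export
sweep_polarization <- function(base = default_parameters(),
                               ratios = 10^seq(-1, 1, length.out = 25),
                               options = solver_options(),
                               mode = c("geometric_mean", "hold_front"),
                               channel = c("Cl", "NHE")) {
  mode <- match.arg(mode)
  channel <- match.arg(channel)
  if (any(ratios <= 0) || is.unsorted(ratios)) {
    abort("`ratios` must be positive and sorted increasing.",
      class = "osmigrate_invalid_input"
    )
  }
  base <- validate_parameters(base)
  n <- length(ratios)
  rows <- vector("list", n)
  mid <- which.min(abs(log(ratios)))
  order_out <- list(mid:n, rev(seq_len(mid)))
  for (idx_set in order_out) {
    state <- NULL
    for (i in idx_set) {
      pk <- set_polarization_ratio(base, ratios[i], channel = channel, mode = mode)
      o <- options
      o$init <- state
      st <- tryCatch(solve_steady(pk, o), error = function(e) NULL)
      if (is.null(st)) {
        rows[[i]] <- tibble::tibble(
          ratio = ratios[i], v0 = NA_real_, converged = FALSE,
          iterations = NA_integer_, residual_norm = NA_real_,
          V_m_front_mV = NA_real_, J_water_front = NA_real_
        )
      } else {
        state <- st
        rows[[i]] <- tibble::tibble(
          ratio = ratios[i], v0 = st$v0, converged = TRUE,
          iterations = st$iterations, residual_norm = st$residual_norm,
          V_m_front_mV = 1e3 * st$fluxes$front$V_m,
          J_water_front = st$fluxes$front$water
        )
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "base") <- base
  attr(out, "options") <- options[c("grid_size", "newton_tol", "seed")]
  attr(out, "mode") <- mode
  attr(out, "channel") <- channel
  class(out) <- c("oem_sweep", class(out))
  out
}

contour_axis_set <- function(params, axis, value) {
  if (axis == "swell1_ratio") {
    set_polarization_ratio(params, value, channel = "Cl")
  } else if (axis == "nhe1_ratio") {
    set_polarization_ratio(params, value, channel = "NHE")
  } else {
    param_set(params, axis, value)
  }
}

#' Two-parameter sensitivity contour
#'
#' Cell velocity over the product grid of two parameter axes. Axes are
#' either the special names `"swell1_ratio"` / `"nhe1_ratio"` (polarization
#' ratios applied at fixed total conductance) or dotted parameter paths set
#' to absolute values (e.g. `"front.actin_polymerization_rate"`,
#' `"adhesion_strength"`). Points are warm-started serpentine along the grid;
#' non-converged points carry `NA`.
#'
#' @param base Base parameter set.
#' @param axis_x,axis_y Axis names (see Details).
#' @param grid_x,grid_y Monotone value grids.
#' @param options [solver_options()].
#' @return An `oem_contour` tibble: `x`, `y`, `v0`, `converged`.
#' @export
sensitivity_contour <- function(base = default_parameters(),
                                axis_x = "swell1_ratio", axis_y = "nhe1_ratio",
                                grid_x = 10^seq(-1, 1, length.out = 7),
                                grid_y = 10^seq(-1, 1, length.out = 7),
                                options = solver_options()) {
  base <- validate_parameters(base)
  if (is.unsorted(grid_x) || is.unsorted(grid_y)) {
    abort("contour grids must be sorted increasing.", class = "osmigrate_invalid_input")
  }
  rows <- list()
  state_row_start <- NULL
  for (j in seq_along(grid_y)) {
    py <- contour_axis_set(base, axis_y, grid_y[j])
    xs <- if (j %% 2 == 1) seq_along(grid_x) else rev(seq_along(grid_x))
    state <- state_row_start
    first_in_row <- TRUE
    for (i in xs) {
      pk <- contour_axis_set(py, axis_x, grid_x[i])
      o <- options
      o$init <- state
      st <- tryCatch(solve_steady(pk, o), error = function(e) NULL)
      rows[[length(rows) + 1]] <- tibble::tibble(
        x = grid_x[i], y = grid_y[j],
        v0 = if (is.null(st)) NA_real_ else st$v0,
        converged = !is.null(st)
      )
      if (!is.null(st)) {
        state <- st
        if (first_in_row) state_row_start <- st
      }
      first_in_row <- FALSE
    }
  }
  out <- dplyr::arrange(dplyr::bind_rows(rows), .data$y, .data$x)
  attr(out, "axes") <- c(x = axis_x, y = axis_y)
  attr(out, "options") <- options[c("grid_size", "newton_tol", "seed")]
  class(out) <- c("oem_contour", class(out))
  out
}

free_param_set <- function(params, name, value) contour_axis_set(params, name, value)

#' Least-squares parameter fitting to velocity observations
#'
#' Fits selected model parameters to observed single-cell velocities by
#' minimizing the sum of squared residuals between each condition's observed
#' velocities and the model's steady-state velocity under that condition.
#' One free parameter is fitted by Brent search on its interval; several by
#' bounded quasi-Newton with seeded multi-starts. Model solves are
#' memoized and warm-started, and confidence intervals come from the local
#' curvature (Gauss-Newton approximation) of the residual surface.
#'
#' @param observations A tibble with columns `condition` and `v_obs` (um/s),
#'   e.g. from [gen_velocity_observations()]. Per-condition parameter
#'   overrides are taken from `attr(observations, "conditions")` (a named
#'   list of override lists) unless supplied via `conditions`.
#' @param base Base parameter set.
#' @param free Named list of free parameters: each entry is `c(lower, upper)`
#'   bounds. Names are dotted parameter paths or the special axes
#'   `"swell1_ratio"` / `"nhe1_ratio"`.
#' @param options [solver_options()].
#' @param conditions Optional override of the per-condition parameter
#'   overrides.
#' @param n_starts Multi-start count for multi-parameter fits.
#' @param seed Seed for the multi-start draws.
#' @return An `oem_fit`: `par` (named estimates), `rss`, `sigma`,
#'   `std_error`, `conf_low`/`conf_high` (95%), `predictions` tibble,
#'   `n_obs`, `converged`.
#' @export
fit_parameters <- function(observations, base = default_parameters(),
                           free = list(swell1_ratio = c(0.5, 20)),
                           options = solver_options(),
                           conditions = NULL, n_starts = 3, seed = 1L) {
  base <- validate_parameters(base)
  stopifnot(all(c("condition", "v_obs") %in% names(observations)))
  conditions <- conditions %||% attr(observations, "conditions") %||%
    setNames(
      rep(list(list()), length(unique(observations$condition))),
      unique(observations$condition)
    )
  lower <- vapply(free, `[`, numeric(1), 1)
  upper <- vapply(free, `[`, numeric(1), 2)
  if (any(lower >= upper)) {
    abort("free-parameter bounds must satisfy lower < upper.",
      class = "osmigrate_invalid_input"
    )
  }

  cache <- new.env(parent = emptyenv())
  warm <- new.env(parent = emptyenv())
  predict_v0 <- function(theta, cond) {
    key <- paste(cond, paste(signif(theta, 12), collapse = "|"))
    if (!is.null(cache[[key]])) {
      return(cache[[key]])
    }
    pk <- apply_overrides(base, conditions[[cond]])
    for (k in seq_along(theta)) pk <- free_param_set(pk, names(free)[k], theta[k])
    o <- options
    o$init <- warm[[cond]] %||% options$init
    st <- tryCatch(solve_steady(pk, o), error = function(e) NULL)
    v <- if (is.null(st)) NA_real_ else st$v0
    if (!is.null(st)) warm[[cond]] <- st
    cache[[key]] <- v
    v
  }
  conds <- unique(observations$condition)
  rss_fn <- function(theta) {
    tot <- 0
    for (cond in conds) {
      v <- predict_v0(theta, cond)
      if (is.na(v)) {
        return(1e6)
      }
      tot <- tot + sum((observations$v_obs[observations$condition == cond] - v)^2)
    }
    tot
  }

  if (length(free) == 1) {
    opt <- optimize(function(t) rss_fn(t), lower = lower, upper = upper,
      tol = 1e-6 * (upper - lower))
    est <- setNames(opt$minimum, names(free))
    rss <- opt$objective
    conv <- TRUE
  } else {
    starts <- list((lower + upper) / 2)
    draws <- local_rnorm(n_starts * length(free), seed)
    for (k in seq_len(n_starts)) {
      u <- stats::pnorm(draws[((k - 1) * length(free) + 1):(k * length(free))])
      starts[[k + 1]] <- lower + u * (upper - lower)
    }
    best <- NULL
    conv <- FALSE
    for (s in starts) {
      o <- tryCatch(
        optim(s, rss_fn, method = "L-BFGS-B", lower = lower, upper = upper,
          control = list(factr = 1e10)),
        error = function(e) NULL
      )
      if (!is.null(o) && (is.null(best) || o$value < best$value)) {
        best <- o
        conv <- conv || o$convergence == 0
      }
    }
    if (is.null(best)) {
      abort("All optimizer starts failed.", class = "osmigrate_fit_failure")
    }
    est <- setNames(best$par, names(free))
    rss <- best$value
  }

  # Gauss-Newton curvature: jacobian of per-observation predictions
  n_obs <- nrow(observations)
  p <- length(free)
  preds <- vapply(observations$condition, function(cond) predict_v0(est, cond), numeric(1))
  Jac <- matrix(0, n_obs, p)
  for (k in seq_len(p)) {
    hstep <- 1e-4 * (upper[k] - lower[k])
    ep <- est
    ep[k] <- min(ep[k] + hstep, upper[k])
    em <- est
    em[k] <- max(em[k] - hstep, lower[k])
    vp <- vapply(observations$condition, function(cond) predict_v0(ep, cond), numeric(1))
    vm <- vapply(observations$condition, function(cond) predict_v0(em, cond), numeric(1))
    Jac[, k] <- (vp - vm) / (ep[k] - em[k])
  }
  dof <- max(n_obs - p, 1)
  sigma2 <- rss / dof
  covm <- tryCatch(sigma2 * solve(crossprod(Jac)), error = function(e) {
    matrix(NA_real_, p, p)
  })
  se <- sqrt(pmax(diag(covm), 0))
  tq <- qt(0.975, dof)
  structure(
    list(
      par = est, rss = rss, sigma = sqrt(sigma2), std_error = setNames(se, names(free)),
      conf_low = est - tq * se, conf_high = est + tq * se,
      predictions = tibble::tibble(
        condition = observations$condition,
        v_obs = observations$v_obs, v_pred = unname(preds),
        residual = observations$v_obs - unname(preds)
      ),
      n_obs = n_obs, converged = conv,
      free = free, seed = seed
    ),
    class = "oem_fit"
  )
}

#' @export
print.oem_fit <- function(x, ...) {
  cat("<oem_fit> least-squares fit to velocity observations\n")
  for (k in seq_along(x$par)) {
    cat(sprintf(
      "  %s = %.5g (SE %.3g, 95%% CI [%.5g, %.5g])\n",
      names(x$par)[k], x$par[k], x$std_error[k], x$conf_low[k], x$conf_high[k]
    ))
  }
  cat(sprintf("  RSS = %.4g over %d observations\n", x$rss, x$n_obs))
  invisible(x)
}
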