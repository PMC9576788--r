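#' Acid-base relations shared by the whole model
#'
#' Proton concentration, bicarbonate concentration and buffer protonation are
#' never independent unknowns: they are algebraic functions of pH (and, for
#' bicarbonate, of the dissolved CO2 level set by `pco2 / henry_constant`).
#' These helpers are the single place those relations live; every residual
#' and flux evaluation calls them so derived fields can never drift out of
#' sync with pH.
#'
#' Concentrations are in mM throughout (1 mM = 1 mol/m^3, so `RT * c` with
#' `RT` in J/mol is a pressure in Pa).
#'
#' @param pH Dimensionless pH value(s); must be finite.
#' @return Proton concentration in mM, `10^3 * 10^(-pH)`.
#' @examples
#' proton_from_ph(7.4)
#' @export
proton_from_ph <- function(pH) {
  if (!is.numeric(pH) || any(!is.finite(pH))) {
    abort("`pH` must be finite numeric.", class = "osmigrate_invalid_input")
  }
  1e3 * 10^(-pH)
}

#' @rdname proton_from_ph
#' @param pco2 Partial pressure of CO2 (same units as `henry_constant * c`,
#'   i.e. `pco2 / henry_constant` is the dissolved CO2 concentration in mM).
#' @param henry_constant Henry constant linking pCO2 to dissolved CO2; > 0.
#' @param pK_c Effective pK of the CO2/bicarbonate equilibrium.
#' @return Bicarbonate concentration in mM,
#'   `(pco2 / henry_constant) * 10^(pH - pK_c)`. The same relation holds on
#'   both sides of the membrane because CO2 equilibrates freely.
#' @export
bicarbonate_from_ph <- function(pH, pco2, henry_constant, pK_c) {
  if (!is.numeric(henry_constant) || any(henry_constant <= 0)) {
    abort("`henry_constant` must be > 0.", class = "osmigrate_invalid_parameter")
  }
  (pco2 / henry_constant) * 10^(pH - pK_c)
}

#' @rdname proton_from_ph
#' @param c_Buf Deprotonated buffer concentration in mM; >= 0.
#' @param pK_B pK of the intracellular buffer.
#' @return Protonated buffer concentration `c_Buf * 10^(pK_B - pH)` in mM.
#' @export
buffer_partition <- function(pH, c_Buf, pK_B) {
  if (!is.numeric(c_Buf) || any(c_Buf < 0)) {
    abort("`c_Buf` must be >= 0.", class = "osmigrate_invalid_input")
  }
  c_Buf * 10^(pK_B - pH)
}

species_names <- c("Na", "K", "Cl", "H", "HCO3", "A", "Buf", "HBuf")
passive_species <- c("Na", "K", "Cl")

end_param_names <- c(
  "water_permeability", "hydraulic_resistance", "external_pressure",
  "passive_permeability", "nke_permeability", "nhe_permeability",
  "ae2_permeability", "actin_polymerization_rate"
)

scalar_param_names <- c(
  "cell_length", "cross_section", "interfacial_friction", "adhesion_strength",
  "wall_friction", "depolymerization_rate", "gactin_diffusivity",
  "actin_stiffness", "mean_actin", "polymerization_saturation",
  "membrane_thickness_factor", "gas_constant", "temperature", "faraday",
  "henry_constant", "pco2", "pK_c", "pK_B", "extracellular_pH",
  "extracellular_potential", "symmetric_resistance_in_force_balance"
)

gating_names <- paste0("beta", 1:8)
nke_scaling_names <- c("Na", "K")
impermeant_names <- c("N_A", "N_Buf_total")

#' Read a model parameter file
#'
#' Parameters live in a single YAML document whose keys mirror the model's
#' constants one-for-one (membrane-end values under `front:` / `back:`, the
#' ion species registry under `species:`). Unknown keys are rejected so typos
#' cannot silently become defaults. The packaged file
#' `system.file("extdata", "default_parameters.yaml", package = "osmigrate")`
#' holds the default constants: standard physiological boundary conditions
#' (extracellular Na 140 / K 5 / Cl 110 mM, pH 7.4, T 310 K) together with
#' transport and mechanical coefficients calibrated once so the baseline cell
#' (rear-enriched Cl conductance, front-enriched Na/H exchange) migrates
#' forward at tens of nm/s.
#'
#' @param path Path to a YAML parameter file.
#' @return A validated `oem_parameters` object.
#' @seealso [default_parameters()], [validate_parameters()]
#' @export
read_parameters <- function(path) {
  raw <- yaml::read_yaml(path)
  params_from_list(raw)
}

#' @rdname read_parameters
#' @export
default_parameters <- function() {
  read_parameters(system.file("extdata", "default_parameters.yaml",
    package = "osmigrate", mustWork = TRUE
  ))
}

#' @rdname read_parameters
#' @param params An `oem_parameters` object.
#' @export
write_parameters <- function(params, path) {
  stopifnot(inherits(params, "oem_parameters"))
  keep <- params[setdiff(names(params), "derived")]
  yaml::write_yaml(keep, path)
  invisible(path)
}

check_known_keys <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra) > 0) {
    abort(
      sprintf("Unknown parameter key(s) in %s: %s", where, paste(extra, collapse = ", ")),
      class = "osmigrate_validation_error"
    )
  }
  missing <- setdiff(allowed, names(x))
  if (length(missing) > 0) {
    abort(
      sprintf("Missing parameter key(s) in %s: %s", where, paste(missing, collapse = ", ")),
      class = "osmigrate_validation_error"
    )
  }
  invisible(x)
}

params_from_list <- function(raw) {
  top <- c(
    scalar_param_names, "gating_constants", "nke_scalings",
    "impermeant_totals", "front", "back", "species"
  )
  check_known_keys(raw, top, "parameter file")
  check_known_keys(raw$gating_constants, gating_names, "gating_constants")
  check_known_keys(raw$nke_scalings, nke_scaling_names, "nke_scalings")
  check_known_keys(raw$impermeant_totals, impermeant_names, "impermeant_totals")
  for (end in c("front", "back")) {
    check_known_keys(raw[[end]], end_param_names, end)
    check_known_keys(raw[[end]]$passive_permeability, passive_species,
      paste0(end, ".passive_permeability"))
  }
  check_known_keys(raw$species, species_names, "species")
  for (sp in species_names) {
    allowed <- c("valence", "diffusivity")
    if (sp %in% c("Na", "K", "Cl", "A")) allowed <- c(allowed, "extracellular_concentration")
    check_known_keys(raw$species[[sp]], allowed, paste0("species.", sp))
  }
  params <- structure(raw, class = "oem_parameters")
  validate_parameters(params)
}

#' Validate a parameter set and attach derived constants
#'
#' Checks every structural invariant of the parameter set (positivity of
#' geometric and thermodynamic constants, non-negative permeabilities, zero
#' actin polymerization at the cell rear, the fixed eight-species registry)
#' and attaches commonly reused derived quantities under `$derived`:
#' `RT` (J/mol), `F_over_RT` (1/V), vectors of valences and diffusivities,
#' extracellular concentrations completed with protons and bicarbonate from
#' the extracellular pH, and the extracellular osmolarity total.
#'
#' @param params An `oem_parameters` object (or plain list with the same shape).
#' @return The validated `oem_parameters` with `$derived` populated.
#' @export
validate_parameters <- function(params) {
  fail <- function(field, msg) {
    abort(sprintf("Invalid parameter `%s`: %s", field, msg),
      class = "osmigrate_validation_error"
    )
  }
  pos <- c(
    "cell_length", "cross_section", "temperature", "gas_constant", "faraday",
    "henry_constant", "mean_actin", "polymerization_saturation",
    "membrane_thickness_factor"
  )
  for (f in pos) {
    if (!is.numeric(params[[f]]) || length(params[[f]]) != 1 || !is.finite(params[[f]]) ||
      params[[f]] <= 0) {
      fail(f, "must be a single positive finite number")
    }
  }
  nonneg <- c(
    "interfacial_friction", "adhesion_strength", "wall_friction",
    "depolymerization_rate", "gactin_diffusivity", "actin_stiffness", "pco2"
  )
  for (f in nonneg) {
    if (!is.numeric(params[[f]]) || params[[f]] < 0) fail(f, "must be >= 0")
  }
  for (f in c("pK_c", "pK_B", "extracellular_pH", "extracellular_potential")) {
    if (!is.finite(params[[f]])) fail(f, "must be finite")
  }
  for (f in impermeant_names) {
    if (params$impermeant_totals[[f]] < 0) fail(paste0("impermeant_totals.", f), "must be >= 0")
  }
  for (end in c("front", "back")) {
    ep <- params[[end]]
    for (f in c(
      "water_permeability", "hydraulic_resistance", "nke_permeability",
      "nhe_permeability", "ae2_permeability", "actin_polymerization_rate"
    )) {
      if (!is.numeric(ep[[f]]) || ep[[f]] < 0) fail(paste0(end, ".", f), "must be >= 0")
    }
    for (sp in passive_species) {
      if (ep$passive_permeability[[sp]] < 0) {
        fail(paste0(end, ".passive_permeability.", sp), "must be >= 0")
      }
    }
  }
  if (params$back$actin_polymerization_rate != 0) {
    fail(
      "back.actin_polymerization_rate",
      "actin polymerization is restricted to the cell front; the actin flux at the back is zero"
    )
  }
  if (!identical(names(params$species), species_names)) {
    fail("species", paste(
      "registry must contain exactly",
      paste(species_names, collapse = ", "), "in that order"
    ))
  }
  for (sp in species_names) {
    if (params$species[[sp]]$diffusivity <= 0) fail(paste0("species.", sp, ".diffusivity"), "must be > 0")
  }
  if (params$species$HBuf$valence != 0) fail("species.HBuf.valence", "protonated buffer is neutral")

  RT <- params$gas_constant * params$temperature
  z <- vapply(params$species, function(s) as.numeric(s$valence), numeric(1))
  D <- vapply(params$species, function(s) as.numeric(s$diffusivity), numeric(1))
  c0 <- c(
    Na = params$species$Na$extracellular_concentration,
    K = params$species$K$extracellular_concentration,
    Cl = params$species$Cl$extracellular_concentration,
    H = proton_from_ph(params$extracellular_pH),
    HCO3 = bicarbonate_from_ph(
      params$extracellular_pH, params$pco2,
      params$henry_constant, params$pK_c
    ),
    A = params$species$A$extracellular_concentration,
    Buf = 0, HBuf = 0
  )
  if (any(c0[c("Na", "K", "Cl", "A")] < 0)) fail("species", "extracellular concentrations must be >= 0")
  params$derived <- list(
    RT = RT,
    F_over_RT = params$faraday / RT,
    z = z,
    D = D,
    c0 = c0,
    c0_total = sum(c0),
    c_H0 = c0[["H"]],
    c_HCO3_0 = c0[["HCO3"]]
  )
  class(params) <- "oem_parameters"
  params
}

#' @export
print.oem_parameters <- function(x, ...) {
  cat("<oem_parameters>\n")
  cat(sprintf(
    "  cell: L = %g um, S = %g um^2, T = %g K, pH0 = %g\n",
    x$cell_length, x$cross_section, x$temperature, x$extracellular_pH
  ))
  rat <- function(f) x$back$passive_permeability[[f]] / x$front$passive_permeability[[f]]
  cat(sprintf(
    "  polarization: alpha_Cl back/front = %.3g, alpha_NHE front/back = %.3g\n",
    rat("Cl"), x$front$nhe_permeability / x$back$nhe_permeability
  ))
  cat(sprintf("  actin: J_actin^f = %g mM um/s\n", x$front$actin_polymerization_rate))
  invisible(x)
}

#' Get or set a parameter by dotted path
#'
#' Scenario definitions and sweeps address individual constants by dotted
#' paths such as `"front.passive_permeability.Cl"` or `"wall_friction"`.
#'
#' @param params An `oem_parameters` object.
#' @param path Dotted path string.
#' @return `param_get()` returns the value; `param_set()` the modified,
#'   revalidated parameter set.
#' @export
param_get <- function(params, path) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  out <- params
  for (k in keys) {
    if (!k %in% names(out)) {
      abort(sprintf("Unknown parameter path `%s`", path), class = "osmigrate_validation_error")
    }
    out <- out[[k]]
  }
  out
}

#' @rdname param_get
#' @param value New value (numeric scalar).
#' @export
param_set <- function(params, path, value) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  param_get(params, path) # errors on unknown path
  params[[keys]] <- if (is.numeric(value)) unname(value) else value
  validate_parameters(params)
}

#' @rdname param_get
#' @param overrides Named list mapping dotted paths to either a numeric value
#'   (assignment) or a `list(mul = m)` (multiplicative scaling of the current
#'   value).
#' @export
apply_overrides <- function(params, overrides) {
  for (path in names(overrides)) {
    ov <- overrides[[path]]
    if (is.list(ov) && identical(names(ov), "mul")) {
      params <- param_set(params, path, param_get(params, path) * ov$mul)
    } else {
      params <- param_set(params, path, ov)
    }
  }
  params
}
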