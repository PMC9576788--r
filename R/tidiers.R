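#' Tidiers and plots for solver and fit objects
#'
#' `tidy()` returns node-level (or term-level) tibbles, `glance()` one-row
#' summaries, and `autoplot()` quick diagnostic figures, following the
#' conventions of broom and ggplot2.
#'
#' @param x An `oem_state`, `oem_sweep`, `oem_contour` or `oem_fit`.
#' @param ... Unused.
#' @name oem-tidiers
NULL

#' @rdname oem-tidiers
#' @export
tidy.oem_state <- function(x, ...) {
  x$profiles
}

#' @rdname oem-tidiers
#' @export
glance.oem_state <- function(x, ...) {
  d <- x$diagnostics
  tibble::tibble(
    v0 = x$v0,
    v0_um_min = 60 * x$v0,
    J_water_front = x$fluxes$front$water,
    J_water_back = x$fluxes$back$water,
    V_m_front_mV = 1e3 * x$fluxes$front$V_m,
    V_m_back_mV = 1e3 * x$fluxes$back$V_m,
    tau_m_front = x$fluxes$front$tau_m,
    tau_m_back = x$fluxes$back$tau_m,
    iterations = x$iterations,
    residual_norm = x$residual_norm,
    flux_constancy_rel = d$flux_constancy_rel,
    electroneutrality_rel = d$electroneutrality_rel,
    converged = x$converged
  )
}

#' @rdname oem-tidiers
#' @param object An `oem_state`.
#' @export
autoplot.oem_state <- function(object, ...) {
  prof <- object$profiles
  long <- tidyr::pivot_longer(
    prof[, c("x", "p", "theta_n", "theta_c", "c_Na", "c_K", "c_Cl", "pH", "phi")],
    -"x",
    names_to = "field", values_to = "value"
  )
  long$field <- factor(long$field,
    levels = c("p", "theta_n", "theta_c", "c_Na", "c_K", "c_Cl", "pH", "phi")
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$x, y = .data$value)) +
    ggplot2::geom_line(color = "#2c7fb8") +
    ggplot2::facet_wrap(~field, scales = "free_y") +
    ggplot2::labs(
      x = "position along cell (um, back to front)", y = NULL,
      title = sprintf("Steady state, v0 = %.3g um/s", object$v0)
    ) +
    ggplot2::theme_minimal()
}

#' @rdname oem-tidiers
#' @export
tidy.oem_sweep <- function(x, ...) {
  tibble::as_tibble(unclass(x)[names(x)])
}

#' @rdname oem-tidiers
#' @export
glance.oem_sweep <- function(x, ...) {
  v <- x$v0[x$converged]
  r <- x$ratio[x$converged]
  cross <- which(diff(sign(v)) != 0)
  tibble::tibble(
    n_points = nrow(x),
    n_converged = sum(x$converged),
    v0_min = min(v), v0_max = max(v),
    sign_changes = length(cross),
    ratio_at_sign_change = if (length(cross) == 1) {
      # linear interpolation in log-ratio
      exp(log(r[cross]) + (0 - v[cross]) / (v[cross + 1] - v[cross]) *
        (log(r[cross + 1]) - log(r[cross])))
    } else {
      NA_real_
    }
  )
}

#' @rdname oem-tidiers
#' @export
autoplot.oem_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$ratio, y = .data$v0 * 60)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, color = "grey50") +
    ggplot2::geom_line(color = "#d7301f", na.rm = TRUE) +
    ggplot2::geom_point(color = "#d7301f", na.rm = TRUE) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "Cl permeability ratio, back / front",
      y = "cell velocity (um/min)"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname oem-tidiers
#' @export
autoplot.oem_contour <- function(object, ...) {
  axes <- attr(object, "axes")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$v0 * 60)) +
    ggplot2::geom_raster() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white", high = "#b2182b") +
    ggplot2::labs(x = axes[["x"]], y = axes[["y"]], fill = "v0 (um/min)") +
    ggplot2::theme_minimal()
}

#' @rdname oem-tidiers
#' @export
tidy.oem_fit <- function(x, ...) {
  tibble::tibble(
    term = names(x$par),
    estimate = unname(x$par),
    std.error = unname(x$std_error),
    conf.low = unname(x$conf_low),
    conf.high = unname(x$conf_high)
  )
}

#' @rdname oem-tidiers
#' @export
glance.oem_fit <- function(x, ...) {
  tibble::tibble(
    rss = x$rss, sigma = x$sigma, n_obs = x$n_obs,
    n_par = length(x$par), converged = x$converged
  )
}

#' @rdname oem-tidiers
#' @export
autoplot.oem_fit <- function(object, ...) {
  ggplot2::ggplot(
    object$predictions,
    ggplot2::aes(x = .data$condition, y = .data$v_obs * 60)
  ) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.5, color = "grey40") +
    ggplot2::geom_point(
      ggplot2::aes(y = .data$v_pred * 60),
      color = "#d7301f", size = 3, shape = 18
    ) +
    ggplot2::labs(x = NULL, y = "velocity (um/min)") +
    ggplot2::theme_minimal()
}
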