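#' Seeded evaluation leaving the global RNG untouched
#'
#' All generators route their randomness through this helper so that every
#' output is reproducible from its recorded seed and no generator perturbs
#' the caller's RNG stream.
#' @noRd
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  )
  set.seed(seed)
  force(code)
}

#' Generate noisy per-cell velocity observations
#'
#' Statistical twin of an optogenetic polarization experiment: for each
#' condition (a named list of parameter overrides, e.g. a prescribed
#' SWELL1 polarization ratio), the model's steady-state velocity is solved
#' and `n_per` single-cell observations are drawn as `v0 + N(0, noise_sd)`.
#' The default noise is 30% of the baseline speed, resembling the cell-to-
#' cell spread of confined-migration measurements.
#'
#' @param base Base parameter set.
#' @param conditions Named list of override lists (see [apply_overrides()]);
#'   a numeric vector is interpreted as SWELL1 back/front ratios.
#' @param n_per Observations per condition (the experiments this emulates
#'   typically report ~11 cells).
#' @param noise_sd Observation noise SD in um/s; default 0.3 x |baseline v0|.
#' @param seed Integer seed; the output records it.
#' @param options [solver_options()].
#' @return Tibble (`condition`, `cell`, `v_obs`, `v_true`) with attributes
#'   `conditions`, `noise_sd`, `seed`.
#' @export
gen_velocity_observations <- function(base = default_parameters(),
                                      conditions = list(baseline = list()),
                                      n_per = 11, noise_sd = NULL, seed = 1L,
                                      options = solver_options()) {
  base <- validate_parameters(base)
  stopifnot(n_per >= 1)
  if (is.numeric(conditions)) {
    ratios <- conditions
    conditions <- lapply(ratios, function(r) list(swell1_ratio = r))
    names(conditions) <- paste0("ratio_", signif(ratios, 4))
  }
  base_state <- solve_steady(base, options)
  if (is.null(noise_sd)) noise_sd <- 0.3 * abs(base_state$v0)
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.", class = "osmigrate_invalid_input")
  rows <- list()
  for (cond in names(conditions)) {
    ov <- conditions[[cond]]
    pk <- base
    for (nm in names(ov)) {
      pk <- if (nm %in% c("swell1_ratio", "nhe1_ratio")) {
        contour_axis_set(pk, nm, ov[[nm]])
      } else {
        apply_overrides(pk, ov[nm])
      }
    }
    o <- options
    o$init <- base_state
    st <- tryCatch(solve_steady(pk, o), error = function(e) {
      abort(sprintf("Solver failed for condition `%s`: %s", cond, conditionMessage(e)),
        class = "osmigrate_generation_error"
      )
    })
    rows[[cond]] <- tibble::tibble(
      condition = cond, cell = seq_len(n_per), v_true = st$v0
    )
  }
  out <- dplyr::bind_rows(rows)
  out$v_obs <- with_seed(seed, out$v_true + rnorm(nrow(out), 0, noise_sd))
  out <- out[, c("condition", "cell", "v_obs", "v_true")]
  # conditions are stored in override form so fits can reapply them
  cond_overrides <- lapply(conditions, function(ov) {
    ov[setdiff(names(ov), c("swell1_ratio", "nhe1_ratio"))]
  })
  cond_axes <- lapply(conditions, function(ov) {
    ov[intersect(names(ov), c("swell1_ratio", "nhe1_ratio"))]
  })
  attr(out, "conditions") <- cond_overrides
  attr(out, "condition_axes") <- cond_axes
  attr(out, "noise_sd") <- noise_sd
  attr(out, "seed") <- seed
  class(out) <- c("oem_observations", class(out))
  out
}

#' Generate a synthetic polarized-cell intensity image
#'
#' A grayscale phantom of a confined cell stained for a polarized membrane
#' protein: a rectangular cell with bright membrane bands of prescribed mean
#' intensity at the two poles, a dimmer (vesicle-poor) interior, a
#' zero-intensity background margin, and additive Gaussian noise truncated
#' at zero. The phantom's ground truth (pole means and their ratio) is
#' recorded for round-trip tests of the polarization quantifier. These are
#' intensity phantoms, not renderings of the transport model.
#'
#' @param shape_px `c(length, width)` of the cell rectangle in pixels; the
#'   image adds a 2 px background margin on each side. Length runs along the
#'   migration axis (front = high column index).
#' @param pole_depth_px Depth of each pole band in pixels;
#'   `2 * pole_depth_px` must be smaller than the cell length.
#' @param front_mean,rear_mean,interior_mean Mean intensities (arbitrary
#'   units in `[0, 1]` scale) of the two pole bands and the interior.
#' @param noise_sd Additive Gaussian noise SD (truncated at zero).
#' @param seed Integer seed.
#' @return An `oem_image`: `pixels` (matrix, rows = width, columns = length
#'   axis), `cell_rows`/`cell_cols` (the cell rectangle), `pole_depth_px`,
#'   `ground_truth` (front/rear means and ratio), `noise_sd`, `seed`.
#' @export
gen_polarized_cell_image <- function(shape_px = c(60, 24), pole_depth_px = 6,
                                     front_mean = 0.8, rear_mean = 0.4,
                                     interior_mean = 0.05, noise_sd = 0,
                                     seed = 1L) {
  if (any(c(front_mean, rear_mean, interior_mean) < 0)) {
    abort("intensity means must be >= 0.", class = "osmigrate_invalid_input")
  }
  len <- shape_px[1]
  wid <- shape_px[2]
  if (2 * pole_depth_px >= len) {
    abort("pole bands must not overlap: 2 * pole_depth_px < length.",
      class = "osmigrate_invalid_input"
    )
  }
  margin <- 2L
  nx <- len + 2 * margin
  ny <- wid + 2 * margin
  img <- matrix(0, nrow = ny, ncol = nx)
  cell_rows <- (margin + 1):(margin + wid)
  cell_cols <- (margin + 1):(margin + len)
  img[cell_rows, cell_cols] <- interior_mean
  rear_cols <- cell_cols[1:pole_depth_px]
  front_cols <- cell_cols[(len - pole_depth_px + 1):len]
  img[cell_rows, rear_cols] <- rear_mean
  img[cell_rows, front_cols] <- front_mean
  if (noise_sd > 0) {
    img <- with_seed(seed, pmax(img + matrix(rnorm(ny * nx, 0, noise_sd), ny, nx), 0))
  }
  structure(
    list(
      pixels = img,
      cell_rows = cell_rows, cell_cols = cell_cols,
      pole_depth_px = pole_depth_px,
      ground_truth = list(
        front_mean = front_mean, rear_mean = rear_mean,
        ratio = front_mean / rear_mean
      ),
      noise_sd = noise_sd, seed = seed
    ),
    class = "oem_image"
  )
}

#' Write / read a synthetic image as 16-bit grayscale TIFF
#'
#' The pixel array is scaled to the 16-bit range; the ground-truth record is
#' written alongside as a YAML sidecar (`<path>.truth.yaml`).
#'
#' @param image An `oem_image`.
#' @param path Output TIFF path.
#' @return `write_image_tiff()` the path, invisibly; `read_image_tiff()` a
#'   plain intensity matrix on the original `[0, 1]`-ish scale.
#' @export
write_image_tiff <- function(image, path) {
  rlang::check_installed("tiff")
  px <- image$pixels / max(image$pixels, 1)
  tiff::writeTIFF(px, path, bits.per.sample = 16)
  sidecar <- c(
    image$ground_truth,
    list(
      noise_sd = image$noise_sd, seed = image$seed,
      scale = max(image$pixels, 1), pole_depth_px = image$pole_depth_px
    )
  )
  yaml::write_yaml(sidecar, paste0(path, ".truth.yaml"))
  invisible(path)
}

#' @rdname write_image_tiff
#' @export
read_image_tiff <- function(path) {
  rlang::check_installed("tiff")
  px <- tiff::readTIFF(path)
  truth_path <- paste0(path, ".truth.yaml")
  if (file.exists(truth_path)) {
    truth <- yaml::read_yaml(truth_path)
    px <- px * (truth$scale %||% 1)
  }
  px
}

#' Generate a drift-diffusion trajectory
#'
#' Positions sampled at uniform intervals from
#' `x_{k+1} = x_k + v dt + N(0, sqrt(2 D dt))` along the first axis (drift +
#' diffusion) and pure diffusion on any further axes — the fixture for the
#' velocity and mean-squared-displacement quantifiers.
#'
#' @param v Drift velocity along the first axis, um/s.
#' @param D Diffusion coefficient, um^2/s.
#' @param dt Sampling interval, s; > 0.
#' @param n_steps Number of steps (>= 2); the track has `n_steps + 1` points.
#' @param dims 1 or 2 spatial dimensions.
#' @param seed Integer seed.
#' @return Tibble `t`, `x` (and `y` for 2D) with attributes `v`, `D`, `dt`,
#'   `seed`.
#' @export
gen_trajectory <- function(v = 0.01, D = 0.001, dt = 60, n_steps = 100,
                           dims = 2, seed = 1L) {
  if (dt <= 0 || n_steps < 2) {
    abort("`dt` must be > 0 and `n_steps` >= 2.", class = "osmigrate_invalid_input")
  }
  stopifnot(dims %in% 1:2, D >= 0)
  sd_step <- sqrt(2 * D * dt)
  steps <- with_seed(seed, matrix(rnorm(n_steps * dims, 0, sd_step), n_steps, dims))
  steps[, 1] <- steps[, 1] + v * dt
  pos <- apply(steps, 2, cumsum)
  out <- tibble::tibble(
    t = (0:n_steps) * dt,
    x = c(0, pos[, 1])
  )
  if (dims == 2) out$y <- c(0, pos[, 2])
  attr(out, "v") <- v
  attr(out, "D") <- D
  attr(out, "dt") <- dt
  attr(out, "seed") <- seed
  class(out) <- c("oem_trajectory", class(out))
  out
}
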