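#' Front-to-rear polarization ratio of a membrane stain
#'
#' The polarity readout used for polarized channels and exchangers in
#' confined cells: within a rectangular window at each pole, pixel
#' intensities are summed and divided by the number of pixels above the
#' zero threshold (the interior and background, dominated by unlabeled
#' cytoplasm or internal vesicles, are excluded by construction of the
#' windows and by the nonzero rule). The ratio is front mean over rear mean.
#'
#' For an `oem_image` the pole windows default to the phantom's own pole
#' geometry; for a plain matrix the window geometry is an explicit input
#' (window placement was a manual step in the original workflow, so it is
#' never inferred from the data).
#'
#' @param image An `oem_image` or a numeric intensity matrix (rows = width,
#'   columns = migration axis, front at high column index).
#' @param pole_window_px Window depth in pixels along the migration axis.
#' @param rows Rows spanned by the windows (defaults to the cell rows of an
#'   `oem_image`, all rows otherwise).
#' @param cols Column span of the cell (defaults likewise).
#' @param zero_threshold Pixels with intensity <= this are excluded (0 keeps
#'   the strict nonzero rule; raise it for noisy backgrounds).
#' @return One-row tibble: `front_mean`, `rear_mean`, `ratio`, `n_front`,
#'   `n_rear`, `pole_window_px`.
#' @export
front_rear_ratio <- function(image, pole_window_px = NULL, rows = NULL,
                             cols = NULL, zero_threshold = 0) {
  if (inherits(image, "oem_image")) {
    pole_window_px <- pole_window_px %||% image$pole_depth_px
    rows <- rows %||% image$cell_rows
    cols <- cols %||% image$cell_cols
    image <- image$pixels
  }
  stopifnot(is.matrix(image), is.numeric(image))
  if (zero_threshold < 0) {
    abort("`zero_threshold` must be >= 0.", class = "osmigrate_invalid_input")
  }
  rows <- rows %||% seq_len(nrow(image))
  cols <- cols %||% seq_len(ncol(image))
  if (is.null(pole_window_px)) {
    abort("`pole_window_px` is required for plain matrices.",
      class = "osmigrate_invalid_input"
    )
  }
  if (2 * pole_window_px > length(cols)) {
    abort("pole windows overlap: 2 * pole_window_px exceeds the cell length.",
      class = "osmigrate_invalid_input"
    )
  }
  rear_win <- image[rows, cols[seq_len(pole_window_px)], drop = FALSE]
  front_win <- image[rows, cols[(length(cols) - pole_window_px + 1):length(cols)],
    drop = FALSE
  ]
  pole_mean <- function(w, which) {
    keep <- w[w > zero_threshold]
    if (length(keep) == 0) {
      abort(
        sprintf("Undefined ratio: %s pole window has no pixels above threshold.", which),
        class = "osmigrate_undefined_ratio"
      )
    }
    c(mean = sum(keep) / length(keep), n = length(keep))
  }
  fr <- pole_mean(front_win, "front")
  re <- pole_mean(rear_win, "rear")
  tibble::tibble(
    front_mean = fr[["mean"]], rear_mean = re[["mean"]],
    ratio = fr[["mean"]] / re[["mean"]],
    n_front = fr[["n"]], n_rear = re[["n"]],
    pole_window_px = pole_window_px
  )
}

trajectory_dt <- function(traj) {
  dts <- diff(traj$t)
  if (length(dts) < 1 || any(abs(dts - dts[1]) > 1e-9 * dts[1])) {
    abort("Trajectory must have uniform time steps.", class = "osmigrate_invalid_input")
  }
  dts[1]
}

#' Instantaneous migration velocity along the channel axis
#'
#' Signed finite-difference velocity along the first (migration) axis:
#' `v_k = (x_{k+window} - x_k) / (window * dt)`. Positive = toward the
#' front (increasing coordinate); direction reversal shows as negative
#' values.
#'
#' @param traj Trajectory tibble with uniform `t` and `x` (e.g. from
#'   [gen_trajectory()]).
#' @param window Frame lag used for differencing (>= 1).
#' @return Tibble `t` (window start time), `v` (um per time unit of `t`),
#'   with `n - window` rows.
#' @export
instantaneous_velocity <- function(traj, window = 1) {
  n <- nrow(traj)
  if (window < 1 || window >= n) {
    abort("`window` must be in [1, n_points - 1].", class = "osmigrate_invalid_input")
  }
  dt <- trajectory_dt(traj)
  idx <- seq_len(n - window)
  tibble::tibble(
    t = traj$t[idx],
    v = (traj$x[idx + window] - traj$x[idx]) / (window * dt)
  )
}

#' Time-averaged mean squared displacement
#'
#' `MSD(tau)` averaged over all start times for lags up to
#' `max_lag_fraction` of the track length, using all spatial axes present
#' (`x`, and `y` if available). Drift shows as `MSD ~ (v tau)^2`, diffusion
#' as `MSD ~ 2 d D tau`.
#'
#' @param traj Trajectory tibble with uniform `t`.
#' @param max_lag_fraction Largest lag as a fraction of track length, in
#'   (0, 1].
#' @return Tibble `lag` (time), `msd` (um^2), `n_pairs`.
#' @export
msd <- function(traj, max_lag_fraction = 0.25) {
  if (max_lag_fraction <= 0 || max_lag_fraction > 1) {
    abort("`max_lag_fraction` must be in (0, 1].", class = "osmigrate_invalid_input")
  }
  n <- nrow(traj)
  max_lag <- max(1, floor((n - 1) * max_lag_fraction))
  if (n < 2) abort("Track too short for MSD.", class = "osmigrate_invalid_input")
  dt <- trajectory_dt(traj)
  coords <- as.matrix(traj[, intersect(c("x", "y"), names(traj)), drop = FALSE])
  rows <- lapply(seq_len(max_lag), function(lag) {
    d <- coords[(lag + 1):n, , drop = FALSE] - coords[1:(n - lag), , drop = FALSE]
    tibble::tibble(lag = lag * dt, msd = mean(rowSums(d^2)), n_pairs = n - lag)
  })
  dplyr::bind_rows(rows)
}

shoelace_area <- function(xy) {
  x <- xy[, 1]
  y <- xy[, 2]
  xs <- c(x[-1], x[1])
  ys <- c(y[-1], y[1])
  sum(x * ys - xs * y) / 2
}

segments_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1)
  d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3)
  d4 <- d(p1, p2, p4)
  ((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
    ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))
}

check_simple_polygon <- function(xy) {
  n <- nrow(xy)
  if (n < 3) abort("Polygon needs >= 3 vertices.", class = "osmigrate_invalid_input")
  if (abs(shoelace_area(xy)) < 1e-300) {
    abort("Degenerate polygon (zero area).", class = "osmigrate_invalid_input")
  }
  # non-adjacent edge pairs must not cross
  if (n <= 720) {
    idx <- rbind(seq_len(n), c(2:n, 1))
    for (i in seq_len(n - 2)) {
      jmax <- if (i == 1) n - 1 else n
      for (j in (i + 2):jmax) {
        if (segments_intersect(
          xy[idx[1, i], ], xy[idx[2, i], ],
          xy[idx[1, j], ], xy[idx[2, j], ]
        )) {
          abort("Self-intersecting polygon.", class = "osmigrate_invalid_input")
        }
      }
    }
  }
  invisible(xy)
}

#' Spheroid shape metrics
#'
#' Shoelace area, vertex-chain perimeter, circularity `4 pi A / P^2` (1 for
#' a circle) and the normalized area expansion `A_t / A_0` between two
#' traced outlines of the same spheroid.
#'
#' @param polygon_t Outline at the later time: a 2-column matrix or data
#'   frame of vertices (simple, non-self-intersecting, >= 3 vertices).
#' @param polygon_0 Outline at the reference time (defaults to `polygon_t`,
#'   giving expansion 1).
#' @return One-row tibble: `area`, `perimeter`, `circularity`,
#'   `area_0`, `expansion`.
#' @export
shape_metrics <- function(polygon_t, polygon_0 = polygon_t) {
  as_xy <- function(p) {
    m <- as.matrix(p)
    stopifnot(ncol(m) == 2, is.numeric(m))
    m
  }
  pt <- check_simple_polygon(as_xy(polygon_t))
  p0 <- check_simple_polygon(as_xy(polygon_0))
  area <- abs(shoelace_area(pt))
  per <- sum(sqrt(rowSums((pt - rbind(pt[-1, , drop = FALSE], pt[1, , drop = FALSE]))^2)))
  area0 <- abs(shoelace_area(p0))
  tibble::tibble(
    area = area, perimeter = per,
    circularity = 4 * pi * area / per^2,
    area_0 = area0, expansion = area / area0
  )
}
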