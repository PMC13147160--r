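# Synthetic amoeboid-cell generator: radial-Fourier shapes riding a
# persistent random walk, rasterized into labeled mask movies with ground
# truth. All randomness is derived from the config root seed through
# child_seed(), so output is bit-identical for identical config + seed and
# adding a cell never perturbs earlier cells.

theta_grid <- function(n_theta) seq(0, 2 * pi, length.out = n_theta + 1L)[-(n_theta + 1L)]

#' Area enclosed by a radial contour
#'
#' Continuous-geometry area `(1/2) integral r(theta)^2 dtheta`, evaluated on
#' the uniform theta grid of the contour. Exact for a circle (constant r).
#'
#' @param contour a list with elements `theta` and `r_um` as produced by
#'   [simulate_shape_series()].
#' @return area in um^2.
#' @export
contour_area <- function(contour) {
  dtheta <- 2 * pi / length(contour$theta)
  0.5 * sum(contour$r_um^2) * dtheta
}

#' Simulate a time series of radial cell contours
#'
#' Shape model: `r(theta, t) = R (1 + sum_k a_k(t) cos(k theta + phi_k))`
#' with `R = base_radius_um`, summed over modes `k = 2 .. n_fourier_modes +
#' 1`. The `k = 1` mode is deliberately excluded: to first order it
#' translates the contour rather than deforming it, and including it would
#' couple shape noise into the centroid, making deformation and translation
#' no longer independently tunable. Each mode amplitude `a_k` follows a
#' stationary Ornstein-Uhlenbeck process with standard deviation
#' `protrusion_amplitude / k` and relaxation rate
#' `protrusion_rate_per_min`, so protrusions decay on a timescale of
#' `1 / protrusion_rate_per_min` minutes. With `protrusion_amplitude = 0`
#' every contour is an exact circle of the base radius. Radii that would
#' fall below `0.2 * base_radius_um` are clamped there (with one warning
#' per call).
#'
#' @param config a [motility_sim_config()].
#' @param cell_index 1-based cell index (`<= config$n_cells`).
#' @param n_theta number of uniformly spaced contour samples.
#' @return a list of `config$n_frames` contours, each a list with `theta`
#'   (radians) and `r_um` (radius, um).
#' @export
#' @examples
#' cfg <- motility_sim_config(n_cells = 1, protrusion_amplitude = 0, seed = 7)
#' sh <- simulate_shape_series(cfg, 1)
#' abs(contour_area(sh[[1]]) - pi * cfg$base_radius_um^2) < 1e-9
simulate_shape_series <- function(config, cell_index, n_theta = 120L) {
  stopifnot(inherits(config, "motility_sim_config"))
  if (cell_index < 1 || cell_index > config$n_cells)
    stopf("cell_index %d out of range 1..%d", cell_index, config$n_cells)
  K <- config$n_fourier_modes
  R <- config$base_radius_um
  A <- config$protrusion_amplitude
  theta <- theta_grid(n_theta)
  dt_min <- config$frame_interval_s / 60
  lambda <- config$protrusion_rate_per_min
  decay <- exp(-lambda * dt_min)
  modes <- seq_len(K) + 1L # k = 2 .. K+1; k = 1 is translation, not shape
  sigma_k <- if (A > 0) A / modes else rep(0, K)

  withr::with_seed(child_seed(config$seed, cell_index, 1L), {
    phi <- runif(K, 0, 2 * pi)
    a <- rnorm(K, 0, sigma_k)
    basis <- sapply(seq_len(K), function(j)
      cos(modes[j] * theta + phi[j])) # n_theta x K
    n_clamped <- 0L
    out <- vector("list", config$n_frames)
    for (t in seq_len(config$n_frames)) {
      if (t > 1L)
        a <- a * decay + rnorm(K, 0, sigma_k * sqrt(1 - decay^2))
      r <- R * (1 + as.vector(basis %*% a))
      low <- r < 0.2 * R
      if (any(low)) {
        n_clamped <- n_clamped + sum(low)
        r[low] <- 0.2 * R
      }
      out[[t]] <- list(theta = theta, r_um = r)
    }
    if (n_clamped > 0L)
      warnf("protrusion amplitude drove %d contour radii below 0.2*base_radius; clamped",
            n_clamped)
    out
  })
}

#' Simulate a persistent-random-walk centroid path
#'
#' The step length per frame is fixed at `mean_speed_um_per_min *
#' frame_interval`, so the programmed frame-to-frame speed is exact.
#' Successive headings differ by wrapped-normal turns with
#' `E[cos(dtheta)] = persistence`; `persistence = 1` gives exactly collinear
#' (ballistic) motion and `persistence = 0` gives independent uniform
#' headings.
#'
#' @param config a [motility_sim_config()].
#' @param cell_index 1-based cell index.
#' @return a `n_frames x 2` matrix of (x, y) positions in um, starting at
#'   the origin.
#' @export
simulate_track <- function(config, cell_index) {
  stopifnot(inherits(config, "motility_sim_config"))
  if (cell_index < 1 || cell_index > config$n_cells)
    stopf("cell_index %d out of range 1..%d", cell_index, config$n_cells)
  n <- config$n_frames
  L <- config$mean_speed_um_per_min * config$frame_interval_s / 60
  p <- config$persistence
  withr::with_seed(child_seed(config$seed, cell_index, 2L), {
    if (p == 0) {
      headings <- runif(n - 1L, 0, 2 * pi)
    } else {
      h0 <- runif(1, 0, 2 * pi)
      turns <- if (p == 1) rep(0, n - 2L) else
        rnorm(n - 2L, 0, sqrt(-2 * log(p)))
      headings <- cumsum(c(h0, turns))
    }
    path <- rbind(c(0, 0),
                  cbind(cumsum(L * cos(headings)), cumsum(L * sin(headings))))
    dimnames(path) <- list(NULL, c("x_um", "y_um"))
    path
  })
}

# Rasterize one radial contour centered at center_um into the field grid.
# Pixel centers sit at ((col - 0.5) * s, (row - 0.5) * s) um. Returns integer
# linear indices (column-major) of foreground pixels, possibly empty.
raster_radial_cell <- function(contour, center_um, dim_px, pixel_size_um) {
  s <- pixel_size_um
  max_r <- max(contour$r_um)
  rows <- max(1L, floor((center_um[2] - max_r) / s)):
          min(dim_px[1], ceiling((center_um[2] + max_r) / s + 1))
  cols <- max(1L, floor((center_um[1] - max_r) / s)):
          min(dim_px[2], ceiling((center_um[1] + max_r) / s + 1))
  if (!length(rows) || !length(cols)) return(integer(0))
  xc <- (cols - 0.5) * s - center_um[1]
  yc <- (rows - 0.5) * s - center_um[2]
  dx <- matrix(xc, nrow = length(rows), ncol = length(cols), byrow = TRUE)
  dy <- matrix(yc, nrow = length(rows), ncol = length(cols))
  rho <- sqrt(dx^2 + dy^2)
  ang <- atan2(dy, dx) %% (2 * pi)
  n_theta <- length(contour$theta)
  dtheta <- 2 * pi / n_theta
  pos <- ang / dtheta
  i0 <- floor(pos)
  w <- pos - i0
  r0 <- contour$r_um[(i0 %% n_theta) + 1L]
  r1 <- contour$r_um[((i0 + 1L) %% n_theta) + 1L]
  inside <- rho <= (1 - w) * r0 + w * r1
  if (!any(inside)) return(integer(0))
  ij <- which(inside, arr.ind = TRUE)
  as.integer(rows[ij[, 1]] + (cols[ij[, 2]] - 1L) * dim_px[1])
}

# Chebyshev dilation of a pixel index set by `gap` px, returned as indices.
dilate_indices <- function(idx, dim_px, gap) {
  if (!length(idx) || gap < 1) return(idx)
  r0 <- ((idx - 1L) %% dim_px[1]) + 1L
  c0 <- ((idx - 1L) %/% dim_px[1]) + 1L
  off <- expand.grid(dr = -gap:gap, dc = -gap:gap)
  rr <- rep(r0, times = nrow(off)) + rep(off$dr, each = length(idx))
  cc <- rep(c0, times = nrow(off)) + rep(off$dc, each = length(idx))
  ok <- rr >= 1L & rr <= dim_px[1] & cc >= 1L & cc <= dim_px[2]
  unique(as.integer(rr[ok] + (cc[ok] - 1L) * dim_px[1]))
}

#' Rasterize simulated cells into a labeled mask movie with ground truth
#'
#' Places each simulated cell at a random in-field position and rasterizes
#' its contour series into per-frame label images (label = cell index).
#' Placement is rejected and re-drawn whenever any frame would bring the
#' cell within `min_gap_px` pixels (Chebyshev distance) of an already placed
#' cell or within `border_margin_px` of the field border, so generated
#' movies satisfy the downstream cell-inclusion criteria by construction.
#'
#' @param config a [motility_sim_config()].
#' @param shapes optional list of contour series (one per cell); generated
#'   from `config` when `NULL`.
#' @param tracks optional list of centroid paths (one per cell); generated
#'   from `config` when `NULL`.
#' @param min_gap_px minimum Chebyshev pixel gap maintained between any two
#'   cells at every frame.
#' @param border_margin_px minimum distance from the field border, px.
#' @param max_retries placement retries per cell before giving up.
#' @param gt_interval_s interval (s) at which programmed newly-gained areas
#'   are recorded in the ground truth; use `NULL` to skip.
#' @param gt_oversample linear oversampling factor for the programmed
#'   newly-gained-area computation.
#' @return a list with elements `frames` (list of integer label matrices),
#'   `ground_truth` (data.frame `cell_id, frame, x_um, y_um` of programmed
#'   centroids), `gt_gain` (data.frame of programmed per-interval newly
#'   gained areas, or `NULL`), `label_map` (data.frame `cell_id, label`) and
#'   `config`.
#' @export
rasterize_movie <- function(config, shapes = NULL, tracks = NULL,
                            min_gap_px = 3L, border_margin_px = 3L,
                            max_retries = 500L,
                            gt_interval_s = 180, gt_oversample = 3L) {
  stopifnot(inherits(config, "motility_sim_config"))
  if (is.null(shapes))
    shapes <- lapply(seq_len(config$n_cells), function(i)
      simulate_shape_series(config, i))
  if (is.null(tracks))
    tracks <- lapply(seq_len(config$n_cells), function(i)
      simulate_track(config, i))
  if (length(shapes) != length(tracks))
    stopf("shapes (%d) and tracks (%d) must have the same length",
          length(shapes), length(tracks))
  n_cells <- length(shapes)
  nf <- config$n_frames
  if (any(vapply(shapes, length, 1L) != nf) ||
      any(vapply(tracks, nrow, 1L) != nf))
    stopf("every shape series and track must cover %d frames", nf)

  dim_px <- config$field_size_px
  s <- config$pixel_size_um
  frames <- lapply(seq_len(nf), function(i)
    matrix(0L, dim_px[1], dim_px[2]))
  gt <- vector("list", n_cells)

  for (i in seq_len(n_cells)) {
    path <- tracks[[i]]
    max_r <- max(vapply(shapes[[i]], function(ct) max(ct$r_um), 1))
    # admissible placement offsets keep shape + margin in-field at all frames
    lo_x <- (border_margin_px + 1) * s + max_r - min(path[, 1])
    hi_x <- (dim_px[2] - border_margin_px - 1) * s - max_r - max(path[, 1])
    lo_y <- (border_margin_px + 1) * s + max_r - min(path[, 2])
    hi_y <- (dim_px[1] - border_margin_px - 1) * s - max_r - max(path[, 2])
    if (lo_x >= hi_x || lo_y >= hi_y)
      stopf(paste("field %dx%d px too small for cell %d: trajectory extent",
                  "plus radius %.1f um plus %d px margin does not fit"),
            dim_px[1], dim_px[2], i, max_r, border_margin_px)

    placed <- FALSE
    withr::with_seed(child_seed(config$seed, i, 3L), {
      for (try in seq_len(max_retries)) {
        offset <- c(runif(1, lo_x, hi_x), runif(1, lo_y, hi_y))
        pix <- vector("list", nf)
        ok <- TRUE
        for (t in seq_len(nf)) {
          idx <- raster_radial_cell(shapes[[i]][[t]], path[t, ] + offset,
                                    dim_px, s)
          if (!length(idx)) { ok <- FALSE; break }
          guard <- dilate_indices(idx, dim_px, min_gap_px - 1L)
          if (any(frames[[t]][guard] != 0L)) { ok <- FALSE; break }
          pix[[t]] <- idx
        }
        if (ok) {
          for (t in seq_len(nf)) frames[[t]][pix[[t]]] <- i
          gt[[i]] <- data.frame(
            cell_id = i, frame = seq_len(nf) - 1L,
            x_um = path[, 1] + offset[1], y_um = path[, 2] + offset[2])
          placed <- TRUE
          break
        }
      }
    })
    if (!placed)
      stopf(paste("could not place cell %d without violating the %d-px",
                  "non-contact gap after %d retries; enlarge the field or",
                  "reduce n_cells"), i, min_gap_px, max_retries)
  }

  gt <- do.call(rbind, gt)
  gt_gain <- NULL
  if (!is.null(gt_interval_s)) {
    step <- gt_interval_s / config$frame_interval_s
    if (abs(step - round(step)) < 1e-9 && round(step) >= 1 &&
        nf > round(step)) {
      step <- as.integer(round(step))
      starts <- seq(1L, nf - step, by = step)
      gdim <- dim_px * gt_oversample
      rows <- lapply(seq_len(n_cells), function(i) {
        off <- as.numeric(gt[gt$cell_id == i, c("x_um", "y_um")][1, ]) -
          tracks[[i]][1, ]
        do.call(rbind, lapply(seq_along(starts), function(j) {
          t0 <- starts[j]; t1 <- t0 + step
          a <- raster_radial_cell(shapes[[i]][[t0]], tracks[[i]][t0, ] + off,
                                  gdim, s / gt_oversample)
          b <- raster_radial_cell(shapes[[i]][[t1]], tracks[[i]][t1, ] + off,
                                  gdim, s / gt_oversample)
          data.frame(cell_id = i, pair_index = j,
                     frame_from = t0 - 1L, frame_to = t1 - 1L,
                     gain_um2 = length(setdiff(b, a)) * (s / gt_oversample)^2)
        }))
      })
      gt_gain <- do.call(rbind, rows)
    }
  }

  list(frames = frames, ground_truth = gt, gt_gain = gt_gain,
       label_map = data.frame(cell_id = seq_len(n_cells),
                              label = seq_len(n_cells)),
       config = config)
}
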