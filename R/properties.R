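## Defect properties: +1/2 polarity, oriented ensemble averaging of
## vector and director fields around defects, and the single-point
## correlation between averaged fields.

#' Polarity of a +1/2 defect
#'
#' The comet axis of a +1/2 defect, computed as the direction of the
#' divergence of the nematic tensor,
#' \eqn{p = (\partial_x Q_{xx} + \partial_y Q_{xy},\;
#' \partial_x Q_{xy} - \partial_y Q_{xx})}, evaluated by centred finite
#' differences and averaged over a small disk of nodes around the core.
#' For the ideal field \eqn{\theta = \phi/2 + \theta_0} this gives
#' \eqn{\psi = 2\theta_0} (the frozen sign convention; the synthetic
#' velocity template plants its jet along the same \eqn{\psi}, so detected
#' and planted polarities agree).
#'
#' @param grid a [build_director_grid()] result.
#' @param core numeric length-2 core position.
#' @param disk averaging-disk radius in nodes (default 1: the 3x3
#'   neighbourhood).
#' @return polarity angle psi in `(-pi, pi]`.
#' @export
defect_polarity <- function(grid, core, disk = 1L) {
  if (!inherits(grid, "director_grid"))
    stop_nemadef("`grid` must be a director_grid", "nemadef_invalid_input")
  nx <- length(grid$x); ny <- length(grid$y)
  ci <- nearest_index(core[1], grid$x, grid$box[1], grid$periodic, grid$spacing[1])
  cj <- nearest_index(core[2], grid$y, grid$box[2], grid$periodic, grid$spacing[2])
  qxx <- cos(2 * grid$theta)
  qxy <- sin(2 * grid$theta)
  px <- py <- 0; nacc <- 0L
  for (di in -disk:disk) for (dj in -disk:disk) {
    if (di^2 + dj^2 > disk^2 + 0.5) next
    i <- ci + di; j <- cj + dj
    if (grid$periodic) {
      i <- ((i - 1L) %% nx) + 1L; j <- ((j - 1L) %% ny) + 1L
    } else if (i < 2L || i > nx - 1L || j < 2L || j > ny - 1L) next
    ip <- if (grid$periodic) (i %% nx) + 1L else i + 1L
    im <- if (grid$periodic) ((i - 2L) %% nx) + 1L else i - 1L
    jp <- if (grid$periodic) (j %% ny) + 1L else j + 1L
    jm <- if (grid$periodic) ((j - 2L) %% ny) + 1L else j - 1L
    dqxx_dx <- (qxx[ip, j] - qxx[im, j]) / (2 * grid$spacing[1])
    dqxy_dx <- (qxy[ip, j] - qxy[im, j]) / (2 * grid$spacing[1])
    dqxx_dy <- (qxx[i, jp] - qxx[i, jm]) / (2 * grid$spacing[2])
    dqxy_dy <- (qxy[i, jp] - qxy[i, jm]) / (2 * grid$spacing[2])
    px <- px + dqxx_dx + dqxy_dy
    py <- py + dqxy_dx - dqxx_dy
    nacc <- nacc + 1L
  }
  if (nacc == 0L || sqrt(px^2 + py^2) / nacc < 1e-8)
    stop_nemadef("polarity undefined: |div Q| below tolerance at the core",
                 "nemadef_polarity_error")
  atan2(py, px)
}

#' Vector field sampled on a regular grid
#'
#' Container for velocity (or any vector) fields used in oriented
#' averaging, with the same geometry conventions as [build_director_grid()]
#' (`[i, j]` = x, y).
#'
#' @param vx,vy matrices of components.
#' @param origin,spacing grid geometry (spacing scalar or per-axis).
#' @param box domain size; defaults to the grid extent.
#' @param periodic logical.
#' @return an object of class `vector_grid`.
#' @export
vector_grid <- function(vx, vy, origin = c(0, 0), spacing, box = NULL,
                        periodic = FALSE) {
  stopifnot(all(dim(vx) == dim(vy)))
  spacing <- rep_len(as.numeric(spacing), 2L)
  x <- origin[1] + (seq_len(nrow(vx)) - 1) * spacing[1]
  y <- origin[2] + (seq_len(ncol(vx)) - 1) * spacing[2]
  if (is.null(box)) box <- c(max(x) + spacing[1], max(y) + spacing[2])
  structure(list(vx = vx, vy = vy, x = x, y = y, origin = origin,
                 spacing = spacing, box = box, periodic = periodic),
            class = "vector_grid")
}

#' Interpolate per-cell velocities onto a regular grid
#'
#' Same deposit-and-window scheme as the director field: cell velocities
#' are deposited at their nearest grid node and averaged over the sliding
#' window (plain vector mean; velocities are polar, not nematic).
#'
#' @param frame a [cell_frame()] with `vx`, `vy` columns.
#' @inheritParams build_director_grid
#' @return a [vector_grid()].
#' @export
build_velocity_grid <- function(frame, spacing = NULL, window = NULL) {
  if (!all(c("vx", "vy") %in% names(frame$cells)))
    stop_nemadef("frame has no velocity columns", "nemadef_invalid_input")
  d <- cell_diameter(frame)
  if (is.null(spacing)) spacing <- 0.25 * d
  if (is.null(window)) window <- 1.5 * d
  geom <- grid_geometry(frame$box, spacing, frame$periodic)
  nx <- length(geom$x); ny <- length(geom$y)
  ii <- nearest_index(frame$cells$x, geom$x, frame$box[1], frame$periodic,
                      geom$spacing[1])
  jj <- nearest_index(frame$cells$y, geom$y, frame$box[2], frame$periodic,
                      geom$spacing[2])
  lin <- ii + (jj - 1L) * nx
  acc <- function(v) {
    m <- matrix(0, nx, ny)
    s <- rowsum(v, lin)
    m[as.integer(rownames(s))] <- s
    m
  }
  cnt <- acc(rep(1, length(lin)))
  sx <- acc(frame$cells$vx)
  sy <- acc(frame$cells$vy)
  hx <- round(window / geom$spacing[1]); hy <- round(window / geom$spacing[2])
  n <- box_sum(cnt, hx, hy, frame$periodic)
  n[n == 0] <- NA
  vector_grid(box_sum(sx, hx, hy, frame$periodic) / n,
              box_sum(sy, hx, hy, frame$periodic) / n,
              origin = geom$origin, spacing = geom$spacing,
              box = frame$box, periodic = frame$periodic)
}

## Bilinear sampling of a vector_grid at arbitrary points, with periodic
## wrap or edge clamping.
sample_vector_grid <- function(vg, px, py) {
  nx <- length(vg$x); ny <- length(vg$y)
  fx <- (px - vg$origin[1]) / vg$spacing[1]
  fy <- (py - vg$origin[2]) / vg$spacing[2]
  if (vg$periodic) {
    fx <- fx %% nx; fy <- fy %% ny
    i0 <- floor(fx); j0 <- floor(fy)
    wi <- fx - i0; wj <- fy - j0
    i1 <- (i0 + 1L) %% nx; j1 <- (j0 + 1L) %% ny
    i0 <- i0 %% nx; j0 <- j0 %% ny
  } else {
    fx <- pmin(pmax(fx, 0), nx - 1L)
    fy <- pmin(pmax(fy, 0), ny - 1L)
    i0 <- pmin(floor(fx), nx - 2L); j0 <- pmin(floor(fy), ny - 2L)
    wi <- fx - i0; wj <- fy - j0
    i1 <- i0 + 1L; j1 <- j0 + 1L
  }
  at <- function(m, i, j) m[cbind(as.integer(i) + 1L, as.integer(j) + 1L)]
  bil <- function(m) {
    at(m, i0, j0) * (1 - wi) * (1 - wj) + at(m, i1, j0) * wi * (1 - wj) +
      at(m, i0, j1) * (1 - wi) * wj + at(m, i1, j1) * wi * wj
  }
  cbind(vx = bil(vg$vx), vy = bil(vg$vy))
}

#' Ensemble-average a vector field around +1/2 defects
#'
#' For each defect the field is cropped in a square window around the
#' core, the window and its vectors are rotated by `-psi` so every
#' defect's polarity aligns with +x, the crop is bilinearly resampled onto
#' a common grid, and the aligned crops are averaged element-wise. This is
#' how the characteristic mean flow pattern around +1/2 defects is
#' extracted from noisy per-defect fields.
#'
#' @param defects data.frame with columns `x`, `y`, `psi` and optionally
#'   `field` (index into `fields`; default 1). All rows must be +1/2
#'   defects with defined polarity.
#' @param fields a [vector_grid()] or list of them, one per frame.
#' @param half_width half-size of the averaging window (length units).
#' @param n_max use at most this many defects (in row order).
#' @param out_points nodes per side of the common output grid (odd).
#' @return an object of class `average_field`: `vx`, `vy` matrices on the
#'   defect-aligned local grid, local coordinates `x`, `y`, ensemble size
#'   `n`, `spacing`.
#' @export
average_field_around_defects <- function(defects, fields, half_width,
                                         n_max = Inf, out_points = 21L) {
  if (inherits(fields, "vector_grid")) fields <- list(fields)
  if (!nrow(defects))
    stop_nemadef("empty defect list", "nemadef_invalid_input")
  if (is.null(defects$field)) defects$field <- 1L
  if (anyNA(defects$psi))
    stop_nemadef("all defects must have a defined polarity psi",
                 "nemadef_invalid_input")
  n_use <- min(nrow(defects), n_max)
  out_points <- as.integer(out_points)
  offs <- seq(-half_width, half_width, length.out = out_points)
  gx <- rep(offs, times = out_points)
  gy <- rep(offs, each = out_points)
  sx <- sy <- numeric(out_points^2)
  used <- 0L
  for (r in seq_len(n_use)) {
    vg <- fields[[defects$field[r]]]
    psi <- defects$psi[r]
    cpsi <- cos(psi); spsi <- sin(psi)
    wx <- defects$x[r] + cpsi * gx - spsi * gy
    wy <- defects$y[r] + spsi * gx + cpsi * gy
    if (!vg$periodic &&
        (min(wx) < min(vg$x) || max(wx) > max(vg$x) ||
         min(wy) < min(vg$y) || max(wy) > max(vg$y))) {
      warning(sprintf("defect %d window crosses a non-periodic boundary; skipped", r))
      next
    }
    v <- sample_vector_grid(vg, wx, wy)
    if (anyNA(v)) { warning(sprintf("defect %d window has unsampled nodes; skipped", r)); next }
    # rotate vectors into the defect frame (polarity -> +x)
    sx <- sx + cpsi * v[, 1] + spsi * v[, 2]
    sy <- sy + -spsi * v[, 1] + cpsi * v[, 2]
    used <- used + 1L
  }
  if (used == 0L)
    stop_nemadef("no usable defects for averaging", "nemadef_invalid_input")
  structure(list(vx = matrix(sx / used, out_points, out_points),
                 vy = matrix(sy / used, out_points, out_points),
                 x = offs, y = offs, n = used,
                 spacing = offs[2] - offs[1]),
            class = "average_field")
}

#' Ensemble-average the director field around defects
#'
#' The nematic analogue of [average_field_around_defects()]: director
#' patches are rotated into the defect frame (grid by `-psi`, directors by
#' `-psi` mod pi), averaged as Q components, and the mean director and
#' order parameter extracted.
#'
#' @param defects data.frame with `x`, `y`, `psi`, optional `field`.
#' @param grids a `director_grid` or list of them.
#' @inheritParams average_field_around_defects
#' @return list with `theta` (mean director, `[0, pi)`), `S` (coherence of
#'   the ensemble), local `x`, `y`, `n`.
#' @export
average_director_around_defects <- function(defects, grids, half_width,
                                            n_max = Inf, out_points = 21L) {
  if (inherits(grids, "director_grid")) grids <- list(grids)
  if (!nrow(defects))
    stop_nemadef("empty defect list", "nemadef_invalid_input")
  if (is.null(defects$field)) defects$field <- 1L
  n_use <- min(nrow(defects), n_max)
  out_points <- as.integer(out_points)
  offs <- seq(-half_width, half_width, length.out = out_points)
  gx <- rep(offs, times = out_points)
  gy <- rep(offs, each = out_points)
  sc <- ss <- numeric(out_points^2)
  used <- 0L
  for (r in seq_len(n_use)) {
    g <- grids[[defects$field[r]]]
    psi <- defects$psi[r]
    cpsi <- cos(psi); spsi <- sin(psi)
    wx <- defects$x[r] + cpsi * gx - spsi * gy
    wy <- defects$y[r] + spsi * gx + cpsi * gy
    if (!g$periodic &&
        (min(wx) < min(g$x) || max(wx) > max(g$x) ||
         min(wy) < min(g$y) || max(wy) > max(g$y))) {
      warning(sprintf("defect %d window crosses a non-periodic boundary; skipped", r))
      next
    }
    ii <- nearest_index(wx, g$x, g$box[1], g$periodic, g$spacing[1])
    jj <- nearest_index(wy, g$y, g$box[2], g$periodic, g$spacing[2])
    th <- g$theta[cbind(ii, jj)] - psi
    sc <- sc + cos(2 * th)
    ss <- ss + sin(2 * th)
    used <- used + 1L
  }
  if (used == 0L)
    stop_nemadef("no usable defects for averaging", "nemadef_invalid_input")
  list(theta = matrix(reduce_mod_pi(0.5 * atan2(ss, sc)),
                      out_points, out_points),
       S = matrix(sqrt(sc^2 + ss^2) / used, out_points, out_points),
       x = offs, y = offs, n = used)
}

#' @export
print.average_field <- function(x, ...) {
  cat(sprintf("<average_field> %d x %d grid, ensemble of %d defects, max |v| = %.3g\n",
              nrow(x$vx), ncol(x$vx), x$n, max(sqrt(x$vx^2 + x$vy^2))))
  invisible(x)
}

#' @export
plot.average_field <- function(x, scale = NULL, ...) {
  spd <- sqrt(x$vx^2 + x$vy^2)
  if (is.null(scale)) scale <- 0.8 * x$spacing / max(spd)
  px <- rep(x$x, times = length(x$y))
  py <- rep(x$y, each = length(x$x))
  graphics::plot(NA, xlim = range(x$x), ylim = range(x$y), asp = 1,
                 xlab = "x (defect frame)", ylab = "y", ...)
  graphics::arrows(px, py, px + scale * as.vector(x$vx),
                   py + scale * as.vector(x$vy), length = 0.03)
  invisible(x)
}

#' Single-point correlation between two averaged vector fields
#'
#' The mean over grid nodes of the dot product of paired vectors,
#' normalized by the product of the fields' root-mean-square magnitudes:
#' a cosine-type score in `[-1, 1]` with self-correlation exactly 1.
#'
#' @param A,B `average_field` objects (or any lists with `vx`, `vy`
#'   matrices of equal shape).
#' @return scalar correlation.
#' @export
field_correlation <- function(A, B) {
  if (!all(dim(A$vx) == dim(B$vx)))
    stop_nemadef("fields must share a grid shape", "nemadef_invalid_input")
  na <- sqrt(mean(A$vx^2 + A$vy^2))
  nb <- sqrt(mean(B$vx^2 + B$vy^2))
  if (na == 0 || nb == 0)
    stop_nemadef("correlation undefined for a zero field", "nemadef_invalid_input")
  mean(A$vx * B$vx + A$vy * B$vy) / (na * nb)
}
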