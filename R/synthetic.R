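## Synthetic tissue generator: seeded frames and labelled ROI datasets with
## planted, analytically known defects. Stands in for simulation-derived
## training data; every artefact is a pure function of its config (seed
## included).

#' Configuration for the synthetic tissue generator
#'
#' @param box numeric length-2 domain size in cell diameters (cells have
#'   unit diameter by construction when `n_cells = prod(box)`).
#' @param n_cells target number of cells; actual count is the nearest
#'   triangular-lattice fill.
#' @param defects `NULL` or a data.frame with columns `x`, `y`, `charge`
#'   (+0.5 or -0.5); planted defect cores.
#' @param phase global phase theta0 of the planted director field.
#' @param kappa angular-noise concentration, applied as a wrapped von
#'   Mises perturbation of the *double* angle 2*theta (so theta stays
#'   nematic-valid). `Inf` = noise free, `0` = isotropic orientations.
#' @param jitter cell-position jitter as a fraction of the lattice
#'   constant (normal, per axis).
#' @param v0 velocity-template amplitude; 0 disables velocities.
#' @param sigma_v isotropic Gaussian velocity noise (per component).
#' @param decay length scale of the velocity template (cell diameters).
#' @param periodic logical; periodic frames require total planted charge 0.
#' @param seed integer seed fixing all randomness.
#' @return a `synth_config` list.
#' @export
synth_config <- function(box = c(20, 20), n_cells = 400, defects = NULL,
                         phase = 0, kappa = Inf, jitter = 0.15,
                         v0 = 0, sigma_v = 0, decay = NULL,
                         periodic = TRUE, seed = 1L) {
  box <- as.numeric(box)
  if (!is.null(defects)) {
    defects <- as.data.frame(defects)
    if (!all(c("x", "y", "charge") %in% names(defects)))
      stop_nemadef("`defects` needs columns x, y, charge", "nemadef_config_error")
    if (!all(defects$charge %in% c(0.5, -0.5)))
      stop_nemadef("planted charges must be +0.5 or -0.5", "nemadef_config_error")
    if (periodic && abs(sum(defects$charge)) > 1e-12)
      stop_nemadef("periodic frames require total planted charge 0",
                   "nemadef_config_error")
    d <- sqrt(prod(box) / n_cells)
    if (nrow(defects) > 1L) {
      for (a in seq_len(nrow(defects) - 1L)) for (b in (a + 1L):nrow(defects)) {
        dd <- c(defects$x[a] - defects$x[b], defects$y[a] - defects$y[b])
        if (periodic) dd <- min_image(dd, box)
        if (sqrt(sum(dd^2)) < 3 * d)
          stop_nemadef("defect cores closer than 3 cell diameters are not resolvable",
                       "nemadef_config_error")
      }
    }
  }
  if (kappa < 0) stop_nemadef("`kappa` must be >= 0", "nemadef_config_error")
  if (is.null(decay)) decay <- 1.5 * sqrt(prod(box) / n_cells)
  structure(list(box = box, n_cells = n_cells, defects = defects,
                 phase = phase, kappa = kappa, jitter = jitter, v0 = v0,
                 sigma_v = sigma_v, decay = decay, periodic = periodic,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Ideal director angle of a superposition of point defects
#'
#' The standard nematic defect field: \eqn{\theta(p) = \sum_j k_j \phi_j +
#' \theta_0}, where \eqn{\phi_j} is the polar angle of `p` relative to
#' core j. A single `k = +1/2` core produces the comet-shaped pattern, a
#' `k = -1/2` core the trefoil.
#'
#' @param x,y coordinates of evaluation points (vectorized).
#' @param defects data.frame with `x`, `y`, `charge`.
#' @param phase global phase theta0.
#' @return director angles reduced to `[0, pi)`.
#' @export
ideal_defect_angle <- function(x, y, defects, phase = 0) {
  th <- rep(phase, length(x))
  if (!is.null(defects) && nrow(defects)) {
    for (j in seq_len(nrow(defects))) {
      dx <- x - defects$x[j]
      dy <- y - defects$y[j]
      if (any(dx == 0 & dy == 0))
        stop_nemadef("evaluation point coincides with a defect core (singular)",
                     "nemadef_singular_point")
      th <- th + defects$charge[j] * atan2(dy, dx)
    }
  }
  reduce_mod_pi(th)
}

## Local phase of the field at core j excluding j's own singular term;
## the +1/2 polarity is psi = 2 * local phase (frozen convention, verified
## against the finite-difference oracle).
local_phase <- function(defects, j, phase) {
  ph <- phase
  if (nrow(defects) > 1L) {
    for (l in seq_len(nrow(defects))[-j]) {
      ph <- ph + defects$charge[l] *
        atan2(defects$y[j] - defects$y[l], defects$x[j] - defects$x[l])
    }
  }
  ph
}

## Best-Fisher (1979) rejection sampler for the von Mises distribution,
## mean 0, concentration kappa, support (-pi, pi].
rvonmises <- function(n, kappa) {
  if (n == 0L) return(numeric(0))
  if (!is.finite(kappa)) return(rep(0, n))
  if (kappa == 0) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[2]) + 1 - c0 >= 0) {
      out[i] <- sign(u[3] - 0.5) * acos(f)
      i <- i + 1L
    }
  }
  out
}

## Angular noise in double-angle space: theta + delta/2 with
## delta ~ vonMises(0, kappa). kappa = 0 makes orientations isotropic.
perturb_directors <- function(theta, kappa) {
  reduce_mod_pi(theta + rvonmises(length(theta), kappa) / 2)
}

#' Generate a synthetic cell frame with planted defects
#'
#' Cell centres sit on a jittered triangular lattice at the configured
#' density; orientations follow the ideal planted defect field plus
#' wrapped angular noise; optional velocities superpose the +1/2 defect
#' flow template (jet along each defect's polarity flanked by two
#' counter-rotating vortices) with isotropic Gaussian noise. The output
#' format matches what segmentation software produces, and the ground
#' truth is returned alongside.
#'
#' @param cfg a [synth_config()].
#' @return list with `frame` (a [cell_frame()]) and `truth` (data.frame of
#'   planted defects: `x`, `y`, `charge`, `class`, `psi` -- polarity, for
#'   +1/2 cores only).
#' @export
generate_frame <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  with_seed(cfg$seed, {
    pts <- triangular_points(cfg$box, cfg$n_cells, cfg$jitter, cfg$periodic)
    th0 <- ideal_defect_angle(pts$x, pts$y, cfg$defects, cfg$phase)
    th <- perturb_directors(th0, cfg$kappa)
    cells <- data.frame(x = pts$x, y = pts$y, theta = th)
    truth <- synth_truth(cfg)
    if (cfg$v0 > 0) {
      v <- matrix(0, nrow(cells), 2)
      if (!is.null(truth) && nrow(truth)) {
        for (j in which(truth$charge > 0)) {
          v <- v + defect_velocity_template(cells$x, cells$y,
                                            core = c(truth$x[j], truth$y[j]),
                                            psi = truth$psi[j],
                                            v0 = cfg$v0, decay = cfg$decay)
        }
      }
      v <- v + matrix(stats::rnorm(2 * nrow(cells), sd = cfg$sigma_v),
                      ncol = 2)
      cells$vx <- v[, 1]
      cells$vy <- v[, 2]
    }
    list(frame = cell_frame(cells, box = cfg$box, periodic = cfg$periodic),
         truth = truth)
  })
}

synth_truth <- function(cfg) {
  if (is.null(cfg$defects) || !nrow(cfg$defects)) {
    return(data.frame(x = numeric(0), y = numeric(0), charge = numeric(0),
                      class = character(0), psi = numeric(0)))
  }
  d <- cfg$defects
  d$class <- ifelse(d$charge > 0, "+1/2", "-1/2")
  d$psi <- NA_real_
  for (j in seq_len(nrow(d))) {
    if (d$charge[j] > 0) d$psi[j] <- 2 * local_phase(cfg$defects, j, cfg$phase)
  }
  d
}

triangular_points <- function(box, n_cells, jitter, periodic) {
  a <- sqrt(2 * prod(box) / (sqrt(3) * n_cells))  # lattice constant at density
  dy <- a * sqrt(3) / 2
  ny <- max(2L, round(box[2] / dy))
  dy <- box[2] / ny
  nx <- max(2L, round(box[1] / a))
  dx <- box[1] / nx
  xs <- ys <- numeric(0)
  for (row in seq_len(ny)) {
    off <- if (row %% 2 == 0) dx / 2 else 0
    xs <- c(xs, (seq_len(nx) - 1) * dx + off)
    ys <- c(ys, rep((row - 0.5) * dy, nx))
  }
  xs <- xs + stats::rnorm(length(xs), sd = jitter * a)
  ys <- ys + stats::rnorm(length(ys), sd = jitter * a)
  if (periodic) {
    xs <- xs %% box[1]
    ys <- ys %% box[2]
  } else {
    xs <- pmin(pmax(xs, 0), box[1])
    ys <- pmin(pmax(ys, 0), box[2])
  }
  list(x = xs, y = ys)
}

#' Planted +1/2 defect velocity template
#'
#' A fixed analytic stand-in for the flow around a +1/2 defect in an
#' extensile layer: a forward (tail-to-head) Gaussian jet along the
#' polarity axis flanked by two counter-rotating Gaussian vortices,
#' decaying over `decay`. Normalised so the velocity at the core is
#' exactly `v0` along the polarity `psi`. It is a recoverable planted
#' pattern for benchmarking oriented averaging, with no claim of
#' hydrodynamic fidelity.
#'
#' @param x,y evaluation points (vectorized).
#' @param core defect core position, length 2.
#' @param psi polarity angle (radians); the jet points along `psi`.
#' @param v0 core speed.
#' @param decay Gaussian length scale.
#' @param vortex relative strength of the vortex pair.
#' @return matrix with columns `vx`, `vy`.
#' @export
defect_velocity_template <- function(x, y, core = c(0, 0), psi = 0, v0 = 1,
                                     decay = 1.5, vortex = 0.6) {
  if (v0 < 0) stop_nemadef("`v0` must be >= 0", "nemadef_parameter_error")
  R <- decay
  # local frame: polarity along +x
  dx0 <- x - core[1]; dy0 <- y - core[2]
  cx <- cos(psi); sx <- sin(psi)
  lx <- cx * dx0 + sx * dy0
  ly <- -sx * dx0 + cx * dy0
  g <- exp(-(lx^2 + ly^2) / (2 * R^2))
  gt <- exp(-(lx^2 + (ly - R)^2) / (2 * R^2))
  gb <- exp(-(lx^2 + (ly + R)^2) / (2 * R^2))
  # top vortex counter-clockwise, bottom clockwise: both push +x between them
  ux <- g + (vortex / R) * (-gt * (ly - R) + gb * (ly + R))
  uy <- (vortex / R) * (gt - gb) * lx
  norm0 <- 1 + 2 * vortex * exp(-0.5)
  ux <- v0 * ux / norm0
  uy <- v0 * uy / norm0
  cbind(vx = cx * ux - sx * uy, vy = sx * ux + cx * uy)
}

#' Generate a balanced labelled ROI dataset with known ground truth
#'
#' Builds 9x9 director patches of the three classes directly from the
#' analytic defect field plus angular noise. Defect ROIs (`+1/2`, `-1/2`)
#' have a core planted at the patch centre (sub-node-jittered, random
#' phase). No-defect ROIs mix two recipes 50/50, mirroring the hard
#' negatives of real tissue: `disordered` patches of iid isotropic
#' orientations (low nematic order without any defect), and `farfield`
#' crops of a smooth two-defect field far from both cores. At `kappa =
#' Inf` no-defect ROIs use the far-field recipe only (an iid-isotropic
#' patch is maximal noise by construction, not noise free).
#'
#' @param n_per_class ROIs per class.
#' @param kappa noise concentration(s) in double-angle space; a vector is
#'   recycled across items so a dataset can span difficulty levels.
#' @param side_points patch side (default 9).
#' @param span physical patch side in cell diameters (default 6, the
#'   midpoint of the 5-7 cell ROI sizing rule).
#' @param seed integer seed.
#' @return an object of class `roi_dataset`: `theta` array
#'   `(n, side, side)`, `label` factor over [defect_classes()], `meta`
#'   data.frame (`kappa`, `recipe`, `phase`), `spacing`.
#' @export
generate_labeled_rois <- function(n_per_class, kappa = 6, side_points = 9L,
                                  span = 6, seed = 1L) {
  if (n_per_class < 1L)
    stop_nemadef("`n_per_class` must be >= 1", "nemadef_parameter_error")
  side <- as.integer(side_points)
  step <- span / (side - 1L)
  offs <- (seq_len(side) - (side + 1L) / 2) * step
  px <- rep(offs, times = side)   # [i, j] = (x_i, y_j)
  py <- rep(offs, each = side)
  n <- 3L * n_per_class
  labels <- rep(defect_classes(), each = n_per_class)
  kap <- rep_len(kappa, n_per_class)
  with_seed(seed, {
    theta <- array(NA_real_, dim = c(n, side, side))
    recipe <- character(n)
    phase <- stats::runif(n, 0, pi)
    kappas <- rep(kap, times = 3L)
    for (i in seq_len(n)) {
      k <- kappas[i]
      if (labels[i] %in% c("+1/2", "-1/2")) {
        q <- if (labels[i] == "+1/2") 0.5 else -0.5
        core <- stats::runif(2, -step / 2, step / 2)
        th <- ideal_defect_angle(px - core[1], py - core[2],
                                 data.frame(x = 0, y = 0, charge = q),
                                 phase = phase[i])
        recipe[i] <- "defect"
      } else {
        use_far <- !is.finite(k) || stats::runif(1) < 0.5
        if (use_far) {
          beta <- stats::runif(1, 0, 2 * pi)
          D <- 3 * span
          far <- data.frame(x = c(D * cos(beta), -D * cos(beta)),
                            y = c(D * sin(beta), -D * sin(beta)),
                            charge = c(0.5, -0.5))
          th <- ideal_defect_angle(px, py, far, phase = phase[i])
          recipe[i] <- "farfield"
        } else {
          th <- stats::runif(side * side, 0, pi)
          recipe[i] <- "disordered"
        }
      }
      theta[i, , ] <- matrix(perturb_directors(th, k), side, side)
    }
    structure(list(theta = theta,
                   label = factor(labels, levels = defect_classes()),
                   meta = data.frame(kappa = kappas, recipe = recipe,
                                     phase = phase),
                   spacing = step),
              class = "roi_dataset")
  })
}

#' @export
print.roi_dataset <- function(x, ...) {
  cat(sprintf("<roi_dataset> %d ROIs (%s), %d x %d nodes, step %.3g\n",
              dim(x$theta)[1],
              paste(sprintf("%s: %d", levels(x$label), table(x$label)),
                    collapse = ", "),
              dim(x$theta)[2], dim(x$theta)[3], x$spacing))
  invisible(x)
}

#' Extract one ROI from a dataset
#'
#' @param dataset a `roi_dataset`.
#' @param i item index.
#' @return a `defect_roi`.
#' @export
dataset_roi <- function(dataset, i) {
  new_roi(dataset$theta[i, , ], spacing = dataset$spacing,
          label = as.character(dataset$label[i]),
          source_id = sprintf("dataset[%d]", i))
}

#' Subset a labelled ROI dataset
#'
#' @param x a `roi_dataset`; @param i index vector.
#' @param ... ignored.
#' @return a `roi_dataset`.
#' @export
`[.roi_dataset` <- function(x, i, ...) {
  structure(list(theta = x$theta[i, , , drop = FALSE],
                 label = x$label[i],
                 meta = x$meta[i, , drop = FALSE],
                 spacing = x$spacing),
            class = "roi_dataset")
}
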