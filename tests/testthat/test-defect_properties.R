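# Polarity, oriented averaging and field correlation.

# Brute-force finite-difference oracle for the polarity direction
# p = (dQxx/dx + dQxy/dy, dQxy/dx - dQxx/dy) on the analytic field,
# evaluated on a ring of points around the core.
oracle_polarity <- function(theta0, h = 1e-4) {
  pts <- expand.grid(x = c(-1, 0, 1), y = c(-1, 0, 1))
  pts <- pts[!(pts$x == 0 & pts$y == 0), ]
  q <- function(x, y) {
    th <- (0.5 * atan2(y, x) + theta0)
    c(cos(2 * th), sin(2 * th))
  }
  px <- py <- 0
  for (r in seq_len(nrow(pts))) {
    x <- pts$x[r]; y <- pts$y[r]
    dqx <- (q(x + h, y) - q(x - h, y)) / (2 * h)
    dqy <- (q(x, y + h) - q(x, y - h)) / (2 * h)
    px <- px + dqx[1] + dqy[2]
    py <- py + dqx[2] - dqy[1]
  }
  atan2(py, px)
}

test_that("polarity follows the psi = 2 * theta0 convention of the oracle", {
  for (th0 in c(0, 0.3, 1.2)) {
    expected <- Arg(exp(1i * 2 * th0))
    expect_equal(oracle_polarity(th0), expected, tolerance = 1e-6)
    cfg <- synth_config(box = c(20, 20), n_cells = 400,
                        defects = data.frame(x = c(5, 15), y = c(10, 10),
                                             charge = c(0.5, -0.5)),
                        phase = th0, kappa = Inf, jitter = 0.05, seed = 70)
    sim <- generate_frame(cfg)
    g <- build_director_grid(sim$frame)
    psi_hat <- defect_polarity(g, c(5, 10))
    psi_true <- sim$truth$psi[1]
    expect_lt(abs(Arg(exp(1i * (psi_hat - psi_true)))), 0.15)
  }
})

test_that("polarity is equivariant under rigid rotation and undefined on uniform fields", {
  # rotating the phase by alpha rotates psi by 2 * alpha for the ideal
  # single +1/2 field (phase enters the director once, psi doubles it)
  expect_equal(Arg(exp(1i * (oracle_polarity(0.5) - oracle_polarity(0)))), 1,
               tolerance = 1e-6)
  cells <- expand.grid(x = seq(0.5, 19.5, 1), y = seq(0.5, 19.5, 1))
  cells$theta <- 0.8
  g <- build_director_grid(cell_frame(cells, box = c(20, 20), periodic = TRUE))
  expect_error(defect_polarity(g, c(10, 10)), class = "nemadef_polarity_error")
})

make_template_grid <- function(psi, noise, seed, v0 = 1, decay = 1.5) {
  set.seed(seed)
  xs <- seq(-10, 10, by = 0.25)
  px <- rep(xs, times = length(xs)); py <- rep(xs, each = length(xs))
  v <- defect_velocity_template(px, py, psi = psi, v0 = v0, decay = decay)
  vector_grid(matrix(v[, 1] + rnorm(length(px), sd = noise), length(xs)),
              matrix(v[, 2] + rnorm(length(px), sd = noise), length(xs)),
              origin = c(-10, -10), spacing = 0.25)
}

clean_template <- function(out_points = 21L, half_width = 4.5) {
  offs <- seq(-half_width, half_width, length.out = out_points)
  tpl <- defect_velocity_template(rep(offs, times = out_points),
                                  rep(offs, each = out_points))
  list(vx = matrix(tpl[, 1], out_points), vy = matrix(tpl[, 2], out_points))
}

test_that("averaging identical aligned templates reproduces the template", {
  grids <- lapply(c(0, 0.9, 2.2), function(p) make_template_grid(p, 0, 1))
  defs <- data.frame(x = 0, y = 0, psi = c(0, 0.9, 2.2), field = 1:3)
  avg <- average_field_around_defects(defs, grids, half_width = 4.5)
  tpl <- clean_template()
  expect_lt(max(abs(avg$vx - tpl$vx)), 0.02)  # bilinear resampling error only
  expect_lt(max(abs(avg$vy - tpl$vy)), 0.02)
  expect_gt(field_correlation(avg, tpl), 0.999)
  # permutation invariance and determinism
  avg2 <- average_field_around_defects(defs[c(3, 1, 2), ], grids, half_width = 4.5)
  expect_equal(avg$vx, avg2$vx, tolerance = 1e-12)
  avg3 <- average_field_around_defects(defs, grids, half_width = 4.5)
  expect_identical(avg$vx, avg3$vx)
  expect_error(average_field_around_defects(defs[0, ], grids, half_width = 4.5),
               class = "nemadef_invalid_input")
})

test_that("field correlation anchors: self 1, antiparallel -1, orthogonal 0", {
  tpl <- clean_template()
  expect_equal(field_correlation(tpl, tpl), 1)
  neg <- list(vx = -tpl$vx, vy = -tpl$vy)
  expect_equal(field_correlation(tpl, neg), -1)
  rot <- list(vx = -tpl$vy, vy = tpl$vx)  # every vector rotated by pi/2
  expect_equal(field_correlation(tpl, rot), 0, tolerance = 1e-12)
  expect_error(field_correlation(tpl, list(vx = tpl$vx * 0, vy = tpl$vy * 0)),
               class = "nemadef_invalid_input")
})

test_that("oriented averaging of directors reproduces the +1/2 pattern", {
  sims <- lapply(1:6, function(k) {
    th0 <- (k - 1) * pi / 6
    generate_frame(synth_config(box = c(20, 20), n_cells = 400,
                                defects = data.frame(x = c(5, 15), y = c(10, 10),
                                                     charge = c(0.5, -0.5)),
                                phase = th0, kappa = 12, jitter = 0.1,
                                seed = 500 + k))
  })
  grids <- lapply(sims, function(s) build_director_grid(s$frame))
  defs <- do.call(rbind, lapply(seq_along(sims), function(k) {
    data.frame(x = 5, y = 10, psi = sims[[k]]$truth$psi[1], field = k)
  }))
  avg <- average_director_around_defects(defs, grids, half_width = 3,
                                         out_points = 15)
  # reference: ideal +1/2 pattern in a frame whose polarity points along +x
  offs <- avg$x
  ref <- matrix(reduce_mod_pi(0.5 * atan2(rep(offs, each = 15),
                                          rep(offs, times = 15))),
                15, 15)
  dev <- abs(nemadef:::wrap_half_pi(avg$theta - ref))
  r <- sqrt(outer(offs^2, offs^2, "+"))
  expect_lt(median(dev[r > 1]), 0.25)
  # ensemble coherence is high away from the core
  expect_gt(mean(avg$S[r > 1]), 0.8)
})
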