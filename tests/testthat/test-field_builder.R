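# Director-field construction and the scalar nematic order parameter.

make_uniform_frame <- function(theta, n_side = 20) {
  cells <- expand.grid(x = seq(0.5, n_side - 0.5, 1),
                       y = seq(0.5, n_side - 0.5, 1))
  cells$theta <- theta
  cell_frame(cells, box = c(n_side, n_side), periodic = TRUE)
}

test_that("a uniform orientation field is a fixed point of interpolation and smoothing", {
  g <- build_director_grid(make_uniform_frame(0.3))
  expect_equal(range(g$theta), c(0.3, 0.3))
  expect_equal(range(g$theta_raw), c(0.3, 0.3))
})

test_that("nematic averaging crosses the pi wrap correctly", {
  # two directors 0.1 and pi - 0.1: <cos 2theta> = cos 0.2 > 0,
  # <sin 2theta> = 0, so the nematic mean is 0, not the naive pi/2
  cells <- data.frame(x = c(9.9, 10.1, 3), y = c(10, 10, 3),
                      theta = c(0.1, pi - 0.1, 0.5))
  fr <- cell_frame(cells, box = c(20, 20), periodic = FALSE)
  g <- build_director_grid(fr, spacing = 0.5, window = 1)
  node_i <- which.min(abs(g$x - 10))
  node_j <- which.min(abs(g$y - 10))
  # nematic mean sits at ~0, far from the naive arithmetic mean pi/2
  dev <- abs(wrap_half_pi_test(g$theta[node_i, node_j]))
  expect_lt(dev, 0.1)
  # exact hand evaluation of the double-angle average itself:
  # <cos 2theta> = cos 0.2 > 0, <sin 2theta> = 0 -> mean director 0
  expect_equal(nemadef:::nematic_mean(c(0.1, pi - 0.1)), 0, tolerance = 1e-12)
})

test_that("order parameter matches hand-evaluated Q tensors", {
  expect_identical(nematic_order(rep(0, 7)), 1)        # aligned: exactly 1
  expect_equal(nematic_order(rep(1.1, 5)), 1, tolerance = 1e-12)
  expect_equal(nematic_order(c(0, pi / 2)), 0)         # orthogonal: 0
  # {0, 0, pi/4}: Qxx = 2/3, Qxy = 1/3, S = sqrt(5)/3
  expect_equal(nematic_order(c(0, 0, pi / 4)), sqrt(5) / 3, tolerance = 1e-12)
})

test_that("uniform input gives S = 1 at every node; disorder lowers S", {
  of <- order_parameter_field(build_director_grid(make_uniform_frame(0.3)))
  expect_true(all(abs(of$S - 1) < 1e-12))
  # isotropic orientations: S well below 1 everywhere on average
  sim <- generate_frame(synth_config(box = c(20, 20), n_cells = 400,
                                     kappa = 0, seed = 7))
  of0 <- order_parameter_field(build_director_grid(sim$frame))
  expect_lt(mean(of0$S), 0.5)
  expect_true(all(of0$S >= 0 & of0$S <= 1))
})

test_that("grid interpolation reproduces an ideal +1/2 defect field", {
  sim <- generate_frame(pair_config())
  g <- build_director_grid(sim$frame)
  # node-wise agreement with the analytic field away from both cores,
  # within a tolerance set by the smoothing window
  px <- rep(g$x, times = length(g$y))
  py <- rep(g$y, each = length(g$x))
  ref <- oracle_defect_field(px, py, list(c(5, 10), c(15, 10)), c(0.5, -0.5))
  r1 <- sqrt((px - 5)^2 + (py - 10)^2)
  r2 <- sqrt((px - 15)^2 + (py - 10)^2)
  far <- r1 > 3 & r2 > 3 & px > 2 & px < 18 & py > 2 & py < 18  # avoid cores and the periodic seam
  dev <- abs(wrap_half_pi_test(as.vector(g$theta)[far] - ref[far]))
  expect_lt(stats::quantile(dev, 0.95), 0.2)
  # winding of a grid-sampled ROI around the +1/2 core is +1/2
  roi <- extract_roi(g, c(5, 10))
  expect_equal(as.character(classify_roi_winding(roi)), "+1/2")
})


test_that("S is invariant under global rotation and head-tail relabeling", {
  set.seed(31)
  for (rep_i in 1:3) {
    th <- runif(40, 0, pi)
    alpha <- runif(1, 0, pi)
    flip <- sample(c(0, pi), 40, replace = TRUE)
    expect_equal(nematic_order(th), nematic_order(th + alpha), tolerance = 1e-12)
    expect_equal(nematic_order(th), nematic_order(th + flip), tolerance = 1e-12)
  }
  # whole-pipeline version: rotate every cell orientation by alpha
  sim <- generate_frame(pair_config(kappa = 8, seed = 13))
  fr <- sim$frame
  fr2 <- cell_frame(transform(fr$cells, theta = reduce_mod_pi(theta + 0.9)),
                    box = fr$box, periodic = TRUE)
  S1 <- order_parameter_field(build_director_grid(fr))$S
  S2 <- order_parameter_field(build_director_grid(fr2))$S
  expect_equal(S1, S2, tolerance = 1e-10)
})

test_that("degenerate inputs are rejected", {
  expect_error(cell_frame(data.frame(x = 1, y = 1, theta = 0), box = c(5, 5)),
               class = "nemadef_invalid_input")
  fr <- make_uniform_frame(0.3)
  expect_error(build_director_grid(fr, spacing = -1),
               class = "nemadef_parameter_error")
  expect_error(build_director_grid(fr, spacing = 1, window = 0.1),
               class = "nemadef_parameter_error")
  g <- build_director_grid(fr)
  expect_error(order_parameter_field(g, window = 1e-6),
               class = "nemadef_parameter_error")
})
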