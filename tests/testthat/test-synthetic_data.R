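# Synthetic frames, labelled ROIs and the planted velocity template.

test_that("ideal defect field evaluates analytically", {
  one <- data.frame(x = 0, y = 0, charge = 0.5)
  # +1/2 at origin, theta0 = 0, point at polar angle pi: theta = pi/2
  expect_equal(ideal_defect_angle(-3, 0, one), pi / 2)
  expect_equal(ideal_defect_angle(5, 0, one), 0)
  expect_error(ideal_defect_angle(0, 0, one), class = "nemadef_singular_point")
  # winding around a planted core recovers the planted charge
  for (q in c(0.5, -0.5)) {
    d <- data.frame(x = 1, y = -1, charge = q)
    phi <- seq(0, 2 * pi, length.out = 33)[-33]
    loop <- ideal_defect_angle(1 + 2 * cos(phi), -1 + 2 * sin(phi), d, phase = 0.7)
    expect_equal(attr(winding_charge(loop), "charge"), q, tolerance = 1e-9)
  }
})

test_that("frame generation is a pure function of its config", {
  cfg <- pair_config(kappa = 6, seed = 101, v0 = 1, sigma_v = 0.3)
  s1 <- generate_frame(cfg)
  s2 <- generate_frame(cfg)
  expect_identical(s1$frame$cells, s2$frame$cells)
  expect_identical(s1$truth, s2$truth)
  # the generator does not disturb the caller's RNG stream
  set.seed(1); a <- runif(1)
  set.seed(1); invisible(generate_frame(cfg)); b <- runif(1)
  expect_identical(a, b)
})

test_that("config invariants are enforced", {
  expect_error(synth_config(defects = data.frame(x = 5, y = 5, charge = 0.5),
                            periodic = TRUE),
               class = "nemadef_config_error")
  expect_error(synth_config(defects = data.frame(x = c(5, 5.5), y = c(5, 5),
                                                 charge = c(0.5, -0.5))),
               class = "nemadef_config_error")
  expect_error(synth_config(kappa = -1), class = "nemadef_config_error")
})

test_that("noise dial spans ordered to isotropic", {
  base <- synth_config(box = c(20, 20), n_cells = 400, kappa = Inf, seed = 7)
  S_inf <- mean(order_parameter_field(
    build_director_grid(generate_frame(base)$frame))$S)
  expect_gt(S_inf, 0.999)
  iso <- synth_config(box = c(20, 20), n_cells = 400, kappa = 0, seed = 7)
  S_0 <- mean(order_parameter_field(
    build_director_grid(generate_frame(iso)$frame))$S)
  expect_lt(S_0, 0.3)
})

test_that("planted charge is conserved on the domain boundary loop", {
  sim <- generate_frame(pair_config())
  g <- build_director_grid(sim$frame)
  # loop just inside the periodic box encloses both cores: net charge 0
  n <- length(g$x)
  ring <- boundary_loop(new_roi_test(g$theta))
  expect_identical(as.character(winding_charge(ring)), "none")
})

test_that("end-to-end: the pipeline recovers a planted pair", {
  sim <- generate_frame(pair_config(kappa = 20, seed = 8))
  rec <- detect_defects(sim$frame, method = "winding")
  expect_identical(nrow(rec), 2L)
  for (k in 1:2) {
    d <- sqrt((rec$x - sim$truth$x[k])^2 + (rec$y - sim$truth$y[k])^2)
    hit <- which.min(d)
    expect_identical(rec$class[hit], sim$truth$class[k])
    expect_lt(min(d), 1.5 * cell_diameter(sim$frame))
  }
})

test_that("labelled ROI datasets are balanced, seeded and label-faithful", {
  ds <- generate_labeled_rois(10, kappa = 8, seed = 5)
  expect_identical(dim(ds$theta), c(30L, 9L, 9L))
  expect_identical(as.vector(table(ds$label)), rep(10L, 3L))
  ds2 <- generate_labeled_rois(10, kappa = 8, seed = 5)
  expect_identical(ds$theta, ds2$theta)
  expect_identical(ds$meta, ds2$meta)
  # zero noise: winding classification equals the planted label exactly
  clean <- generate_labeled_rois(15, kappa = Inf, seed = 6)
  expect_true(all(winding_labels(clean) == clean$label))
  # no-defect ROIs never enclose a core at zero noise: far-field recipe only
  expect_true(all(clean$meta$recipe[clean$label == "none"] == "farfield"))
})

test_that("velocity template: core speed, mirror symmetry, rotation equivariance", {
  v <- defect_velocity_template(0, 0, psi = 0.7, v0 = 2)
  expect_equal(sqrt(sum(v^2)), 2, tolerance = 1e-12)
  expect_equal(atan2(v[2], v[1]), 0.7, tolerance = 1e-12)
  # psi = 0: mirror about the x axis flips vy, keeps vx
  set.seed(9)
  pts <- matrix(runif(40, -4, 4), ncol = 2)
  up <- defect_velocity_template(pts[, 1], pts[, 2])
  dn <- defect_velocity_template(pts[, 1], -pts[, 2])
  expect_equal(up[, 1], dn[, 1], tolerance = 1e-12)
  expect_equal(up[, 2], -dn[, 2], tolerance = 1e-12)
  # rotating psi by alpha rotates the whole template
  alpha <- 1.1
  rot <- cbind(cos(alpha) * pts[, 1] - sin(alpha) * pts[, 2],
               sin(alpha) * pts[, 1] + cos(alpha) * pts[, 2])
  va <- defect_velocity_template(rot[, 1], rot[, 2], psi = alpha)
  expect_equal(va[, 1], cos(alpha) * up[, 1] - sin(alpha) * up[, 2],
               tolerance = 1e-12)
  expect_equal(va[, 2], sin(alpha) * up[, 1] + cos(alpha) * up[, 2],
               tolerance = 1e-12)
})

test_that("accuracy is non-decreasing as noise falls", {
  kappas <- c(1, 6, 30)
  acc <- vapply(kappas, function(k) {
    ds <- generate_labeled_rois(100, kappa = k, seed = 300 + k)
    mean(winding_labels(ds) == ds$label)
  }, 0)
  # monotone in expectation; allow ~3 sigma of binomial noise at n = 300
  expect_true(all(diff(acc) >= -0.05))
  expect_gt(acc[3], acc[1])
})
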