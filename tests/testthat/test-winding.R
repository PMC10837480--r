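# Winding-number arithmetic and classification.

test_that("boundary loop walks the ROI perimeter counter-clockwise", {
  th <- matrix(seq(0, 3, length.out = 81) %% pi, 9, 9)
  loop <- boundary_loop(new_roi_test(th))
  expect_length(loop, 32L)                       # 4 * (9 - 1)
  expect_length(boundary_loop(new_roi_test(matrix(0.2, 3, 3))), 8L)
  # a uniform ROI gives a loop of identical angles
  expect_true(all(boundary_loop(new_roi_test(matrix(0.7, 9, 9))) == 0.7))
  # first element is the bottom-left corner, loop starts along the bottom edge
  expect_identical(loop[1], th[1, 1])
  expect_identical(loop[2], th[2, 1])
})


test_that("ideal loops give exact half-integer charges", {
  # theta(phi) = phi/2: rotates by pi around the loop -> charge +1/2
  lp <- oracle_loop(32, 1, list(c(0, 0)), 0.5)
  res <- winding_charge(lp)
  expect_identical(as.character(res), "+1/2")
  expect_equal(attr(res, "rotation"), pi, tolerance = 1e-12)
  # theta(phi) = -phi/2 + theta0 for several theta0 -> -1/2
  for (th0 in c(0, 0.4, 1.3, 2.9)) {
    lm <- oracle_loop(32, 1, list(c(0, 0)), -0.5, theta0 = th0)
    expect_identical(as.character(winding_charge(lm)), "-1/2")
  }
  expect_identical(as.character(winding_charge(rep(0.3, 32))), "none")
})

test_that("total rotation is always an integer multiple of pi", {
  set.seed(11)
  for (i in 1:20) {
    loop <- runif(sample(8:40, 1), 0, pi)
    t_over_pi <- attr(winding_charge(loop), "rotation") / pi
    expect_equal(t_over_pi, round(t_over_pi), tolerance = 1e-9)
  }
})

test_that("charge is invariant to loop start, global offset and relabeling; reversal negates", {
  set.seed(12)
  lp <- oracle_loop(32, 1, list(c(0, 0)), 0.5, theta0 = 0.8)
  k0 <- attr(winding_charge(lp), "charge")
  for (i in 1:5) {
    s <- sample(32, 1)
    cyc <- c(lp[s:32], lp[seq_len(s - 1)])
    off <- (lp + runif(1, 0, pi)) %% pi
    flip <- (lp + sample(c(0, pi), 32, replace = TRUE)) %% pi
    expect_equal(attr(winding_charge(cyc), "charge"), k0, tolerance = 1e-9)
    expect_equal(attr(winding_charge(off), "charge"), k0, tolerance = 1e-9)
    expect_equal(attr(winding_charge(flip), "charge"), k0, tolerance = 1e-9)
  }
  expect_equal(attr(winding_charge(rev(lp)), "charge"), -k0, tolerance = 1e-9)
})

test_that("charges add: a loop enclosing a +1/2 and a -1/2 pair winds to zero", {
  cores <- list(c(-2, 0), c(2, 0))
  both <- oracle_loop(64, 6, cores, c(0.5, -0.5))
  expect_identical(as.character(winding_charge(both)), "none")
  only_p <- oracle_loop(64, 1, cores, c(0.5, -0.5), center = c(-2, 0))
  expect_identical(as.character(winding_charge(only_p)), "+1/2")
  # agreement with the independent complex-phase accumulator
  expect_equal(attr(winding_charge(both), "charge"), oracle_winding(both),
               tolerance = 1e-9)
  expect_equal(attr(winding_charge(only_p), "charge"), oracle_winding(only_p),
               tolerance = 1e-9)
})

test_that("classification is invariant under quarter-turn ROI rotation", {
  sim <- generate_frame(pair_config(kappa = 8, seed = 21))
  g <- build_director_grid(sim$frame)
  for (core in list(c(5, 10), c(15, 10))) {
    roi <- extract_roi(g, core)
    lab0 <- as.character(classify_roi_winding(roi))
    arr <- array(roi$theta, dim = c(1L, 9L, 9L))
    for (q in 1:3) {
      rot <- nemadef:::rot_patch(arr, q)
      expect_identical(as.character(classify_roi_winding(new_roi_test(rot[1, , ]))),
                       lab0)
    }
  }
})

test_that("on-lattice detection finds planted cores at lattice resolution", {
  sim <- generate_frame(pair_config())
  g <- build_director_grid(sim$frame)
  # uniform field: no detections anywhere
  uni <- generate_frame(synth_config(box = c(15, 15), n_cells = 225,
                                     kappa = Inf, seed = 3))
  gu <- build_director_grid(uni$frame)
  expect_identical(nrow(classify_on_lattice(gu, 2)), 0L)
  for (spacing in c(1.5, 3)) {
    rec <- classify_on_lattice(g, spacing)
    for (k in 1:2) {
      d <- sqrt((rec$x - sim$truth$x[k])^2 + (rec$y - sim$truth$y[k])^2)
      hit <- which.min(d)
      expect_identical(rec$class[hit], sim$truth$class[k])
      # positional error bounded by half the lattice diagonal
      expect_lte(min(d), spacing / sqrt(2) + 1e-9)
    }
  }
})
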