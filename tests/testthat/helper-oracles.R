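# Independent reference implementations used as oracles. These are kept
# deliberately separate from the package internals: the analytic defect
# field is re-derived from the polar-angle definition, and the reference
# winding accumulates phase through complex double-angle ratios rather
# than wrapped real differences.

# Analytic director of point defects: theta = sum_j k_j * phi_j + theta0.
oracle_defect_field <- function(px, py, cores, charges, theta0 = 0) {
  th <- rep(theta0, length(px))
  for (j in seq_along(charges)) {
    th <- th + charges[j] * atan2(py - cores[[j]][2], px - cores[[j]][1])
  }
  th %% pi
}

# Reference winding: phase of the complex ratio e^{2i theta_{k+1}} /
# e^{2i theta_k} accumulated around the closed loop, halved.
oracle_winding <- function(thetas) {
  z <- exp(2i * thetas)
  z2 <- c(z[-1], z[1])
  sum(Arg(z2 / z)) / 2 / (2 * pi)
}

# Sample a loop of directors from an analytic field on a circle of radius
# r around a centre.
oracle_loop <- function(n, r, cores, charges, theta0 = 0, center = c(0, 0)) {
  phi <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  oracle_defect_field(center[1] + r * cos(phi), center[2] + r * sin(phi),
                      cores, charges, theta0)
}

# Minimal ROI construction for synthetic patches.
new_roi_test <- function(th) structure(list(theta = th), class = "defect_roi")

# Local copy of the director-increment wrap for test arithmetic.
wrap_half_pi_test <- function(d) {
  m <- d %% pi
  m[m > pi / 2] <- m[m > pi / 2] - pi
  m
}

# Small noise-free frame with one +1/2 and one -1/2 core, shared by
# several module tests.
pair_config <- function(kappa = Inf, seed = 42L, v0 = 0, sigma_v = 0) {
  synth_config(box = c(20, 20), n_cells = 400,
               defects = data.frame(x = c(5, 15), y = c(10, 10),
                                    charge = c(0.5, -0.5)),
               kappa = kappa, jitter = 0.1, v0 = v0, sigma_v = sigma_v,
               periodic = TRUE, seed = seed)
}

# Winding-number classification of every ROI in a dataset, with `other`
# mapped to `none` for three-class comparison.
winding_labels <- function(dataset) {
  n <- dim(dataset$theta)[1]
  out <- vapply(seq_len(n), function(i) {
    as.character(classify_roi_winding(dataset_roi(dataset, i)))
  }, "")
  out[out == "other"] <- "none"
  factor(out, levels = defect_classes())
}
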