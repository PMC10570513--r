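# Shared fixtures: small hinge configurations and independent oracle
# implementations kept deliberately separate from the package internals.

unitize <- function(v) v / sqrt(sum(v * v))

fixture_axes <- function() {
  list(j1 = unitize(c(0.2, -0.5, 0.8)), j2 = unitize(c(0.9, 0.1, -0.3)),
       o1 = c(0.15, 0.02, -0.03), o2 = c(-0.12, 0.04, 0.02))
}

quick_hinge <- function(duration = 15, seed = NULL, motion = "walking", ...) {
  ax <- fixture_axes()
  simulate_hinge(hinge_sim_config(
    duration = duration, rate = 60,
    true_axis_1 = ax$j1, true_axis_2 = ax$j2,
    true_center_1 = ax$o1, true_center_2 = ax$o2,
    motion = motion, seed = seed, ...))
}

# independent oracles (plain arithmetic, no package helpers)
oracle_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

oracle_axis_residuals <- function(g1, g2, j1, j2) {
  vapply(seq_len(nrow(g1)), function(k) {
    sqrt(sum(oracle_cross(g1[k, ], j1)^2)) -
      sqrt(sum(oracle_cross(g2[k, ], j2)^2))
  }, numeric(1))
}

oracle_gamma <- function(g, gd, o) {
  oracle_cross(g, oracle_cross(g, o)) + oracle_cross(gd, o)
}

oracle_center_residuals <- function(a1, a2, g1, g2, gd1, gd2, o1, o2) {
  vapply(seq_len(nrow(a1)), function(k) {
    sqrt(sum((a1[k, ] - oracle_gamma(g1[k, ], gd1[k, ], o1))^2)) -
      sqrt(sum((a2[k, ] - oracle_gamma(g2[k, ], gd2[k, ], o2))^2))
  }, numeric(1))
}

angle_between_deg <- function(a, b) {
  acos(min(1, abs(sum(a * b) / sqrt(sum(a^2) * sum(b^2))))) * 180 / pi
}

# tiny cycle dataset built directly (no simulator) for model-level tests
toy_cycle_dataset <- function(n_subjects = 4, strides = 4, seed = 11) {
  set.seed(seed)
  grid <- seq(0, 100, by = 1)
  rows <- list()
  pk <- list(lp = 1.1, lp_t = 14, mp = 0.8, mp_t = 30, tp = 1.05, tp_t = 46,
             stance_end = 62)
  for (s in seq_len(n_subjects)) for (k in seq_len(strides)) {
    d <- data.frame(subject = s, speed = 2.5, stride = k, cycle_pct = grid)
    d$hip_angle <- 20 * cos(2 * pi * grid / 100) + rnorm(101, sd = 0.5)
    d$knee_angle <- 30 * sin(2 * pi * grid / 100 + 1) + rnorm(101, sd = 0.5)
    d$ankle_angle <- 8 * sin(4 * pi * grid / 100) + rnorm(101, sd = 0.5)
    d$hip_velocity <- 100 * sin(2 * pi * grid / 100) + rnorm(101, sd = 2)
    d$knee_velocity <- 150 * cos(2 * pi * grid / 100 + 1) + rnorm(101, sd = 2)
    d$ankle_velocity <- 60 * cos(4 * pi * grid / 100) + rnorm(101, sd = 2)
    d$a_vert <- 1.5 * sin(4 * pi * grid / 100) + rnorm(101, sd = 0.1)
    d$vgrf <- vgrf_template(grid, pk) + rnorm(101, sd = 0.01) * (grid <= 62)
    rows[[length(rows) + 1]] <- d
  }
  out <- do.call(rbind, rows)
  class(out) <- c("cycle_dataset", "data.frame")
  out
}
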