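test_that("spherical parameterization produces unit vectors", {
  expect_equal(spherical_to_unit(0, 0), c(1, 0, 0))
  expect_equal(spherical_to_unit(pi / 2, 1.3), c(0, 0, 1),
               tolerance = 1e-12)
  set.seed(1)
  for (k in 1:20) {
    v <- spherical_to_unit(runif(1, -pi / 2, pi / 2), runif(1, -pi, pi))
    expect_equal(sum(v^2), 1, tolerance = 1e-12)
    sp <- unit_to_spherical(v)
    expect_equal(spherical_to_unit(sp[1], sp[2]), v, tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})

test_that("gamma_accel reproduces centripetal and tangential terms", {
  expect_equal(gamma_accel(c(0, 0, 1), c(0, 0, 0), c(1, 0, 0)), c(-1, 0, 0))
  expect_equal(gamma_accel(c(0, 0, 0), c(0, 0, 2), c(1, 0, 0)), c(0, 2, 0))
})

test_that("gamma_accel matches a finite-difference rigid-body oracle", {
  # a point at offset o from a fixed centre, rotating with Omega(t):
  # its acceleration must equal Gamma evaluated with the local rates
  dt <- 1e-5
  ts <- seq(0, 1, by = dt)
  axis <- unitize(c(0.3, -0.8, 0.52))
  angle <- function(t) 0.9 * sin(2 * pi * 0.8 * t) + 0.4 * t
  o <- c(0.2, -0.1, 0.15)
  rot <- function(t) {
    th <- angle(t)
    k <- axis
    K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
    diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  }
  t0 <- 0.4
  pos <- function(t) drop(rot(t) %*% o)
  acc_num <- (pos(t0 + dt) - 2 * pos(t0) + pos(t0 - dt)) / dt^2
  # local angular rate and acceleration for rotation about a fixed axis
  thd <- (angle(t0 + dt) - angle(t0 - dt)) / (2 * dt)
  thdd <- (angle(t0 + dt) - 2 * angle(t0) + angle(t0 - dt)) / dt^2
  g_loc <- drop(t(rot(t0)) %*% (thd * axis))
  gd_loc <- drop(t(rot(t0)) %*% (thdd * axis))
  acc_local <- gamma_accel(g_loc, gd_loc, o)
  expect_equal(drop(rot(t0) %*% acc_local), acc_num, tolerance = 1e-4)
})

test_that("axis and centre residuals match brute-force oracles", {
  sim <- quick_hinge(duration = 5, seed = 3, gyro_noise_sd = 0.02,
                     accel_noise_sd = 0.2)
  s1 <- sim$stream1; s2 <- sim$stream2
  set.seed(8)
  for (k in 1:5) {
    sp <- runif(4, -1.5, 1.5)
    mine <- axis_residuals(s1, s2, sp[1], sp[2], sp[3], sp[4])
    oj1 <- spherical_to_unit(sp[1], sp[2]); oj2 <- spherical_to_unit(sp[3], sp[4])
    expect_lt(max(abs(mine - oracle_axis_residuals(s1$gyro, s2$gyro,
                                                   oj1, oj2))), 1e-12)
    o1 <- rnorm(3, sd = 0.2); o2 <- rnorm(3, sd = 0.2)
    gd1 <- imugait:::central_diff(s1$gyro, s1$time)
    gd2 <- imugait:::central_diff(s2$gyro, s2$time)
    mine2 <- center_residuals(s1, s2, o1, o2)
    expect_lt(max(abs(mine2 - oracle_center_residuals(
      s1$accel, s2$accel, s1$gyro, s2$gyro, gd1, gd2, o1, o2))), 1e-12)
  }
})

test_that("residuals vanish for identical streams and symmetric parameters", {
  sim <- quick_hinge(duration = 5, seed = 2)
  s1 <- sim$stream1
  sp <- unit_to_spherical(c(0, 1, 0))
  expect_equal(max(abs(axis_residuals(s1, s1, sp[1], sp[2], sp[1], sp[2]))), 0)
  expect_equal(max(abs(center_residuals(s1, s1, c(0, 0, 0), c(0, 0, 0)))), 0)
})

test_that("axes are recovered to high accuracy", {
  ax <- fixture_axes()
  sim <- quick_hinge(duration = 20)
  fit <- estimate_joint_axes(sim$stream1, sim$stream2)
  expect_lt(angle_between_deg(fit$j1, ax$j1), 0.5)
  expect_lt(angle_between_deg(fit$j2, ax$j2), 0.5)
  # noisy recovery within 2 degrees
  for (s in 1:5) {
    simn <- quick_hinge(duration = 60, seed = 100 + s, gyro_noise_sd = 0.01)
    fitn <- estimate_joint_axes(simn$stream1, simn$stream2)
    expect_lt(angle_between_deg(fitn$j1, ax$j1), 2)
    expect_lt(angle_between_deg(fitn$j2, ax$j2), 2)
  }
})

test_that("optimizer beats a randomized parameter search on a small record", {
  sim <- quick_hinge(duration = 200 / 60, seed = 5, gyro_noise_sd = 0.02)
  fit <- estimate_joint_axes(sim$stream1, sim$stream2)
  set.seed(17)
  sse <- replicate(4000, {
    sp <- c(runif(2, -pi / 2, pi / 2), runif(2, -pi, pi))[c(1, 3, 2, 4)]
    sum(axis_residuals(sim$stream1, sim$stream2,
                       sp[1], sp[2], sp[3], sp[4])^2)
  })
  expect_lte(fit$sse, min(sse) * (1 + 1e-8))
})

test_that("centres are recovered and the axis component is projected out", {
  ax <- fixture_axes()
  sim <- quick_hinge(duration = 20, motion = "circling")
  fit <- estimate_joint_centers(sim$stream1, sim$stream2, ax$j1, ax$j2,
                                gdot1 = sim$truth$clean$gyro_dot1,
                                gdot2 = sim$truth$clean$gyro_dot2)
  proj <- function(o, j) o - sum(o * j) * j
  expect_lt(sqrt(sum((fit$o1 - proj(ax$o1, ax$j1))^2)), 0.005)
  expect_lt(sqrt(sum((fit$o2 - proj(ax$o2, ax$j2))^2)), 0.005)
  expect_lt(abs(sum(fit$o1 * ax$j1)), 1e-9)
  expect_lt(abs(sum(fit$o2 * ax$j2)), 1e-9)
  # noisy data: fitted objective no worse than at the true centres
  simn <- quick_hinge(duration = 20, motion = "circling", seed = 31,
                      gyro_noise_sd = 0.01, accel_noise_sd = 0.1)
  fitn <- estimate_joint_centers(simn$stream1, simn$stream2, ax$j1, ax$j2)
  sse_truth <- sum(center_residuals(simn$stream1, simn$stream2,
                                    ax$o1, ax$o2)^2)
  expect_lte(fitn$sse, sse_truth * (1 + 1e-8))
})

test_that("centre solutions are degenerate under a common axis slide", {
  # both offsets sliding to the same new point on the hinge axis leave the
  # objective at zero; the canonical (projected) offsets are slide-invariant
  ax <- fixture_axes()
  sim <- quick_hinge(duration = 5, motion = "circling")
  for (s in c(-0.3, 0.1, 0.5)) {
    shifted <- sum(center_residuals(sim$stream1, sim$stream2,
                                    ax$o1 + s * ax$j1, ax$o2 + s * ax$j2,
                                    sim$truth$clean$gyro_dot1,
                                    sim$truth$clean$gyro_dot2)^2)
    expect_lt(shifted, 1e-18)
    proj <- function(o, j) o - sum(o * j) * j
    expect_equal(proj(ax$o1 + s * ax$j1, ax$j1), proj(ax$o1, ax$j1))
  }
})

test_that("axis objective is sign-invariant and signs are resolved", {
  sim <- quick_hinge(duration = 10, seed = 12, gyro_noise_sd = 0.005)
  ax <- fixture_axes()
  sse <- function(j1, j2) {
    s1 <- unit_to_spherical(j1); s2 <- unit_to_spherical(j2)
    sum(axis_residuals(sim$stream1, sim$stream2, s1[1], s1[2],
                       s2[1], s2[2])^2)
  }
  expect_equal(sse(ax$j1, ax$j2), sse(-ax$j1, ax$j2), tolerance = 1e-10)
  expect_equal(sse(ax$j1, ax$j2), sse(ax$j1, -ax$j2), tolerance = 1e-10)

  r <- resolve_axis_sign(c(-1, 0, 0), ax$j2, sim$stream1, sim$stream2)
  expect_equal(r$j1, c(1, 0, 0))
  a <- resolve_axis_sign(ax$j1, ax$j2, sim$stream1, sim$stream2)
  b <- resolve_axis_sign(-ax$j1, -ax$j2, sim$stream1, sim$stream2)
  expect_equal(a$j1, b$j1)
  expect_equal(a$j2, b$j2)
})

test_that("static data is rejected as insufficient excitation", {
  n <- 600
  t <- seq(0, by = 1 / 60, length.out = n)
  still <- imu_stream(t, matrix(rnorm(3 * n, sd = 0.001), n, 3),
                      matrix(rep(c(0, 0, 9.81), each = n), n, 3))
  expect_error(estimate_joint_axes(still, still), "excitation")
  expect_error(estimate_joint_centers(still, still, c(0, 0, 1), c(0, 0, 1)),
               "excitation|degenerate")
})
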