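test_that("gyro angle integrates the axis-projected rate difference", {
  n <- 601
  t <- seq(0, 10, length.out = n)
  j <- c(0, 0, 1)
  g1 <- cbind(0, 0, rep(0.1, n))
  g2 <- matrix(0, n, 3)
  a <- matrix(rep(c(0, 0, 9.81), each = n), n, 3)
  s1 <- imu_stream(t, g1, a); s2 <- imu_stream(t, g2, a)
  ang <- gyro_angle(s1, s2, j, j)
  expect_equal(ang[n], 1 * 180 / pi, tolerance = 1e-10)
  expect_equal(gyro_angle(s2, s2, j, j), rep(0, n))
})

test_that("gyro bias along the axis drifts the integrated angle linearly", {
  ax <- fixture_axes()
  sim <- quick_hinge(duration = 30, seed = 6, gyro_bias = 0.01 * ax$j1)
  ang <- gyro_angle(sim$stream1, sim$stream2, ax$j1, ax$j2)
  clean <- sim$truth$angle_deg - sim$truth$angle_deg[1]
  drift <- ang[length(ang)] - clean[length(clean)]
  expect_equal(drift, 0.01 * 30 * 180 / pi, tolerance = 0.15)
})

test_that("acceleration shifting recovers the joint-centre acceleration", {
  sim <- quick_hinge(duration = 10)
  tr <- sim$truth
  at1 <- shift_accelerations(sim$stream1, tr$geometry$o1,
                             gdot = tr$clean$gyro_dot1)
  at2 <- shift_accelerations(sim$stream2, tr$geometry$o2,
                             gdot = tr$clean$gyro_dot2)
  # both equal the joint-centre specific force in their own frames: norms agree
  expect_lt(max(abs(sqrt(rowSums(at1^2)) - sqrt(rowSums(at2^2)))), 1e-12)
  # o = 0 is the identity
  expect_equal(shift_accelerations(sim$stream1, c(0, 0, 0)),
               sim$stream1$accel)
  # static stream: Gamma = 0 regardless of o
  n <- 200; t <- seq(0, by = 1 / 60, length.out = n)
  acc <- matrix(rep(c(0, 1, 9.7), each = n), n, 3)
  still <- imu_stream(t, matrix(0, n, 3), acc)
  expect_equal(shift_accelerations(still, c(0.4, -0.2, 0.1)), acc)
})

test_that("joint-plane axes are orthogonal and auto-selection works", {
  p <- joint_plane_axes(c(0, 0, 1), c(1, 0, 0))
  expect_equal(p$x, c(0, 1, 0))
  expect_equal(p$y, c(-1, 0, 0))  # j x x
  set.seed(4)
  for (k in 1:10) {
    j <- unitize(rnorm(3)); c0 <- rnorm(3)
    if (sqrt(sum((j * sum(j * c0) - c0)^2)) < 1e-3) next
    q <- joint_plane_axes(j, c0)
    expect_lt(abs(sum(q$x * j)), 1e-12)
    expect_lt(abs(sum(q$y * j)), 1e-12)
    expect_lt(abs(sum(q$x * q$y)), 1e-12)
  }
  auto <- joint_plane_axes(c(0.99, 0.1, 0.1))
  expect_equal(auto$c, c(0, 1, 0))  # smallest |j . e|
  expect_error(joint_plane_axes(c(0, 0, 1), c(0, 0, 2)), "parallel")
})

test_that("accelerometer angle tracks the true joint angle", {
  # symmetric mounting (j1 = j2) makes the constant offset zero
  j <- unitize(c(0.3, 0.9, 0.1))
  sim <- simulate_hinge(hinge_sim_config(
    duration = 20, rate = 60, true_axis_1 = j, true_axis_2 = j,
    true_center_1 = c(0.1, 0, -0.05), true_center_2 = c(-0.1, 0.02, 0.05)))
  at1 <- shift_accelerations(sim$stream1, c(0.1, 0, -0.05),
                             gdot = sim$truth$clean$gyro_dot1)
  at2 <- shift_accelerations(sim$stream2, c(-0.1, 0.02, 0.05),
                             gdot = sim$truth$clean$gyro_dot2)
  aa <- accel_angle(at1, at2, j, j)
  d <- aa - sim$truth$angle_deg
  d <- d - round(mean(d) / 360) * 360
  expect_lt(max(abs(d)), 0.1)
})

test_that("accelerometer angle is invariant to the plane reference", {
  sim <- quick_hinge(duration = 10)
  ax <- fixture_axes()
  at1 <- shift_accelerations(sim$stream1, ax$o1, sim$truth$clean$gyro_dot1)
  at2 <- shift_accelerations(sim$stream2, ax$o2, sim$truth$clean$gyro_dot2)
  a1 <- accel_angle(at1, at2, ax$j1, ax$j2, c = c(1, 0, 0))
  a2 <- accel_angle(at1, at2, ax$j1, ax$j2, c = c(0.2, 1, -0.4))
  d <- (a1 - a2) - mean(a1 - a2)
  expect_lt(max(abs(d)), 1e-6)
})

test_that("complementary filter collapses and converges correctly", {
  aa <- rep(10, 100); ag <- rep(0, 100)
  expect_equal(fuse_angles(aa, ag, lambda = 1), aa)
  # constant sources: geometric approach to the accel angle
  f <- fuse_angles(c(0, rep(10, 99)), ag, lambda = 0.1)
  resid <- 10 - f
  ratio <- resid[3:50] / resid[2:49]
  expect_equal(ratio, rep(0.9, 48), tolerance = 1e-10)
  expect_error(fuse_angles(aa, ag, lambda = 1.5), "lambda")
  expect_error(fuse_angles(aa, ag[1:10]), "length")
})

test_that("fusion stays bounded under gyro bias on a long record", {
  ax <- fixture_axes()
  sim <- quick_hinge(duration = 600, seed = 15, gyro_noise_sd = 0.01,
                     accel_noise_sd = 0.1, gyro_bias = 0.01 * ax$j1)
  ang <- joint_angles(sim$stream1, sim$stream2,
                      c(ax, list(joint = "sim")))
  gyro_err <- abs(ang$alpha_gyr -
                    (sim$truth$angle_deg - sim$truth$angle_deg[1]))
  tail_idx <- sim$truth$time > 500
  expect_gt(median(gyro_err[tail_idx]), 100)  # pure gyro has drifted away
  al <- align_angle_convention(ang$alpha, sim$truth$angle_deg)
  expect_lt(max(abs(al - sim$truth$angle_deg)[tail_idx]), 5)
})

test_that("fused angle has the ground-truth sign after axis-sign resolution", {
  sim <- quick_hinge(duration = 30, seed = 44, gyro_noise_sd = 0.005,
                     accel_noise_sd = 0.05)
  ax <- estimate_joint_axes(sim$stream1, sim$stream2)
  sg <- resolve_axis_sign(ax$j1, ax$j2, sim$stream1, sim$stream2)
  ce <- estimate_joint_centers(sim$stream1, sim$stream2, sg$j1, sg$j2)
  ang <- joint_angles(sim$stream1, sim$stream2,
                      c(sg, ce[c("o1", "o2")], list(joint = "sim")))
  expect_gt(abs(cor(ang$alpha, sim$truth$angle_deg)), 0.99)
})

test_that("angular velocity differentiates within passband accuracy", {
  rate <- 60
  t <- seq(0, 10, by = 1 / rate)
  ramp <- 3 * t
  v <- angular_velocity(ramp, rate)
  core <- seq(30, length(v) - 30)
  expect_lt(max(abs(v[core] - 3)) / 3, 0.01)
  sine <- 5 * sin(2 * pi * 1 * t)
  vs <- angular_velocity(sine, rate)
  expect_lt(abs(max(vs[core]) - 5 * 2 * pi) / (5 * 2 * pi), 0.02)
  expect_equal(angular_velocity(rep(2, length(t)), rate),
               rep(0, length(t)), tolerance = 1e-9)
})

test_that("vertical acceleration removes gravity through orientation", {
  n <- 300
  t <- seq(0, by = 1 / 60, length.out = n)
  # stationary sensor at an arbitrary fixed orientation
  R <- imugait:::rot_axis_angle(c(0.3, 0.8, 0.52), 1.1)
  q <- imugait:::rotmat_to_quat(R)
  f_local <- drop(t(R) %*% c(0, 0, 9.81))
  s <- imu_stream(t, matrix(0, n, 3),
                  matrix(rep(f_local, each = n), n, 3),
                  quat = matrix(rep(q, each = n), n, 4))
  va <- vertical_acceleration(s)
  expect_lt(max(abs(va$a_vert)), 1e-10)
  # free fall: zero specific force reads -9.81
  ff <- imu_stream(t, matrix(0, n, 3), matrix(0, n, 3),
                   quat = matrix(rep(c(1, 0, 0, 0), each = n), n, 4))
  expect_equal(vertical_acceleration(ff)$a_vert, rep(-9.81, n))
  # vertical sinusoid: amplitude recovered within 2%
  A <- 0.02; f0 <- 1.5
  z <- A * sin(2 * pi * f0 * t)
  acc <- -A * (2 * pi * f0)^2 * sin(2 * pi * f0 * t)
  sv <- imu_stream(t, matrix(0, n, 3), cbind(0, 0, acc + 9.81),
                   quat = matrix(rep(c(1, 0, 0, 0), each = n), n, 4))
  got <- vertical_acceleration(sv)$a_vert
  expect_lt(abs(max(abs(got)) - A * (2 * pi * f0)^2) /
              (A * (2 * pi * f0)^2), 0.02)
  expect_error(vertical_acceleration(quick_hinge(duration = 3)$stream1),
               "orientation")
})
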