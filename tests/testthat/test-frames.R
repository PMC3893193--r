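test_that("rotation matrix handles identity and quarter-turn cases", {
  expect_equal(rotation_matrix(orientation()), diag(3))
  # pure 90 deg yaw takes the body x axis onto the tunnel y axis
  R <- rotation_matrix(orientation(yaw = 90))
  expect_equal(drop(R %*% c(1, 0, 0)), c(0, 1, 0), tolerance = 1e-12)
  # nose-up pitch lifts the nose (z is down, so up is negative z)
  R <- rotation_matrix(orientation(pitch = 30))
  expect_lt((R %*% c(1, 0, 0))[3], 0)
})

test_that("rotation matrix equals the explicit three-matrix product", {
  phi <- 10 * pi / 180; al <- 35 * pi / 180; ps <- -20 * pi / 180
  Rx <- rbind(c(1, 0, 0), c(0, cos(phi), -sin(phi)), c(0, sin(phi), cos(phi)))
  Ry <- rbind(c(cos(al), 0, sin(al)), c(0, 1, 0), c(-sin(al), 0, cos(al)))
  Rz <- rbind(c(cos(ps), -sin(ps), 0), c(sin(ps), cos(ps), 0), c(0, 0, 1))
  expect_equal(rotation_matrix(orientation(10, 35, -20)), Rz %*% Ry %*% Rx,
               tolerance = 1e-14)
})

test_that("composition order is pinned for a non-commuting triple", {
  # frozen regression values: yaw(-20) o pitch(35) o roll(10)
  expected <- matrix(c(0.769751131320, -0.280166499593, -0.573576436351,
                       0.430417946459, 0.891351200113, 0.142244259723,
                       0.471405968564, -0.356370271717, 0.806707284112),
                     3, 3)
  expect_equal(rotation_matrix(orientation(10, 35, -20)), expected,
               tolerance = 1e-10)
  # the reversed composition (roll o pitch o yaw) differs: the order
  # genuinely matters for this triple
  reversed <- rotation_matrix(orientation(10, 0, 0)) %*%
    rotation_matrix(orientation(0, 35, 0)) %*%
    rotation_matrix(orientation(0, 0, -20))
  expect_gt(max(abs(reversed - expected)), 1e-3)
})

test_that("rotation matrices are orthonormal with det +1 everywhere", {
  set.seed(11)
  for (k in 1:25) {
    o <- orientation(roll = stats::runif(1, -180, 180),
                     pitch = stats::runif(1, -90, 180),
                     yaw = stats::runif(1, -180, 180))
    R <- rotation_matrix(o)
    expect_equal(t(R) %*% R, diag(3), tolerance = 1e-12)
    expect_equal(det(R), 1, tolerance = 1e-12)
  }
})

test_that("frame transforms agree with the quaternion oracle", {
  set.seed(12)
  for (k in 1:20) {
    o <- orientation(roll = stats::runif(1, -180, 180),
                     pitch = stats::runif(1, -90, 180),
                     yaw = stats::runif(1, -180, 180))
    v <- stats::rnorm(3); m <- stats::rnorm(3)
    w <- to_tunnel_frame(wrench(v, m), o)
    expect_equal(w$force, quat_rotate(v, o$roll, o$pitch, o$yaw),
                 tolerance = 1e-12)
    expect_equal(w$moment, quat_rotate(m, o$roll, o$pitch, o$yaw),
                 tolerance = 1e-12)
  }
})

test_that("tunnel-frame transform preserves norms and round-trips", {
  set.seed(13)
  for (k in 1:10) {
    o <- orientation(roll = stats::runif(1, -180, 180),
                     pitch = stats::runif(1, -90, 180),
                     yaw = stats::runif(1, -180, 180))
    w0 <- wrench(stats::rnorm(3), stats::rnorm(3))
    w1 <- to_tunnel_frame(w0, o)
    expect_equal(sqrt(sum(w1$force^2)), sqrt(sum(w0$force^2)),
                 tolerance = 1e-12)
    expect_equal(sqrt(sum(w1$moment^2)), sqrt(sum(w0$moment^2)),
                 tolerance = 1e-12)
    w2 <- to_sensor_frame(w1, o)
    expect_equal(w2$force, w0$force, tolerance = 1e-12)
    expect_equal(w2$moment, w0$moment, tolerance = 1e-12)
  }
  expect_equal(to_tunnel_frame(wrench(1:3, 4:6), orientation())$force,
               as.numeric(1:3))
})

test_that("frame tags are enforced and bad angles rejected", {
  w <- wrench(c(1, 0, 0))
  wt <- to_tunnel_frame(w, orientation())
  expect_error(to_tunnel_frame(wt, orientation()), "already")
  expect_error(to_sensor_frame(w, orientation()), "already")
  expect_error(orientation(pitch = NaN), "finite")
  expect_error(orientation(pitch = 200), "pitch")
  expect_error(orientation(yaw = 500), "-180")
})

test_that("recording averages reduce to mean and n-1 sd", {
  constant <- as.data.frame(matrix(2, nrow = 5, ncol = 6,
                                   dimnames = list(NULL, c("Fx", "Fy", "Fz",
                                                           "Mx", "My", "Mz"))))
  avg <- average_recording(recording(constant))
  expect_equal(avg$mean$force, rep(2, 3))
  expect_equal(unname(avg$sd), rep(0, 6))

  two <- constant[1:2, ]; two$Fx <- c(0, 2)
  avg2 <- average_recording(recording(two))
  expect_equal(avg2$mean$force[1], 1)
  expect_equal(unname(avg2$sd["Fx"]), sqrt(2))

  # order invariance
  set.seed(14)
  s <- as.data.frame(matrix(stats::rnorm(600), ncol = 6,
                            dimnames = list(NULL, names(constant))))
  a1 <- average_recording(recording(s))
  a2 <- average_recording(recording(s[sample(nrow(s)), ]))
  expect_equal(a1$mean$force, a2$mean$force)
  expect_equal(a1$sd, a2$sd)

  expect_error(recording(s[0, ]), ">= 1 sample")
})

test_that("white-noise recording mean lies within the CLT band", {
  set.seed(15)
  n <- 4000; mu <- 0.37; sd <- 0.05
  s <- as.data.frame(matrix(stats::rnorm(6 * n, mu, sd), ncol = 6,
                            dimnames = list(NULL, c("Fx", "Fy", "Fz",
                                                    "Mx", "My", "Mz"))))
  avg <- average_recording(recording(s))
  expect_true(all(abs(c(avg$mean$force, avg$mean$moment) - mu) <
                    4 * sd / sqrt(n)))
})

test_that("Reynolds number follows U * lambda / nu", {
  expect_equal(reynolds_number(tunnel_conditions(U = 1, rho = 1, nu = 1), 1), 1)
  expect_equal(reynolds_number(tunnel_conditions(U = 6, nu = 1.5e-5), 0.08),
               32000)
  c1 <- tunnel_conditions(U = 4); c2 <- tunnel_conditions(U = 8)
  expect_equal(reynolds_number(c2, 0.08), 2 * reynolds_number(c1, 0.08))
  expect_error(reynolds_number(c1, -1), "positive")
})
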