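quiet_cfg <- function(posture = "tent")
  preset_config(posture, noise_force_sd = 0, noise_moment_sd = 0,
                misalign_sd = 0)

test_that("flat-plate closure has the right endpoints and lever arms", {
  cfg <- glider_config(list(
    glider_surface("s", area_frac = 0.4, x_arm = 0.6)),
    A = 2, B = 1.4, CD0 = 0.1)
  surf <- cfg$surfaces[[1]]
  at0 <- surface_coefficients(surf, cfg, alpha = 0)
  expect_equal(at0[["CL"]], 0)
  expect_equal(at0[["CD"]], 0.4 * 0.1)        # parasitic only
  at90 <- surface_coefficients(surf, cfg, alpha = 90)
  expect_equal(at90[["CL"]], 0, tolerance = 1e-15)
  expect_equal(at90[["CD"]], 0.4 * (0.1 + 1.4))  # drag maximal
  # moment = force x arm for a single off-CoM surface (hand lever oracle)
  at30 <- surface_coefficients(surf, cfg, alpha = 30)
  lift_hand <- 0.4 * 2 * sin(pi / 6) * cos(pi / 6)
  expect_equal(at30[["CL"]], lift_hand, tolerance = 1e-12)
  expect_equal(at30[["Cm"]], 0.6 * lift_hand, tolerance = 1e-12)
  # absent surface contributes nothing
  gone <- surf; gone$present <- FALSE
  expect_equal(unname(surface_coefficients(gone, cfg, 30)), rep(0, 6))
})

test_that("left-right symmetric configurations have exactly zero lateral terms", {
  cfg <- quiet_cfg("sprawled")
  for (a in c(-10, 0, 25, 60, 90)) {
    co <- body_coefficients(cfg, orientation(pitch = a))
    expect_identical(co$CY, 0)
    expect_identical(co$Cl, 0)
    expect_identical(co$Cn, 0)
  }
  # symmetric deflection keeps the symmetry
  co <- body_coefficients(cfg, orientation(pitch = 20),
                          deflections = c(wing_pronation_sym = 10))
  expect_identical(co$Cl, 0)
  expect_identical(co$Cn, 0)
  # asymmetric deflection breaks it
  co2 <- body_coefficients(cfg, orientation(pitch = 20),
                           deflections = c(wing_pronation_asym = 10))
  expect_gt(abs(co2$Cl), 1e-4)
})

test_that("tail-up deflection pitches the nose up and raises the trim angle", {
  cfg <- quiet_cfg("tent")
  a0 <- body_coefficients(cfg, orientation(pitch = 10))$Cm
  a1 <- body_coefficients(cfg, orientation(pitch = 10),
                          deflections = c(tail_pitch = 10))$Cm
  expect_gt(a1, a0)  # tail up -> nose-up moment at low angle of attack
  t0 <- analytic_pitch_trim(cfg)$alpha[1]
  t1 <- analytic_pitch_trim(cfg, deflections = c(tail_pitch = 10))$alpha[1]
  expect_gt(t1, t0)
})

test_that("two-surface trim matches the closed-form root", {
  cfg <- two_surface_config(ax_fore = 0.12, i_fore = 2, ax_aft = -0.2,
                            i_aft = -8)
  roots <- analytic_pitch_trim(cfg)$alpha
  expected <- two_surface_trim(0.12, 2, -0.2, -8)
  expect_equal(length(roots), length(expected))
  expect_equal(roots, expected, tolerance = 1e-6)
})

test_that("noise-free generation inverts exactly through the pipeline", {
  cfg <- quiet_cfg("tent")
  o <- orientation(roll = 3, pitch = 35, yaw = -8)
  run <- generate_run(cfg, o, tunnel_conditions(), model_geometry(),
                      duration = 0.01, seed = 9)
  tbl <- reduce_runs(list(run), model_geometry())
  truth <- body_coefficients(cfg, o)
  rec <- unlist(tbl[c("CL", "CD", "CY", "Cl", "Cm", "Cn")])
  expect_equal(unname(rec), unname(unlist(truth)), tolerance = 1e-10)
})

test_that("generation is reproducible for a fixed seed", {
  cfg <- preset_config("sprawled")
  r1 <- generate_run(cfg, orientation(pitch = 20), tunnel_conditions(),
                     model_geometry(), duration = 0.05, seed = 77)
  r2 <- generate_run(cfg, orientation(pitch = 20), tunnel_conditions(),
                     model_geometry(), duration = 0.05, seed = 77)
  expect_identical(r1$samples, r2$samples)
  r3 <- generate_run(cfg, orientation(pitch = 20), tunnel_conditions(),
                     model_geometry(), duration = 0.05, seed = 78)
  expect_false(identical(r3$samples, r1$samples))
})

test_that("recovered channel means satisfy the CLT bound across seeds", {
  cfg <- preset_config("tent", misalign_sd = 0)
  o <- orientation(pitch = 30)
  n <- 50
  truth <- generate_run(
    glider_config(cfg$surfaces, noise_force_sd = 0, noise_moment_sd = 0,
                  misalign_sd = 0),
    o, tunnel_conditions(), model_geometry(), duration = 1 / cfg$rate,
    seed = 1)
  base <- c(colMeans(truth$samples))
  bound <- 4 * c(rep(cfg$noise_force_sd, 3), rep(cfg$noise_moment_sd, 3)) /
    sqrt(n)
  inside <- vapply(1:1000, function(seed) {
    run <- generate_run(cfg, o, tunnel_conditions(), model_geometry(),
                        duration = n / cfg$rate, seed = seed)
    avg <- average_recording(recording(run$samples, run$rate))
    got <- c(avg$mean$force, avg$mean$moment)
    all(abs(got - base) <= bound)
  }, logical(1))
  expect_gte(mean(inside), 0.99)
})

test_that("study generation counts the full factorial and writes truth", {
  cfgs <- lapply(c("sprawled", "tent", "biplane", "down"), quiet_cfg)
  st <- generate_study(cfgs, alpha_grid = seq(-15, 90, 5), replicates = 5,
                       duration = 0.005, seed = 3)
  expect_equal(nrow(st$manifest), 4 * 22 * 5)
  expect_equal(length(st$runs), 440)
  expect_equal(sort(unique(st$manifest$posture)),
               c("biplane", "down", "sprawled", "tent"))
  # manifest truth pitch slopes vs finite differences of body_coefficients
  cfg <- cfgs[[2]]
  for (a in c(0, 25, 60)) {
    h <- 1e-4
    fd <- (body_coefficients(cfg, orientation(pitch = a + h))$Cm -
             body_coefficients(cfg, orientation(pitch = a - h))$Cm) / (2 * h)
    expect_equal(analytic_pitch_slope(cfg, a), fd, tolerance = 1e-6)
  }
})

test_that("feather removal eliminates leg/tail forces and control authority", {
  st <- generate_study(quiet_cfg("tent"), alpha_grid = c(0, 10, 20),
                       replicates = 1, duration = 0.005, seed = 4,
                       feathers_off = TRUE)
  man <- st$manifest
  expect_setequal(unique(man$feathers), c(TRUE, FALSE))
  # with feathers off, the analytic tail control derivative vanishes
  off <- quiet_cfg("tent")
  for (i in seq_along(off$surfaces))
    if (grepl("^(leg|tail)", off$surfaces[[i]]$name))
      off$surfaces[[i]]$present <- FALSE
  expect_identical(analytic_control_derivative(off, "tail_pitch", 10,
                                               "pitch"), 0)
  expect_gt(abs(analytic_control_derivative(quiet_cfg("tent"), "tail_pitch",
                                            10, "pitch")), 1e-3)
  # and the pitch stability contribution of the hind surfaces is gone
  expect_gt(analytic_pitch_slope(off, 27), analytic_pitch_slope(
    quiet_cfg("tent"), 27))
})

test_that("generated data are coefficient-true across tunnel speeds", {
  cfg <- quiet_cfg("biplane")
  o <- orientation(pitch = 20)
  rec <- function(U) {
    cond <- tunnel_conditions(U = U)
    run <- generate_run(cfg, o, cond, model_geometry(), duration = 0.005,
                        seed = 11)
    unlist(reduce_runs(list(run))[c("CL", "CD", "CY", "Cl", "Cm", "Cn")])
  }
  expect_equal(rec(4), rec(8), tolerance = 1e-10)
})

test_that("analytic control derivatives differentiate every channel type", {
  cfg <- quiet_cfg("tent")
  h <- 1e-5
  for (ch in c("tail_pitch", "tail_lateral", "wing_pronation_asym",
               "leg_dihedral", "wing_tuck", "legs_pitch")) {
    for (axis in c("pitch", "yaw", "roll")) {
      num <- (body_coefficients(cfg, orientation(pitch = 20),
                                stats::setNames(h, ch))[[
               switch(axis, pitch = "Cm", yaw = "Cn", roll = "Cl")]] -
              body_coefficients(cfg, orientation(pitch = 20),
                                stats::setNames(-h, ch))[[
               switch(axis, pitch = "Cm", yaw = "Cn", roll = "Cl")]]) / (2 * h)
      ana <- analytic_control_derivative(cfg, ch, 20, axis)
      expect_equal(ana, num, tolerance = 1e-6,
                   label = sprintf("%s/%s analytic", ch, axis))
    }
  }
})
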