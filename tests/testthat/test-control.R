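test_that("control derivatives are exact on linear deflection responses", {
  tbl <- coef_table(alphas = c(0, 15, 30), deltas = c(-15, 0, 15),
                    replicates = 2, appendage = "tail_pitch",
                    coef_fun = function(a, d) list(Cm = 0.004 * d))
  fam <- deflection_family(tbl, "tail_pitch")
  e <- control_derivative(fam, axis = "pitch")
  expect_equal(e$derivative, rep(0.004, 3), tolerance = 1e-12)
  expect_equal(e$neutral, rep(0, 3), tolerance = 1e-12)

  # the documented symmetric three-point case
  tb2 <- coef_table(alphas = 0, deltas = c(-15, 0, 15),
                    appendage = "tail_pitch",
                    coef_fun = function(a, d)
                      list(Cm = c(`-15` = -0.06, `0` = 0,
                                  `15` = 0.06)[[as.character(d)]]))
  e2 <- control_derivative(deflection_family(tb2, "tail_pitch"), "pitch")
  expect_equal(e2$derivative, 0.004, tolerance = 1e-12)

  # secant mode reduces to the extreme-deflection finite difference
  e3 <- control_derivative(fam, "pitch", mode = "secant")
  expect_equal(e3$derivative, rep(0.004, 3), tolerance = 1e-12)
})

test_that("derivatives ignore delta-independent offsets and row order", {
  set.seed(41)
  base <- coef_table(alphas = c(0, 20), deltas = c(-10, -5, 0, 5, 10),
                     replicates = 3, appendage = "tail_pitch",
                     coef_fun = function(a, d) list(Cm = 0.003 * d - 0.01 * a))
  shifted <- base; shifted$Cm <- shifted$Cm + 0.42
  e1 <- control_derivative(deflection_family(base, "tail_pitch"), "pitch")
  e2 <- control_derivative(deflection_family(shifted, "tail_pitch"), "pitch")
  e3 <- control_derivative(deflection_family(base[sample(nrow(base)), ],
                                             "tail_pitch"), "pitch")
  expect_equal(e1$derivative, e2$derivative, tolerance = 1e-12)
  expect_equal(e1$derivative, e3$derivative, tolerance = 1e-12)
  expect_equal(e2$neutral - e1$neutral, rep(0.42, 2), tolerance = 1e-12)
})

test_that("deflection family enforces its grid contract", {
  tbl <- coef_table(alphas = 0, deltas = c(0, 10), appendage = "tail_pitch",
                    coef_fun = function(a, d) list(Cm = 0.004 * d))
  expect_s3_class(deflection_family(tbl, "tail_pitch"), "deflection_family")
  only0 <- tbl[tbl$deflection_deg == 0, ]
  expect_error(deflection_family(only0, "tail_pitch"), ">= 2 distinct")
  no0 <- coef_table(alphas = 0, deltas = c(5, 10), appendage = "tail_pitch",
                    coef_fun = function(a, d) list(Cm = 0.004 * d))
  expect_error(deflection_family(no0[no0$deflection_deg != 0, ],
                                 "tail_pitch"), "neutral")
})

test_that("reversal detection finds the analytic cosine crossing", {
  mk <- function(fun) {
    tbl <- coef_table(alphas = seq(0, 120, by = 10), deltas = c(-5, 0, 5),
                      appendage = "tail_pitch",
                      coef_fun = function(a, d) list(Cm = fun(a) * d))
    control_derivative(deflection_family(tbl, "tail_pitch"), "pitch")
  }
  # monotone-sign curve: no reversal
  expect_equal(nrow(detect_reversal(mk(function(a) 0.004 + 1e-5 * a))), 0)
  # derivative 0.004 cos(alpha): one crossing at 90 deg
  rev <- detect_reversal(mk(function(a) 0.004 * cos(a * pi / 180)))
  expect_equal(nrow(rev), 1)
  expect_equal(rev$alpha_cross, 90, tolerance = 1)
  expect_equal(c(rev$sign_from, rev$sign_to), c(1, -1))
  # everything inside the band: indeterminate, no crossings
  flat <- detect_reversal(mk(function(a) 1e-5 * cos(a * pi / 180)),
                          tol = 1e-3)
  expect_equal(nrow(flat), 0)
  expect_true(attr(flat, "indeterminate"))
})

test_that("roll/yaw dominance classifies by derivative ratio", {
  mk <- function(cl, cn) {
    tbl <- coef_table(alphas = 10, deltas = c(-5, 0, 5),
                      appendage = "wing_pronation_asym",
                      coef_fun = function(a, d) list(Cl = cl * d, Cn = cn * d))
    axis_shift_profile(deflection_family(tbl, "wing_pronation_asym"))
  }
  expect_equal(mk(0.01, 0.001)$dominance, "roll")
  expect_equal(mk(0.001, 0.01)$dominance, "yaw")
  expect_equal(mk(0.004, 0.004)$dominance, "mixed")
})

test_that("asymmetric pronation shifts from roll to yaw with angle of attack", {
  # the flat-plate closure rotates the moment axis: roll ~ cos(2a),
  # yaw ~ sin(2a), so on (0, 45] dominance flips at the closed-form
  # thresholds (the profile mirrors above 45 where |cos 2a| regrows)
  cfg <- preset_config("tent", noise_force_sd = 0, noise_moment_sd = 0,
                       misalign_sd = 0)
  alphas <- seq(5, 45, by = 5)
  st <- generate_study(cfg, alpha_grid = alphas,
                       deflections = list(wing_pronation_asym = c(-5, 0, 5)),
                       replicates = 1, duration = 0.01, seed = 7)
  prof <- axis_shift_profile(
    deflection_family(reduce_runs(st), "wing_pronation_asym"))
  A <- cfg$A; B <- cfg$B; r <- 2
  # analytic thresholds of (A cos 2a)/(B sin 2a) crossing r and 1/r
  a_roll <- atan(A / (B * r)) * 90 / pi
  a_yaw <- atan(A * r / B) * 90 / pi
  last_roll <- max(prof$alpha[prof$dominance == "roll"])
  first_yaw <- min(prof$alpha[prof$dominance == "yaw"])
  expect_lt(abs(last_roll - (a_roll - 2.5)), 5)
  expect_lt(abs(first_yaw - (a_yaw + 2.5)), 5)
  expect_true(all(prof$dominance[prof$alpha > a_roll &
                                   prof$alpha < a_yaw] == "mixed"))
})

test_that("injected control derivatives are recovered under noise", {
  cfg <- preset_config("tent")
  alphas <- c(0, 20, 40)
  set.seed(43)
  ests <- replicate(10, {
    seed <- sample.int(1e6, 1)
    st <- generate_study(cfg, alpha_grid = alphas,
                         deflections = list(tail_pitch = c(-5, 0, 5)),
                         replicates = 3, duration = 0.2, seed = seed)
    e <- control_derivative(deflection_family(reduce_runs(st), "tail_pitch"),
                            "pitch")
    e$derivative
  })
  truth <- vapply(alphas, function(a)
    analytic_control_derivative(cfg, "tail_pitch", a, "pitch"), numeric(1))
  est_mean <- rowMeans(ests)
  est_se <- apply(ests, 1, stats::sd) / sqrt(ncol(ests))
  expect_true(all(abs(est_mean - truth) < 3 * est_se + 0.01 * abs(truth)))
})
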