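test_that("system period matches the LCM of rationally related scales", {
  expect_equal(system_period(grid_system(50)), 50)
  expect_equal(system_period(sys3()), 300)
  expect_equal(system_period(sys2()), 60)
  # coincidence scan confirms the rational result
  expect_equal(system_period(sys3(), method = "scan", resolution = 0.5), 300)
  expect_equal(system_period(sys2(), method = "scan", resolution = 0.25), 60)
  # fewer modules, smaller unambiguous range
  expect_gt(system_period(sys3()), system_period(sys2()))
  # ellipticity rescales axis 2
  sys_e <- grid_system(c(50, 30, 20), ellipticity = 0.5)
  expect_equal(system_period(sys_e, axis = 2), 150)
  # irrational ratio: scan finds nothing within range, Inf sentinel
  sys_irr <- grid_system(c(50 * sqrt(2), 30))
  expect_warning(C_irr <- system_period(sys_irr, method = "scan",
                                        resolution = 0.5, max_range = 500),
                 "aperiodic")
  expect_identical(C_irr, Inf)
})

test_that("unwrap candidates contain the coherent integer set", {
  sys <- sys3()
  cand0 <- unwrap_candidates(phase_diff(c(0, 0, 0)), sys)
  expect_true(any(vapply(cand0$n, function(n) all(n == 0L), logical(1))))
  # worked example: n = {1, 2, 3} unwraps {pi, pi, 3pi/2} onto the d = 75 line
  cand <- unwrap_candidates(phase_diff(DP_75), sys)
  hit <- vapply(cand$n, function(n) all(n == c(1L, 2L, 3L)), logical(1))
  expect_true(any(hit))
  u <- cand$unwrapped[[which(hit)]]
  expect_equal(u, 2 * pi * 75 / c(50, 30, 20), tolerance = 1e-12)
  # counting bounds
  C <- system_period(sys)
  n_max <- ceiling(C / min(sys$scale_cm)) + 1
  expect_lte(nrow(cand), (2 * n_max + 1)^3)
  expect_gte(nrow(cand), C / sys$scale_cm[1])
  expect_error(unwrap_candidates(phase_diff(numeric(0)), grid_system(numeric(0))))
})

test_that("line fit decodes the worked example and round-trips", {
  sys <- sys3()
  rep75 <- decode_linefit(phase_diff(DP_75), sys)
  expect_equal(rep75$d_cm, 75, tolerance = 1e-9)
  expect_lt(rep75$residual, 1e-9)
  expect_true(rep75$success)
  expect_equal(decode_linefit(phase_diff(c(0, 0, 0)), sys)$d_cm, 0)
  # forward-encode then decode d = 25
  rep25 <- decode_linefit(phase_diff(c(pi, 5 * pi / 3, pi / 2)), sys)
  expect_equal(rep25$d_cm, 25, tolerance = 1e-9)
})

test_that("noise-free 1D round trips are exact across the signed range", {
  sys <- sys3()
  set.seed(42)
  d <- runif(200, -149.999, 149.999)
  for (dk in d) {
    dp <- phase_difference(encode_location(c(0, 0), sys),
                           encode_location(c(dk, 0), sys))
    expect_equal(decode_linefit(dp, sys)$d_cm, dk, tolerance = 1e-6)
  }
})

test_that("plane fit recovers the 2D worked example and random vectors", {
  sys <- sys3()
  rep <- decode_planefit(phase_diff(DP_75, DP_37.5), sys)
  expect_equal(rep$d_axis1_cm, 75, tolerance = 1e-9)
  expect_equal(rep$d_axis2_cm, 37.5, tolerance = 1e-9)
  expect_true(rep$success)
  zero <- decode_planefit(phase_diff(c(0, 0, 0)), sys)
  expect_equal(c(zero$d_axis1_cm, zero$d_axis2_cm), c(0, 0))
  # cartesian view is the linear image of the axis components
  B <- axis_basis(0, pi / 3)
  expect_equal(c(rep$dx_cm, rep$dy_cm),
               as.vector(B %*% c(75, 37.5)), tolerance = 1e-9)
  # 200 random displacements within capacity: 100% exact recovery
  set.seed(1)
  scen <- random_scenarios(sys, 200, seed = 1)
  for (r in seq_len(nrow(scen))) {
    a <- encode_location(c(scen$start_x_cm[r], scen$start_y_cm[r]), sys)
    b <- encode_location(c(scen$goal_x_cm[r], scen$goal_y_cm[r]), sys)
    est <- decode_planefit(phase_difference(a, b), sys)
    expect_equal(est$d_axis1_cm, scen$true_d1_cm[r], tolerance = 1e-6)
    expect_equal(est$d_axis2_cm, scen$true_d2_cm[r], tolerance = 1e-6)
  }
})

test_that("general plane fit agrees with the per-axis decomposition", {
  sys <- sys3()
  set.seed(8)
  for (rep in 1:10) {
    d <- runif(2, -140, 140)
    B <- axis_basis(0, pi / 3)
    cart <- as.vector(B %*% d)
    dp <- phase_difference(encode_location(c(0, 0), sys),
                           encode_location(cart, sys))
    shared <- decode_planefit(dp, sys)
    general <- gridnav:::plane_fit_general(dp, sys)
    expect_equal(general$d_axis1_cm, shared$d_axis1_cm, tolerance = 1e-6)
    expect_equal(general$d_axis2_cm, shared$d_axis2_cm, tolerance = 1e-6)
  }
  # modules with different orientations still decode
  sys_rot <- grid_system(c(50, 30, 20), orientation = c(0, 0.2, 0.4))
  d_true <- c(40, -25)
  codes <- lapply(list(c(0, 0), d_true), function(xy) {
    encode_location(xy, sys_rot)
  })
  est <- decode_planefit(phase_difference(codes[[1]], codes[[2]]), sys_rot)
  expect_equal(c(est$dx_cm, est$dy_cm), d_true, tolerance = 1e-6)
})

test_that("the code is periodic: d and d + C decode identically", {
  sys <- sys3()
  C <- system_period(sys)
  for (d in c(-80, 12.5, 60)) {
    dp1 <- phase_difference(encode_location(c(0, 0), sys),
                            encode_location(c(d, 0), sys))
    dp2 <- phase_difference(encode_location(c(0, 0), sys),
                            encode_location(c(d + C, 0), sys))
    expect_equal(dp1$dp_x, dp2$dp_x, tolerance = 1e-9)
    expect_equal(decode_linefit(dp1, sys)$d_cm,
                 decode_linefit(dp2, sys)$d_cm, tolerance = 1e-6)
  }
})

test_that("brute-force oracle matches the plane fit on random cases", {
  sys <- sys3()
  set.seed(5)
  scen <- random_scenarios(sys, 30, seed = 5)
  for (r in seq_len(nrow(scen))) {
    a <- encode_location(c(scen$start_x_cm[r], scen$start_y_cm[r]), sys)
    b <- encode_location(c(scen$goal_x_cm[r], scen$goal_y_cm[r]), sys)
    dp <- phase_difference(a, b)
    alg <- decode_planefit(dp, sys)
    orc <- brute_force_oracle(dp, sys, resolution = 1)
    expect_lte(abs(alg$d_axis1_cm - orc$d_axis1_cm), 1 + 1e-9)
    expect_lte(abs(alg$d_axis2_cm - orc$d_axis2_cm), 1 + 1e-9)
  }
  expect_error(brute_force_oracle(phase_diff(DP_75), sys, resolution = 5),
               "resolution")
})

test_that("oracle and line fit pick the same candidate under phase noise", {
  sys <- sys3()
  set.seed(99)
  sigma <- 0.2
  n_trials <- 500
  agree <- logical(n_trials)
  for (t in seq_len(n_trials)) {
    d <- runif(1, -145, 145)
    dp_clean <- 2 * pi * d / c(50, 30, 20)
    dp <- phase_diff(dp_clean + rnorm(3, 0, sigma))
    alg <- decode_linefit(dp, sys, residual_threshold = 1)
    orc <- brute_force_oracle(dp, sys, resolution = 1)
    agree[t] <- abs(alg$d_cm - orc$d_axis1_cm) <= min(sys$scale_cm) / 2
  }
  expect_gte(mean(agree), 0.95)
})
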