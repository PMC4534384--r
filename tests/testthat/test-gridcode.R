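test_that("grid_system validates its invariants", {
  expect_s3_class(sys3(), "grid_system")
  expect_error(grid_system(numeric(0)), "at least one")
  expect_error(grid_system(c(20, 30)), "largest first")
  expect_error(grid_system(50, axis_separation = pi), "between 0 and pi")
  expect_error(grid_system(50, ellipticity = 0), "positive")
  expect_error(grid_system(50, cells_per_axis = 1), "at least 2")
  expect_true(shared_axes(sys3()))
  expect_false(shared_axes(grid_system(c(50, 30), orientation = c(0, 0.1))))
})

test_that("axis projection solves the (non-orthogonal) basis exactly", {
  sys <- sys3()
  # points on the axes themselves
  expect_equal(unlist(project_onto_axes(c(1, 0), sys)[, c("u_cm", "v_cm")]),
               c(u_cm = 1, v_cm = 0))
  B <- axis_basis(0, pi / 3)
  on_sum <- B[, 1] + B[, 2]
  expect_equal(unlist(project_onto_axes(on_sum, sys)[, c("u_cm", "v_cm")]),
               c(u_cm = 1, v_cm = 1))
  # hand inversion of the 60-degree basis for (0, 1)
  expect_equal(unlist(project_onto_axes(c(0, 1), sys)[, c("u_cm", "v_cm")]),
               c(u_cm = -1 / sqrt(3), v_cm = 2 / sqrt(3)))
  expect_error(axis_basis(0, 0), "collinear")
})

test_that("basis round trip recovers locations to 1e-12 cm", {
  set.seed(11)
  sys <- grid_system(c(40, 25), orientation = 0.3, axis_separation = 1.1)
  locs <- random_locs(50)
  uv <- project_onto_axes(locs, sys)
  B <- axis_basis(0.3, 1.1)
  back <- t(B %*% rbind(uv$u_cm, uv$v_cm))
  expect_equal(back[, 1], locs$x_cm, tolerance = 1e-12)
  expect_equal(back[, 2], locs$y_cm, tolerance = 1e-12)
})

test_that("encoding reproduces the modular worked example and wraps", {
  sys <- sys3()
  code <- encode_location(c(75, 0), sys)
  expect_equal(code$p_x, DP_75, tolerance = 1e-12)
  expect_equal(code$p_y, rep(0, 3), tolerance = 1e-12)
  # d = 25 on scale 30: 25/30 * 2*pi
  code25 <- encode_location(c(25, 0), sys)
  expect_equal(code25$p_x, c(pi, 5 * pi / 3, pi / 2), tolerance = 1e-12)
  # origin encodes to all zeros
  expect_equal(encode_location(c(0, 0), sys)$p_x, rep(0, 3))
  # all phases in [0, 2*pi)
  set.seed(4)
  codes <- encode_location(random_locs(40), sys)
  expect_true(all(codes$p_x >= 0 & codes$p_x < 2 * pi))
  expect_true(all(codes$p_y >= 0 & codes$p_y < 2 * pi))
})

test_that("encoding is periodic in each module with period s_i per axis", {
  sys <- sys3()
  B <- axis_basis(0, pi / 3)
  set.seed(7)
  for (rep in 1:20) {
    loc <- c(runif(1, -300, 300), runif(1, -300, 300))
    i <- sample(3, 1); k <- sample(c(-3, -1, 1, 2), 1)
    shifted <- loc + k * sys$scale_cm[i] * B[, 1]
    c0 <- encode_location(loc, sys); c1 <- encode_location(shifted, sys)
    gap <- min(abs(c1$p_x[i] - c0$p_x[i]), 2 * pi - abs(c1$p_x[i] - c0$p_x[i]))
    expect_equal(gap, 0, tolerance = 1e-9)
    expect_equal(c1$p_y, c0$p_y, tolerance = 1e-9)  # axis-2 untouched
  }
})

test_that("phase differences depend only on the displacement", {
  sys <- sys3()
  a <- encode_location(c(0, 0), sys)
  b <- encode_location(c(75, 0), sys)
  dp <- phase_difference(a, b)
  expect_equal(dp$dp_x, DP_75, tolerance = 1e-12)
  expect_equal(phase_difference(a, a)$dp_x, rep(0, 3))
  # same displacement from a shifted start
  a2 <- encode_location(c(10, 0), sys)
  b2 <- encode_location(c(85, 0), sys)
  expect_equal(phase_difference(a2, b2)$dp_x, dp$dp_x, tolerance = 1e-9)
  # property: random pairs sharing a displacement share the diff
  set.seed(21)
  B <- axis_basis(0, pi / 3)
  for (rep in 1:15) {
    start <- runif(2, -200, 200); shift <- runif(2, -200, 200)
    d <- runif(2, -100, 100)
    dp1 <- phase_difference(encode_location(start, sys),
                            encode_location(start + d, sys))
    dp2 <- phase_difference(encode_location(start + shift, sys),
                            encode_location(start + shift + d, sys))
    expect_equal(dp1$dp_x, dp2$dp_x, tolerance = 1e-9)
    expect_equal(dp1$dp_y, dp2$dp_y, tolerance = 1e-9)
  }
  expect_error(
    phase_difference(encode_location(c(0, 0), sys2()), b), "different modules")
})

test_that("three-cosine rate map peaks at field centres and dips to zero", {
  mod <- sys3()[1, ]
  expect_equal(rate_map(c(0, 0), c(0, 0), mod), 1)
  # periodic under lattice translations
  B <- axis_basis(0, pi / 3)
  a1 <- 50 * B[, 1]; a2 <- 50 * B[, 2]
  loc <- c(12.3, -4.5)
  expect_equal(rate_map(c(0, 0), loc, mod),
               rate_map(c(0, 0), loc + 2 * a1 - a2, mod), tolerance = 1e-9)
  # centroid of three adjacent field centres (0, a1, a2) is the anti-node
  centroid <- (a1 + a2) / 3
  expect_equal(rate_map(c(0, 0), centroid, mod), 0, tolerance = 1e-12)
  # grid-search oracle: global min of the map is 0, global max is 1
  xs <- seq(-50, 50, length.out = 101)
  grid <- expand.grid(x_cm = xs, y_cm = xs)
  vals <- rate_map(c(0, 0), grid, mod)
  expect_gte(min(vals), 0)
  expect_lte(max(vals), 1 + 1e-12)
})

test_that("population activity peaks at the encoded phase", {
  mod <- grid_system(20, cells_per_axis = 16)[1, ]
  act0 <- population_activity(c(0, 0), mod)
  expect_equal(act0$off_x[which.max(act0$rate)], 0)
  expect_equal(act0$off_y[which.max(act0$rate)], 0)
  # half a tile along axis 1
  B <- axis_basis(0, pi / 3)
  act_half <- population_activity(10 * B[, 1], mod)
  w <- which.max(act_half$rate)
  expect_equal(act_half$off_x[w], pi, tolerance = 2 * pi / 16 + 1e-9)
  expect_equal(act_half$off_y[w], 0, tolerance = 2 * pi / 16 + 1e-9)
  # argmax agrees with encode_location within one phase-grid step
  set.seed(3)
  step <- 2 * pi / 16
  for (rep in 1:5) {
    loc <- runif(2, -40, 40)
    act <- population_activity(loc, mod)
    code <- encode_location(loc, grid_system(20, cells_per_axis = 16))
    w <- which.max(act$rate)
    expect_lte(min(abs(act$off_x[w] - code$p_x), 2 * pi - abs(act$off_x[w] - code$p_x)),
               step + 1e-9)
    expect_lte(min(abs(act$off_y[w] - code$p_y), 2 * pi - abs(act$off_y[w] - code$p_y)),
               step + 1e-9)
  }
  # total activity is translation invariant on the periodic sheet
  s1 <- sum(population_activity(c(0, 0), mod)$rate)
  s2 <- sum(population_activity(c(7.7, -3.1), mod)$rate)
  expect_equal(s1, s2, tolerance = 1e-9 * abs(s1))
})

test_that("config and location files round-trip", {
  cfg <- tempfile(fileext = ".yaml")
  writeLines(c(
    "axis_separation_rad: 1.0471975511965976",
    "seed: 7",
    "modules:",
    "  - scale_cm: 50",
    "  - scale_cm: 30",
    "  - {scale_cm: 20, cells_per_axis: 16, ellipticity: 1.5}"
  ), cfg)
  conf <- read_grid_config(cfg)
  expect_equal(conf$system$scale_cm, c(50, 30, 20))
  expect_equal(conf$system$cells_per_axis, c(32L, 32L, 16L))
  expect_equal(conf$system$ellipticity, c(1, 1, 1.5))
  expect_equal(conf$seed, 7)
  csv <- tempfile(fileext = ".csv")
  writeLines(c("id,x_cm,y_cm", "a,0,0", "b,75,0"), csv)
  locs <- read_locations(csv)
  expect_equal(locs$x_cm, c(0, 75))
  expect_equal(locs$id, c("a", "b"))
})
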