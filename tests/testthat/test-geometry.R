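test_that("single-view projection matches exact rational evaluation", {
  g <- example_rig()
  # (a=5, b=3, c=100, d=10): numerator 13*110 = 1430, denominator 118
  expect_equal(forward_single_view(5, 3, g), 1430 / 118, tolerance = 1e-12)
  # numerator identity (b+d)(c+d) = bc + dc + bd + d^2, random draws
  set.seed(41)
  for (i in 1:50) {
    b <- runif(1, -20, 20); cc <- runif(1, 1, 200); d <- runif(1, 0.1, 30)
    expect_equal((b + d) * (cc + d), b * cc + d * cc + b * d + d^2,
                 tolerance = 1e-12)
  }
  # zero numerator at b = -d, any a
  expect_equal(forward_single_view(a = 7.3, b = -g$d, g), 0)
  # zero denominator a = b + c + 2d
  expect_error(forward_single_view(a = 3 + 100 + 20, b = 3, g),
               class = "fluorloc_singular_geometry")
})

test_that("opposite-pair projection evaluates both printed equations", {
  g <- example_rig()
  xs <- forward_opposite_pair(5, 3, g)
  expect_equal(unname(xs["x"]), 1430 / 118, tolerance = 1e-12)
  expect_equal(unname(xs["x1"]), 1430 / (3 - 5 - 100), tolerance = 1e-12)
  # shared zero numerator
  expect_equal(unname(forward_opposite_pair(2, b = -g$d, g)), c(0, 0))
  # far-mirror denominator vanishes at a = b - c
  expect_error(forward_opposite_pair(a = 3 - 100, b = 3, g),
               class = "fluorloc_singular_geometry")
})

test_that("opposite-mirror solver inverts the projections in closed form", {
  g <- example_rig()
  sol <- solve_opposite(1430 / 118, 1430 / -102, g)
  expect_equal(unname(sol), c(5, 3), tolerance = 1e-9)
  expect_error(solve_opposite(4.2, 4.2, g),
               class = "fluorloc_degenerate_observation")
  # 1000 random non-degenerate draws: round-trip identity within 1e-9
  set.seed(42)
  for (i in 1:1000) {
    a <- runif(1, -8, 8); b <- runif(1, 0.2, 12)
    xs <- forward_opposite_pair(a, b, g)
    sol <- solve_opposite(xs["x"], xs["x1"], g)
    expect_equal(unname(sol), c(a, b), tolerance = 1e-9)
  }
})

test_that("solvers work under the symmetric far-mirror variant too", {
  g <- rig_geometry(camera_height_cm = 100, mirror_offset_cm = 10,
                    eq4_variant = "symmetric")
  set.seed(43)
  for (i in 1:200) {
    a <- runif(1, -8, 8); b <- runif(1, 0.2, 12)
    xs <- forward_opposite_pair(a, b, g)
    expect_equal(unname(xs["x1"]),
                 -(b + 10) * (110) / (a + b + 100 + 20), tolerance = 1e-12)
    sol <- solve_opposite(xs["x"], xs["x1"], g)
    expect_equal(unname(sol), c(a, b), tolerance = 1e-9)
  }
})

test_that("two-frame projection applies the travel shift", {
  g <- example_rig()
  xs <- forward_two_frames(5, 3, g, l = 4)
  expect_equal(unname(xs["x1"]), 1430 / 118, tolerance = 1e-12)
  # a2 = 5 + 4 sin(45 deg); denominator 118 - 4/sqrt(2)
  expect_equal(unname(xs["x2"]), 1430 / (118 - 4 * sin(pi / 4)),
               tolerance = 1e-12)
  # no parallax without travel or with travel parallel to the mirror
  expect_equal(unname(diff(forward_two_frames(5, 3, g, l = 0))), 0)
  g0 <- rig_geometry(100, 10, mirror_angle_deg = 1e-9 + .Machine$double.eps)
  xs0 <- forward_two_frames(5, 3, g0, l = 4)
  expect_equal(unname(xs0["x1"]), unname(xs0["x2"]), tolerance = 1e-6)
})

test_that("single-mirror solver inverts the two-frame projections", {
  g <- example_rig()
  xs <- forward_two_frames(5, 3, g, l = 4)
  sol <- solve_single_mirror(xs["x1"], xs["x2"], g, l = 4)
  expect_equal(unname(sol), c(5, 3), tolerance = 1e-9)
  expect_error(solve_single_mirror(12.1, 12.1, g, l = 4),
               class = "fluorloc_degenerate_observation")
  expect_error(solve_single_mirror(12.1, 12.4, g, l = -1),
               class = "fluorloc_config_error")
  # 1000 random draws, including signed travel shifts
  set.seed(44)
  for (i in 1:1000) {
    a <- runif(1, -8, 8); b <- runif(1, 0.2, 12)
    l <- runif(1, 1, 8); sgn <- sample(c(-1, 1), 1)
    shift <- sgn * l * sin(g$theta_deg * pi / 180)
    xs <- forward_two_frames(a, b, g, l, signed_shift = shift)
    sol <- solve_single_mirror(xs["x1"], xs["x2"], g, l, signed_shift = shift)
    expect_equal(unname(sol), c(a, b), tolerance = 1e-9)
  }
})

test_that("closed forms agree with an independent numeric root search", {
  skip_if_not_installed("pracma")
  g <- example_rig()
  set.seed(45)
  for (i in 1:100) {
    a <- runif(1, -6, 6); b <- runif(1, 0.5, 10)
    xs <- forward_opposite_pair(a, b, g)
    ref <- oracle_solve_opposite(xs["x"], xs["x1"], g)
    sol <- solve_opposite(xs["x"], xs["x1"], g)
    expect_equal(unname(sol), ref, tolerance = 1e-6)

    l <- runif(1, 2, 6)
    shift <- l * sin(pi / 4)
    x2s <- forward_two_frames(a, b, g, l, signed_shift = shift)
    ref2 <- oracle_solve_single(x2s["x1"], x2s["x2"], g, shift)
    sol2 <- solve_single_mirror(x2s["x1"], x2s["x2"], g, l,
                                signed_shift = shift)
    expect_equal(unname(sol2), ref2, tolerance = 1e-6)
  }
})

test_that("solvers reject observations below the parallax epsilon", {
  g <- rig_geometry(100, 10, parallax_epsilon = 1e-6)
  x <- 12.0
  expect_error(solve_opposite(x, x + 1e-7, g),
               class = "fluorloc_degenerate_observation")
  expect_error(solve_single_mirror(x, x + 1e-7, g, l = 4),
               class = "fluorloc_degenerate_observation")
  # conditioning diverges as separation shrinks: error amplification of a
  # fixed observation perturbation grows monotonically
  g2 <- example_rig()
  amp <- sapply(c(1, 0.3, 0.1), function(l) {
    xs <- forward_two_frames(2, 3, g2, l)
    eps <- 1e-9
    sol0 <- solve_single_mirror(xs["x1"], xs["x2"], g2, l)
    sol1 <- solve_single_mirror(xs["x1"], xs["x2"] + eps, g2, l)
    abs(sol1["a"] - sol0["a"]) / eps
  })
  expect_true(all(diff(amp) > 0))
})

test_that("derivation intermediates are consistent: y = x - d solves the similar-triangle relation", {
  # the near-mirror projection follows from y = x - d and
  # x/(b + d) = (y - c)/(a - d - c) with the printed sign conventions;
  # check the chain symbolically on random numbers
  g <- example_rig()
  set.seed(46)
  for (i in 1:50) {
    a <- runif(1, -6, 6); b <- runif(1, 0.5, 10)
    x <- forward_single_view(a, b, g)
    y <- x - g$d
    # the projected coordinate must satisfy the similar-triangle
    # proportionality it was derived from
    expect_equal(x / (b + g$d), (y - g$c) / (a - g$d - g$c),
                 tolerance = 1e-9)
  }
})

test_that("pixel/world conversion scales linearly and inverts exactly", {
  g <- rig_geometry()
  expect_equal(convert_coords(0.5, g, "world_to_px"), 43.5)
  expect_equal(convert_coords(0, g, "world_to_px"), 0)
  set.seed(47)
  for (i in 1:100) {
    p <- runif(2, -500, 500)
    o <- runif(2, -100, 100)
    back <- convert_coords(convert_coords(p, g, "px_to_world", origin = o),
                           g, "world_to_px", origin = o)
    expect_equal(back, p, tolerance = 1e-12)
  }
})

test_that("rig geometry validates its parameters and reads config files", {
  expect_error(rig_geometry(camera_height_cm = -1),
               class = "fluorloc_config_error")
  expect_error(rig_geometry(mirror_angle_deg = 180),
               class = "fluorloc_config_error")
  expect_error(rig_geometry(pixel_scale = 0),
               class = "fluorloc_config_error")
  cfgfile <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("camera_height_cm: 120", "mirror_offset_cm: 6",
               "pixel_scale_px_per_cm: 50", "eq4_variant: symmetric"),
             cfgfile)
  cfg <- read_rig_config(cfgfile)
  expect_equal(cfg$geometry$c, 120)
  expect_equal(cfg$geometry$d, 6)
  expect_equal(cfg$geometry$pixel_scale, 50)
  expect_equal(cfg$geometry$eq4_variant, "symmetric")
  # JSON parses through the same reader
  jsonfile <- withr::local_tempfile(fileext = ".json")
  writeLines('{"camera_height_cm": 90}', jsonfile)
  expect_equal(read_rig_config(jsonfile)$geometry$c, 90)
})
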