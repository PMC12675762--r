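test_that("bezier_eval matches hand-expanded Bernstein values and endpoints", {
  lin <- bezier_curve(rbind(c(0, 0), c(1, 1)))
  expect_equal(drop(bezier_eval(lin, 0.5)), c(u = 0.5, v = 0.5))
  quad <- bezier_curve(rbind(c(0, 0), c(1, 2), c(2, 0)))
  expect_equal(drop(bezier_eval(quad, 0)), c(u = 0, v = 0))
  expect_equal(drop(bezier_eval(quad, 1)), c(u = 2, v = 0))
  # 0.25 p0 + 0.5 p1 + 0.25 p2
  expect_equal(drop(bezier_eval(quad, 0.5)), c(u = 1, v = 1))
  expect_error(bezier_eval(quad, 1.5), class = "spinecurve_domain_error")
})

test_that("bezier_eval agrees with recursive de Casteljau on random curves", {
  set.seed(42)
  for (deg in 2:7) {
    cp <- matrix(rnorm(2 * (deg + 1), sd = 40), ncol = 2)
    curve <- bezier_curve(cp)
    for (t in runif(20)) {
      expect_equal(drop(bezier_eval(curve, t)), de_casteljau(cp, t),
                   tolerance = 1e-12, ignore_attr = TRUE)
    }
  }
})

test_that("collinear control points produce points on the same line", {
  set.seed(1)
  d <- c(3, 4) / 5
  cp <- outer(c(0, 10, 25, 60), d)   # collinear along d
  curve <- bezier_curve(cp)
  pts <- bezier_eval(curve, runif(100))
  # perpendicular component vanishes
  expect_lt(max(abs(pts[, 1] * d[2] - pts[, 2] * d[1])), 1e-10)
})

test_that("bezier_tangent returns the hodograph", {
  lin <- bezier_curve(rbind(c(0, 0), c(2, 2)))
  expect_equal(drop(bezier_tangent(lin, 0.3)), c(u = 2, v = 2))
  quad <- bezier_curve(rbind(c(0, 0), c(1, 2), c(2, 0)))
  expect_equal(drop(bezier_tangent(quad, 0)), c(u = 2, v = 4))  # 2 (p1 - p0)
  expect_equal(drop(bezier_tangent(quad, 0.5))[["v"]], 0)       # symmetry
  degen <- bezier_curve(rbind(c(1, 1), c(1, 1)))
  expect_error(bezier_tangent(degen, 0.5), class = "spinecurve_zero_tangent")
})

test_that("intersect_lines solves the 2x2 system and flags parallels", {
  a <- line2d(c(0, 0), c(1, 1))
  b <- line2d(c(0, 100), c(1, -1))
  hit <- intersect_lines(a, b)
  expect_false(hit$parallel)
  expect_equal(hit$point, c(50, 50))
  expect_gt(hit$s_a, 0); expect_gt(hit$s_b, 0)
  expect_true(intersect_lines(line2d(c(0, 0), c(0, 1)),
                              line2d(c(5, 0), c(0, 1)))$parallel)
  # collinear anti-parallel rays of a straight spine
  expect_true(intersect_lines(line2d(c(0, 0), c(0, 1)),
                              line2d(c(0, 100), c(0, -1)))$parallel)
})

test_that("intersect_curve_line finds the analytic roots", {
  straight <- bezier_curve(rbind(c(0, 0), c(0, 100)))
  hit <- intersect_curve_line(straight, line2d(c(0, 25), c(1, 0)))
  expect_true(hit$found)
  expect_equal(hit$t, 0.25, tolerance = 1e-9)
  expect_equal(hit$point, c(u = 0, v = 25), tolerance = 1e-9)
  quad <- bezier_curve(rbind(c(0, 0), c(20, 50), c(0, 100)))
  hit <- intersect_curve_line(quad, line2d(c(0, 50), c(1, 0)), t_hint = 0.5)
  expect_equal(hit$point, c(u = 10, v = 50), tolerance = 1e-9)
  miss <- intersect_curve_line(quad, line2d(c(0, 500), c(1, 0)))
  expect_false(miss$found)
})

test_that("curve/line roots agree with the dense-sampling argmin oracle", {
  set.seed(7)
  for (k in 1:25) {
    cp <- cbind(rnorm(4, sd = 20), c(0, 30, 60, 90) + rnorm(4, sd = 5))
    curve <- bezier_curve(cp)
    ln <- line2d(c(rnorm(1, sd = 5), runif(1, 10, 80)), c(1, rnorm(1, sd = 0.1)))
    hit <- intersect_curve_line(curve, ln, t_hint = runif(1))
    if (!hit$found) next
    # residual at the root
    p <- hit$point; d <- ln$direction
    expect_lt(abs(d[1] * (p[2] - ln$point[2]) - d[2] * (p[1] - ln$point[1])), 1e-7)
    # some root lies within 1e-4 of the dense argmin
    t_oracle <- argmin_distance_t(curve, ln)
    pc <- spinecurve:::bezier_power_coefs(curve)
    coefs <- d[1] * pc[, 2] - d[2] * pc[, 1]
    coefs[1] <- coefs[1] - (d[1] * ln$point[2] - d[2] * ln$point[1])
    all_roots <- spinecurve:::poly_roots_in(coefs)
    expect_lt(min(abs(all_roots - t_oracle)), 1e-4)
  }
})

test_that("curve_point_at_height takes the most cranial root", {
  straight <- bezier_curve(rbind(c(0, 0), c(0, 100)))
  hit <- curve_point_at_height(straight, 75)
  expect_equal(hit$t, 0.75, tolerance = 1e-9)
  quad <- bezier_curve(rbind(c(0, 0), c(20, 50), c(0, 100)))
  expect_equal(curve_point_at_height(quad, 50)$point, c(u = 10, v = 50),
               tolerance = 1e-9)
  expect_error(curve_point_at_height(quad, 150),
               class = "spinecurve_out_of_range")
  # non-monotone height: smallest t wins
  wiggle <- bezier_curve(rbind(c(0, 0), c(0, 200), c(0, -100), c(0, 100)))
  ts <- curve_point_at_height(wiggle, 50)$t
  expect_lt(ts, 0.2)
})

test_that("signed_angle has arccos magnitude and cross-product sign", {
  expect_equal(signed_angle(c(0, 1), c(0, 1)), 0)
  expect_equal(abs(signed_angle(c(0, 1), c(1, 1) / sqrt(2))), 45)
  expect_equal(abs(signed_angle(c(0, 1), c(0, -1))), 180)
  expect_error(signed_angle(c(0, 0), c(1, 0)), class = "spinecurve_domain_error")
  set.seed(3)
  for (k in 1:50) {
    a <- rnorm(2); b <- rnorm(2)
    expect_equal(signed_angle(a, b), -signed_angle(b, a), tolerance = 1e-9)
    phi <- runif(1, -pi, pi)
    R <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2, 2)
    expect_equal(abs(signed_angle(R %*% a, R %*% b)), abs(signed_angle(a, b)),
                 tolerance = 1e-9)
  }
})

test_that("plane projection drops the correct LAI axis", {
  expect_equal(project_to_plane(c(1, 2, 3), "sagittal"), c(2, 3))
  expect_equal(project_to_plane(c(1, 2, 3), "coronal"), c(1, 3))
  expect_error(spinecurve:::project_direction(c(1, 0, 0), "sagittal"),
               class = "spinecurve_degenerate_projection")
})

test_that("rotation_from_plane_angles is a rotation about the expected axes", {
  expect_equal(rotation_from_plane_angles(0, 0), diag(4))
  # 90 degrees about the left axis maps anterior onto inferior
  T <- rotation_from_plane_angles(90, 0)
  expect_equal(drop(T[1:3, 1:3] %*% c(0, 1, 0)), c(0, 0, 1), tolerance = 1e-12)
  # small-angle agreement with sequential x-then-y rotations: O(theta^2)
  Ta <- rotation_from_plane_angles(1, 1)
  Tb <- rotation_from_plane_angles(1, 1, method = "euler_xy")
  expect_lt(max(abs(Ta - Tb)), 3e-4)
  set.seed(11)
  for (k in 1:1000) {
    T <- rotation_from_plane_angles(runif(1, -180, 180), runif(1, -180, 180))
    R <- T[1:3, 1:3]
    expect_lt(max(abs(crossprod(R) - diag(3))), 1e-9)
  }
})
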