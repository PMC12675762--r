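# ---- in-plane (2D) primitives -----------------------------------------------
#
# All planar work uses (u, v) coordinates where v is the cranio-caudal
# ("height") coordinate, increasing caudally.  Angles are degrees in the
# public API, radians internally.

DEG <- 180 / pi

#' Construct a planar Bezier curve
#'
#' A Bezier curve \eqn{C(t) = \sum_i B_{i,k-1}(t) p_i} on \eqn{t \in [0,1]}
#' defined by at least two control points in a named anatomical plane.
#' The curve interpolates its first control point at `t = 0` and its last at
#' `t = 1`.
#'
#' @param control_points numeric matrix with one row per control point and two
#'   columns (u, v), in mm. At least two rows.
#' @param plane `"sagittal"` or `"coronal"`.
#' @return an object of class `bezier_curve`.
#' @export
bezier_curve <- function(control_points, plane = c("sagittal", "coronal")) {
  plane <- match.arg(plane)
  cp <- as.matrix(control_points)
  if (!is.numeric(cp) || ncol(cp) != 2 || nrow(cp) < 2)
    stop("control_points must be a numeric k x 2 matrix with k >= 2")
  if (any(!is.finite(cp)))
    stop("control points must be finite")
  structure(list(control_points = unname(cp), plane = plane),
            class = "bezier_curve")
}

#' @export
print.bezier_curve <- function(x, ...) {
  cat(sprintf("<bezier_curve> degree %d, %s plane\n",
              nrow(x$control_points) - 1L, x$plane))
  invisible(x)
}

#' Evaluate a Bezier curve
#'
#' Bernstein-form evaluation of \eqn{C(t)}.
#'
#' @param curve a [bezier_curve()].
#' @param t parameter(s) in \[0, 1\].
#' @return numeric matrix, one row per `t`, columns (u, v).
#' @export
bezier_eval <- function(curve, t) {
  stopifnot(inherits(curve, "bezier_curve"))
  if (any(!is.finite(t)) || any(t < 0) || any(t > 1))
    stop(errorCondition("t must lie in [0, 1]", class = "spinecurve_domain_error"))
  cp <- curve$control_points
  n <- nrow(cp) - 1L
  # Bernstein basis matrix: length(t) x (n+1)
  B <- vapply(0:n, function(i) choose(n, i) * t^i * (1 - t)^(n - i),
              numeric(length(t)))
  B <- matrix(B, nrow = length(t))
  out <- B %*% cp
  colnames(out) <- c("u", "v")
  out
}

#' Tangent (first derivative) of a Bezier curve
#'
#' Returns the unnormalized hodograph value
#' \eqn{C'(t) = k \sum_i B_{i,k-2}(t)(p_{i+1}-p_i)}; callers may normalize.
#'
#' @inheritParams bezier_eval
#' @return numeric matrix, one row per `t`, columns (u, v).
#' @export
bezier_tangent <- function(curve, t) {
  stopifnot(inherits(curve, "bezier_curve"))
  if (any(!is.finite(t)) || any(t < 0) || any(t > 1))
    stop(errorCondition("t must lie in [0, 1]", class = "spinecurve_domain_error"))
  cp <- curve$control_points
  n <- nrow(cp) - 1L
  d <- n * diff(cp)                       # hodograph control points
  if (all(abs(d) < 1e-12))
    stop(errorCondition("degenerate curve: all control points identical",
                        class = "spinecurve_zero_tangent"))
  if (n == 1L) {
    out <- matrix(rep(d, each = length(t)), ncol = 2)
  } else {
    hod <- bezier_curve(d, curve$plane)
    out <- bezier_eval(hod, t)
  }
  colnames(out) <- c("u", "v")
  out
}

# Bernstein -> power basis: coefficients c_j of sum_j c_j t^j for each
# coordinate of the curve.  Exact combinatorial conversion; fine for the low
# degrees (<= 7) this pipeline produces.
bezier_power_coefs <- function(curve) {
  cp <- curve$control_points
  n <- nrow(cp) - 1L
  coefs <- matrix(0, nrow = n + 1L, ncol = 2)
  for (j in 0:n) {
    s <- c(0, 0)
    for (i in 0:j)
      s <- s + (-1)^(j - i) * choose(j, i) * cp[i + 1L, ]
    coefs[j + 1L, ] <- choose(n, j) * s
  }
  coefs   # row j+1 = coefficient of t^j, columns (u, v)
}

# Real roots of a univariate polynomial (power-basis coefficients, ascending)
# restricted to [lo - tol, hi + tol], polished with uniroot when bracketed.
poly_roots_in <- function(coefs, lo = 0, hi = 1, tol = 1e-9) {
  # drop numerically-dead leading terms (cancellation residue when a high
  # degree curve is geometrically a line); harmless for roots in [0, 1]
  eps <- 1e-10 * max(abs(coefs), 1)
  while (length(coefs) > 1 && abs(coefs[length(coefs)]) < eps)
    coefs <- coefs[-length(coefs)]
  if (length(coefs) <= 1) return(numeric(0))   # constant: no isolated roots
  r <- polyroot(coefs)
  re <- Re(r)[abs(Im(r)) < 1e-7]
  re <- re[re >= lo - 1e-9 & re <= hi + 1e-9]
  if (!length(re)) return(numeric(0))
  f <- function(t) drop(outer(t, seq_along(coefs) - 1, `^`) %*% coefs)
  re <- pmin(pmax(re, lo), hi)
  # polish: bracket each root locally and refine
  polished <- vapply(re, function(t0) {
    h <- 1e-4
    a <- max(lo, t0 - h); b <- min(hi, t0 + h)
    fa <- f(a); fb <- f(b)
    if (is.finite(fa) && is.finite(fb) && sign(fa) != sign(fb))
      stats::uniroot(f, c(a, b), tol = tol)$root
    else t0
  }, numeric(1))
  sort(unique(round(polished, 12)))
}

#' Line in the plane
#'
#' @param point numeric length-2, a point on the line.
#' @param direction numeric length-2 direction; normalized internally.
#' @return an object of class `line2d`. For non-vertical lines a
#'   slope/intercept view (`m`, `b`) is attached; vertical lines carry
#'   `vertical = TRUE` instead.
#' @export
line2d <- function(point, direction) {
  point <- as.numeric(point); direction <- as.numeric(direction)
  nrm <- sqrt(sum(direction^2))
  if (!is.finite(nrm) || nrm < 1e-12) stop("line direction must be nonzero")
  d <- direction / nrm
  vertical <- abs(d[1]) < 1e-12
  l <- list(point = point, direction = d, vertical = vertical)
  if (!vertical) {
    l$m <- d[2] / d[1]
    l$b <- point[2] - l$m * point[1]
  }
  structure(l, class = "line2d")
}

#' Intersect two rays/lines
#'
#' Solves `a$point + s_a a$direction == b$point + s_b b$direction`. When the
#' directions are parallel within `parallel_tol` (including the collinear
#' anti-parallel case of a straight spine) a `parallel` flag is returned
#' instead of a point.
#'
#' @param a,b [line2d()] objects.
#' @param parallel_tol threshold on the cross product of the unit directions.
#' @return list with `parallel`; when `FALSE` also `point`, `s_a`, `s_b`.
#' @export
intersect_lines <- function(a, b, parallel_tol = 1e-9) {
  stopifnot(inherits(a, "line2d"), inherits(b, "line2d"))
  cr <- a$direction[1] * b$direction[2] - a$direction[2] * b$direction[1]
  if (abs(cr) <= parallel_tol) return(list(parallel = TRUE))
  dp <- b$point - a$point
  s_a <- (dp[1] * b$direction[2] - dp[2] * b$direction[1]) / cr
  s_b <- (dp[1] * a$direction[2] - dp[2] * a$direction[1]) / cr
  list(parallel = FALSE, point = a$point + s_a * a$direction, s_a = s_a, s_b = s_b)
}

#' Intersect a Bezier curve with a line
#'
#' Finds the parameter `t` in \[0, 1\] where the signed distance from `C(t)`
#' to the line vanishes. The signed distance is polynomial in `t`, so roots
#' come from the power-basis polynomial; among multiple roots the one nearest
#' `t_hint` is returned.
#'
#' @param curve a [bezier_curve()].
#' @param line a [line2d()].
#' @param t_hint preferred root location (e.g. a chain fraction).
#' @return list `t`, `point`, `found`; `found = FALSE` (class
#'   `spinecurve_no_intersection` condition is NOT raised here, caller policy
#'   decides) when no root lies in \[0, 1\].
#' @export
intersect_curve_line <- function(curve, line, t_hint = 0.5) {
  stopifnot(inherits(curve, "bezier_curve"), inherits(line, "line2d"))
  pc <- bezier_power_coefs(curve)
  d <- line$direction; p <- line$point
  # signed distance ~ cross(d, C(t) - p): d_u * (Cv - pv) - d_v * (Cu - pu)
  coefs <- d[1] * pc[, 2] - d[2] * pc[, 1]
  coefs[1] <- coefs[1] - (d[1] * p[2] - d[2] * p[1])
  roots <- poly_roots_in(coefs)
  if (!length(roots)) return(list(found = FALSE, t = NA_real_, point = c(NA_real_, NA_real_)))
  t <- roots[which.min(abs(roots - t_hint))]
  list(found = TRUE, t = t, point = drop(bezier_eval(curve, t)))
}

#' Point on a Bezier curve at a given height
#'
#' Solves \eqn{C_v(t) = v_{target}} on \[0, 1\]; with several roots the
#' smallest (most cranial) `t` is returned.
#'
#' @param curve a [bezier_curve()].
#' @param v_target target height (v-coordinate), mm.
#' @return list `t`, `point`.
#' @export
curve_point_at_height <- function(curve, v_target) {
  stopifnot(inherits(curve, "bezier_curve"))
  pc <- bezier_power_coefs(curve)
  coefs <- pc[, 2]
  coefs[1] <- coefs[1] - v_target
  roots <- poly_roots_in(coefs)
  if (!length(roots))
    stop(errorCondition(
      sprintf("height %.3f outside the curve's v-range", v_target),
      class = "spinecurve_out_of_range"))
  t <- roots[1]
  list(t = t, point = drop(bezier_eval(curve, t)))
}

#' Signed angle between two planar vectors
#'
#' Magnitude \eqn{\arccos(a \cdot b / |a||b|)} in degrees; sign from the 2D
#' cross product (counterclockwise positive in the (u, v) chart).
#'
#' @param ref,target numeric length-2, nonzero.
#' @return degrees in \[-180, 180\].
#' @export
signed_angle <- function(ref, target) {
  ref <- as.numeric(ref); target <- as.numeric(target)
  na <- sqrt(sum(ref^2)); nb <- sqrt(sum(target^2))
  if (na < 1e-12 || nb < 1e-12)
    stop(errorCondition("signed_angle of zero vector",
                        class = "spinecurve_domain_error"))
  cosv <- min(1, max(-1, sum(ref * target) / (na * nb)))
  mag <- acos(cosv) * DEG
  cr <- ref[1] * target[2] - ref[2] * target[1]
  if (cr < 0) -mag else mag
}

# ---- 3D / LAI-plane plumbing ------------------------------------------------
#
# 3D coordinates follow the scan's LAI orientation: x = left, y = anterior,
# z = inferior.  Sagittal plane chart: (u, v) = (anterior, inferior) = (y, z).
# Coronal plane chart:  (u, v) = (left, inferior) = (x, z).

#' Project a 3D point or direction onto an anatomical plane
#'
#' @param p3 numeric length-3 in LAI coordinates, or a matrix with 3 columns.
#' @param plane `"sagittal"` or `"coronal"`.
#' @return (u, v) coordinates; matrix input gives matrix output.
#' @export
project_to_plane <- function(p3, plane = c("sagittal", "coronal")) {
  plane <- match.arg(plane)
  idx <- if (plane == "sagittal") c(2L, 3L) else c(1L, 3L)
  if (is.matrix(p3)) {
    out <- p3[, idx, drop = FALSE]
    colnames(out) <- c("u", "v")
    out
  } else {
    as.numeric(p3)[idx]
  }
}

# project a unit direction and renormalize; error if (nearly) perpendicular
# to the plane
project_direction <- function(d3, plane, what = "direction") {
  p <- project_to_plane(d3, plane)
  n <- sqrt(sum(p^2))
  if (n < 1e-6)
    stop(errorCondition(
      sprintf("%s is perpendicular to the %s plane", what, plane),
      class = "spinecurve_degenerate_projection"))
  p / n
}

rot_x <- function(a) matrix(c(1, 0, 0,
                              0, cos(a), sin(a),
                              0, -sin(a), cos(a)), 3, 3)
rot_y <- function(a) matrix(c(cos(a), 0, -sin(a),
                              0, 1, 0,
                              sin(a), 0, cos(a)), 3, 3)

# Rodrigues rotation from a rotation vector (radians)
rotvec_to_matrix <- function(r) {
  th <- sqrt(sum(r^2))
  if (th < 1e-300) return(diag(3))
  k <- r / th
  K <- matrix(c(0, k[3], -k[2],
                -k[3], 0, k[1],
                k[2], -k[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Combined 3D rotation from per-plane correction angles
#'
#' The sagittal correction acts about the left (x) axis and the coronal
#' correction about the anterior (y) axis. The two are combined through the
#' rotation-vector exponential of \eqn{r_\theta = [\theta_s, \theta_c, 0]}
#' (axis \eqn{r_\theta/|r_\theta|}, angle \eqn{|r_\theta|}), which is
#' order-free in the two planes; a fixed x-then-y Euler composition is
#' available via `method = "euler_xy"` and differs at \eqn{O(\theta^2)}.
#'
#' @param theta_s sagittal-plane correction, degrees.
#' @param theta_c coronal-plane correction, degrees.
#' @param method `"rotvec"` (default) or `"euler_xy"`.
#' @return 4x4 homogeneous rigid transform (pure rotation).
#' @export
rotation_from_plane_angles <- function(theta_s, theta_c, method = c("rotvec", "euler_xy")) {
  method <- match.arg(method)
  stopifnot(is.finite(theta_s), is.finite(theta_c))
  r <- c(theta_s, theta_c, 0) / DEG
  R <- if (method == "rotvec") rotvec_to_matrix(r)
       else rot_y(r[2]) %*% rot_x(r[1])
  T <- diag(4)
  T[1:3, 1:3] <- R
  T
}
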