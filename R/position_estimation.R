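# Position estimation: place the untracked vertebrae's CoMs on the estimated
# curve, transferring the CT-time chain fractions either through the height
# difference of the tracked pair (PE_H) or through perpendiculars to their
# chord (PE_P).

new_position_estimate <- function(com2d, t, method, fallback) {
  structure(list(com2d = com2d, t = t, method = method, fallback = fallback),
            class = "position_estimate")
}

#' Position estimation by height fraction (PE_H)
#'
#' Each intermediate vertebra's target height is
#' \eqn{v_i = v_0 + \%d_i \, h_t}; its CoM is the (most cranial) point of the
#' estimated curve at that height.
#'
#' @param est a `curve_estimate`.
#' @param view the [planar_view()] the curve was estimated from.
#' @param fractions chain fractions, length n - 2.
#' @return `position_estimate`: `com2d` ((n-2) x 2), curve parameters `t`,
#'   `method = "H"`, logical `fallback` (always `FALSE` for PE_H).
#' @export
estimate_positions_H <- function(est, view, fractions) {
  stopifnot(inherits(est, "curve_estimate"), inherits(view, "planar_view"))
  if (abs(view$h_t) < 1e-6)
    stop(errorCondition("tracked CoMs are level (h_t ~ 0); PE_H undefined",
                        class = "spinecurve_degenerate_height"))
  v0 <- view$com2d[1, 2]
  m <- length(fractions)
  com2d <- matrix(NA_real_, m, 2)
  tt <- numeric(m)
  labs <- seq_len(m) + 1L
  for (i in seq_len(m)) {
    hit <- tryCatch(curve_point_at_height(est$curve, v0 + fractions[i] * view$h_t),
                    spinecurve_out_of_range = function(e)
                      stop(errorCondition(
                        sprintf("vertebra %d: target height outside the curve", labs[i]),
                        class = "spinecurve_out_of_range")))
    com2d[i, ] <- hit$point
    tt[i] <- hit$t
  }
  new_position_estimate(com2d, tt, "H", rep(FALSE, m))
}

#' Position estimation by chord perpendiculars (PE_P)
#'
#' Base points are spaced along the tracked chord by the chain fractions,
#' \eqn{(x_i, y_i) = CM_0 + \hat u \, \%d_i \, d_{pos}}; through each base
#' point the line perpendicular to the chord is intersected with the curve
#' (perpendicularity is taken direction-vector-wise, so vertical and
#' horizontal chords are safe). If a perpendicular misses the curve the CoM
#' falls back to the nearest curve point and the vertebra is flagged, unless
#' `strict` is set.
#'
#' @inheritParams estimate_positions_H
#' @param strict error instead of nearest-point fallback on a missed
#'   intersection.
#' @return `position_estimate` with `method = "P"`.
#' @export
estimate_positions_P <- function(est, view, fractions, strict = FALSE) {
  stopifnot(inherits(est, "curve_estimate"), inherits(view, "planar_view"))
  n <- nrow(view$com2d)
  cm0 <- view$com2d[1, ]; cmn <- view$com2d[n, ]
  u <- (cmn - cm0) / view$d_pos
  perp <- c(-u[2], u[1])                  # u rotated by 90 degrees
  m <- length(fractions)
  com2d <- matrix(NA_real_, m, 2)
  tt <- numeric(m)
  fb <- logical(m)
  for (i in seq_len(m)) {
    base <- cm0 + u * fractions[i] * view$d_pos
    ln <- line2d(base, perp)
    hit <- intersect_curve_line(est$curve, ln, t_hint = fractions[i])
    if (hit$found) {
      com2d[i, ] <- hit$point
      tt[i] <- hit$t
    } else {
      if (strict)
        stop(errorCondition(
          sprintf("vertebra %d: perpendicular does not intersect the curve", i + 1L),
          class = "spinecurve_no_intersection"))
      np <- nearest_point_on_curve_to_line(est$curve, ln)
      com2d[i, ] <- np$point
      tt[i] <- np$t
      fb[i] <- TRUE
      warning(sprintf(
        "vertebra %d: perpendicular missed the curve; nearest-point fallback used",
        i + 1L))
    }
  }
  new_position_estimate(com2d, tt, "P", fb)
}

# nearest point of C(t), t in [0,1], to a line (minimum |signed distance|);
# coarse grid + local refinement, only used on degraded geometry
nearest_point_on_curve_to_line <- function(curve, line, n_grid = 512) {
  t <- seq(0, 1, length.out = n_grid)
  pts <- bezier_eval(curve, t)
  d <- line$direction
  sd <- abs(d[1] * (pts[, 2] - line$point[2]) - d[2] * (pts[, 1] - line$point[1]))
  i <- which.min(sd)
  lo <- t[max(1, i - 1)]; hi <- t[min(n_grid, i + 1)]
  f <- function(s) {
    p <- drop(bezier_eval(curve, s))
    abs(d[1] * (p[2] - line$point[2]) - d[2] * (p[1] - line$point[1]))
  }
  opt <- stats::optimize(f, c(lo, hi), tol = 1e-10)
  list(t = opt$minimum, point = drop(bezier_eval(curve, opt$minimum)))
}

estimate_positions <- function(est, view, fractions, method = c("H", "P"),
                               strict = FALSE) {
  method <- match.arg(method)
  if (method == "H") estimate_positions_H(est, view, fractions)
  else estimate_positions_P(est, view, fractions, strict = strict)
}
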