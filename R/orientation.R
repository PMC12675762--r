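# Orientation correction: per-plane signed angles that rotate each untracked
# vertebra to follow the estimated curve, and their combination into one 3D
# rotation composed onto registration-time orientation.
#
# Sign conventions. In-plane angles are counterclockwise-positive in the
# (u, v) chart. In the sagittal chart (anterior, inferior) a counterclockwise
# in-plane rotation equals a positive rotation about the left (x) axis; in
# the coronal chart (left, inferior) it equals a NEGATIVE rotation about the
# anterior (y) axis. apply_corrections() performs that axis-sign mapping, so
# the per-plane corrections themselves stay chart-local.

new_orientation_correction <- function(theta, tangent, reference, method, plane) {
  structure(list(theta = theta, tangent = tangent, reference = reference,
                 method = method, plane = plane),
            class = "orientation_correction")
}

tangent_at <- function(est, t) {
  tg <- drop(bezier_tangent(est$curve, t))
  nr <- sqrt(sum(tg^2))
  if (nr < 1e-12)
    stop(errorCondition("zero curve tangent", class = "spinecurve_zero_tangent"))
  tg / nr
}

#' Orientation correction relative to the superior tracked vertebra (STV)
#'
#' The curve tangent at the superior tracked CoM, \eqn{t_0 = C'(0)}, is the
#' reference; each intermediate vertebra is assigned the signed angle
#' \eqn{\theta_i = \angle(t_0, t_i)} between that reference and the tangent
#' at its own curve parameter — the curve's local deviation from the superior
#' tangent, later composed onto the vertebra's registration-time orientation.
#'
#' @param est a `curve_estimate`.
#' @param pos a `position_estimate` carrying the curve parameters.
#' @return `orientation_correction`: per-vertebra `theta` (degrees),
#'   unit `tangent` rows, unit `reference` rows, `method = "STV"`.
#' @export
correct_orientation_STV <- function(est, pos) {
  stopifnot(inherits(est, "curve_estimate"), inherits(pos, "position_estimate"))
  t0 <- tangent_at(est, 0)
  m <- length(pos$t)
  tangents <- t(vapply(pos$t, function(ti) tangent_at(est, ti), numeric(2)))
  theta <- vapply(seq_len(m), function(i) signed_angle(t0, tangents[i, ]),
                  numeric(1))
  new_orientation_correction(theta, tangents,
                             matrix(t0, m, 2, byrow = TRUE),
                             "STV", est$curve$plane)
}

#' Orientation correction by the intermediate endplate vector (IVN)
#'
#' Each intermediate vertebra's registration-time endplate normals define the
#' intermediate vector \eqn{v_i = (n_{Ii} - n_{Si}) / 2} (projected,
#' caudal-pointing); the correction is the signed angle
#' \eqn{\theta_i = \angle(v_i, t_i)} that turns it onto the curve tangent at
#' the vertebra's estimated position.
#'
#' @inheritParams correct_orientation_STV
#' @param view the registration-time (initial) [planar_view()] providing the
#'   projected endplate normals of the intermediate vertebrae.
#' @return `orientation_correction` with `method = "IVN"`.
#' @export
correct_orientation_IVN <- function(est, pos, view) {
  stopifnot(inherits(est, "curve_estimate"), inherits(pos, "position_estimate"),
            inherits(view, "planar_view"))
  m <- length(pos$t)
  tangents <- t(vapply(pos$t, function(ti) tangent_at(est, ti), numeric(2)))
  vi <- (view$n_inf2d[2:(m + 1L), , drop = FALSE] -
           view$n_sup2d[2:(m + 1L), , drop = FALSE]) / 2
  theta <- numeric(m)
  for (i in seq_len(m)) {
    if (sqrt(sum(vi[i, ]^2)) < 1e-9)
      stop(errorCondition(
        sprintf("vertebra %d: endplate normals coincide, intermediate vector is zero",
                i + 1L),
        class = "spinecurve_domain_error"))
    theta[i] <- signed_angle(vi[i, ], tangents[i, ])
  }
  new_orientation_correction(theta, tangents, vi, "IVN", est$curve$plane)
}

# counterclockwise in-plane angle -> signed rotation about the plane's axis
plane_axis_angle <- function(theta_inplane, plane) {
  if (plane == "sagittal") theta_inplane else -theta_inplane
}

#' Apply the combined per-plane corrections to a segment
#'
#' Reassembles each intermediate vertebra in 3D from the two planar
#' estimates: the coronal estimate supplies the left coordinate, the sagittal
#' estimate the anterior coordinate, and the duplicated inferior coordinate
#' is reconciled by averaging. The sagittal and coronal correction angles are
#' combined into one rotation (see [rotation_from_plane_angles()]) composed
#' onto the registration-time orientation — never onto the previous frame, so
#' repeated updates cannot drift. Tracked vertebrae are left untouched.
#'
#' @param segment a [spine_segment()].
#' @param sagittal,coronal `orientation_correction`s for the two planes.
#' @param pos_sagittal,pos_coronal matching `position_estimate`s.
#' @param rotation_method passed to [rotation_from_plane_angles()].
#' @return the segment with intermediate vertebrae re-placed, re-oriented and
#'   un-flagged.
#' @export
apply_corrections <- function(segment, sagittal, coronal,
                              pos_sagittal, pos_coronal,
                              rotation_method = "rotvec") {
  m <- length(segment$vertebrae) - 2L
  if (length(sagittal$theta) != m || length(coronal$theta) != m ||
      nrow(pos_sagittal$com2d) != m || nrow(pos_coronal$com2d) != m)
    stop("correction/position lists do not cover the intermediate vertebrae")
  for (i in seq_len(m)) {
    idx <- i + 1L
    v0 <- segment$initial[[idx]]
    sag <- pos_sagittal$com2d[i, ]   # (anterior, inferior)
    cor <- pos_coronal$com2d[i, ]    # (left, inferior)
    com <- c(cor[1], sag[1], (sag[2] + cor[2]) / 2)
    T <- rotation_from_plane_angles(plane_axis_angle(sagittal$theta[i], "sagittal"),
                                    plane_axis_angle(coronal$theta[i], "coronal"),
                                    method = rotation_method)
    R <- T[1:3, 1:3]
    v <- v0
    v$com <- com
    v$n_sup <- drop(R %*% v0$n_sup)
    v$n_inf <- drop(R %*% v0$n_inf)
    pose <- diag(4)
    pose[1:3, 1:3] <- R %*% v0$pose[1:3, 1:3]
    pose[1:3, 4] <- com
    v$pose <- pose
    v$stale <- FALSE
    segment$vertebrae[[idx]] <- v
  }
  segment
}
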