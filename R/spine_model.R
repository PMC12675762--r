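# ---- rigid transforms -------------------------------------------------------

#' Validate a 4x4 rigid transform
#'
#' Checks the rotation block is orthonormal with determinant +1 and the last
#' row is (0, 0, 0, 1).
#'
#' @param T 4x4 numeric matrix.
#' @param tol orthonormality tolerance.
#' @return `T`, invisibly, or an error of class `spinecurve_invalid_transform`.
#' @export
check_rigid <- function(T, tol = 1e-9) {
  ok <- is.matrix(T) && all(dim(T) == c(4, 4)) && all(is.finite(T)) &&
    all(abs(T[4, ] - c(0, 0, 0, 1)) <= tol)
  if (ok) {
    R <- T[1:3, 1:3]
    ok <- max(abs(crossprod(R) - diag(3))) <= max(tol, 1e-7) && det(R) > 0
  }
  if (!ok)
    stop(errorCondition("not a rigid 4x4 transform",
                        class = "spinecurve_invalid_transform"))
  invisible(T)
}

rigid_inverse <- function(T) {
  R <- T[1:3, 1:3]
  out <- diag(4)
  out[1:3, 1:3] <- t(R)
  out[1:3, 4] <- -t(R) %*% T[1:3, 4]
  out
}

apply_rigid_point <- function(T, p) drop(T[1:3, 1:3] %*% p + T[1:3, 4])
apply_rigid_dir   <- function(T, d) drop(T[1:3, 1:3] %*% d)

#' Pose of a tracked vertebra relative to the superior tracked reference
#'
#' The superior tracked vertebra is held as a fixed reference during surgery;
#' every other tracked pose reported by the optical tracking system (OTS) is
#' re-expressed in its frame:
#' \deqn{T_{rel} = (T^{OTS}_{VR_0})^{-1} \, T^{OTS}_{VR_i}.}
#' Any rigid motion common to all OTS poses (patient repositioning on the
#' table) cancels exactly.
#'
#' @param T_ots_vr0 OTS pose of the superior tracked vertebra.
#' @param T_ots_vri OTS pose of the i-th tracked vertebra.
#' @return 4x4 relative transform.
#' @export
relative_pose <- function(T_ots_vr0, T_ots_vri) {
  check_rigid(T_ots_vr0); check_rigid(T_ots_vri)
  rigid_inverse(T_ots_vr0) %*% T_ots_vri
}

# ---- vertebra / segment -----------------------------------------------------

#' Construct a vertebra
#'
#' @param label vertebra name, e.g. `"L1"`.
#' @param com center of mass, LAI mm, length-3.
#' @param n_sup unit normal of the superior endplate, pointing cranially
#'   (negative inferior component for a roughly upright vertebra).
#' @param n_inf unit normal of the inferior endplate, pointing caudally.
#' @param pose 4x4 rigid placement in the segment reference frame.
#' @return object of class `vertebra`.
#' @export
vertebra <- function(label, com, n_sup, n_inf, pose = diag(4)) {
  com <- as.numeric(com); n_sup <- as.numeric(n_sup); n_inf <- as.numeric(n_inf)
  stopifnot(length(com) == 3, length(n_sup) == 3, length(n_inf) == 3,
            all(is.finite(c(com, n_sup, n_inf))))
  normalize <- function(v, what) {
    n <- sqrt(sum(v^2))
    if (n < 1e-6) stop(sprintf("%s normal of %s is zero", what, label))
    v / n
  }
  n_sup <- normalize(n_sup, "superior")
  n_inf <- normalize(n_inf, "inferior")
  if (sum(n_sup * n_inf) >= 0)
    warning(sprintf("vertebra %s: endplate normals do not oppose (n_sup.n_inf >= 0)",
                    label))
  check_rigid(pose, tol = 1e-7)
  structure(list(label = label, com = com, n_sup = n_sup, n_inf = n_inf,
                 pose = pose, stale = FALSE),
            class = "vertebra")
}

#' Construct a spine segment
#'
#' An ordered (superior to inferior) chain of vertebrae, of which at least the
#' first and last are tracked. The construction-time geometry is retained as
#' the registration (CT-time) snapshot against which intraoperative motion and
#' baseline angle tables are referenced; the chain fractions of the
#' intermediate vertebrae are computed from it.
#'
#' @param vertebrae list of [vertebra()] objects, superior first.
#' @param tracked integer indices (1-based) or labels of tracked vertebrae;
#'   must include the first and last vertebra.
#' @param registration_poses optional named/indexed list of OTS poses captured
#'   at registration for the tracked vertebrae; defaults to identity, in which
#'   case intraoperative OTS poses are interpreted directly as motion relative
#'   to registration.
#' @param fraction_mode `"chain"` (cumulative polyline distance, default) or
#'   `"straight"` (projection on the end-to-end chord).
#' @return object of class `spine_segment`.
#' @export
spine_segment <- function(vertebrae, tracked = c(1L, length(vertebrae)),
                          registration_poses = NULL,
                          fraction_mode = c("chain", "straight")) {
  fraction_mode <- match.arg(fraction_mode)
  stopifnot(length(vertebrae) >= 2,
            all(vapply(vertebrae, inherits, logical(1), "vertebra")))
  labels <- vapply(vertebrae, `[[`, character(1), "label")
  if (anyDuplicated(labels)) stop("duplicate vertebra labels")
  if (is.character(tracked)) tracked <- match(tracked, labels)
  tracked <- sort(unique(as.integer(tracked)))
  if (any(is.na(tracked)) || !(1L %in% tracked) || !(length(vertebrae) %in% tracked))
    stop("tracked vertebrae must include the first and last of the segment")
  n <- length(vertebrae)
  fractions <- if (n >= 3) {
    coms <- t(vapply(vertebrae, `[[`, numeric(3), "com"))
    chain_fractions(coms, mode = fraction_mode)
  } else numeric(0)
  if (is.null(registration_poses)) {
    registration_poses <- rep(list(diag(4)), length(tracked))
    names(registration_poses) <- labels[tracked]
  }
  seg <- structure(list(vertebrae = vertebrae, labels = labels,
                        tracked = tracked, fractions = fractions,
                        fraction_mode = fraction_mode,
                        registration_poses = registration_poses,
                        initial = NULL),
                   class = "spine_segment")
  seg$initial <- seg$vertebrae   # CT-time snapshot
  seg
}

#' @export
print.spine_segment <- function(x, ...) {
  cat(sprintf("<spine_segment> %d vertebrae (%s), tracked: %s\n",
              length(x$vertebrae), paste(x$labels, collapse = " "),
              paste(x$labels[x$tracked], collapse = ", ")))
  invisible(x)
}

#' Chain fractions of intermediate vertebrae
#'
#' Fraction of the total center-of-mass chain length accumulated at each
#' intermediate vertebra in the initial CT:
#' \deqn{\%d_i = \sum_{j \le i} \|CM_j - CM_{j-1}\| / \sum_j \|CM_j - CM_{j-1}\|.}
#' These transfer the CT-time spacing onto the estimated intraoperative curve.
#'
#' @param coms numeric n x 3 (or n x 2) matrix of CoMs, superior first, n >= 3.
#' @param mode `"chain"` for cumulative polyline distance (default) or
#'   `"straight"` for the fraction of each CoM's projection on the chord.
#' @return numeric vector of length n - 2, strictly increasing in (0, 1).
#' @export
chain_fractions <- function(coms, mode = c("chain", "straight")) {
  mode <- match.arg(mode)
  coms <- as.matrix(coms)
  n <- nrow(coms)
  stopifnot(n >= 3)
  if (mode == "chain") {
    d <- sqrt(rowSums(diff(coms)^2))
    if (any(d < 1e-9)) stop("consecutive CoMs coincide")
    f <- cumsum(d) / sum(d)
    f[seq_len(n - 2L)]
  } else {
    chord <- coms[n, ] - coms[1, ]
    L2 <- sum(chord^2)
    if (L2 < 1e-12) stop("tracked CoMs coincide")
    f <- as.numeric((coms[2:(n - 1L), , drop = FALSE] -
                       matrix(coms[1, ], n - 2L, ncol(coms), byrow = TRUE)) %*% chord / L2)
    if (any(diff(c(0, f, 1)) <= 0)) stop("straight-line fractions not increasing")
    f
  }
}

#' Planar view of a segment
#'
#' Projects the segment's current CoMs and endplate normals onto one
#' anatomical plane, renormalizing projected normals, and derives the two
#' scalars the estimation algorithms need: `d_pos`, the in-plane distance
#' between the tracked CoMs, and `h_t`, their height (v-coordinate)
#' difference.
#'
#' @param segment a [spine_segment()].
#' @param plane `"sagittal"` or `"coronal"`.
#' @param which `"current"` or `"initial"` (registration snapshot) geometry.
#' @return list of class `planar_view` with `com2d` (n x 2), `n_sup2d`,
#'   `n_inf2d`, `d_pos`, `h_t`, `plane`.
#' @export
planar_view <- function(segment, plane = c("sagittal", "coronal"),
                        which = c("current", "initial")) {
  plane <- match.arg(plane); which <- match.arg(which)
  vs <- if (which == "current") segment$vertebrae else segment$initial
  n <- length(vs)
  com2d <- t(vapply(vs, function(v) project_to_plane(v$com, plane), numeric(2)))
  n_sup2d <- t(vapply(vs, function(v)
    project_direction(v$n_sup, plane, sprintf("superior normal of %s", v$label)),
    numeric(2)))
  n_inf2d <- t(vapply(vs, function(v)
    project_direction(v$n_inf, plane, sprintf("inferior normal of %s", v$label)),
    numeric(2)))
  d_pos <- sqrt(sum((com2d[n, ] - com2d[1, ])^2))
  if (d_pos < 1e-6)
    stop(errorCondition("tracked CoMs coincide in this plane",
                        class = "spinecurve_coincident_tracked"))
  structure(list(plane = plane, com2d = com2d, n_sup2d = n_sup2d,
                 n_inf2d = n_inf2d, d_pos = d_pos,
                 h_t = com2d[n, 2] - com2d[1, 2]),
            class = "planar_view")
}

#' Apply intraoperative OTS poses to the tracked vertebrae
#'
#' The superior tracked vertebra stays at its registered placement. Every
#' other tracked vertebra is moved by the change of its relative pose
#' since registration: with `A = relative_pose(ots[VR0], ots[VRi])` now and
#' `B` the same quantity at registration time, the motion `A B^{-1}` is
#' composed onto the registration-time geometry. Untracked vertebrae are
#' flagged stale until the estimation pipeline re-places them.
#'
#' @param segment a [spine_segment()].
#' @param ots_poses named list (by label) or indexed list of 4x4 OTS poses
#'   covering every tracked vertebra.
#' @return the updated segment.
#' @export
update_tracked_poses <- function(segment, ots_poses) {
  labs <- segment$labels[segment$tracked]
  if (!is.null(names(ots_poses))) {
    missing <- setdiff(labs, names(ots_poses))
    if (length(missing))
      stop(sprintf("missing OTS pose for tracked vertebra %s",
                   paste(missing, collapse = ", ")))
    poses <- ots_poses[labs]
  } else {
    if (length(ots_poses) != length(labs))
      stop("unnamed ots_poses must match the number of tracked vertebrae")
    poses <- ots_poses
    names(poses) <- labs
  }
  for (p in poses) check_rigid(p, tol = 1e-7)
  T0_now <- poses[[1]]
  T0_reg <- segment$registration_poses[[labs[1]]]
  for (k in seq_along(segment$tracked)) {
    i <- segment$tracked[k]
    lab <- labs[k]
    A <- relative_pose(T0_now, poses[[lab]])
    B <- relative_pose(T0_reg, segment$registration_poses[[lab]])
    M <- A %*% rigid_inverse(B)          # identity for VR0 by construction
    v0 <- segment$initial[[i]]
    v <- segment$vertebrae[[i]]
    v$com <- apply_rigid_point(M, v0$com)
    v$n_sup <- apply_rigid_dir(M, v0$n_sup)
    v$n_inf <- apply_rigid_dir(M, v0$n_inf)
    v$pose <- M %*% v0$pose
    v$stale <- FALSE
    segment$vertebrae[[i]] <- v
  }
  for (i in setdiff(seq_along(segment$vertebrae), segment$tracked))
    segment$vertebrae[[i]]$stale <- TRUE
  segment
}
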