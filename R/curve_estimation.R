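# Curve estimation: construct the Bezier control points that model the
# in-plane spinal curvature from the two tracked vertebrae.
#
# Both constructions anchor the curve at the projected CoMs of the tracked
# pair and shape it with the inferior endplate normal of the superior tracked
# vertebra (pointing caudally, into the segment) and the superior endplate
# normal of the inferior tracked vertebra (pointing cranially, into the
# segment).

#' Curve estimation from tracked endplate normals (EN)
#'
#' Case split on the two endplate-normal rays. If the ray from the superior
#' tracked CoM along its inferior endplate normal and the ray from the
#' inferior tracked CoM along its superior endplate normal intersect with both
#' ray parameters positive (the intersection lies between the vertebrae on
#' the concave side), a quadratic curve through `[CM_0, intersection,
#' CM_{n-1}]` is used. Otherwise, including parallel/collinear normals of a
#' straight spine, a cubic with the two inner control points offset by
#' `d_pos / 4` along each normal keeps the four control points equally
#' spaced.
#'
#' @param view a [planar_view()].
#' @return list of class `curve_estimate`: `curve`, `method = "EN"`,
#'   `case` (`"INTERSECTING"` or `"NON_INTERSECTING"`).
#' @export
estimate_curve_EN <- function(view) {
  stopifnot(inherits(view, "planar_view"))
  n <- nrow(view$com2d)
  cm0 <- view$com2d[1, ]; cmn <- view$com2d[n, ]
  d0 <- view$n_inf2d[1, ]        # caudal, unit after projection
  dn <- view$n_sup2d[n, ]        # cranial, unit after projection
  hit <- intersect_lines(line2d(cm0, d0), line2d(cmn, dn))
  if (!hit$parallel && hit$s_a > 1e-9 && hit$s_b > 1e-9) {
    cp <- rbind(cm0, hit$point, cmn)
    case <- "INTERSECTING"
  } else {
    cp <- rbind(cm0,
                cm0 + d0 * view$d_pos / 4,
                cmn + dn * view$d_pos / 4,
                cmn)
    case <- "NON_INTERSECTING"
  }
  structure(list(curve = bezier_curve(cp, view$plane),
                 method = "EN", case = case),
            class = "curve_estimate")
}

#' Curve estimation from endplate normals and initial positions (ENIP)
#'
#' One control point per vertebra. The endpoints are the projected tracked
#' CoMs; each intermediate vertebra contributes a point offset from the
#' nearer (by vertebra count) tracked CoM along that vertebra's endplate
#' normal ray, at its chain-fraction share of `d_pos`:
#' \deqn{p_i = CM_0 + n_{I0}\,\%d_i\,d_{pos}} from above, or
#' \deqn{p_i = CM_{n-1} + n_{S,n-1}\,(1-\%d_i)\,d_{pos}} from below; the
#' middle vertebra of an odd intermediate count takes the midpoint of the two
#' candidates.
#'
#' @param view a [planar_view()].
#' @param fractions chain fractions of the intermediate vertebrae
#'   (length n - 2).
#' @return list of class `curve_estimate` with `method = "ENIP"`.
#' @export
estimate_curve_ENIP <- function(view, fractions) {
  stopifnot(inherits(view, "planar_view"))
  n <- nrow(view$com2d)
  if (length(fractions) != n - 2L)
    stop("fractions must have one entry per intermediate vertebra")
  cm0 <- view$com2d[1, ]; cmn <- view$com2d[n, ]
  d0 <- view$n_inf2d[1, ]; dn <- view$n_sup2d[n, ]
  cp <- matrix(NA_real_, n, 2)
  cp[1, ] <- cm0; cp[n, ] <- cmn
  for (i in seq_len(n - 2L)) {            # vertebra index i (0-based i, here row i+1)
    from_top <- cm0 + d0 * fractions[i] * view$d_pos
    from_bot <- cmn + dn * (1 - fractions[i]) * view$d_pos
    n_above <- i            # vertebra count to the superior tracked
    n_below <- n - 1L - i   # vertebra count to the inferior tracked
    cp[i + 1L, ] <- if (n_above < n_below) from_top
                    else if (n_above > n_below) from_bot
                    else (from_top + from_bot) / 2
  }
  structure(list(curve = bezier_curve(cp, view$plane),
                 method = "ENIP", case = NA_character_),
            class = "curve_estimate")
}

estimate_curve <- function(view, fractions, method = c("EN", "ENIP")) {
  method <- match.arg(method)
  if (method == "EN") estimate_curve_EN(view)
  else estimate_curve_ENIP(view, fractions)
}
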