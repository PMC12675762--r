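# Independent oracles and small fixture builders shared across tests.

# recursive de Casteljau evaluation: independent of the Bernstein-form path
de_casteljau <- function(cp, t) {
  while (nrow(cp) > 1)
    cp <- (1 - t) * cp[-nrow(cp), , drop = FALSE] + t * cp[-1, , drop = FALSE]
  drop(cp)
}

# dense-sampling argmin of |signed distance to a line| over t in [0, 1]
argmin_distance_t <- function(curve, line, n = 1e4) {
  t <- seq(0, 1, length.out = n)
  pts <- bezier_eval(curve, t)
  d <- line$direction
  sd <- abs(d[1] * (pts[, 2] - line$point[2]) - d[2] * (pts[, 1] - line$point[1]))
  t[which.min(sd)]
}

random_rigid <- function() {
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  T <- diag(4)
  T[1:3, 1:3] <- spinecurve:::rotvec_to_matrix(ax * stats::runif(1, 0, pi))
  T[1:3, 4] <- stats::rnorm(3, sd = 50)
  T
}

# hand-built planar view (bypasses 3D projection) for unit tests of the
# estimation stages
mk_view <- function(com2d, n_sup2d, n_inf2d, plane = "sagittal") {
  com2d <- as.matrix(com2d)
  n <- nrow(com2d)
  structure(list(plane = plane, com2d = com2d,
                 n_sup2d = as.matrix(n_sup2d), n_inf2d = as.matrix(n_inf2d),
                 d_pos = sqrt(sum((com2d[n, ] - com2d[1, ])^2)),
                 h_t = com2d[n, 2] - com2d[1, 2]),
            class = "planar_view")
}

# straight-chain planar view with n vertebrae spaced `s` apart along v
straight_view <- function(n = 5, s = 25, plane = "sagittal") {
  com <- cbind(0, s * (seq_len(n) - 1))
  mk_view(com, matrix(c(0, -1), n, 2, byrow = TRUE),
          matrix(c(0, 1), n, 2, byrow = TRUE), plane)
}

# minimal 3-vertebra upright segment for model-level tests
mk_segment <- function(coms = rbind(c(0, 0, 0), c(0, 0, 30), c(0, 0, 60)),
                       labels = c("L1", "L2", "L3")) {
  verts <- lapply(seq_len(nrow(coms)), function(i)
    vertebra(labels[i], coms[i, ], c(0, 0, -1), c(0, 0, 1)))
  spine_segment(verts)
}
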