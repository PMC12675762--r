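mk_est <- function(cp, plane = "sagittal")
  structure(list(curve = bezier_curve(cp, plane), method = "EN", case = NA),
            class = "curve_estimate")

test_that("STV angles are the curve's tangent deviation from the superior tangent", {
  # straight curve: every tangent equals t_0
  view <- straight_view(5, 25)
  est <- estimate_curve_EN(view)
  pos <- estimate_positions_H(est, view, c(0.25, 0.5, 0.75))
  orc <- correct_orientation_STV(est, pos)
  expect_equal(orc$theta, rep(0, 3), tolerance = 1e-9)
  # symmetric quadratic: mirrored parameters give opposite signed angles
  est2 <- mk_est(rbind(c(0, 0), c(20, 50), c(0, 100)))
  pos2 <- structure(list(com2d = rbind(c(5, 18.75), c(5, 81.25)),
                         t = c(0.25, 0.75), method = "H",
                         fallback = c(FALSE, FALSE)),
                    class = "position_estimate")
  orc2 <- correct_orientation_STV(est2, pos2)
  # deviations from the apex tangent are antisymmetric at mirrored parameters
  t0 <- drop(bezier_tangent(est2$curve, 0))
  theta_mid <- signed_angle(t0, drop(bezier_tangent(est2$curve, 0.5)))
  expect_equal(orc2$theta[1] - theta_mid, -(orc2$theta[2] - theta_mid),
               tolerance = 1e-9)
  expect_gt(abs(orc2$theta[1]), 1)
  # 45-degree magnitude example
  expect_equal(abs(signed_angle(c(0, 1), c(1, 1) / sqrt(2))), 45)
})

test_that("IVN angles align the intermediate endplate vector with the tangent", {
  # v_i definition: (n_inf - n_sup) / 2
  view <- straight_view(5, 25)
  est <- estimate_curve_EN(view)
  pos <- estimate_positions_H(est, view, c(0.25, 0.5, 0.75))
  orc <- correct_orientation_IVN(est, pos, view)
  expect_equal(orc$reference, matrix(c(0, 1), 3, 2, byrow = TRUE),
               ignore_attr = TRUE)     # ((0,1) - (0,-1)) / 2
  expect_equal(orc$theta, rep(0, 3), tolerance = 1e-9)   # aligned case
  # v_i perpendicular to the tangent: 90-degree magnitude
  view90 <- view
  view90$n_sup2d[2, ] <- c(-1, 0)
  view90$n_inf2d[2, ] <- c(1, 0)
  orc90 <- correct_orientation_IVN(est, pos, view90)
  expect_equal(abs(orc90$theta[1]), 90, tolerance = 1e-9)
  # coincident normals make v_i vanish
  bad <- view
  bad$n_sup2d[3, ] <- c(0, 1)
  expect_error(correct_orientation_IVN(est, pos, bad),
               class = "spinecurve_domain_error")
})

test_that("STV and IVN coincide when every intermediate vector equals the superior tangent", {
  est <- mk_est(rbind(c(0, 0), c(15, 40), c(5, 100)))
  t0 <- drop(bezier_tangent(est$curve, 0)); t0 <- t0 / sqrt(sum(t0^2))
  pos <- structure(list(com2d = rbind(c(0, 0), c(0, 0)), t = c(0.3, 0.7),
                        method = "H", fallback = c(FALSE, FALSE)),
                   class = "position_estimate")
  view <- mk_view(rbind(c(0, 0), c(1, 30), c(2, 60), c(5, 100)),
                  n_sup2d = rbind(-t0, -t0, -t0, -t0),
                  n_inf2d = rbind(t0, t0, t0, t0))
  stv <- correct_orientation_STV(est, pos)
  ivn <- correct_orientation_IVN(est, pos, view)
  expect_equal(stv$theta, ivn$theta, tolerance = 1e-9)
})

test_that("apply_corrections composes the planar results into rigid 3D updates", {
  ph <- generate_phantom(phantom_spec(profile = "straight"))
  seg <- ph$segment
  # identity: zero angles and planar CoMs at the initial projections
  rep <- run_pipeline(seg, NULL, "M8")
  for (i in seq_along(seg$vertebrae)) {
    expect_equal(rep$segment$vertebrae[[i]]$com, seg$vertebrae[[i]]$com,
                 tolerance = 1e-7)
    expect_equal(rep$segment$vertebrae[[i]]$n_sup, seg$vertebrae[[i]]$n_sup,
                 tolerance = 1e-7)
  }
  # single-plane correction rotates sagittal projections only
  m <- 4
  new_oc <- function(theta) structure(
    list(theta = theta, tangent = NULL, reference = NULL,
         method = "IVN", plane = NA), class = "orientation_correction")
  pos_of <- function(plane) {
    v <- planar_view(seg, plane)
    structure(list(com2d = v$com2d[2:5, ], t = seq(0.2, 0.8, 0.2),
                   method = "H", fallback = rep(FALSE, m)),
              class = "position_estimate")
  }
  upd <- apply_corrections(seg, new_oc(c(10, 0, 0, 0)), new_oc(rep(0, m)),
                           pos_of("sagittal"), pos_of("coronal"))
  v2 <- upd$vertebrae[[2]]
  sag_ref <- spinecurve:::project_direction(seg$initial[[2]]$n_sup, "sagittal")
  sag_new <- spinecurve:::project_direction(v2$n_sup, "sagittal")
  expect_equal(signed_angle(sag_ref, sag_new), 10, tolerance = 1e-9)
  cor_ref <- spinecurve:::project_direction(seg$initial[[2]]$n_sup, "coronal")
  cor_new <- spinecurve:::project_direction(v2$n_sup, "coronal")
  expect_equal(abs(signed_angle(cor_ref, cor_new)), 0, tolerance = 1e-9)
  # rigidity: normal lengths and their mutual angle are preserved
  for (i in 2:5) {
    v <- upd$vertebrae[[i]]
    expect_equal(sqrt(sum(v$n_sup^2)), 1, tolerance = 1e-9)
    expect_equal(sum(v$n_sup * v$n_inf),
                 sum(seg$initial[[i]]$n_sup * seg$initial[[i]]$n_inf),
                 tolerance = 1e-9)
  }
  # mismatched inferior coordinates between planes are averaged
  ps <- pos_of("sagittal"); pc <- pos_of("coronal")
  ps$com2d[1, 2] <- ps$com2d[1, 2] + 2
  upd2 <- apply_corrections(seg, new_oc(rep(0, m)), new_oc(rep(0, m)), ps, pc)
  expect_equal(upd2$vertebrae[[2]]$com[3], seg$initial[[2]]$com[3] + 1)
  expect_error(apply_corrections(seg, new_oc(c(0, 0)), new_oc(rep(0, m)), ps, pc))
})
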