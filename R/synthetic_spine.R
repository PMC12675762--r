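# Synthetic spine phantoms: segments with known ground truth standing in for
# the porcine proof-of-concept specimen, so every stage and the full pipeline
# are testable without scans.
#
# Geometry convention: phantoms are built in LAI coordinates with the chain
# running caudally (increasing z). "Curvature" bends the chain in the
# sagittal (y-z) plane unless a coronal component is requested.

#' Phantom specification
#'
#' @param n_vertebrae total vertebra count (first and last tracked), >= 3.
#'   Default 6: four intermediate vertebrae between two tracked ones, the
#'   evaluable configuration of the porcine proof of concept.
#' @param spacing inter-CoM spacing in mm; scalar or per-gap vector. Default
#'   30 mm, a typical lumbar CoM-to-CoM distance.
#' @param profile `"straight"`, `"arc"` (circular arc of `total_angle`) or
#'   `"V"` (straight chain kinked by `wedge_angle` at `apex`).
#' @param total_angle total arc angle in degrees (sagittal), for `"arc"`.
#' @param apex 1-based index of the kink vertebra, for `"V"`.
#' @param wedge_angle sagittal kink angle in degrees, for `"V"`.
#' @param endplates `"tangent"` (endplate normals aligned with the local
#'   chain tangent) or `"wedge"` (each vertebra carries a fixed wedge of
#'   `wedge_deg` between its endplates).
#' @param wedge_deg per-vertebra endplate wedge in degrees for
#'   `endplates = "wedge"`.
#' @param noise_pos_mm sd of isotropic Gaussian CoM noise, mm.
#' @param noise_normal_deg sd of random endplate-normal tilt, degrees.
#' @param labels optional vertebra labels; default `V1..Vn`.
#' @param seed integer; fixes all randomness of the generator.
#' @return list of class `phantom_spec`.
#' @export
phantom_spec <- function(n_vertebrae = 6L, spacing = 30,
                         profile = c("straight", "arc", "V"),
                         total_angle = 0, apex = NULL, wedge_angle = 0,
                         endplates = c("tangent", "wedge"), wedge_deg = 0,
                         noise_pos_mm = 0, noise_normal_deg = 0,
                         labels = NULL, seed = 1L) {
  profile <- match.arg(profile)
  endplates <- match.arg(endplates)
  n <- as.integer(n_vertebrae)
  if (n < 3) stop("phantom needs at least 3 vertebrae")
  spacing <- rep_len(as.numeric(spacing), n - 1L)
  if (any(spacing <= 0)) stop("spacing must be positive")
  if (abs(total_angle) >= 180) stop("|total_angle| must be below 180 degrees")
  if (profile == "V") {
    if (is.null(apex)) apex <- (n + 1L) %/% 2L
    if (apex <= 1L || apex >= n) stop("V apex must be an intermediate vertebra")
  }
  if (is.null(labels)) labels <- paste0("V", seq_len(n))
  structure(list(n = n, spacing = spacing, profile = profile,
                 total_angle = total_angle, apex = apex,
                 wedge_angle = wedge_angle, endplates = endplates,
                 wedge_deg = wedge_deg, noise_pos_mm = noise_pos_mm,
                 noise_normal_deg = noise_normal_deg, labels = labels,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# small random 3D rotation with angle ~ |N(0, sd_deg)|
random_tilt <- function(sd_deg) {
  ang <- stats::rnorm(1, 0, sd_deg) / DEG
  ax <- stats::rnorm(3)
  rotvec_to_matrix(ax / sqrt(sum(ax^2)) * ang)
}

#' Generate a spine phantom with ground truth
#'
#' Places CoMs along the requested profile, attaches endplate normals per the
#' chosen convention, marks the first and last vertebrae tracked, and returns
#' the observable segment together with a ground-truth record (true CoMs and
#' normals plus all pairwise endplate angles in both planes) kept separate so
#' tests cannot leak truth into the pipeline.
#'
#' @param spec a [phantom_spec()].
#' @return list `segment` ([spine_segment()]) and `truth` (list with `coms`,
#'   `n_sup`, `n_inf`, and `angles$sagittal` / `angles$coronal` data.frames
#'   `pair`, `angle_deg`).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  n <- spec$n
  # sagittal tilt (radians) of each vertebra's cranio-caudal tangent and of
  # each inter-CoM gap; a tilt of `a` turns the caudal +z direction toward
  # the anterior +y axis
  bend <- function(a) c(0, sin(a), cos(a))
  if (spec$profile == "straight") {
    vert_ang <- rep(0, n)
    gap_ang <- rep(0, n - 1L)
  } else if (spec$profile == "arc") {
    # tangents equally spaced over the total arc angle: consecutive-pair
    # endplate angles are exactly total_angle / (n - 1), tracked-pair angle
    # is total_angle; gaps follow the chord bisectors of a circular arc
    th <- spec$total_angle / DEG
    vert_ang <- th * ((seq_len(n) - 1) / (n - 1) - 0.5)
    gap_ang <- (vert_ang[-n] + vert_ang[-1]) / 2
  } else {
    th <- spec$wedge_angle / DEG
    gap_ang <- ifelse(seq_len(n - 1L) >= spec$apex, th, 0)
    vert_ang <- c(gap_ang[1], (gap_ang[-(n - 1L)] + gap_ang[-1]) / 2,
                  gap_ang[n - 1L])
  }
  gap_dirs <- t(vapply(gap_ang, bend, numeric(3)))
  vert_dir <- t(vapply(vert_ang, bend, numeric(3)))
  coms <- matrix(0, n, 3L)
  for (g in seq_len(n - 1L))
    coms[g + 1L, ] <- coms[g, ] + spec$spacing[g] * gap_dirs[g, ]
  half_wedge <- if (spec$endplates == "wedge") spec$wedge_deg / 2 / DEG else 0
  n_sup <- matrix(0, n, 3L); n_inf <- matrix(0, n, 3L)
  for (i in seq_len(n)) {
    d <- vert_dir[i, ]
    n_sup[i, ] <- drop(rot_x(half_wedge) %*% (-d))
    n_inf[i, ] <- drop(rot_x(-half_wedge) %*% d)
    if (spec$noise_normal_deg > 0) {
      n_sup[i, ] <- drop(random_tilt(spec$noise_normal_deg) %*% n_sup[i, ])
      n_inf[i, ] <- drop(random_tilt(spec$noise_normal_deg) %*% n_inf[i, ])
    }
  }
  obs_coms <- coms
  if (spec$noise_pos_mm > 0)
    obs_coms <- coms + matrix(stats::rnorm(3 * n, 0, spec$noise_pos_mm), n, 3L)
  verts <- lapply(seq_len(n), function(i) {
    pose <- diag(4)
    # body frame: map canonical +z onto the vertebra tangent (sagittal tilt)
    tilt <- atan2(vert_dir[i, 2], vert_dir[i, 3])
    pose[1:3, 1:3] <- rot_x(-tilt)
    pose[1:3, 4] <- obs_coms[i, ]
    vertebra(spec$labels[i], obs_coms[i, ], n_sup[i, ], n_inf[i, ], pose)
  })
  segment <- spine_segment(verts, tracked = c(1L, n))
  truth_seg <- spine_segment(lapply(seq_len(n), function(i)
    vertebra(spec$labels[i], coms[i, ], n_sup[i, ], n_inf[i, ])), c(1L, n))
  angles <- list(
    sagittal = alignment_table(truth_seg, "sagittal")[, c("pair", "simulated_deg")],
    coronal = alignment_table(truth_seg, "coronal")[, c("pair", "simulated_deg")])
  angles <- lapply(angles, function(df) {
    names(df)[2] <- "angle_deg"
    df
  })
  list(segment = segment,
       truth = list(coms = coms, n_sup = n_sup, n_inf = n_inf,
                    angles = angles, spec = spec))
}

#' Simulate a deformity-correction event (osteotomy) on a phantom
#'
#' Opens a wedge at an intermediate (apex) vertebra: the sub-chain inferior
#' to the apex, together with the apex's own inferior endplate, is rigidly
#' rotated about the apex CoM by the requested sagittal/coronal wedge
#' angles. Returns the post-event ground truth and the OTS pose stream a
#' tracker would report for the tracked pair (superior reference unmoved).
#'
#' @param phantom output of [generate_phantom()].
#' @param apex label or index of the osteotomy vertebra; must be untracked.
#' @param wedge_sagittal,wedge_coronal wedge opening angles in degrees.
#'   Positive sagittal values bow the inferior chain anteriorly
#'   (lordosis-increasing).
#' @return list `truth` (post-event truth record as in [generate_phantom()]),
#'   `ots_poses` (named list of 4x4 poses for the tracked labels), and
#'   `transform` (the rigid motion applied to the inferior sub-chain).
#' @export
simulate_correction <- function(phantom, apex, wedge_sagittal,
                                wedge_coronal = 0) {
  seg <- phantom$segment
  n <- length(seg$vertebrae)
  if (is.character(apex)) apex <- match(apex, seg$labels)
  if (is.na(apex) || apex %in% c(1L, n))
    stop("apex must be an existing untracked (intermediate) vertebra")
  tr <- phantom$truth
  pivot <- tr$coms[apex, ]
  R <- rotation_from_plane_angles(plane_axis_angle(-wedge_sagittal, "sagittal"),
                                  plane_axis_angle(wedge_coronal, "coronal"))[1:3, 1:3]
  move_pt <- function(p) drop(R %*% (p - pivot)) + pivot
  coms <- tr$coms; n_sup <- tr$n_sup; n_inf <- tr$n_inf
  n_inf[apex, ] <- drop(R %*% n_inf[apex, ])      # the resected wedge
  for (i in seq_len(n)[-seq_len(apex)]) {
    coms[i, ] <- move_pt(coms[i, ])
    n_sup[i, ] <- drop(R %*% n_sup[i, ])
    n_inf[i, ] <- drop(R %*% n_inf[i, ])
  }
  truth_seg <- spine_segment(lapply(seq_len(n), function(i)
    vertebra(seg$labels[i], coms[i, ], n_sup[i, ], n_inf[i, ])), c(1L, n))
  angles <- list(
    sagittal = alignment_table(truth_seg, "sagittal")[, c("pair", "simulated_deg")],
    coronal = alignment_table(truth_seg, "coronal")[, c("pair", "simulated_deg")])
  angles <- lapply(angles, function(df) { names(df)[2] <- "angle_deg"; df })
  M <- diag(4)
  M[1:3, 1:3] <- R
  M[1:3, 4] <- pivot - drop(R %*% pivot)
  labs <- seg$labels[seg$tracked]
  ots <- stats::setNames(vector("list", length(labs)), labs)
  for (k in seq_along(seg$tracked)) {
    i <- seg$tracked[k]
    reg <- seg$registration_poses[[labs[k]]]
    ots[[labs[k]]] <- if (i > apex) M %*% reg else reg
  }
  list(truth = list(coms = coms, n_sup = n_sup, n_inf = n_inf, angles = angles),
       ots_poses = ots, transform = M)
}
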