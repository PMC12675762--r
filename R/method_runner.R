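# Method runner: composes curve estimation x position estimation x
# orientation correction into the eight evaluation methods and runs the
# end-to-end intraoperative pipeline.

#' Method configuration
#'
#' @param curve `"EN"` or `"ENIP"`.
#' @param position `"H"` or `"P"`.
#' @param orientation `"STV"` or `"IVN"`.
#' @param label optional display label (`"M1"`..`"M8"`); checked against the
#'   documented mapping when given.
#' @return list of class `method_config`.
#' @export
method_config <- function(curve = c("EN", "ENIP"), position = c("H", "P"),
                          orientation = c("STV", "IVN"), label = NULL) {
  cfg <- list(curve = match.arg(curve), position = match.arg(position),
              orientation = match.arg(orientation), label = label)
  if (!is.null(label)) {
    known <- enumerate_methods()
    ref <- Filter(function(m) identical(m$label, label), known)
    if (!length(ref))
      stop(sprintf("unknown method label %s", label))
    ref <- ref[[1]]
    if (!identical(ref[c("curve", "position", "orientation")],
                   cfg[c("curve", "position", "orientation")]))
      stop(sprintf("label %s is documented as (%s, %s, %s)", label,
                   ref$curve, ref$position, ref$orientation))
  }
  structure(cfg, class = "method_config")
}

#' The eight evaluation methods M1-M8
#'
#' All 2 x 2 x 2 combinations of curve estimation (EN/ENIP), position
#' estimation (H/P) and orientation correction (STV/IVN). M1-M4 use STV and
#' M5-M8 IVN; M8 is the ENIP + PE_H + IVN composition that performed best in
#' the porcine proof of concept, and M6 its PE_P counterpart.
#'
#' @return list of 8 [method_config()]s.
#' @export
enumerate_methods <- function() {
  spec <- list(
    M1 = c("EN",   "H", "STV"),
    M2 = c("ENIP", "H", "STV"),
    M3 = c("EN",   "P", "STV"),
    M4 = c("ENIP", "P", "STV"),
    M5 = c("EN",   "P", "IVN"),
    M6 = c("ENIP", "P", "IVN"),
    M7 = c("EN",   "H", "IVN"),
    M8 = c("ENIP", "H", "IVN"))
  lapply(names(spec), function(lab) {
    s <- spec[[lab]]
    structure(list(curve = s[1], position = s[2], orientation = s[3],
                   label = lab),
              class = "method_config")
  })
}

#' Look up a method by label
#' @param label `"M1"`..`"M8"`.
#' @return the matching [method_config()].
#' @export
method_by_label <- function(label) {
  for (m in enumerate_methods()) if (m$label == label) return(m)
  stop(sprintf("unknown method label %s", label))
}

# sub-segment over vertebra indices i0..i1 of `segment`, keeping the parent's
# registration snapshot as its own and the parent's current geometry
subsegment <- function(segment, i0, i1) {
  sub <- spine_segment(segment$initial[i0:i1],
                       tracked = c(1L, i1 - i0 + 1L),
                       fraction_mode = segment$fraction_mode)
  sub$vertebrae <- segment$vertebrae[i0:i1]
  sub
}

run_plane <- function(segment, plane, config, strict = FALSE,
                      rotation_method = "rotvec") {
  view <- planar_view(segment, plane, "current")
  view0 <- planar_view(segment, plane, "initial")
  est <- estimate_curve(view, segment$fractions, config$curve)
  pos <- estimate_positions(est, view, segment$fractions, config$position,
                            strict = strict)
  orc <- if (config$orientation == "STV") correct_orientation_STV(est, pos)
         else correct_orientation_IVN(est, pos, view0)
  list(view = view, curve = est, positions = pos, corrections = orc)
}

#' Run the full intraoperative estimation pipeline
#'
#' Applies the OTS poses to the tracked vertebrae, estimates the in-plane
#' curve, places and re-orients the untracked vertebrae in both anatomical
#' planes, and reports the baseline/simulated/delta alignment tables.
#' Deterministic given its inputs. Segments with more than two tracked
#' vertebrae are processed as independent consecutive tracked spans; tracked
#' vertebrae always keep their measured poses. Two-vertebra segments skip
#' estimation and report the single tracked pair.
#'
#' @param segment a [spine_segment()].
#' @param ots_poses OTS poses for the tracked vertebrae (see
#'   [update_tracked_poses()]); `NULL` keeps the current geometry.
#' @param config a [method_config()] or a method label string.
#' @param strict fail instead of falling back on a missed perpendicular.
#' @param rotation_method `"rotvec"` or `"euler_xy"` (see
#'   [rotation_from_plane_angles()]).
#' @param intervened optional labels of vertebrae altered by the procedure
#'   (e.g. an osteotomy site); the pipeline cannot model the altered anatomy
#'   and only logs a warning for them.
#' @return list of class `pipeline_report`: per-plane stage results, the
#'   updated `segment`, `tables` for both planes, `warnings`, `config`.
#' @export
run_pipeline <- function(segment, ots_poses = NULL, config = method_by_label("M8"),
                         strict = FALSE, rotation_method = "rotvec",
                         intervened = character(0)) {
  if (is.character(config)) config <- method_by_label(config)
  stopifnot(inherits(config, "method_config"))
  warnings <- character(0)
  if (length(intervened)) {
    warnings <- c(warnings, sprintf(
      "vertebra %s flagged as intervened: shape/spacing changes are not modelled",
      intervened))
    for (w in warnings) warning(w)
  }
  if (!is.null(ots_poses)) segment <- update_tracked_poses(segment, ots_poses)
  n <- length(segment$vertebrae)
  planes <- list()
  # each consecutive tracked pair is an independent estimation span
  tracked <- segment$tracked
  for (k in seq_len(length(tracked) - 1L)) {
    i0 <- tracked[k]; i1 <- tracked[k + 1L]
    if (i1 - i0 < 2L) next                 # no untracked vertebrae in between
    span_label <- paste(segment$labels[i0], segment$labels[i1], sep = ":")
    sub <- subsegment(segment, i0, i1)
    span <- list()
    for (plane in c("sagittal", "coronal")) {
      span[[plane]] <- withCallingHandlers(
        tryCatch(run_plane(sub, plane, config, strict, rotation_method),
                 error = function(e)
                   stop(sprintf("%s plane, span %s: %s", plane, span_label,
                                conditionMessage(e)))),
        warning = function(w) {
          warnings <<- c(warnings, sprintf("%s plane, span %s: %s", plane,
                                           span_label, conditionMessage(w)))
          invokeRestart("muffleWarning")
        })
    }
    sub <- apply_corrections(sub,
                             span$sagittal$corrections,
                             span$coronal$corrections,
                             span$sagittal$positions,
                             span$coronal$positions,
                             rotation_method = rotation_method)
    segment$vertebrae[(i0 + 1L):(i1 - 1L)] <- sub$vertebrae[2:(i1 - i0)]
    planes[[span_label]] <- span
  }
  if (n >= 3 && length(planes) == 1L) planes <- planes[[1L]]
  tables <- list(sagittal = alignment_table(segment, "sagittal"),
                 coronal = alignment_table(segment, "coronal"))
  structure(list(segment = segment, planes = planes, tables = tables,
                 warnings = warnings, config = config,
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<pipeline_report> method %s (%s, %s, %s)\n",
              cfg$label %||% "custom", cfg$curve, cfg$position, cfg$orientation))
  for (plane in names(x$tables)) {
    cat(sprintf("\n%s plane:\n", plane))
    print(x$tables[[plane]], digits = 4, row.names = FALSE)
  }
  if (length(x$warnings)) cat("\nwarnings:\n", paste("-", x$warnings, collapse = "\n"), "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate all eight methods against ground-truth angles
#'
#' Runs every method of [enumerate_methods()] on the same segment and poses
#' and scores each plane's simulated pairwise angles against a ground-truth
#' table with [abs_error_extrema()].
#'
#' @param segment a [spine_segment()].
#' @param ots_poses poses passed to [run_pipeline()].
#' @param truth named list with `sagittal` and `coronal` data.frames holding
#'   `pair` and a truth angle column (`angle_deg` or `simulated_deg`).
#' @param ... passed to [run_pipeline()].
#' @return data.frame `method`, `plane`, `rmse_deg`, `min_abs_deg`,
#'   `max_abs_deg`, `min_pair`, `max_pair`.
#' @export
evaluate_methods <- function(segment, ots_poses, truth, ...) {
  truth_col <- function(df) if ("angle_deg" %in% names(df)) "angle_deg" else "simulated_deg"
  out <- list()
  for (cfg in enumerate_methods()) {
    rep <- suppressWarnings(run_pipeline(segment, ots_poses, cfg, ...))
    for (plane in c("coronal", "sagittal")) {
      tab <- rep$tables[[plane]]
      tr <- truth[[plane]]
      if (!identical(tab$pair, tr$pair))
        stop("truth table pairs do not match the segment's pairs")
      ex <- abs_error_extrema(tab$simulated_deg, tr[[truth_col(tr)]], tab$pair)
      out[[length(out) + 1L]] <- data.frame(
        method = cfg$label, plane = plane, rmse_deg = ex$rmse,
        min_abs_deg = ex$min_abs, max_abs_deg = ex$max_abs,
        min_pair = ex$min_label, max_pair = ex$max_label,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
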