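# Alignment metrics: pairwise Cobb-style endplate angles per plane,
# baseline/simulated/delta feedback tables, and the RMSE / absolute-error
# summaries used to evaluate the estimation methods.

#' Pairwise endplate angle in a plane
#'
#' Unsigned angle between the line of the superior vertebra's superior
#' endplate and the line of the inferior vertebra's inferior endplate,
#' measured between the projected endplate normal lines and folded to the
#' acute range \[0, 90\] degrees (Cobb-style line angle; 150 degrees between
#' normal vectors reads as a 30-degree endplate angle).
#'
#' @param sup,inf [vertebra()] objects, `sup` the superior one.
#' @param plane `"sagittal"` or `"coronal"`.
#' @return degrees in \[0, 90\].
#' @export
endplate_angle <- function(sup, inf, plane = c("sagittal", "coronal")) {
  plane <- match.arg(plane)
  a <- project_direction(sup$n_sup, plane, sprintf("superior normal of %s", sup$label))
  b <- project_direction(inf$n_inf, plane, sprintf("inferior normal of %s", inf$label))
  acos(min(1, abs(sum(a * b)))) * DEG
}

#' Baseline/simulated/delta alignment table for one plane
#'
#' Angles between all unordered vertebra pairs of the segment (superior
#' listed first), with the baseline column taken from the registration-time
#' segment, the simulated column from the current geometry, and
#' `delta = simulated - baseline` (positive when an angle increased
#' intraoperatively).
#'
#' @param segment segment carrying the current (simulated) geometry.
#' @param plane `"sagittal"` or `"coronal"`.
#' @param baseline segment supplying the baseline geometry; defaults to
#'   `segment`'s own registration snapshot.
#' @return data.frame `pair`, `baseline_deg`, `simulated_deg`, `delta_deg`.
#' @export
alignment_table <- function(segment, plane = c("sagittal", "coronal"),
                            baseline = NULL) {
  plane <- match.arg(plane)
  cur <- segment$vertebrae
  base <- if (is.null(baseline)) segment$initial else {
    if (!identical(baseline$labels, segment$labels))
      stop("baseline segment has different vertebra labels")
    baseline$vertebrae
  }
  n <- length(cur)
  pairs <- utils::combn(n, 2)
  df <- data.frame(
    pair = apply(pairs, 2, function(ij)
      paste0(segment$labels[ij[1]], "-", segment$labels[ij[2]])),
    baseline_deg = apply(pairs, 2, function(ij)
      endplate_angle(base[[ij[1]]], base[[ij[2]]], plane)),
    simulated_deg = apply(pairs, 2, function(ij)
      endplate_angle(cur[[ij[1]]], cur[[ij[2]]], plane)),
    stringsAsFactors = FALSE)
  df$delta_deg <- df$simulated_deg - df$baseline_deg
  df
}

#' Root mean square error between two angle lists
#'
#' \eqn{\sqrt{\mathrm{mean}((a_i - b_i)^2)}} with the population divisor
#' (the number of vertebra pairs).
#'
#' @param a,b numeric vectors of equal nonzero length, degrees.
#' @return degrees.
#' @export
rmse <- function(a, b) {
  if (length(a) != length(b) || !length(a))
    stop("rmse needs two equal-length nonempty vectors")
  sqrt(mean((a - b)^2))
}

#' Minimum and maximum absolute error with their pair labels
#'
#' @param a,b numeric vectors of equal length, degrees.
#' @param labels pair labels, same length.
#' @return list `rmse`, `min_abs`, `min_label`, `max_abs`, `max_label`.
#' @export
abs_error_extrema <- function(a, b, labels = seq_along(a)) {
  if (length(a) != length(b) || length(a) != length(labels))
    stop("a, b, labels must have equal length")
  e <- abs(a - b)
  list(rmse = rmse(a, b),
       min_abs = min(e), min_label = labels[which.min(e)],
       max_abs = max(e), max_label = labels[which.max(e)])
}

#' Porcine proof-of-concept measurement table
#'
#' The published angle measurements from an ex vivo porcine lumbar segment
#' (L1-L4, references on L1 and L4): manual expert readings, the system's
#' direct CT-based readings, and the eight estimation methods M1-M8, before
#' and after an L3 osteotomy, for all six vertebra pairs in each plane. The
#' `rmse_deg` column is the value printed alongside each row; RMSE is always
#' taken against the Manual row of the same phase and plane. The
#' postoperative System row is based on an erroneous automatic segmentation
#' and is retained as published.
#'
#' @return data.frame with columns `phase` (`preoperative`/`postoperative`),
#'   `source` (`Manual`, `System`, `M1`..`M8`), `plane`, the six pair columns
#'   `L1-L2` .. `L3-L4` (degrees) and `rmse_deg`.
#' @export
poc_measurements <- function() {
  path <- system.file("extdata", "porcine_poc_angles.csv",
                      package = "spinecurve", mustWork = TRUE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  stopifnot(nrow(df) == 40)
  df
}

#' Pair-angle columns of the proof-of-concept table
#' @return character vector of the six pair column names.
#' @export
poc_pairs <- function() c("L1-L2", "L1-L3", "L1-L4", "L2-L3", "L2-L4", "L3-L4")

#' Recompute the proof-of-concept error statistics
#'
#' For every non-Manual row of [poc_measurements()], recomputes the RMSE and
#' the absolute-error extrema against the Manual row of the same phase and
#' plane, alongside the published RMSE for comparison.
#'
#' @return data.frame `phase`, `source`, `plane`, `rmse_deg` (recomputed),
#'   `rmse_published`, `min_abs`, `min_pair`, `max_abs`, `max_pair`.
#' @export
poc_error_statistics <- function() {
  df <- poc_measurements()
  pairs <- poc_pairs()
  rows <- df[df$source != "Manual", ]
  out <- do.call(rbind, lapply(seq_len(nrow(rows)), function(k) {
    r <- rows[k, ]
    manual <- df[df$source == "Manual" & df$phase == r$phase & df$plane == r$plane, ]
    ex <- abs_error_extrema(as.numeric(r[pairs]), as.numeric(manual[pairs]), pairs)
    data.frame(phase = r$phase, source = r$source, plane = r$plane,
               rmse_deg = ex$rmse, rmse_published = r$rmse_deg,
               min_abs = ex$min_abs, min_pair = ex$min_label,
               max_abs = ex$max_abs, max_pair = ex$max_label,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
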