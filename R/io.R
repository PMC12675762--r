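# File I/O: spine-segment JSON, pose-stream CSV, alignment-table CSV.
# JSON carries matrices row-major and a format_version field.

SEGMENT_FORMAT_VERSION <- "1.0"

mat_to_rows <- function(M) lapply(seq_len(nrow(M)), function(i) unname(M[i, ]))
rows_to_mat <- function(rows) do.call(rbind, lapply(rows, as.numeric))

#' Write a spine segment to JSON
#'
#' Schema: `{"format_version", "orientation": "LAI", "vertebrae": [{"label",
#' "com", "n_sup", "n_inf", "pose" (4x4, row-major rows)}], "tracked":
#' [labels]}`.
#'
#' @param segment a [spine_segment()].
#' @param path output file.
#' @export
write_segment_json <- function(segment, path) {
  obj <- list(
    format_version = SEGMENT_FORMAT_VERSION,
    orientation = "LAI",
    vertebrae = lapply(segment$vertebrae, function(v)
      list(label = v$label, com = v$com, n_sup = v$n_sup, n_inf = v$n_inf,
           pose = mat_to_rows(v$pose))),
    tracked = segment$labels[segment$tracked])
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a spine segment from JSON
#'
#' Accepts the schema of [write_segment_json()]. Endplate normals violating
#' the orientation convention (superior normal cranial, i.e. negative
#' inferior component; inferior normal caudal) are flipped with a warning.
#'
#' @param path JSON file.
#' @return a [spine_segment()].
#' @export
read_segment_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$orientation, "LAI"))
    stop("segment JSON must declare LAI orientation")
  fix_normal <- function(v, sign_wanted, field, label) {
    # convention: n_sup has negative z (cranial), n_inf positive z (caudal)
    if (sign(v[3]) == sign_wanted || v[3] == 0) return(v)
    warning(sprintf("flipping %s normal of %s to match orientation convention",
                    field, label))
    -v
  }
  verts <- lapply(obj$vertebrae, function(vo) {
    ns <- as.numeric(unlist(vo$n_sup)); ni <- as.numeric(unlist(vo$n_inf))
    ns <- fix_normal(ns, -1, "superior", vo$label)
    ni <- fix_normal(ni, +1, "inferior", vo$label)
    pose <- if (is.null(vo$pose)) diag(4) else rows_to_mat(vo$pose)
    vertebra(vo$label, as.numeric(unlist(vo$com)), ns, ni, pose)
  })
  spine_segment(verts, tracked = vapply(obj$tracked, as.character, character(1)))
}

#' Write a pose stream CSV
#'
#' One row per (timestamp, label) with the 16 row-major entries `m11..m44`.
#'
#' @param poses named list of 4x4 poses (names are vertebra labels).
#' @param path output file.
#' @param timestamp numeric timestamp for all rows.
#' @export
write_pose_csv <- function(poses, path, timestamp = 0) {
  rows <- lapply(names(poses), function(lab) {
    M <- poses[[lab]]
    entries <- as.numeric(t(M))
    df <- data.frame(timestamp = timestamp, label = lab)
    for (k in 1:16)
      df[[sprintf("m%d%d", (k - 1) %/% 4 + 1, (k - 1) %% 4 + 1)]] <- entries[k]
    df
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read a pose stream CSV
#'
#' @param path CSV from [write_pose_csv()].
#' @param at optional timestamp to select; default the last one present.
#' @return named list of 4x4 poses.
#' @export
read_pose_csv <- function(path, at = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("timestamp", "label",
            sprintf("m%d%d", rep(1:4, each = 4), rep(1:4, 4)))
  if (!all(need %in% names(df)))
    stop("pose CSV must have timestamp, label and m11..m44 columns")
  if (is.null(at)) at <- max(df$timestamp)
  df <- df[df$timestamp == at, ]
  poses <- lapply(seq_len(nrow(df)), function(i)
    matrix(as.numeric(df[i, need[-(1:2)]]), 4, 4, byrow = TRUE))
  stats::setNames(poses, df$label)
}

#' Write per-plane alignment tables to CSV
#'
#' @param report a `pipeline_report`.
#' @param dir output directory; files `alignment_sagittal.csv` and
#'   `alignment_coronal.csv` are written.
#' @return the file paths, invisibly.
#' @export
write_alignment_csv <- function(report, dir) {
  paths <- character(0)
  for (plane in names(report$tables)) {
    p <- file.path(dir, sprintf("alignment_%s.csv", plane))
    utils::write.csv(report$tables[[plane]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
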