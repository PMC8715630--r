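## Readers / writers for the trajectory CSV dialect and feature tables -------

# Trajectory files carry metadata in '#'-prefixed header lines followed by a
# CSV body with columns t,q1[,q2][,f1,f2],target_id,segment_id. Angles are in
# degrees at the file boundary and radians internally; shoulder-elbow endpoint
# positions are metres throughout.

DEG2RAD <- pi / 180

angular_task <- function(device, task) {
  device == "wrist_forearm" && task %in% c("wrist_point8", "forearm_ps",
                                           "circle_draw", "resistance",
                                           "isometric_hold")
}

#' Write a task recording to the trajectory CSV dialect
#'
#' @param rec A \code{\link{task_recording}}.
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "task_recording"))
  q_out <- rec$q
  unit_q <- "m"
  if (angular_task(rec$device, rec$task)) {
    q_out <- q_out / DEG2RAD
    unit_q <- "deg"
  }
  seg_id <- integer(length(rec$t))
  if (nrow(rec$segments) > 0) {
    for (i in seq_len(nrow(rec$segments)))
      seg_id[rec$segments$start[i]:rec$segments$end[i]] <- i
  }
  target_col <- rep(NA_integer_, length(rec$t))
  if (nrow(rec$segments) > 0) {
    for (i in seq_len(nrow(rec$segments)))
      target_col[rec$segments$start[i]:rec$segments$end[i]] <-
        rec$segments$target_id[i]
  }
  body <- data.frame(t = rec$t)
  for (j in seq_len(ncol(q_out))) body[[paste0("q", j)]] <- q_out[, j]
  if (!is.null(rec$f))
    for (j in seq_len(ncol(rec$f))) body[[paste0("f", j)]] <- rec$f[, j]
  body$target_id <- target_col
  body$segment_id <- seg_id
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# patient_id: %s", rec$patient_id),
               sprintf("# session_label: %s", rec$session_label),
               sprintf("# device: %s", rec$device),
               sprintf("# task: %s", rec$task),
               sprintf("# units: t=s,q=%s,f=N", unit_q)), con)
  utils::write.table(body, con, sep = ",", row.names = FALSE, quote = FALSE,
                     na = "NA")
  invisible(path)
}

parse_header_meta <- function(lines) {
  meta <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^#\\s*([a-z_]+):\\s*(.*)$", ln))[[1]]
    if (length(m) == 3) meta[[m[2]]] <- trimws(m[3])
  }
  meta
}

#' Read a task recording from the trajectory CSV dialect
#'
#' Metadata (patient, session, device, task, units) is read from
#' \code{#}-prefixed header lines. If the body carries a \code{segment_id}
#' column, segments are taken from it; otherwise movement attempts are
#' derived from target cues and a speed threshold (onset when speed first
#' exceeds 5\% of the recording's peak speed after a target change, offset
#' when the endpoint is inside the target radius with speed below that
#' threshold for at least 0.1 s).
#'
#' @param path Input file path.
#' @param geometry A \code{\link{task_geometry}}, needed for derived
#'   segmentation; defaults to the standard protocol geometry.
#' @return A validated \code{\link{task_recording}}.
#' @export
read_recording <- function(path, geometry = task_geometry()) {
  if (!file.exists(path)) stop("recording file not found: ", path)
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  meta <- parse_header_meta(hdr)
  for (key in c("patient_id", "session_label", "device", "task"))
    if (is.null(meta[[key]]))
      stop("malformed header: missing '", key, "' line in ", path)
  if (!meta$task %in% TASKS)
    stop("unknown task label '", meta$task, "' in ", path)
  body <- utils::read.csv(text = lines[!startsWith(lines, "#")],
                          stringsAsFactors = FALSE)
  if (!"t" %in% names(body)) stop("malformed header: no 't' column in ", path)
  bad <- which(diff(body$t) <= 0)
  if (length(bad) > 0)
    stop(sprintf("non-monotone time in %s at data row %d", path, bad[1] + 1))
  qcols <- grep("^q[0-9]+$", names(body), value = TRUE)
  fcols <- grep("^f[0-9]+$", names(body), value = TRUE)
  q <- as.matrix(body[qcols])
  in_deg <- angular_task(meta$device, meta$task)
  if (!is.null(meta$units) && grepl("q=deg", meta$units)) in_deg <- TRUE
  if (in_deg) q <- q * DEG2RAD
  f <- if (length(fcols) > 0) as.matrix(body[fcols]) else NULL
  segments <- if ("segment_id" %in% names(body) &&
                  any(body$segment_id > 0, na.rm = TRUE)) {
    segments_from_column(body$segment_id, body$target_id)
  } else {
    derive_segments(body$t, q, body$target_id, meta$task, geometry)
  }
  task_recording(meta$patient_id, meta$session_label, meta$device, meta$task,
                 t = body$t, q = q, f = f, segments = segments)
}

segments_from_column <- function(segment_id, target_id) {
  segment_id[is.na(segment_id)] <- 0L
  ids <- sort(unique(segment_id[segment_id > 0]))
  segs <- lapply(ids, function(k) {
    idx <- which(segment_id == k)
    data.frame(start = min(idx), end = max(idx),
               target_id = target_id[min(idx)])
  })
  do.call(rbind, segs)
}

# Fallback segmentation: a movement attempt starts when speed rises above 5%
# of the recording's peak speed after a target cue (target_id change), and
# ends once inside the target radius with speed below threshold for >= 0.1 s.
derive_segments <- function(t, q, target_id, task, geometry) {
  n <- length(t)
  if (is.null(target_id) || all(is.na(target_id)))
    return(data.frame(start = integer(0), end = integer(0),
                      target_id = integer(0)))
  speed <- path_speed(t, q)
  thr <- 0.05 * max(speed)
  targets <- task_targets(geometry, task)
  cue_idx <- c(1L, which(diff(target_id) != 0) + 1L)
  segs <- list()
  for (ci in seq_along(cue_idx)) {
    i0 <- cue_idx[ci]
    i1 <- if (ci < length(cue_idx)) cue_idx[ci + 1] - 1L else n
    tid <- target_id[i0]
    if (is.na(tid)) next
    rng <- i0:i1
    on <- rng[which(speed[rng] > thr)[1]]
    if (is.na(on)) next
    off <- i1
    if (!is.null(targets) && tid >= 1 && tid <= nrow(targets)) {
      tgt <- targets[tid, ]
      d <- sqrt(rowSums((q[rng, , drop = FALSE] -
                           matrix(tgt, length(rng), ncol(q), byrow = TRUE))^2))
      inside <- d < geometry$target_radius & speed[rng] < thr
      run_start <- NA_integer_
      for (k in seq_along(rng)) {
        if (inside[k]) {
          if (is.na(run_start)) run_start <- k
          if (t[rng[k]] - t[rng[run_start]] >= 0.1) { off <- rng[run_start]; break }
        } else run_start <- NA_integer_
      }
    }
    if (off > on) segs[[length(segs) + 1]] <-
        data.frame(start = on, end = off, target_id = tid)
  }
  if (length(segs) == 0)
    return(data.frame(start = integer(0), end = integer(0),
                      target_id = integer(0)))
  do.call(rbind, segs)
}

## Feature tables ------------------------------------------------------------

#' Assemble a session feature row
#'
#' One row of the analysis dataset: identity, mean-aggregated metric values
#' and the session's clinical scores.
#'
#' @param patient_id Patient identifier.
#' @param session_label Session label.
#' @param features Named numeric vector or list of metric values.
#' @param scores A \code{\link{clinical_scores}} object.
#' @return One-row data.frame.
#' @export
session_feature_row <- function(patient_id, session_label, features, scores) {
  stopifnot(inherits(scores, "clinical_scores"))
  session_label <- match.arg(session_label, SESSION_LABELS)
  features <- as.list(features)
  if (is.null(names(features)) || any(names(features) == ""))
    stop("features must be named")
  row <- c(list(patient_id = as.character(patient_id),
                session_label = session_label),
           lapply(features, as.numeric), unclass(scores))
  as.data.frame(row, stringsAsFactors = FALSE)
}

#' Write the session feature table
#'
#' Columns are \code{patient_id}, \code{session_label}, the metric columns in
#' a deterministic (sorted) order, then the four clinical scales. Rows must
#' be unique per (patient, session); features missing in some rows become
#' explicit NA.
#'
#' @param rows data.frame of stacked session feature rows.
#' @param path Output CSV path.
#' @return Invisibly, \code{path}.
#' @export
write_feature_table <- function(rows, path) {
  rows <- as.data.frame(rows)
  id_cols <- c("patient_id", "session_label")
  stopifnot(all(id_cols %in% names(rows)))
  if (anyDuplicated(rows[id_cols]))
    stop("duplicate (patient_id, session_label) pair in feature table")
  feat <- setdiff(names(rows), c(id_cols, CLINICAL_SCALES))
  ord <- c(id_cols, sort(feat), intersect(CLINICAL_SCALES, names(rows)))
  for (s in setdiff(CLINICAL_SCALES, names(rows)))
    rows[[s]] <- rep(NA_real_, nrow(rows))
  ord <- c(id_cols, sort(feat), CLINICAL_SCALES)
  utils::write.csv(rows[ord], path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Read a session feature table
#'
#' @param path CSV path written by \code{\link{write_feature_table}} or a
#'   conforming external file.
#' @return data.frame with typed columns; \code{NA} preserved as missing.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("feature table not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "NA")
  stopifnot(all(c("patient_id", "session_label") %in% names(tab)))
  tab$patient_id <- as.character(tab$patient_id)
  num_cols <- setdiff(names(tab), c("patient_id", "session_label"))
  for (cn in num_cols) {
    v <- tab[[cn]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(!is.na(v) & is.na(vn))
      if (length(bad) > 0)
        stop(sprintf("non-numeric value '%s' at row %d, column '%s'",
                     v[bad[1]], bad[1], cn))
      v <- vn
    }
    tab[[cn]] <- v
  }
  tab
}

#' Names of feature columns in a feature table
#' @param tab Feature table data.frame.
#' @return Character vector of metric column names.
#' @export
feature_columns <- function(tab) {
  setdiff(names(tab), c("patient_id", "session_label", CLINICAL_SCALES))
}
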