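#' @keywords internal
"_PACKAGE"

## Controlled vocabularies shared across the pipeline ------------------------

#' Session, device and task vocabularies
#'
#' The evaluation protocol has up to four sessions per patient (two
#' pre-intervention baselines, discharge, follow-up), two robots, and seven
#' evaluation task types (four shoulder-elbow, three wrist/forearm).
#'
#' @name vocabularies
#' @keywords internal
NULL

SESSION_LABELS <- c("baseline1", "baseline2", "discharge", "followup")
DEVICES <- c("shoulder_elbow", "wrist_forearm")
TASKS <- c("reach8", "wrist_point8", "forearm_ps", "circle_draw",
           "resistance", "isometric_hold", "kinetic_strength")

#' Clinical outcome scale definitions
#'
#' Bounds and granularity of the four clinical scales: Fugl-Meyer Assessment
#' upper extremity (0-66, integer), Wolf Motor Function Test (non-negative;
#' the functional-ability variant tops out at 75 but time-based variants can
#' exceed it, so only the lower bound is enforced), Barthel Index (0-100,
#' steps of 5), Medical Research Council motor power (non-negative, steps of
#' 0.5).
#'
#' @return A data.frame with one row per scale: \code{scale}, \code{min},
#'   \code{max} (NA when unbounded above), \code{step}.
#' @export
#' @examples
#' clinical_scale_info()
clinical_scale_info <- function() {
  data.frame(
    scale = c("fma_ue", "wmft", "bi", "mrc"),
    min = c(0, 0, 0, 0),
    max = c(66, NA, 100, NA),
    step = c(1, 1, 5, 0.5),
    stringsAsFactors = FALSE
  )
}

CLINICAL_SCALES <- c("fma_ue", "wmft", "bi", "mrc")

#' Construct a set of clinical scores for one session
#'
#' @param fma_ue Fugl-Meyer Assessment upper-extremity score, integer 0-66, or
#'   NA.
#' @param wmft Wolf Motor Function Test score, non-negative, or NA.
#' @param bi Barthel Index, 0-100, or NA.
#' @param mrc Medical Research Council motor power sum, non-negative, or NA.
#' @return An object of class \code{clinical_scores} (named list).
#' @export
#' @examples
#' clinical_scores(fma_ue = 25, wmft = 58, bi = 85, mrc = 45.5)
clinical_scores <- function(fma_ue = NA_real_, wmft = NA_real_,
                            bi = NA_real_, mrc = NA_real_) {
  s <- list(fma_ue = as.numeric(fma_ue), wmft = as.numeric(wmft),
            bi = as.numeric(bi), mrc = as.numeric(mrc))
  if (!is.na(s$fma_ue) && (s$fma_ue < 0 || s$fma_ue > 66))
    stop("fma_ue must lie in [0, 66]")
  if (!is.na(s$bi) && (s$bi < 0 || s$bi > 100))
    stop("bi must lie in [0, 100]")
  if (!is.na(s$wmft) && s$wmft < 0) stop("wmft must be non-negative")
  if (!is.na(s$mrc) && s$mrc < 0) stop("mrc must be non-negative")
  structure(s, class = "clinical_scores")
}

#' Construct a task recording
#'
#' A \code{task_recording} holds the sampled trajectory of one robotic
#' evaluation task, segmented into movement attempts.
#'
#' @param patient_id Opaque patient identifier (string).
#' @param session_label One of \code{baseline1, baseline2, discharge,
#'   followup}.
#' @param device \code{shoulder_elbow} or \code{wrist_forearm}.
#' @param task One of the seven task types (see \code{TASKS}).
#' @param t Numeric vector of timestamps in seconds, strictly increasing.
#' @param q Numeric matrix of coordinates, one row per sample. Two columns of
#'   endpoint metres for the shoulder-elbow device; two columns of wrist
#'   angles (flexion/extension, radial/ulnar deviation) in radians, or one
#'   column of forearm pronation/supination angle, for the wrist device.
#' @param f Optional numeric matrix of force samples in newtons (same row
#'   count as \code{q}), or NULL.
#' @param segments data.frame with columns \code{start}, \code{end} (sample
#'   indices, inclusive) and \code{target_id}; segments must be ordered and
#'   non-overlapping.
#' @return An object of class \code{task_recording}.
#' @export
task_recording <- function(patient_id, session_label, device, task,
                           t, q, f = NULL, segments = NULL) {
  session_label <- match.arg(session_label, SESSION_LABELS)
  device <- match.arg(device, DEVICES)
  task <- match.arg(task, TASKS)
  t <- as.numeric(t)
  q <- as.matrix(q)
  storage.mode(q) <- "double"
  if (length(t) != nrow(q)) stop("t and q must have the same number of samples")
  bad <- which(diff(t) <= 0)
  if (length(bad) > 0)
    stop(sprintf("timestamps must be strictly increasing; violation at row %d",
                 bad[1] + 1))
  expected_dim <- task_coord_dim(device, task)
  if (!is.na(expected_dim) && ncol(q) != expected_dim)
    stop(sprintf("task '%s' on device '%s' expects %d coordinate column(s), got %d",
                 task, device, expected_dim, ncol(q)))
  if (!is.null(f)) {
    f <- as.matrix(f)
    storage.mode(f) <- "double"
    if (nrow(f) != nrow(q)) stop("force channel must match sample count")
  }
  if (is.null(segments)) {
    segments <- data.frame(start = integer(0), end = integer(0),
                           target_id = integer(0))
  }
  segments <- as.data.frame(segments)
  stopifnot(all(c("start", "end", "target_id") %in% names(segments)))
  if (nrow(segments) > 0) {
    if (any(segments$start > segments$end))
      stop("segment start must not exceed end")
    if (any(segments$start < 1) || any(segments$end > length(t)))
      stop("segment indices out of range")
    if (is.unsorted(segments$start))
      stop("segments must be ordered by start index")
    if (nrow(segments) > 1 &&
        any(segments$start[-1] <= segments$end[-nrow(segments)]))
      stop("segments must be non-overlapping")
  }
  structure(list(patient_id = as.character(patient_id),
                 session_label = session_label, device = device, task = task,
                 t = t, q = q, f = f, segments = segments),
            class = "task_recording")
}

#' Coordinate dimensionality expected for a task
#' @keywords internal
task_coord_dim <- function(device, task) {
  if (task == "forearm_ps") return(1L)
  if (task == "kinetic_strength") return(NA_integer_) # displacement optional
  2L
}

#' @export
print.task_recording <- function(x, ...) {
  cat(sprintf("<task_recording> %s / %s / %s / %s\n", x$patient_id,
              x$session_label, x$device, x$task))
  cat(sprintf("  %d samples over %.2f s, %d coordinate(s), %s force channel, %d segment(s)\n",
              length(x$t), diff(range(x$t)), ncol(x$q),
              if (is.null(x$f)) "no" else "with", nrow(x$segments)))
  invisible(x)
}

#' Extract one movement segment from a recording
#'
#' @param rec A \code{task_recording}.
#' @param i Segment index.
#' @return List with \code{t}, \code{q}, \code{f} (possibly NULL) and
#'   \code{target_id} restricted to the segment's samples.
#' @export
recording_segment <- function(rec, i) {
  stopifnot(inherits(rec, "task_recording"), i >= 1, i <= nrow(rec$segments))
  idx <- rec$segments$start[i]:rec$segments$end[i]
  list(t = rec$t[idx], q = rec$q[idx, , drop = FALSE],
       f = if (is.null(rec$f)) NULL else rec$f[idx, , drop = FALSE],
       target_id = rec$segments$target_id[i])
}
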