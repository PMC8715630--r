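## Session-level metric aggregation ------------------------------------------

#' Metric registry
#'
#' Names, units, device and task of origin of every implemented metric.
#' Shoulder-elbow metric names are unprefixed (matching the conventional
#' heatmap labels, e.g. \code{offset}, \code{deltaz},
#' \code{circle_joint_independence}, \code{max_displacement},
#' \code{deviation}, \code{speed_shape}); wrist and forearm metrics carry
#' \code{wrist_} / \code{forearm_} prefixes.
#'
#' @return data.frame with columns \code{name}, \code{unit}, \code{device},
#'   \code{task}.
#' @export
metric_registry <- function() {
  macro <- function(prefix, unit_len, unit_ang, device, task) {
    nm <- c("aim", "duration", "deviation", "dwell_time", "mean_speed",
            "peak_speed", "speed_shape", "jerk_discrete", "jerk_rhythmic",
            "submovement_number", "submovement_duration",
            "submovement_overlap", "submovement_peak",
            "submovement_interpeak")
    un <- c("rad", "s", unit_len, "s", paste0(unit_len, "/s"),
            paste0(unit_len, "/s"), "", "", "", "count", "s", "s",
            paste0(unit_len, "/s"), "s")
    data.frame(name = paste0(prefix, nm), unit = un, device = device,
               task = task, stringsAsFactors = FALSE)
  }
  rbind(
    macro("", "m", "rad", "shoulder_elbow", "reach8"),
    data.frame(name = c("circle_major_axis", "circle_minor_axis",
                        "circle_axis_ratio", "circle_orientation",
                        "circle_joint_independence", "horizontal_axes"),
               unit = c("m", "m", "", "rad", "", "m"),
               device = "shoulder_elbow", task = "circle_draw",
               stringsAsFactors = FALSE),
    data.frame(name = c("max_displacement", "overall_aim"),
               unit = c("m", "rad"), device = "shoulder_elbow",
               task = "resistance", stringsAsFactors = FALSE),
    data.frame(name = c("scatter", "offset"), unit = c("m", "m"),
               device = "shoulder_elbow", task = "isometric_hold",
               stringsAsFactors = FALSE),
    data.frame(name = c("deltaz", "strength_f", "strength_e", "strength_ab",
                        "strength_ad"),
               unit = "N", device = "shoulder_elbow",
               task = "kinetic_strength", stringsAsFactors = FALSE),
    macro("wrist_", "rad", "rad", "wrist_forearm", "wrist_point8"),
    macro("forearm_", "rad", "rad", "wrist_forearm", "forearm_ps"),
    data.frame(name = c("wrist_max_displacement", "wrist_overall_aim"),
               unit = c("rad", "rad"), device = "wrist_forearm",
               task = "resistance", stringsAsFactors = FALSE),
    data.frame(name = c("wrist_scatter", "wrist_offset"),
               unit = c("rad", "rad"), device = "wrist_forearm",
               task = "isometric_hold", stringsAsFactors = FALSE))
}

#' Shoulder-elbow / wrist split of metric names
#'
#' @param names Character vector of metric names.
#' @param device \code{"shoulder_elbow"}, \code{"wrist"} or \code{"both"}.
#' @return The subset of \code{names} belonging to the device group.
#' @export
metrics_for_device <- function(names, device = c("shoulder_elbow", "wrist",
                                                 "both")) {
  device <- match.arg(device)
  wristish <- grepl("^(wrist|forearm)_", names)
  switch(device,
         shoulder_elbow = names[!wristish],
         wrist = names[wristish],
         both = names)
}

# Mean over non-flagged, finite per-segment values; NA when none.
agg_mean <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0) NA_real_ else mean(x)
}

# Macro (and optionally micro) metrics of a pointing-task recording,
# averaged over segments.
aggregate_pointing <- function(rec, geometry, prefix = "",
                               micrometrics = TRUE, smooth_window = 5,
                               decompose_opts = list()) {
  targets <- task_targets(geometry, rec$task)
  nseg <- nrow(rec$segments)
  per <- vector("list", nseg)
  micro <- vector("list", nseg)
  for (i in seq_len(nseg)) {
    seg <- recording_segment(rec, i)
    tgt <- targets[seg$target_id, ]
    # alternate back-to-centre movements target the centre
    endq <- seg$q[nrow(seg$q), ]
    if (sqrt(sum((endq - tgt)^2)) > sqrt(sum(endq^2)) + 1e-9)
      tgt <- rep(0, length(endq))
    m <- tryCatch(reach_macro_metrics(seg, target = tgt,
                                      target_radius = geometry$target_radius,
                                      smooth_window = smooth_window),
                  error = function(e) NULL)
    per[[i]] <- m
    if (micrometrics && !is.null(m) && !isTRUE(m$flagged)) {
      sp <- path_speed(seg$t, seg$q, smooth_window = smooth_window)
      dec <- do.call(decompose_speed,
                     c(list(speed = pmax(sp, 0), t = seg$t), decompose_opts))
      micro[[i]] <- micrometrics(dec)
    }
  }
  ok <- !vapply(per, is.null, logical(1))
  fields <- c("aim", "duration", "deviation", "dwell_time", "mean_speed",
              "peak_speed", "speed_shape", "jerk_discrete", "jerk_rhythmic")
  out <- vapply(fields, function(f)
    agg_mean(vapply(per[ok], function(m)
      if (isTRUE(m$flagged)) NA_real_ else m[[f]], numeric(1))),
    numeric(1))
  names(out) <- paste0(prefix, fields)
  if (micrometrics) {
    mok <- !vapply(micro, is.null, logical(1))
    mf <- c(number = "submovement_number", duration = "submovement_duration",
            overlap = "submovement_overlap", peak = "submovement_peak",
            interpeak_interval = "submovement_interpeak")
    mv <- vapply(names(mf), function(f)
      agg_mean(vapply(micro[mok], function(m) {
        v <- m[[f]]
        if (is.null(v)) NA_real_ else as.numeric(v)
      }, numeric(1))), numeric(1))
    names(mv) <- paste0(prefix, mf)
    out <- c(out, mv)
  }
  out
}

aggregate_circle <- function(rec, arm) {
  nseg <- nrow(rec$segments)
  fits <- vector("list", nseg)
  conds <- integer(nseg)
  for (i in seq_len(nseg)) {
    seg <- recording_segment(rec, i)
    fits[[i]] <- tryCatch(circle_metrics(seg$q, arm = arm),
                          error = function(e) NULL)
    conds[i] <- seg$target_id
  }
  ok <- !vapply(fits, is.null, logical(1))
  g <- function(f) agg_mean(vapply(fits[ok], function(x)
    as.numeric(x[[f]]), numeric(1)))
  # horizontal_axes: mean major-axis length of the horizontally started
  # conditions (3 o'clock start = conditions 1-2 of the 4-condition grid)
  horiz <- which(ok & conds %in% c(1, 2))
  horiz_axes <- agg_mean(vapply(fits[horiz], function(x)
    as.numeric(x$major), numeric(1)))
  c(circle_major_axis = g("major"), circle_minor_axis = g("minor"),
    circle_axis_ratio = g("axis_ratio"),
    circle_orientation = agg_mean(abs(vapply(fits[ok], function(x)
      as.numeric(x$orientation), numeric(1)))),
    circle_joint_independence = g("joint_independence"),
    horizontal_axes = horiz_axes)
}

aggregate_resistance <- function(rec, geometry, prefix = "") {
  targets <- if (rec$device == "shoulder_elbow") geometry$reach_targets else
    geometry$wrist_targets
  segs <- lapply(seq_len(nrow(rec$segments)),
                 function(i) recording_segment(rec, i))
  rm_ <- resistance_metrics(segs, targets)
  stats::setNames(c(rm_$max_displacement, rm_$overall_aim),
                  paste0(prefix, c("max_displacement", "overall_aim")))
}

aggregate_isometric <- function(rec, prefix = "") {
  sm <- stabilization_metrics(rec$q, hold_point = c(0, 0))
  stats::setNames(c(sm$scatter, sm$offset),
                  paste0(prefix, c("scatter", "offset")))
}

aggregate_strength <- function(rec) {
  dirs <- rec$directions
  if (is.null(dirs)) stop("kinetic_strength recording lacks direction labels")
  peaks <- vapply(seq_len(nrow(rec$segments)), function(i) {
    seg <- recording_segment(rec, i)
    max(seg$f[, 1])
  }, numeric(1))
  ss <- shoulder_strength(data.frame(direction = dirs, peak_force = peaks,
                                     stringsAsFactors = FALSE))
  c(deltaz = ss$deltaz,
    strength_f = ss$per_direction[["F"]],
    strength_e = ss$per_direction[["E"]],
    strength_ab = ss$per_direction[["AB"]],
    strength_ad = ss$per_direction[["AD"]])
}

#' Compute session-level features from a set of recordings
#'
#' Computes every applicable metric for each recording, mean-aggregates
#' per-segment values within the session, and joins the clinical scores, one
#' row per (patient, session).
#'
#' @param recordings List of \code{\link{task_recording}} objects.
#' @param scores data.frame with \code{patient_id}, \code{session_label} and
#'   the four scale columns (e.g. the \code{scores} element of
#'   \code{\link{simulate_cohort}}).
#' @param geometry A \code{\link{task_geometry}}.
#' @param arm An \code{\link{arm_geometry}} for circle joint independence
#'   (NULL skips it).
#' @param micrometrics Run the submovement decomposition on every pointing
#'   segment (default TRUE; the costly stage).
#' @param smooth_window Derivative smoothing window (samples).
#' @param decompose_opts List of options passed to
#'   \code{\link{decompose_speed}}.
#' @return Feature table data.frame (one row per patient-session).
#' @export
session_feature_table <- function(recordings, scores,
                                  geometry = task_geometry(),
                                  arm = arm_geometry(),
                                  micrometrics = TRUE, smooth_window = 5,
                                  decompose_opts = list()) {
  keys <- vapply(recordings, function(r)
    paste(r$patient_id, r$session_label, sep = "\r"), character(1))
  rows <- list()
  for (key in unique(keys)) {
    recs <- recordings[keys == key]
    parts <- strsplit(key, "\r")[[1]]
    feats <- numeric(0)
    for (rec in recs) {
      vals <- switch(
        rec$task,
        reach8 = aggregate_pointing(rec, geometry, "", micrometrics,
                                    smooth_window, decompose_opts),
        wrist_point8 = aggregate_pointing(rec, geometry, "wrist_",
                                          micrometrics, smooth_window,
                                          decompose_opts),
        forearm_ps = aggregate_pointing(rec, geometry, "forearm_",
                                        micrometrics, smooth_window,
                                        decompose_opts),
        circle_draw = aggregate_circle(rec, arm),
        resistance = aggregate_resistance(
          rec, geometry,
          if (rec$device == "shoulder_elbow") "" else "wrist_"),
        isometric_hold = aggregate_isometric(
          rec, if (rec$device == "shoulder_elbow") "" else "wrist_"),
        kinetic_strength = aggregate_strength(rec))
      feats <- c(feats, vals)
    }
    sc <- scores[scores$patient_id == parts[1] &
                   scores$session_label == parts[2], , drop = FALSE]
    cs <- if (nrow(sc) == 1) {
      clinical_scores(fma_ue = sc$fma_ue, wmft = sc$wmft, bi = sc$bi,
                      mrc = sc$mrc)
    } else clinical_scores()
    rows[[length(rows) + 1]] <-
      session_feature_row(parts[1], parts[2], as.list(feats), cs)
  }
  all_cols <- Reduce(union, lapply(rows, names))
  rows <- lapply(rows, function(r) {
    for (cn in setdiff(all_cols, names(r))) r[[cn]] <- NA_real_
    r[all_cols]
  })
  do.call(rbind, rows)
}
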