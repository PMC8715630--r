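## Macro kinematic metrics of a movement segment -----------------------------

#' Macro kinematic metrics of one reaching / pointing segment
#'
#' Computes the whole-movement summary metrics for a point-to-point movement
#' attempt: aim (unsigned angle between the velocity at the first speed peak
#' and the straight line to the target), duration, deviation (RMS or maximum
#' perpendicular distance from the start-to-target chord), dwell time
#' (terminal time spent inside the target radius below the speed threshold),
#' mean and peak speed, speed shape (mean/peak speed, which approaches the
#' minimum-jerk value 8/15 for smooth movements), and two dimensionless
#' squared-jerk smoothness measures.
#'
#' Jerk normalisation: for discrete (terminated) movements
#' \eqn{J = \int \|j\|^2 dt \cdot D^5 / A^2} with \eqn{D} the segment
#' duration and \eqn{A} the path length (720 for an ideal minimum-jerk
#' reach); the rhythmic variant normalises by mean speed,
#' \eqn{J_r = \int \|j\|^2 dt \cdot D^3 / \bar v^2}.
#'
#' @param seg Segment as returned by \code{\link{recording_segment}} (list
#'   with \code{t}, \code{q}) or a \code{task_recording} whose full sample
#'   range is one movement.
#' @param target Target coordinates for the segment (vector matching the
#'   coordinate dimension).
#' @param target_radius Tolerance radius used for dwell time.
#' @param deviation_stat \code{"rms"} (default) or \code{"max"}.
#' @param smooth_window Savitzky-Golay window for derivative estimation
#'   (samples, odd; 1 disables smoothing). Default 5.
#' @return List of class \code{macro_metrics} with fields \code{aim},
#'   \code{duration}, \code{deviation}, \code{dwell_time}, \code{mean_speed},
#'   \code{peak_speed}, \code{speed_shape}, \code{jerk_discrete},
#'   \code{jerk_rhythmic}, and \code{flagged} (TRUE for degenerate segments,
#'   which are excluded from session means).
#' @export
#' @examples
#' # dense minimum-jerk reach: speed shape is 8/15, discrete jerk 720
#' tt <- seq(0, 1, length.out = 2000)
#' x <- 0.14 * (10 * tt^3 - 15 * tt^4 + 6 * tt^5)
#' m <- reach_macro_metrics(list(t = tt, q = cbind(x, 0)),
#'                          target = c(0.14, 0), smooth_window = 1)
#' c(m$speed_shape, m$jerk_discrete)
reach_macro_metrics <- function(seg, target, target_radius = 0.01,
                                deviation_stat = c("rms", "max"),
                                smooth_window = 5) {
  deviation_stat <- match.arg(deviation_stat)
  if (inherits(seg, "task_recording"))
    seg <- list(t = seg$t, q = seg$q)
  t <- seg$t
  q <- as.matrix(seg$q)
  if (length(t) < 5) stop("segment must have at least 5 samples")
  start <- q[1, ]
  displacement <- sqrt(sum((q[nrow(q), ] - start)^2))
  A <- path_length(q)
  if (displacement <= 0 || A <= 0)
    return(structure(list(aim = NA_real_, duration = NA_real_,
                          deviation = NA_real_, dwell_time = NA_real_,
                          mean_speed = NA_real_, peak_speed = NA_real_,
                          speed_shape = NA_real_, jerk_discrete = NA_real_,
                          jerk_rhythmic = NA_real_, flagged = TRUE),
                     class = "macro_metrics"))
  qs <- smooth_columns(q, smooth_window)
  vel <- apply(qs, 2, num_deriv, t = t)
  speed <- sqrt(rowSums(as.matrix(vel)^2))
  D <- t[length(t)] - t[1]
  mean_speed <- trapz_int(t, speed) / D
  peak_speed <- max(speed)
  # aim at the first local speed maximum
  ip <- first_local_max(speed)
  v_at_peak <- as.matrix(vel)[ip, ]
  to_target <- target - start
  aim <- vector_angle(v_at_peak, to_target)
  deviation <- chord_deviation(q, start, target, deviation_stat)
  dwell_time <- terminal_dwell(t, q, speed, target, target_radius,
                               0.05 * peak_speed)
  jrk <- apply(qs, 2, num_deriv3, t = t)
  jsq <- trapz_int(t, rowSums(as.matrix(jrk)^2))
  structure(list(aim = aim, duration = D, deviation = deviation,
                 dwell_time = dwell_time, mean_speed = mean_speed,
                 peak_speed = peak_speed,
                 speed_shape = mean_speed / peak_speed,
                 jerk_discrete = jsq * D^5 / A^2,
                 jerk_rhythmic = jsq * D^3 / mean_speed^2,
                 flagged = FALSE),
            class = "macro_metrics")
}

first_local_max <- function(x) {
  n <- length(x)
  for (i in 2:(n - 1)) if (x[i] >= x[i - 1] && x[i] > x[i + 1]) return(i)
  which.max(x)
}

vector_angle <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(NA_real_)
  acos(pmin(1, pmax(-1, sum(a * b) / (na * nb))))
}

chord_deviation <- function(q, start, target, stat) {
  chord <- target - start
  L <- sqrt(sum(chord^2))
  if (L == 0) return(NA_real_)
  if (length(start) == 1) return(0)
  u <- chord / L
  rel <- sweep(q, 2, start)
  along <- as.vector(rel %*% u)
  perp2 <- rowSums(rel^2) - along^2
  perp <- sqrt(pmax(perp2, 0))
  if (stat == "rms") sqrt(mean(perp^2)) else max(perp)
}

terminal_dwell <- function(t, q, speed, target, target_radius, thr) {
  d <- sqrt(rowSums(sweep(as.matrix(q), 2, target)^2))
  inside <- d < target_radius & speed < thr
  n <- length(t)
  if (!inside[n]) return(0)
  i <- n
  while (i > 1 && inside[i - 1]) i <- i - 1
  t[n] - t[i]
}

## Resistance, stabilization and strength metrics ----------------------------

#' Metrics of the movement-against-resistance task
#'
#' The patient reaches toward targets against an increasing opposing force.
#' Maximum displacement is the largest progress made from the start toward
#' the target over all attempts; overall aim is the circular mean of the
#' per-segment aim angles.
#'
#' @param segments List of segments (each with \code{t}, \code{q}, \code{f},
#'   \code{target_id}).
#' @param targets Matrix of target coordinates indexed by \code{target_id}.
#' @param smooth_window Derivative smoothing window passed through to the aim
#'   computation.
#' @return List with \code{max_displacement} and \code{overall_aim}.
#' @export
resistance_metrics <- function(segments, targets, smooth_window = 5) {
  stopifnot(length(segments) > 0)
  if (any(vapply(segments, function(s) is.null(s$f), logical(1))))
    warning("resistance segments without force channel; metrics computed from kinematics only")
  disp <- numeric(0); aims <- numeric(0)
  for (s in segments) {
    q <- as.matrix(s$q)
    tgt <- targets[s$target_id, ]
    u <- tgt - q[1, ]
    L <- sqrt(sum(u^2))
    if (L == 0) next
    u <- u / L
    along <- as.vector(sweep(q, 2, q[1, ]) %*% u)
    disp <- c(disp, max(along))
    if (length(s$t) >= 5) {
      aim_s <- signed_aim(s$t, q, tgt, smooth_window)
      if (is.finite(aim_s)) aims <- c(aims, aim_s)
    }
  }
  list(max_displacement = if (length(disp)) max(disp) else NA_real_,
       overall_aim = if (length(aims)) circular_mean(aims) else NA_real_)
}

# Signed aim of a segment: angle from the start-to-target line to the
# velocity at the first speed peak, positive counter-clockwise (the unsigned
# macro aim cannot average out opposite errors; the resistance task's
# overall aim is a circular mean of signed errors).
signed_aim <- function(t, q, target, smooth_window = 5) {
  if (ncol(q) == 1) {
    v <- num_deriv(as.vector(smooth_columns(q, smooth_window)), t)
    ip <- first_local_max(abs(v))
    return(if (sign(v[ip]) == sign(target - q[1, 1])) 0 else pi)
  }
  qs <- smooth_columns(q, smooth_window)
  vel <- apply(qs, 2, num_deriv, t = t)
  speed <- sqrt(rowSums(vel^2))
  ip <- first_local_max(speed)
  u <- target - q[1, ]
  v <- vel[ip, ]
  atan2(u[1] * v[2] - u[2] * v[1], sum(u * v))
}

#' Metrics of the isometric stabilization task
#'
#' The patient holds the limb still at a commanded point while the robot
#' pushes outward. Offset is the norm of the mean displacement from the hold
#' point; scatter is the root-mean-square excursion of the position about its
#' own mean.
#'
#' @param q Matrix of position samples (rows) during the hold.
#' @param hold_point Commanded hold coordinates.
#' @return List with \code{scatter} and \code{offset}.
#' @export
stabilization_metrics <- function(q, hold_point) {
  q <- as.matrix(q)
  if (nrow(q) < 10) stop("stabilization metrics need at least 10 samples")
  mu <- colMeans(q)
  offset <- sqrt(sum((mu - hold_point)^2))
  scatter <- sqrt(mean(rowSums(sweep(q, 2, mu)^2)))
  list(scatter = scatter, offset = offset)
}

#' Mean shoulder strength from force-transducer trials
#'
#' Trials are labelled by direction (flexion F, extension E, abduction AB,
#' adduction AD), up to 5 per direction. The per-direction strength is the
#' mean of per-trial peak forces; deltaz (mean shoulder strength) is the mean
#' of the four direction means.
#'
#' @param trials data.frame with columns \code{direction} (one of
#'   F/E/AB/AD) and \code{peak_force} (newtons), one row per trial.
#' @return List with \code{per_direction} (named numeric, NA for directions
#'   without trials) and \code{deltaz}.
#' @export
shoulder_strength <- function(trials) {
  stopifnot(is.data.frame(trials),
            all(c("direction", "peak_force") %in% names(trials)))
  dirs <- c("F", "E", "AB", "AD")
  if (!all(trials$direction %in% dirs))
    stop("direction must be one of F, E, AB, AD")
  per <- vapply(dirs, function(d) {
    v <- trials$peak_force[trials$direction == d]
    if (length(v) == 0) NA_real_ else mean(v)
  }, numeric(1))
  if (anyNA(per))
    warning("direction(s) without trials: deltaz computed over available directions")
  list(per_direction = per, deltaz = mean(per, na.rm = TRUE))
}
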