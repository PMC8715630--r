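## Synthetic cohort generator ------------------------------------------------

# Emulates the trial's structure: ~82 patients, up to 4 evaluation sessions
# (two baselines, discharge, follow-up), shoulder-elbow and wrist/forearm
# robotic tasks, clinical scores on bounded ordinal scales. A latent
# impairment z in [0, 1] per patient/session drives both trajectory quality
# (submovement count, blending, curvature, slowness, strength) and the
# noise-free clinical scores, so every downstream stage has ground truth.

#' Default per-scale link configuration for the simulator
#'
#' Each scale maps the latent impairment z in [0, 1] monotonically onto its
#' range: z = 0 (no impairment) gives the scale maximum. Scales without a
#' hard upper bound (WMFT, MRC) use their nominal simulation maxima.
#'
#' @param link \code{"linear"} or \code{"sigmoid"} (applied to all scales).
#' @param noise_sd Observation noise standard deviation, in scale units,
#'   applied to all scales (recycled to length 4).
#' @return Named list of per-scale link configs (\code{link}, \code{min},
#'   \code{max}, \code{step}, \code{slope}, \code{offset}, \code{noise_sd}).
#' @export
default_scale_links <- function(link = "linear", noise_sd = c(4, 6, 8, 5)) {
  noise_sd <- rep_len(noise_sd, 4)
  mk <- function(mn, mx, step, ns)
    list(link = link, min = mn, max = mx, step = step, slope = 8,
         offset = 0.5, noise_sd = ns)
  list(fma_ue = mk(0, 66, 1, noise_sd[1]),
       wmft = mk(0, 75, 1, noise_sd[2]),
       bi = mk(0, 100, 5, noise_sd[3]),
       mrc = mk(0, 80, 0.5, noise_sd[4]))
}

#' Simulation configuration
#'
#' Defaults mirror the emulated trial: 82 patients, 4 evaluation sessions,
#' 200 Hz sampling, 80 reaching movements per pointing task, 5 circle
#' attempts per drawing condition, 5 strength trials per direction.
#' \code{kinematic_effects} sets how trajectory quality degrades with the
#' latent impairment z: the Poisson rate of corrective submovements grows as
#' \code{submovement_lambda_max * z}, submovement blending (overlap) shrinks
#' with z, path curvature noise and movement duration grow with z, and
#' strength falls as \code{1 - strength_loss * z}.
#'
#' @param n_patients Number of patients (>= 8 so cross-validation is
#'   feasible).
#' @param sessions_per_patient 1-4 sessions per patient.
#' @param seed Integer seed; fully determines the generated cohort.
#' @param latent_mean,latent_sd Mean and sd of the truncated-normal latent
#'   impairment z on [0, 1].
#' @param scale_links Per-scale link configuration
#'   (\code{\link{default_scale_links}}).
#' @param kinematic_effects Named list of effect magnitudes (see above).
#' @param sample_rate_hz Sampling rate of generated trajectories.
#' @param n_reaches Movement attempts per pointing task (default 80).
#' @param circle_reps Attempts per circle-drawing condition (default 5).
#' @param round_scores Round observed scores to the scale granularity
#'   (default TRUE; turn off for exact-affine checks against ground truth).
#' @param recovery_per_session Mean decrease of z per later session.
#' @param z_session_sd Session-to-session wobble of z (default 0.02).
#' @param geometry A \code{\link{task_geometry}}.
#' @return Object of class \code{sim_config}.
#' @export
sim_config <- function(n_patients = 82, sessions_per_patient = 4, seed = 1,
                       latent_mean = 0.5, latent_sd = 0.25,
                       scale_links = default_scale_links(),
                       kinematic_effects = list(submovement_lambda_max = 3,
                                                overlap_base = 0.5,
                                                curvature_gain = 0.25,
                                                duration_gain = 0.8,
                                                strength_loss = 0.8),
                       sample_rate_hz = 200, n_reaches = 80, circle_reps = 5,
                       round_scores = TRUE, recovery_per_session = 0.04,
                       z_session_sd = 0.02,
                       geometry = task_geometry()) {
  stopifnot(n_patients >= 8, sessions_per_patient >= 1,
            sessions_per_patient <= 4, sample_rate_hz > 0, n_reaches >= 1)
  structure(list(n_patients = n_patients,
                 sessions_per_patient = sessions_per_patient,
                 seed = as.integer(seed), latent_mean = latent_mean,
                 latent_sd = latent_sd, scale_links = scale_links,
                 kinematic_effects = kinematic_effects,
                 sample_rate_hz = sample_rate_hz, n_reaches = n_reaches,
                 circle_reps = circle_reps, round_scores = round_scores,
                 recovery_per_session = recovery_per_session,
                 z_session_sd = z_session_sd,
                 geometry = geometry),
            class = "sim_config")
}

#' Map latent impairment to a clinical score (noise-free link)
#'
#' Monotone non-increasing in z: no impairment (z = 0) maps to the scale
#' maximum. The linear link is an affine map onto [min, max]; the sigmoid
#' link is a logistic curve centred at \code{offset} with steepness
#' \code{slope}, rescaled to hit the scale bounds exactly at z = 0 and
#' z = 1. The result is clipped to the bounds and rounded to the scale step
#' unless \code{round} is FALSE.
#'
#' @param z Latent impairment in [0, 1] (vectorized).
#' @param scale_cfg One element of \code{\link{default_scale_links}}.
#' @param round Round to the scale granularity (default TRUE).
#' @return Score value(s).
#' @export
latent_to_clinical <- function(z, scale_cfg, round = TRUE) {
  stopifnot(all(z >= 0 & z <= 1))
  mn <- scale_cfg$min; mx <- scale_cfg$max
  raw <- if (identical(scale_cfg$link, "sigmoid")) {
    s <- scale_cfg$slope; o <- scale_cfg$offset
    sig <- function(u) 1 / (1 + exp(-s * (u - o)))
    frac <- (sig(1 - z) - sig(0)) / (sig(1) - sig(0))   # 1 at z=0, 0 at z=1
    mn + (mx - mn) * frac
  } else {
    mx - (mx - mn) * z
  }
  raw <- pmin(mx, pmax(mn, raw))
  if (round) round(raw / scale_cfg$step) * scale_cfg$step else raw
}

# Truncated-normal draw on [0, 1] by inverse-CDF (vectorized, uses current
# RNG stream).
rtrunc01 <- function(n, mean, sd) {
  lo <- stats::pnorm(0, mean, sd); hi <- stats::pnorm(1, mean, sd)
  stats::qnorm(lo + stats::runif(n) * (hi - lo), mean, sd)
}

## Trajectory assembly -------------------------------------------------------

# Generating submovements for one point-to-point movement of path length L:
# one primary pulse plus Poisson(lambda_max * z) corrective pulses, blended
# less (later onsets) and lasting longer as impairment grows. Amplitudes are
# normalized to sum to L so the movement lands on the target.
draw_submovements <- function(L, z, eff) {
  n <- 1 + stats::rpois(1, eff$submovement_lambda_max * z)
  w <- c(1, stats::runif(n - 1, 0.1, 0.35))[seq_len(n)]
  w <- w / sum(w)
  D1 <- 0.6 + eff$duration_gain * z * stats::runif(1, 0.8, 1.2)
  Ds <- c(D1, stats::runif(max(n - 1, 0), 0.3, 0.45) + 0.2 * z)
  overlap_frac <- pmax(eff$overlap_base * (1 - z), 0.05)
  t0 <- numeric(n)
  t0[1] <- 0.02
  if (n > 1)
    for (i in 2:n) t0[i] <- t0[i - 1] + Ds[i - 1] * (1 - overlap_frac)
  lapply(seq_len(n), function(i)
    submovement(t0 = t0[i], D = Ds[i], A = w[i] * L,
                sigma = stats::runif(1, 0.25, 0.4)))
}

# Assemble one movement segment from start toward target: tangential
# displacement integrates the submovement speed profile; perpendicular
# curvature noise grows with impairment. Returns t (from 0), q, and the
# generating submovements.
assemble_segment <- function(start, target, z, eff, rate) {
  d <- target - start
  L <- sqrt(sum(d^2))
  u <- d / L
  sms <- draw_submovements(L, z, eff)
  t_end <- max(vapply(sms, function(s) s$t0 + s$D, numeric(1))) + 0.15
  t <- seq(0, t_end, by = 1 / rate)
  speed <- synth_speed_profile(sms, t)
  along <- cumsum(c(0, (speed[-1] + speed[-length(speed)]) / 2 * diff(t)))
  along <- along * (L / max(along))            # exact landing on target
  ncoord <- length(start)
  q <- matrix(start, nrow = length(t), ncol = ncoord, byrow = TRUE) +
    outer(along, u)
  if (ncoord == 2) {
    perp <- c(-u[2], u[1])
    s01 <- along / L
    wob <- eff$curvature_gain * z * L *
      (stats::runif(1, -1, 1) * sin(pi * s01) +
         0.3 * stats::runif(1, -1, 1) * sin(2 * pi * s01))
    q <- q + outer(wob, perp)
  }
  list(t = t, q = q, submovements = sms)
}

# Stitch movement segments into one task recording: rest samples at each
# via-point separate consecutive attempts.
stitch_segments <- function(pieces, target_ids, rate, patient_id,
                            session_label, device, task, f_list = NULL) {
  dt <- 1 / rate
  t_all <- numeric(0); q_all <- NULL; f_all <- NULL
  seg_rows <- list()
  clock <- 0
  for (i in seq_along(pieces)) {
    p <- pieces[[i]]
    n_rest <- 5
    rest_q <- matrix(p$q[1, ], nrow = n_rest, ncol = ncol(p$q), byrow = TRUE)
    rest_t <- clock + dt * seq_len(n_rest)
    start_idx <- length(t_all) + n_rest + 1
    t_all <- c(t_all, rest_t, rest_t[n_rest] + dt + p$t)
    q_all <- rbind(q_all, rest_q, p$q)
    if (!is.null(f_list)) {
      rest_f <- matrix(0, nrow = n_rest, ncol = ncol(f_list[[i]]))
      f_all <- rbind(f_all, rest_f, f_list[[i]])
    }
    seg_rows[[i]] <- data.frame(start = start_idx,
                                end = length(t_all),
                                target_id = target_ids[i])
    clock <- t_all[length(t_all)]
  }
  task_recording(patient_id, session_label, device, task,
                 t = t_all, q = q_all, f = f_all,
                 segments = do.call(rbind, seg_rows))
}

# One pointing-task recording (reach8 / wrist_point8 / forearm_ps):
# alternating centre-to-target and back movements.
gen_pointing_task <- function(patient_id, session_label, device, task, z,
                              cfg, truth_env) {
  geom <- cfg$geometry
  targets <- task_targets(geom, task)
  center <- if (task == "reach8") geom$center else rep(0, ncol(targets))
  eff <- cfg$kinematic_effects
  pieces <- list(); ids <- integer(0); sm_truth <- list()
  for (i in seq_len(cfg$n_reaches)) {
    tid <- ((i - 1) %/% 2) %% nrow(targets) + 1
    outward <- i %% 2 == 1
    from <- if (outward) center else targets[tid, ]
    to <- if (outward) targets[tid, ] else center
    p <- assemble_segment(from, to, z, eff, cfg$sample_rate_hz)
    pieces[[i]] <- p; ids[i] <- tid
    sm_truth[[i]] <- p$submovements
  }
  rec <- stitch_segments(pieces, ids, cfg$sample_rate_hz, patient_id,
                         session_label, device, task)
  truth_env$segments[[rec_key(rec)]] <- sm_truth
  rec
}

# Circle drawing: 4 conditions (CW/CCW x start 3/9 o'clock), circle_reps
# attempts each; drawn radius shrinks and flattens with impairment.
gen_circle_task <- function(patient_id, session_label, z, cfg) {
  geom <- cfg$geometry
  r <- geom$reach_radius_m * (1 - 0.2 * z)
  ratio <- 1 - 0.35 * z
  rate <- cfg$sample_rate_hz
  conds <- expand.grid(dir = c(1, -1), start = c(0, pi))
  pieces <- list(); ids <- integer(0)
  k <- 0
  for (ci in seq_len(nrow(conds))) {
    for (rep_i in seq_len(cfg$circle_reps)) {
      k <- k + 1
      tt <- seq(0, 3, by = 1 / rate)
      ph <- conds$start[ci] + conds$dir[ci] * 2 * pi * tt / 3
      wob <- 1 + 0.06 * z * sin(3 * ph + stats::runif(1, 0, 2 * pi))
      x <- geom$center[1] + r * wob * cos(ph)
      y <- geom$center[2] + r * ratio * wob * sin(ph)
      pieces[[k]] <- list(t = tt, q = cbind(x, y))
      ids[k] <- ci
    }
  }
  stitch_segments(pieces, ids, rate, patient_id, session_label,
                  "shoulder_elbow", "circle_draw")
}

# Movement against resistance: reach toward each target against a ramping
# opposing force; progress toward the target shrinks with impairment.
gen_resistance_task <- function(patient_id, session_label, device, z, cfg) {
  geom <- cfg$geometry
  targets <- if (device == "shoulder_elbow") geom$reach_targets else
    geom$wrist_targets
  center <- if (device == "shoulder_elbow") geom$center else c(0, 0)
  eff <- cfg$kinematic_effects
  frac <- max(1 - 0.6 * z, 0.2)
  pieces <- list(); f_list <- list(); ids <- integer(0)
  for (tid in seq_len(nrow(targets))) {
    part_target <- center + frac * (targets[tid, ] - center)
    p <- assemble_segment(center, part_target, z, eff, cfg$sample_rate_hz)
    pieces[[tid]] <- p
    f_list[[tid]] <- cbind(10 * p$t, 0)   # ramping opposing force, N
    ids[tid] <- tid
  }
  stitch_segments(pieces, ids, cfg$sample_rate_hz, patient_id, session_label,
                  device, "resistance", f_list = f_list)
}

# Isometric stabilization: hold at the centre for 5 s under robot forces;
# bias and wander grow with impairment.
gen_isometric_task <- function(patient_id, session_label, device, z, cfg) {
  rate <- cfg$sample_rate_hz
  tt <- seq(0, 5, by = 1 / rate)
  n <- length(tt)
  bias_mag <- 0.025 * z * if (device == "shoulder_elbow") 1 else 0.5
  ang <- stats::runif(1, 0, 2 * pi)
  wander_sd <- (0.002 + 0.01 * z) * if (device == "shoulder_elbow") 1 else 0.5
  smooth_noise <- function() {
    raw <- stats::rnorm(n, 0, wander_sd)
    stats::filter(raw, rep(1 / 25, 25), circular = TRUE) * 5
  }
  q <- cbind(bias_mag * cos(ang) + as.numeric(smooth_noise()),
             bias_mag * sin(ang) + as.numeric(smooth_noise()))
  f <- cbind(5 * cos(2 * pi * tt / 5), 5 * sin(2 * pi * tt / 5))
  task_recording(patient_id, session_label, device, "isometric_hold",
                 t = tt, q = q, f = f,
                 segments = data.frame(start = 1, end = n, target_id = 1))
}

# Kinetic strength: 5 force trials in each of F/E/AB/AD; per-direction peak
# force is base * (1 - strength_loss * z) + noise.
gen_strength_task <- function(patient_id, session_label, z, cfg) {
  eff <- cfg$kinematic_effects
  rate <- cfg$sample_rate_hz
  base <- c(F = 60, E = 55, AB = 50, AD = 50)
  dirs <- rep(names(base), each = 5)
  pieces <- list(); f_list <- list(); ids <- integer(0)
  for (i in seq_along(dirs)) {
    peak <- max(base[[dirs[i]]] * (1 - eff$strength_loss * z) +
                  stats::rnorm(1, 0, 3), 1)
    tt <- seq(0, 2, by = 1 / rate)
    pulse <- peak * sin(pi * tt / 2)^2
    pieces[[i]] <- list(t = tt, q = matrix(0.001 * pulse / peak, ncol = 1))
    f_list[[i]] <- matrix(pulse, ncol = 1)
    ids[i] <- i
  }
  rec <- stitch_segments(pieces, ids, rate, patient_id, session_label,
                         "shoulder_elbow", "kinetic_strength",
                         f_list = f_list)
  rec$directions <- dirs
  rec
}

rec_key <- function(rec) {
  paste(rec$patient_id, rec$session_label, rec$device, rec$task, sep = "/")
}

#' Simulate a synthetic evaluation cohort
#'
#' Generates, per patient and session, the shoulder-elbow task battery
#' (reaching, circle drawing, resistance, isometric hold, kinetic strength)
#' and the wrist/forearm battery (wrist pointing, forearm rotation,
#' resistance, isometric hold), together with clinical scores linked to the
#' latent impairment, and a ground-truth record (latent z, noise-free
#' scores, generating submovements per segment) that is carried alongside
#' but never fed to the pipeline. Regenerating with the same configuration
#' is bit-identical.
#'
#' @param cfg A \code{\link{sim_config}}.
#' @return List with \code{recordings} (list of \code{task_recording}),
#'   \code{scores} (data.frame: patient, session, four scales), and
#'   \code{truth} (list: \code{latent} data.frame with z and noise-free
#'   scores; \code{segments}: generating submovements keyed by
#'   patient/session/device/task).
#' @export
simulate_cohort <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, simulate_cohort_impl(cfg))
}

simulate_cohort_impl <- function(cfg) {
  truth_env <- new.env()
  truth_env$segments <- list()
  sessions <- SESSION_LABELS[seq_len(cfg$sessions_per_patient)]
  recordings <- list()
  score_rows <- list()
  latent_rows <- list()
  for (pi in seq_len(cfg$n_patients)) {
    pid <- sprintf("P%03d", pi)
    z0 <- rtrunc01(1, cfg$latent_mean, cfg$latent_sd)
    for (si in seq_along(sessions)) {
      drift <- if (si <= 2) 0 else (si - 2) * cfg$recovery_per_session
      z <- min(max(z0 - drift + stats::rnorm(1, 0, cfg$z_session_sd), 0), 1)
      sl <- sessions[si]
      recs <- list(
        gen_pointing_task(pid, sl, "shoulder_elbow", "reach8", z, cfg,
                          truth_env),
        gen_circle_task(pid, sl, z, cfg),
        gen_resistance_task(pid, sl, "shoulder_elbow", z, cfg),
        gen_isometric_task(pid, sl, "shoulder_elbow", z, cfg),
        gen_strength_task(pid, sl, z, cfg),
        gen_pointing_task(pid, sl, "wrist_forearm", "wrist_point8", z, cfg,
                          truth_env),
        gen_pointing_task(pid, sl, "wrist_forearm", "forearm_ps", z, cfg,
                          truth_env),
        gen_resistance_task(pid, sl, "wrist_forearm", z, cfg),
        gen_isometric_task(pid, sl, "wrist_forearm", z, cfg))
      recordings <- c(recordings, recs)
      clean <- vapply(CLINICAL_SCALES, function(s)
        latent_to_clinical(z, cfg$scale_links[[s]], round = FALSE),
        numeric(1))
      noisy <- vapply(CLINICAL_SCALES, function(s) {
        v <- clean[[s]] + stats::rnorm(1, 0, cfg$scale_links[[s]]$noise_sd)
        v <- min(max(v, cfg$scale_links[[s]]$min), cfg$scale_links[[s]]$max)
        if (cfg$round_scores)
          round(v / cfg$scale_links[[s]]$step) * cfg$scale_links[[s]]$step
        else v
      }, numeric(1))
      score_rows[[length(score_rows) + 1]] <-
        data.frame(patient_id = pid, session_label = sl,
                   as.list(noisy), stringsAsFactors = FALSE)
      latent_rows[[length(latent_rows) + 1]] <-
        data.frame(patient_id = pid, session_label = sl, z = z,
                   as.list(stats::setNames(clean,
                                           paste0(CLINICAL_SCALES, "_clean"))),
                   stringsAsFactors = FALSE)
    }
  }
  list(recordings = recordings,
       scores = do.call(rbind, score_rows),
       truth = list(latent = do.call(rbind, latent_rows),
                    segments = truth_env$segments))
}

#' Simulate a score-level cohort with known population correlation
#'
#' A lightweight generator for validating the modelling stage: one (or more)
#' informative session-level features whose population Pearson correlation
#' with the target scale is exactly \code{rho} by construction
#' (\eqn{y = \rho x + \sqrt{1-\rho^2}\,\epsilon} on standardized variables,
#' then mapped onto the scale range). With \code{link = "sigmoid"} the
#' feature enters through a logistic transform, giving the nonlinear model a
#' realizable advantage.
#'
#' @param n_patients Number of patients.
#' @param sessions Sessions per patient.
#' @param rho Generating population correlation (linear link).
#' @param seed Integer seed.
#' @param target Target scale name (default \code{"fma_ue"}).
#' @param link \code{"linear"} or \code{"sigmoid"}.
#' @param n_features Number of informative features (default 1).
#' @return Feature table data.frame with columns \code{patient_id},
#'   \code{session_label}, \code{metric_1} ... and the four scales (only
#'   \code{target} non-missing).
#' @export
simulate_score_cohort <- function(n_patients = 80, sessions = 3, rho = 0.85,
                                  seed = 1, target = "fma_ue",
                                  link = c("linear", "sigmoid"),
                                  n_features = 1) {
  link <- match.arg(link)
  stopifnot(rho > 0, rho < 1)
  with_seed(seed, {
    n <- n_patients * sessions
    pid <- rep(sprintf("P%03d", seq_len(n_patients)), each = sessions)
    sl <- rep(SESSION_LABELS[seq_len(sessions)], times = n_patients)
    x <- stats::rnorm(n)
    lat <- if (link == "sigmoid") tanh(1.5 * x) / stats::sd(tanh(1.5 * x))
           else x
    y <- rho * lat + sqrt(1 - rho^2) * stats::rnorm(n)
    info <- clinical_scale_info()
    info <- info[info$scale == target, ]
    mx <- if (is.na(info$max)) 100 else info$max
    score <- (y - min(y)) / (max(y) - min(y)) * mx
    tab <- data.frame(patient_id = pid, session_label = sl,
                      metric_1 = x, stringsAsFactors = FALSE)
    if (n_features > 1)
      for (j in 2:n_features)
        tab[[paste0("metric_", j)]] <- stats::rnorm(n)
    for (s in CLINICAL_SCALES) tab[[s]] <- NA_real_
    tab[[target]] <- score
    tab
  })
}

#' Write a simulated cohort to disk
#'
#' Writes every recording as a trajectory CSV, the clinical scores as a
#' CSV, and the ground truth (latent impairment, noise-free scores,
#' generating submovement parameters) as a JSON manifest.
#'
#' @param cohort A \code{\link{simulate_cohort}} result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, \code{dir}.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (rec in cohort$recordings) {
    fn <- file.path(dir, paste0(gsub("/", "_", rec_key(rec)), ".csv"))
    write_recording(rec, fn)
  }
  utils::write.csv(cohort$scores, file.path(dir, "scores.csv"),
                   row.names = FALSE, quote = FALSE)
  truth <- cohort$truth
  truth$segments <- lapply(truth$segments, function(segs)
    lapply(segs, function(sms) lapply(sms, unclass)))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
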