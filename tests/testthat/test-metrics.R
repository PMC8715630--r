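test_that("minimum-jerk reaches hit the closed-form macro metric values", {
  seg <- minjerk_segment(n = 2000)
  m <- reach_macro_metrics(list(t = seg$t, q = seg$q), target = seg$target,
                           smooth_window = 1)
  expect_equal(m$speed_shape, 8 / 15, tolerance = 1e-3)
  expect_equal(m$jerk_discrete, 720, tolerance = 0.005 * 720)
  expect_equal(m$aim, 0, tolerance = 1e-6)
  expect_equal(m$deviation, 0, tolerance = 1e-9)
  expect_false(m$flagged)
  # same with default smoothing on
  m5 <- reach_macro_metrics(list(t = seg$t, q = seg$q), target = seg$target)
  expect_equal(m5$jerk_discrete, 720, tolerance = 0.005 * 720)
})

test_that("constant-speed straight segments have speed shape 1", {
  tt <- seq(0, 1, by = 0.002)
  q <- cbind(0.1 * tt, 0)
  m <- reach_macro_metrics(list(t = tt, q = q), target = c(0.1, 0),
                           smooth_window = 1)
  expect_equal(m$speed_shape, 1, tolerance = 1e-9)
})

test_that("speed shape lies in (0, 1] for nondegenerate generated segments", {
  ch <- small_cohort()
  reach <- Filter(function(r) r$task == "reach8", ch$recordings)[[1]]
  for (i in seq_len(min(6, nrow(reach$segments)))) {
    seg <- recording_segment(reach, i)
    m <- reach_macro_metrics(seg, target = seg$q[nrow(seg$q), ])
    if (!m$flagged) {
      expect_gt(m$speed_shape, 0)
      expect_lte(m$speed_shape, 1)
      expect_gte(m$peak_speed, m$mean_speed)
    }
  }
})

test_that("dimensionless discrete jerk is invariant to amplitude and duration scaling", {
  base <- minjerk_segment(n = 1500, L = 0.14, T = 1)
  j0 <- reach_macro_metrics(list(t = base$t, q = base$q),
                            target = base$target, smooth_window = 1)$jerk_discrete
  for (sc in list(c(A = 3, T = 1), c(A = 1, T = 2.5), c(A = 0.2, T = 0.4))) {
    seg <- minjerk_segment(n = 1500, L = 0.14 * sc["A"], T = sc["T"])
    j <- reach_macro_metrics(list(t = seg$t, q = seg$q),
                             target = seg$target, smooth_window = 1)$jerk_discrete
    expect_equal(j, j0, tolerance = 1e-6 * j0)
  }
})

test_that("zero-displacement segments are flagged and excluded", {
  tt <- seq(0, 1, by = 0.01)
  m <- reach_macro_metrics(list(t = tt, q = cbind(rep(0, length(tt)), 0)),
                           target = c(0.1, 0))
  expect_true(m$flagged)
})

test_that("resistance metrics: displacement and circular mean of aims", {
  targets <- matrix(c(0.1, 0), 1)
  mk <- function(frac, perp = 0) {
    seg <- minjerk_segment(n = 400, L = 0.1 * frac)
    q <- seg$q; q[, 2] <- q[, 2] + perp * sin(pi * seq(0, 1, length.out = 400))
    list(t = seg$t, q = q, f = cbind(10 * seg$t, 0), target_id = 1)
  }
  # reaching exactly the target then held: max displacement = full distance
  rm_ <- resistance_metrics(list(mk(1)), targets)
  expect_equal(rm_$max_displacement, 0.1, tolerance = 1e-9)
  expect_equal(rm_$overall_aim, 0, tolerance = 1e-6)
  # aims +a and -a average to 0 circularly
  s_up <- mk(1, perp = 0.02); s_dn <- mk(1, perp = -0.02)
  rm2 <- resistance_metrics(list(s_up, s_dn), targets)
  expect_equal(rm2$overall_aim, 0, tolerance = 1e-9)
  # missing force channel warns but still computes
  s_nf <- mk(0.6); s_nf$f <- NULL
  expect_warning(rm3 <- resistance_metrics(list(s_nf), targets), "force")
  expect_equal(rm3$max_displacement, 0.06, tolerance = 1e-9)
})

test_that("stabilization metrics: offset and scatter definitions", {
  n <- 200
  hold <- c(0.02, -0.01)
  q0 <- matrix(hold, n, 2, byrow = TRUE)
  sm <- stabilization_metrics(q0, hold)
  expect_equal(sm$offset, 0, tolerance = 1e-12)
  expect_equal(sm$scatter, 0, tolerance = 1e-12)
  d <- c(0.01, 0.02)
  sm <- stabilization_metrics(sweep(q0, 2, d, "+"), hold)
  expect_equal(sm$offset, sqrt(sum(d^2)), tolerance = 1e-12)
  expect_equal(sm$scatter, 0, tolerance = 1e-12)
  expect_error(stabilization_metrics(q0[1:5, ], hold), "10 samples")
})

test_that("scatter of isotropic 2D wander matches the closed form sigma*sqrt(2)", {
  set.seed(31)
  sigma <- 0.013
  q <- matrix(rnorm(2e5, 0, sigma), ncol = 2)
  sm <- stabilization_metrics(q, c(0, 0))
  expect_equal(sm$scatter, sigma * sqrt(2), tolerance = 0.02)
})

test_that("shoulder strength aggregates per-direction trial peaks", {
  trials <- data.frame(direction = rep(c("F", "E", "AB", "AD"), each = 5),
                       peak_force = rep(10, 20))
  ss <- shoulder_strength(trials)
  expect_equal(unname(ss$per_direction), rep(10, 4))
  expect_equal(ss$deltaz, 10)
  trials2 <- data.frame(direction = c("F", "E", "AB", "AD"),
                        peak_force = c(8, 10, 12, 14))
  expect_equal(shoulder_strength(trials2)$deltaz, 11)
  # direction with no trials: warning, deltaz over the rest
  trials3 <- trials2[1:3, ]
  expect_warning(ss3 <- shoulder_strength(trials3), "without trials")
  expect_equal(ss3$deltaz, 10)
})

test_that("strength aggregation agrees with a brute-force group-mean oracle", {
  set.seed(12)
  trials <- data.frame(direction = sample(c("F", "E", "AB", "AD"), 18,
                                          replace = TRUE),
                       peak_force = runif(18, 5, 60))
  ss <- suppressWarnings(shoulder_strength(trials))
  oracle <- tapply(trials$peak_force, trials$direction, mean)
  for (d in names(oracle))
    expect_equal(ss$per_direction[[d]], unname(oracle[d]), tolerance = 1e-12)
  expect_equal(ss$deltaz, mean(ss$per_direction, na.rm = TRUE),
               tolerance = 1e-12)
})

test_that("session values are the arithmetic mean of non-flagged segment values", {
  ch <- small_cohort()
  reach <- Filter(function(r) r$task == "reach8", ch$recordings)[[1]]
  tab <- suppressWarnings(
    session_feature_table(list(reach), ch$scores, micrometrics = FALSE))
  geom <- task_geometry()
  vals <- sapply(seq_len(nrow(reach$segments)), function(i) {
    seg <- recording_segment(reach, i)
    tgt <- geom$reach_targets[seg$target_id, ]
    endq <- seg$q[nrow(seg$q), ]
    if (sqrt(sum((endq - tgt)^2)) > sqrt(sum(endq^2)) + 1e-9) tgt <- c(0, 0)
    m <- reach_macro_metrics(seg, target = tgt,
                             target_radius = geom$target_radius)
    if (m$flagged) NA_real_ else m$speed_shape
  })
  expect_equal(tab$speed_shape[1], mean(vals, na.rm = TRUE),
               tolerance = 1e-12)
})
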