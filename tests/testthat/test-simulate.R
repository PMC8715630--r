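test_that("cohort generation is bit-identical under a fixed seed", {
  cfg <- sim_config(n_patients = 8, sessions_per_patient = 1, seed = 7,
                    n_reaches = 2, circle_reps = 1)
  c1 <- suppressWarnings(simulate_cohort(cfg))
  c2 <- suppressWarnings(simulate_cohort(cfg))
  expect_identical(c1, c2)
  c3 <- suppressWarnings(simulate_cohort(sim_config(
    n_patients = 8, sessions_per_patient = 1, seed = 8, n_reaches = 2,
    circle_reps = 1)))
  expect_false(identical(c1$scores, c3$scores))
})

test_that("unimpaired patients produce single-submovement reaches", {
  cfg <- sim_config(n_patients = 8, sessions_per_patient = 1, seed = 3,
                    latent_mean = 0, latent_sd = 1e-12, z_session_sd = 0,
                    n_reaches = 4, circle_reps = 1)
  ch <- suppressWarnings(simulate_cohort(cfg))
  expect_true(all(abs(ch$truth$latent$z) < 1e-9))
  counts <- unlist(lapply(ch$truth$segments, function(segs)
    vapply(segs, length, integer(1))))
  expect_true(all(counts == 1))
})

test_that("generated submovement load is monotone in impairment", {
  mean_count <- sapply(c(0, 0.45, 0.9), function(zv) {
    cfg <- sim_config(n_patients = 8, sessions_per_patient = 1,
                      seed = 13, latent_mean = zv, latent_sd = 1e-12,
                      z_session_sd = 0, n_reaches = 8, circle_reps = 1)
    ch <- suppressWarnings(simulate_cohort(cfg))
    mean(unlist(lapply(ch$truth$segments, function(segs)
      vapply(segs, length, integer(1)))))
  })
  expect_true(all(diff(mean_count) > 0))
})

test_that("noise-free linear links make scores exact affine images of z", {
  links <- default_scale_links(noise_sd = 0)
  cfg <- sim_config(n_patients = 8, sessions_per_patient = 1, seed = 5,
                    scale_links = links, round_scores = FALSE,
                    n_reaches = 2, circle_reps = 1)
  ch <- suppressWarnings(simulate_cohort(cfg))
  z <- ch$truth$latent$z
  expect_equal(ch$scores$fma_ue, 66 * (1 - z), tolerance = 1e-9)
  expect_equal(ch$scores$bi, 100 * (1 - z), tolerance = 1e-9)
  expect_equal(ch$scores$fma_ue, ch$truth$latent$fma_ue_clean,
               tolerance = 1e-9)
  # correlation with the latent is exactly -1
  expect_equal(pearson_r(z, ch$scores$fma_ue), -1, tolerance = 1e-12)
})

test_that("latent-to-clinical links respect bounds, symmetry and monotonicity", {
  links <- default_scale_links()
  expect_equal(latent_to_clinical(0, links$fma_ue), 66)
  expect_equal(latent_to_clinical(1, links$fma_ue), 0)
  sig <- default_scale_links(link = "sigmoid")$bi
  expect_equal(latent_to_clinical(0.5, sig), 50, tolerance = sig$step)
  zg <- seq(0, 1, by = 0.01)
  for (cfg in list(links$fma_ue, links$bi, sig)) {
    sc <- latent_to_clinical(zg, cfg, round = FALSE)
    expect_true(all(diff(sc) <= 1e-12))
    expect_true(all(sc >= cfg$min & sc <= cfg$max))
  }
  expect_error(latent_to_clinical(1.5, links$fma_ue))
})

test_that("strength trials follow the protocol count and weaken with impairment", {
  ch <- small_cohort()
  ks <- Filter(function(r) r$task == "kinetic_strength", ch$recordings)
  expect_equal(nrow(ks[[1]]$segments), 20)
  expect_equal(table(ks[[1]]$directions),
               table(rep(c("F", "E", "AB", "AD"), each = 5)))
  # per-patient deltaz anti-correlates with z
  tab <- small_feature_table()
  z <- ch$truth$latent$z[match(paste(tab$patient_id, tab$session_label),
                               paste(ch$truth$latent$patient_id,
                                     ch$truth$latent$session_label))]
  expect_lt(pearson_r(z, tab$deltaz), -0.8)
})

test_that("generated recordings satisfy task_recording invariants", {
  ch <- small_cohort()
  for (rec in ch$recordings) {
    expect_s3_class(rec, "task_recording")
    expect_true(all(diff(rec$t) > 0))
    expect_true(nrow(rec$segments) >= 1)
  }
  # all seven task types appear across the two devices
  expect_setequal(unique(vapply(ch$recordings, `[[`, character(1), "task")),
                  c("reach8", "circle_draw", "resistance", "isometric_hold",
                    "kinetic_strength", "wrist_point8", "forearm_ps"))
})

test_that("micrometric aggregation integrates decomposition into the feature table", {
  ch <- small_cohort()
  reach <- Filter(function(r) r$task == "reach8", ch$recordings)[[1]]
  tab <- suppressWarnings(
    session_feature_table(list(reach), ch$scores, micrometrics = TRUE,
                          decompose_opts = list(max_n = 4, restarts = 1)))
  expect_true(all(c("submovement_number", "submovement_duration",
                    "submovement_peak") %in% names(tab)))
  expect_gte(tab$submovement_number[1], 1)
  expect_gt(tab$submovement_duration[1], 0)
})

test_that("the score-level cohort generator hits its population correlation", {
  tab <- simulate_score_cohort(n_patients = 400, sessions = 3, rho = 0.7,
                               seed = 12)
  r <- abs(pearson_r(tab$metric_1, tab$fma_ue))
  se3 <- 3 * (1 - 0.7^2) / sqrt(nrow(tab))   # three sampling standard errors
  expect_lt(abs(r - 0.7), se3)
})

test_that("a written cohort can be re-read and re-analysed", {
  ch <- small_cohort()
  dir <- withr::local_tempdir()
  sub <- list(recordings = ch$recordings[1:9], scores = ch$scores,
              truth = ch$truth)
  write_cohort(sub, dir)
  files <- list.files(dir, pattern = "\\.csv$")
  expect_gte(length(files), 10)   # 9 recordings + scores.csv
  expect_true(file.exists(file.path(dir, "truth.json")))
  rec <- read_recording(list.files(dir, pattern = "reach8",
                                   full.names = TRUE)[1])
  expect_s3_class(rec, "task_recording")
})
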