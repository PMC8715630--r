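# Shared fixtures, all generated in code.

# Dense minimum-jerk straight reach of amplitude L over duration T.
minjerk_segment <- function(n = 2000, L = 0.14, T = 1, dir = c(1, 0)) {
  tau <- seq(0, 1, length.out = n)
  s <- L * (10 * tau^3 - 15 * tau^4 + 6 * tau^5)
  list(t = tau * T, q = cbind(s * dir[1], s * dir[2]), target = L * dir)
}

# Points on an ellipse with semi-axes a, b, rotated by theta, centred at c0.
ellipse_points <- function(a, b, theta = 0, c0 = c(0, 0), n = 100) {
  ph <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  P <- cbind(a * cos(ph), b * sin(ph))
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  sweep(P %*% t(R), 2, c0, "+")
}

# A random in-gauge submovement and its sampled profile.
random_pulse_profile <- function(seed, rate = 200) {
  set.seed(seed)
  true <- list(t0 = runif(1, 0.05, 0.2), D = runif(1, 0.4, 0.8),
               A = runif(1, 0.05, 0.2), sigma = runif(1, 0.25, 0.4))
  sm <- submovement(true$t0, true$D, true$A, sigma = true$sigma)
  tg <- seq(0, true$t0 + true$D + 0.1, by = 1 / rate)
  list(true = true, sm = sm, t = tg,
       speed = synth_speed_profile(list(sm), tg))
}

# Small simulated cohort, cached per session so several tests can share it.
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_patients = 8, sessions_per_patient = 2, seed = 11,
                        n_reaches = 6, circle_reps = 1)
      cache <<- suppressWarnings(simulate_cohort(cfg))
    }
    cache
  }
})

small_feature_table <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ch <- small_cohort()
      cache <<- suppressWarnings(
        session_feature_table(ch$recordings, ch$scores,
                              micrometrics = FALSE))
    }
    cache
  }
})

# Random feature table with iid Gaussian columns.
random_table <- function(seed, n = 60, p = 4) {
  set.seed(seed)
  tab <- data.frame(patient_id = sprintf("P%02d", rep(1:(n / 2), each = 2)),
                    session_label = rep(c("baseline1", "discharge"), n / 2),
                    stringsAsFactors = FALSE)
  for (j in seq_len(p)) tab[[paste0("m", j)]] <- rnorm(n)
  tab$fma_ue <- pmin(pmax(round(33 + 10 * tab$m1 + 5 * rnorm(n)), 0), 66)
  tab$wmft <- NA_real_; tab$bi <- NA_real_; tab$mrc <- NA_real_
  tab
}
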