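test_that("lognormal pulses are support-bounded and integrate to their amplitude", {
  sm <- submovement(t0 = 0.1, D = 0.6, A = 0.1, sigma = 0.3)
  expect_equal(lognormal_pulse(c(0.05, 0.1, 0.7, 1), sm), rep(0, 4))
  q <- integrate(function(t) lognormal_pulse(t, sm), 0.1, 0.7,
                 rel.tol = 1e-10, subdivisions = 500)
  expect_equal(q$value, 0.1, tolerance = 0.005 * 0.1)
  # unimodal on the support
  tt <- seq(0.101, 0.699, length.out = 500)
  v <- lognormal_pulse(tt, sm)
  ip <- which.max(v)
  expect_true(all(diff(v[1:ip]) >= -1e-12))
  expect_true(all(diff(v[ip:length(v)]) <= 1e-12))
})

test_that("pulse peak time shifts earlier as mu decreases", {
  tt <- seq(0, 1, by = 1e-4)
  peaks <- sapply(seq(-1.2, -0.3, by = 0.15), function(mu) {
    sm <- submovement(0, 1, 1, mu = mu, sigma = 0.3)
    tt[which.max(lognormal_pulse(tt, sm))]
  })
  expect_true(all(diff(peaks) > 0))
})

test_that("speed profile synthesis sums pulses and rejects empty grids", {
  tg <- seq(0, 2, by = 0.005)
  expect_equal(synth_speed_profile(list(), tg), numeric(length(tg)))
  expect_error(synth_speed_profile(list(), numeric(0)), "empty")
  s1 <- submovement(0.0, 0.5, 0.1, sigma = 0.3)
  s2 <- submovement(1.2, 0.5, 0.05, sigma = 0.3)   # disjoint supports
  prof <- synth_speed_profile(list(s1, s2), tg)
  expect_true(all(prof >= 0))
  p1 <- max(synth_speed_profile(list(s1), tg))
  p2 <- max(synth_speed_profile(list(s2), tg))
  expect_equal(max(prof), max(p1, p2), tolerance = 1e-12)
})

test_that("a noise-free single pulse is recovered essentially exactly", {
  fx <- random_pulse_profile(101)
  dec <- decompose_speed(fx$speed, fx$t, seed = 101)
  expect_equal(length(dec$submovements), 1)
  s <- dec$submovements[[1]]
  tr <- fx$true
  rel <- abs(c(s$t0 - tr$t0, s$D - tr$D, s$A - tr$A,
               s$sigma - tr$sigma) / c(tr$t0, tr$D, tr$A, tr$sigma))
  expect_lt(max(rel), 0.01)
  expect_lt(dec$residual_rmse, 1e-8 * max(fx$speed))
})

test_that("an all-zero profile decomposes into zero submovements", {
  tg <- seq(0, 1, by = 0.01)
  dec <- decompose_speed(numeric(length(tg)), tg)
  expect_equal(length(dec$submovements), 0)
  expect_equal(micrometrics(dec)$number, 0L)
})

test_that("the greedy residual path is monotone non-increasing", {
  set.seed(55)
  sms <- list(submovement(0.05, 0.5, 0.1, sigma = 0.3),
              submovement(0.45, 0.4, 0.05, sigma = 0.33),
              submovement(0.8, 0.35, 0.03, sigma = 0.28))
  tg <- seq(0, 1.4, by = 1 / 200)
  sp <- pmax(synth_speed_profile(sms, tg) +
               rnorm(length(tg), 0, 0.015 * 0.5), 0)
  dec <- decompose_speed(sp, tg, seed = 9)
  expect_true(all(diff(dec$rmse_path) <= 1e-12))
})

test_that("decomposition is scale-equivariant in the speed axis", {
  fx <- random_pulse_profile(77)
  dec1 <- decompose_speed(fx$speed, fx$t, seed = 3)
  dec2 <- decompose_speed(5 * fx$speed, fx$t, seed = 3)
  s1 <- dec1$submovements[[1]]; s2 <- dec2$submovements[[1]]
  expect_equal(s2$A / s1$A, 5, tolerance = 0.01)
  expect_equal(s2$t0, s1$t0, tolerance = 0.01 * max(fx$t))
  expect_equal(s2$D, s1$D, tolerance = 0.01 * s1$D)
})

test_that("noise-free K-pulse profiles with moderate overlap recover K (K <= 3)", {
  hits <- 0; cases <- 0
  for (seed in 1:50) {
    set.seed(seed)
    K <- sample(1:3, 1)
    t0 <- 0.05; sms <- list()
    for (k in seq_len(K)) {
      D <- runif(1, 0.35, 0.55)
      sms[[k]] <- submovement(t0, D, runif(1, 0.05, 0.12),
                              sigma = runif(1, 0.27, 0.38))
      t0 <- t0 + D * (1 - runif(1, 0.2, 0.45))  # pairwise overlap < 50%
    }
    tg <- seq(0, t0 + 0.6, by = 1 / 200)
    sp <- synth_speed_profile(sms, tg)
    dec <- decompose_speed(sp, tg, seed = seed)
    cases <- cases + 1
    if (length(dec$submovements) == K) hits <- hits + 1
  }
  expect_equal(hits, cases)
})

test_that("micrometric summaries follow their definitions", {
  # first pulse ends exactly when the second starts: overlap 0
  s1 <- submovement(0.0, 0.5, 0.1, sigma = 0.3)
  s2 <- submovement(0.5, 0.4, 0.05, sigma = 0.3)
  dec <- structure(list(submovements = list(s1, s2), residual_rmse = 0,
                        reconstruction = NULL, rmse_path = numeric(0)),
                   class = "decomposition")
  mm <- micrometrics(dec)
  expect_equal(mm$number, 2)
  expect_equal(mm$overlap, 0, tolerance = 1e-12)
  expect_equal(mm$duration, 0.45, tolerance = 1e-12)
  # single pulse: overlap and interpeak missing
  mm1 <- micrometrics(structure(list(submovements = list(s1)),
                                class = "decomposition"))
  expect_equal(mm1$number, 1)
  expect_true(is.na(mm1$overlap) && is.na(mm1$interpeak_interval))
})

test_that("interpeak interval is the mean gap between consecutive peaks", {
  # construct three pulses whose peaks land at 0.2, 0.5, 0.9 s
  mk_at <- function(tp, D = 0.3, sigma = 0.3) {
    tau_star <- exp(gauge_mu(sigma) - sigma^2)
    submovement(tp - tau_star * D, D, 0.05, sigma = sigma)
  }
  dec <- structure(list(submovements = lapply(c(0.2, 0.5, 0.9), mk_at)),
                   class = "decomposition")
  expect_equal(micrometrics(dec)$interpeak_interval, 0.35, tolerance = 1e-9)
})
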