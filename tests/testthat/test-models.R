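test_that("the linear model interpolates exact affine data", {
  set.seed(3)
  X <- matrix(runif(60), 30, 2, dimnames = list(NULL, c("a", "b")))
  y <- 1.5 + 2 * X[, 1] - 3 * X[, 2]
  fit <- fit_linear(X, y)
  expect_equal(unname(predict(fit, as.data.frame(X))), y, tolerance = 1e-9)
  # single feature: coefficient and intercept recovered
  x <- runif(20)
  f1 <- fit_linear(matrix(x, dimnames = list(NULL, "x")), 2 * x + 1)
  expect_equal(unname(f1$coefficients), 2, tolerance = 1e-9)
  expect_equal(unname(f1$intercept), 1, tolerance = 1e-9)
})

test_that("rank-deficient designs are rejected with the dependent column named", {
  X <- cbind(a = runif(20), b = runif(20))
  X <- cbind(X, c = X[, "a"] + X[, "b"])
  expect_error(fit_linear(X, rnorm(20)), "dependent column.*c")
})

test_that("pure-noise features get near-zero linear coefficients", {
  set.seed(17)
  n <- 500
  X <- matrix(rnorm(2 * n), n, 2, dimnames = list(NULL, c("a", "b")))
  y <- rnorm(n)
  fit <- fit_linear(X, y)
  # analytic standard error of a coefficient under independence ~ sd(y)/ (sd(x) sqrt(n))
  se <- sd(y) / sqrt(n)
  expect_true(all(abs(fit$coefficients) < 3 * se))
})

test_that("the 2-sigmoid-unit network realizes its own function class", {
  set.seed(9)
  n <- 500
  X <- matrix(runif(n * 2), n, 2, dimnames = list(NULL, c("f1", "f2")))
  sig <- function(u) 1 / (1 + exp(-u))
  y <- 0.3 + 0.8 * sig(3 * X[, 1] - 2 * X[, 2] + 0.5) -
    0.6 * sig(-2 * X[, 1] + 4 * X[, 2] - 1)
  fit <- fit_mlp(X, y, seed = 5)
  expect_gte(cor(predict(fit, as.data.frame(X)), y), 0.999)
})

test_that("the network matches linear training fit on linear data", {
  set.seed(11)
  x <- runif(200)
  y <- 2 * x + 0.1
  X <- matrix(x, dimnames = list(NULL, "x"))
  rl <- cor(predict(fit_linear(X, y), data.frame(x = x)), y)
  rm_ <- cor(predict(fit_mlp(X, y, seed = 2), data.frame(x = x)), y)
  expect_gte(rm_, rl - 0.01)
})

test_that("MLP training is deterministic under seed", {
  set.seed(4)
  X <- matrix(runif(80), 40, 2, dimnames = list(NULL, c("a", "b")))
  y <- runif(40)
  f1 <- fit_mlp(X, y, seed = 42, restarts = 3)
  f2 <- fit_mlp(X, y, seed = 42, restarts = 3)
  expect_identical(f1$net$wts, f2$net$wts)
})

test_that("patient-wise folds partition patients with no leakage", {
  tab <- random_table(1, n = 52, p = 1)   # 26 patients, 2 sessions
  for (seed in c(1, 7, 23)) {
    cv <- suppressWarnings(
      patientwise_cv(tab, "m1", "fma_ue", "linear", seed = seed))
    fa <- cv$fold_assignments
    expect_setequal(names(fa), unique(tab$patient_id))
    expect_true(all(fa %in% 1:4))
    # a patient's rows never straddle folds by construction of fa; check
    # every row is tested exactly once
    expect_equal(cv$n_rows, nrow(tab))
    expect_equal(cv$mean_R, mean(cv$per_fold_R))
  }
})

test_that("a noise-free affine target gives mean CV correlation 1", {
  tab <- random_table(2, n = 60, p = 1)
  tab$fma_ue <- 3 * tab$m1 + 5
  cv <- suppressWarnings(patientwise_cv(tab, "m1", "fma_ue", "linear",
                                        seed = 1))
  expect_equal(cv$mean_R, 1, tolerance = 1e-9)
})

test_that("stratified evaluation restricts rows and degenerates sanely", {
  tab <- random_table(3, n = 80, p = 1)
  cv_all <- suppressWarnings(patientwise_cv(tab, "m1", "fma_ue", "linear",
                                            seed = 5))
  cv_range <- suppressWarnings(
    stratified_evaluation(tab, "m1", "fma_ue", range = c(0, 66),
                          kind = "linear", seed = 5))
  expect_equal(cv_range$mean_R, cv_all$mean_R, tolerance = 1e-12)
  expect_error(
    stratified_evaluation(tab, "m1", "fma_ue", range = c(1000, 2000),
                          kind = "linear"),
    "empty stratum")
})

test_that("the balance check flags separated samples and tolerates ties", {
  expect_lt(partition_balance_test(1:20, 100:120), 0.001)
  expect_warning(p <- partition_balance_test(rep(5, 10), rep(5, 8)), "tied")
  expect_equal(p, 1)
  expect_error(partition_balance_test(1:2, 1:10), "at least 3")
})

test_that("VIF follows 1/(1 - R_j^2) with exact collinearity flagged", {
  set.seed(19)
  n <- 100
  tab <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  # near-orthogonal columns: VIF ~ 1 (exactly 1 after orthogonalization)
  Q <- qr.Q(qr(cbind(1, tab$a, tab$b, tab$c)))
  tab_o <- data.frame(a = Q[, 2], b = Q[, 3], c = Q[, 4])
  v <- vif(tab_o, c("a", "b", "c"))
  expect_equal(v$vif, rep(1, 3), tolerance = 1e-9)
  expect_false(any(v$flag_high))
  # duplicated feature pair: both effectively infinite
  tab$d <- tab$a
  v2 <- vif(tab, c("a", "b", "d"))
  expect_true(all(v2$infinite[v2$feature %in% c("a", "d")]))
  expect_true(all(v2$flag_high[v2$feature %in% c("a", "d")]))
  expect_error(vif(tab[1:3, ], c("a", "b", "c", "d")), "more complete rows")
})

test_that("VIF agrees with explicit normal-equations regression", {
  set.seed(23)
  n <- 150
  tab <- data.frame(x1 = rnorm(n))
  tab$x2 <- 0.6 * tab$x1 + rnorm(n)
  tab$x3 <- -0.3 * tab$x1 + 0.5 * tab$x2 + rnorm(n)
  v <- vif(tab, c("x1", "x2", "x3"))
  for (j in 1:3) {
    y <- tab[[j]]
    X <- cbind(1, as.matrix(tab[-j]))
    beta <- solve(t(X) %*% X, t(X) %*% y)
    res <- y - X %*% beta
    r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
    expect_equal(v$r_squared[j], r2, tolerance = 1e-8)
    expect_equal(v$vif[j], 1 / (1 - r2), tolerance = 1e-8)
  }
})

test_that("both models approach perfect CV correlation as generator noise vanishes", {
  rs <- c(0.85, 0.95, 0.999)
  lin <- mlp <- numeric(length(rs))
  for (i in seq_along(rs)) {
    tab <- simulate_score_cohort(n_patients = 40, sessions = 2, rho = rs[i],
                                 seed = 70 + i)
    lin[i] <- suppressWarnings(
      patientwise_cv(tab, "metric_1", "fma_ue", "linear",
                     seed = 80 + i))$mean_R
    mlp[i] <- suppressWarnings(
      patientwise_cv(tab, "metric_1", "fma_ue", "mlp", seed = 80 + i,
                     mlp_restarts = 3))$mean_R
  }
  expect_true(all(diff(lin) > 0))
  expect_gt(lin[3], 0.99)
  expect_gt(mlp[3], 0.99)
})
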