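test_that("pearson_r follows the product-moment definition", {
  x <- c(1, 2, 3); y <- c(1, 2, 4)
  # direct evaluation of the definition as oracle
  oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_r(x, y), oracle, tolerance = 1e-12)
  expect_equal(pearson_r(x, y), 0.9820, tolerance = 1e-4)
  expect_equal(pearson_r(x, x), 1)
  expect_equal(pearson_r(x, -x), -1)
  expect_error(pearson_r(x, c(1, 1, 1)), "zero variance")
  expect_error(pearson_r(c(1, NA, 3), c(1, 2, NA)), "3 complete pairs")
})

test_that("feature selection thresholds |R| and keeps all candidate correlations", {
  set.seed(21)
  n <- 400
  y <- rnorm(n)
  tab <- data.frame(patient_id = as.character(1:n),
                    session_label = "baseline1",
                    f1 = 0.6 * y + sqrt(1 - 0.36) * rnorm(n),
                    f2 = 0.4 * y + sqrt(1 - 0.16) * rnorm(n),
                    fma_ue = y, wmft = NA_real_, bi = NA_real_,
                    mrc = NA_real_)
  sel <- select_features(tab, "fma_ue")
  expect_true("f1" %in% sel$selected)
  expect_false("f2" %in% sel$selected)
  expect_named(sel$candidate_correlations, c("f1", "f2"))
  # a duplicated target is selected with R = 1
  tab$copy <- tab$fma_ue
  sel2 <- select_features(tab, "fma_ue")
  expect_equal(sel2$candidate_correlations[["copy"]], 1)
  expect_equal(sel2$selected[1], "copy")
  # negatively coded metrics pass through |R|
  tab$neg <- -tab$fma_ue
  sel3 <- select_features(tab, "fma_ue")
  expect_true("neg" %in% sel3$selected)
  expect_false("neg" %in% select_features(tab, "fma_ue",
                                          signed = TRUE)$selected)
})

test_that("when nothing passes, the strongest top_k are returned flagged", {
  set.seed(22)
  n <- 300
  tab <- data.frame(patient_id = as.character(1:n),
                    session_label = "baseline1")
  y <- rnorm(n)
  for (j in 1:6) tab[[paste0("w", j)]] <- 0.2 * y + rnorm(n)
  tab$bi <- y; tab$fma_ue <- NA_real_; tab$wmft <- NA_real_
  tab$mrc <- NA_real_
  expect_warning(sel <- select_features(tab, "bi", top_k = 4), "falling back")
  expect_length(sel$selected, 4)
  expect_true(sel$sub_threshold)
})

test_that("selection is invariant to positive affine rescaling of features", {
  tab <- random_table(33, n = 200, p = 3)
  s0 <- suppressWarnings(select_features(tab, "fma_ue", r_threshold = 0.3))
  tab2 <- tab
  tab2$m1 <- 100 * tab2$m1 + 7
  tab2$m2 <- 0.001 * tab2$m2 - 2
  s1 <- suppressWarnings(select_features(tab2, "fma_ue", r_threshold = 0.3))
  expect_identical(s0$selected, s1$selected)
  expect_equal(s0$candidate_correlations, s1$candidate_correlations,
               tolerance = 1e-12)
})

test_that("empirical selection matches population-threshold selection at n = 1e4", {
  set.seed(44)
  n <- 1e4
  y <- rnorm(n)
  rho <- c(a = 0.8, b = 0.6, c = 0.4, d = 0.2)
  tab <- data.frame(patient_id = as.character(1:n),
                    session_label = "baseline1")
  for (f in names(rho))
    tab[[f]] <- rho[[f]] * y + sqrt(1 - rho[[f]]^2) * rnorm(n)
  tab$fma_ue <- y; tab$wmft <- NA_real_; tab$bi <- NA_real_
  tab$mrc <- NA_real_
  sel <- select_features(tab, "fma_ue", r_threshold = 0.5)
  expect_setequal(sel$selected, c("a", "b"))
})

test_that("collinearity pruning keeps one representative per dependent group", {
  set.seed(9)
  n <- 300
  y <- rnorm(n)
  base <- 0.7 * y + 0.7 * rnorm(n)
  tab <- data.frame(patient_id = as.character(1:n),
                    session_label = "baseline1",
                    f1 = base, f2 = base + 1e-8 * rnorm(n),
                    f3 = 0.6 * y + 0.8 * rnorm(n),
                    fma_ue = y, wmft = NA_real_, bi = NA_real_,
                    mrc = NA_real_)
  sel <- select_features(tab, "fma_ue")
  pr <- prune_collinear(tab, sel)
  expect_equal(sum(c("f1", "f2") %in% pr$selected), 1)   # identical pair
  expect_true("f3" %in% pr$selected)                     # independent kept
  # keep-list precedence over higher |R|
  pr2 <- prune_collinear(tab, sel, keep_list = "f2")
  expect_true("f2" %in% pr2$selected)
  expect_false("f1" %in% pr2$selected)
  expect_equal(pr2$pruned$f1$kept, "f2")
})

test_that("mutually independent features are never pruned", {
  tab <- random_table(55, n = 500, p = 3)
  sel <- suppressWarnings(select_features(tab, "fma_ue", r_threshold = 0))
  pr <- prune_collinear(tab, sel)
  expect_setequal(pr$selected, sel$selected)
  expect_length(pr$pruned, 0)
})

test_that("max-rescaling is learned on training rows and exactly invertible", {
  tab <- random_table(66, n = 80, p = 2)
  tab$m1 <- abs(tab$m1) * 5
  spec <- fit_scaling(tab, c("m1", "m2"), "fma_ue", mode = "linear")
  scaled <- apply_scaling(tab, spec)
  expect_equal(max(abs(scaled$m1)), 1, tolerance = 1e-12)
  expect_equal(scaled$fma_ue, tab$fma_ue)     # linear mode: target untouched
  spec_nl <- fit_scaling(tab, c("m1", "m2"), "fma_ue", mode = "nonlinear")
  scaled_nl <- apply_scaling(tab, spec_nl)
  expect_equal(max(abs(scaled_nl$fma_ue)), 1, tolerance = 1e-12)
  back <- apply_scaling(scaled_nl, spec_nl, invert = TRUE)
  expect_equal(back$m1, tab$m1, tolerance = 1e-12)
  expect_equal(back$fma_ue, tab$fma_ue, tolerance = 1e-12)
  # a value of 5 under max 10 maps to 0.5
  toy <- data.frame(patient_id = "P", session_label = "baseline1",
                    m = c(5, 10), fma_ue = c(1, 2))
  sp <- fit_scaling(toy, "m", "fma_ue", mode = "linear")
  expect_equal(apply_scaling(toy, sp)$m, c(0.5, 1))
  toy$zero <- 0
  expect_error(fit_scaling(toy, "zero", "fma_ue"), "zero")
})
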