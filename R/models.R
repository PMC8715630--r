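## Linear and shallow-MLP predictors, patient-wise CV, VIF -------------------

# Evaluate an expression with a temporary RNG seed, restoring the caller's
# RNG state afterwards so seeded pipeline stages do not interfere.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Fit the linear (ordinary least squares) predictor
#'
#' @param X data.frame or matrix of feature rows (already max-rescaled when
#'   used inside the pipeline).
#' @param y Numeric response.
#' @param scaling Optional \code{\link{fit_scaling}} spec stored with the
#'   model and applied by \code{predict}.
#' @return Object of class \code{robokin_model} with \code{kind = "linear"},
#'   \code{intercept}, \code{coefficients}, \code{training_rmse}.
#' @export
fit_linear <- function(X, y, scaling = NULL) {
  X <- as.matrix(as.data.frame(X))
  stopifnot(nrow(X) == length(y))
  if (nrow(X) < ncol(X) + 2)
    stop("need at least features + 2 rows to fit the linear model")
  Xd <- cbind(`(Intercept)` = 1, X)
  qrX <- qr(Xd)
  if (qrX$rank < ncol(Xd)) {
    dep <- colnames(Xd)[qrX$pivot[(qrX$rank + 1):ncol(Xd)]]
    stop("rank-deficient design; dependent column(s): ",
         paste(dep, collapse = ", "))
  }
  beta <- qr.coef(qrX, y)
  fitted <- drop(Xd %*% beta)
  structure(list(kind = "linear", intercept = beta[1],
                 coefficients = beta[-1], features = colnames(X),
                 scaling = scaling,
                 training_rmse = sqrt(mean((y - fitted)^2))),
            class = "robokin_model")
}

#' Fit the shallow neural-network predictor
#'
#' A multilayer perceptron with exactly one hidden layer of 2 logistic
#' (sigmoid) units and a single linear output unit, trained by full-batch
#' quasi-Newton least squares. Training is restarted from \code{restarts}
#' seeded random initializations and the fit with the lowest training RMSE
#' is kept; results are deterministic under \code{seed}.
#'
#' @param X Feature rows, expected max-rescaled to about [0, 1].
#' @param y Response, expected rescaled by its maximum (the nonlinear-model
#'   convention).
#' @param seed Integer seed.
#' @param restarts Number of random initializations (default 10).
#' @param max_iter Optimizer iteration cap (default 2000).
#' @param tol Convergence tolerance on the fit criterion (default 1e-8).
#' @param scaling Optional scaling spec stored with the model.
#' @return Object of class \code{robokin_model} with \code{kind = "mlp"},
#'   the fitted \code{nnet} weights, and \code{training_rmse}.
#' @export
fit_mlp <- function(X, y, seed = 1, restarts = 10, max_iter = 2000,
                    tol = 1e-8, scaling = NULL) {
  X <- as.matrix(as.data.frame(X))
  stopifnot(nrow(X) == length(y))
  best <- NULL
  nw <- (ncol(X) + 1) * 2 + (2 + 1)   # input->hidden + hidden->output weights
  for (r in seq_len(restarts)) {
    w0 <- with_seed(seed + r - 1, stats::runif(nw, -0.7, 0.7))
    net <- tryCatch(
      nnet::nnet(x = X, y = y, size = 2, linout = TRUE, decay = 0,
                 maxit = max_iter, abstol = tol, reltol = tol, Wts = w0,
                 trace = FALSE),
      error = function(e) NULL)
    if (is.null(net)) next
    rmse <- sqrt(mean((y - drop(net$fitted.values))^2))
    if (is.null(best) || rmse < best$rmse)
      best <- list(net = net, rmse = rmse, restart = r)
  }
  if (is.null(best))
    stop("MLP training failed to converge in all restarts")
  structure(list(kind = "mlp", net = best$net, features = colnames(X),
                 seed = seed, scaling = scaling,
                 training_rmse = best$rmse),
            class = "robokin_model")
}

#' @export
predict.robokin_model <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  if (!is.null(object$scaling))
    newdata <- apply_scaling(newdata, object$scaling)
  X <- as.matrix(newdata[object$features])
  pred <- if (object$kind == "linear") {
    drop(X %*% object$coefficients) + object$intercept
  } else {
    drop(stats::predict(object$net, X))
  }
  if (!is.null(object$scaling)) pred <- pred * object$scaling$target_max
  pred
}

#' @export
print.robokin_model <- function(x, ...) {
  cat(sprintf("<robokin_model> %s predictor on %d feature(s); training RMSE %.4g\n",
              x$kind, length(x$features), x$training_rmse))
  invisible(x)
}

#' Mann-Whitney balance check between train and test outcomes
#'
#' Two-sided rank-sum test that the target values of the training and test
#' partitions come from the same distribution; a fold is deemed unbalanced
#' when p < 0.05.
#'
#' @param train_y,test_y Numeric outcome samples (each >= 3 values).
#' @return p-value in (0, 1].
#' @export
partition_balance_test <- function(train_y, test_y) {
  train_y <- train_y[!is.na(train_y)]; test_y <- test_y[!is.na(test_y)]
  if (length(train_y) < 3 || length(test_y) < 3)
    stop("balance test needs at least 3 values per partition")
  if (stats::var(c(train_y, test_y)) == 0) {
    warning("all outcome values tied: balance test degenerate, p = 1")
    return(1)
  }
  suppressWarnings(
    stats::wilcox.test(train_y, test_y, alternative = "two.sided")$p.value)
}

#' Patient-wise k-fold cross-validated correlation
#'
#' Patients (not rows) are partitioned into \code{k} folds so that all of a
#' patient's evaluation sessions stay on the same side of every split,
#' preventing identity leakage. Per fold, max-rescaling and the model are
#' fit on the training rows only; the fold's R is the Pearson correlation
#' between predicted and observed target on the held-out rows. The reported
#' R is the average over folds (a pooled-prediction R is reported as a
#' secondary), with a p-value from the t-transform of the mean R at the
#' pooled test-set size. A rank-sum balance check is run per fold; if any
#' fold is unbalanced the whole partition is redrawn (up to
#' \code{max_redraws} times) before proceeding with a warning.
#'
#' @param rows Feature table.
#' @param features Feature columns entering the model.
#' @param target Target scale column.
#' @param kind \code{"linear"} or \code{"mlp"}.
#' @param k Number of folds (default 4).
#' @param seed Integer seed driving fold assignment and MLP starts.
#' @param max_redraws Maximum partition redraws on balance failure
#'   (default 20).
#' @param mlp_restarts Restarts per MLP fit (default 10).
#' @return Object of class \code{cv_result}: \code{fold_assignments}
#'   (patient -> fold), \code{per_fold_R}, \code{mean_R}, \code{pooled_R},
#'   \code{p_value}, \code{balance_p}, \code{model_kind}, \code{target},
#'   \code{features}, \code{n_rows}, \code{n_dropped}, \code{seed}.
#' @export
patientwise_cv <- function(rows, features, target, kind = c("linear", "mlp"),
                           k = 4, seed = 1, max_redraws = 20,
                           mlp_restarts = 10) {
  kind <- match.arg(kind)
  rows <- as.data.frame(rows)
  stopifnot(all(features %in% names(rows)), target %in% names(rows))
  keep <- stats::complete.cases(rows[c(features, target)])
  n_dropped <- sum(!keep)
  rows <- rows[keep, , drop = FALSE]
  patients <- unique(rows$patient_id)
  if (length(patients) < k)
    stop("need at least k patients with the target present")
  draw <- 0
  repeat {
    fold_of <- with_seed(seed + 1000L * draw, {
      shuffled <- sample(patients)
      stats::setNames(rep(seq_len(k), length.out = length(shuffled)),
                      shuffled)
    })
    fold_rows <- fold_of[rows$patient_id]
    sizes <- tabulate(fold_rows, nbins = k)
    if (any(sizes < 3))
      stop("a fold has fewer than 3 test rows; use fewer folds")
    balance_p <- vapply(seq_len(k), function(fi) {
      partition_balance_test(rows[[target]][fold_rows != fi],
                             rows[[target]][fold_rows == fi])
    }, numeric(1))
    if (all(balance_p >= 0.05) || draw >= max_redraws) break
    draw <- draw + 1
  }
  if (any(balance_p < 0.05))
    warning("proceeding with an unbalanced partition after ", draw,
            " redraws")
  per_fold_R <- numeric(k)
  pooled_pred <- numeric(nrow(rows))
  for (fi in seq_len(k)) {
    tr <- rows[fold_rows != fi, , drop = FALSE]
    te <- rows[fold_rows == fi, , drop = FALSE]
    spec <- fit_scaling(tr, features, target,
                        mode = if (kind == "mlp") "nonlinear" else "linear")
    trs <- apply_scaling(tr, spec)
    fit <- if (kind == "linear") {
      fit_linear(trs[features], trs[[target]], scaling = spec)
    } else {
      fit_mlp(trs[features], trs[[target]], seed = seed + fi,
              restarts = mlp_restarts, scaling = spec)
    }
    pred <- predict(fit, te)
    pooled_pred[fold_rows == fi] <- pred
    per_fold_R[fi] <- pearson_r(pred, te[[target]])
  }
  mean_R <- mean(per_fold_R)
  n_test <- nrow(rows)
  p_value <- r_to_p(mean_R, n_test)
  structure(list(fold_assignments = fold_of, per_fold_R = per_fold_R,
                 mean_R = mean_R,
                 pooled_R = pearson_r(pooled_pred, rows[[target]]),
                 p_value = p_value, balance_p = balance_p,
                 model_kind = kind, target = target, features = features,
                 n_rows = n_test, n_dropped = n_dropped, seed = seed,
                 redraws = draw),
            class = "cv_result")
}

# Two-sided p-value of a correlation via the t-transform.
r_to_p <- function(r, n) {
  if (n <= 2) return(NA_real_)
  r <- min(max(r, -1 + 1e-15), 1 - 1e-15)
  tv <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(tv), df = n - 2)
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s ~ %s [%s]: mean R = %.3f (p = %.3g) over %d folds, n = %d rows\n",
              x$target, paste(x$features, collapse = " + "), x$model_kind,
              x$mean_R, x$p_value, length(x$per_fold_R), x$n_rows))
  invisible(x)
}

#' Cross-validated correlation within a target stratum
#'
#' Identical to \code{\link{patientwise_cv}} restricted to rows whose target
#' value lies in the closed interval \code{range} — used to probe whether
#' the models hold within severity strata, where the restricted target
#' variance typically lowers attainable correlations.
#'
#' @inheritParams patientwise_cv
#' @param range Length-2 numeric closed interval on the target scale.
#' @return A \code{cv_result} for the stratum.
#' @export
stratified_evaluation <- function(rows, features, target, range,
                                  kind = c("linear", "mlp"), k = 4,
                                  seed = 1, max_redraws = 20,
                                  mlp_restarts = 10) {
  stopifnot(length(range) == 2, range[1] <= range[2])
  rows <- as.data.frame(rows)
  inside <- !is.na(rows[[target]]) & rows[[target]] >= range[1] &
    rows[[target]] <= range[2]
  if (!any(inside)) stop("empty stratum: no rows with target in range")
  patientwise_cv(rows[inside, , drop = FALSE], features, target,
                 kind = kind, k = k, seed = seed, max_redraws = max_redraws,
                 mlp_restarts = mlp_restarts)
}

#' Variance inflation factors of a feature set
#'
#' For each feature, the coefficient of determination \eqn{R_j^2} of its
#' ordinary least-squares regression on all other features is computed, and
#' \eqn{VIF_j = 1 / (1 - R_j^2)}. Features with VIF > 10 (equivalently
#' \eqn{R_j^2 > 0.9}) are flagged as highly multicollinear; a VIF that large
#' means the model remains valid for prediction but the individual
#' contribution of that feature cannot be established.
#'
#' @param rows Feature table.
#' @param features At least two feature columns; complete rows must
#'   outnumber features.
#' @return data.frame with columns \code{feature}, \code{r_squared},
#'   \code{vif}, \code{flag_high}, \code{infinite} (TRUE when collinearity
#'   is numerically exact).
#' @export
vif <- function(rows, features) {
  rows <- as.data.frame(rows)
  stopifnot(length(features) >= 2)
  X <- rows[features]
  X <- X[stats::complete.cases(X), , drop = FALSE]
  if (nrow(X) <= length(features))
    stop("need more complete rows than features for VIF")
  out <- lapply(features, function(f) {
    fml <- stats::reformulate(sprintf("`%s`", setdiff(features, f)),
                              response = sprintf("`%s`", f))
    r2 <- summary(stats::lm(fml, data = X))$r.squared
    inf <- r2 > 1 - 1e-12
    r2c <- min(r2, 1 - 1e-12)
    data.frame(feature = f, r_squared = r2, vif = 1 / (1 - r2c),
               flag_high = (1 / (1 - r2c)) > 10, infinite = inf,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
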