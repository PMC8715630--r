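## Direct least-squares ellipse fitting (circle-drawing task) ----------------

#' Fit an ellipse to planar points by direct least squares
#'
#' Fits the conic \eqn{ax^2 + bxy + cy^2 + dx + ey + f = 0} subject to the
#' ellipse constraint \eqn{4ac - b^2 = 1} (direct least-squares conic
#' fitting), then converts to geometric parameters. Used on the unassisted
#' circle-drawing paths to quantify drawing quality via the best-fitting
#' ellipse axes and orientation.
#'
#' @param points Matrix or data.frame of at least 6 non-collinear 2D points.
#' @return List with \code{major}, \code{minor} (full semi-axes lengths,
#'   major >= minor > 0), \code{axis_ratio} (minor/major), \code{orientation}
#'   of the major axis in \eqn{(-\pi/2, \pi/2]}, and \code{center}.
#' @export
#' @examples
#' th <- seq(0, 2 * pi, length.out = 101)[-101]
#' fit_ellipse(cbind(2 * cos(th), sin(th)))
fit_ellipse <- function(points) {
  P <- as.matrix(points)
  stopifnot(ncol(P) == 2)
  if (nrow(P) < 6) stop("ellipse fit needs at least 6 points")
  # centre and scale for conditioning
  mu <- colMeans(P)
  sc <- mean(apply(P, 2, stats::sd))
  if (!is.finite(sc) || sc <= 0) stop("degenerate point set: no spread")
  x <- (P[, 1] - mu[1]) / sc
  y <- (P[, 2] - mu[2]) / sc
  D1 <- cbind(x^2, x * y, y^2)
  D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1)
  S2 <- crossprod(D1, D2)
  S3 <- crossprod(D2)
  qrS3 <- qr(S3)
  if (qrS3$rank < 3) stop("degenerate or collinear points: cannot fit ellipse")
  Tm <- -solve(S3, t(S2))
  M <- S1 + S2 %*% Tm
  # constraint-reduced eigenproblem (Fitzgibbon / Halir-Flusser reduction)
  M2 <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M2)
  evec <- Re(ev$vectors)
  cond <- 4 * evec[1, ] * evec[3, ] - evec[2, ]^2
  ok <- which(cond > 1e-12)
  if (length(ok) == 0) stop("points do not determine an ellipse")
  a1 <- evec[, ok[which.max(cond[ok])]]
  coef <- c(a1, Tm %*% a1)       # a, b, c, d, e, f in scaled frame
  geo <- conic_to_geometry(coef)
  # undo conditioning
  geo$major <- geo$major * sc
  geo$minor <- geo$minor * sc
  geo$center <- geo$center * sc + mu
  geo$axis_ratio <- geo$minor / geo$major
  geo[c("major", "minor", "axis_ratio", "orientation", "center")]
}

conic_to_geometry <- function(coef) {
  A <- coef[1]; B <- coef[2]; C <- coef[3]
  D <- coef[4]; E <- coef[5]; F <- coef[6]
  den <- B^2 - 4 * A * C
  if (den >= 0) stop("conic is not an ellipse")
  cx <- (2 * C * D - B * E) / den
  cy <- (2 * A * E - B * D) / den
  # orientation of the major axis in (-pi/2, pi/2]
  num <- A * E^2 + C * D^2 + F * B^2 - B * D * E - 4 * A * C * F
  common <- 2 * num
  root <- sqrt((A - C)^2 + B^2)
  a_len <- -sqrt(common * (A + C + root)) / den
  b_len <- -sqrt(common * (A + C - root)) / den
  major <- max(a_len, b_len)
  minor <- min(a_len, b_len)
  theta <- if (abs(B) < .Machine$double.eps^0.5 && A <= C) {
    0
  } else if (abs(B) < .Machine$double.eps^0.5) {
    pi / 2
  } else {
    atan2(C - A - root, B)
  }
  if (a_len < b_len) theta <- theta + pi / 2
  theta <- ((theta + pi / 2) %% pi) - pi / 2
  if (theta <= -pi / 2 + .Machine$double.eps) theta <- theta + pi
  list(major = major, minor = minor, orientation = theta,
       center = c(cx, cy))
}

#' Circle-drawing metrics for one drawing condition
#'
#' @param path Matrix of 2D endpoint samples for one circle-drawing attempt.
#' @param arm An \code{\link{arm_geometry}} for the joint-independence
#'   correlation (optional; NULL skips it).
#' @return List with the ellipse parameters of \code{\link{fit_ellipse}} plus
#'   \code{joint_independence} (NA when \code{arm} is NULL).
#' @export
circle_metrics <- function(path, arm = NULL) {
  fit <- fit_ellipse(path)
  ji <- if (is.null(arm)) NA_real_ else joint_independence(path, arm)
  c(fit, list(joint_independence = ji))
}
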