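## Planar two-link arm kinematics -------------------------------------------

#' Forward kinematics of the planar two-link arm
#'
#' @param theta Numeric vector \code{c(theta_shoulder, theta_elbow)} or a
#'   two-column matrix of joint angles (radians). The elbow angle is measured
#'   relative to the upper-arm direction (0 = full extension).
#' @param arm An \code{\link{arm_geometry}}.
#' @return Endpoint coordinates (vector, or matrix for matrix input).
#' @export
forward_kinematics_2link <- function(theta, arm) {
  th <- if (is.matrix(theta)) theta else matrix(theta, ncol = 2)
  L1 <- arm$upper_arm_length_m; L2 <- arm$forearm_length_m
  s <- arm$shoulder_position
  x <- s[1] + L1 * cos(th[, 1]) + L2 * cos(th[, 1] + th[, 2])
  y <- s[2] + L1 * sin(th[, 1]) + L2 * sin(th[, 1] + th[, 2])
  out <- cbind(x, y)
  if (is.matrix(theta)) out else drop(out)
}

#' Inverse kinematics of the planar two-link arm
#'
#' Estimates shoulder and elbow joint angles from endpoint position, using
#' the elbow-down branch (elbow angle in \eqn{[0, \pi]}) consistently, as
#' appropriate for a right arm working in front of the body.
#'
#' @param xy Endpoint coordinates (vector or two-column matrix, metres).
#' @param arm An \code{\link{arm_geometry}}.
#' @return \code{c(theta_shoulder, theta_elbow)} in radians (matrix for
#'   matrix input).
#' @export
#' @examples
#' arm <- arm_geometry(0.3, 0.25, c(0, 0))
#' inverse_kinematics_2link(c(0.55, 0), arm)  # full extension: elbow 0
inverse_kinematics_2link <- function(xy, arm) {
  P <- if (is.matrix(xy)) xy else matrix(xy, ncol = 2)
  L1 <- arm$upper_arm_length_m; L2 <- arm$forearm_length_m
  s <- arm$shoulder_position
  rx <- P[, 1] - s[1]; ry <- P[, 2] - s[2]
  d <- sqrt(rx^2 + ry^2)
  lo <- abs(L1 - L2); hi <- L1 + L2
  tol <- 1e-9 * max(1, hi)
  bad <- which(d > hi + tol | d < lo - tol)
  if (length(bad) > 0)
    stop(sprintf("unreachable point: distance %.6g outside reachable annulus [%.6g, %.6g]",
                 d[bad[1]], lo, hi))
  cth <- pmin(1, pmax(-1, (d^2 - L1^2 - L2^2) / (2 * L1 * L2)))
  theta_e <- acos(cth)                       # elbow-down: [0, pi]
  theta_s <- atan2(ry, rx) -
    atan2(L2 * sin(theta_e), L1 + L2 * cos(theta_e))
  out <- cbind(theta_shoulder = theta_s, theta_elbow = theta_e)
  if (is.matrix(xy)) out else drop(out)
}

#' Joint independence of a circle-drawing path
#'
#' Pearson correlation between the shoulder and elbow joint-angle time
#' series obtained by inverse kinematics along the path. Independent joint
#' use during circle drawing yields correlations near zero; stereotyped
#' coupling pushes the correlation toward +/-1.
#'
#' @param path Matrix of 2D endpoint samples, all reachable.
#' @param arm An \code{\link{arm_geometry}}.
#' @return Correlation in [-1, 1], or NA (with a warning) when either joint
#'   angle series is constant.
#' @export
joint_independence <- function(path, arm) {
  th <- inverse_kinematics_2link(as.matrix(path), arm)
  spread <- apply(th, 2, function(v) diff(range(v)))
  if (any(spread < 1e-9)) {
    warning("constant joint-angle series: joint independence undefined")
    return(NA_real_)
  }
  stats::cor(th[, 1], th[, 2])
}
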