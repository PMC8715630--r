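## Numerical helpers: derivatives and quadrature on a timestamp grid ---------

# Derivative weights at x0 from a small Lagrange stencil (exact for
# polynomials up to the stencil size minus one).
lagrange_deriv_weights <- function(x0, xs) {
  m <- length(xs)
  vapply(seq_len(m), function(j) {
    if (isTRUE(all.equal(xs[j], x0))) {
      sum(1 / (x0 - xs[-j]))
    } else {
      others <- xs[-j]
      rest <- others[!vapply(others, function(u)
        isTRUE(all.equal(u, x0)), logical(1))]
      prod(x0 - rest) / prod(xs[j] - others)
    }
  }, numeric(1))
}

# Finite differences on a (possibly nonuniform) grid: second-order central
# stencils in the interior, third-order one-sided 4-point stencils at the
# two samples on each boundary (repeated differentiation for jerk otherwise
# loses an order of accuracy exactly where squared jerk is largest).
num_deriv <- function(y, t) {
  n <- length(y)
  stopifnot(length(t) == n, n >= 3)
  d <- numeric(n)
  h1 <- t[2:(n - 1)] - t[1:(n - 2)]
  h2 <- t[3:n] - t[2:(n - 1)]
  d[2:(n - 1)] <- (-h2 / (h1 * (h1 + h2))) * y[1:(n - 2)] +
    ((h2 - h1) / (h1 * h2)) * y[2:(n - 1)] +
    (h1 / (h2 * (h1 + h2))) * y[3:n]
  if (n >= 5) {
    for (i in 1:2) {
      w <- lagrange_deriv_weights(t[i], t[1:4])
      d[i] <- sum(w * y[1:4])
    }
    for (i in (n - 1):n) {
      w <- lagrange_deriv_weights(t[i], t[(n - 3):n])
      d[i] <- sum(w * y[(n - 3):n])
    }
  } else {
    w <- lagrange_deriv_weights(t[1], t[1:3]); d[1] <- sum(w * y[1:3])
    w <- lagrange_deriv_weights(t[n], t[(n - 2):n]); d[n] <- sum(w * y[(n - 2):n])
  }
  d
}

# Fornberg's algorithm: weights of the m-th derivative at z from the nodes
# x (exact for polynomials of degree length(x) - 1).
fornberg_weights <- function(z, x, m) {
  n <- length(x)
  w <- matrix(0, n, m + 1)
  c1 <- 1; c4 <- x[1] - z
  w[1, 1] <- 1
  for (i in 2:n) {
    mn <- min(i, m + 1)
    c2 <- 1; c5 <- c4; c4 <- x[i] - z
    for (j in 1:(i - 1)) {
      c3 <- x[i] - x[j]
      c2 <- c2 * c3
      if (j == i - 1) {
        if (mn > 1) for (k in mn:2)
          w[i, k] <- c1 * ((k - 1) * w[i - 1, k - 1] - c5 * w[i - 1, k]) / c2
        w[i, 1] <- -c1 * c5 * w[i - 1, 1] / c2
      }
      if (mn > 1) for (k in mn:2)
        w[j, k] <- (c4 * w[j, k] - (k - 1) * w[j, k - 1]) / c3
      w[j, 1] <- c4 * w[j, 1] / c3
    }
    c1 <- c2
  }
  w[, m + 1]
}

# Third derivative on the timestamp grid via sliding 7-point Fornberg
# stencils (repeatedly applying first differences loses boundary accuracy;
# the direct stencil is exact up to degree-6 local behaviour).
num_deriv3 <- function(y, t) {
  n <- length(y)
  stopifnot(length(t) == n)
  if (n < 7) {
    return(num_deriv(num_deriv(num_deriv(y, t), t), t))
  }
  d <- numeric(n)
  uniform <- diff(range(diff(t))) < 1e-9 * mean(diff(t))
  if (uniform) {
    wc <- fornberg_weights(t[4], t[1:7], 3)
    for (off in 0:6) {
      seg <- y[(1 + off):(n - 6 + off)]
      d[4:(n - 3)] <- d[4:(n - 3)] + wc[off + 1] * seg
    }
    for (i in c(1:3, (n - 2):n)) {
      idx <- if (i <= 3) 1:7 else (n - 6):n
      w <- fornberg_weights(t[i], t[idx], 3)
      d[i] <- sum(w * y[idx])
    }
  } else {
    for (i in seq_len(n)) {
      lo <- min(max(1, i - 3), n - 6)
      idx <- lo:(lo + 6)
      w <- fornberg_weights(t[i], t[idx], 3)
      d[i] <- sum(w * y[idx])
    }
  }
  d
}

# Trapezoidal integral of y over t.
trapz_int <- function(t, y) {
  n <- length(t)
  if (n < 2) return(0)
  sum((t[2:n] - t[1:(n - 1)]) * (y[2:n] + y[1:(n - 1)])) / 2
}

# Optional Savitzky-Golay smoothing of each column of a sample matrix.
# window must be odd and > poly order; window <= 1 disables smoothing.
smooth_columns <- function(q, window = 5, order = 3) {
  if (window <= 1 || nrow(q) < window + 2) return(q)
  if (window %% 2 == 0) window <- window + 1
  apply(q, 2, function(col) signal::sgolayfilt(col, p = order, n = window))
}

# Speed (norm of the coordinate time-derivative) of a sampled path.
path_speed <- function(t, q, smooth_window = 1) {
  q <- as.matrix(q)
  q <- smooth_columns(q, smooth_window)
  v <- apply(q, 2, num_deriv, t = t)
  sqrt(rowSums(as.matrix(v)^2))
}

# Cumulative path length of a sampled path.
path_length <- function(q) {
  q <- as.matrix(q)
  if (nrow(q) < 2) return(0)
  sum(sqrt(rowSums((q[-1, , drop = FALSE] - q[-nrow(q), , drop = FALSE])^2)))
}

# Circular mean of angles (radians).
circular_mean <- function(theta) {
  atan2(mean(sin(theta)), mean(cos(theta)))
}
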