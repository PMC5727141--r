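#' Wrap angles to (-pi, pi]
#'
#' All angles handled by the package (polarity phases, contact midpoints,
#' signal directions) are reported in the half-open interval (-pi, pi].
#'
#' @param x numeric vector of angles in radians.
#' @return numeric vector of the same length, wrapped to (-pi, pi].
#' @export
#' @examples
#' wrap_angle(c(0, pi, -pi, 3 * pi / 2))
wrap_angle <- function(x) {
  -(((-x + pi) %% (2 * pi)) - pi)
}

#' Uniform periodic grid on the cell boundary
#'
#' @param n number of grid points (>= 64, even).
#' @return numeric vector theta_m = 2*pi*m/n, m = 0..n-1.
#' @export
ring_grid <- function(n) {
  stopifnot(is.numeric(n), length(n) == 1, n >= 64, n %% 2 == 0)
  2 * pi * (0:(n - 1)) / n
}

# Signed integer wavenumbers in stats::fft ordering:
# 0, 1, ..., n/2, -(n/2 - 1), ..., -1
.wavenumbers <- function(n) {
  c(0:(n / 2), -((n / 2 - 1):1))
}

# Values of the trigonometric interpolant of `u` (length n, on ring_grid(n))
# at the points c - theta_m, m = 0..n-1, i.e. the profile reflected about
# c/2.  Exact for band-limited u (Nyquist handled as a pure cosine, which is
# what fft of a real vector stores).  Used for evaluating a neighbour's
# field at the facing points theta_j* = eta_ji - (theta_i - eta_ij).
.reflect_shift <- function(u, c) {
  n <- length(u)
  # W(theta) = u(-theta): index reversal on the grid
  w <- u[c(1L, n:2L)]
  # then shift: want W(theta_m - c); spectral coefficients pick up e^{-i k c}
  wh <- stats::fft(w)
  k <- .wavenumbers(n)
  fac <- exp(-1i * k * c)
  # keep the Nyquist mode real (cos((n/2) theta) shifted -> cos term only)
  fac[n / 2 + 1] <- cos(k[n / 2 + 1] * c)
  Re(stats::fft(wh * fac, inverse = TRUE)) / n
}

# Values of the trigonometric interpolant of u at grid shifted by `s`:
# returns u(theta_m + s).
.spectral_shift <- function(u, s) {
  n <- length(u)
  uh <- stats::fft(u)
  k <- .wavenumbers(n)
  fac <- exp(1i * k * s)
  fac[n / 2 + 1] <- cos(k[n / 2 + 1] * s)
  Re(stats::fft(uh * fac, inverse = TRUE)) / n
}

# Evaluate the trigonometric interpolant of u (on ring_grid(n)) at arbitrary
# points `at` (radians).  O(n * length(at)); used in quadrature oracles, not
# in inner loops.
.trig_eval <- function(u, at) {
  n <- length(u)
  uh <- stats::fft(u) / n
  kmax <- n / 2
  a <- 2 * Re(uh[2:kmax])          # cos coefficients k = 1..n/2-1
  b <- -2 * Im(uh[2:kmax])         # sin coefficients
  ks <- 1:(kmax - 1)
  out <- rep(Re(uh[1]), length(at))
  C <- cos(outer(at, ks))
  S <- sin(outer(at, ks))
  out <- out + as.vector(C %*% a + S %*% b)
  out + Re(uh[kmax + 1]) * cos(kmax * at)
}

# Fourier spectral second-derivative matrix (n x n, circulant, symmetric).
.d2_matrix <- function(n) {
  k <- .wavenumbers(n)
  col1 <- Re(stats::fft(-k^2 + 0i, inverse = TRUE)) / n
  idx <- outer(0:(n - 1), 0:(n - 1), function(i, j) ((i - j) %% n) + 1L)
  matrix(col1[idx], n, n)
}

# Gauss-Legendre nodes/weights on [a, b] via Golub-Welsch.
.gauss_legendre <- function(m, a = -1, b = 1) {
  i <- 1:(m - 1)
  beta <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, m, m)
  J[cbind(i, i + 1)] <- beta
  J[cbind(i + 1, i)] <- beta
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- 2 * e$vectors[1, ]^2
  ord <- order(x)
  list(nodes = (b - a) / 2 * x[ord] + (a + b) / 2,
       weights = (b - a) / 2 * w[ord])
}

#' Extract the polarity phase of a boundary concentration profile
#'
#' The polarity angle is defined through the first circular Fourier mode of
#' the activator profile: with `Uhat = (1/2pi) int U(theta) exp(-i theta)
#' dtheta = C exp(-i phi)`, the phase is `phi = -Arg(Uhat)`.  For a nearly
#' harmonic profile this coincides with the position of the maximum of U.
#'
#' @param u numeric vector: activator values on `ring_grid(length(u))`, or a
#'   matrix whose first column is the activator.
#' @param tol_C positive scalar; if the first-mode magnitude `C` falls below
#'   this value the polarity direction is undefined and an error is raised.
#' @return named numeric vector with elements `phase` (radians, in
#'   (-pi, pi]) and `C` (first-mode magnitude).
#' @export
#' @examples
#' th <- ring_grid(128)
#' extract_phase(cos(th - 1.2))
extract_phase <- function(u, tol_C = 1e-8) {
  if (is.matrix(u)) u <- u[, 1]
  n <- length(u)
  uhat <- stats::fft(u)[2] / n
  C <- Mod(uhat)
  if (!is.finite(C) || C <= tol_C) {
    stop("polarity direction undefined: first Fourier mode magnitude ",
         format(C), " <= tol_C = ", format(tol_C))
  }
  c(phase = wrap_angle(-Arg(uhat)), C = C)
}
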