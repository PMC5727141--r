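#' Steady polarity pattern of a single uncoupled cell
#'
#' Solves `F(X) + D d2X/dtheta2 = 0` on the periodic boundary grid for the
#' stable unimodal pattern, starting from a small perturbation of the
#' homogeneous state.  Integration uses Lie splitting with the diffusion
#' applied spectrally (exact `exp(-D k^2 dt)` factor per wavenumber) and the
#' reaction stepped explicitly; once the residual is small the solution is
#' polished by Newton iterations with the translational (Goldstone) mode
#' pinned through a bordered linear system.  The converged pattern is
#' rotated so that the activator maximum sits at theta = 0, and the
#' Goldstone mode `Y0 = -dX^S/dtheta` is computed spectrally.
#'
#' @param model a `reaction_model`.
#' @param n_theta grid size (even, >= 64); default 256.
#' @param init optional `n_theta x n_species` initial field.  The default
#'   for the activator-inhibitor model is the homogeneous fixed point plus a
#'   `0.1 cos(theta - phi0)` perturbation of the activator; for the GLE it
#'   is `0.1 (cos(theta - phi0), sin(theta - phi0))` (a U-only perturbation
#'   would stay in the invariant V = 0 subspace and miss the polar pattern).
#' @param phi0 initial polarity direction of the default perturbation.
#' @param dt splitting step; `NULL` picks a model-appropriate default.
#' @param t_max integration budget before declaring non-convergence.
#' @param residual_tol final residual (sup-norm of the discretised
#'   right-hand side) required from the Newton polish.
#' @return object of class `reduced_cell`: list with `model`, `n_theta`,
#'   `theta`, `XS` (`n_theta x n_species` steady pattern), `Y0`, `residual`,
#'   and `C` (first-mode magnitude).  `Z0` is added by
#'   [adjoint_zero_mode()].
#' @export
find_steady_state <- function(model, n_theta = 256, init = NULL, phi0 = 0,
                              dt = NULL, t_max = 40000,
                              residual_tol = 1e-8) {
  stopifnot(inherits(model, "reaction_model"))
  n <- as.integer(n_theta)
  if (n < 64 || n %% 2 != 0) stop("n_theta must be even and >= 64")
  th <- ring_grid(n)
  if (is.null(init)) {
    init <- .default_pattern_init(model, th, phi0)
  }
  stopifnot(is.matrix(init), nrow(init) == n,
            ncol(init) == model$n_species)
  if (is.null(dt)) {
    dt <- if (model$name == "gle") 0.05 else 0.2
  }

  k2 <- .wavenumbers(n)^2
  damp <- exp(-outer(k2, model$diffusion) * dt)  # n x n_species
  X <- init
  t_now <- 0
  check_every <- 50L
  steps <- 0L
  res_prev <- Inf
  repeat {
    X <- X + dt * model$reaction(X)
    X <- Re(stats::mvfft(stats::mvfft(X) * damp, inverse = TRUE)) / n
    t_now <- t_now + dt
    steps <- steps + 1L
    if (steps %% check_every == 0L) {
      if (any(!is.finite(X))) stop("steady-state search diverged")
      res <- max(abs(.rd_residual(model, X)))
      # hand over to Newton once the splitting iteration has converged to
      # its own fixed point (the O(dt) splitting bias dominates res then)
      if (res < 1e-5 || (res < 1e-2 && abs(res_prev - res) < 1e-4 * res)) {
        break
      }
      res_prev <- res
      if (t_now >= t_max) {
        stop("steady-state search did not converge within t_max ",
             "(residual ", format(res), ")")
      }
    }
  }
  # pattern lost? (converged to a homogeneous state)
  if (Mod(stats::fft(X[, 1])[2] / n) < 1e-4) {
    stop("pattern lost: the model converged to a homogeneous state ",
         "(no polarity for these parameters)")
  }
  X <- .newton_polish(model, X, residual_tol)
  # align: activator maximum to theta = 0, then re-polish
  shift <- .profile_argmax(X[, 1], th)
  if (abs(shift) > 1e-14) {
    X <- apply(X, 2, .spectral_shift, s = shift)
    X <- .newton_polish(model, X, residual_tol)
  }
  Y0 <- -.spectral_deriv(X)
  res <- max(abs(.rd_residual(model, X)))
  if (res >= residual_tol) {
    stop("Newton polish stalled at residual ", format(res))
  }
  structure(list(model = model, n_theta = n, theta = th, XS = X, Y0 = Y0,
                 residual = res,
                 C = Mod(stats::fft(X[, 1])[2] / n)),
            class = "reduced_cell")
}

.default_pattern_init <- function(model, th, phi0) {
  n <- length(th)
  if (model$name == "gle") {
    cbind(0.1 * cos(th - phi0), 0.1 * sin(th - phi0))
  } else if (model$name == "activator_inhibitor") {
    p <- model$params
    # homogeneous fixed point: with the defaults (1, 1)
    u0 <- p$mu_V * p$rho_U / (p$mu_U * p$rho_V)  # kappa = sigma_U = 0 case
    if (p$kappa != 0 || p$sigma_U != 0) u0 <- 1   # fall back to the default
    v0 <- p$rho_V * u0^2 / p$mu_V
    cbind(u0 + 0.1 * cos(th - phi0), rep(v0, n))
  } else {
    matrix(0.1 * cos(th - phi0), n, model$n_species)
  }
}

# Discrete steady-state residual F(X) + D X'' (spectral second derivative).
.rd_residual <- function(model, X) {
  n <- nrow(X)
  k2 <- .wavenumbers(n)^2
  lap <- Re(stats::mvfft(stats::mvfft(X) * (-k2), inverse = TRUE)) / n
  model$reaction(X) + lap %*% diag(model$diffusion, model$n_species)
}

.spectral_deriv <- function(X) {
  n <- nrow(X)
  k <- .wavenumbers(n)
  ik <- 1i * k
  ik[n / 2 + 1] <- 0  # odd derivative of the Nyquist cosine vanishes on grid
  Re(stats::mvfft(stats::mvfft(X) * ik, inverse = TRUE)) / n
}

# Location of the maximum of the trigonometric interpolant of u.
.profile_argmax <- function(u, th) {
  i0 <- which.max(u)
  f <- function(x) -.trig_eval(u, x)
  opt <- stats::optimize(f, interval = th[i0] + c(-1, 1) * (th[2] - th[1]),
                         tol = 1e-14)
  wrap_angle(opt$minimum)
}

# Newton iterations on the discretised steady-state system with the
# translational mode pinned by a bordered system [L, Y0; Y0^T, 0].
.newton_polish <- function(model, X, tol, max_iter = 40L) {
  n <- nrow(X); ns <- ncol(X)
  for (iter in seq_len(max_iter)) {
    G <- .rd_residual(model, X)
    if (max(abs(G)) < max(tol * 1e-2, 1e-12) && iter > 1) break
    L <- .linear_operator_matrix(model, X)
    y0 <- as.vector(-.spectral_deriv(X))
    A <- rbind(cbind(L, y0), c(y0, 0))
    rhs <- c(-as.vector(G), 0)
    sol <- tryCatch(solve(A, rhs), error = function(e) NULL)
    if (is.null(sol)) break
    step <- matrix(sol[seq_len(n * ns)], n, ns)
    X <- X + step
    if (max(abs(step)) < 1e-14) break
  }
  X
}

#' Discretised linearised operator about a steady pattern
#'
#' Returns the `(n*s) x (n*s)` matrix of the operator
#' `L = J + D d2/dtheta2` linearised about `XS`, in species-block ordering
#' (all grid values of species 1, then species 2, ...).  Its transpose is
#' the discrete adjoint with respect to the uniform-weight inner product
#' `<A, B> = int A.B dtheta`.
#'
#' @param model a `reaction_model`.
#' @param XS `n x s` steady pattern.
#' @return dense matrix.
#' @export
linear_operator_matrix <- function(model, XS) {
  .linear_operator_matrix(model, XS)
}

.linear_operator_matrix <- function(model, XS) {
  n <- nrow(XS); ns <- ncol(XS)
  J <- model$jacobian(XS)  # n x ns x ns
  D2 <- .d2_matrix(n)
  L <- matrix(0, n * ns, n * ns)
  for (a in seq_len(ns)) {
    for (b in seq_len(ns)) {
      blk <- diag(J[, a, b], n)
      if (a == b) blk <- blk + model$diffusion[a] * D2
      L[((a - 1) * n + 1):(a * n), ((b - 1) * n + 1):(b * n)] <- blk
    }
  }
  L
}

#' Adjoint zero eigenfunction (phase sensitivity function)
#'
#' Computes the null vector `Z0` of the discretised adjoint operator
#' `L^T = J^T + D d2/dtheta2`, normalised so that `<Z0, Y0> = 1` with the
#' inner product `int A.B dtheta`.  `Z0` projects perturbations of the
#' pattern onto shifts of the polarity angle.  The null space must be
#' one-dimensional at tolerance (only the translational Goldstone mode);
#' otherwise an error is raised.
#'
#' @param model a `reaction_model`.
#' @param cell a `reduced_cell` from [find_steady_state()].
#' @param null_tol eigenvalue magnitude below which a mode counts as zero.
#' @return the `reduced_cell` with fields `Z0` (`n x s` matrix) and
#'   `L_eigenvalues` (the five smallest-magnitude eigenvalues) added.
#' @export
adjoint_zero_mode <- function(model, cell, null_tol = 1e-6) {
  stopifnot(inherits(cell, "reduced_cell"))
  n <- cell$n_theta; ns <- model$n_species
  L <- .linear_operator_matrix(model, cell$XS)
  ev <- eigen(t(L))
  mags <- Mod(ev$values)
  ord <- order(mags)
  nzero <- sum(mags < null_tol)
  if (nzero != 1) {
    stop("adjoint null space has dimension ", nzero,
         " at tolerance ", format(null_tol), " (expected 1)")
  }
  z <- Re(ev$vectors[, ord[1]])
  Z0 <- matrix(z, n, ns)
  dth <- 2 * pi / n
  nrm <- dth * sum(Z0 * cell$Y0)
  if (abs(nrm) < 1e-12) stop("degenerate normalisation <Z0, Y0> ~ 0")
  Z0 <- Z0 / nrm
  cell$Z0 <- Z0
  cell$L_eigenvalues <- ev$values[ord[seq_len(min(5, length(mags)))]]
  cell
}

#' Inner product of two periodic vector fields
#'
#' `<A, B> = int_0^{2pi} A . B dtheta`, evaluated by the (spectrally exact)
#' uniform-grid quadrature.
#'
#' @param A,B `n x s` matrices on a common grid.
#' @return scalar.
#' @export
ring_inner <- function(A, B) {
  stopifnot(all(dim(A) == dim(B)))
  (2 * pi / nrow(A)) * sum(A * B)
}

#' Fourier coefficients of the aligned steady pattern and adjoint mode
#'
#' Uses the two-sided convention of the reduction: the activator profile is
#' `U^S(theta) = sum_k u_k cos(k theta)` over all integers k with
#' `u_{-k} = u_k`, and the activator component of the adjoint mode is
#' `Z0^(U)(theta) = sum_k -z_k sin(k theta)` with `z_{-k} = -z_k`.
#' Operationally `u_k = (1/2pi) int U^S cos(k theta) dtheta` for k >= 0 and
#' `z_k = -(1/2pi) int Z0^(U) sin(k theta) dtheta` for k >= 1.
#'
#' @param cell a `reduced_cell` with `Z0` (see [adjoint_zero_mode()]).
#' @param K truncation order (default 8).
#' @param asym_tol maximum tolerated odd-part (sine) residual of `U^S`; a
#'   larger residual means the alignment failed.
#' @return object of class `fourier_data`: list with `u` (length K+1,
#'   entries u_0..u_K), `z` (length K, entries z_1..z_K), `K`, and
#'   `asymmetry` (the measured sine residual of U^S).
#' @export
fourier_coefficients <- function(cell, K = 8, asym_tol = 1e-6) {
  stopifnot(inherits(cell, "reduced_cell"))
  if (is.null(cell$Z0)) {
    stop("cell has no adjoint mode; call adjoint_zero_mode() first")
  }
  n <- cell$n_theta
  if (K >= n / 2) stop("K too large for the grid")
  uh <- stats::fft(cell$XS[, 1]) / n
  zh <- stats::fft(cell$Z0[, 1]) / n
  u <- Re(uh[1:(K + 1)])                 # u_k = (1/2pi) int U cos(k th)
  z <- Im(zh[2:(K + 1)])                 # z_k = -(1/2pi) int Z sin(k th)
  asym <- max(abs(Im(uh[2:(K + 1)])))
  if (asym > asym_tol) {
    stop("steady profile is not even about theta = 0 (sine residual ",
         format(asym), "); alignment failed")
  }
  structure(list(u = u, z = z, K = as.integer(K), asymmetry = asym),
            class = "fourier_data")
}

#' Shape (contact-indicator) Fourier coefficients
#'
#' Cosine coefficients of the centred contact indicator of width `d`:
#' `s_0 = d/(2pi)`, `s_k = sin(k d/2)/(k pi)` for k >= 1, with
#' `s_{-k} = s_k`.
#'
#' @param d contact width, radians, in (0, 2pi).
#' @param K highest order returned.
#' @return numeric vector of length K+1: `s_0, s_1, ..., s_K`.
#' @export
#' @examples
#' shape_coefficients(pi / 3, 2)  # 1/6, 1/(2pi), ...
shape_coefficients <- function(d, K) {
  stopifnot(d > 0, d < 2 * pi)
  k <- seq_len(K)
  c(d / (2 * pi), sin(k * d / 2) / (k * pi))
}

# ---- phase coupling function ---------------------------------------------

#' Construct a phase coupling function from explicit sinusoidal terms
#'
#' A coupling function is a finite sum
#' `Gamma(phi_i, phi_j; eta) = sum A sin(p eta - q phi_i - r phi_j)`.
#' Terms are canonicalised (keys folded so that p >= 0, using
#' sin(-x) = -sin(x)), merged, and pruned below `amp_tol`.
#'
#' @param amp,p,q,r parallel vectors: amplitudes and the integer multipliers
#'   of `eta`, `phi_i`, `phi_j`.
#' @param amp_tol terms with `|A| < amp_tol` are dropped.
#' @param kind provenance label (`"difference"`, `"pure_inhibition"`,
#'   `"custom"`).
#' @return object of class `phase_coupling`: a data.frame with columns
#'   `amp`, `p`, `q`, `r` plus attributes.
#' @export
#' @examples
#' # XY-model coupling: a sin(phi_j - phi_i)
#' phase_coupling(amp = 0.1, p = 0, q = 1, r = -1)
phase_coupling <- function(amp, p, q, r, amp_tol = 0, kind = "custom") {
  stopifnot(length(amp) == length(p), length(p) == length(q),
            length(q) == length(r))
  flip <- p < 0 | (p == 0 & q < 0) | (p == 0 & q == 0 & r < 0)
  amp <- ifelse(flip, -amp, amp)
  p <- ifelse(flip, -p, p); q <- ifelse(flip, -q, q)
  r <- ifelse(flip, -r, r)
  key <- paste(p, q, r)
  amp <- tapply(amp, key, sum)
  pqr <- do.call(rbind, strsplit(names(amp), " "))
  tab <- data.frame(amp = as.numeric(amp),
                    p = as.integer(pqr[, 1]),
                    q = as.integer(pqr[, 2]),
                    r = as.integer(pqr[, 3]))
  tab <- tab[abs(tab$amp) >= amp_tol & !(tab$p == 0 & tab$q == 0 &
                                           tab$r == 0), , drop = FALSE]
  tab <- tab[order(tab$p, tab$q, tab$r), , drop = FALSE]
  rownames(tab) <- NULL
  structure(tab, class = c("phase_coupling", "data.frame"), kind = kind)
}

#' Named canonical coefficients of a coupling function
#'
#' Accessors for the canonical low-harmonic terms: `a` multiplies
#' `sin(phi_j - phi_i)`, `b` multiplies `sin 2(eta - phi_i)`, `bprime`
#' multiplies `sin(eta - phi_i)` and `c` multiplies
#' `sin(2 eta - phi_i - phi_j)`.
#'
#' @param pc a `phase_coupling`.
#' @param which one of `"a"`, `"b"`, `"bprime"`, `"c"`; or `NULL` for all
#'   four as a named vector.
#' @return numeric scalar or named numeric vector (0 for absent terms).
#' @export
coupling_coef <- function(pc, which = NULL) {
  stopifnot(inherits(pc, "phase_coupling"))
  keys <- list(a = c(0, 1, -1), b = c(2, 2, 0), bprime = c(1, 1, 0),
               c = c(2, 1, 1))
  # canonical form of a = sin(phi_j - phi_i): stored as (0, 1, -1) with
  # amplitude -A since sin(0 - phi_i + phi_j) = +A requires care: the term
  # A sin(phi_j - phi_i) = A sin(-(phi_i - phi_j)) has p=0,q=1,r=-1 with
  # stored amplitude -(-A)... resolved by direct lookup below.
  get1 <- function(k) {
    hit <- pc$p == k[1] & pc$q == k[2] & pc$r == k[3]
    if (any(hit)) pc$amp[hit] else 0
  }
  # a-term: A sin(phi_j - phi_i) = -A sin(0*eta - 1*phi_i... ) check:
  # sin(p eta - q phi_i - r phi_j) with (0,1,-1) = sin(-phi_i + phi_j)
  # = sin(phi_j - phi_i).  So the stored amplitude IS a.
  out <- c(a = get1(keys$a), b = get1(keys$b), bprime = get1(keys$bprime),
           c = get1(keys$c))
  if (is.null(which)) out else out[[which]]
}

#' Assemble the coupling function from Fourier data
#'
#' Builds `Gamma_ij(phi_i, phi_j)` for an edge of contact width `d` from
#' the Fourier coefficients of the aligned pattern and adjoint mode, by the
#' closed double sum over harmonics `k, l` in `-K..K`:
#' the cross part (from the neighbour's activator entering the contact
#' interaction) contributes `2pi z_k u_l (-1)^l s_{k-l}
#' sin((k+l) eta - k phi_i - l phi_j)` and, for the `"difference"` coupling
#' only, the self part contributes `-2pi z_k u_l s_{k+l}
#' sin((k+l)(eta - phi_i))`.  For nearly harmonic profiles the leading
#' coefficients obey `a = b = -4pi z1 u1 s2`, `c = -4pi z1 u1 s0`, and for
#' the pure-inhibition variant `bprime = 4pi z1 u0 s1`.
#'
#' @param fd a `fourier_data`.
#' @param d contact width, radians.
#' @param kind `"difference"` (self + cross parts of the contact coupling
#'   `U_i - U_j*`) or `"pure_inhibition"` (cross part `-U_j*` only).
#' @param amp_tol pruning tolerance for assembled terms (default 1e-4).
#' @return a `phase_coupling`.
#' @export
gamma_from_fourier <- function(fd, d, kind = c("difference",
                                               "pure_inhibition"),
                               amp_tol = 1e-4) {
  kind <- match.arg(kind)
  stopifnot(inherits(fd, "fourier_data"))
  K <- fd$K
  s <- shape_coefficients(d, 2 * K)      # s_0..s_{2K}; s_{-m} = s_m
  sv <- function(m) s[abs(m) + 1]
  uv <- function(l) fd$u[abs(l) + 1]
  zv <- function(k) sign(k) * fd$z[abs(k)]
  amp <- numeric(0); p <- integer(0); q <- integer(0); r <- integer(0)
  for (k in c(-K:-1, 1:K)) {
    for (l in -K:K) {
      # cross part: from -U_j(theta_j*)
      amp <- c(amp, 2 * pi * zv(k) * uv(l) * (-1)^l * sv(k - l))
      p <- c(p, k + l); q <- c(q, k); r <- c(r, l)
      if (kind == "difference") {
        # self part: from +U_i(theta_i)
        amp <- c(amp, -2 * pi * zv(k) * uv(l) * sv(k + l))
        p <- c(p, k + l); q <- c(q, k + l); r <- c(r, 0L)
      }
    }
  }
  phase_coupling(amp, p, q, r, amp_tol = amp_tol, kind = kind)
}

#' Evaluate a coupling function
#'
#' @param pc a `phase_coupling`.
#' @param eta contact midpoint(s), radians.
#' @param phi_i,phi_j phase(s).  Arguments recycle.
#' @return numeric vector of `Gamma_ij` values.
#' @export
gamma_eval <- function(pc, eta, phi_i, phi_j) {
  out <- 0
  for (t in seq_len(nrow(pc))) {
    out <- out + pc$amp[t] *
      sin(pc$p[t] * eta - pc$q[t] * phi_i - pc$r[t] * phi_j)
  }
  out
}

#' Coupling function by direct quadrature (brute-force oracle)
#'
#' Evaluates `Gamma_ij(phi_i, phi_j) = <Z0(theta - phi_i), H_ij^S>` directly
#' by Gauss-Legendre quadrature over the contact surface, with the steady
#' pattern and adjoint mode evaluated by trigonometric interpolation.  This
#' is the independent check on [gamma_from_fourier()].
#'
#' @param cell a `reduced_cell` with `Z0`.
#' @param edge list with `eta_ij`, `eta_ji`, `d` describing the contact.
#' @param kind `"difference"` or `"pure_inhibition"`.
#' @param grid_n lattice resolution: `Gamma` is returned on a
#'   `grid_n x grid_n` grid of (phi_i, phi_j) in [0, 2pi).
#' @param quad_n Gauss-Legendre node count on the contact arc.
#' @return list with `phi` (grid), `gamma` (`grid_n x grid_n` matrix,
#'   rows phi_i, columns phi_j).
#' @export
gamma_direct <- function(cell, edge, kind = c("difference",
                                              "pure_inhibition"),
                         grid_n = 64, quad_n = 64) {
  kind <- match.arg(kind)
  stopifnot(inherits(cell, "reduced_cell"), !is.null(cell$Z0))
  eta <- edge$eta_ij
  eta_ji <- if (!is.null(edge$eta_ji)) edge$eta_ji else
    wrap_angle(eta + pi)
  d <- edge$d
  gl <- .gauss_legendre(quad_n, eta - d / 2, eta + d / 2)
  th_q <- gl$nodes                     # theta_i quadrature points
  th_star <- eta_ji + eta - th_q       # facing points on cell j
  phi <- 2 * pi * (0:(grid_n - 1)) / grid_n
  # Z0^U(theta_q - phi_i) and U^S(theta_q - phi_i): quad_n x grid_n
  pts_i <- outer(th_q, phi, "-")
  Zm <- matrix(.trig_eval(cell$Z0[, 1], as.vector(pts_i)), quad_n)
  Um <- matrix(.trig_eval(cell$XS[, 1], as.vector(pts_i)), quad_n)
  pts_j <- outer(th_star, phi, "-")
  Uj <- matrix(.trig_eval(cell$XS[, 1], as.vector(pts_j)), quad_n)
  w <- gl$weights
  cross <- -crossprod(Zm * w, Uj)      # grid_n x grid_n: -<Z, U_j*>
  g <- cross
  if (kind == "difference") {
    self <- colSums(Zm * Um * w)       # depends on phi_i only
    g <- g + matrix(self, grid_n, grid_n)
  }
  list(phi = phi, gamma = g)
}

#' Full reduction pipeline for a model
#'
#' Convenience wrapper: steady state, adjoint zero mode, Fourier
#' coefficients, and a coupling-function factory.
#'
#' @param model a `reaction_model`.
#' @param n_theta grid size.
#' @param K Fourier truncation order.
#' @param ... passed to [find_steady_state()].
#' @return list with `cell` (a `reduced_cell` incl. `Z0`), `fourier`
#'   (a `fourier_data`) and `coupling(d, kind, amp_tol)`, a function
#'   returning the `phase_coupling` for a contact width.
#' @export
reduce_model <- function(model, n_theta = 256, K = 8, ...) {
  cell <- find_steady_state(model, n_theta = n_theta, ...)
  cell <- adjoint_zero_mode(model, cell)
  fd <- fourier_coefficients(cell, K = K)
  list(model = model, cell = cell, fourier = fd,
       coupling = function(d, kind = "difference", amp_tol = 1e-4) {
         gamma_from_fourier(fd, d, kind = kind, amp_tol = amp_tol)
       })
}

#' @export
print.phase_coupling <- function(x, ...) {
  cat("<phase_coupling> kind =", attr(x, "kind"), "\n")
  for (t in seq_len(nrow(x))) {
    term <- sprintf("%+.5f sin(%d eta %+d phi_i %+d phi_j)",
                    x$amp[t], x$p[t], -x$q[t], -x$r[t])
    cat("  ", term, "\n")
  }
  invisible(x)
}

#' @export
print.reduced_cell <- function(x, ...) {
  cat("<reduced_cell>", x$model$name, "on", x$n_theta, "points\n")
  cat("  residual:   ", format(x$residual), "\n")
  cat("  first mode C:", format(x$C), "\n")
  cat("  adjoint mode:", if (is.null(x$Z0)) "not computed" else "computed",
      "\n")
  invisible(x)
}
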