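#' Reduced phase model specification
#'
#' Bundles a tissue graph with a coupling function (possibly per contact
#' width), the coupling strength, and optional external signal and noise,
#' into the right-hand side
#' `dphi_i/dt = eps * sum_j (1 + alpha_ij) Gamma_ij(phi_i, phi_j)
#' + eps_e * Pi_i(phi_i) + q_i(t)`.
#'
#' @param tissue a `tissue_graph`.
#' @param coupling a single `phase_coupling` (used for every edge), or a
#'   function `function(d)` returning the coupling for a contact width.
#' @param epsilon coupling strength; defaults to 1, the convention for
#'   phase-level runs.
#' @param signal optional list `list(eps_e =, psi =, amplitude =)`:
#'   `Pi_i = amplitude * sin(psi - phi_i)` with `psi` a constant or a
#'   function of time.  For first-harmonic adjoint modes
#'   `amplitude = -2 pi z_1` (see [signal_amplitude()]).
#' @param noise optional list: either `list(nu =)` (phase-level intensity)
#'   or `list(nu_m =, cell =)` from which `nu` is derived via
#'   [noise_variance()].
#' @return object of class `phase_model`.
#' @export
phase_model <- function(tissue, coupling, epsilon = 1, signal = NULL,
                        noise = NULL) {
  stopifnot(inherits(tissue, "tissue_graph"))
  e <- tissue$edges
  widths <- unique(round(e$d, 10))
  cfun <- if (inherits(coupling, "phase_coupling")) {
    function(d) coupling
  } else if (is.function(coupling)) {
    coupling
  } else {
    stop("coupling must be a phase_coupling or a function of the width")
  }
  per_width <- lapply(widths, cfun)
  for (pc in per_width) {
    if (!inherits(pc, "phase_coupling")) {
      stop("coupling function must return phase_coupling objects")
    }
  }
  wid_id <- match(round(e$d, 10), widths)
  nu <- 0
  if (!is.null(noise)) {
    nu <- if (!is.null(noise$nu)) noise$nu else
      noise_variance(noise$nu_m, noise$cell)
    if (nu < 0) stop("noise intensity must be >= 0")
  }
  if (!is.null(signal)) {
    if (is.null(signal$amplitude)) stop("signal needs an amplitude")
    if (!is.function(signal$psi)) {
      psi0 <- signal$psi
      signal$psi <- function(t) psi0
    }
  }
  structure(list(tissue = tissue, couplings = per_width, width_id = wid_id,
                 epsilon = epsilon, signal = signal, nu = nu),
            class = "phase_model")
}

#' Right-hand side of the phase model
#'
#' @param phi per-cell phases.
#' @param spec a `phase_model`.
#' @param t time (used by time-dependent signals).
#' @return per-cell deterministic rates.
#' @export
phase_rhs <- function(phi, spec, t = 0) {
  stopifnot(inherits(spec, "phase_model"))
  e <- spec$tissue$edges
  N <- nrow(spec$tissue$cells)
  rate <- numeric(N)
  if (nrow(e) > 0 && spec$epsilon != 0) {
    pre <- spec$epsilon * (1 + e$alpha)
    gi <- numeric(nrow(e))
    for (w in seq_along(spec$couplings)) {
      idx <- which(spec$width_id == w)
      if (!length(idx)) next
      pc <- spec$couplings[[w]]
      eta <- e$eta[idx]; pi_ <- phi[e$i[idx]]; pj_ <- phi[e$j[idx]]
      acc <- numeric(length(idx))
      for (tt in seq_len(nrow(pc))) {
        acc <- acc + pc$amp[tt] *
          sin(pc$p[tt] * eta - pc$q[tt] * pi_ - pc$r[tt] * pj_)
      }
      gi[idx] <- acc
    }
    contrib <- pre * gi
    sums <- rowsum(contrib, group = e$i, reorder = FALSE)
    rate[as.integer(rownames(sums))] <- sums[, 1]
  }
  if (!is.null(spec$signal)) {
    s <- spec$signal
    rate <- rate + s$eps_e * s$amplitude * sin(s$psi(t) - phi)
  }
  rate
}

#' Integrate the phase model
#'
#' Deterministic runs use an embedded Dormand-Prince RK45 pair with
#' adaptive step control; stochastic runs (`nu > 0`) use Euler-Maruyama
#' with per-step Gaussian increments of variance `nu * dt` and require a
#' seed.  Output phases are wrapped to (-pi, pi].
#'
#' @param spec a `phase_model`.
#' @param init initial phases (length = number of cells).
#' @param T_end horizon.
#' @param dt Euler-Maruyama step (stochastic runs); ignored for
#'   deterministic runs.
#' @param sample_dt spacing of saved samples (default `T_end/200`).
#' @param seed RNG seed, required iff `nu > 0`.
#' @param atol,rtol error control for the adaptive integrator.
#' @return object of class `phase_trajectory`: list with `time`, `phi`
#'   (matrix time x cell, wrapped), `seed`, `spec`.
#' @export
integrate_phase <- function(spec, init, T_end, dt = 0.01,
                            sample_dt = NULL, seed = NULL,
                            atol = 1e-8, rtol = 1e-6) {
  stopifnot(inherits(spec, "phase_model"))
  N <- nrow(spec$tissue$cells)
  stopifnot(length(init) == N)
  if (is.null(sample_dt)) sample_dt <- T_end / 200
  times <- seq(0, T_end, by = sample_dt)
  if (times[length(times)] < T_end - 1e-12) times <- c(times, T_end)
  if (spec$nu > 0) {
    if (is.null(seed)) stop("stochastic runs require a seed")
    out <- .integrate_em(spec, init, times, dt, seed)
  } else {
    out <- .integrate_rk45(spec, init, times, atol, rtol)
  }
  structure(list(time = times, phi = wrap_angle(out), phi_unwrapped = out,
                 seed = seed, spec = spec),
            class = "phase_trajectory")
}

.integrate_em <- function(spec, init, times, dt, seed) {
  set.seed(seed)
  N <- length(init)
  sd_step <- sqrt(spec$nu * dt)
  phi <- init
  out <- matrix(NA_real_, length(times), N)
  out[1, ] <- phi
  t_now <- 0
  for (s in 2:length(times)) {
    t_target <- times[s]
    while (t_now < t_target - 1e-12) {
      h <- min(dt, t_target - t_now)
      phi <- phi + h * phase_rhs(phi, spec, t_now) +
        sd_step * sqrt(h / dt) * stats::rnorm(N)
      t_now <- t_now + h
      if (any(!is.finite(phi))) stop("non-finite state at t = ", t_now)
    }
    out[s, ] <- phi
  }
  out
}

# Dormand-Prince 5(4) embedded pair with PI step control.
.integrate_rk45 <- function(spec, init, times, atol, rtol) {
  A <- list(c(1 / 5),
            c(3 / 40, 9 / 40),
            c(44 / 45, -56 / 15, 32 / 9),
            c(19372 / 6561, -25360 / 2187, 64448 / 6561, -212 / 729),
            c(9017 / 3168, -355 / 33, 46732 / 5247, 49 / 176,
              -5103 / 18656),
            c(35 / 384, 0, 500 / 1113, 125 / 192, -2187 / 6784, 11 / 84))
  b5 <- c(35 / 384, 0, 500 / 1113, 125 / 192, -2187 / 6784, 11 / 84, 0)
  b4 <- c(5179 / 57600, 0, 7571 / 16695, 393 / 640, -92097 / 339200,
          187 / 2100, 1 / 40)
  cs <- c(0, 1 / 5, 3 / 10, 4 / 5, 8 / 9, 1, 1)
  N <- length(init)
  phi <- init
  out <- matrix(NA_real_, length(times), N)
  out[1, ] <- phi
  t_now <- times[1]
  h <- min(0.1, diff(range(times)) / 100)
  k1 <- phase_rhs(phi, spec, t_now)
  for (s in 2:length(times)) {
    t_target <- times[s]
    while (t_now < t_target - 1e-12) {
      h <- min(h, t_target - t_now)
      ks <- matrix(0, 7, N)
      ks[1, ] <- k1
      for (st in 2:7) {
        a <- if (st <= 6) A[[st - 1]] else b5[1:6]
        inc <- colSums(ks[seq_along(a), , drop = FALSE] * a)
        ks[st, ] <- phase_rhs(phi + h * inc, spec, t_now + cs[st] * h)
      }
      phi5 <- phi + h * colSums(ks * b5)
      phi4 <- phi + h * colSums(ks * b4)
      sc <- atol + rtol * pmax(abs(phi), abs(phi5))
      err <- sqrt(mean(((phi5 - phi4) / sc)^2))
      if (!is.finite(err)) stop("non-finite state at t = ", t_now)
      if (err <= 1) {
        t_now <- t_now + h
        phi <- phi5
        k1 <- ks[7, ]  # FSAL
      }
      h <- h * min(5, max(0.2, 0.9 * (if (err > 0) err^(-0.2) else 5)))
    }
    out[s, ] <- phi
  }
  out
}

#' Polarity order parameter
#'
#' Modulus and argument of the population-mean phasor
#' `Q e^{i Phi} = mean(e^{i phi_j})`.
#'
#' @param phi phase vector.
#' @return named vector `c(Q =, Phi =)`; `Phi` is an error when
#'   `Q < 1e-12`.
#' @export
order_parameter <- function(phi) {
  stopifnot(length(phi) >= 1)
  z <- mean(exp(1i * phi))
  Q <- Mod(z)
  if (Q < 1e-12) stop("order parameter modulus ~ 0: mean phase undefined")
  c(Q = Q, Phi = wrap_angle(Arg(z)))
}

#' Potential of a gradient-type phase model
#'
#' For couplings containing only the canonical `a`, `b`, `bprime`, `c`
#' terms the phase model is a gradient system `dphi/dt = -dH/dphi + q` with
#' `H = -(eps/2) sum_i sum_{j in A(i)} (1+alpha_ij) {a cos(phi_j - phi_i)
#' + b cos 2(eta_ij - phi_i) + 2 bprime cos(eta_ij - phi_i)
#' + c cos(2 eta_ij - phi_i - phi_j)} - eps_e sum_i amplitude *
#' cos(psi - phi_i)`.  Couplings with other harmonics are refused.
#'
#' @param phi phase vector.
#' @param spec a `phase_model`.
#' @param t time (for time-dependent signals).
#' @return scalar potential value.
#' @export
phase_potential <- function(phi, spec, t = 0) {
  stopifnot(inherits(spec, "phase_model"))
  allowed <- rbind(c(0, 1, -1), c(2, 2, 0), c(1, 1, 0), c(2, 1, 1))
  for (pc in spec$couplings) {
    keys <- cbind(pc$p, pc$q, pc$r)
    ok <- apply(keys, 1, function(k)
      any(apply(allowed, 1, function(a) all(a == k))))
    if (!all(ok)) {
      stop("coupling contains non-gradient terms beyond the a/b/b'/c ",
           "family; no potential is defined")
    }
  }
  e <- spec$tissue$edges
  H <- 0
  if (nrow(e) > 0) {
    for (w in seq_along(spec$couplings)) {
      idx <- which(spec$width_id == w)
      if (!length(idx)) next
      co <- coupling_coef(spec$couplings[[w]])
      eta <- e$eta[idx]; pi_ <- phi[e$i[idx]]; pj_ <- phi[e$j[idx]]
      pre <- 1 + e$alpha[idx]
      H <- H - spec$epsilon / 2 * sum(pre * (
        co["a"] * cos(pj_ - pi_) +
          co["b"] * cos(2 * (eta - pi_)) +
          2 * co["bprime"] * cos(eta - pi_) +
          co["c"] * cos(2 * eta - pi_ - pj_)))
    }
  }
  if (!is.null(spec$signal)) {
    s <- spec$signal
    H <- H - s$eps_e * s$amplitude * sum(cos(s$psi(t) - phi))
  }
  H
}

#' Boltzmann stationary density of the noisy gradient phase model
#'
#' For a gradient-type spec with noise intensity `nu`, the stationary
#' density is `P({phi_i}) = C exp(-2 H({phi_i}) / nu)`.  Evaluated by
#' quadrature on a regular lattice of phase configurations; guarded to
#' N <= 3 cells.
#'
#' @param spec a `phase_model` (gradient type).
#' @param nu noise intensity (overrides the spec's).
#' @param grid_n lattice points per phase dimension.
#' @return list with `phi` (marginal grid), `joint` (N-dim array),
#'   `marginals` (list of per-cell marginal densities on `phi`), each
#'   normalised to integrate to 1.
#' @export
stationary_density <- function(spec, nu = NULL, grid_n = 120) {
  stopifnot(inherits(spec, "phase_model"))
  N <- nrow(spec$tissue$cells)
  if (N > 3) stop("stationary_density is limited to N <= 3 cells")
  if (is.null(nu)) nu <- spec$nu
  stopifnot(nu > 0)
  g <- 2 * pi * (0:(grid_n - 1)) / grid_n - pi
  dg <- 2 * pi / grid_n
  grids <- rep(list(g), N)
  conf <- as.matrix(expand.grid(grids))
  # vectorised H over all configurations (validated against
  # phase_potential(), which also performs the gradient-type check)
  phase_potential(conf[1, ], spec)
  e <- spec$tissue$edges
  Hv <- numeric(nrow(conf))
  if (nrow(e) > 0) {
    for (w in seq_along(spec$couplings)) {
      idx <- which(spec$width_id == w)
      if (!length(idx)) next
      co <- coupling_coef(spec$couplings[[w]])
      for (ei in idx) {
        eta <- e$eta[ei]
        pi_ <- conf[, e$i[ei]]; pj_ <- conf[, e$j[ei]]
        pre <- 1 + e$alpha[ei]
        Hv <- Hv - spec$epsilon / 2 * pre * (
          co[["a"]] * cos(pj_ - pi_) +
            co[["b"]] * cos(2 * (eta - pi_)) +
            2 * co[["bprime"]] * cos(eta - pi_) +
            co[["c"]] * cos(2 * eta - pi_ - pj_))
      }
    }
  }
  if (!is.null(spec$signal)) {
    s <- spec$signal
    for (i in seq_len(N)) {
      Hv <- Hv - s$eps_e * s$amplitude * cos(s$psi(0) - conf[, i])
    }
  }
  Hv <- Hv - min(Hv)
  P <- exp(-2 * Hv / nu)
  P <- P / (sum(P) * dg^N)
  joint <- array(P, dim = rep(grid_n, N))
  marginals <- lapply(seq_len(N), function(i) {
    m <- apply(joint, i, sum) * dg^(N - 1)
    m
  })
  list(phi = g, joint = joint, marginals = marginals)
}

#' Two-cell in-phase fixed points and stability
#'
#' For a straight pair (`eta_12 = 0`, `eta_21 = pi`) with coupling
#' coefficients `a`, `b`, `c`, the in-phase states `phi* = 0, pi, +/-pi/2`
#' are steady; in the sum/difference coordinates `xi = phi_1 + phi_2`,
#' `zeta = phi_1 - phi_2` the linearised rates are
#' `-2 eps (b + c) cos(2 phi*)` and `-2 eps (a + b cos(2 phi*))`.
#'
#' @param a,b,c coupling coefficients.
#' @param epsilon coupling strength.
#' @return data.frame with `phi_star`, `lambda_xi`, `lambda_zeta`,
#'   `stable` (both eigenvalues negative), `neutral` (an eigenvalue is 0).
#' @export
two_cell_analysis <- function(a, b, c, epsilon = 1) {
  phi_star <- c(0, pi, pi / 2, -pi / 2)
  l_xi <- -2 * epsilon * (b + c) * cos(2 * phi_star)
  l_zeta <- -2 * epsilon * (a + b * cos(2 * phi_star))
  data.frame(phi_star = phi_star,
             lambda_xi = l_xi,
             lambda_zeta = l_zeta,
             stable = l_xi < 0 & l_zeta < 0,
             neutral = l_xi == 0 | l_zeta == 0)
}

#' In-phase effective field
#'
#' Under the approximation that neighbours share the cell's phase, the
#' model reduces to `dphi_i/dt = eps R_i sin 2(eta_bar_i - phi_i)` with
#' `R_i e^{i 2 eta_bar_i} = sum_{j in A(i)} (b_ij + c_ij) e^{i 2 eta_ij}`:
#' the effective strength and preferred axis of the net geometric drive.
#'
#' @param tissue a `tissue_graph`.
#' @param coupling as in [phase_model()].
#' @return data.frame with per-cell `R` (>= 0) and `eta_bar` (radians, in
#'   (-pi/2, pi/2]; the axis is defined mod pi).
#' @export
in_phase_effective_field <- function(tissue, coupling) {
  spec <- phase_model(tissue, coupling, epsilon = 1)
  e <- tissue$edges
  bc <- vapply(spec$couplings, function(pc) {
    co <- coupling_coef(pc)
    co["b"] + co["c"]
  }, numeric(1))
  w <- bc[spec$width_id]
  z <- w * exp(2i * e$eta)
  N <- nrow(tissue$cells)
  out <- data.frame(R = numeric(N), eta_bar = numeric(N))
  agg <- rowsum(cbind(Re(z), Im(z)), group = e$i, reorder = FALSE)
  idx <- as.integer(rownames(agg))
  zz <- complex(real = agg[, 1], imaginary = agg[, 2])
  out$R[idx] <- Mod(zz)
  eb <- Arg(zz) / 2
  # report the axis representative in (-pi/2, pi/2]
  eb <- wrap_angle(eb)
  eb[eb <= -pi / 2] <- eb[eb <= -pi / 2] + pi
  eb[eb > pi / 2] <- eb[eb > pi / 2] - pi
  out$eta_bar[idx] <- eb
  out
}

#' Axial-asymmetry alignment rates
#'
#' `elongation_lambda` evaluates the closed-form elongation coefficient
#' `lambda(delta) = sin(delta)/(4pi) + delta/(4pi)
#'  - 2 (sin((pi-delta)/2)/(4pi) + (pi-delta)/(8pi)) sin(delta/2)`
#' of a uniformly elongated hexagonal sheet; the in-phase dynamics is
#' `dphi/dt = -2 eps lambda sin 2 phi`, so `lambda > 0` stabilises
#' `phi in {0, pi}` and `lambda < 0` stabilises `phi = +/-pi/2`
#' (`lambda(pi/3) = 0`: neutral).  `heterogeneity_rate` gives the analogous
#' rate coefficient `2 alpha (b + c)` of vertical-surface coupling
#' heterogeneity.  `axial_asymmetry_rates` combines both.
#'
#' @param delta axis-facing edge width, radians.
#' @return `lambda` (scalar) / rate coefficient / named list.
#' @export
elongation_lambda <- function(delta) {
  stopifnot(delta > 0, delta < pi)
  sin(delta) / (4 * pi) + delta / (4 * pi) -
    2 * (sin((pi - delta) / 2) / (4 * pi) + (pi - delta) / (8 * pi)) *
      sin(delta / 2)
}

#' @rdname elongation_lambda
#' @param alpha heterogeneity value.
#' @param b,c coupling coefficients.
#' @export
heterogeneity_rate <- function(alpha, b, c) {
  2 * alpha * (b + c)
}

#' @rdname elongation_lambda
#' @export
axial_asymmetry_rates <- function(delta = NULL, alpha = NULL, b = NULL,
                                  c = NULL) {
  out <- list()
  if (!is.null(delta)) out$lambda <- elongation_lambda(delta)
  if (!is.null(alpha)) {
    stopifnot(!is.null(b), !is.null(c))
    out$heterogeneity_rate <- heterogeneity_rate(alpha, b, c)
  }
  out
}

#' Phase-level noise intensity from species-level noise
#'
#' Projects per-species space-time white noise intensities onto the phase:
#' `nu = sum_m nu_m int_0^{2pi} (Z0^(m)(theta))^2 dtheta`.
#'
#' @param nu_m per-species intensities.
#' @param cell a `reduced_cell` with the normalised adjoint mode `Z0`.
#' @return scalar phase-noise intensity.
#' @export
noise_variance <- function(nu_m, cell) {
  stopifnot(inherits(cell, "reduced_cell"), !is.null(cell$Z0))
  ns <- ncol(cell$Z0)
  nu_m <- rep_len(nu_m, ns)
  dth <- 2 * pi / cell$n_theta
  sum(vapply(seq_len(ns), function(m) nu_m[m] * dth * sum(cell$Z0[, m]^2),
             numeric(1)))
}

#' External-signal projection amplitude
#'
#' For a unimodal signal field `G = (cos(psi - theta), 0)` the phase-level
#' drive is `Pi = -2 pi z_1 sin(psi - phi)`; this returns the amplitude
#' `-2 pi z_1` (for the GLE: `1/(2 sqrt(1 - D0))`).
#'
#' @param fd a `fourier_data` (or a list with `z`).
#' @return scalar amplitude.
#' @export
signal_amplitude <- function(fd) {
  -2 * pi * fd$z[1]
}

#' Seeded initial phases
#'
#' @param kind `"uniform"` or `"constant"`.
#' @param n number of cells.
#' @param seed RNG seed (uniform draws).
#' @param lo,hi uniform bounds.
#' @param phi0 constant value.
#' @return numeric phase vector.
#' @export
initial_phases <- function(kind = c("uniform", "constant"), n, seed = NULL,
                           lo = -pi / 2, hi = pi / 2, phi0 = 0) {
  kind <- match.arg(kind)
  if (kind == "uniform") {
    if (lo >= hi) stop("need lo < hi")
    if (!is.null(seed)) set.seed(seed)
    stats::runif(n, lo, hi)
  } else {
    rep(phi0, n)
  }
}

#' @export
print.phase_model <- function(x, ...) {
  cat("<phase_model>", nrow(x$tissue$cells), "cells,",
      nrow(x$tissue$edges), "edges, epsilon =", x$epsilon, "\n")
  cat("  noise nu =", x$nu, "| signal:",
      if (is.null(x$signal)) "none" else "present", "\n")
  invisible(x)
}

#' @export
print.phase_trajectory <- function(x, ...) {
  cat("<phase_trajectory>", ncol(x$phi), "cells,", length(x$time),
      "samples, t in [0,", max(x$time), "]\n")
  invisible(x)
}
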