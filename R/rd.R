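#' Facing point on a neighbouring cell boundary
#'
#' Two adjacent counter-clockwise-parametrised cell boundaries run
#' antiparallel along their shared contact surface, so the point of cell j
#' that faces `theta_i` of cell i is
#' `theta_j* = wrap(eta_ji - (theta_i - eta_ij))`.
#'
#' @param eta_ij,eta_ji contact-surface midpoints on the two cells, radians.
#' @param theta_i position on cell i, radians.
#' @param d_ij optional contact width; when given, `theta_i` outside the
#'   contact surface is an error.
#' @return theta_j* in \[0, 2pi).
#' @export
#' @examples
#' facing_point(0, pi, 0.1)  # pi - 0.1
facing_point <- function(eta_ij, eta_ji, theta_i, d_ij = NULL) {
  if (!is.null(d_ij)) {
    if (any(abs(wrap_angle(theta_i - eta_ij)) > d_ij / 2)) {
      stop("theta_i lies outside the contact surface")
    }
  }
  (eta_ji - (theta_i - eta_ij)) %% (2 * pi)
}

#' Contact-surface indicator
#'
#' 1 where the wrapped angular distance from the contact midpoint is less
#' than half the contact width, 0 elsewhere.
#'
#' @param eta contact midpoint, radians.
#' @param d contact width, radians, in (0, 2pi).
#' @param theta positions, radians.
#' @return integer vector of 0/1.
#' @export
contact_indicator <- function(eta, d, theta) {
  stopifnot(d > 0, d < 2 * pi)
  as.integer(abs(wrap_angle(theta - eta)) < d / 2)
}

#' Contact interaction between two cells
#'
#' Evaluates the interaction field `H_ij(theta)` on the grid of cell i for
#' one directed edge.  The interaction acts on the activator only and
#' vanishes off the contact surface: `"difference"` gives
#' `S_ij(theta) (U_i(theta) - U_j(theta_j*))`, `"pure_inhibition"` gives
#' `S_ij(theta) (-U_j(theta_j*))`.  The neighbour's activator is evaluated
#' at the facing points by trigonometric (spectral) interpolation.
#'
#' @param kind `"difference"` or `"pure_inhibition"`.
#' @param edge list with `eta_ij`, `eta_ji`, `d`.
#' @param field_i,field_j `n x s` fields of the two cells (shared grid).
#' @return `n x s` matrix: the interaction field (nonzero first column
#'   only).
#' @export
coupling_term <- function(kind = c("difference", "pure_inhibition"), edge,
                          field_i, field_j) {
  kind <- match.arg(kind)
  if (!all(dim(field_i) == dim(field_j))) {
    stop("fields must share a grid")
  }
  n <- nrow(field_i)
  th <- ring_grid(n)
  mask <- contact_indicator(edge$eta_ij, edge$d, th)
  eta_ji <- if (!is.null(edge$eta_ji)) edge$eta_ji else
    wrap_angle(edge$eta_ij + pi)
  cshift <- edge$eta_ij + eta_ji       # theta_j* = cshift - theta
  ustar <- .u_at_facing(field_j[, 1], cshift)
  H <- matrix(0, n, ncol(field_i))
  H[, 1] <- if (kind == "difference") mask * (field_i[, 1] - ustar) else
    mask * (-ustar)
  H
}

# Neighbour activator at the facing points c - theta_m.  When c is a grid
# multiple the reflection is an exact index permutation (always the case
# for straight chains, where eta in {0, pi} gives c = pi); otherwise the
# spectral reflect-shift is used.
.u_at_facing <- function(u, cshift) {
  n <- length(u)
  dth <- 2 * pi / n
  m <- cshift / dth
  if (abs(m - round(m)) < 1e-12) {
    idx <- (round(m) - (0:(n - 1))) %% n
    u[idx + 1]
  } else {
    .reflect_shift(u, cshift)
  }
}

#' Initial tissue fields
#'
#' `tissue_init_steady` places the steady pattern in every cell with
#' per-cell polarity angles (shifted spectrally); `tissue_init_pattern`
#' gives the homogeneous state plus a small unimodal perturbation (the
#' pattern-formation init).
#'
#' @param cell a `reduced_cell`.
#' @param phases per-cell polarity angles.
#' @return `n_theta x n_species x N` array.
#' @export
tissue_init_steady <- function(cell, phases) {
  n <- cell$n_theta; ns <- ncol(cell$XS)
  out <- array(0, c(n, ns, length(phases)))
  for (i in seq_along(phases)) {
    # X_i(theta) = X^S(theta - phi_i): shift the pattern by -phi_i
    out[, , i] <- apply(cell$XS, 2, .spectral_shift, s = -phases[i])
  }
  out
}

#' @rdname tissue_init_steady
#' @param model a `reaction_model`.
#' @param n_theta grid size.
#' @param phi0 per-cell perturbation directions (recycled to N).
#' @param N number of cells.
#' @export
tissue_init_pattern <- function(model, n_theta, N, phi0 = 0) {
  th <- ring_grid(n_theta)
  phi0 <- rep_len(phi0, N)
  out <- array(0, c(n_theta, model$n_species, N))
  for (i in seq_len(N)) {
    out[, , i] <- .default_pattern_init(model, th, phi0[i])
  }
  out
}

#' Integrate the coupled reaction-diffusion tissue model
#'
#' Advances `dX_i/dt = F(X_i) + D d2X_i/dtheta_i^2 +
#' eps * sum_j H_ij + eps_e G_i + p_i` for every cell of a tissue.  Time
#' stepping is Lie splitting: reaction, coupling, signal and noise advance
#' by an explicit (Euler / Euler-Maruyama) step, then diffusion is applied
#' spectrally with the exact `exp(-D k^2 dt)` factor per wavenumber.
#' Space-time white noise is discretised as independent Gaussians per grid
#' cell with variance `nu_m / (dtheta * dt)`.
#'
#' @param tissue a `tissue_graph`.
#' @param model a `reaction_model`.
#' @param epsilon coupling strength (a warning is given above
#'   `eps_warn`).
#' @param init `n_theta x n_species x N` array of initial fields.
#' @param T_end,dt integration horizon and splitting step.
#' @param kind contact coupling kind.
#' @param noise optional list `list(nu = c(nu_1, ...), seed =)`.
#' @param signal optional list `list(eps_e =, psi =)`; the signal field is
#'   `G_i = (cos(psi - theta), 0)` with `psi` a constant or a function of
#'   time.
#' @param sample_dt spacing of saved samples (defaults to 50 steps).
#' @param keep_fields if `TRUE` the full fields at sample times are kept.
#' @param eps_warn warn threshold for `epsilon`.
#' @param tol_C phase-extraction tolerance passed to [extract_phase()].
#' @return object of class `rd_trajectory`: list with `time`, `phase`
#'   (matrix time x cell, wrapped to (-pi, pi\]), `C` (first-mode
#'   magnitudes), `final` (final fields), optional `fields`, and metadata
#'   (`dt`, `seed`, `model`, `kind`).
#' @export
integrate_tissue_rd <- function(tissue, model, epsilon, init, T_end, dt,
                                kind = c("difference", "pure_inhibition"),
                                noise = NULL, signal = NULL,
                                sample_dt = NULL, keep_fields = FALSE,
                                eps_warn = 0.1, tol_C = 1e-8) {
  kind <- match.arg(kind)
  stopifnot(inherits(tissue, "tissue_graph"),
            inherits(model, "reaction_model"))
  if (abs(epsilon) > eps_warn) {
    warning("epsilon = ", epsilon, " is outside the weak-coupling regime ",
            "the reduction assumes")
  }
  N <- nrow(tissue$cells)
  n <- dim(init)[1]; ns <- dim(init)[2]
  stopifnot(dim(init)[3] == N, ns == model$n_species, n %% 2 == 0, n >= 64)
  th <- ring_grid(n)
  dth <- 2 * pi / n
  n_steps <- ceiling(T_end / dt - 1e-9)
  if (is.null(sample_dt)) sample_dt <- 50 * dt
  stride <- max(1L, round(sample_dt / dt))
  edges <- tissue$edges
  masks <- lapply(seq_len(nrow(edges)), function(e)
    contact_indicator(edges$eta[e], edges$d[e], th) == 1L)
  eta_rev <- wrap_angle(edges$eta + pi)
  # eta_ji of the reverse edge equals eta_ij + pi for all generated
  # tissues; facing shift c = eta_ij + eta_ji
  cshifts <- edges$eta + edges$eta + pi

  have_noise <- !is.null(noise) && any(noise$nu > 0)
  if (have_noise) {
    if (is.null(noise$seed)) stop("noise requires a seed")
    set.seed(noise$seed)
    nu <- rep_len(noise$nu, ns)
    noise_sd <- sqrt(nu / (dth * dt)) * sqrt(dt)  # per-step increment sd
  }
  psi_fun <- NULL
  if (!is.null(signal)) {
    psi_fun <- if (is.function(signal$psi)) signal$psi else
      function(t) signal$psi
  }

  k2 <- .wavenumbers(n)^2
  damp <- exp(-outer(k2, model$diffusion) * dt)
  X <- init
  sample_times <- numeric(0)
  phases <- list(); Cs <- list(); fields <- list()
  record <- function(t_now) {
    ph <- numeric(N); Cv <- numeric(N)
    for (i in seq_len(N)) {
      pc <- extract_phase(X[, , i], tol_C = tol_C)
      ph[i] <- pc[1]; Cv[i] <- pc[2]
    }
    sample_times <<- c(sample_times, t_now)
    phases[[length(phases) + 1L]] <<- ph
    Cs[[length(Cs) + 1L]] <<- Cv
    if (keep_fields) fields[[length(fields) + 1L]] <<- X
  }
  record(0)
  t_now <- 0
  for (step in seq_len(n_steps)) {
    dX <- array(0, c(n, ns, N))
    for (i in seq_len(N)) dX[, , i] <- model$reaction(X[, , i])
    if (epsilon != 0 && nrow(edges) > 0) {
      for (e in seq_len(nrow(edges))) {
        i <- edges$i[e]; j <- edges$j[e]
        mask <- masks[[e]]
        ustar <- .u_at_facing(X[, 1, j], cshifts[e])
        h <- if (kind == "difference") X[mask, 1, i] - ustar[mask] else
          -ustar[mask]
        dX[mask, 1, i] <- dX[mask, 1, i] +
          epsilon * (1 + edges$alpha[e]) * h
      }
    }
    if (!is.null(psi_fun)) {
      g <- cos(psi_fun(t_now) - th) * signal$eps_e
      for (i in seq_len(N)) dX[, 1, i] <- dX[, 1, i] + g
    }
    X <- X + dt * dX
    if (have_noise) {
      for (m in seq_len(ns)) {
        if (noise_sd[m] > 0) {
          X[, m, ] <- X[, m, ] + noise_sd[m] * stats::rnorm(n * N)
        }
      }
    }
    for (i in seq_len(N)) {
      X[, , i] <- Re(stats::mvfft(stats::mvfft(X[, , i]) * damp,
                                  inverse = TRUE)) / n
    }
    if (any(!is.finite(X))) {
      stop("instability detected: non-finite values at t = ",
           signif(t_now, 6))
    }
    t_now <- step * dt
    if (step %% stride == 0L || step == n_steps) record(t_now)
  }
  structure(list(time = sample_times,
                 phase = do.call(rbind, phases),
                 C = do.call(rbind, Cs),
                 final = X,
                 fields = if (keep_fields) fields else NULL,
                 dt = dt, n_theta = n, epsilon = epsilon, kind = kind,
                 seed = if (have_noise) noise$seed else NULL,
                 model = model$name),
            class = "rd_trajectory")
}

#' @export
print.rd_trajectory <- function(x, ...) {
  cat("<rd_trajectory>", x$model, "-", ncol(x$phase), "cells,",
      length(x$time), "samples, t in [0,", max(x$time), "]\n")
  invisible(x)
}
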