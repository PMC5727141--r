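test_that("phase_rhs vanishes at the documented fixed points", {
  tg <- tissue_chain(2)
  spec <- phase_model(tg, gle_closed_coupling(pi / 3))
  expect_equal(phase_rhs(c(0, 0), spec), c(0, 0), tolerance = 1e-15)
  # single cell, signal only, phi = psi
  tg1 <- tissue_chain(1)
  amp <- 1 / (2 * sqrt(1 - 0.2))
  s1 <- phase_model(tg1, gle_closed_coupling(pi / 3),
                    signal = list(eps_e = 0.3, psi = 1.1,
                                  amplitude = amp))
  expect_equal(phase_rhs(1.1, s1), 0)
  # signal amplitude from the adjoint mode: 1/(2 sqrt(1 - D0))
  red <- reduce_model(make_model("gle", list(D0 = 0.2)), n_theta = 128)
  expect_equal(signal_amplitude(red$fourier), amp, tolerance = 1e-6)
  expect_equal(amp, 0.559, tolerance = 1e-3)
})

test_that("heterogeneity enters the rhs as (1 + alpha)", {
  tg <- tissue_chain(2)
  tgh <- apply_heterogeneity(tg, alpha = 0.25, eta = c(0, pi))
  pc <- gle_closed_coupling(pi / 3)
  phi <- c(0.4, -0.2)
  r0 <- phase_rhs(phi, phase_model(tg, pc))
  r1 <- phase_rhs(phi, phase_model(tgh, pc))
  expect_equal(r1, 1.25 * r0, tolerance = 1e-12)
})

test_that("gradient identity: -dH/dphi equals the rhs", {
  tg <- tissue_hex_sheet(3, 4)
  tgh <- apply_heterogeneity(tg, alpha = 0.1, eta = c(0, pi))
  spec <- phase_model(tgh, gle_closed_coupling,
                      signal = list(eps_e = 0.05, psi = 0.9,
                                    amplitude = 0.5))
  N <- nrow(tg$cells)
  set.seed(5)
  h <- 1e-6
  for (rep in 1:100) {
    phi <- runif(N, -pi, pi)
    rhs <- phase_rhs(phi, spec)
    grad <- vapply(seq_len(N), function(i) {
      up <- phi; up[i] <- up[i] + h
      dn <- phi; dn[i] <- dn[i] - h
      (phase_potential(up, spec) - phase_potential(dn, spec)) / (2 * h)
    }, numeric(1))
    expect_lt(max(abs(rhs + grad)), 1e-6)
  }
})

test_that("potential refuses non-gradient couplings", {
  red <- cached_reduction("activator_inhibitor")
  tg <- tissue_chain(2)
  spec <- phase_model(tg, red$coupling(pi / 3))
  expect_error(phase_potential(c(0, 0), spec), "non-gradient")
  # but the dynamics still integrate the full term set
  tr <- integrate_phase(spec, c(0.4, -0.3), T_end = 10)
  expect_true(all(is.finite(tr$phi)))
})

test_that("potential basics: rotation invariance and orderings", {
  # XY limit: H depends only on phase differences
  tg <- tissue_hex_sheet(3, 3)
  xy <- phase_coupling(amp = sqrt(3) / (8 * pi), p = 0, q = 1, r = -1)
  spec <- phase_model(tg, xy)
  set.seed(8)
  phi <- runif(9, -pi, pi)
  expect_equal(phase_potential(phi, spec),
               phase_potential(phi + 1.234, spec), tolerance = 1e-12)
  # two GLE-coupled cells: aligned beats perpendicular
  tg2 <- tissue_chain(2)
  s2 <- phase_model(tg2, gle_closed_coupling(pi / 3))
  expect_lt(phase_potential(c(0, 0), s2),
            phase_potential(c(pi / 2, pi / 2), s2))
})

test_that("global rotational covariance of the integrated dynamics", {
  # shifting all phases and all contact midpoints by chi commutes with
  # the flow
  tg <- tissue_hex_sheet(3, 3)
  chi <- 0.77
  tg_rot <- tg
  tg_rot$edges$eta <- wrap_angle(tg$edges$eta + chi)
  red <- cached_reduction("gle")
  spec <- phase_model(tg, red$coupling(pi / 3))
  spec_rot <- phase_model(tg_rot, red$coupling(pi / 3))
  set.seed(21)
  phi0 <- runif(9, -1, 1)
  t1 <- integrate_phase(spec, phi0, T_end = 100, sample_dt = 20,
                        atol = 1e-12, rtol = 1e-12)
  t2 <- integrate_phase(spec_rot, phi0 + chi, T_end = 100, sample_dt = 20,
                        atol = 1e-12, rtol = 1e-12)
  expect_lt(max(abs(wrap_angle(t2$phi - t1$phi - chi))), 1e-8)
})

test_that("order_parameter handles the canonical cases", {
  expect_equal(order_parameter(rep(0.3, 7)), c(Q = 1, Phi = 0.3))
  expect_error(order_parameter(c(0, pi)), "undefined")
  expect_error(order_parameter(c(0, 2 * pi / 3, -2 * pi / 3)), "undefined")
  op <- order_parameter(c(0.1, 0.5))
  expect_equal(op[["Phi"]], 0.3, tolerance = 1e-12)
})

test_that("two_cell_analysis matches the numerical Jacobian", {
  a <- sin(pi / 3) / (4 * pi); b <- a; cc <- 1 / 12
  res <- two_cell_analysis(a, b, cc, epsilon = 1)
  expect_true(res$stable[res$phi_star == 0])
  expect_false(res$stable[res$phi_star == pi / 2])
  # epsilon sign flip inverts all rates
  res_neg <- two_cell_analysis(a, b, cc, epsilon = -1)
  expect_equal(res_neg$lambda_xi, -res$lambda_xi)
  expect_equal(res_neg$lambda_zeta, -res$lambda_zeta)
  # pure-inhibition limit b = 0: stability of (0,0) needs a > 0 and c > 0
  res_b0 <- two_cell_analysis(a, 0, cc, epsilon = 1)
  expect_true(res_b0$stable[1])
  expect_equal(res_b0$lambda_zeta[1], -2 * a)
  expect_equal(res_b0$lambda_xi[1], -2 * cc)
  # numerical Jacobian of the actual rhs in (xi, zeta) coordinates
  tg <- tissue_chain(2)
  spec <- phase_model(tg, phase_coupling(amp = c(a, b, cc), p = c(0, 2, 2),
                                         q = c(1, 2, 1), r = c(-1, 0, 1)))
  h <- 1e-6
  for (row in 1:4) {
    ps <- res$phi_star[row]
    J <- matrix(0, 2, 2)
    for (j in 1:2) {
      up <- c(ps, ps); dn <- c(ps, ps)
      up[j] <- up[j] + h; dn[j] <- dn[j] - h
      J[, j] <- (phase_rhs(up, spec) - phase_rhs(dn, spec)) / (2 * h)
    }
    ev <- sort(Re(eigen(J, only.values = TRUE)$values))
    expect_equal(ev, sort(c(res$lambda_xi[row], res$lambda_zeta[row])),
                 tolerance = 1e-5)
  }
})

test_that("chain in-phase states are stable for GLE coupling", {
  pc <- gle_closed_coupling(pi / 3)
  xy <- phase_coupling(amp = sqrt(3) / (8 * pi), p = 0, q = 1, r = -1)
  for (N in c(3, 5, 10)) {
    for (bdry in c("open", "periodic")) {
      tg <- tissue_chain(N, bdry)
      spec <- phase_model(tg, pc)
      h <- 1e-6
      J <- matrix(0, N, N)
      for (j in 1:N) {
        up <- rep(0, N); dn <- rep(0, N)
        up[j] <- h; dn[j] <- -h
        J[, j] <- (phase_rhs(up, spec) - phase_rhs(dn, spec)) / (2 * h)
      }
      ev <- Re(eigen(J, only.values = TRUE)$values)
      expect_lt(max(ev), -1e-8)          # strictly stable
      # XY limit keeps exactly one neutral (global-rotation) mode
      spec_xy <- phase_model(tg, xy)
      for (j in 1:N) {
        up <- rep(0, N); dn <- rep(0, N)
        up[j] <- h; dn[j] <- -h
        J[, j] <- (phase_rhs(up, spec_xy) - phase_rhs(dn, spec_xy)) /
          (2 * h)
      }
      ev <- sort(Re(eigen(J, only.values = TRUE)$values),
                 decreasing = TRUE)
      expect_lt(abs(ev[1]), 1e-8)
      expect_lt(ev[2], -1e-8)
    }
  }
})

test_that("stationary density: normalisation and the Laplace limit", {
  tg <- tissue_chain(2)
  spec <- phase_model(tg, gle_closed_coupling(pi / 3),
                      signal = list(eps_e = 0.01, psi = pi,
                                    amplitude = 0.559))
  sd_small <- stationary_density(spec, nu = 2e-4, grid_n = 90)
  dg <- 2 * pi / 90
  expect_equal(sum(sd_small$joint) * dg^2, 1, tolerance = 1e-8)
  for (m in sd_small$marginals) {
    expect_equal(sum(m) * dg, 1, tolerance = 1e-8)
  }
  # nu -> 0: mass concentrates at the potential minimum (phi = (pi, pi):
  # aligned with the signal)
  mode_idx <- which(sd_small$joint == max(sd_small$joint), arr.ind = TRUE)
  mode <- sd_small$phi[mode_idx[1, ]]
  expect_lt(max(axis_distance(mode, c(pi, pi))), 2 * dg)
  big <- tissue_hex_sheet(2, 2)
  expect_error(stationary_density(phase_model(big,
                                              gle_closed_coupling(pi / 3)),
                                  nu = 0.1), "N <= 3")
})

test_that("noise_variance projects species noise onto the phase", {
  red <- reduce_model(make_model("gle", list(D0 = 0.2)), n_theta = 128)
  nu <- noise_variance(c(0.005, 0.005), red$cell)
  expect_equal(nu, 0.005 / (2 * pi * 0.8), tolerance = 1e-6)
  expect_equal(nu, 9.947e-4, tolerance = 1e-3)
  expect_equal(noise_variance(c(0, 0), red$cell), 0)
  expect_equal(noise_variance(c(0.01, 0.01), red$cell), 2 * nu,
               tolerance = 1e-12)
})

test_that("initial_phases draws are seeded and in range", {
  p1 <- initial_phases("uniform", 1200, seed = 77, lo = -0.5, hi = 0.5)
  p2 <- initial_phases("uniform", 1200, seed = 77, lo = -0.5, hi = 0.5)
  expect_identical(p1, p2)
  expect_true(all(p1 > -0.5 & p1 < 0.5))
  expect_lt(abs(mean(p1)), 0.05)            # CLT bound at N = 1200
  pm <- initial_phases("uniform", 50, seed = 1, lo = -pi / 2, hi = pi / 2)
  expect_true(all(abs(pm) < pi / 2))
  expect_equal(initial_phases("constant", 3, phi0 = pi / 4),
               rep(pi / 4, 3))
  expect_error(initial_phases("uniform", 5, seed = 1, lo = 1, hi = 0),
               "lo < hi")
})

test_that("stochastic phase integration requires and honours seeds", {
  tg <- tissue_chain(2)
  spec <- phase_model(tg, gle_closed_coupling(pi / 3),
                      noise = list(nu = 1e-3))
  expect_error(integrate_phase(spec, c(0, 0), T_end = 1), "seed")
  a <- integrate_phase(spec, c(0, 0), T_end = 5, dt = 0.01, seed = 9)
  b <- integrate_phase(spec, c(0, 0), T_end = 5, dt = 0.01, seed = 9)
  expect_identical(a$phi, b$phi)
})

test_that("boundary cells of a straight strip prefer the boundary axis", {
  # bottom-row cell of an open horizontal strip: eta_bar = 0
  tg <- tissue_hex_sheet(3, 7)
  ef <- in_phase_effective_field(tg, gle_closed_coupling)
  bottom <- which(tg$cells$row == 0 & tg$cells$col %in% 2:4)
  expect_true(all(ef$R[bottom] > 0.01))
  expect_lt(max(axis_distance(ef$eta_bar[bottom], 0)), 1e-10)
  # bulk cell of a regular sheet: R vanishes
  tgp <- tissue_hex_sheet(4, 4, "periodic")
  efp <- in_phase_effective_field(tgp, gle_closed_coupling)
  expect_lt(max(efp$R), 1e-14)
})

test_that("winding alignment follows the local boundary tangent", {
  # staircase band one cell wide: horizontal, diagonal, horizontal
  path <- rbind(cbind(0, 0:7),
                c(1, 7), c(2, 8), c(3, 8), c(4, 9),
                cbind(4, 10:16))
  tg <- tissue_winding(path)
  spec <- phase_model(tg, gle_closed_coupling)
  init <- initial_phases("uniform", nrow(tg$cells), seed = 3,
                         lo = -pi / 2, hi = pi / 2)
  tr <- integrate_phase(spec, init, T_end = 3000, sample_dt = 500)
  fin <- tr$phi[nrow(tr$phi), ]
  ef <- in_phase_effective_field(tg, gle_closed_coupling)
  sel <- ef$R > 1e-6
  expect_lt(max(axis_distance(fin, ef$eta_bar)[sel]), 15 * pi / 180)
  # defect-free: no near-antiphase neighbour pairs
  e <- tg$edges
  expect_lt(max(abs(wrap_angle(fin[e$i] - fin[e$j]))), pi / 2)
})

test_that("axial asymmetry rates combine lambda and heterogeneity", {
  expect_equal(elongation_lambda(pi / 3), 0, tolerance = 1e-15)
  expect_lt(elongation_lambda(pi / 3 - pi / 10), 0)
  expect_gt(elongation_lambda(pi / 3 + pi / 10), 0)
  rate <- heterogeneity_rate(0.1, sqrt(3) / (8 * pi), 1 / 12)
  expect_equal(rate, 2 * 0.1 * (sqrt(3) / (8 * pi) + 1 / 12))
  expect_equal(rate, 0.0305, tolerance = 2e-3)
  both <- axial_asymmetry_rates(delta = pi / 2, alpha = 0.1,
                                b = sqrt(3) / (8 * pi), c = 1 / 12)
  expect_equal(both$lambda, elongation_lambda(pi / 2))
  expect_equal(both$heterogeneity_rate, rate)
})
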