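test_that("GLE reduction matches every closed form", {
  red <- cached_reduction("gle")
  cell <- red$cell
  th <- cell$theta
  A <- sqrt(1 - 0.3)
  expect_lt(cell$residual, 1e-8)
  expect_lt(max(abs(cell$XS[, 1] - A * cos(th))), 1e-6)
  expect_lt(max(abs(cell$XS[, 2] - A * sin(th))), 1e-6)
  expect_lt(max(abs(cell$Y0[, 1] - A * sin(th))), 1e-6)
  Z0exp <- cbind(sin(th), -cos(th)) / (2 * pi * A)
  expect_lt(max(abs(cell$Z0 - Z0exp)), 1e-6)
  fd <- red$fourier
  expect_equal(fd$u[1], 0, tolerance = 1e-8)
  expect_equal(fd$u[2], A / 2, tolerance = 1e-8)
  expect_equal(fd$z[1], -1 / (4 * pi * A), tolerance = 1e-8)
  expect_lt(max(abs(fd$u[3:9])), 1e-8)
})

test_that("reduced cell invariants hold for both models", {
  for (name in c("gle", "activator_inhibitor")) {
    red <- cached_reduction(name)
    cell <- red$cell
    expect_lt(cell$residual, 1e-8)
    expect_equal(ring_inner(cell$Z0, cell$Y0), 1, tolerance = 1e-8)
    # activator maximum at theta = 0 (to half a grid cell)
    th_max <- cell$theta[which.max(cell$XS[, 1])]
    expect_lt(min(abs(wrap_angle(th_max))), pi / cell$n_theta)
    # null space of the discretised operator is one-dimensional
    L <- linear_operator_matrix(red$model, cell$XS)
    mags <- sort(Mod(eigen(L, only.values = TRUE)$values))
    expect_lt(mags[1], 1e-6)
    expect_gt(mags[2], 1e-6)
  }
})

test_that("activator-inhibitor steady state loses its pattern gracefully", {
  # GLE with D0 >= 1: the polar amplitude sqrt(1 - D0) vanishes
  expect_error(find_steady_state(make_model("gle", list(D0 = 1.2)),
                                 n_theta = 64),
               "pattern lost|homogeneous")
})

test_that("adjoint mode annihilates the range of L (brute force)", {
  red <- cached_reduction("activator_inhibitor")
  cell <- red$cell
  n <- cell$n_theta
  L <- linear_operator_matrix(red$model, cell$XS)
  z <- as.vector(cell$Z0)
  dth <- 2 * pi / n
  set.seed(12)
  for (rep in 1:20) {
    # random smooth periodic field
    y <- numeric(2 * n)
    th <- cell$theta
    for (s in 0:1) {
      y[s * n + 1:n] <- rnorm(1) +
        colSums(rnorm(10) * rbind(cos(outer(1:5, th)),
                                  sin(outer(1:5, th))))
    }
    expect_lt(abs(dth * sum(z * (L %*% y))), 1e-6)
  }
})

test_that("adjoint relaxation flow agrees with the eigenvector route", {
  # integrating dZ/dt = L^T Z relaxes onto the adjoint zero mode
  red <- cached_reduction("activator_inhibitor", 128)
  cell <- red$cell
  n <- cell$n_theta
  L <- linear_operator_matrix(red$model, cell$XS)
  Lt <- t(L)
  z <- rep(1, 2 * n) + as.vector(cell$Y0)  # generic start
  # implicit Euler on the adjoint flow (the operator is stiff: explicit
  # steps would need dt ~ 1/(D (n/2)^2)); the zero mode is the only
  # non-decaying direction
  dt <- 5
  P <- solve(diag(2 * n) - dt * Lt)
  for (i in 1:800) {
    z <- P %*% z
    if (i %% 100 == 0) z <- z / sqrt(sum(z^2))
  }
  z <- z / (2 * pi / n * sum(z * as.vector(cell$Y0)))
  expect_lt(max(abs(z - as.vector(cell$Z0))), 1e-3)
})

test_that("fourier_coefficients follows the two-sided convention", {
  # synthetic profile: pure cos(2 theta) leaves only u_2
  th <- ring_grid(128)
  cell <- structure(list(n_theta = 128L, theta = th,
                         XS = cbind(0.5 * cos(2 * th), 0 * th),
                         Z0 = cbind(-0.3 * sin(th), 0 * th),
                         Y0 = cbind(sin(th), 0 * th)),
                    class = "reduced_cell")
  fd <- fourier_coefficients(cell, K = 6)
  expect_equal(fd$u[3], 0.25)          # two-sided: u_2 = amplitude/2
  expect_lt(max(abs(fd$u[-3])), 1e-12)
  expect_equal(fd$z[1], 0.15)          # Z = -2 z_1 sin(theta)
  # reconstruction from the coefficients
  red <- cached_reduction("activator_inhibitor")
  fdA <- red$fourier
  ks <- 1:fdA$K
  recon <- fdA$u[1] + 2 * colSums(fdA$u[-1] * cos(outer(ks, red$cell$theta)))
  expect_lt(max(abs(recon - red$cell$XS[, 1])), 1e-3)
  reconZ <- -2 * colSums(fdA$z * sin(outer(ks, red$cell$theta)))
  expect_lt(max(abs(reconZ - red$cell$Z0[, 1])), 1e-3)
  # misaligned profile is rejected
  bad <- cell
  bad$XS[, 1] <- cos(2 * th - 0.3)
  expect_error(fourier_coefficients(bad, K = 6), "alignment failed")
})

test_that("shape coefficients match the closed form", {
  s <- shape_coefficients(pi / 3, 6)
  expect_equal(s[1], 1 / 6)
  expect_equal(s[2], 1 / (2 * pi))
  expect_equal(s[7], 0)                       # k d / 2 = pi: sine zero
  expect_equal(shape_coefficients(1.7, 4)[4], sin(3 * 1.7 / 2) / (3 * pi))
  expect_error(shape_coefficients(0, 4))
})

test_that("gamma_from_fourier reproduces the closed-form couplings", {
  red <- cached_reduction("gle")
  for (d in c(pi / 3, 0.8, 2.0)) {
    pc <- red$coupling(d)
    co <- coupling_coef(pc)
    expect_equal(co[["a"]], sin(d) / (4 * pi), tolerance = 1e-6)
    expect_equal(co[["b"]], sin(d) / (4 * pi), tolerance = 1e-6)
    expect_equal(co[["c"]], d / (4 * pi), tolerance = 1e-6)
    expect_equal(co[["bprime"]], 0, tolerance = 1e-6)
    expect_lte(nrow(pc), 3)  # all other terms pruned
  }
  # pure-inhibition variant: u0 = 0 kills the bprime term, a and c remain
  pcp <- red$coupling(pi / 3, kind = "pure_inhibition")
  cop <- coupling_coef(pcp)
  expect_equal(cop[["a"]], sin(pi / 3) / (4 * pi), tolerance = 1e-6)
  expect_equal(cop[["c"]], (pi / 3) / (4 * pi), tolerance = 1e-6)
  expect_equal(cop[["bprime"]], 0, tolerance = 1e-6)
  expect_equal(cop[["b"]], 0, tolerance = 1e-6)
  # harmonic approximation identity on the computed coefficients
  fd <- red$fourier
  s <- shape_coefficients(pi / 3, 2)
  expect_equal(-4 * pi * fd$z[1] * fd$u[2] * s[3],
               sin(pi / 3) / (4 * pi), tolerance = 1e-8)
  expect_equal(-4 * pi * fd$z[1] * fd$u[2] * s[1],
               (pi / 3) / (4 * pi), tolerance = 1e-8)
})

test_that("activator-inhibitor coupling: pure-inhibition bprime", {
  red <- cached_reduction("activator_inhibitor")
  fd <- red$fourier
  pcp <- red$coupling(pi / 3, kind = "pure_inhibition")
  s <- shape_coefficients(pi / 3, 2)
  expect_equal(coupling_coef(pcp)[["bprime"]],
               4 * pi * fd$z[1] * fd$u[1] * s[2], tolerance = 1e-3)
})

test_that("gamma_direct is rotationally covariant and matches the series", {
  red <- cached_reduction("gle")
  # rotational covariance: shifting phi_i, phi_j, eta together is neutral
  g1 <- gamma_direct(red$cell, list(eta_ij = 0.0, d = pi / 3), grid_n = 8)
  chi <- 0.37
  g2 <- gamma_direct(red$cell,
                     list(eta_ij = chi, eta_ji = chi + pi, d = pi / 3),
                     grid_n = 8)
  pc <- red$coupling(pi / 3, amp_tol = 1e-8)
  for (i in 1:8) {
    for (j in 1:8) {
      expect_equal(g2$gamma[i, j],
                   gamma_eval(pc, chi, g2$phi[i] + 0, g2$phi[j] + 0),
                   tolerance = 1e-6)
      expect_equal(g1$gamma[i, j],
                   gamma_eval(pc, 0, g1$phi[i], g1$phi[j]),
                   tolerance = 1e-6)
    }
  }
  # invariance under the simultaneous shift, sampled directly
  gshift <- outer(g1$phi, g1$phi, function(a, b)
    gamma_eval(pc, chi, a + chi, b + chi))
  expect_lt(max(abs(gshift - g1$gamma)), 1e-8)
  # straight pair at the aligned state: every term vanishes
  expect_equal(gamma_eval(pc, 0, 0, 0), 0)
})

test_that("reduce errors when K exceeds the grid", {
  red <- cached_reduction("gle", 128)
  expect_error(fourier_coefficients(red$cell, K = 64), "too large")
})
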