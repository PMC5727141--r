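# Shared fixtures.  The reductions are deterministic but not free
# (steady-state search + dense eigen-decomposition), so they are memoised
# across test files.

.pp_cache <- new.env(parent = emptyenv())

cached_reduction <- function(name, n_theta = 256) {
  key <- paste0(name, "_", n_theta)
  if (is.null(.pp_cache[[key]])) {
    .pp_cache[[key]] <- reduce_model(make_model(name), n_theta = n_theta)
  }
  .pp_cache[[key]]
}

# Closed-form coupling of the GLE: a = b = sin(d)/(4pi), c = d/(4pi).
gle_closed_coupling <- function(d) {
  phase_coupling(amp = c(sin(d) / (4 * pi), sin(d) / (4 * pi),
                         d / (4 * pi)),
                 p = c(0, 2, 2), q = c(1, 2, 1), r = c(-1, 0, 1))
}

# Distance between two axes (angles mod pi).
axis_distance <- function(a, b) {
  d <- abs(wrap_angle(a - b))
  pmin(d, pi - d)
}

# Coupling amplitude for a canonical (p, q, r) key, 0 when absent.
term_amp <- function(pc, p, q, r) {
  hit <- pc$p == p & pc$q == q & pc$r == r
  if (any(hit)) pc$amp[hit] else 0
}

# Total-variation distance between a sample of angles and a theoretical
# density tabulated on a uniform circular grid.  Bins are centred on the
# grid points so each bin carries exactly one density value.
tv_distance <- function(sample, phi_grid, density) {
  dg <- phi_grid[2] - phi_grid[1]
  brk <- c(phi_grid - dg / 2, phi_grid[length(phi_grid)] + dg / 2)
  s <- brk[1] + ((sample - brk[1]) %% (2 * pi))
  emp <- hist(s, breaks = brk, plot = FALSE)$counts
  emp <- emp / sum(emp)
  theo <- density / sum(density)
  sum(abs(emp - theo)) / 2
}
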