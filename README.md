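# polarphase

Planar cell polarity — the coordinated alignment of a polarity axis across
a tissue, as in hair follicles or cilia — is often modelled in one of two
ways that don't talk to each other: *detailed* models in which every cell
carries a reaction–diffusion system on its boundary and couples to its
neighbours through shared contact surfaces, and *phenomenological* lattice
models of XY/Kuramoto type.  `polarphase` implements the bridge: a
weak-coupling phase reduction that collapses each cell's boundary field to
a single polarity angle while keeping the geometry — contact directions,
contact widths, cell elongation, per-junction coupling strength — inside
the reduced interaction.  It is aimed at modellers who want
quantitatively derived (not postulated) lattice models of polarity, and
at anyone studying how anisotropic cues orient tissue-scale order.

## The model

Each cell obeys, on its boundary coordinate `θ ∈ [0, 2π)`,

    ∂t X_i = F(X_i) + D ∂²θ X_i + ε Σ_{j∈A(i)} H_ij ,

with `H_ij` a contact interaction acting on the activator over the shared
surface (midpoint `η_ij`, width `d_ij`).  When the single-cell dynamics
form a stable unimodal pattern `X^S(θ)`, weak coupling gives the phase
model

    dφ_i/dt = ε Σ_j Γ_ij(φ_i, φ_j),   Γ_ij = ⟨Z₀(θ−φ_i), H_ij^S⟩ ,

where `Z₀` is the adjoint zero eigenfunction (phase sensitivity function)
of the linearisation about `X^S`, normalised by `⟨Z₀, Y₀⟩ = 1` against
the Goldstone mode `Y₀ = −∂θ X^S`.  `Γ_ij` is assembled in closed form
from Fourier coefficients `u_k` (pattern), `z_k` (adjoint mode) and
`s_k` (contact shape); its leading terms are

    a sin(φ_j−φ_i) + b sin 2(η_ij−φ_i) + c sin(2η_ij−φ_i−φ_j),

with `a = b = −4π z₁u₁s₂`, `c = −4π z₁u₁s₀` for nearly harmonic
patterns.  The `a` term is the XY model; `b` and `c` carry the geometry
and are what lets elongation or junction-strength asymmetry orient the
whole tissue.

## Worked example

Reduce the built-in activator–inhibitor model and inspect the coupling for
regular hexagonal cells (contact width `d = π/3`):

```r
library(polarphase)
model <- make_model("activator_inhibitor")
red   <- reduce_model(model)          # steady state + adjoint mode + Fourier

round(red$fourier$u[1:3], 3)
#> [1] 0.925 0.397 0.066
round(red$fourier$z[1:2], 3)
#> [1] -0.180 -0.062

red$coupling(pi/3)
#> <phase_coupling> kind = difference
#>    +0.12408 sin(0 eta -1 phi_i +1 phi_j)
#>    ...
#>    +0.15004 sin(2 eta -1 phi_i -1 phi_j)
#>    ...
#>    +0.04936 sin(3 eta -2 phi_i -1 phi_j)
#>    +0.03290 sin(1 eta -2 phi_i +1 phi_j)   # (reordered excerpt)
```

`u₀ = 0.925, u₁ = 0.397, u₂ = 0.066, z₁ = −0.180, z₂ = −0.062` are the
pattern/adjoint Fourier coefficients; the leading coupling amplitudes
0.124 (XY term), 0.150 (`c` term) etc. are the reduced interaction for
hexagonal packing.  Stability of a straight pair follows directly:

```r
two_cell_analysis(a = 0.124, b = 0.124, c = 0.150)
#>    phi_star lambda_xi lambda_zeta stable neutral
#> 1  0.000000    -0.548      -0.496   TRUE   FALSE
#> 2  3.141593    -0.548      -0.496   TRUE   FALSE
#> 3  1.570796     0.548       0.000  FALSE    TRUE
#> 4 -1.570796     0.548       0.000  FALSE    TRUE
```

so head-to-tail alignment along the contact axis is stable and the
perpendicular state is not.  Elongating cells flips the preferred axis:

```r
elongation_lambda(pi/3)            # 0: regular hexagon is neutral
elongation_lambda(pi/3 - pi/10)    # -0.0104: vertical polarity is stable
```

Full tissue runs (`integrate_tissue_rd`, `integrate_phase`), noisy runs
with Boltzmann stationary densities (`stationary_density`), and
configuration-driven pipelines (`pp_run`, CLI in `inst/cli/polarphase.R`)
are documented in the function reference and in
`vignettes/polarity-phase-reduction.Rmd`.

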