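---
title: "Reducing reaction-diffusion tissue polarity to a phase model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reducing reaction-diffusion tissue polarity to a phase model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polarphase)
```

## The model

A planar tissue is a lattice of hexagonal cells, each with boundary
perimeter $2\pi$.  Cell $i$ carries concentrations
$\boldsymbol X_i(\theta_i, t)$ of chemical species on its boundary
coordinate $\theta_i \in [0, 2\pi)$, obeying

$$\partial_t \boldsymbol X_i
 = \boldsymbol F(\boldsymbol X_i)
 + \hat D\, \partial^2_{\theta_i} \boldsymbol X_i
 + \varepsilon \sum_{j \in A(i)} \boldsymbol H_{ij},$$

where $A(i)$ are the neighbours and $\boldsymbol H_{ij}$ is a contact
interaction: on the shared surface of width $d_{ij}$ centred at the
arclength midpoint $\eta_{ij}$, the activator of cell $i$ is compared with
(or inhibited by) the neighbour's activator at the geometrically facing
point $\theta_j^* = \eta_{ji} - (\theta_i - \eta_{ij})$.  Two reaction
models are built in: the real Ginzburg–Landau equation (GLE), whose polar
pattern and reduction are available in closed form, and a two-species
activator–inhibitor model whose reduction must be computed numerically.
Both form a stable unimodal ("polar") boundary pattern for
$\varepsilon = 0$; the angle of the activator maximum is the cell's
polarity $\varphi_i$.

## The phase reduction

Let $\boldsymbol X^{\rm S}(\theta)$ be the aligned steady pattern
(activator maximum at $\theta = 0$) and
$\mathcal L = J + \hat D \partial_\theta^2$ the linearisation about it.
Translational symmetry gives the Goldstone mode
$\boldsymbol Y_0 = -\partial_\theta \boldsymbol X^{\rm S}$ with
$\mathcal L \boldsymbol Y_0 = 0$; the adjoint zero mode (phase
sensitivity function) $\boldsymbol Z_0$ solves
$\mathcal L^\dagger \boldsymbol Z_0 = 0$,
$\mathcal L^\dagger = J^{\rm T} + \hat D \partial_\theta^2$, normalised by
$\langle \boldsymbol Z_0, \boldsymbol Y_0 \rangle
 = \int_0^{2\pi} \boldsymbol Z_0 \cdot \boldsymbol Y_0\, d\theta = 1$.
For weak coupling each cell's state stays near a shifted copy of
$\boldsymbol X^{\rm S}$ and projecting the interaction onto
$\boldsymbol Z_0$ yields the closed phase model

$$\dot\varphi_i = \varepsilon \sum_{j\in A(i)}
  \Gamma_{ij}(\varphi_i, \varphi_j), \qquad
  \Gamma_{ij} = \langle \boldsymbol Z_0(\theta - \varphi_i),
                 \boldsymbol H^{\rm S}_{ij}\rangle.$$

With the two-sided Fourier conventions
$U^{\rm S} = \sum_k u_k \cos k\theta$ ($u_{-k} = u_k$),
$Z_0^{(U)} = \sum_k -z_k \sin k\theta$ ($z_{-k} = -z_k$) and shape
coefficients $s_0 = d/2\pi$, $s_k = \sin(k d/2)/k\pi$, the coupling
function is a finite sum of sinusoids
$A \sin(p\,\eta_{ij} - q\,\varphi_i - r\,\varphi_j)$.  `polarphase`
assembles it from the double sum over harmonics: the cross part (the
neighbour's activator) contributes
$2\pi z_k u_l (-1)^l s_{k-l} \sin\{(k{+}l)\eta - k\varphi_i -
l\varphi_j\}$ and, for the difference coupling only, the self part
contributes $-2\pi z_k u_l s_{k+l} \sin\{(k{+}l)(\eta - \varphi_i)\}$.
An instructive identity falls out of this split: all terms with $l = 0$
cancel between the two parts, which is why the difference coupling carries
no large $\sin(\eta - \varphi_i)$ harmonic even when the activator mean
$u_0$ is large, while the pure-inhibition coupling (cross part only)
gains exactly the $b' = 4\pi z_1 u_0 s_1$ term.

For nearly harmonic patterns the leading coefficients are
$a = b = -4\pi z_1 u_1 s_2$ and $c = -4\pi z_1 u_1 s_0$; for the GLE these
evaluate to $a = b = \sin(d)/4\pi$, $c = d/4\pi$ exactly.

Everything downstream uses only these per-edge-width coefficient tables:
two-cell stability ($\lambda_\xi = -2\varepsilon(b{+}c)\cos 2\varphi^*$,
$\lambda_\zeta = -2\varepsilon(a + b\cos 2\varphi^*)$), the in-phase
effective field $R_i e^{2 i \bar\eta_i} = \sum_j (b_{ij} + c_{ij})
e^{2 i \eta_{ij}}$, the elongation coefficient $\lambda(\delta)$, the
heterogeneity rate $2\alpha(b{+}c)$, the gradient potential
$\mathcal H$, and the Boltzmann stationary density
$P \propto \exp(-2\mathcal H/\nu)$ under phase noise of intensity
$\nu = \sum_m \nu_m \int (Z_0^{(m)})^2 d\theta$.

## Numerical choices

* **Discretisation.**  Uniform periodic grids, default
  $n_\theta = 256$; all spatial operations (second derivative,
  differentiation for $Y_0$, interpolation at facing points, phase
  extraction) are spectral, so the only non-spectral error source is time
  stepping.
* **Steady-state solver.**  Lie splitting with the diffusion factor
  $e^{-Dk^2\,dt}$ applied exactly per wavenumber and an explicit reaction
  step (an explicit diffusion step would force
  $dt \lesssim 1.5\times10^{-3}$ at $n_\theta = 256$ with $D_V = 0.2$).
  The splitting iteration is run to its own fixed point, whose residual is
  dominated by the $O(dt)$ splitting bias; Newton iterations with the
  translational mode pinned by a bordered system then polish the solution
  to a residual below $10^{-8}$ (typically $10^{-12}$).  The pattern is
  rotated spectrally so the activator maximum is exactly at $\theta = 0$
  and re-polished.
* **Initial condition for pattern formation.**  Homogeneous fixed point
  plus a $0.1\cos(\theta - \varphi_0)$ activator perturbation.  For the
  GLE this fails: its $V = 0$ subspace is invariant, so an activator-only
  perturbation relaxes to a scalar bimodal pattern instead of the polar
  one.  The GLE default is therefore
  $0.1(\cos(\theta-\varphi_0), \sin(\theta-\varphi_0))$, which lies on the
  invariant manifold of the exact solution
  $\sqrt{1-D_0}(\cos\theta, \sin\theta)$.
* **Adjoint mode.**  Null vector of the transposed dense operator matrix
  by eigen-decomposition — deterministic, no time-stepping tolerance.  The
  relaxation route (integrating $\dot{\boldsymbol Z} = \mathcal L^\dagger
  \boldsymbol Z$) is kept as a cross-check in the test suite, run with an
  implicit scheme because the operator is stiff.  The discretised null
  space must be one-dimensional at tolerance $10^{-6}$; anything else is
  reported as a degenerate discretisation.
* **Truncation.**  Coupling functions keep harmonics $|k|, |l| \le K = 8$
  and prune assembled amplitudes below $10^{-4}$; for the built-in models
  the discarded tail is below $10^{-6}$.  Oracle-equivalence tests pass a
  smaller pruning tolerance so that truncation, not pruning, is what they
  measure.
* **Phase integration.**  Deterministic runs use an embedded
  Dormand–Prince 5(4) pair with PI step control (`deSolve` is not a
  dependency); stochastic runs use Euler–Maruyama (additive noise, weak
  order 1 suffices for density comparisons) with per-step variance
  $\nu\,dt$ and mandatory seeds.
* **Angle convention.**  All reported angles live in $(-\pi, \pi]$;
  preferred axes in $(-\pi/2, \pi/2]$.

## Tissue geometry

Cells are hexagons parametrised by the arc width $\delta$ of the two edges
whose midpoints face $\eta = 0, \pi$; the four oblique edges have width
$\delta' = (\pi - \delta)/2$ and midpoints at $\pm(\pi+\delta)/4$,
$\pm(3\pi-\delta)/4$.  $\eta_{ij}$ is the arclength midpoint of the
contact surface in the cell's own boundary coordinate — not the bearing of
the neighbour's centre.  This reading is pinned by a geometric
consistency test: for a uniformly elongated periodic sheet the in-phase
effective field computed from these midpoints equals $2\lambda(\delta)$
with the closed-form elongation coefficient, to $10^{-10}$, across twenty
values of $\delta$.  The two $\delta$-edges face $\eta = 0, \pi$, so
$\lambda < 0$ (for $\delta < \pi/3$) stabilises vertical polarity
$\varphi = \pm\pi/2$ — elongated cells align polarity along their long
axis.  Time-dependent shape protocols are represented as piecewise
constant sequences of tissues, since the phase model consumes only
$(\eta, d, \alpha)$ per edge.

## What the synthetic protocols do and do not establish

The simulated experiments are generated by the package itself, under the
stated parameter values:

* the three-cell straight chain at $\varepsilon = 10^{-3}$ compares the
  full reaction–diffusion trajectory with the reduced phase model
  (agreement within 0.05 rad over $t \in [0, 2000]$), starting both
  representations from phases $(0.5, 0, -0.5)$ — the source material does
  not print its initial phases, so agreement is asserted along the whole
  transient rather than at a printed curve;
* the $60\times20$ periodic sheet with the elongation window
  ($\delta: \pi/3 \to \pi/3 - \pi/10 \to \pi/3$) starts from phases
  uniform in $(-0.5, 0.5)$; which of $\pm\pi/2$ is selected depends on the
  sign of the mean initial phase, so tests assert $|\Phi| \to \pi/2$, not
  the sign, and persistence after the shape reverts;
* the two-cell noise + signal ensemble uses the printed values
  $\nu_1 = \nu_2 = 0.005$, $\varepsilon_e = 2\times10^{-4}$, $D_0 = 0.2$,
  $\psi = \pi$.  The coupling strength for this comparison is not printed;
  we use $\varepsilon = 10^{-3}$, the same weak-coupling value as the
  chain comparison, because for $\varepsilon = 1$ the Boltzmann barrier
  $2\Delta\mathcal H/\nu \sim 10^3$ makes the two wells dynamically
  disconnected on any feasible run and the stationary density could not be
  sampled.  The empirical marginal is pooled over both cells of 800
  independent replica pairs (the marginals coincide by the swap symmetry
  of the pair), binned at $3^\circ$ with the first 20% of each run
  discarded as burn-in.

These runs emulate idealised tissues: identical cells, perfectly periodic
or perfectly open boundaries, piecewise-constant shapes and white noise.
They say nothing about disordered packings, moving junctions, or
non-hexagonal geometries — all outside the model class.  A green test
establishes internal consistency of the reduction and its analytical
consequences, not biological validity.

## Degenerate inputs and failure modes

Flat activator profiles have no polarity: phase extraction fails below a
first-mode magnitude of $10^{-8}$.  The GLE with $D_0 \ge 1$ loses its
pattern (the polar amplitude $\sqrt{1-D_0}$ vanishes); the steady-state
solver detects collapse to a homogeneous state and says so.  The
activator–inhibitor model is only defined for $V > 0$; trajectories are
never clamped — leaving the domain raises an error, since silent clamping
would corrupt steady-state accuracy.  The potential (and therefore the
stationary density) exists only for the $a/b/b'/c$ coupling family;
richer harmonic content is integrated dynamically but refused by
`phase_potential` with an explanatory message.

## Known limitations

Reaction–diffusion simulation of elongated-hexagon tissues is not
supported (the phase level carries elongation instead); eigenmodes beyond
the zero pair are not computed; densities are limited to three cells
(quadrature); arbitrary polygonal packings are out of scope.
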