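---
title: "Diffuse-interface lateral stress profiles: model, conventions, and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diffuse-interface lateral stress profiles: model, conventions, and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memstress)
```

## The model

A fluid lipid bilayer at the vesicle scale is described by the
Canham–Helfrich surface energy: tension γ times area, bending rigidity k
penalizing deviations of the mean curvature M from the spontaneous curvature
m, and a Gaussian modulus k_G multiplying the Gaussian curvature (a
topological invariant on closed surfaces).  The diffuse-interface route
replaces the sharp mid-surface with a smooth order parameter φ ∈ [−1, 1]
whose transition layer has width set by a parameter ε.  To leading order in
λ = ε/D_ve (interface width over vesicle size) the layer profile is the kink

f0(u) = tanh(u/√2), u = −z/ε,

and every quantity in this package is an explicit functional of f0 and its
derivatives.  The kink saturates to ±1 within about 3% at |u| = 3, which is
why 6ε is identified with the membrane thickness l_me = 5 nm.

The lateral stress — tangential minus normal stress as a function of the
normal coordinate z (z = 0 at the mid-surface, z > 0 the outer leaflet) —
comes out in closed form as five superposed components, sB2, sB1, sB0, sG,
sT, each linear in exactly one combination of elastic constants
(k, mk, m²k, k_G0, γ).  Their moments P_i = ∫ z^i s dz reproduce the
thermodynamic relations P0 = Σ = γ + 2km², P1 = −2km, and
P2 = 2k + k_G|Σ=0 + z_D²Σ, where z_D = √((12+π²)/6)·ε is a finite-thickness
tension correction that lands, pleasingly, at the rule-of-thumb location of
the monolayer neutral plane (≈ 2/3 of a monolayer length).

## Conventions that are choices

Several typeset sources of these formulas are ambiguous about factors of √2,
so the package pins everything to two unambiguous anchors: the kink form
f0 = tanh(u/√2) and the stationarity identity f0″ = (f0² − 1)f0.  The five
component prefactors — 3/√2, −3√2, −3/√2, 35/(16√2), −3/(2√2) — are then
*derived* constants, fixed by requiring the moment table

| | P0 | P1 | P2 |
|---|---|---|---|
| sB2 | 0 | 0 | 2k |
| sB1 | 0 | −2km | 0 |
| sB0 | 2km² | 0 | 2km²·z_D² |
| sG | 0 | 0 | k_G0 |
| sT | γ | 0 | γ·z_D² |

to hold; the test suite re-verifies every cell by quadrature rather than
trusting the algebra.  Note the table has seven nonzero cells: the two
tension-carrying components contribute to P2 as well as P0; that is exactly
the z_D²Σ correction.

Other conventions fixed here once:

* **Units.**  Energies in kBT, lengths in nm, hence stresses in kBT/nm³ and
  tensions in kBT/nm².  Conversions (bar, Pa, mN/m) live only in
  `convert_stress()`, with a default temperature of 298.15 K (none is
  dictated by the theory; the flag `--temperature` overrides it).  At 300 K,
  1 kBT/nm³ ≈ 41.4 bar, which puts the profile peaks at the "hundreds of
  bars" familiar from molecular dynamics.
* **Geometry.**  `interface_geometry()` defaults to l_me = 6ε = 5 nm;
  ratios l_me/ε in [5, 7] are accepted so the alternative convention
  l_me = 5.73ε (which makes z_D exactly l_me/3) is available via
  `ratio = 5.73`.  z_D itself is implemented ε-based,
  z_D = √((12+π²)/6)·ε: that is the quantity the quadrature of z²·sT/γ
  actually produces, and it reduces to 0.64·(l_me/2) under the default
  convention.
* **Leaflet indexing.**  In `combine_monolayers()` leaflet 1 is the outer
  one (neutral surface at +z0).  Monolayer spontaneous curvatures are
  per-leaflet-outward: under that convention symmetric leaflets give m = 0,
  and relabeling the leaflets negates m while leaving k, Σ and k_G
  invariant — the property test that guards the convention.  The first-order
  z0 term in m (from a tension difference between leaflets) is kept, with
  `drop_z0_tension_term = TRUE` reproducing the commonly quoted reduced
  form.
* **"Central peak"** means s(0).  At z = 0 the m- and γ-carrying components
  vanish, leaving s(0) = −(3k/2 + 35k_G0/16)/(√2ε³), which crosses zero at
  k_G0/k = −24/35; `zero_bump_ratio()` finds that root by bisection and the
  closed form is asserted to 1e−12.

## Numerical choices

* **Quadrature.**  Closed-form components are integrated by a dense
  composite Simpson rule on |z| ≤ 40ε (h = 0.005ε, relative accuracy
  ~1e−12).  Adaptive quadrature was tried first and abandoned for the moment
  table: the parity integrands that are identically zero (odd moments of
  even components) make the adaptive error estimator abort.  Tabulated
  profiles are integrated on their own grid by composite Simpson, which is
  why `numeric_moments()` insists on a span of at least [−2l_me, 2l_me].
* **Radial energies.**  The sphere quadratures are restricted to
  r̄ ∈ [max(0, 1/2 − 20λ), 1/2 + 20λ]; the integrands are exponentially
  localized at r̄ = 1/2 and the cut keeps the integrable 1/r̄ behaviour near
  the origin out of the numerics.  Empirically the bending and tension
  energies converge to their sharp-interface limits at second order in λ
  (the first-order term cancels by parity of f0′² in the reduced integral;
  the formal asymptotic guarantee is only first order for bending, and the
  tests assert the guaranteed bounds).  The reduced Gaussian integral has no
  r̄ weight at all, so it equals 4πk_G up to exponentially small truncation
  at *every* λ; `convergence_order()` reports it as "converged" (order ∞)
  rather than fitting a meaningless slope to roundoff.
* **Planar relaxation.**  The 1D gradient flow
  φ_t = φ_zz − (φ² − 1)φ/ε² is integrated by explicit Euler with the stable
  default step dz²/4 and fixed boundary values; energy is monitored every
  100 steps and any increase (or non-finite state) aborts with a divergence
  error.  The relaxed discrete solution differs from the continuum kink by
  the O(dz²) truncation floor — about 2.5e−5 in sup norm at dz = 0.025 nm —
  which is the budget behind the 1e−4 acceptance threshold.
* **Shape-fit extraction.**  The profile is split into even and odd parts
  before fitting: the odd part determines mk alone, the even part (k, Σ,
  k_G0) by ordinary least squares on three basis shapes.  The split makes
  the m = 0 case exact and decouples the conditioning of the two
  subproblems.  γ and the spontaneous tension 2km² share one shape
  (sT ∝ sB0 pointwise), so only Σ is directly identifiable; γ is
  reconstructed afterwards as Σ − 2km².  With `epsilon = "fit"` a 1D golden
  search over ε (half to double the nominal value) minimizes the residual
  before the linear solve.

## What the synthetic generator does and does not emulate

`synthesize_noisy_profile()` adds i.i.d. zero-mean Gaussian noise to the
total stress of a model-generated profile, with sd quoted in kBT/nm³ (the
recovery experiments use 1% of the peak height, a typical scatter for
well-averaged MD profiles on ~800-point grids).  Real MD lateral-pressure
curves differ in ways the generator deliberately ignores: their noise is
correlated across z (block averaging), their fine structure is not a
five-shape superposition (individual peaks per headgroup/interface region),
and the local stress tensor itself is not unique.  A green recovery test
therefore establishes that the inverse map is well-conditioned and unbiased
*within the model family*, not that MD-derived constants would be recovered
to the same accuracy.

## Known limitations

* Only the planar/radial reductions of the 3D functionals are implemented —
  enough for every quantitative statement the package makes, but not for
  dynamical vesicle simulations or topological transitions.
* The constant-chemical-potential derivative corrections to the moment
  relations are out of scope; the closed forms here are self-consistent
  without them.
* Insertion effects (`insertion_effect()`) are sign rules only; the theory
  gives no magnitudes for Δm or Δk_G.
* The moment route cannot separate k from k_G0 (only 2k + k_G0 + z_D²Σ is
  observable in P2); use the shape fit when both are needed.
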