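---
title: "Electrodiffusion in a fixed-charge hydrogel: model and numerics"
author: "pnpgel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Electrodiffusion in a fixed-charge hydrogel: model and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pnpgel)
```

## The physical model

A polyelectrolyte hydrogel scaffold sits in a NaCl bath between two
electrodes. The gel network carries bound anionic groups — a fixed charge
density `c_f` (mol m⁻³, stored as a magnitude) with valence `z_f` (−1 for
a carboxylated gel) — that cannot move, while Na⁺ and Cl⁻ diffuse and
migrate freely through gel and bath. Two equations govern the fields:

* **Nernst–Planck** for each mobile species `k`, with flux composed of
  diffusion and electromigration,
  `∂c_k/∂t = ∇·(D_k ∇c_k + z_k (F/RT) D_k c_k ∇ψ)`.
  The mobility is eliminated through the Nernst–Einstein relation
  `μ_k = D_k F/(RT)` (`nernst_einstein_mobility()`); a user-supplied
  mobility that disagrees with it by more than 1e−4 relative triggers a
  warning, not an error, since measured mobilities can legitimately
  deviate.
* **Poisson** for the potential,
  `∇²ψ + (F/ε_r ε₀)(Σ_k z_k c_k + z_f c_f·1_gel) = 0`,
  where the indicator confines the fixed charge to the gel region.

Modelling assumptions, chosen to keep the transport problem closed:
convective flux is zero (no fluid flow relative to the network), no
chemical reactions or electrode electrochemistry, uniform activity
coefficients, constant diffusivities, 1D/2D geometry. Mechanical
swelling of the network is **not** coupled — the gel shape is fixed.

At zero applied voltage the equilibrium is the classical Donnan state.
For a monovalent binary electrolyte, gel electroneutrality
`c⁺ − c⁻ = −z_f c_f` and the ideal Donnan product `c⁺ c⁻ = c_sol²` give

```
c_gel± = ∓ z_f c_f / 2 + sqrt((c_f/2)² + c_sol²)
Δφ(gel − bath) = (RT / z_k F) · ln(c_sol,k / c_gel,k)
```

implemented in closed form (`donnan_concentrations()`,
`donnan_potential()`). Two sign conventions are worth stating explicitly,
because the literature is not consistent about them. First, the fixed
charge is stored as magnitude plus valence and only the signed product
`z_f·c_f` enters any equation; with `z_f = −1` and `c_f = 2`,
`c_sol = 1` mol m⁻³ this yields cation 2.4142 and anion 0.4142 mol m⁻³ in
the gel. Second, the potential ratio is oriented so that an anionic gel
sits at negative potential relative to the bath: `ln(c_sol⁺/c_gel⁺)`,
giving −22.25 mV at 293 K. Both forms of the potential (cation- or
anion-based) agree identically whenever the state satisfies the Donnan
product; `donnan_potential()` warns if they do not.

## Parameters and defaults

`physical_constants()` defaults encode the standard simulation set for
this system: `F = 9.6487×10⁴ C mol⁻¹`, `R = 8.3143 J mol⁻¹ K⁻¹`,
`T = 293 K` (thermal voltage `RT/F ≈ 25.25 mV`),
`ε₀ = 8.854×10⁻¹² A s V⁻¹ m⁻¹`, `ε_r = 100`. The relative permittivity
of 100 is treated as a property of the hydrated gel/bath medium; with a
1 mM bath it puts the Debye length at
`λ_D = sqrt(ε_r ε₀ RT / (2 F² c_sol)) ≈ 10.8 nm`, which sets every
meshing decision below. Species defaults (`nacl_bath()`):
`D = 1.0×10⁻⁷ m² s⁻¹` for both ions (hence `μ = 3.9607×10⁻⁶ m² s⁻¹ V⁻¹`),
`z = ±1`. The standard scenarios use `c_sol = 1 mol m⁻³` (1 mM; the
package treats 1 mM = 1 mol m⁻³ throughout) and `c_f = 2 mol m⁻³`,
`z_f = −1`.

## Geometry and the scaled presets

The bench-scale geometry is a 0.015 m bath with a gel of half-width
0.0025 m at its centre (the disc scaffold uses radius 0.0025 m), with a
mesh-refinement band extending 0.002 m to either side of the
gel–solution interface. These numbers are conventions of the package's
presets — they are consistent with profiles quoted at mid-bath height
0.0075 m — and every one of them is configurable.

At bench scale the domain spans ~10⁶ Debye lengths, so resolving the
interfacial space-charge layers needs tens of millions of unknowns —
cluster work, not a desk machine. The `_scaled` presets therefore shrink
**all lengths by 10⁴** (bath 1.5 µm, gel 0.5 µm, band 0.2 µm). The bulk
Donnan values are geometry-independent — they depend only on `c_f`,
`c_sol` and the constants — so the scaled runs validate the solver
quantitatively; what changes is the ratio of layer thickness to domain
size, i.e. the layers are visible rather than infinitesimally thin, and
transients complete in ~10⁻⁵ s instead of ~10³ s (the diffusive clock is
`L²/D`). What the scaled runs consequently *cannot* show is the
bench-scale steady-state time (~minutes) or the exact shape of
bench-scale profiles outside the layers; qualitative conclusions —
cathode-side enrichment under stimulation, interface layer structure —
transfer, and full-scale configurations remain expressible for offline
use.

Meshing: the 1D and tensor-product square meshes grade element size from
`base_resolution` down to `refined_resolution` inside the band, with the
interface exactly on mesh nodes/lines. The disc scaffold uses a
boundary-fitted O-grid (polar fan inside, radial blend onto the bath
rectangle outside) whose angular resolution tracks
`refined_resolution` at the interface; the four bath-corner directions
are always included so each exterior edge lies on exactly one side. In
the scaled presets `refined_resolution = 4 nm ≈ λ_D/2.7` (1D) resolves
the layers fully; the 2D presets use 12.5–25 nm, which is marginal in
the layer but leaves the bulk plateau intact (the gel radius spans ~23
Debye lengths, so the plateau error stays below 1%).

## Discretization and solvers

All three fields share nodal Lagrange elements of order 1–3 (default 2)
on the same mesh; quadrature is exact to degree `2·order`. Assembly
produces the analytic Jacobian of the coupled weak form; zero-flux
boundaries are natural, Dirichlet data replace matrix rows.

**Scaling.** By default the solver works in scaled unknowns —
concentrations divided by the bath molarity, potential by the thermal
voltage — which turns the hostile raw Poisson coupling
`F/(ε_r ε₀) ≈ 10¹⁴` into the dimensionless Debye coefficient
`ε_r ε₀ RT/(F² c_ref L²)` (`nondimensionalize()` exposes the scales and
the back-transform; `solver_options(nondimensionalize = FALSE)` solves in
physical units and agrees with the scaled path to the solver tolerance).

**Stationary solves** use damped Newton with the affine-covariant
("natural monotonicity") acceptance test: a step `λ·du` is accepted when
the simplified correction `‖J(u)⁻¹F(u + λdu)‖` drops below
`(1 − λ/2)‖du‖`. A raw residual-decrease test is useless here — the weak
residual of an O(1) field scales with the DOF patch volume (10⁻⁹ in the
scaled 1D mesh, 10⁻¹⁶ in 2D), so residual norms are additionally
normalized row-wise by patch volumes for the convergence checks.
Convergence is declared on the scaled residual (`newton_abs_tol`,
`newton_rel_tol`) or on the simplified-correction norm
(`newton_step_tol = 1e−9`, the workhorse criterion). The line search also
rejects trial states whose scaled concentrations drop below −0.2 —
accepted states are never clipped, so this guard cannot break
conservation. If Newton still fails from a uniform start, the fixed
charge is ramped in four continuation steps. The alternative
`strategy = "gummel"` runs a quasi-Fermi Gummel fixed point — the
*nonlinear* Poisson equation with concentrations slaved through Boltzmann
factors frozen at the current state, then the two linear transport solves
— and hands over to Newton when the alternation stalls at its
interpolation-mismatch floor (~10⁻⁵ relative); a plain linear Poisson
step would produce unscreened potentials of hundreds of thermal volts and
destroy the species solves.

**Transients** use backward Euler (first order; the per-step system is
solved implicitly by the same Newton). A step that fails to converge or
produces concentrations below −10⁻¹² of the reference is rejected and
retried with half the step, up to `max_dt_halvings`; the step recovers
gradually afterwards. Negative concentrations are never clipped —
clipping destroys mass conservation, which with zero-flux ion boundaries
holds to round-off per step (the test suite checks ≤10⁻¹⁰ relative).
Steady state is declared when the relative inter-step change rate
`max_field(‖Δ‖∞/‖·‖∞)/Δt` falls below `steady_tolerance` (s⁻¹); the
default 10⁻⁸ s⁻¹ suits bench-scale runs, while the scaled presets use
100 s⁻¹ because their diffusive clock is 10⁹ times faster — the
tolerance should scale like `D/L²` times a relative threshold.

**Initial conditions.** The chemical scenario starts from the uniform
bath state and jumps directly to the stationary solution; the electrical
scenario starts from that equilibrium, per the protocol contract
(`electrical_protocol()$initial_requirement`). Starting a *transient*
from the uniform state with the fixed charge switched on is outside the
intended regime: the instantaneous Poisson solution then carries
unscreened potentials of order `c_f L_gel²/(ε_r ε₀ RT/F²c_ref)` —
hundreds of thermal volts — and the centred drift discretization (no
exponential fitting) is not designed for that transient; the test suite
perturbs the equilibrium instead.

**Conventions left open by the problem statement.** The 50 mV stimulation
is applied as anode = +50 mV, cathode = 0 V (configurable per side); only
the difference matters to the fields. Electrode boundaries keep the ion
concentrations fixed at bath values during stimulation — a well-stirred
bath idealization consistent with salt-bridge-isolated electrodes — and
`insulated` boundaries are zero-flux for everything. If a configuration
supplies no potential Dirichlet datum at all, the solver pins ψ at one
node to fix the Neumann gauge.

## Validation strategy and problem sizes

The tests validate along independent routes: the closed-form Donnan
oracle against a brute-force root search; assembled element matrices
against hand-written and dense-quadrature references; the 1D stationary
solver against a dense finite-difference PNP solve (explicit per-node
formulas, numerically differentiated Jacobian) to 10⁻⁶ relative on a
matched grid; a manufactured Poisson solution confirming spatial order
`p+1` for orders 1–3; pure diffusion against a dense backward-Euler heat
solve; and the stimulation transient for first-order time accuracy,
polarity-swap mirror symmetry and steady-state stability under `Δt`
halving. Suite problem sizes are kept modest — 1D meshes of 200–450
elements (up to ~1300 scalar DOFs at order 2), 2D meshes of 1.5–3k cells
(~10k unknowns) — sizes at which the whole suite runs in well under a
minute while every claim above is still discriminating.

## Known limitations

* No mechanical/swelling coupling (fixed geometry) and no cell-level
  (chondrocyte) effects.
* Ideal Donnan: uniform activity coefficients; the product rule is exact
  only in that idealization.
* Monovalent binary electrolytes only for the closed-form oracle; the
  PDE solver itself takes general valences but is untested beyond ±1.
* Ideal electrodes: Dirichlet data, no Butler–Volmer kinetics, no
  electrolysis products.
* Centred (non-upwinded) drift discretization: robust in the intended
  regimes (≤ a few thermal volts across an element), not for shock-like
  unscreened starts.
* 3D geometry and error-driven adaptive refinement are out of scope; the
  disc scaffold is the 2D stand-in for a cylindrical sample.
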