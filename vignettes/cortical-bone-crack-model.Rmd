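---
title: "Modeling crack deflection at cement lines: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling crack deflection at cement lines: methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(osteocrack)
```

This vignette is the package's own account of its model: what is computed,
under which assumptions, which numerical choices were open and how they were
closed, and what the passing tests do and do not demonstrate about real
cortical bone.

## The model

A single osteon is embedded in a 1 mm × 1 mm square of interstitial matrix
with out-of-plane thickness 100 µm. The osteon cross-section is a circle
(diameter 150 µm) in the *radial* model and a stadium (total length 650 µm,
width 150 µm, rotated 10°) in the *longitudinal* and *transversal* models;
a cement-line band of uniform thickness 5 µm separates osteon from matrix.
All three phases are isotropic linear elastic under plane stress; Haversian
canals are not modeled (the osteon region is solid osteon material). An
initial traction-free edge crack of length 0.1 L enters horizontally at
mid-height, and the plate is loaded in displacement-controlled tension
perpendicular to it: bottom edge fixed in the loading direction, one bottom
corner pinned, top edge displaced uniformly, lateral edges free. The figures
the geometry derives from do not fully specify the constraint set or the
osteon position; we fix *centered osteon, counter-clockwise rotation, free
lateral edges* as configurable defaults.

Damage initiation is strain-driven. Bulk elements (matrix, osteon) use the
maximum principal strain criterion `f_MAXPE = ⟨ε_max⟩/ε⁰_max`, with the
crack normal along the principal direction. Cement-line elements additionally
evaluate the quadratic interface criterion
`f_QUADE = (⟨ε_n⟩/ε⁰_n)² + (ε_s/ε⁰_s)²`, whose crack normal is the interface
normal — exceeding it deflects the crack along the cement line. The Macaulay
brackets make both criteria insensitive to compression; this reading of the
brace notation matches the behaviour of the strain-based initiation criteria
the model names, and a compressive principal strain must not open a crack.
`ε_s` is the engineering shear strain (γ) resolved on the interface frame;
the criterion uses its square, so the sign convention is immaterial.

The cohesive response is mode-independent linear softening: a segment
initiated at traction `T0` transmits `T = T0 (1 − δ*/δ_f)` at the
history-maximum effective separation `δ* `, with
`δ = √(⟨δ_n⟩² + δ_s²)` and `δ_f = 2G/T0`, so the area under the
traction–separation curve equals the strain energy release rate `G` exactly.
Unloading and reloading follow the secant through the origin (irreversible
damage `d = δ*/δ_f`). Because the model prescribes an initiation *strain*
and an energy, not a strength, `T0` is closed from the local state: the
elastic stress of the triggering element resolved on the crack plane at the
moment of initiation (its mode-independent effective traction). This keeps
the triangle law consistent with the strain state that nucleated the segment.

## Crack tracking

The crack is a single polyline of mesh edges. Extension works by
*edge release*: the node at the current tip is duplicated, the element fan
is rewired, and a cohesive segment ties the two new faces. The package's
contract is the polyline plus the cohesive law, not the enrichment
technology; edge release was chosen over Heaviside enrichment because the
graded mesh already provides interface-aligned edges (the cement band is
exactly one element across its thickness, with circumferential edges along
the interface and radial edges across it), so both deflection and
penetration have natural discrete paths.

Per displacement increment the solver: (1) equilibrates with the current
cohesive state, (2) evaluates the initiation criteria at the centroids of
the elements around the tip (the fan, ≈ the 1.5-element-size search radius),
(3) if some criterion exceeds 1, extends the crack by one edge — the fan
edge best aligned with the direction perpendicular to the returned crack
normal, continuing away from the polyline — and re-equilibrates at fixed
displacement until no further initiation. Elements satisfying a criterion
far from the tip cannot fracture (single-crack constraint); the resulting
stiffness overestimation is accepted. When the tip reaches the domain
boundary the last node is also split (the specimen is then fully severed)
and loading continues until the force tail drops, so fracture energies
include the tail.

**Criterion competition.** Initiation requires `max(f_QUADE, f_MAXPE) > 1`.
When a finite increment pushes *both* criteria past 1, the raw maximum is a
biased arbiter: MAXPE grows linearly with the strain amplitude while QUADE
grows quadratically, so any overshoot favours QUADE and produces spurious
interface kinks at osteon entry and exit. The implementation therefore picks
the criterion crossed *first* under proportional scaling of the strain state
(equivalently: it compares `f_MAXPE` with `√f_QUADE`), with ties going to
MAXPE/penetration, mirroring the strict inequality that defines deflection
in the crack-score taxonomy. With infinitesimal increments the two rules
coincide.

A second deliberate asymmetry: when a deflection starts exactly head-on
(propagation direction perpendicular to the interface tangent), the upward
and downward tangents are equivalent; the tie is broken toward the
counter-clockwise tangent, deterministically.

## Numerical choices

- **Integration.** Full 2×2 Gauss quadrature instead of one-point reduced
  integration with hourglass stabilization: the stabilization is proprietary
  to the original solver, and full integration avoids hourglassing outright.
  Criteria are evaluated at element centroids, matching the single-point
  spirit of the original elements. The bilinear quads pass the patch test
  exactly (verified on 100 random distorted patches).
- **Cohesive regularization.** The pure softening law has no elastic branch
  (infinite initial secant). The solver uses a bilinear variant with a short
  elastic branch `δ0 = 0.01 δ_f`; the triangle area — and hence `G` — is
  unchanged exactly. `cohesive_traction()` exposes `δ0 = 0` as the default
  for the law itself.
- **Softening solve.** Equilibrium at fixed displacement is a fixed point
  over the per-segment secant stiffnesses. The history vector converges
  geometrically; Aitken extrapolation accelerates it, the contact set is
  frozen after 50 iterations to stop chattering, and the loop ends when the
  relative change falls below 1e-6 (states within 1e-4 are accepted with a
  warning rather than aborting a sweep). A diagonal shift of 1e-9 times the
  largest stiffness diagonal keeps the factorization definite when fully
  failed faces leave a region floating — the physically meaningful case
  being an osteon completely encircled by the crack.
- **Increments.** The displacement step (default 0.1 µm, capped at 0.5 µm)
  halves when an increment initiates more than 3 segments and doubles after
  5 quiet increments; termination on maximum displacement, force drop below
  1% of the running peak, or boundary contact plus tail drop.
- **Crack-score constants.** The taxonomy's qualitative wordings are fixed
  as documented constants: short deflection < 25 µm (scores 2/3 boundary,
  the printed threshold), far-side matrix exit for score 4, and ≥ 95% of the
  cement-line perimeter for score 5. Deflection length `D` is the summed
  length of QUADE-provenance segments; penetration is any segment midpoint
  more than t/2 inside the osteon boundary (so the chords of a discretized
  interface arc never count as penetration).
- **Fracture energy.** Defined as total external work (trapezoidal area
  under force–displacement to termination). The specimens are loaded to
  failure, so the stored elastic energy at termination is negligible; the
  source analysis never defines the quantity more precisely, and this choice
  is the one consistent with the energy ledger (verified: external work
  equals elastic plus dissipated energy within 2% at every increment).

## Meshing

Osteon models use a conforming O-grid built on a fan of rays from the osteon
centre: a small axis-aligned structured core inside the osteon, rings out to
the osteon boundary, exactly one ring of cement-line elements across the
band, and geometrically graded matrix rings out to the square. The fan
always contains the horizontal rays, so the initial notch is a straight
mid-height edge path. Presets: coarse (512 elements), medium (1 056), fine
(1 856). Phase areas are conserved within 2% at the default (fine) spec and
converge under refinement; the coarse preset, used for parameter sweeps,
carries ≈ 5% polygonalization error on the stadium models — acceptable
because the sweeps read out the ordinal crack score, not converged forces.
Peak forces of the notched-strip fixture change by < 5% between the two
finest of three refinement levels.

## Parameters

The 14-parameter baseline (SI units throughout the API — m, Pa, J/m²;
derived quantities are converted only for display):
`E_mat = 15`, `E_ost = 12`, `E_cl = 18` GPa; all Poisson ratios 0.3; all
MAXPE initiation strains 0.004; `G_mat = G_ost = G_cl = 0.2 kJ/m²`; critical
interface strains `ε⁰_n = ε⁰_s` = 0.00105 (longitudinal), 0.0015 (radial),
0.0035 (transversal) — the midpoints between penetration and deflection per
orientation, which is why baseline behaviour sits near the regime boundary
by construction. Both experiment designs span ±20% of baseline; the
response-surface stage ties the two interface strains into one factor
`eps_cl`. The mapping stage spans G ∈ 0.05–0.4 kJ/m² and
`ε⁰_cl` ∈ 1e-5–0.0045 (0.0005–0.003 for the stiffness variants at
`E_cl` ∈ {9.6, 15, 18} GPa).

## The ANOVA machinery

Importance is `%TSS`: the level-mean sum of squares
`SS_F = Σ N_{F,i}(ȳ_{F,i} − ȳ)²` of a factor's coded column as a percentage
of `SS_T = Σ(y_i − ȳ)²`. In the response-surface analysis the same formula
applies to product and squared coded columns for interaction and quadratic
terms. Note a deliberate property of this estimator: on a three-level
design, a factor's own column carries its quadratic contrast, so the main
term and its square term overlap — `%TSS` columns are descriptive shares,
not an orthogonal decomposition (the screening table, all two-level, *is*
orthogonal and sums exactly with the residual to `SS_T`). The source
analysis reports `%TSS` but never states its error term; for p-values we
take the residual from the least-squares fit of the corresponding
linear/full-quadratic model — on the screening design that is
`df_res = 32 − 1 − 14 = 17`, the only construction consistent with the
available degrees of freedom. Crack score enters the ANOVA as a numeric
response, ordinal as it is — faithful to the analysis being reproduced.

The fold-over construction (14 factors assigned to distinct interaction
columns of a 2⁴ factorial, then mirrored) yields the 32-run resolution IV
array: columns balanced and mutually orthogonal, and every main effect
exactly orthogonal to all 91 two-factor interactions (verified by brute
force). The 62-run Box–Behnken design crosses the 7 triples of a Steiner
system with all 2³ sign patterns plus 6 centre replicates. Both are
textbook-standard arrays; the original study's JMP-generated arrays are
equivalent by design class but not row-for-row identical, which affects no
outcome statistic.

## The surrogate stage

`surrogate_response()` evaluates a polynomial with known main, interaction
and quadratic coefficients on the coded design and adds seeded Gaussian
noise (default σ = 10% of the largest coefficient — strong enough to
exercise the significance machinery, weak enough not to drown planted
effects). It emulates exactly what the ANOVA assumes: a smooth response
surface with known ground truth. It does *not* emulate FEM force–
displacement curves, solver noise, or the discreteness of crack scores, so
surrogate-based tests validate the statistical machinery, not the simulator.
`fixture_crack_path()` plays the same role for the crack-score classifier:
randomized polylines constructed to satisfy exactly one class definition
(class 2 draws its interface arc in 1–22 µm so the discretized arc stays
strictly below the 25 µm threshold; class 5 draws coverage in 95.5–99% of
the perimeter). Classifier agreement over 20 seeds × 5 classes is exact.

## Problem sizes

The test suite and the acceptance script run the coarse preset
(512 elements, ≈ 1 100 dof) with the default loading program; a single
osteon simulation takes a few seconds and a 5-point interface-strain sweep
under a minute. These sizes resolve the region *structure* of the crack
score maps; they do not reproduce the source study's meshes (11 915–27 116
elements) or its absolute outcome values, which came from a different
solver and tracking scheme. The analysis scripts and the mapping stage use
desk-scale 4 × 4 grids by default; finer grids are configuration, not code.

## Known limitations

- Coarse-mesh crack paths are polygonal and slightly asymmetric (the
  head-on deflection tie-break always starts counter-clockwise); scores 2/3
  boundaries can shift by one mesh edge length.
- Baseline behaviour is solver-specific by construction (the interface
  baselines are regime midpoints); our transversal model penetrates at its
  0.0035 baseline, with its deflection threshold between 0.0025 and 0.0035.
- At intermediate interface strains the low-toughness (G = 0.05 kJ/m²)
  column keeps more deflection than the published region maps suggest; the
  encoded qualitative checks (penetration at high interface strength with
  low G, saturation above 0.2 kJ/m², stiffness shift, matrix-toughness
  equivalence) all reproduce, but pixel-level region boundaries are out of
  scope.
- On the coarse mesh the ±20% screening span does not always flip the
  longitudinal crack score (a constant outcome with undefined %TSS); the
  ANOVA stage flags such outcomes instead of ranking them. Occasional
  treatment conditions fail the softening loop and are skipped and flagged.
- Single crack, no branching, no rate effects, no plasticity; compressive
  crack-face contact is penalty-based and frictionless.
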