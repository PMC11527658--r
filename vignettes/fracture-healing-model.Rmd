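---
title: "The callusim fracture-healing model: mechanics, controller, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The callusim fracture-healing model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(callusim)
```

`callusim` is a deterministic mechanobiological simulator of secondary bone
fracture healing. This vignette is the package's own account of the model:
what is computed, which parameters matter, which choices were genuinely
open and how they were made, and what the automated tests do and do not
demonstrate.

## The physical scenario

The simulated scenario is a transverse mid-diaphyseal osteotomy of a
long bone held by an external fixator and loaded axially. Six fixation
groups combine compressed-state gap widths of 1, 2 and 6 mm with allowed
inter-fragmentary strains (IFS) of 7% and 31%. Because the experimental gap
widths refer to the loaded state, the unloaded model is built with the gap
scaled up, `GW_unc = GW(1 + IFS)`, giving 1.07, 1.31, 2.14, 2.62, 6.42 and
7.86 mm for groups A–F; the fixator's compliant free travel is `GW · IFS`.

The bone is a hollow cylinder (outer radius 8 mm, cortex 2 mm) of lamellar
bone; the callus starts as pure soft tissue inside a standardised domain of
maximal radius 24 mm and axial length 52 mm. Loading is purely axial
(500 N), which justifies the axisymmetric idealisation: the fixator of the
reference experiments is reported to be torsionally and laterally rigid,
and the instrumented bone is predominantly axially loaded.

### The callus outline

Only the bounding dimensions of the standardised callus domain are
published; the exact outline is shown in figures without equations. The
package constructs the outer profile as a cosine arc
`R(z) = 8 + 16·cos(πz/52)` — smooth, attached to the periosteum at
`z = ±26` mm, reaching 24 mm radius at the mid-plane — and exposes it as a
config-overridable function (`fracture_geometry(profile = ...)`). This
openness is deliberate: the healing outcome is demonstrated (by test) to be
insensitive to the domain size, so any smooth profile with the stated
bounding box is acceptable.

## Finite-element core

The (r, z) cross-section is meshed with linear (constant-strain) triangles
at a target mean edge of 0.35 mm: structured grids in the cortex and gap,
and a deterministic column-zipper triangulation in the external callus.
Meshing has no randomness; node order depends only on geometry and target
edge, so repeated runs are bit-identical.

Elements use one-point (centroid) quadrature with the full-ring volume
weight `2π r̄ A`; all forces, reactions and the fixator spring are total
(full-ring) quantities — mixing per-radian and full-ring conventions is the
classic axisymmetric bug, so the convention is stated here once and used
everywhere. Strains are element-wise constant; the hoop strain is `u_r/r`
at the centroid (with the `∂u_r/∂r` limit on the axis). The three principal
strains are the two in-plane eigenvalues plus the hoop strain, and the
distortional strain is the octahedral shear strain
`γ_oct = (2/3)·√[(ε₁−ε₂)² + (ε₂−ε₃)² + (ε₃−ε₁)²]`, the convention of the
tissue-differentiation threshold literature (the source text never defines
it); the choice is configurable in principle by supplying a different
post-processing of `recover_strains()` output.

Rigid end plates are modelled by tying each end-face node to a control
node: `u_r = 0` and a shared axial displacement (a rigid plate cannot
deform radially). The distal control node is fixed; the proximal one
carries the load and the spring. The piecewise-linear spring
(4600 N/mm → 10 N/mm over the free travel → 4600 N/mm, continuous and
non-decreasing) makes the problem nonlinear in exactly one scalar, so
instead of Newton iteration the solver factorises the spring-free operator
once, solves for the load case and a unit control force, and resolves the
scalar balance segment-by-segment in closed form. The residual is at
round-off, well below the 10⁻⁸ relative tolerance the solver is tested
against. No bone-end contact is modelled: the spring stiffens before the
gap can close, which matches the reference model description.

### The axisymmetric patch test

A subtlety worth recording: in axisymmetry an arbitrary linear
displacement field does *not* have constant strain (the hoop strain is
`u_r/r`), and a constant `γ_rz` is not even an equilibrium state (the
z-equilibrium equation carries a `σ_rz/r` term). The admissible
constant-strain equilibrium family is `u_r = b·r`, `u_z = a + c·z`, for
which `σ_rr = σ_θθ` and `σ_rz = 0`. For this family the one-point rule
integrates every internal-force term exactly (the `r̄` in the volume weight
cancels against the `1/r̄` of the hoop row), and the test suite verifies
reproduction to ~10⁻¹⁶. Testing the literal "any linear field" would fail
for any consistent axisymmetric element and would be testing the wrong
statement.

## The biological controller

Each callus element carries fractions `(c_soft, c_cart, c_bone)` on the
unit simplex; `c_soft` is always derived as `1 − c_cart − c_bone`. Element
properties follow a cubic rule of mixtures for stiffness and a linear one
for the Poisson ratio. The cubic law has a consequence worth knowing: a
dilute mixture is *softer* than either constituent (0.9 soft / 0.1
cartilage gives 2.4 MPa against 3 MPa for pure soft tissue), so the IFM
can tick up by a fraction of a percent when chondrogenesis first switches
on. This is visible as a small bump around iterations 8–12 and is treated
as part of the "early phase" by the tests.

Controller inputs per element: the compressive magnitude of the minimum
principal strain, the tensile part of the maximum principal strain and the
distortional strain (all in percent — the membership functions' axes are
interpreted as percentages, the natural scale of the threshold literature);
the element's own `c_bone`, `c_cart`; and the maxima `cnBone`, `cnCart`
over all elements sharing at least one node. Bone-fragment elements are
included in neighbour sets with `c_bone = 1`: without this the rule table
could never activate from the initial all-soft state, and it is exactly
what makes ossification fronts start at the cortex/periosteum.

Four biological processes are encoded as fuzzy rules (AND = min,
OR-within-a-clause = max, standard Mamdani-style operators; the inference
scheme is a design choice, as the source only states that each rule yields
a degree in [0, 1]):

| process | antecedents | ΔBone | ΔCart |
|---|---|---|---|
| intramembranous ossification | Cart Low, nBone Med∨High, ε_max Med, γ_oct Low | +1 | 0 |
| chondrogenesis (×2: nBone or nCart variant) | Bone Low, nBone/nCart Med∨High, ε_min Med, ε_max Low, γ_oct Low | 0 | +1 |
| cartilage calcification | Bone High, Cart Low, nBone High | +1 | −1 |
| endochondral ossification | Cart Med∨High, nBone Med∨High, ε_min Low | +1 | −1 |

Both chondrogenesis rows act simultaneously and their contributions sum.
Chondrogenesis is disabled for the first 7 iterations (preventing
non-physiological periosteal cartilage). The cartilage-calcification row is
implemented exactly as published even though it reads oddly (it requires
Cart Low yet consumes cartilage); clamping prevents negative cartilage, and
the rule table is config-overridable for anyone wanting to experiment with
a transposed variant.

Summed rule effects are scaled by `κ · ℓ_ref/ℓ_elem` with
`ℓ_elem = √(2·area)` and `ℓ_ref = 0.35` mm: smaller elements change
proportionally faster, which keeps the ossification-front *speed* (mm per
iteration) mesh-independent — the stated purpose of the element-size
coefficient. Increments are added to a running un-smoothed composition; if
they would push `c_bone + c_cart` past 1 both increments are scaled down
jointly (preserving the ΔBone:ΔCart ratio — scaling the totals instead
would violate bone monotonicity), then cartilage is clamped at zero. The
composition used for mechanics and as controller input is the arithmetic
mean of the last `N = 5` un-smoothed states. Because every default rule has
ΔBone ≥ 0, the un-smoothed bone fraction is non-decreasing, and so is any
windowed mean of it — a property the tests assert every iteration.

## Convergence of a healing run

Healing is declared converged once the relative IFM change (vs the
previous iteration) stays below 1% for the remainder of the history. The
"stays" matters: during the first several iterations newly formed bone is
mechanically nearly invisible (E ∝ c³), so the IFM curve is briefly flat
before the active phase; a literal "first iteration with < 1% change"
criterion would declare every run converged at iteration 2 and, worse,
would declare the non-union group converged while its IFM is still
drifting. The settled reading reproduces both published signatures: the
low-strain 1 mm-gap group settles at iteration 55 and the 6 mm/31% group
never settles within 150 iterations. Runs always complete all 150
iterations — convergence is recorded, not used to stop — because the final
fields are needed for the bending assessment.

## Calibration: membership functions, κ and N

The membership-function breakpoints are published only as figure shapes,
so the shipped defaults are a reconstruction, anchored to the classical
tissue-differentiation thresholds and then calibrated — exactly the role
the temporal-smoothing window `N` and element-size coefficient `κ` play in
the original description (they were used to achieve mesh convergence, and
the stated design target is that the 1 mm/7% group settles in roughly
50–60 iterations). The calibration procedure was: measure the iteration-1
strain distributions in three zones (periosteal layer, external over-gap
region, gap interior) for the extreme groups, place the Med bands so that
intramembranous ossification fires periosteally near the gap,
chondrogenesis fires in the over-gap external region at moderate
compression, and the gap interior stays initially inert; then tune κ so
the 1 mm/7% group settles at iteration 55. The result is
`κ = 0.457`, `N = 5`, and the trapezoids returned by
`membership_defaults()` (strain axes in percent):

* ε_min (compressive): Low (0,0,3,8), Med (4,8,18,28), High (18,28,∞)
* ε_max (tensile): Low (0,0,2,6), Med (4,8,12,17), High (12,17,∞)
* γ_oct: Low (0,0,8,18), Med (8,18,25,35), High (25,35,∞)
* tissue fractions: Low (0,0,0.15,0.4), Med (0.25,0.5,0.6,0.8), High (0.6,0.8,1,1)

Two caveats are flagged deliberately. First, the settle iteration is
*chaotically* sensitive to κ: activity arrives in discrete waves, and a
±1% change in κ can move the settle point by ±10 iterations. The value is
reproducible because the pipeline is bit-deterministic, but any
quantitative statement tied to a specific settle iteration should be read
with that sensitivity in mind. Second, all downstream quantities that
depend on the figure-digitised breakpoints (settle iterations, absolute
bending stiffnesses) inherit their uncertainty; the robust, calibration-
insensitive outputs are the *qualitative* signatures — periosteal onset,
external bridging, union vs non-union discrimination — and those are what
the acceptance-style tests gate on.

## Virtual bending test

After 150 iterations the fixator is removed, the fragments are extended to
a 150 mm construct and the cross-section (cortex at 1 mm, callus at
0.5 mm target edges, scalable by a `coarse` factor) is revolved into
tetrahedra. Prisms are split into three tets with the smallest-global-index
diagonal rule (prisms are flipped when their minimal vertex lies on the top
face — without that normalisation adjacent prisms can disagree about a
shared quad diagonal and the mesh leaks); the tests verify every interior
face is shared by exactly two tets. Callus tets take the E and ν of the
nearest 2D callus-element centroid after collapsing their centroid to
(r, z). Since element fields are piecewise constant, nearest-centroid
lookup agrees with linear interpolation at every sampling site the
published mapping defines, and *is* the published "nearest" rule outside
the centroid hull; constant fields map to constant fields exactly.

End faces are tied to control nodes (6 rigid-body DOFs); the distal control
is fixed in 5 DOFs, the proximal in 4 (axial translation free), and equal
and opposite 1500 N mm moments about a transverse axis produce pure
bending. Deflection is read as the bending-plane transverse displacement at
the callus node nearest the construct centre (the component, not the total
magnitude — the difference is negligible in pure bending), and stiffness is
reported in N m per mm. A homogeneous lamellar tube agrees with the
`M L²/(8EI)` beam solution within 10% at desk-scale resolution (within 1%
at 1 mm edges), and the response is exactly linear in the moment.

## Problem sizes used by the automated checks

The default 2D resolution (0.35 mm, ≈ 15 000 triangles, ≈ 75 s per
150-iteration run) is used wherever a published quantity is checked: the
group A settle iteration, the group F non-convergence, and the healing
states feeding the bending discrimination test. The bending models for
those checks use a 4× coarsened mesh (≈ 43 000 tets): the discrimination
ratio changes by under 2% between 4× and 3×, while the full 0.5 mm
resolution (millions of tets) is far beyond a desk-scale run. Unit and
property tests use 1.2–4 mm meshes, chosen so the entire suite stays in
the minutes range.

## What the tests show — and what they do not

The suite demonstrates, at the resolutions above: exact geometry
derivations; an exact axisymmetric patch test and a 1%-accurate
closed-form tube compression; machine-precision load balance; simplex
conservation and bone monotonicity at every iteration; the zero-load fixed
point (an unloaded callus stays pure soft tissue for 150 iterations);
share-a-node adjacency equal to a brute-force oracle; periosteal
ossification onset and external (never purely inter-cortical) first
bridging; insensitivity of the outcome to a +13%-radius/+20%-length callus
domain; group A settling at 55 and group F not settling; and a ≥ 3×
bending-stiffness separation between united groups and the non-union.

They do not demonstrate: absolute bending-stiffness magnitudes comparable
to experiments (woven bone never remodels to lamellar here, so simulated
healed stiffnesses sit well below experimental means — a known limitation
of the model class); behaviour under non-axial or dynamic loads;
anisotropic tissue response; or biological variability — the simulator is
deterministic, and borderline scenarios that in vivo split into healers
and non-healers produce a single intermediate trajectory here.
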