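# callusim — strain-based simulation of bone fracture healing

`callusim` simulates secondary fracture healing of a long-bone osteotomy
stabilised by an external fixator, and predicts whether the fracture unites
or ends in non-union. It is written for computational mechanobiologists and
implant/fixator engineers who want an *in silico* test bench for fixation
stiffness, gap width and loading scenarios.

## The model

The simulator couples three components in an iterative loop (150 iterations
by default):

1. **Axisymmetric finite-element model.** An 80 mm section of a hollow
   diaphysis (outer radius 8 mm, cortex 2 mm, lamellar bone,
   E = 10000 MPa) with a transverse osteotomy and a standardised callus
   domain (max radius 24 mm, length 52 mm) is meshed with linear triangles
   (mean edge 0.35 mm). The external fixator is a nonlinear axial spring —
   4600 N/mm up to 100 N, then 10 N/mm over the group-specific free travel,
   then 4600 N/mm again — and a 500 N axial load is applied through rigid
   end plates. Six fixation groups A–F combine compressed-state gap widths
   of 1, 2 and 6 mm with allowed inter-fragmentary strains (IFS) of 7% and
   31%; the modelled (unloaded) gap is `GW(1 + IFS)`.

2. **Fuzzy-logic biological controller.** Each callus element is a mixture
   on the simplex `c_soft + c_cart + c_bone = 1`, with element properties
   given by mixture rules `E = Σ E_t c_t³` and `ν = Σ ν_t c_t` over soft
   tissue (3 MPa, 0.30), cartilage (200 MPa, 0.45) and woven bone
   (4000 MPa, 0.36). The element's minimum-principal, maximum-principal and
   octahedral-shear (distortional) strains, its own bone/cartilage
   fractions, and the maxima over its share-a-node neighbours are fuzzified
   into Low/Med/High categories and fed to four rules: intramembranous
   ossification (moderate tension near existing bone), chondrogenesis
   (moderate compression; disabled for the first 7 iterations), cartilage
   calcification, and endochondral ossification (low compression in
   cartilage near bone). Rule activations (min/max inference) move the
   composition by ±1 consequents scaled by `κ · ℓ_ref/ℓ_elem`, and the
   state driving the mechanics is the mean over the last N = 5 un-smoothed
   updates.

3. **Healing assessment.** The inter-fragmentary movement (IFM) is recorded
   every iteration; healing has converged once the relative IFM change
   stays below 1%. At the end, the final state is revolved into a 3D
   tetrahedral model of a 150 mm construct (fixator explanted), a
   1500 N mm pure bending moment is applied, and the bending stiffness
   (moment / mid-callus deflection, N m/mm) quantifies union vs non-union.

With the shipped defaults the low/moderate-strain groups unite (external
callus bridging, IFM decaying to a few hundredths of a millimetre; group A
settles at iteration 55) while group F (6 mm gap, 31% IFS) never converges,
never bridges and keeps an order-of-magnitude lower bending stiffness.

## Worked example

```r
library(callusim)

cfg <- healing_config("B", target_edge = 1.2, iterations = 80) # desk scale
res <- run_healing(cfg)
print(res)
#> <healing_result> group B - 80 iterations
#>   IFM: 0.3808 -> 0.0369 mm
#>   converged at iteration 37 (<1% IFM change)
#>   final composition: max bone 1.000, max cartilage 0.195

bm <- build_bending_model(res, coarse = 6)
br <- virtual_bend(bm)
print(br)
#> <bending_result> M = 1500 N mm, deflection 0.1795 mm, stiffness 8.36 N m/mm
```

The run above uses a coarsened mesh (1.2 mm edges instead of 0.35 mm, and a
6× coarser bending mesh) so it finishes in seconds: the 31%-IFS group B
starts with a large IFM (0.38 mm), stiffens as periosteal bone and then
cartilage form, settles below a 1% IFM change at iteration 37 at this
resolution, and its healed construct resists bending at 8.4 N m/mm — close
to the homogeneous lamellar tube (≈ 7.9 N m/mm), i.e. a solid union. At the
default 0.35 mm resolution the same group settles at iteration 86.

A command-line driver with `mesh`, `heal`, `bend`, `campaign`,
`domain-independence` and `dump-defaults` subcommands lives at
`inst/scripts/callusim-cli.R`.

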