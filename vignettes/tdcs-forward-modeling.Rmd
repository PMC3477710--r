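---
title: "Forward modeling of tDCS current flow on voxelized head phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forward modeling of tDCS current flow on voxelized head phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tdcssim)
```

## The problem

Transcranial direct current stimulation (tDCS) passes a weak direct
current (conventionally 1--2 mA) through scalp electrodes. How much of
that current reaches the cortex — and where — depends both on the
operator-controlled *dose* (electrode montage and total current) and on
the subject's anatomy: head size, skull thickness, the conductive CSF
layer, and cortical folding. `tdcssim` implements the forward problem on
voxelized multi-tissue head models: it predicts the cortical electric
field (EF) for a given head and montage, quantifies how much that
prediction varies across heads, and computes the current rescaling that
equalizes peak cortical EF across subjects.

Because subject MRIs are not distributed with the package, heads are
*synthetic phantoms*: layered spheres (skin, skull, CSF, gray matter
around a white-matter core) with optional sinusoidal gyral folding. The
spherical geometry is deliberate — it admits an exact series solution
against which the numerical solver is validated.

## Physical model

At DC the quasi-static volume-conduction approximation holds and the
potential obeys

$$\nabla \cdot (\sigma \nabla V) = 0,$$

with isotropic conductivity $\sigma(\mathbf{x})$, insulated external
surfaces, a fixed total current $I$ injected at the anode, and ground
($V = 0$) at the cathode(s). The electric field is $\mathbf{E} = -\nabla
V$. Tissue conductivities (S/m) are the standard literature averages:
skin 0.465, skull 0.01, CSF 1.65, gray matter 0.276, white matter 0.126,
air $10^{-7}$, electrode conductor $5.8\times10^{7}$, saline-soaked
sponge 1.4, conductive gel 0.3. Air keeps a small positive conductivity
instead of being masked out, so the insulating head boundary emerges
physically from the conductivity contrast rather than from a special
boundary treatment.

Two montages are built in:

* **Pad (M1--SO)**: two 5 cm x 5 cm sponge pads, anode over a left
  motor-cortex-like site, cathode over the contralateral supraorbital
  region.
* **4x1 high-definition ring**: a central 12 mm anode disc surrounded by
  four 12 mm cathode discs at 6 cm scalp-geodesic distance, coupled
  through gel.

## Discretization

The PDE is discretized with a 7-point finite-volume stencil on the voxel
grid. The conductance of the face between two adjacent voxels is the
harmonic mean of their conductivities times face area over spacing —
the exact series composition of two half-voxel resistors, so layered
media aligned with the grid are reproduced to machine precision. The
anode's total current enters as a uniform Neumann flux across the
exterior faces of its conductor voxels (`electrodeMode = "resistive"`);
since the conductor is eight orders of magnitude more conductive than
tissue it is effectively equipotential, and an explicit
floating-potential formulation (`electrodeMode = "equipotential"`, which
merges the anode conductor into a single supernode carrying the total
current) agrees with it on tissue fields to well under 1%. Cathode
conductor voxels are grounded (Dirichlet $V=0$). The operator is
symmetric positive definite on the free voxels and is solved with
Jacobi-preconditioned conjugate gradients from a zero start to a
relative residual of $10^{-6}$ (the `solverConfig()` default), making
solves bit-reproducible. All internal computation is in SI units; the
grid spacing is converted from millimeters once at assembly.

A per-electrode current audit integrates $\sigma \nabla V \cdot
\hat{n}$ over each electrode's contact surface after every solve;
conservation holds to fractions of a percent of the injected current
(dominated by the CG residual).

## The analytic oracle

An N-layer concentric-sphere model with two point current electrodes on
the scalp has a closed-form Legendre-series solution. Per harmonic
degree the radial coefficients follow from continuity of $V$ and
$\sigma \partial V/\partial r$ at each interface, regularity at the
origin, and the surface point-source flux condition; the implementation
propagates a 2x2 recursion across layers in a radius-ratio
parametrization that stays numerically stable to degree 240 and beyond.
The series is checked in the tests against the textbook homogeneous
closed form, against finite differences of itself, and against its own
interface conditions. The default truncation (120 terms) resolves
mid-cortex queries to much better than 0.1%; a successive-term bound
raises an error suggesting a larger `nTerms` when a query point is too
close to the surface for the truncation.

Solver-versus-oracle comparisons exclude a 24 mm zone around each
electrode point (two 12 mm electrode diameters), where the rasterized
disc electrodes and the oracle's point electrodes legitimately differ,
and compare potentials after removing each side's mean over the
comparison set, because the numerical ground and the series reference
differ by a constant.

### What the voxel model can and cannot reproduce

On grid-aligned layered media the discretization is exact, and on a
homogeneous sphere the solver agrees with the oracle to about 1% at
2 mm voxels. On a *multilayer* sphere with the full skull/CSF contrast
(ratio 165), the staircase representation of curved tissue interfaces
systematically overestimates transmission through the resistive skull:
the gray-shell relative L2 discrepancy is dominated by a nearly uniform
scale factor (shape agreement after rescaling is a few percent) and
shrinks roughly linearly with voxel size — the acceptance script
measures it at 3 mm and 2 mm. This is a known property of voxelized
(staircase) volume-conductor models at high conductivity contrast, and
it is the reason the package reports the oracle discrepancy prominently
rather than hiding it: comparisons *between* phantoms solved at the same
resolution (fold-variation, containment, dose scaling) share the bias
and are much more accurate than the absolute field values.

## Synthetic phantoms: what they emulate

The phantom generator stands in for segmented subject MRIs:

* **Layered spheres** emulate the six-tissue segmentation (skin, skull,
  CSF, gray, white, air) at 1 mm isotropic resolution by default. Voxels
  are classified by their center's distance from the head center — no
  partial-volume fractions — which keeps an independent brute-force
  oracle trivial and matches a voxelized segmentation workflow.
* **Subject presets** (M1, M2, F in `inst/extdata/subjects.yaml`)
  emulate inter-individual variation with ~10% spread in head radius and
  skull thickness spanning 4--7 mm; the smallest head (F) also has the
  thinnest skull and CSF. The presets are illustrative conventions, not
  reconstructions of any real subject, since no quantitative anatomy is
  available for the heads they emulate.
* **Gyrated spheres** modulate the gray/CSF interface radius as
  $r(\theta,\varphi) = r_0 + A \sin(k\theta)\sin(k\varphi +
  \text{phase})$ with the gray sheet keeping its radial thickness, so
  CSF fills the grooves. This reproduces the *mechanism* of sulcal field
  hotspots (highly conductive CSF channeling current to the fold
  bottoms) with a testable parametric form; it makes no claim to
  anatomically realistic folding. The fold phase derives from the
  integer seed by the golden-ratio map $\text{phase} = 2\pi\,
  \mathrm{frac}(s\cdot(\sqrt5-1)/2)$, so phantoms are portable across
  implementations. The amplitude must stay below the CSF + gray
  thickness so folds never pierce the skull or the white core.
* **Slabs** provide the closed-form Ohm's-law test bed
  ($|E| = I/(A\sigma)$ between opposing plates).

Consequently, passing tests demonstrate correct physics and correct
code on idealized geometry; they do not demonstrate accuracy on real
gyrified anatomy, where segmentation quality and anisotropic white
matter/skull conductivity (not modeled here) matter.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| total current | 1e-3 | A | conventional 1 mA dose |
| CG tolerance | 1e-6 | relative residual | solver stopping rule |
| voxel size | 1 | mm | emulated segmentation resolution |
| pad size | 50 x 50 | mm | conventional sponge pad |
| disc diameter | 12 | mm | HD electrode |
| ring distance | 60 | mm | geodesic anode-to-cathode spacing |
| sponge / gel / conductor thickness | 5 / 2 / 1 | mm | physically typical; never stated with the montage definitions, recorded in `montage_defaults.yaml` so they are auditable |
| robust peak | 99.9th percentile | — | guards metrics against single-voxel spikes |
| focality threshold | 50% of robust peak | — | convention for "modulated" cortex |
| containment region | ring-radius geodesic disc | — | scalp projection is radial |

The 6 cm ring spacing is interpreted as *geodesic* distance along the
scalp (electrodes are physically placed on the head); a chord
interpretation would understate separation on small heads. Pad edges
align with the local $(\theta,\varphi)$ tangent axes at the pad center —
a reproducible default in the absence of any stated orientation. On
coarse grids the rasterizer guarantees at least one voxel layer of
contact medium and conductor regardless of the nominal thicknesses.

## Metrics and dose normalization

`peakCorticalEF()` reports both the raw maximum over cortical-surface
locations (the headline number, matching how peak EF values are
conventionally quoted) and a robust 99.9th-percentile peak, because
voxelized fields produce occasional discretization spikes; ties break by
grid storage order. "Cortical surface" is operationalized as gray voxels
with a 6-connected CSF neighbor; outward normals come from the gradient
of a Gaussian-smoothed gray+white indicator. The signed normal component
uses the convention *positive = inward current* (anodal, depolarizing).

`containmentFraction()` operationalizes "activation circumscribed by the
ring": the fraction of suprathreshold (>= 50% of robust peak) cortical
locations whose radial scalp projection falls inside the ring's geodesic
disc. The 50% threshold and the 95% acceptance level are package
conventions — the claims they operationalize are qualitative — and both
are parameters.

`normalizeDose()` exploits linearity of the DC problem: scaling the
injected current scales every field value identically (verified to
solver tolerance in the tests), so a subject reaching peak $p_s$ at the
base current matches a reference peak $p_r$ at current $I \cdot p_r /
p_s$. A head that concentrates x-fold more field than the reference
therefore gets its current divided by x.

## Numerical choices and degenerate inputs

* Zero CG start and a fixed iteration order make residual histories
  bit-reproducible; non-convergence raises a structured error carrying
  the residual history.
* Gradients use central differences, falling back to one-sided where the
  stencil would cross into air, so scalp fields are not contaminated by
  the (unphysical) air potentials. Air voxels are excluded from every
  reported metric.
* An empty suprathreshold set makes containment undefined; it is
  reported as `NA` with a warning rather than a number.
* Degenerate gyration (amplitude 0) reproduces the smooth sphere
  bit-for-bit; equal subject specs give fold-variation exactly 1.
* Overlapping electrode footprints, footprints off the skin, montages
  without exactly one anode, unknown conductivity labels, and malformed
  NIfTI sidecars all fail with errors naming the offending entity.

## Problem sizes used by the tests and acceptance script

The shipped tests validate the solver on reduced geometries chosen so
the whole suite runs in minutes: a 96 x 96 x 48 mm slab at 2 mm voxels
for the closed form, the full-size (92 mm) four-layer sphere at 3 and
2 mm for the oracle comparison, and 60 mm heads at 2.5 mm voxels for the
montage-level claims (containment, sulcal hotspots, skull shielding,
dose round trip). The acceptance script repeats those computations from
scratch at the same sizes. Full-resolution (1 mm, 204^3) solves use
about 8 million unknowns and a few GiB of memory and are supported by
the same code path.

## Known limitations

* Staircase interface bias at high conductivity contrast, as described
  above: absolute cortical-field magnitudes carry a systematic,
  resolution-dependent scale error against the analytic sphere (the
  acceptance script prints the measured values); cross-subject
  comparisons at matched resolution largely cancel it.
* Isotropic conductivities only; skull and white-matter anisotropy are
  out of scope.
* Spherical scalp assumed by the montage rasterizer (radial extrusion);
  slab faces are handled specially. Arbitrary imported heads can be
  read and solved, but electrode placement on strongly non-spherical
  scalps is not supported.
* The sinusoidal fold model produces gentle, wide grooves (aspect ratio
  well below 1). It reproduces the *field-raising* effect of folding —
  the gyrated phantom's peak cortical EF exceeds the smooth phantom's —
  but the surface peak localizes on fold crowns (nearest the anode, with
  only a thin CSF film above) rather than at trough bottoms: the
  crack-tip-like concentration that pins hotspots to the bottom of real
  sulci needs narrow, deep, slit-like grooves that a spherical-angle
  sinusoid cannot express at resolvable wavenumbers. The corresponding
  trough-location check in the test suite documents this as an expected
  failure of the parametric fold model, not of the solver.
* Point-electrode oracle vs disc-electrode solver near-field mismatch is
  handled by exclusion, not modeled.
* No claim is made about behavioral or clinical consequences of any
  simulated field value.
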