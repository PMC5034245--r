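---
title: "Parameterizing protein helices: model, fitting and motion analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parameterizing protein helices: model, fitting and motion analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(helixforge)
```

## The four-sub-helix model

`helixforge` describes a straight protein helix as four co-axial
sub-helices, one traced by each backbone atom type N, Cα, C and O. All
four share the axis direction **n**, a reference point **P** on the axis,
the pitch $s$ (Å per 360° revolution) and the angular turn per residue
$\Omega$ (degrees); each sub-helix has its own radius $r_A$, axial offset
$t_A$ and phase $\phi_A$. The atom of type $A$ at residue index $i$ sits
at

$$
x_A(i) = P + \left(\tfrac{i\,s\,\Omega}{360} + t_A\right) n
       + r_A \cos(i\Omega + \phi_A)\, a
       + r_A \sin(i\Omega + \phi_A)\, b ,
$$

where $(a, b)$ is an orthonormal frame normal to $n$, built
deterministically from an auxiliary vector ($+z$ globally, $+x$ when the
axis is within ~25° of $z$) so that identical axes always give identical
frames and phases are comparable between fits. The axial rise per residue
is $s\Omega/360$ — for the canonical α helix ($\Omega = 100$,
$s \approx 5.67$ Å) that is about 1.58 Å.

The model assumes the segment is *straight*: one axis for all residues.
Bent or kinked ranges are deliberately out of scope for a single fit —
the fit does not fail, but its rmsd grows several-fold, which is exactly
how the quality-check panel flags them. The intended treatment is to
split the range at the kink and fit the parts separately.

### Why 19 free parameters

With $t_{C\alpha}$ pinned at 0 as the axial reference, the free scalars
are: $P$ (3), the axis direction cosines (3), four radii, $s$, $\Omega$,
three axial offsets and four phases — 19 in total. We expose the axis to
the optimizer as all three direction cosines, normalized inside the
forward model, rather than as two spherical angles. The count of 19 with
the Cα offset structurally excluded is a fixed design contract of the
model (tested as such); the magnitude of the direction-cosine vector is a
gauge direction with zero gradient, which the Levenberg–Marquardt damping
absorbs without ill-conditioning, and the parameterization has no polar
singularities, unlike spherical angles for near-$z$ axes.

All four phases are fitted independently. Real backbone geometry makes
the inter-atom phase offsets nearly constant, but constraining them would
change the parameter count and blind the fit to genuine local
distortions; the independent phases are also what makes the circular mean
(the *torsional position*) a meaningful aggregate.

## Fitting and gauge conventions

`fitHelix()` minimizes the sum of squared distances between observed and
model atoms with `minpack.lm::nls.lm`. Tolerances: relative cost
`ftol = 1e-12`, parameter `ptol = 1e-12`, gradient-orthogonality
`gtol = 1e-10`, at most 1024 iterations (the optimizer's ceiling). The
gradient criterion matters on noisy data, where the $10^{-12}$ cost
tolerance sits below the numerical-Jacobian noise floor; without it, fully
converged fits would run to the iteration cap and be mislabeled.
Non-convergence is reported (`converged = FALSE`, with the best-so-far
parameters), never silently accepted.

Initialization is deterministic and needs no seed: the axis starts at the
principal axis of the Cα covariance, and all remaining parameters come
from closed-form regressions about that axis — the twist from unwrapped
azimuth increments, the rise and offsets from axial projections, phases
from circular means. We deliberately do not start the twist at a fixed
100 °/residue: a 3/10 (120) or π (80) segment started 20°/residue away
risks converging into a phase-aliased local minimum, whereas the
closed-form start is already near-exact on clean data and unbiased on
noisy data.

A fitted helix has gauge freedom: the axis sign, the position of $P$
along the axis, and the phase origin leave the coordinates unchanged.
Fits are normalized so that independent fits of the same coordinates are
comparable to $10^{-6}$:

* the axis is oriented from the first to the last residue (N→C);
* $P$ is the axial foot of the Cα sub-helix at the first residue
  (residue index 0), which is precisely what makes $t_{C\alpha} = 0$
  exact rather than approximate;
* phases are reported in the deterministic basis frame and wrapped to
  $[-180, 180)$.

An alternative convention — $P$ at the perpendicular foot of the atom
centroid — is equally deterministic but incompatible with keeping
$t_{C\alpha}$ identically zero at a fixed index origin; we chose the
convention that preserves the parameter structure. Right-handed helices
carry $\Omega > 0$; a genuinely left-handed solution is reported with
$\Omega < 0$ and flagged, since for protein transmembrane helices it
signals pathological input. Degenerate inputs error early: fewer than 5
complete residues ("segment too short" — 19 parameters against 12
coordinates per residue wants a comfortably overdetermined system), or
all atoms collinear within $10^{-6}$ Å (no axis is defined). Residues
missing any backbone atom are dropped with a warning before fitting;
imputing them would bias radii and phases.

## Dihedrals and twist

The map between backbone dihedrals and helical twist is built from exact
geometry rather than an empirical formula: two consecutive residues are
constructed with standard bond lengths and angles (N–Cα 1.458 Å, Cα–C
1.525 Å, C–N 1.329 Å; N–Cα–C 111.2°, Cα–C–N 116.2°, C–N–Cα 121.7°;
planar trans peptide) at the given $(\phi, \psi)$, and
`omegaFromDihedrals()` returns the signed rotation angle of the rigid
screw that carries one (N, Cα, C) triad onto the next. On the helical
ridge this reproduces the classical calibration — dihedral sums
$\phi+\psi$ near $-75$, $-105$ and $-140$° for twists of 120, 100 and
80 °/residue:

```{r calibration}
omegaFromDihedrals(c(-42.5, -57.5, -75), c(-32.5, -47.5, -65))
idealHelixDihedralSum(c(120, 100, 80))
```

The inverse, `idealHelixDihedralSum()`, root-finds along a line in
$(\phi, \psi)$ space parameterized by the sum with the difference
$\phi - \psi$ held at $-10$° (the ideal-α value). The choice of line is a
convention we had to fix: the twist surface over the helical region is
nearly a function of the sum alone (under 2° of twist variation as the
difference sweeps $\pm 30$°), so any reasonable line gives the same sums
to within a couple of degrees.

Form classification (`classifyHelixForm()`) is nearest-ideal with
boundaries at the midpoints 110 and 90 °/residue; exact boundary values
resolve to α as the overwhelmingly most common form, and anything outside
[70, 130] is "other".

## Comparing states and helices

Cross-state comparison (`stateMotion()`, driven by `cmdCompare()`)
requires two conventions the raw model does not fix:

* **Superposition frame.** Phases and reference points live in the
  crystal frame, so state 2 must first be rigidly superposed onto state
  1. The caller names the reference selection; `cmdCompare()` defaults to
  the Cα atoms of all configured segments, matched by chain and residue
  number, aligned by least squares (Kabsch). The choice is recorded in
  the output metadata — different references answer different questions
  (e.g. superposing on TM6 alone isolates motions relative to TM6).
* **Common phase frame.** Azimuths about two slightly different axes are
  only comparable in one frame; both states' phases are recomputed in the
  basis frame built from the state-1 axis after superposition.

`deltaPhase` is then the circular-mean phase change (torsion), `sliding`
the displacement of $P$ along the state-1 axis (positive toward the
C-terminus), `deltaOmega` the winding change, and gear-like relative
torsion of a helix pair is the difference of their `deltaPhase` values.
The within-structure relative phase of two helices is also reported, but
note it inherits the per-helix frame convention; only its *change* across
states is convention-free, which is why both readouts appear in compare
tables. Interhelix angles are reported on N→C oriented axes in
$[0, 180)$ rather than the crystallographic crossing-angle convention in
$[0, 90]$; fold them if needed. The axis–axis distance uses the common
perpendicular between the infinite axis lines, falling back to the
clamped segment–segment distance (flagged `clamped`) when the
perpendicular feet fall outside the fitted residue spans.

## Spiral diagrams

`makeSpiral()` reduces a fit to the per-residue phase picture: each
residue is the average of its four backbone atoms, its observed azimuth
is measured in the fit's frame, and the fitted series advances by exactly
$\Omega$ per residue (rotation is linear, so the average point inherits
the exact twist). Both series are offset so the first residue's fitted
phase is 0 — the diagram starts on the horizontal axis — and drawn on a
radius growing linearly with residue index (0.35 radius units per
residue, a plotting constant), colored in cycles of black, red, green,
blue. Coincidence of dots (observed) and circles (fitted) is the visual
goodness-of-fit; a residue pushed tangentially off the model shows up as
its dot leading or trailing its circle by that many degrees.

## The synthetic-fixture generator

`makeFixture()` and `makeTwoStateBundle()` exist so that every analysis
path is testable without downloading structures. The generator shares the
single forward-model implementation with the fitter (no duplicated
formula to drift), placing backbone atoms from canonical per-form
constants derived once from ideal covalent geometry at the dihedrals
whose exact screw yields each form's ideal twist:

| form | Ω (°/res) | pitch (Å) | $r_{C\alpha}$ (Å) | diameter (Å) |
|------|-----------|-----------|-------------------|--------------|
| 3/10 | 120 | 5.96 | 1.87 | 2.9 |
| α    | 100 | 5.67 | 2.26 | 3.7 |
| π    | 80  | 3.36 | 2.90 | 4.9 |

These reproduce the qualitative signatures used throughout: the π form
about 1.2 Å wider in diameter than α, the 3/10 form tighter and
narrower. Perturbations (axial shift, axis rotation, rigid move, kink)
are applied in listed order; noise is isotropic per-coordinate Gaussian
under a caller-supplied seed — the simplest model sufficient for
parameter-recovery testing. The two-state bundle arranges seven α
helices on a 16 Å ring with small deterministic outward tilts and
distinct phase origins, programs per-helix winding/torsion/sliding/tilt
changes into state 2, and by default moves state 2 rigidly as a whole so
that any cross-state analysis must handle superposition, as with real
data.

What the fixtures do *not* emulate: side chains, sequence-dependent
geometry, crystallographic disorder, correlated coordinate error, or
curved helices. Passing the recovery tests therefore demonstrates the
correctness of the estimator chain (generation → PDB round trip →
extraction → fitting → differencing), not robustness to every artifact of
experimental structures; on real data the rmsd QC panel and the
convergence flags carry that burden.

## Problem sizes and numerical checks

The test suite works at the scale the method is designed for: segments of
5–20 residues, 18-residue fixtures for recovery tests, 100 seeded noise
replicates at σ = 0.1 Å for the stability check, 100 random axis pairs
against a brute-force line-distance oracle, and a seven-helix two-state
bundle for the end-to-end motion recovery. Forward–inverse round trips
are required to recover parameters to $10^{-6}$ (after gauge
normalization) with rmsd below $10^{-6}$ Å; dihedrals must match an
independent four-point torsion formulation to $10^{-9}$°; rigid-motion
invariance of the internal parameters holds to $10^{-6}$. PDB files carry
three decimals, so anything passing through the format is comparable only
to ~$10^{-3}$ Å — the fixture API returns the exact in-memory segment
alongside the written file for tests that need machine precision.

## Limitations

* One straight axis per fit: kinks must be split by the caller; there is
  no automatic kink detection.
* The dihedral↔twist map assumes ideal covalent geometry; refined
  structures deviate by a few degrees, which is why cross-method
  agreement is only expected at the 5 °/residue level.
* Group membership in survey plots is configuration, not computation:
  functional grouping of structures is the user's scientific judgment.
* Phases, and hence torsional positions, are defined relative to a fixed
  global auxiliary vector; absolute values are convention-bound and only
  differences (across states, or along a helix) are physical.
* NMR ensembles are reduced to model 1; altloc resolution keeps the
  highest-occupancy conformer (ties to 'A').
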