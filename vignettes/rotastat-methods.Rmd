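---
title: "Methods: rotational-state statistics for in situ ATP synthase"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rotational-state statistics for in situ ATP synthase}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rotastat)
```

## The scientific question

Mitochondrial ATP synthase converts a proton gradient into rotation of its
membrane-embedded c-ring and central stalk, driving ATP synthesis in the
catalytic F1 head. In situ cryo-electron tomography with per-particle
heterogeneity analysis yields, for tens of thousands of individual
subtomogram-averaged monomers, a rotation angle of the F1 head and of the
central stalk about the complex axis, plus a displacement coordinate for the
upper peripheral stalk (UPS, the ASA2/4 region of the chlorophycean stator).
The statistical question is whether these per-particle states are coupled:
does the F1 head co-rotate with the central stalk (as purified-complex
studies suggested for 20–30 degree arcs), does the UPS flex with the F1
head, and do the two monomers of a dimer move together?

`rotastat` implements that statistical layer as a reusable, fully testable
pipeline. Upstream image processing (tilt-series alignment, template
matching, map refinement, latent-space heterogeneity embedding) is out of
scope; the package starts from particle metadata tables and density
volumes, and ships a synthetic-data module that generates both with the
calibrated statistical structure of the in situ *Chlamydomonas reinhardtii*
ensemble (22,630 monomer particles from 93 tomograms) so that every
downstream stage can be exercised and validated without any raw data.

## Conventions

All angles are degrees wrapped to (-180, 180]; positive rotation is
clockwise viewed from the matrix (F1) side down the z axis toward the
membrane. Volumes are cubic grids with the z axis as symmetry axis and
tomogram normal; in R they are stored in the native column-major
`[x, y, z]` layout (x fastest), which is also the MRC on-disk order.
Displacements are in Angstrom, thicknesses in nm.

## The synthetic ensemble and its calibration

The generator defaults are the study conditions, fixed once:

* **F1-head angle**: wrapped normal, sd `19/1.96 = 9.694` degrees, so the
  central 95% of a large sample spans exactly the observed ±19 degrees.
* **Central-stalk angle**: trimodal wrapped mixture at 0, +120 and -120
  degrees (pseudo-c3 catalytic dwells spanning the full turn). Reported
  dwell arcs are one small (15 degrees) and two large (29, 32 degrees);
  we set each mode sd to a quarter of its dwell arc — 3.75, 7.25 and 8.0
  degrees — and assign the narrow mode to 0 degrees (the assignment is
  arbitrary and configurable, since the data do not identify which dwell is
  narrow). Mode occupancies default to equal because no occupancies are
  reported; the uneven observed bin counts (654–1288 per 18-degree bin)
  imply some non-uniformity, but do not determine it.
* **Measurement noise**: `add_wrapped_noise()` uses sd `19/2.355 = 8.07`
  degrees, reading the ~19-degree angular resolution of per-particle
  assignment as a FWHM-like width. At this level the stalk trimodality
  remains clearly visible, as observed.
* **UPS displacement**: normal with sd 1.276 Å truncated at ±3.5 Å. These
  two numbers are jointly calibrated so that at n = 22,630 the *extreme*
  span is 7 Å (truncation bound) while the *middle-95%* span is 5 Å — the
  two printed anchors of the trajectory analysis.
* **UPS–F1 coupling** `g(d)`: odd piecewise-linear, slope 1.2 degrees/Å up
  to 2.5 Å, then linear from (2.5 Å, 3.0 degrees) to (3.5 Å, 3.25 degrees).
  The two calibration pairs — 5 Å over 6 degrees (middle 95%) and 7 Å over
  6.5 degrees (full span) — are not proportional, so a single slope cannot
  reproduce both; the piecewise map does. The residual F1 scatter on top of
  `g(d)` has sd 9.57 degrees, chosen so the marginal F1 width stays at the
  ±19-degree calibration (`sqrt(9.694^2 - var(g(d))) ≈ 9.57`).
* **Dimers**: `make_particle_table()` draws the two monomers of each dimer
  independently by default; `intradimer_correlation = 1` makes monomer 1 an
  exact copy of monomer 0 (positive control for the intradimer tests).
  Each monomer's F1 angle combines `g(ups)`, the optional tri-periodic
  stalk coupling `a sin(3θ - b)` (default amplitude 0), and the residual;
  the default stalk and F1 widths therefore describe the *observed*
  (noise-inclusive) distributions, and no additional noise stage is applied
  inside the table generator.

One explicit integer seed controls each generator operation; a fixed seed
gives byte-identical tables and volumes, while `seed = NULL` continues the
current RNG stream (needed by Monte Carlo calibration loops).

### What the phantoms emulate — and what they do not

The c-ring phantom is a ring of Gaussian blobs (default: 10 subunits,
radius 30 Å, blob sd 4 Å, box 64 at 2 Å/voxel) plus optional white noise;
the slab phantom is a noise-textured layer in an empty box. These are
direct 3D densities: no tilt-series image formation, contrast transfer
function, missing wedge, or alignment error is simulated. Passing tests
therefore validate the *statistical machinery* under the stated model, not
the upstream reconstruction chain; conclusions about real maps inherit all
caveats of that chain.

## Volume primitives

Rotation about z uses separable Catmull-Rom bicubic interpolation per z
slice, with out-of-footprint samples filled by the grid mean so that
correlations are not biased by zero padding. Cubic rather than linear
interpolation is a deliberate choice: the symmetry-imposition scan averages
up to 15 rotated copies, and linear interpolation blurs each copy enough to
make *fewer-rotation* (low-order) impositions score systematically higher —
an artefact, since exact symmetries of the map should score near 1. With
the cubic kernel, rotations of a smooth noiseless ring by its own symmetry
angles retain similarity ≥ 0.999.

Similarity is masked Pearson correlation over voxels (weights in [0, 1]
from spherical, cylindrical or z-slab soft masks with cosine edges). The
underlying similarity metric used in the original map comparisons is not
specified; Pearson is the simplest faithful choice, and every inference
made here uses only orderings of scores, which are robust to monotone
re-normalisations.

MRC I/O is a minimal little-endian mode-2 (float32) reader/writer; headers
with axis permutations other than the default `mapc,mapr,maps = 1,2,3` are
rejected rather than silently reinterpreted.

## Symmetry-order inference

Two indirect metrics are combined:

1. **Self-rotation curve**: similarity of the ring volume to itself at
   every degree of rotation about z. A cN ring produces N evenly spaced
   minima (and N maxima) per turn. Minima are counted on a 3-degree
   circular moving average, requiring prominence ≥ 5% of the curve range;
   both constants absorb noise and are configurable. Evenness is reported
   as the coefficient of variation of the circular gaps.
2. **Imposition scan**: for each order c1..c15, the n-fold symmetrised
   volume is scored against the original. Every divisor of the true order
   is an exact symmetry and scores near 1, so plain argmax is ill-posed;
   the scan's order call is the *largest* order scoring within 90% of the
   best score over orders ≥ 2.

The final call requires agreement between the scan's largest-order call and
the minima count; disagreement (e.g. an asymmetric single-blob control) is
reported explicitly rather than resolved silently. On noisy phantoms both
metrics are computed under a ring-focused cylindrical soft mask
(`ring_mask()`: radius + 3 blob sd, half-height 3 blob sd): the ring fills
under 1% of the box, so an unmasked global correlation would be dominated
by background noise rather than by the ring — consistent with the original
analysis, which focused soft masks on the target region.

## Angle assignment

`estimate_rotation_cc()` searches z rotations of a masked reference
exhaustively on a 2-degree grid and refines the peak by a parabolic fit
through the three surrounding scores — sub-degree precision without a
0.1-degree grid; the refinement is clamped to one grid step, and grid ties
resolve deterministically to the angle nearest 0. Only z rotation is
searched because particles are already aligned to the monomer frame by the
upstream refinement. This transparent estimator stands in for the
latent-space rigid-body heterogeneity method used on the real data; on
noiseless rotated phantoms it matches an exhaustive 1-degree search within
1 degree, and at signal-to-noise 1 its error sd stays below 10 degrees,
consistent with the ~19-degree angular resolution regime.

## The statistical core

**Binned KS protocol.** Central-stalk angles are cut into 20 half-open
bins of 18 degrees starting at -180 (the phase of the observed binning grid
is unstated; the last bin closes at +180 so the bins tile (-180, 180]).
Each bin's F1-head angles are compared to the F1 reference distribution
(n = 22,630) by a two-sample Kolmogorov–Smirnov test via `stats::ks.test`.
Following the headline protocol, the reference *includes* the binned
particles and no multiple-testing correction is applied to the reported
per-bin p-values. Because each bin overlaps the reference (~4% of it), the
p-values are mildly conservative: in null calibration at the observed bin
sizes the per-bin rejection rate at 0.05 is ~0.035–0.04 rather than 0.05,
and the Bonferroni-corrected any-bin detector used in the power analysis
has size ~0.03. The reported "no significant difference (p = 1)" of the
original analysis is treated as a rounding/protocol artefact: exact
two-sample KS p-values on continuous overlapping samples are approximately
uniform under the null, not identically 1, and this package reports them
exactly.

**Sinusoid fit.** Simple coupled rotation predicts a tri-periodic relation
`theta_f1 = a sin(3 theta_stalk - b)`. The fit linearises to
`c0 + c1 sin(3x) + c2 cos(3x)` and solves the normal equations exactly, so
noiseless model data are recovered to machine precision
(`a = sqrt(c1^2 + c2^2)`, `b = atan2(-c2, c1)`). Significance of the
amplitude comes from a permutation test that shuffles the pairing between
stalk and F1 angles (default 999 permutations, seed-controlled; p computed
with the add-one convention). A fitted intercept `c0` guards against a
non-zero mean F1 angle biasing the amplitude.

**Detection power.** `detection_power()` simulates ensembles at the
observed size (19,262 particles in the 20 bins) with coupling amplitudes of
interest and reports the permutation-test rejection rate. At amplitudes of
20–30 degrees — the coupling arc suggested by purified-complex work — the
power is indistinguishable from 1, which substantiates the claim that such
coupling would have been observed if present. The residual F1 scatter in
these simulations is the full marginal width (9.694 degrees), a
conservative choice: any smaller residual only increases power.

**Intradimer tests.** Dimers with exactly two monomers are analysed; the
protocol splits on monomer 0 (which monomer defines the split is ambiguous
in the original description; one defensible reading is fixed here and
documented). F1: dimers split by the sign of monomer 0's F1 angle, partner
distributions compared by KS. Stalk: monomer-0 angles within ±30 degrees of
each dwell mode define three groups of partner stalk distributions,
compared pairwise. Under the independent default generator all four
p-values are uniform; in copy mode they collapse below 1e-6.

**Trajectory binning.** UPS displacements are bucketed at 1 Å; each bucket
reports median, quartiles, 1.5·IQR whiskers and outlier count (the whisker
convention is not stated in the source figure; 1.5·IQR is the standard
choice) plus the mean F1 angle. Spans are reported as max-min (full) and
empirical 2.5–97.5 percentile range (middle 95%), with the corresponding F1
spans taken from the bucket means (interpolated at the displacement
percentiles for the middle-95% figure).

**Angular resolution bound.** The smallest detectable rotation at radius r
for local resolution (chord) d is `theta = 2 asin(d / 2r)`; with the
outermost stalk features at ~30 Å and ~10 Å local resolution this is
19.19 ≈ 19 degrees, the limit below which higher-frequency coupling cannot
be assessed.

## Numerical and degenerate-input choices

* `wrap_deg` maps exactly onto (-180, 180]; 180 stays 180, -180 becomes 180.
* Zero-variance inputs to similarity or rotation estimation raise explicit
  undefined-score / undefined-angle errors rather than returning NaN.
* A flat (zero-contrast) z profile yields thickness 0 with a `flat` flag; a
  profile with contrast everywhere but no resolvable background (peak minus
  baseline under 25% of peak) reports the full extent as slab. The baseline
  is the median of the outer 10% of slices and the slab threshold is at
  half prominence; both constants are package decisions, as the source
  describes only the principle of contrast-based ranking against the
  150 nm cutoff.
* Degenerate sinusoid designs (all stalk angles equal mod 120) error out.
* KS of a sample against itself returns exactly D = 0, p = 1.

## Problem sizes used in the shipped tests

Distribution calibrations run at the full ensemble size (n = 22,630).
Null-size and intradimer-uniformity suites use 200 replicates at the
observed ensemble structure with 199 permutations per test; power runs 100
replicates per amplitude with 99 permutations. Symmetry properties run on
box-48 phantoms with 2-degree curves, and the headline c10 computation on
the box-64 phantom with a 1-degree curve; assignment oracles use box-32
references. These sizes were chosen as the smallest at which the checked
quantities are stable.

## Known limitations

* The synthetic ensemble is a parametric idealisation: real rotational
  states need not be wrapped-normal, occupancies are not equal, and angular
  noise need not be homoscedastic.
* KS on wrapped angles treats (-180, 180] as a line, matching the original
  protocol; circular alternatives (Kuiper, Watson) are intentionally out of
  scope.
* The symmetry machinery assumes the ring axis is the grid z axis (true
  after subtomogram alignment); no axis search is performed.
* The order-inference rule requires exact agreement of two integer metrics;
  heavily noised or non-ring densities are reported as disagreements, not
  forced to a call.
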