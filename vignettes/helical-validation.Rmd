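---
title: "Validating helical symmetry parameters against cryo-EM density maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating helical symmetry parameters against cryo-EM density maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(helixvalid)
```

## The problem

A helical reconstruction is generated from a single asymmetric unit by a
screw operation: a rotation by the *twist* $\theta$ (degrees) about the
helical axis combined with a translation by the *rise* $z$ (Angstrom)
along it, optionally composed with a cyclic symmetry $C_n$ about the same
axis. The symmetry transforms are

$$T_{i,k} \;=\; R\!\left(i\,\theta + k\,\tfrac{360^\circ}{n}\right)
  \circ S(i\,z), \qquad i \in \mathbb{Z},\; k = 0,\dots,n-1 .$$

These three numbers are metadata, deposited alongside the density map,
and nothing in a standard deposition pipeline verifies that they are a
symmetry of the map they accompany. Typical failure modes are missing
values, twist and rise exchanged (a plausible typo, since both are small
positive numbers), a twist with the wrong sign (equivalently, a mirrored
map), parameters with no relation to the map at all, and *partial*
symmetry: a deposited pair $(n\theta \bmod 360^\circ,\, n z)$ that is a
correct symmetry but relates only every $n$-th subunit and therefore
averages $n$-fold fewer copies than the full screw.

`helixvalid` determines the parameters directly from the map, compares
them with the deposited values under three metrics, assigns each entry to
this error taxonomy, and quantifies what full symmetry buys over partial
symmetry in half-map resolution.

## Map-driven indexing

Unwrapping a helix onto a cylinder turns it into a 2D lattice in
(azimuth, height) coordinates, and helical indexing becomes 2D unit-cell
determination:

1. **Radius.** The radial density profile (shell averages of one-voxel
   width about the axis) is summarized by the density-weighted mean
   radius over shells above 50% of the profile maximum. The weighted mean
   behaves sensibly for both hollow tubes and solid filaments; the 50%
   floor keeps solvent shells out.
2. **Cylindrical projection.** The map is sampled on a band of cylinders
   spanning $[0.7r,\,1.3r]$ and averaged over the band; single-shell
   unwrapping is noisy and the band makes the projection robust to radius
   misestimates. Default sampling is $1^\circ$ in azimuth and 1 A along
   the axis; the *amyloid* preset ($0.5^\circ$, 0.2 A) is used when both
   twist and rise are small (auto-selected below 10 deg and 10 A), since
   amyloid lattice points sit close to the origin.
3. **Autocorrelation.** The mean-subtracted projection is autocorrelated
   (periodic in azimuth, zero-padded axially, per-lag overlap
   normalization so the origin is exactly 1). Axial lags are limited to
   half the box so every value retains at least 50% overlap.
4. **Peak selection.** Local maxima above a relative score floor (0.25)
   are refined to sub-grid positions by a 3-point parabola per axis. The
   lattice point closest to the equator — excluding a band of one axial
   step or one voxel, whichever is larger, since a sub-voxel rise is
   unresolvable — defines the full symmetry: twist = signed azimuth lag
   (sign read in the positive axial half-plane), rise = axial lag. Ties
   within one axial step are broken by score, then by smaller azimuth.

Two guards make the selection robust to features that are *not* lattice
fundamentals:

* **Harmonic support.** A true fundamental $(\theta, z)$ implies peaks at
  $(2\theta, 2z)$ and $(3\theta, 3z)$ (when inside the lag window), and
  the fundamental cannot score clearly *below* its harmonics — at a true
  lattice vector the whole pattern overlaps, at a spurious sub-period
  only part of it does. Candidates failing either condition (a 0.1 score
  margin) are skipped. This rejects cross-correlation peaks between
  different features of the asymmetric unit, including the pathological
  case where an internal azimuth spacing coincides with half the twist.
* **Lattice-line sharpening.** The accepted fundamental is re-estimated
  from the farthest matching peak on its lattice line: a peak at level
  $i$ carries the same quantization error but divided by $i$ after
  back-division. This matters for the integer-multiplier test, where the
  twist residual of $n\theta$ grows $n$-fold.

$C_n$ detection correlates the projection with azimuthally rotated copies
of itself at all multiples of $360^\circ/n$ for $n \le 12$, after
centering each axial slice (otherwise empty slices correlate at every
angle and drown the signal). The largest $n$ whose mean rotational
correlation exceeds both 0.5 and the median correlation over all tested
angles by 0.25 is reported; 1 otherwise. The cap of 12 covers the vast
majority of deposited axial symmetries and is configurable.

## The three comparison metrics

Given deposited parameters $(\theta_d, z_d)$ and map-derived parameters
$(\theta_v, z_v)$:

* **Normalized differences.**
  $\delta\theta = |{\rm wrap}(\theta_d - \theta_v)| / \max(|\theta_d|,
  |\theta_v|, \varepsilon)$ and $\delta z = |z_d - z_v| / \max(z_d, z_v)$.
  Dimensionless, but blind to the helix radius; used for screening. A
  sign flip of equal magnitude gives $\delta\theta = 2$ exactly.
* **Vector difference.** Each parameter set is embedded as the chord
  displacement of a point at radius $r$ under one symmetry step,
  $v = (r\cos\theta - r,\; r\sin\theta,\; z)$, and the Euclidean distance
  $|v_d - v_v|$ is reported in Angstrom. Two sets closer than the
  reported resolution are *similar* — differences below the resolution
  are not resolvable in the map. The chord embedding (rather than the
  arc length $r\theta$) stays continuous across the $\pm 180^\circ$ wrap;
  both forms share the documented small-twist sign insensitivity
  ($+0.4^\circ$ vs $-0.4^\circ$ at $r = 50$ A differ by only
  $2r\sin 0.4^\circ \approx 0.7$ A), which is why sign errors get their
  own explicit test in the cascade. When no resolution was reported the
  similarity threshold falls back to two voxels.
* **Symmetrize and correlate.** The map is central-sliced to a slab of
  height three times the (larger) rise, the slab is symmetrized under
  each parameter set ($x' = \frac1N \sum_i T_i(x)$, trilinear
  interpolation, voxels without any valid contribution marked invalid),
  and each result is correlated with the original over one shared valid
  mask. Three rise levels carry the full asymmetric content while forcing
  the symmetry operations to regenerate the rest of the helix, so wrong
  parameters produce smeared reconstructions and low correlation. A
  correlation difference above 0.1 counts as "significantly higher"; both
  correlations below 0.5 mean neither parameter set explains the map
  (partial depositions, focused maps) and the entry is left to manual
  inspection. The slab uses the larger of the two rises so that a
  partial-symmetry deposited set is not penalized by a slab thinner than
  its own repeat.

## Decision cascade

First match wins: (1) no deposited values; (2) indexing failed or both
correlations < 0.5 → *not validated*; (3) deposited similar to detected →
*consistent*; (4) swapped deposited similar (only when the swapped rise
is physically plausible: larger than a voxel, smaller than the box, so
small-twist amyloids cannot produce nonsense swaps) → *swapped*; (5)
sign-flipped deposited similar → *wrong sign*; (6) integer multiplier
found and both correlations high and close → *partial symmetry*; (7)
candidate correlation significantly higher → *incorrect values*, else
*not validated*.

Consistency is tested before the swap/sign repairs so that
near-degenerate parameter pairs (twist numerically close to rise) are not
relabeled spuriously. The multiplier test accepts
$n = \mathrm{round}(z_{\rm coarse}/z_{\rm fine})$ for $2 \le n \le 100$
when the rise residual is within 2% and the wrapped twist residual
within $1^\circ$; these tolerances admit the published 22-fold example
(residuals 0.38% and 0.46°) with margin, and the classification is
stable under ±20% changes of all of them (property-tested).

## FSC of symmetrized half-maps

Partial symmetry is correct but suboptimal: averaging more asymmetric
units can only improve a map if the parameters are truly a symmetry of
the signal. Both half-maps are symmetrized under each parameter set and
the Fourier shell correlation between like-symmetrized halves is read at
the 0.143 crossing (first crossing, linearly interpolated between
one-voxel-wide shells; curves that never cross report the Nyquist
resolution with a flag). No masking or curve correction is applied; a
soft mask would change absolute numbers but not the partial-vs-full
comparison, which is the quantity of interest.

## The synthetic generator

All test inputs are generated, never downloaded. One asymmetric unit is a
set of 3D Gaussians in cylindrical coordinates; the map is the sum over
all symmetry images whose centers fall in the box, truncated at
$4\sigma$ (< 0.1% amplitude error). The default unit has three Gaussians
at distinct radii (16, 22, 27 A) and *irregularly spaced* azimuths (0,
55, 145°) at a common height: distinct radii and amplitudes break
spurious rotational symmetries, irregular azimuth spacing prevents any
rotation from aligning two pairs of features simultaneously, and the
common height keeps feature-to-feature cross-correlation peaks on the
equator, where the indexing exclusion zone already ignores them. The
default box is $64^3$ at 2 A/voxel (desk scale: under a second to
build). The amyloid preset uses 1 A voxels and $\sigma = 1.2$–1.4 A at
protofilament radii so that the 4.8 A cross-beta rise is resolved as
separate rungs rather than a continuous spiral — with $\sigma$
comparable to the rise the screw operation degenerates into a continuous
symmetry and no discrete lattice exists to index.

Half-map pairs add two independent Gaussian noise realizations (scaled to
the signal RMS) from a private seeded RNG stream; the global RNG state is
never touched.

What the generator does *not* emulate: CTF and optics envelopes,
solvent/membrane background, per-region symmetry variation, and atomic
detail. Passing tests therefore demonstrate the correctness of the
geometry, metrics and decision logic under exactly known symmetry — not
performance on experimental maps with model mismatch.

## Problem sizes and test conditions

The test suites run at sizes a laptop handles comfortably and state their
conditions explicitly:

* parameter recovery: 20 maps, $64^3$ at 2 A/voxel, twist uniform in
  $(-179, 179]$°, rise in $[3, 32]$ A, recovery within one sampling step
  in at least 19 of 20;
* fault injection: 20 seeded fixtures per error class on a $48^3$ grid,
  reported resolution 5 A (a typical mid-resolution helical deposition),
  at least 18 of 20 per class. Swap and sign fixtures draw twists from
  20–140° so the faulted twist remains distinguishable from its repair at
  that resolution — a sign flip of a near-zero or near-180° twist is
  genuinely unresolvable (the vector metric's documented blind spot) and
  is not a meaningful test of the classifier;
* partial-symmetry fixtures use rises of 3.5–6 A with multipliers 3–6 so
  the coarse repeat still fits three times into the box;
* FSC gain: one $64^3$ fixture (twist 23.7°, rise 3.2 A), noise at
  3× signal RMS — enough noise that the half-map FSC crosses 0.143
  mid-band and resolution differences are visible — against multipliers
  2, 4 and 8;
* discrimination: 40 seeded trials, true versus two-sampling-step
  perturbations of one parameter.

## Numerical choices and edge cases

* Rotation angles go through `cospi`/`sinpi`, so quarter- and full-turn
  rotations are exact; a 360° rotation reproduces the map bitwise up to
  interpolation no-ops.
* Trilinear interpolation everywhere; the correlation comparisons are
  relative, so higher-order schemes would change both sides equally.
  Out-of-grid samples and samples touching an invalid voxel propagate
  `NA` and are excluded from averages, correlations and the FSC (where
  they are zero-filled).
* The rotation/unwrapping center is $(N_x/2, N_y/2)$ in 0-based voxel
  coordinates, matching the generator; deposited helical maps are
  reconstructed about the box axis, not the header origin.
* Twist is stored wrapped to $(-180, 180]$; $-180$ maps to $+180$.
* Anisotropic voxel sizes are rejected outright: every formula above
  assumes one Angstrom-per-voxel scale.
* MRC axis-correspondence headers are trusted first; when a file's voxel
  order contradicts its header the CLI `--force-axes` override selects
  any of the six permutations explicitly rather than guessing.
  Reorientation of the helical axis uses cyclic permutations only, so
  handedness — and with it the twist sign — is never silently flipped.

## Limitations

Only the global symmetry of the whole map is determined; assemblies with
different symmetries in different radial regions are reported with the
symmetry of the dominant region. Handedness relative to the true
molecular chirality is out of scope — the package checks consistency
between parameters and map, not which mirror image is correct. Layer-line
indexing of 2D images, dihedral and pseudo-symmetries, and seam-containing
non-integer-start helices are not handled.
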