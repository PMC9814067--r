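---
title: "Pre-acquisition tomographic alignment: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pre-acquisition tomographic alignment: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(tomoalign)
```

This vignette is the package's own account of the science it implements:
the geometric models behind the coarse alignment solves, the genetic
algorithm behind the fine stages, what the virtual beamline does and does
not emulate, and the numerical and design decisions that were genuinely
open.

## The virtual beamline

The simulator is an ideal parallel-beam instrument. A specimen is a 3D
grid of non-negative attenuation values; the rotation axis passes
vertically through the volume center; one voxel maps to one detector
pixel (magnification 1, a deliberate simplification — real beamlines need
a pixel-to-motor calibration before the solves below can command motors in
their own units).

The misalignment state holds the four virtual-motor error terms:

| term | motor | meaning | units |
|------|-------|---------|-------|
| θ_Xt | ν | in-detector-plane tilt of the rotation axis | degrees |
| θ_Zt | μ | out-of-plane tilt (toward/away from the beam) | degrees |
| offset_x | x | sample displacement ⊥ beam, in the rotating frame | px |
| offset_z | z | sample displacement along beam, in the rotating frame | px |

A projection at angle ω applies, in order: the in-plane offsets in the
sample frame, the rotation about the nominal vertical axis, and the two
axis tilts in the lab frame (θ_Zt about the horizontal beam-transverse
axis, then θ_Xt about the beam axis). The detector reads the orthographic
projection: u along lab x, v along lab y, 0-based pixel coordinates with
the origin at the top-left. Angle 0 looks down the volume's third axis and
u increases with the first axis; angles grow counter-clockwise seen from
the top.

**Projector.** Rather than marching rays through the volume (trilinear
sampling at one-voxel steps), the projector transforms every nonzero voxel
once and splats its value onto the detector with bilinear weights — the
adjoint formulation of the same discretisation. Two properties make it
the better choice here: bilinear splatting conserves total mass exactly
(the mass-conservation property test) and preserves first moments
exactly, so projected centroids — the only observable every alignment
stage consumes — are sub-pixel accurate by construction rather than up to
an interpolation error. It is also much faster on the sparse phantoms the
experiments use. The inner loop is a small C++ kernel.

**Axis jitter.** Real rotation stages wobble. Each projection adds a
zero-mean perturbation to both tilt angles with standard deviation
`jitter_sd` (default 0.05°, a configuration knob since no canonical
magnitude exists). The perturbation is a seeded deterministic function of
the angle, not a fresh draw per acquisition: re-acquiring the same angle
reproduces the same image. That choice keeps repeated scans bit-identical
(an explicit contract of the acquisition operation), makes cached GA
fitness values consistent with what a re-acquisition would return, and
still leaves the jitter's effect on any single scan indistinguishable from
per-frame noise.

## Phantoms

Three seeded generators cover the experiments:

* `particle_only` — a single high-attenuation sphere (radius 1.5 voxels,
  value ≥ 5× any background), the classic rotation-axis calibration
  object. The sphere's center voxel carries a slightly higher value than
  its shell so the particle has a well-defined intensity peak.
* `blob_with_particle` — a connected, asymmetric body summed from seeded
  Gaussian lumps, thresholded to compact support, with one fiducial
  sphere placed on its surface (first background voxel along a seeded
  random ray). A walnut-like full-field specimen.
* `lowres_blob` — the same construction block-averaged over 4×4×4 voxels,
  standing in for the blocky projections of scanning (XRF/XANES-type)
  data.

Blob phantoms are **recentered**: the volume is shifted (sub-voxel,
trilinear) so the total attenuation centroid — including the fiducial's
mass, which is compensated by shifting the body only — lands exactly on
the volume center. This is a definition, not a convenience: the "true
residual offset" of an alignment run is read from the motor state, and
that reading is only meaningful if zero motor offset corresponds to the
specimen's centroid sitting on the rotation axis. Without the
compensation the surface fiducial alone drags the centroid a few tenths
of a pixel off axis, which would appear as an irreducible pseudo-residual
in every sub-pixel experiment.

What the generators do **not** emulate: detector noise and point-spread,
beam-hardening or any physically calibrated attenuation scale, cone-beam
geometry, sample drift or vibration during the scan, and multiple
competing high-attenuation features. Passing tests therefore demonstrate
the correctness and convergence of the alignment logic under ideal
imaging with stage jitter, not robustness to detector physics.

## Coarse axis alignment

A full-turn scan is acquired (default step 5°), the fiducial is isolated
per frame by a grayscale threshold and located by its intensity-weighted
centroid (sub-pixel; an integer peak would cap the achievable accuracy at
half a pixel). The track is fitted with a direct algebraic least-squares
conic fit constrained to an ellipse (the numerically stabilised
Halir–Flusser form of Fitzgibbon's method), chosen because it is
closed-form, unbiased enough at full-turn coverage, and has no iteration
to tune.

For a fiducial circling the axis at radius r, the rendered orbit is an
ellipse with semi-axes exactly (r, r·sin θ_Zt) and major-axis inclination
exactly θ_Xt (both independent of the other tilt — a property the
parameter-recovery suite checks rather than assumes). The feature points
are P1, P2 (major-axis vertices) and P3, P4 (the ellipse points sharing
the x-coordinate of the minor-axis midpoint, read as the ellipse center —
the only reading under which the same-x pair is well defined). The
estimates are

* θ_Xt = atan2(y₂ − y₁, x₂ − x₁), exact for noiseless tracks;
* θ_Zt = asin(|y₄ − y₃| / |P₂ − P₁|), exact when θ_Xt = 0 and carrying a
  small coupling bias otherwise (≈ +0.4° when both tilts are 14°), well
  inside the coarse stage's job description since the fine stage's search
  window (±3°) comfortably covers it.

The vertical center chord is unsigned, so the sign of θ_Zt comes from the
orbit's sense of traversal: regressing u(ω) and v(ω) on first harmonics,
the determinant of the 2×2 harmonic coefficient matrix equals
r²·sin θ_Zt up to a positive factor and is invariant to the unknown
particle phase. The correction commanded is the negative of the signed
estimate on each motor.

Degenerate tracks (collinear within tolerance) are returned as a
zero-minor-axis model rather than an error, with the orientation from the
principal axis; the collinearity test compares the smallest singular
value of the centered points to 5·10⁻³ of the largest — below the
apparent opening that threshold-clipped splat centroids can fake on a
perfectly aligned axis, so the no-tilt case degrades gracefully into the
line model it should be.

## Coarse sample alignment

A 0–180° scan at 2° steps measures, per frame, the horizontal
intensity-weighted centroid of all pixels above a small background
threshold (default 0.5% of the image maximum — the virtual detector has
an exactly zero background, so the threshold only needs to reject
numerical dust; on real data it would be set against detector noise).
Frames whose above-threshold mask touches the detector edge are flagged
truncated; their centroid describes only the visible part.

ω₁ is the first angle with the sample fully inside the FoV, `distance_ω1`
the signed center-to-detector-center distance there, and ω₂ the
linearly-interpolated angle at which the center crosses the detector
center. Inverting the forward model `d(ω) = offset_x cos ω + offset_z
sin ω` at `d(ω₁) = distance_ω1`, `d(ω₂) = 0` gives the closed-form solve
quoted in the README; it is validated against exact inversion (1e-9) and
against a least-squares fit of d(ω) over all scan angles. The solve
refuses reference angles closer than sin(ω₂−ω₁) ≈ 1e-9 (degenerate
pair); a sample that is never fully inside the FoV across 0–180° is an
explicit error instructing a manual pre-move (`--set-motor` in the CLI).
If the center never crosses the detector center — an already centered
sample — the solve degenerates gracefully: distance ≈ 0 yields (0, 0)
for any non-singular angle pair.

## Fine alignment by genetic algorithm

Both fine stages share one engine: fixed-length binary genomes (24
Gray-coded bits per motor, 48 genes for two motors), tournament selection
(k = 2), single-point crossover (rate 0.9), per-bit mutation (rate
1/genome length), elitism 1, minimisation. Gray coding makes adjacent
motor positions differ in one bit, so late-stage mutation performs local
refinement instead of teleporting. The operator rates are the
conventional textbook defaults and are exposed in `ga_config()`; nothing
in the experiments tunes them. Two accuracy modes are conventional:
population 20 × 15 generations (standard) and 30 × 15 (higher accuracy).

The genes are **absolute motor target positions** inside a ±window box
around the current (coarsely aligned) position — ±3° for the axis motors,
±8 px for the sample motors, both chosen to cover the worst coarse
residuals observed in the parameter-recovery suites with ample margin.
The incumbent position is seeded into the initial population, so the
stage can never end worse than it started (and a zero-width window
degenerates cleanly to "stay put"). Every evaluated position is cached
under its quantised (Gray-integer) coordinates — identical genomes map to
identical keys, avoiding float-comparison pitfalls — so repeated
genotypes trigger no new virtual acquisitions; the acquisition counter
makes this auditable (≤ 4 projections per unique sample-stage candidate).

**Axis fitness** is the vertical peak-to-peak extent of the fiducial
track over a reduced full-turn scan (default step 15°): zero exactly when
the trajectory is the ideal horizontal line, and growing with both tilt
modes.

**Sample fitness** is the sum of the opposing-projection center
differences, |u(0°) − u(180°)| + |u(90°) − u(270°)|. Under the forward
model this equals 2|offset_x| + 2|offset_z|: the 0/180 pair reads the
x-offset twice (the projection at 180° is the mirror of the one at 0°, so
any shape-dependent centroid bias cancels in the difference), and the
90/270 pair likewise reads the z-offset. An alternative reading —
deviations of the pair *sums* from twice the detector center — is
identically zero for any rigid in-plane offset with ideal centroids and
would leave the optimiser blind except through FoV truncation; the
difference form is the one that makes sub-pixel convergence possible and
is what this package implements.

Early stopping (tolerance + patience) is available but disabled by
default: the experiments run the full generation budget so that runs are
comparable across seeds.

## Study conditions and problem sizes

The shipped experiments use, as fixed conditions: the calibration
scenario (256³ grid, fiducial at voxel [150, 81, 138], θ_Xt = θ_Zt =
14.01°, jitter σ = 0.05°); the blob scenario (96³ grid, 256×96 detector,
offsets (159, 104) px); the low-resolution scenario (64³ grid, offsets
(178, 117.5) px); GA population 20 × 15 generations. Unit and property
tests run the same logic on 48³–65³ phantoms and reduced scan steps to
keep the suite fast; the end-to-end contraction suite uses 20 seeded
random offsets up to 40% of the detector width with a reduced GA
(population 12 × 8 generations).

## Numerical choices, in one place

* Centroids, not peaks, everywhere a position is read off an image.
* Ellipse fit: constrained algebraic conic fit on centered, isotropically
  scaled points; collinearity fallback at singular-value ratio 5e-3;
  feature points P3/P4 from the conic's intersection with the vertical
  line through the center (the two quadratic roots, ordered by y), which
  handles the vertical-major-axis case without special-casing.
* solve_offsets singularity guard at |sin(ω₂−ω₁)| < 1e-9; ω₂ interpolated
  linearly between adjacent scan samples straddling the crossing.
* GA cache keys: per-parameter Gray integers, i.e. the encoding's own
  resolution ((high−low)/(2²⁴−1) per motor).
* Out-of-FoV fitness evaluations return +Inf, so the GA simply never
  selects them.
* Volumes are validated to be finite and non-negative at construction;
  motors reject non-finite targets; tilt magnitudes are restricted to
  < 90°.

## Known limitations

* One fiducial only; no multi-particle tracking or occlusion handling.
* The vertical sample offset is reported but never corrected (only the
  two in-plane motors are aligned, matching the instrument model).
* The θ_Zt estimate's coupling bias means a single coarse pass does not
  fully converge at large simultaneous tilts; it is designed to hand over
  to the fine stage, not to replace it.
* No cone-beam geometry, detector physics, drift or vibration; see the
  phantom section for what that implies about test coverage.
* File interchange uses multi-page float32 TIFF + JSON/CSV sidecars for
  volumes and projection stacks, CSV for tracks and JSON for reports.
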