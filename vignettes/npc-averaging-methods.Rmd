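---
title: "Hierarchical subtomogram averaging of the nuclear pore complex: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical subtomogram averaging of the nuclear pore complex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Cryo-electron tomography images intact nuclear envelopes carrying
nuclear pore complexes (NPCs) — ~100 nm, eightfold-symmetric assemblies
perforating the double membrane.  A single-axis tilt series (here −60°
to +60° in 3° steps) is recorded at strong underfocus (−6 μm nominal),
CTF-corrected, and reconstructed by weighted backprojection.  Each pore
is then a noisy, anisotropically sampled 3-D particle: the limited tilt
range leaves a *missing wedge* — an unsampled double cone around the
beam axis of Fourier space — and the contrast transfer function has
inverted the phases of alternating frequency bands.

`tomopore` implements the full computational route from tilt series to
an averaged, locally resolution-annotated NPC map:

1. simulation of ground-truth pore phantoms and of the imaging chain
   (projection, strip-wise CTF, detector MTF, noise, weighted
   backprojection), so every stage is testable without external data;
2. strip-based periodogram defocus estimation and phase-flip CTF
   correction with a per-image defocus gradient;
3. missing-wedge constrained cross-correlation alignment and
   wedge-compensated averaging;
4. the NPC-specific C8 hierarchy: global alignment to a geometric
   template, orientation verification against the fitted nuclear
   envelope, protomer extraction (8 asymmetric units per pore),
   subprotomer subdivision (cytoplasmic ring, nucleoplasmic ring,
   spoke + central-channel ring), and eightfold model assembly;
5. grid-based local resolution (FSC 0.5) and cross-resolution (0.14)
   mapping;
6. rigid-body docking of a component density by cross-correlation from
   random restarts, with restraint scoring against radial positions.

# Models and conventions

**Rigid transforms.**  Poses are intrinsic Z–X–Z Euler triples
(φ about z, θ about the new x, ψ about the new z; right-handed axes)
plus a voxel-space translation.  The rotation acts on the volume about
voxel `floor(N/2)` (0-based).  The convention is pinned by an impulse
test: a point at `(c+5, c, c)` moves to `(c, c+5, c)` under φ = 90°.
Transforms compose exactly; volumes are resampled by one trilinear
interpolation, with out-of-field voxels set to the volume mean so
correlation normalization stays stable near edges.

**Missing wedge.**  With the tilt axis along y and the beam along z, a
Fourier voxel is sampled when some tilt in the acquired range produces
a central section containing it; the support is evaluated analytically
(and is exactly Friedel-symmetric), and re-orienting a particle's
wedge means composing a rotation onto the mask's frame rather than
resampling a grid.

**Constrained cross-correlation.**  Candidate poses are scored by the
normalized correlation over Ω, the intersection of the rotated
reference support and the particle support, with the DC term excluded
(which removes the mean) and norms taken within Ω.  The translational
search at each orientation is one inverse FFT of the masked cross
spectrum, read at its peak with per-axis 3-point parabolic
interpolation.  Ties break toward the smallest rotation offset, then
the lowest grid index, so alignment is deterministic.

**CTF.**  `CTF(k) = −(√(1−A²) sin χ + A cos χ)` with
`χ = π λ Δz k² − (π/2) Cs λ³ k⁴`, amplitude contrast A = 0.07,
Cs = 2.7 mm, 300 keV, and Δz > 0 for underfocus (the user-facing sign
convention is negative-for-underfocus, matching the −6 μm setting).
The detector MTF is the squared ideal-pixel sinc.  Correction inverts
the forward model in reverse order — regularized MTF division (floor
0.05), then per-strip phase flipping — and is exact: flipping twice is
an involution to machine precision, and a corrupted projection equals
the |CTF|-enveloped clean projection after correction.  Phase flipping
restores *phases*, not amplitudes; a plain correlation between a
corrected and a raw clean image is bounded near 0.67 by the amplitude
zeros alone, which is why restoration is asserted against the
enveloped reference.

**Averaging.**  Each raw particle is resampled exactly once by its
composed inverse transform; the Fourier sum of the aligned particles,
each restricted to its rotated wedge, is divided by the summed wedge
coverage, floored at 10⁻³ of the maximum coverage so barely-sampled
voxels are not amplified.  Averages are normalized to zero mean and
unit variance inside the alignment mask.

# The C8 hierarchy

Global alignment uses the geometric template — eight soft spheres of
40 nm diameter on a 90 nm circle — so no experimental reference enters
the process.  Because the template is C8-symmetric (and nearly
mirror-symmetric in z), a global pose is determined only modulo 45°
in-plane rotations; pose errors are therefore reported modulo C8, and
the pore-axis *sign* is taken from the outward normal of the oblate
spheroid fitted to the envelope, exactly as the orientation seeds are.
Particles whose aligned axis disagrees with the local membrane normal
by more than 20° (strictly) are excluded with reason
`normal_mismatch`; particles railing the angular search window are
excluded with `angle_at_limit`; over-represented top views are capped
per polar-angle bin (`view_balance`); protomer crops that leave the
tomogram are either padded or excluded (`boundary`).  The four reason
codes are mutually exclusive per particle.

A subtlety in the window-limit rule: near θ = 0 the φ and ψ axes of
the Z–X–Z parameterization degenerate (only φ+ψ acts), so a grid can
express a near-identity rotation as the offset pair (+w, −w) that
formally sits on the window boundary.  A particle is flagged only when
the *geodesic* rotation from its previous pose also reaches the
window, which restores the intended semantics.

Protomers are extracted by composing the global transform with 45°·k
rotations about the pore axis plus the radial offset to the protomer
centre (45 nm); crops keep the tomogram axes, so they inherit the
lab-frame wedge unchanged while their transforms differ by exactly
Rz(45°·k).  Subprotomer crops re-centre the transforms on their own
box centres; the algebra is covered by a round-trip consistency test.
Assembly blends the three subprotomer averages back into the protomer
frame with normalized soft-mask weights, replicates eightfold with
normalized blending, and low-pass filters to the target resolution.

# The synthetic data generator

The generator *is* the study condition.  Its defaults encode the
published geometry and acquisition: eight 40 nm spheres on a 90 nm
circle; a double Gaussian-profile membrane with 35 nm luminal spacing
opening at the pore wall; tilts −60°…+60° in 3° steps; −6 μm nominal
underfocus at 300 keV; pixel sizes 13.2 Å (tomograms) and 26.4 Å
(binning-2 pore boxes) at desk scale, with the published constants
(3.3 Å pixels, 512³ particle volumes, 80³ subprotomers, ±22 nm
subprotomer offsets, 100,000 docking starts) stored in the "paper"
preset.  The desk tomogram is 192³ and a pore subtomogram 64³, chosen
so a complete pipeline runs in about a minute; note the full pore
(130 nm across) does not fit a 64-voxel box at 13.2 Å, which is why
pore boxes are extracted at binning 2.

Choices the paper does not constrain, fixed once here:

* **SNR** is signal variance over noise variance, referenced to the
  structure's own voxels (above 10% of maximum density); for the
  membraned pore this nearly coincides with an envelope-referenced
  definition.
* **Noise placement.**  The default noise enters before the wedge
  filter, as weighted backprojection of noisy projections implies.
  For the wedge-benefit study the generator instead adds band-limited
  (300 Å) noise to the reconstructed subvolume: correction residuals
  and crowding contributions in real subtomograms are low-frequency
  dominated and not confined to the measured wedge, and this is
  precisely the regime the constrained correlation was designed for —
  with noise strictly inside the wedge, ignoring the wedge changes
  only a normalization term and both estimators recover essentially
  all orientations on this high-contrast particle.
* **Initial pose estimates** perturb the truth by up to ±18° in φ/ψ,
  ±6° in θ and ±2 voxels, emulating membrane-normal orientation seeds
  plus picking error; the ±30/12/30° protomer-stage search window then
  always contains the truth.
* **Variable subdomain.**  One of the eight spheres can be replaced,
  per particle, by a random arrangement of four lobes — a structurally
  variable domain that should (and does) depress local resolution.
* **Planted body.**  An asymmetric three-lobe rigid body (~45 nm
  extent) is planted above the ring at a recorded pose for docking
  recovery; it is deliberately placed clear of the ring spheres so the
  correlation landscape reflects the body, not its neighbours.

What the phantoms do *not* model: electron–specimen multiple
scattering, dose-dependent damage, gold fiducials, tilt-series
misalignment, structural noise from neighbouring cellular material,
and conformational continua beyond the single variable sphere.
Passing tests therefore demonstrate the correctness and internal
consistency of the algorithms under known ground truth, not
performance on real micrographs.

# Numerical choices

* Angular searches run coarse-to-fine (10° at the global stage, then
  roughly half-window steps down to 1–1.5°), with all rotational
  scoring at binning 2 and a final unbinned translation pass.  An
  exhaustive 1° grid at the full box is supported but unnecessary:
  planted poses at SNR 0.5 are recovered with ~0.8° median error.
* Rotated-volume comparisons are limited by trilinear interpolation to
  roughly 0.5% in correlation; symmetry checks therefore either mask
  the supported region or compare analytic re-renderings, and the
  "energy drift ≤ 5%" guarantee applies to phantoms band-limited to
  ≳8 voxels per cycle.
* Subpart FSC in 20³ boxes carries box-window leakage: a sharp band
  edge reads up to ~1 shell finer than the true limit, on top of the
  one-shell quantization.  The uniformity test budgets 2 subpart
  shells accordingly, and the leakage check for masks evaluates only
  shells holding at least 150 Fourier voxels (smaller shells exceed
  the 0.2 threshold even unmasked; a subpart with no adequate shell —
  e.g. 8³ — fails outright, which is the failure mode the control
  exists to catch).
* The half-set FSC is invariant under any per-particle linear filter,
  so the cost of repeated resampling is only visible when the signal
  reaches Nyquist; the interpolation-accounting benchmark therefore
  uses phantoms with fine granular texture, where stage-wise
  resampling measurably loses resolution relative to the
  composed-transform route.
* Defocus estimation correlates the background-subtracted
  log-periodogram with the identically processed log model spectrum
  (noise floor 0.02) over 0.05–0.55 Nyquist, with strips at least
  64 px wide; narrower strips alias the CTF.  Estimation operates on
  amorphous specimen background — exactly where practical pipelines
  fit Thon rings — because projections of discrete smooth bodies
  superimpose sphere-form-factor oscillations on the rings and can
  bias or bury them.  The 0.45 floor on the correlation peak is a
  decision threshold: on amorphous 41-image series genuine rings score
  ~0.74–0.76 while structureless input usually stays below the floor,
  though chance alignments of a smooth noise residual with some trial
  CTF cannot be ruled out for arbitrary realizations.
* The azimuthal-mean radial profile used for ring-diameter
  measurements is unbiased on continuous rings but reads rings of
  discrete spheres ~2–3 nm inward (the 1/r shell-area weighting);
  template geometry is therefore verified on sphere centroids.
* Docking refinement is coordinate-wise hill climbing over a
  coarse-to-fine schedule (8°, 2°, 0.5°; 2, 1, 0.25 voxels) with a
  10⁻⁴ gain tolerance; scoring weights the correlation by the body's
  own soft support.

# Known limitations

* The spheroid fit is axis-aligned (spread envelopes are flat); a
  tilted-envelope geometry would need a principal-axes pre-rotation.
* The strip-based CTF machinery supports a tilt axis along y only.
* No classification: the pipeline assumes a single conformation per
  region apart from the modelled variable domain.
* The paper-scale preset records the published constants but is not
  intended to run at desk resources.

# Reproducing the headline numbers

`scripts/acceptance.R --seed <int> --out <path>` regenerates every
benchmark from scratch — the analytic cylinder volume of the
central-channel phase (π·(37/2 nm)²·26 nm ≈ 28,000 nm³), planted-pose
recovery, the wedge-constrained versus wedge-ignorant comparison,
half-set resolution versus particle count, C8 consistency, the
interpolation accounting, local-resolution contrast, CTF round trip
and defocus recovery, and docking recovery — and writes them as a flat
JSON object.  The same quantities are asserted, at their stated
thresholds, by `tests/testthat/test-acceptance.R`.
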