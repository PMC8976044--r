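---
title: "Block-based reconstruction of cyclic assemblies: models, conventions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Block-based reconstruction of cyclic assemblies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Very large, flexible particles such as the nuclear pore complex (NPC)
cannot be refined to high resolution as single rigid bodies: the four
stacked rings (cytoplasmic, inner, nuclear, luminal) flex relative to one
another, and within each C8 ring the eight subunits wobble about their
average positions. The field's answer is *block-based* (subparticle)
processing: align the whole particle coarsely, then treat each repeating
block as an independent particle whose initial pose, shift and defocus are
*derived* from the whole-particle alignment, and refine each block locally.
`ringblock` implements this programme at desk scale — a toy imaging engine,
the bookkeeping that is the substance of the method, and the structural
analyses run on the resulting composite models — so that every stage is
testable against ground truth without any external data.

# Conventions

These conventions are load-bearing; every module assumes them.

* **Euler angles.** Poses are intrinsic ZYZ triples `(rot, tilt, psi)` in
  degrees; the matrix `R = Rz(psi) Ry(tilt) Rz(rot)` maps reference-frame
  coordinates to particle-frame coordinates. Projection integrates the
  density along the particle frame's +z axis. `tilt` lies in `[0, 180]`,
  the in-plane angles in `(-180, 180]`.
* **Symmetry expansion composes on the right**: `R_k = R S_k`, with `S_k`
  the rotation by `k * 360 / n_sym` about the symmetry axis. With
  `x_part = R x_ref` this makes the expanded poses project a symmetric
  ring identically — the property the expansion tests assert.
* **Shifts** (`shift_x`, `shift_y`, in Angstrom) are the translation that
  *re-centers* the observed particle: the projected reference appears in
  the image displaced by `-shift`. This is the convention of the dominant
  particle-metadata dialect and the one under which the re-centering
  update `new shift = old shift - q_xy` is exact. (The alternative
  reading — shift as the displacement itself — renders that update
  inconsistent; we follow the operational formula.)
* **Re-centering.** For an expanded record with pose `R_k` and a subunit
  center `c` in the ring frame, `q = R_k c` is the subunit position in the
  particle frame. The in-plane part updates the shifts and is split into
  an integer window offset (pixels) plus a fractional remainder kept in
  the shift fields — fractional shifts are never resampled into pixels.
  The axial part updates the defocus: `defocus + q_z`, with +z pointing
  away from the focal plane toward larger underfocus. The convention is
  validated against the simulator, not against any external dialect.
* **Grids.** Volumes are cubic with even N; the physical origin is voxel
  `(N/2, N/2, N/2)` (0-based). Centered FFTs put DC at index N/2, so the
  central-slice relation `P(k) = V(R^T k)` holds without phase ramps.

# The imaging model

The weak-phase CTF is
`CTF(f, a) = -(sqrt(1 - A^2) sin g + A cos g)` with
`g = pi lambda z(a) f^2 - (pi/2) Cs lambda^3 f^4 + phase`, astigmatic
defocus `z(a)`, and the relativistic electron wavelength from the
acceleration voltage (0.0197 A at 300 kV). Defaults mirror a modern
300 kV collection: Cs 2.7 mm, amplitude contrast 0.1, defocus drawn
uniformly from 1.5-3.0 um, stage tilts {0, 30, 45, 55} degrees with a
2-degree wobble.

Projection has two routes: Fourier central slice (trilinear interpolation
in a centered transform; the production path) and real-space rotate-and-sum
(the cross-check). Reconstruction inserts CTF-premultiplied slices and
normalizes by `sum(CTF * F) / (sum(CTF^2) + eps)` — a Wiener-style filter
with `eps` defaulting to 1% of the mean nonzero CTF^2 weight, which tames
division at CTF zeros without visibly biasing low frequencies. Resolution
is reported where the gold-standard half-set FSC first crosses 0.143
(linearly interpolated between one-voxel shells, never finer than
2 x pixel size). The source study prints resolutions without stating its
criterion; 0.143 with disjoint half-sets is the field convention and is
configurable.

# The synthetic world

The generator's defaults are the stated world of every test:

* a C8 ring of radius 60 A whose subunit is a chiral arrangement of six
  Gaussians (weights 0.7-1, sigma 4-6 A) — chirality makes all three
  Euler angles identifiable;
* a 64^3 grid at 3 A/voxel (the ring plus its motif fits with margin);
* 800 particles at SNR 1, where SNR is the signal/noise variance ratio
  inside a soft disc of radius 0.45 x box — white Gaussian noise applied
  after the CTF, the simplest model sufficient for pose-recovery tests;
* true shifts drawn with a 2 A per-axis sd; whole-ring *alignment error*
  (what block refinement must fix) of 3 degrees / 1 A.

Projections of the Gaussian ring have a closed form (each 3D Gaussian
projects to a 2D Gaussian), and the simulator uses it. This matters: the
simulated images are then *not* produced by the same interpolating
operator that reconstruction and refinement use, so a green recovery test
is evidence about the method rather than an inverse crime. The Fourier
projector pads the volume twofold before the transform (oversampling):
smooth real-space densities are sharply concentrated in Fourier space,
where trilinear interpolation would otherwise be the dominant error — with
padding the slice projector agrees with the analytic projection of the
default ring to within ~8% max-norm (a few tens of percent without), and
with the real-space rotate-and-sum route to ~2% on smooth compact blobs.
The residual acts like broadband model error and is part of what the
SNR-1 tests absorb. Reconstruction inserts on the native grid, whose
extraction/insertion pair is exactly adjoint (`oversample = 1` in
`project_volume()` exposes that pair). What the synthetic world does *not* emulate: structured ice and
background, beam-induced motion, dose damage, defocus gradients within a
micrograph, or conformational flexibility — a green test here establishes
correct geometry/bookkeeping and a working estimator, not performance on
real micrographs.

# Subparticle refinement

Extracted subparticle windows contain the neighboring subunits, not just
the block of interest. Two design consequences:

* the consistent refinement reference is the *neighborhood* volume (the
  ring translated so the subunit center is the origin — exactly what a
  subparticle reconstruction converges to), available as
  `make_toy_subunit_volume(..., neighborhood = TRUE)`;
* scoring applies a soft circular mask (default 30 A here) to the window
  so the neighbors' mass does not dominate the correlation.

The search is an exhaustive grid — angles within `+/-angular_range` at
`angular_step`, shifts within `+/-shift_range` at `shift_step` — scored by
normalized cross-correlation in Fourier space (DC removed; shifts enter as
phase ramps, so each angular candidate costs one slice extraction and the
whole shift grid one matrix product). Exhaustive search was chosen over
stochastic optimizers for bit-stable reproducibility at toy scale; exact
score ties break toward the smallest perturbation norm, then
lexicographically. At SNR 1 the ring-level search recovers essentially all
poses to within one grid step; block-level *angular* refinement is weaker
(a compact motif offers a short lever arm) while block-level shifts and
the defocus bookkeeping are sharp — which is precisely why the pipeline's
resolution gain comes from fixing the expanded consensus alignment.

# Masks

Layered masks are z-interval indicators with raised-cosine ramps of width
`w` *centered on each boundary* (value 0.5 exactly at the boundary). The
centering is a design choice the source protocol leaves open; it makes
adjacent layers exactly complementary, so contiguous layers form a
partition of unity — the property the tests assert. The default `w` is 5
voxels, configurable in Angstrom. Spherical masks use the same radial
ramp.

# Composite assembly and analyses

Fitting a subunit volume into each of the n_sym ring positions searches a
rotation about the axis near `k * 360 / n_sym` plus a small in-plane
translation, scoring a masked local correlation over the subunit's
support, with a sub-degree golden-section polish. The map-to-map metric
and masking of the original protocol are unpublished; local correlation
over the subunit footprint is our default. Composite models replicate the
subunit model under the fitted transforms (chain ids suffixed by subunit
index; clashes reported, never resolved).

Structural measurements follow the field's standard definitions: Kabsch
least-squares superposition with the proper-rotation correction
(reflection cases are flagged, never silently accepted); residue contacts
as minimum inter-atom distance within 4.5 A (all-atom) or 8 A (CA mode) —
the source describes interfaces qualitatively, so the cutoffs are exposed
parameters; linker reachability as the geometric bound
`distance <= n_residues x 3.8 A` (trans CA-CA span); census mass as
residues x 110 Da unless a residue-mass table is supplied. Cross-model
RMSD correspondence matches residues by (entity, copy label, residue
number) by default because deposited files do not publish matched atom
sets; `n_aligned` is therefore reported, never forced to a target.

# Numerical choices and degenerate inputs

* Trilinear interpolation both for slice extraction and insertion: the
  accuracy/complexity compromise appropriate at 32-96^3 grids; padding or
  gridding kernels would be the next step up.
* At `tilt = 0/180` the ZYZ parameterization is degenerate; conversions
  fold the in-plane rotation into `rot` and set `psi = 0`. Refinement
  near these poses can land on an equivalent-rotation grid point; the
  geodesic rotation distance (not per-angle differences) is the metric
  used throughout the tests.
* MRC headers store the cell as float32, so pixel sizes round-trip to
  ~1e-7 relative, not exactly; tests assert 1e-6.
* Excluded subparticles (window centers outside the source box) and
  mean-padded edge windows are counted and reported, not silently fixed.

# Scaling of the shipped checks

The acceptance suite runs the stated world (800 particles, 64^3) for pose
recovery, and 400 particles per seed (3 seeds) for the block-gain
comparison purely to fit the runtime budget — the compared quantities are
resolutions at equal particle count *within* each seed, so the criterion
is unaffected. The defocus-bookkeeping check uses a 0.5-degree residual
pose error, the alignment-converged regime in which that bookkeeping is
actually applied. Checks against deposited coordinates (census, RMSD
against the sibling-ring model, linker distances) require multi-megabyte
files and a network; they are served by the opt-in
`ringblock fetch-and-check` command rather than the offline suite.

# Known limitations

* No per-particle CTF refinement beyond the axial defocus offset; no
  beam tilt, no higher-order aberrations, no Ewald-sphere correction.
* The Fourier projector's interpolation error is the accuracy floor of
  the toy engine; resolutions within ~2 voxels of Nyquist are not
  meaningful differences.
* `fit_subunit_positions` assumes the ring is approximately aligned to
  the stated axis; it does not estimate an unknown axis.
* The cell-list contact search assumes orthorhombic coordinates (no
  symmetry images / periodicity).
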