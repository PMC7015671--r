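---
title: "Helical microtubule reconstruction and motility statistics with kinhelix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Helical microtubule reconstruction and motility statistics with kinhelix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinhelix)
```

kinhelix implements, at desk scale, the two computational halves of a
structural study of kinesin-5 motors on microtubules (MTs): the
iterative-helical-real-space-reconstruction (IHRSR) style image-processing
pipeline used to solve motor-decorated MT structures by cryo-EM — including
protofilament-level signal subtraction and focused classification — and the
statistical fits behind the accompanying single-molecule and cell-biology
assays (Michaelis–Menten ATPase kinetics, Gaussian-mixture velocity and
intensity distributions, right-censored run lengths, force-per-overlap
scaling, and spindle-to-cytoplasm intensity ratios). Synthetic data
generators with known ground truth stand in for micrographs and recordings,
so every stage can be verified quantitatively.

## The microtubule lattice model

An MT is modelled as `n_pf` protofilament columns of alternating α/β-tubulin
monomers on a cylinder (default radius 110 Å), laterally related by a
3-start monomer helix. The one-start helical parameters follow from the
lattice counts alone:

$$\text{twist} = h\,\frac{360^\circ}{n_{pf}},
\qquad \text{rise} = \frac{s\, a}{n_{pf}},$$

with handedness $h = \pm 1$, start number $s = 3$, and monomer rise
$a = 40.95$ Å (so the dimer repeat is 81.9 Å, the familiar "82 Å layer
line"). For 14 protofilaments this gives 25.714° and 8.775 Å; for 13,
27.692° and 9.450 Å.

```{r}
helical_params(lattice_spec(n_pf = 14))
```

Because the lateral 3-start climbs an odd number of monomers per turn, a
binary α/β labelling cannot close around the cylinder: exactly one column
boundary breaks the lateral register. That is the seam, and the package
places it at the boundary entering `seam_index`. Two consequences matter
downstream:

* symmetrizing with the *monomer* one-start operator maps tubulin onto
  tubulin everywhere, but any density bound once per *dimer* (a motor, a
  tail) is carried onto α positions by the symmetry copies whose one-start
  path wraps past the seam. Monomer averaging therefore splits dimer-register
  decoration between the two registers — the familiar α/β ambiguity of MT
  monomer averaging. The package accepts this (seam-register determination is
  out of scope) and the tests account for it explicitly.
* half of the symmetry copies (those crossing the seam) see the "wrong"
  register, so quantitative density-dilution arithmetic is only exact for
  register-free density such as tubulin itself.

Skewed (supertwisted) lattices are representable (`pf_skew_deg`) but the
canonical synthetic case is the unskewed lattice, matching the usual
initial assumption of zero supertwist over one repeat.

## Synthetic data

`build_volume()` sums isotropic Gaussian blobs at every monomer site, plus
motor blobs (offset 35 Å radially outward of each β-monomer) and optional
tail blobs (offset 55 Å) drawn per dimer with the stated occupancies; the
draws are recorded so classification accuracy can be scored against truth.
All species share amplitude 1 (protein is protein); σ is 9 Å for tubulin
monomers and 10 Å for motor/tail domains, roughly matching domain sizes at
the resolutions the desk-scale boxes support. The default grid is 72 voxels
at 5.5 Å/voxel (396 Å box), which holds the full decorated cylinder
(110 + 55 + 3σ < half-box) while keeping each projection under a
millisecond of compute.

`simulate_segment_stack()` mimics how filaments are boxed from micrographs:
overlapping windows spaced 80 Å (one dimer repeat) along the filament, with
`floor((L - \text{box})/\text{spacing}) + 1` segments per filament of
length $L$. Filaments lie in the ice plane, so tilt is 90° (plus optional
jitter) and the in-plane view angle advances with axial position by
`spacing / rise × twist`. A segment at axial offset $\Delta$ of a perfect
helix equals a rotated view of the same volume, so the generator rotates
rather than translates; for stochastically decorated volumes this means the
segments of one filament are repeated views of the *same* decorated
repeat — a fact the focused-classification machinery can exploit via its
`group` argument (below). Noise is Gaussian and white, calibrated so that
signal variance over noise variance *inside the projected filament
footprint* equals the requested SNR; footprint-based SNR is what alignment
quality actually depends on. An optional CTF (defocus + amplitude contrast,
no astigmatism or envelope) can be applied; synthetic truth makes CTF
estimation unnecessary. Ice statistics are not modelled beyond white noise.

The assay generators draw: Michaelis–Menten rates with multiplicative
Gaussian noise; velocities and intensities from 1–2 component Gaussian
mixtures with per-record ground-truth labels; exponential run lengths
right-censored at the observation window; plateau forces linear in overlap
length; and two-compartment cell images (background / cytoplasm / spindle)
with per-region means plus pixel noise.

## Reconstruction

`projection_match()` does exhaustive normalized-cross-correlation matching
against a projection gallery. NCC rather than a regularized likelihood is a
deliberate simplification: it is exact, fast, and testable, and the
restriction of the gallery to in-plane views (tilt ≈ 90°) is honest for MT
cryo-EM. Shifts are searched on the integer pixel grid with parabolic
sub-pixel refinement; ties break toward the lowest gallery index.

`backproject()` smears aligned images back through the volume with
per-voxel hit-count normalization. Plain smearing weights Fourier space by
1/|s|, so images are first ramp-filtered along the transverse image axis —
for in-plane filaments the geometry is parallel-beam tomography about the
filament axis, and this is the classic filtered back-projection weighting.
Zero-coverage voxels are counted and flagged, never silently NaN-filled.

`estimate_helical_params()` grid-searches (twist, rise) for the transform
that best maps the map onto itself (real-space correlation inside a
cylindrical mask restricted to the central half of the axial extent, where
translation edge-loss is negligible), then refines the optimum
parabolically. A map with no twist dependence (no helical signature) is
flagged flat and the guess returned; an optimum on the search edge sets a
boundary flag.

`symmetrize()` averages the `n_pf` one-start symmetry copies, using a
symmetric window of steps `k` so axial edge loss is balanced. Interpolation
makes repeated symmetrization mildly smoothing, so idempotence holds to
NCC ≈ 0.99 rather than machine precision; the tests check it in a central
mask for that reason.

`ihrsr_refine()` alternates the four stages, reusing each symmetrized model
as the next matching reference, and stops when both |Δtwist| and |Δrise|
fall below tolerance. `sort_pf_number()` matches every segment against
13/14/15-protofilament references and assigns filaments by majority vote
over segments (ties are left unassigned); the per-segment/per-filament
granularity is a package decision, since the source procedure does not
state one. `smooth_alignments()` fits per-filament polynomials (degree ≤ 2)
of unwrapped view angle and shifts against axial position, flags residuals
beyond 3 robust SDs, refits without them and replaces only the outliers;
filaments too short to constrain the fit pass through unchanged.

## Protofilament refinement

The wedge mask isolates one column: a soft angular wedge (cosine crossfade,
default 5° — hard edges ring under interpolation) inside a radial annulus,
built so the `n_pf` single-column masks sum to exactly 1 inside the
annulus. Subtraction is implemented as a *single* projection of the
complement, `image − P[map ⊙ (1 − mask_j)]`: under a linear projector this
equals projecting the kept column directly, which is the oracle identity
the tests enforce at NCC > 0.99. Subtracting thirteen rotated single-column
volumes one at a time would double-count overlapping soft edges; the
complement form is unambiguous.

`extract_pf_particles()` emits one recentred particle per column per
segment — with 80 Å segment spacing, one particle per imaged tubulin
dimer — so 19,128 segments at 14 protofilaments become exactly 267,792
particles. Each particle's initial orientation is the segment alignment
composed with the j-th symmetry step, and recentring puts the column's
β-anchor dimer at the particle centre (box defaults to half the segment
box). `local_refine_pf()` then does a constrained grid search about that
initialization against projections of the canonical single-column
reference; a single column's projection is nearly flat against small
rotations about the filament axis at many views, so refinement is
deliberately range-limited and ties prefer the initial value.

`focused_classify()` alternates hard assignment and class averaging with
alignments held fixed. Because particles sit at heterogeneous view angles,
"class means" are class-average *volumes* (filtered back-projections in the
particle frame), and each particle is scored by NCC against its own-view
projections of those volumes inside the focus mask. Three details matter:

* the focus mask should be 3D when the focus is off-axis (a tail site at
  radius 165 Å): its image-plane position moves with the view, and a
  projected 3D ball tracks it. A fixed 2D disc admits projected clutter
  from the other thirteen columns' tail sites and caps single-view accuracy
  near 90 % even without noise.
* scoring a particle against a class average that contains the particle
  itself biases assignment toward the current label and freezes the
  alternation at low SNR; the own-class template is therefore corrected
  leave-one-out. If the alternation cycles without progress (identical
  particles, for instance) a degenerate flag is raised, as is an
  empty-class event.
* the initial split uses the mean density inside each particle's projected
  focus region — the very quantity classification is focused on — rather
  than a random split; it is deterministic and avoids the random-split
  attractor problem. When several particles are known views of the same
  physical unit (the synthetic generator's rotated-window segments; pass
  `group = "dimer_id"`), their scores are pooled and the unit gets one
  label, which restores the contrast a single partly-occluded view lacks.
  At 50 % tail occupancy this reaches 100 % label accuracy at SNR 0.5 on
  the test conditions; per-particle (ungrouped) assignment is
  information-limited by projection overlap to roughly 85–90 %.

## Map validation

`fsc()` computes the per-shell normalized complex correlation of Fourier
coefficients. By default both maps are soft-cylinder masked (45 % of the
box, 10 % cosine edge): a helical specimen lives in a cylinder and the
empty corners carry only reconstruction streaks. Half-sets must be split
**by filament** — 80 Å-spaced segments overlap, and segment-level splits
share noise, inflating the curve — and maps carrying segment-split
provenance are refused unless explicitly overridden.
`resolution_at()` reads the first downward threshold crossing (0.143
between independent half-maps) with linear interpolation between shells,
saturating at Nyquist (flagged) and flagging curves that never rise above
threshold as undefined. `apply_bfactor()` scales amplitudes by
$\exp(-B s^2/4)$, leaving phases untouched; sharpening a final map for
display uses $B = -200$ Å². `local_resolution()` slides a soft (Hann)
window over both half-maps and writes the per-window resolution at a 0.5
threshold — small-window FSC statistics run higher than the global 0.143
criterion — interpolating between window centres.

## Assay statistics

* `fit_michaelis_menten()`: nonlinear least squares on
  $v = k_{cat} S/(K_m + S)$, initialized from the Hanes–Woolf
  linearization, with curvature-based standard errors. Saturated-only data
  (no curvature) returns a `km_unidentifiable` flag rather than a number.
* `fit_gaussian_mixture()`: expectation–maximization on the raw samples,
  not histogram bins — bin-free maximum likelihood needs no bin-width
  choice; a binned least-squares mode is retained behind `binned = TRUE`
  for fidelity with bin-and-fit workflows. Model order between one and two
  components is chosen by BIC; component SDs are floored (and flagged)
  against degenerate collapse, and components are reported sorted by mean.
* `fit_runlength()`: censored-exponential maximum likelihood. The mean is
  total observed length over the number of uncensored events; the naive
  sample mean is biased low under censoring, which the tests demonstrate
  across 100 simulations. Conditions where essentially every run outlives
  the observation window are not quantifiable and error out rather than
  returning an unbounded estimate.
* `fit_force_per_overlap()`: least-squares slope of plateau force against
  overlap length, free intercept by default (origin constraint behind a
  flag), with a seeded nonparametric bootstrap CI over event pairs.
* `roi_intensity_ratio()`: background-subtracted spindle over cytoplasm
  mean intensity, where cytoplasm is cell-minus-spindle; a cytoplasm that
  does not exceed background yields an undefined flag.

All fitters are invariant to record order, seed-stable, and return
broom-style `tidy()`/`glance()` tables plus `autoplot()` methods.

## Numerical conventions

Euler angles are ZYZ `(rot, tilt, psi)` in degrees, rotating the reference
into the image; with tilt = 90° the filament axis projects along image x.
Shifts are in Ångströms and displace image content. Volumes are cubic,
indexed `[x, y, z]`, origin at voxel `floor(N/2) + 1`, MT axis along model
z. Maps are written as MRC2014 (mode 2); tables as STAR (single
`data_particles` loop) or TSV; configurations as YAML with unknown keys
rejected and explicit seeds required wherever randomness enters.

## Problem sizes and what the tests do (and do not) show

The test and acceptance simulations use 72-voxel boxes at 5.5 Å/voxel,
2–4 filaments of 1000–1300 Å (12–48 segments), 4° galleries and 1000-rep
bootstraps; the full suite runs in a couple of minutes on one CPU. These
sizes exercise the geometry, bookkeeping and estimators exactly, and
parameter-recovery claims are calibrated against generator truth. They do
not demonstrate near-atomic resolution, CTF estimation from movies,
beam-induced motion, structured ice, or the behaviour of
regularized-likelihood refinement on real data — the synthetic noiseless
limits (NCC ≥ 0.95 reconstructions, exact subtraction identities) are
sanity anchors, not resolution claims. Table-scale particle counts are
verified through the metadata bookkeeping (`expand_pf_metadata()`), not by
reconstructing hundreds of thousands of images.
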