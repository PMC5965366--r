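---
title: "4D dose reconstruction for MLC-tracked lung SBRT: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{4D dose reconstruction for MLC-tracked lung SBRT: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(dose4d)
```

## The problem

A lung tumour treated with stereotactic body radiotherapy (SBRT) moves with
respiration, typically a few millimetres up to a centimetre and a half
peak-to-peak, mostly superior–inferior (SI). Conventional practice freezes
this motion into the target volume: the internal target volume (ITV) is the
union of the gross target volume (GTV) over all phases of a
respiration-correlated CT (4DCT), and a planning margin (typically 5 mm) is
added on top. The price is a large high-dose volume in healthy lung.
Dynamic multileaf-collimator (MLC) *tracking* moves the treatment aperture
with the target instead, which permits a smaller *moving target volume*
(MTV): the union of the per-phase GTVs after rigidly aligning their
centroids to the reference phase. Whether a tracked MTV-plus-small-margin
plan actually maintains target coverage — and how much lung, spinal-cord
and airway dose it saves — can only be judged by reconstructing the dose
that was actually delivered, phase by phase, and accumulating it onto a
single reference anatomy.

`dose4d` implements that reconstruction loop as a desk-scale, fully
synthetic pipeline: a breathing phantom stands in for the patient 4DCT, an
analytic pencil-beam kernel for the Monte Carlo dose engine, and an
in-process 25 Hz replay for the linac/tracking network. Every other piece —
online phase binning, dose-influence-based per-aperture dose, energy–mass
transfer (EMT) accumulation, DVH endpoints, margin comparison — follows the
clinical workflow.

## The accumulation model

Dose is physically energy per mass. Mapping a dose distribution from a
breathing phase onto the reference anatomy by interpolating dose values
(direct dose mapping, DDM) ignores that the underlying mass moves too, and
is known to misplace steep local features such as field edges. EMT instead
transports energy and mass separately: each phase voxel of mass
$m_v = \rho_v \cdot V_{vox}$ is split into $s^3$ equal subvoxels; each
subvoxel carries mass $m_v/s^3$ and energy $D_v\, m_v/s^3$ through the
phase-to-reference displacement field (the *push* field, evaluated by
trilinear interpolation at the subvoxel center) and deposits both into the
reference voxel containing its landing point. The accumulated dose is then

$$D_{ref}(u) \;=\; \frac{\sum \text{energy deposited in } u}{\sum \text{mass deposited in } u},$$

with the deformed mass per phase precomputed once. Energy and mass are
conserved by construction: everything not deposited on the grid is recorded
in a lost-energy/mass ledger (tolerance $10^{-9}$ relative in the tests).
Dose division uses a mass floor of $10^{-6}$ g per voxel, which suppresses
division blow-up in near-vacuum voxels without affecting tissue. The
subvoxel default is $s = 4$; the suite verifies that refining to $s = 8$
changes no voxel by more than 1%. For an identically-zero displacement
field (the reference phase itself) the implementation short-circuits to an
exact identity transfer, so a motionless delivery accumulates bit-identical
dose in every mode.

The online loop mirrors the four clinical steps for each 40 ms aperture
report: (1) aperture to beamlet weights, (2) weights times precalculated
dose-influence data for the reported beam and phase, (3) energy formation
and division by the phase's deformed mass, (4) addition to the running
reference dose. `accumulate_tick()` implements exactly that; the pipeline
also offers `accumulate_delivery()`, which sums per-(beam, phase) fluence
weights first and maps each phase once — algebraically identical because
EMT is linear in dose at fixed deformed mass, and orders of magnitude
faster in replay. The equivalence is asserted in the tests rather than
assumed.

## The breathing phantom

The phantom is deliberately simple enough to have *exact* deformation
fields, so that accumulation accuracy is isolated from registration error
(which clinical practice delegates to a deformable-registration product and
assesses only visually). Geometry: an elliptical-cylinder soft-tissue body
(density 1.0 g/cm³) containing two lung ellipsoids (0.26 g/cm³), a
spherical tumour (1.0 g/cm³, default radius 9 mm) in the right lung, a
spinal-cord cylinder (1.0 g/cm³) and a proximal-airways tube (0.2 g/cm³).
Mass density stands in for electron density throughout — an declared
equivalence at phantom scale. The tumour boundary is antialiased by
supersampled partial-volume fractions so tissue mass varies smoothly as the
sphere crosses the 2 mm slices.

Motion: the tumour centroid traces a 2D ellipse, SI leading and
anterior–posterior (AP) lagging by a configurable phase (default $\pi/2$);
left–right motion is zero throughout. The default amplitudes, 14 mm SI and
2.6 mm AP peak-to-peak with a 5 s period, emulate a lower-lobe tumour with
large, mostly rigid motion — the regime in which margin reduction without
tracking is expected to fail. Phase displacements are anchored so phase 0
(peak exhale) is exactly the reference: all reference-phase fields are
identically zero.

The deformation is a rigid tumour displacement scaled by a $C^1$ smoothstep
of distance from the reference tumour surface over a falloff shell, zero at
the shell boundary (inside the lung) and beyond. The *pull* field
(reference to phase) is analytic; the *push* field is its numerical inverse,
solved per grid node by fixed-point iteration and stored on a fine
(1 mm isotropic) support sub-box so that the pull-then-push composition
error stays below 0.2 mm. Invertibility requires the contraction
$d_{max} \cdot \max|S'| = 1.5\, d_{max}/w < 1$; the shell width is therefore
widened automatically to twice the peak displacement ($w \ge 2 d_{max}$,
contraction $\le 0.75$). A fixed 15 mm shell would fold at 14 mm motion —
the map would not be invertible — which is why the width adapts to the
amplitude.

What the phantom does *not* emulate: real lung texture and heterogeneity
gradients, hysteresis beyond the elliptical loop, baseline drift, irregular
breathing, registration error, and tumour deformation coupled into the
displacement field (the optional per-phase GTV inflation affects masks and
density only). Passing tests therefore demonstrate the correctness of the
reconstruction machinery under known motion, not robustness to clinical
imaging artefacts.

## Motion, binning and the trajectory

Per-phase GTV centroids are fitted with a linear least-squares sinusoid
pair (the points sample one cycle uniformly, so the cos/sin basis makes the
ellipse fit linear); the 25 Hz trajectory regenerates the fitted ellipse at
a 5 s period. The online phase binner is causal: extrema are confirmed
after a ±0.5 s window with a minimum prominence of 10% of the running
peak-to-peak range (the detector rule and bin-edge convention are declared
choices — the clinical description specifies neither), and each sample is
phase-shifted back one cycle and binned against the last complete
exhale-to-exhale pair. Bins are *centred* on the cycle's phase points
(bin 0 centred on the exhale extremum), mirroring how 4DCT phase binning
centres its reconstruction windows; edge ties resolve toward later time
with a $10^{-9}$ guard. Extremum times are refined by parabolic
interpolation so that, for noiseless periodic signals, online bins agree
with offline binning for essentially all post-warm-up samples. The
respiratory period is estimated from the trailing 20 s by FFT with a Hann
window and parabolic refinement of the log-magnitude peak — the raw 0.05 Hz
bin resolution would otherwise be far too coarse near 0.2 Hz; recovery is
within ±0.03 s across 3–6 s periods.

## Beams, dose influence and delivery

Nine equidistant coplanar beams (SAD 1000 mm) carry a 5 × 5 mm bixel grid
at the isocenter plane (leaf width = bixel height, an Agility-like
approximation). The dose-influence entry for bixel $j$ and dose-grid voxel
$v$ is

$$D_{jv} = A\, e^{-\mu\, d_{rad}(v)}\; E_x(u_x)\,E_y(u_y),$$

with $d_{rad}$ the radiological depth (density-scaled path length from body
entry, marched at 1 mm steps on the CT grid), $(u_x, u_y)$ the lateral
offsets from the bixel's divergent pencil axis scaled to the isocenter
plane, and $E$ the error-function edge profile of the bixel rectangle. The
penumbra width is calibrated to the quoted lung photon penumbra:
$\sigma = 6.4/1.683 \approx 3.8$ mm makes the 80–20 edge distance 6.4 mm.
$\mu = 0.005$/mm approximates 6 MV in water; $A = 0.01$ Gy/MU per unit
weight puts plan monitor units in a clinically familiar range (a few
hundred MU per beam at 18 Gy per fraction). Entries below $10^{-4}$ of the
per-bixel maximum are dropped; columns are restricted to body voxels. No
build-up region or scatter kernels are modelled — the study's mechanism
(attenuation plus penumbra interplay with motion) survives, absolute
dosimetry does not pretend to.

Plans are conformal rather than inverse-optimized: one segment per beam
shaped to the PTV's beam's-eye-view silhouette rounded out one bixel, MU
split equally and rescaled globally so that D95(PTV) = 18 Gy per fraction
exactly on the planning phase. Delivery replays segments at 550 MU/min in
40 ms ticks (0.3667 MU per tick, the segment's last tick carrying the
remainder so MU is conserved exactly), with 2 s beam-off gaps. Tracking
projects the reported displacement orthographically into the
beam's-eye-view — SI always maps to leaf width — applies leaf-travel shifts
continuously and quantizes leaf-width shifts to whole 5 mm leaves
(hardware reality; how the clinical tracker distributes sub-leaf shifts is
not published, so whole-leaf quantization is the declared choice). Latency
is zero and position reporting perfect: prediction-based latency
compensation is explicitly out of scope. Delivery starts 12 s into the
trajectory so the binner is past warm-up for every beam-on tick; a
motionless stream (no extrema to bin against) reports the planning phase.

## Endpoints and the margin study

All endpoints are computed on the reference phase, per fraction: GTV D98
(near-minimum dose), lung-minus-GTV V20 (% of lung receiving ≥ 20 Gy after
scaling the fraction dose to the 3-fraction course), and D2 (near-maximum)
for cord and airways. DVHs use direct voxel counting with 0.01 Gy bins and
linear interpolation of the cumulative curve; for OAR comparisons at
matched coverage, each dose is rescaled so its GTV D98 equals that of the
conventionally delivered ITV+5 plan (exact by linearity).

The default study delivers: ITV+5 static and conventional (untracked);
MTV+1 static, untracked and tracked; MTV+3 and MTV+5 tracked. The expected
pattern — and what the acceptance suite asserts — is that at 14 mm motion
the untracked MTV+1 delivery loses more than 1 Gy of GTV D98 against its
plan, tracking restores it to within 0.25 Gy, and PTV volume and lung V20
rise strictly with margin at fixed normalization.

## Problem sizes and numerical choices

The default phantom covers 128 × 128 × 128 mm: a 1 × 1 × 2 mm CT/DVF grid
(128 × 128 × 64 voxels) and a 2 mm isotropic dose grid (64³), the standard
two-resolution design for this kind of accumulation. A full seven-delivery
study runs in roughly six to seven minutes on one CPU with peak memory
around 4 GB, dominated by the sparse dose-influence store
(~130 bixels × 10 phases × 9 beams, ~1.8 M nonzeros per beam-phase). Unit
tests use a 72 mm phantom at 2 mm/4 mm grids. Other fixed choices:
trilinear interpolation clamps at grid borders for resampling (no
overshoot) and zero-pads for displacement fields; nearest-voxel binning for
EMT deposits; mask dilation is exact Euclidean in world mm (anisotropic
spacing respected); centroid alignment for the MTV uses nearest-voxel
shifts because masks are boolean and sub-voxel mask interpolation would
need a thresholding rule that is not part of the method. Per-tick wall
times are logged and summarized (mean, 5th, 95th percentile) but are
deliberately not a test criterion — real-time behaviour is replayed, not
enforced.

## Worked example

```{r example}
library(dose4d)
run <- run_pipeline(run_config(seed = 1), verbose = TRUE)
run$report[, c("plan", "mode", "d98_gtv", "v20_lung", "dd98_vs_static")]
```

See the README for the printed output of this run and its interpretation,
and `scripts/acceptance.R` for the scripted recomputation of the headline
quantities.

## Known limitations

* The analytic kernel is not a transport calculation: no build-up, no
  lateral scatter beyond the erf penumbra, no heterogeneity-corrected
  kernels. Only relative dosimetric *differences* between modes are
  meaningful.
* The MTV concept compensates rigid shifts only; with the deformation
  coefficient enabled, a single inflated phase propagates into the MTV
  (conservative by construction) but the displacement field remains rigid
  near the tumour.
* The binner presumes quasi-periodic breathing; it has no drift model and
  motion prediction is out of scope.
* VMAT, couch/gantry dynamics, MLC leaf-speed limits, leakage and
  tongue-and-groove effects are not modelled.
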