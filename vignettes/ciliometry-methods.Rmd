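---
title: "Quantifying planar polarity and motility in multiciliated cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying planar polarity and motility in multiciliated cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ciliometry)
```

## The measurement problem

Multiciliated cells (MCCs), such as the ependymal cells lining brain
ventricles, carry dozens of motile cilia whose coordinated beating drives a
directional fluid flow. Whether that flow works depends on two kinds of
planar polarity and on the beating itself:

* **Rotational polarity** — within one cell, every basal body (BB, the
  centriole-derived base of a cilium) carries a basal foot (BF) pointing in
  the cilium's beat direction. In fluorescence images the BB and BF appear
  as paired puncta in two channels; the uniformity of the BB→BF vector
  directions is summarized by the mean resultant vector length
  $\bar R = \left| \tfrac{1}{n}\sum_k e^{i\theta_k} \right| \in [0, 1]$.
* **Translational polarity** — across the tissue, each cell's BB cluster is
  displaced toward one side. The angle $\theta$ from the cell centroid
  $C^c$ to the cluster centre $C^b$ is coherent across cells in a healthy
  tissue; its tissue-level $\bar R$ and circular SD quantify that
  coherence. The *BB directionality* $|C^cC^b| / |C^cE|$ (with $E$ the
  boundary point on the ray through the cluster) normalizes the offset by
  cell size, and the *corrected TT–BB distance* $|C^bC^t| / |C^cC^t|$
  relates the cluster to the polarized tyrosinated-tubulin (TT) domain
  centre $C^t$ at one cell edge.
* **Motility** — ciliary beat frequency (round trips of the tip per
  second), the speed of bead transport over the tissue surface, and — at
  the molecular scale — processive motor velocity read off kymographs.

The package implements this entire measurement chain, together with a
synthetic-scene generator that knows the ground truth, so each stage is
validated by parameter recovery rather than by eye.

## Conventions

All coordinates are micrometres in the image frame (origin top-left, y
down, pixel centre (1,1) at 0 µm). All angles are reported in the
mathematical frame (y negated): 0 rad = image right, $+\pi/2$ = image up,
counterclockwise positive. Motor velocities are nm/s, bead speeds µm/s,
frequencies Hz. No pixel-unit value crosses the API; calibration is always
supplied by the caller because microscope metadata is not trusted.

## Puncta, pairing, and the per-cell metrics

Detection is difference-of-Gaussians (a Laplacian-of-Gaussian
approximation) at the user's spot scale after per-image median background
subtraction, with non-maximum suppression within $2\sigma$ and sub-pixel
localization by intensity-weighted centroid. Detection is deliberately
plain: the metrics downstream, not the detector, are the point of the
package, and pre-detected point tables can be supplied instead.

BB–BF pairing follows the *closest-dot rule*: each BB is joined to the
nearest BF punctum. Because each basal body carries exactly one basal foot,
matching is one-to-one: the globally smallest remaining BB–BF distance is
accepted repeatedly, bounded by a 1 µm cutoff (the true separation is
sub-micron, visible only by electron microscopy; the cutoff and the rule's
tie-break — lower punctum index — are configurable). A cell's rotational
$\bar R$ is reported only when at least ten vectors were available
(`min_pairs_per_cell`, inclusive reading of "more than ten", configurable);
cells below the floor are flagged and excluded, and the exclusion count is
reported at tissue level.

The cluster centre is the **unweighted** centroid of the BB positions —
intensity weighting would couple the geometry to staining efficiency. The
edge point $E$ is computed by exact ray–polygon intersection, making the
directionality a true ratio in $[0, 1]$ for convex cells. The cluster
area is the convex hull of the BB positions; the actin enrichment ratio
divides mean intensity in the union of disks (radius $2\sigma$ by default)
around the BBs by mean intensity in the remainder of the cell mask, so a
uniform image gives exactly 1 and the ratio reads as pure enrichment
contrast.

## Circular statistics

The circular layer is self-contained: circular mean/resultant,
$\mathrm{SD} = \sqrt{-2\ln \bar R}$, a Best–Fisher von Mises sampler, the
Bessel-ratio calibration $E[\bar R] = I_1(\kappa)/I_0(\kappa)$ and its
numerical inverse, and Watson's two-sample $U^2$ from pooled ranks. The
$U^2$ p-value is by seeded label permutation by default — exact-in-spirit,
valid at any n, never exactly zero (the $(b+1)/(m+1)$ convention) — with
exhaustive enumeration for tiny samples and the asymptotic critical-value
table as an option for parity with classic software. Scalar metrics are
compared with Welch's t-test or the Mann–Whitney U-test, both two-sided.

## Kymographs and run/pause segmentation

Kymographs sample intensity along a polyline at one-pixel arc-length
steps, taking the maximum across a three-pixel-wide band. The particle
trace is extracted per row by a Gaussian matched filter with parabolic
peak interpolation inside a tracking window — in synthetic tests this
roughly halves the localization error of a plain windowed centroid.

Because motors pause, velocity is measured *between* pauses. Segmentation
has three stages: (1) candidate pauses are sliding windows
(`min_pause_frames` = 3 frames) whose speed stays under a threshold — the
2 nm/s floor, raised adaptively towards 45% of the typical run speed so
that brief stops of fast motors are still caught; (2) boundaries are then
placed exactly by a least-squares dynamic programme in which pauses are
constants and runs are straight lines; (3) each pause must beat the merged
straight-line alternative in a likelihood-ratio sense (noise estimated
robustly from second differences of the trace), otherwise it is pruned.
Run velocity is the fitted segment displacement over its duration, in
nm/s. On synthetic kymographs at signal-to-noise 10 this recovers
boundaries within ±1 frame for over 90% of segments at the reference
condition (12.2 nm/s, one frame per 3 s) and keeps the mean absolute
velocity error under 10% across 5–30 nm/s. A known limit: at 5 nm/s the
per-frame displacement (15 nm) is comparable to the localization noise,
so individual boundaries there are only reliable to ±2 frames even though
velocities remain accurate.

## Beat frequency

The field's working definition is discrete: count round trips of the
ciliary tip per second. The estimator mirrors that: the displacement trace (2-D
tip tracks are first projected onto their principal axis) is counted by a
mean-level Schmitt trigger whose hysteresis is 40% of the robust amplitude,
after band-limited (sinc) 8× upsampling — a 20 Hz beat recorded at 47
frames/s leaves only 2.35 samples per cycle, and without reconstruction a
sampled-domain trigger misses beats that the record provably contains
(the signal is below Nyquist). A zero-padded periodogram peak with
parabolic interpolation is computed as a cross-check and, when it agrees
with the crossing count within the crossing resolution, refines the
estimate. Records whose peak-to-peak amplitude stays below the immotility
threshold (0.5 µm by default; the source assays score such cilia as zero)
report 0 Hz. With 20% amplitude noise this recovers 5–20 Hz at 47/95/190
frames/s within the 1/duration resolution in ≥95% of records.

## Bead flow

Bead transport is quantified exactly as a manual tracking workflow would:
greedy nearest-neighbour frame-to-frame linking bounded by a maximum step,
new tracks for unlinked detections, tracks under 3 frames dropped, and
*per-frame* speeds pooled across beads (so n counts frames, not beads),
summarized by median and quartiles. Time projections (pixel-wise maximum
over the first n frames) reproduce the familiar streak images.

## The synthetic-scene generator

The generator is first-class, tested code, and its defaults are the study
conditions of the measurements it emulates:

| parameter | default | why |
|---|---|---|
| cells per scene | 30 (100 in the acceptance tissue runs) | typical analysis cohort |
| cell diameter | 15 µm | ependymal apical mosaic scale |
| BBs per cell | Poisson, mean 50 | observed per-cell counts |
| BB–BF distance r | 0.25 µm | sub-micron EM-scale separation |
| BB scatter SD | 1.4 µm | gives hull areas of ~30 µm² at n≈50 |
| minimum BB spacing | 0.45 µm | centrioles cannot overlap (hard-core) |
| κ_rot | 8 (polarized) | strongly aligned basal feet |
| κ_trans | A⁻¹(0.714) ≈ 2.33 | matches the polarized tissue R̄ |
| cluster offset d | 0.5 | directionality ≈ 0.5 |
| actin enrichment ρ | 1.5 | disk-region contrast |
| beat records | 2 s at 47/95/190 fps | acquisition protocol |
| bead assay | 10 fps × 10 s, 53 beads | flow-assay protocol |
| single-molecule imaging | 1 frame / 3 s | slow-motor TIRF protocol |

Cell mosaics are Voronoi tessellations of jittered grid seeds (half-plane
clipping, exact convex cells). Each cell draws its direction
$\theta_{cell}$ from von Mises($\mu_{tissue}, \kappa_{trans}$); the BB
cluster centre sits at fraction d of the centroid-to-edge distance along
it; BBs scatter isotropically with a hard-core minimum separation (dart
throwing, re-projected towards the centroid if the polygon is left — the
count is recorded); each BF sits exactly r from its BB at a von
Mises($\theta_{cell}, \kappa_{rot}$) angle. Channels are rendered as
Gaussian spots over background in [0, 1], the actin channel carries
ρ-fold enrichment inside the BB disks, and the TT channel a crescent band
at the polarized cell edge. Pauses in synthetic kymographs are sustained
dwells (minimum 3 frames): single-frame hesitations are not part of the
data-generating model, since no sustained-pause detector could ever see
them.

What the generator does **not** emulate — and hence what green tests do
not certify on real data: optical aberrations and depth-dependent blur,
photobleaching, spectral bleed-through, segmentation errors in the cell
masks (masks are inputs), BB clusters with non-Gaussian shapes, beat
waveform asymmetry, metachronal phase gradients, and out-of-plane cilia
motion. The angular noise family is von Mises by choice (the standard
circular analogue of the Gaussian); the source measurements state no
distribution.

## Numerical choices and degenerate inputs

Angles are reduced into $(-\pi, \pi]$ on ingestion, and the straight-left
direction reports $+\pi$, never $-\pi$. $\bar R < 10^{-12}$ flags the mean
direction undefined. A cluster within $10^{-6}$ µm of the centroid has
directionality 0 by continuity and an undefined angle. Fewer than three
non-collinear BBs give hull area 0 with a QC flag. Zero-denominator and
empty-mask intensity ratios are flagged, not errors. Equidistant pairing
candidates resolve to the lower punctum index. Every QC event lands in a
per-cell `qc_flags` string rather than silently dropping the cell.
Float-TIFF round trips are exact to single precision (~1e-7 relative);
result CSVs round-trip numerically to 1e-9.

Problem sizes in the tests and the acceptance script — 30–100 cells per
scene, 20–25 kymographs per velocity, 200 beat traces per condition,
1000 null simulations for the permutation-test calibration — were chosen
as the smallest sets at which the recovery statistics stabilize well
inside their tolerances.

## Known limitations

The pipeline is 2-D and assumes the apical surface was imaged in a single
plane. Cell masks come from outside (phalloidin-based segmentation is not
reimplemented). The corrected TT–BB distance depends on where the TT
crescent centre falls; in the generator the TT domain is centred on the
same direction as the BB cluster, which bounds the synthetic ratio below
values seen when the two directions disagree. Bead speed medians inherit
a small positive bias from diffusion at low drift speeds. The Watson test
treats ties by pooled sort order; heavily discretized angle data should be
jittered upstream.
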