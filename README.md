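# ciliometry

Planar-polarity and motility metrics for multiciliated cells (MCCs), such
as the ependymal cells whose beating cilia drive cerebrospinal-fluid flow
across brain ventricular walls.

MCC function depends on quantities that are awkward to measure well by
hand and that this package computes reproducibly from images or point
tables:

* **Rotational polarity.** Each basal body (BB) carries a basal foot (BF)
  pointing in its cilium's beat direction. From paired BB/BF puncta the
  package draws the vector from each BB to its *closest* BF (one-to-one,
  globally greedy, bounded by a configurable cutoff) and summarizes each
  cell by the mean resultant vector length
  R̄ = |Σₖ e^{iθₖ}| / n ∈ [0, 1] — 1 when all basal feet agree, 0 when
  they are uniform. Cells with fewer than 10 vectors are flagged and
  excluded.
* **Translational polarity.** The angle θ from the cell centroid C^c to
  the BB cluster centre C^b (unweighted centroid of the BB puncta), its
  tissue-level R̄ and circular SD √(−2 ln R̄); *BB directionality*
  |C^cC^b| / |C^cE| with E the cell-edge point on the ray through the
  cluster; the *corrected TT–BB distance* |C^bC^t| / |C^cC^t| to the
  centre C^t of the polarized tyrosinated-tubulin domain; plus BB counts,
  convex-hull cluster areas, and region-normalized intensity ratios
  (e.g. actin at the BB disks over the rest of the apical cortex).
* **Circular statistics.** von Mises sampling and the Bessel-ratio
  calibration E[R̄] = I₁(κ)/I₀(κ), Watson's two-sample U² test with
  seeded permutation p-values (exact enumeration and asymptotic options),
  Welch and Mann–Whitney comparisons for scalar metrics.
* **Motility.** Kymograph construction (3-pixel-wide line scans),
  matched-filter trace extraction, run/pause segmentation by least-squares
  changepoint optimization with likelihood-ratio pause validation, and
  per-run velocities in nm/s; ciliary beat frequency by Schmitt-trigger
  round-trip counting on the band-limited trace with a periodogram
  cross-check (immotile records score 0 Hz); bead tracking with pooled
  per-frame speeds and time projections for surface-flow assays.
* **Synthetic scenes.** A seeded generator of ground-truthed apical
  mosaics (Voronoi cells, BB/BF point sets with von Mises angular
  structure, rendered channels), beat traces, bead tracks and
  single-molecule kymographs, so every stage is validated by parameter
  recovery.

## Worked example

Generate a polarized ("wild-type-like") and an unpolarized
("mutant-like") tissue, run the full per-cell metric table, and compare
the groups:

```r
library(ciliometry)

sc  <- generate_scene(scene_config(n_cells = 30, seed = 42))
bb  <- subset(sc$truth$puncta, type == "bb")[, c("x_um", "y_um")]
bf  <- subset(sc$truth$puncta, type == "bf")[, c("x_um", "y_um")]
res <- polarity_table(bb, bf, sc$cells, analysis_config())

median(res$cells$rotational_rbar, na.rm = TRUE)    # 0.897
median(res$cells$bb_directionality, na.rm = TRUE)  # 0.497
res$tissue$rbar                                    # 0.667  (n = 30 cells)
res$tissue$circ_sd_rad                             # 0.900  rad

mut <- generate_scene(scene_config(n_cells = 30, kappa_rot = 0.3,
                                   cluster_offset = 0.15,
                                   kappa_trans = vm_concentration(0.227),
                                   seed = 43))
mres <- polarity_table(subset(mut$truth$puncta, type == "bb")[, c("x_um", "y_um")],
                       subset(mut$truth$puncta, type == "bf")[, c("x_um", "y_um")],
                       mut$cells, analysis_config())
median(mres$cells$rotational_rbar, na.rm = TRUE)   # 0.193

compare_groups(res$cells$rotational_rbar, mres$cells$rotational_rbar,
               "mann_whitney")$p.value             # 1.69e-17
```

The generating conditions are recovered: per-cell R̄ tracks
I₁(κ)/I₀(κ) (κ_rot = 8 gives 0.936; κ_rot = 0.3 with ~50 noisy vectors
per cell gives ~0.19), directionality tracks the cluster offset (0.5 vs
0.15), and the polarized and unpolarized groups separate decisively.

Single-molecule velocity from a synthetic kymograph (one frame per 3 s,
signal-to-noise 10):

```r
g   <- generate_sm_kymograph(velocity_nm_s = 12.2, pause_prob = 0.03,
                             n_frames = 100, noise_sd = 0.07, seed = 1)
seg <- segment_runs(kymo_trace(g$kymograph), frame_interval_s = 3)
seg[, c("kind", "start_frame", "end_frame", "velocity_nm_s")]
#    kind start_frame end_frame velocity_nm_s
# 1   run           1        27          12.4
# 2 pause          27        36           0.0
# 3   run          36        53          12.3
# 4 pause          53        60           0.0
# 5   run          60       100          12.2
```

Beat frequency of 2-second tip traces at 190 frames/s:

```r
trs <- generate_beat_traces(freq_hz = 19.9, fps = 190, n_traces = 5, seed = 2)
sapply(trs, function(t) beat_frequency(t)$freq_hz)
# 19.9 19.9 19.9 19.9 19.9
```

Everything also runs file-to-file (`cmd_simulate()`, `cmd_polarity()`,
`cmd_motility()`, `cmd_compare()`, each writing CSV/JSON plus a manifest
with input hashes and record counts), and a thin command-line wrapper
lives at `inst/cli/ciliometry.R`:

```sh
Rscript inst/cli/ciliometry.R simulate --out scene --seed 5
Rscript inst/cli/ciliometry.R polarity --out scene/out \
        --points scene/puncta.csv --outlines scene/outlines.csv
```

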