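---
title: "Quantifying NMDAR-BK nanodomain coupling: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying NMDAR-BK nanodomain coupling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

BK channels (large-conductance Ca2+- and voltage-activated K+ channels) need
micromolar Ca2+ to open at physiological voltages, concentrations that exist
only within tens of nanometers of an open Ca2+ source. In heterologous cells
and neurons, NMDA receptors (GluN1/GluN2B) can act as that source when the
two channels co-assemble in membrane nanodomains (~20-50 nm). This package
implements the quantitative pipeline used to ask whether a disease-associated
GluN2B mutation disrupts that coupling, across five independent readouts:

1. **Functional coupling** from whole-cell patch clamp: the ratio of outward
   (BK) to inward (NMDAR) charge in a glutamate-evoked sweep.
2. **Ca2+ influx** from a membrane-tethered sensor: background-subtracted
   delta-F/F0, its peak and area under the curve.
3. **Molecular proximity** from PLA: puncta per unit cell area.
4. **Membrane abundance** from TIRF: exposure-normalized integrated density,
   plus immunoblot densitometry ratios.
5. **Nanoscale organization** from two-color SMLM/STORM: cross-channel
   nearest-neighbor distances, density-based clusters classified as homo- or
   heteroclusters, their convex-hull areas, and two-sample
   Kolmogorov-Smirnov comparisons of those distributions.

No raw recordings are redistributable, so the package pairs every analysis
stage with a synthetic-data generator with known ground truth; all tests and
the acceptance script run end to end on those simulations.

# Charge analysis (ephys)

A sweep is uniformly sampled current $I(t)$ (pA, inward negative) with a
stimulus window and a pre-stimulus baseline window. After constant-offset
baseline correction (mean of the baseline window; an optional linear-drift
mode exists but is off by default), charges are separated **by instantaneous
sign**, not by time segmentation:

$$Q_{in} = \left|\int \min(I, 0)\,dt\right|, \qquad
  Q_{out} = \int \max(I, 0)\,dt, \qquad
  CR = Q_{out}/Q_{in},$$

integrated by the trapezoidal rule over a configurable window. Sign
separation is the only option that needs no kinetic model when the inward
and outward components overlap in time; its cost is a rectification bias
under noise (the positive half of zero-mean noise integrates to
$\sigma\sqrt{dt\,T/2\pi}$ per unit time where the signal is silent), which
is why analysis windows should end soon after the outward tail decays
rather than defaulting to the whole sweep.

Key parameters:

* `window` (s): default `stim_onset + c(0, 5)`. The outward BK component is
  slower than the 1-s glutamate pulse, so the window must contain its decay;
  the end point is configurable because the field reports no standard
  convention (fixed time vs return to baseline).
* `baseline_window` (s): default everything before stimulus onset. The
  simulated response begins strictly *after* onset so the onset sample still
  belongs to the baseline.
* Normalization of I-V and Q-V curves is **per cell to the maximum
  magnitude across voltages** (the source figures say only "normalized");
  the choice is recorded in the returned object. Coupling-ratio curves are
  aggregated raw (un-normalized), mean +/- SEM with $n$ = cells, and sweeps
  with $Q_{in} = 0$ are dropped per voltage with a reported count rather
  than propagating NaN.

The trace simulator uses one double-exponential family for both components,
$g(t) = (1 - e^{-t/\tau_r})\,e^{-t/\tau_d}$, because its charge has the
closed form $A\,\tau_d^2/(\tau_r+\tau_d)$ — a single analytic oracle for
both ground-truth charges. Traces are phenomenological: no Markov gating,
no Mg2+ block, no series-resistance artifacts.

# Delta-F/F0 (calcium)

Processing follows the standard imaging chain: frame-wise background-ROI
subtraction, then $\mathrm{d}ff(t) = (F(t) - F_0)/F_0$ with $F_0$ the mean
over the pre-stimulus window ($F_0 \le 0$ is an error — it indicates
over-subtraction). Negative dff (undershoot, bleaching) is retained and
enters the AUC.

The peak is the maximum of dff in the response window. A raw maximum is
upward-biased on noisy traces (the maximum of signal-plus-noise over many
near-peak samples), so `peak_and_auc()` accepts `smooth_s`, a moving-average
width applied only to peak picking: 0 (default, exact on clean data) or
~1.25 s (5 frames at the 4-Hz acquisition rate), which is short against the
~8-s transient decay and removes the bias at the cost of <1% peak
attenuation. The AUC (trapezoidal, units s) is always computed on the raw
series since integration averages noise out on its own. "Normalized AUC" is
interpreted as per-cell normalization to the maximum-magnitude AUC across
voltages, mirroring the I-V convention; absolute AUC is available via
`normalize_auc(..., "none")`.

# Per-cell image quantification (quant)

**Segmentation.** Nuclei by global Otsu threshold + connected components
with a minimum size filter (default 20 um^2, parameter-free and
overridable); cytoplasm estimated by expanding each nucleus by a fixed
radius (`expansion_um`; the source protocol does not specify its estimator,
so the radius is an explicit parameter). Contested pixels go to the nearest
nucleus, ties to the lowest label, so masks always partition: total masked
area equals the sum of per-cell areas.

**Puncta.** Scale-normalized Laplacian-of-Gaussian filtering over a sigma
range (default 0.2-1.0 um; PLA puncta are diffraction-limited), strict
8-neighbor local maxima above `threshold_k` (default 6) robust noise SDs of
the filtered response (MAD, floored so numerically flat images cannot fire
on FFT ripple), cross-scale merging keeping the strongest response, and
masking: only detections on a nonzero label count. At the simulator's
conditions the detector is exact at SNR 10 and keeps full recall/precision
at SNR 4. Density is count/area (um^-2) per cell; zero-area cells are
excluded with a warning.

**TIRF and blots.** TIRF intensity is background-subtracted integrated
density over the mask divided by exposure (a.u./ms), making 5-100 ms
acquisitions comparable; group values are normalized to the mean of a
reference condition. Blot quantification consumes band intensities (target
and loading control) from CSV — densitometry itself is instrument-software
territory — and reports target/loading ratios normalized to the reference
condition's mean.

# Two-color SMLM analysis (smlm)

Localization tables are ThunderSTORM-style CSV (`frame, x_nm, y_nm,
channel, uncertainty_nm`, nm throughout; the `x [um]` dialect is converted
on read). Red is the GluN2B/AF647 channel, green BK/AF488, overridable.
Localization uncertainty is carried as metadata but never deconvolved from
distances, matching direct use of localization coordinates.

**NND** is per-localization and directional: for each query-channel point,
the Euclidean distance to the nearest reference-channel point (self
excluded within a channel). The search uses an exact uniform-grid index —
results are identical to exhaustive search, which the tests assert
literally. Distributions use fixed 5-nm left-closed bins, a
right-continuous ECDF, and report the modal bin and the fraction within the
nanodomain range (0-50 nm), which equals ECDF(50) by construction.

**Clustering** is DBSCAN on the merged two-channel point set: a core point
has at least `min_count` points (self included) within `radius`; clusters
are connected components of core points under radius adjacency; border
points attach to their nearest core point (ties to the lowest cluster id);
cluster ids are ordered by lowest member row index, so results are
independent of input row order. Defaults mirror the study's density
filtering: radius from {20, 40, 60} nm with a count of 10 molecules.
Channel-blind clustering with channel-aware classification is the one
reading under which heteroclusters are detectable at all; clustering each
channel separately and overlapping clusters afterwards is the main
alternative and was rejected because it cannot represent a mixed cluster as
one object.

**Classification**: hetero iff at least `min_minor` (default 1) molecules
of each channel; otherwise homo of the majority channel. Percentages are
over all clusters and sum to 100. The minority threshold is exposed because
a 1-molecule rule is sensitive to background contamination in principle.

**Areas** are 2D convex hulls (`chull` + shoelace) in nm^2; degenerate
hulls (<3 distinct non-collinear points) get area 0, are flagged, and are
excluded from per-class ECDFs. `radius_sweep()` repeats
cluster/classify/area per radius; the set of clustered points is
mathematically non-decreasing in the radius at fixed `min_count`, and the
suite checks that invariant on random scenes.

# Distribution comparison (stats)

The ECDF and the two-sample Kolmogorov-Smirnov test are first-class
implementations because they carry the headline cluster-size and NND
comparisons. $D$ is the supremum of $|F_x - F_y|$ evaluated at the pooled
unique sample points with right-continuous ECDFs — deterministic under
ties and checked against exhaustive evaluation. The two-sided p-value uses
the asymptotic Kolmogorov distribution with effective size
$n_e = n_1 n_2/(n_1+n_2)$ and the Stephens small-sample refinement
$\lambda = (\sqrt{n_e} + 0.12 + 0.11/\sqrt{n_e})\,D$: the plain
$\sqrt{n_e}\,D$ form rejects a true null at ~4.2% instead of 5% at
$n_1=n_2=200$, while the refined form is calibrated to 0.05 +/- 0.01 there
(the suite measures this over 10^4 null pairs). No exact small-sample
p-value is provided; study-relevant samples are hundreds to thousands.
Group tests used elsewhere in the workflow (ANOVA, Kruskal-Wallis) are
called from base R, not re-derived.

# The synthetic-data generator

The generator defines the study conditions for every test:

* **Localization scenes**: cluster centers uniform with a 4-sigma margin
  (avoids edge truncation biasing area recovery); molecules per cluster
  fixed or Poisson-with-floor; true positions Gaussian around the center
  (`cluster_sd`); observed positions add channel-specific Gaussian error,
  defaulting to 13 nm (red/AF647) and 16 nm (green/AF488), typical lateral
  accuracies in dual-color dSTORM; uniform per-channel background (CSR).
  Heterocluster channels are per-molecule Bernoulli draws, redrawn if a
  draw comes out single-channel so the labeled class is always realized.
  Within-channel NND of the background alone follows the CSR closed form
  $P(D \le r) = 1 - e^{-\lambda \pi r^2}$, which the suite verifies with
  border-corrected queries (150-nm guard) at ~10^4 points.
* **Sweeps**: the double-exponential components above; default noise 0.5-2
  pA RMS against hundreds-of-pA signals.
* **Fluorescence**: $F = f_0(1 + \mathrm{peak}\cdot s(t)) + bg$ with $s$
  peaking at exactly 1 (bi-exponential, peak-normalized analytically, or a
  triangle whose AUC is exactly base/2).
* **Cell images**: non-overlapping disks with bright 3-um nuclei (28 um^2,
  safely above the 20-um^2 segmentation filter), puncta as Gaussian spots
  (sigma 0.2 um) strictly inside cells with >=1 um mutual separation so
  every rendered spot is countable.

Scene sizes used by the tests and acceptance script were chosen once, as
study conditions, with cluster detectability in mind: at radius 40 nm and
count 10, a cluster is reliably detected when its expected within-radius
occupancy clearly exceeds 10, so composition-recovery scenes use
Poisson(30, floor 20) molecules at 20-nm spread, and the demo's
40-nm-spread scenes use Poisson(60, floor 40) localizations per cluster
(realistic once blinking overcounting is considered). Earlier drafts that
sat *at* the detectability boundary measured cluster dropout rather than
classification and were revised once, before freezing.

What the simulations do **not** emulate: blinking photophysics and
overcounting correlations, drift and channel misregistration, non-Gaussian
localization error, sample-to-sample antibody labeling variation, cell
morphology beyond disks, and bleaching kinetics. Passing tests therefore
demonstrate correctness of the quantification machinery under known ground
truth, not robustness to every instrumental artifact of real data.

# Numerical choices and degenerate inputs

* Trapezoidal integration throughout (`pracma::trapz`); $O(dt^2)$
  convergence is asserted by halving $dt$ on an analytic exponential.
* Neighbor searches (DBSCAN, NND) use exact grid indexes in compiled code;
  every neighborhood is distance-checked, so the index only prunes.
* Flat sweep: both charges 0, ratio flagged undefined. Empty localization
  table: empty cluster list. Collinear cluster: area 0, degenerate flag.
  Saturated image: warning. Cramped simulation fields: warning, not
  failure; impossible cell placements: error after bounded retries.
* All randomness flows from one integer seed per simulator call
  (`withr::with_seed`), and the demo derives all stage seeds from a single
  master seed; identical seeds give byte-identical outputs.

# Problem sizes

The test suite and `scripts/acceptance.R` run the study at desk scale,
chosen as the package's own verification conditions: 30 cells x 7 voltages
for coupling recovery; 100 random scenes (<= 300 points) for the DBSCAN
oracle; 50 tables (<= 500 points) for the NND oracle; ~10^4 points for the
CSR check; 60 scenes for composition recovery; 100 replicate pairs of 500
clusters for the area-shift power and 800 pairs for the null calibration;
50 images for puncta recovery; 10^4 null pairs at n = 200 for K-S
calibration.

# Known limitations

* Sign-split charges are biased by noise rectification where the signal is
  silent; prefer tight analysis windows, or noise-free simulations when
  verifying exact recovery.
* The 1-molecule heterocluster rule is liberal under heavy background; use
  `min_minor` > 1 in crowded fields.
* The asymptotic K-S p-value is approximate below a few tens of samples
  per group.
* Convex-hull area is an overestimate of cluster area for sparse clusters
  and undefined for degenerate geometry (reported as 0 and excluded from
  ECDFs).
* PLA, TIRF and blot quantification assume the instrument has already
  produced linear, unsaturated intensities.
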