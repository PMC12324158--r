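# nanocouple

Quantification of functional and spatial coupling between NMDA receptors
(NMDARs, GluN1/GluN2B) and BK channels in membrane nanodomains.

BK channels are Ca²⁺- and voltage-activated K⁺ channels that, at
physiological voltages, open only when local Ca²⁺ reaches micromolar
levels — concentrations that exist within ~20–50 nm of an open Ca²⁺ source.
When NMDARs and BK channels co-assemble in such nanodomains, a glutamate
pulse evokes a fast inward NMDAR current followed by a slower outward BK
current. This package implements the full quantification pipeline used to
study whether a disease-associated GluN2B mutation (V618G) disrupts that
coupling, for researchers analysing patch-clamp, Ca²⁺-imaging, PLA, TIRF
and two-color single-molecule localization (SMLM/STORM) data:

* **Charge analysis** — baseline correction, sign-split trapezoidal charge
  integration of whole-cell sweeps, normalized I–V / Q–V curves and the
  functional-coupling statistic
  *CR = Q<sub>outward</sub>/Q<sub>inward</sub>*
  (`baseline_correct`, `split_charges`, `iv_curve`, `qv_curve`,
  `coupling_curve`).
* **ΔF/F₀ analysis** — background subtraction, baseline normalization,
  peak and AUC of membrane Ca²⁺-sensor transients (`delta_f_over_f0`,
  `peak_and_auc`).
* **Per-cell image quantification** — nuclear segmentation with cytoplasm
  expansion, Laplacian-of-Gaussian puncta detection, PLA density
  (count/µm²), exposure-normalized TIRF intensity and blot densitometry
  ratios (`segment_cells`, `detect_puncta`, `puncta_density`,
  `tirf_intensity`, `densitometry_ratio`).
* **Two-color SMLM** — exact cross-channel nearest-neighbor distances,
  exact DBSCAN density clustering on the merged two-channel point set
  (radius 20/40/60 nm, count 10), homo-/heterocluster classification,
  convex-hull cluster areas and radius sweeps (`cross_channel_nnd`,
  `density_cluster`, `classify_clusters`, `cluster_areas`, `radius_sweep`).
* **Distribution comparison** — first-class ECDF and two-sample
  Kolmogorov–Smirnov test, *D* = sup |F₁ − F₂| at pooled sample points with
  an asymptotic p-value at effective size n₁n₂/(n₁+n₂) (`ecdf_step`,
  `ks_two_sample`).
* **Synthetic data with ground truth** — clustered two-color point
  patterns with per-channel localization precision (13 nm / 16 nm
  defaults), biphasic current sweeps with closed-form component charges,
  ΔF/F₀ transients, and cell images with countable puncta
  (`simulate_localizations`, `simulate_current_trace`,
  `simulate_fluorescence_trace`, `simulate_cell_image`), plus a one-seed
  end-to-end rehearsal of the whole WT-vs-V618G comparison (`run_demo`).

## Worked example

```r
library(nanocouple)

## functional coupling from a simulated glutamate-evoked sweep
cfg <- trace_sim_config(dt = 1e-3, duration = 8, stim_onset = 1,
                        stim_duration = 1,
                        inward_amplitude = 1000, inward_rise = 0.02,
                        inward_decay = 0.25,
                        outward_amplitude = 180, outward_delay = 1.5,
                        outward_rise = 0.1, outward_decay = 0.6,
                        noise_sd = 0.5, voltage_mV = 40, seed = 7)
sim <- simulate_current_trace(cfg)
res <- analyze_sweep(sim$trace, window = c(1, 7))
cat(sprintf("Q_in = %.1f pC, Q_out = %.1f pC, Q_out/Q_in = %.3f (truth %.3f)\n",
            res$Q_in_pC, res$Q_out_pC, res$coupling_ratio,
            sim$true_Q_out_pC / sim$true_Q_in_pC))
#> Q_in = 231.0 pC, Q_out = 92.0 pC, Q_out/Q_in = 0.398 (truth 0.400)
```

The measured ratio is the sign-split charge ratio over the analysis
window; at this noise level it recovers the simulator's ground truth to
half a percent.

```r
## two-color SMLM scene: cluster composition across the radius sweep
scene <- simulate_localizations(point_sim_config(
  field_size = c(12000, 12000), n_homo_red = 15, n_homo_green = 15,
  n_hetero = 40, molecules_per_cluster = list(lambda = 60, floor = 40),
  cluster_sd = 30, background_density = 1, seed = 42))
sw <- radius_sweep(scene, radii = c(20, 40, 60), min_count = 10)
print(sw$summary, row.names = FALSE)
#>  radius_nm composition  n percentage n_clustered_points
#>         20    homo_red 15   20.83333               1610
#>         20  homo_green 13   18.05556               1610
#>         20      hetero 44   61.11111               1610
#>         40    homo_red 14   20.58824               3967
#>         40  homo_green 14   20.58824               3967
#>         40      hetero 40   58.82353               3967
#>         60    homo_red 14   21.21212               4101
#>         60  homo_green 13   19.69697               4101
#>         60      hetero 39   59.09091               4101
```

At radius 40 nm the scene's 40 heteroclusters and 30 homoclusters are
recovered almost exactly (40/14/14 against a 40/15/15 truth); at 20 nm the
density filter fragments diffuse clusters, which is why the radius sweep is
reported rather than a single setting.

```r
## K-S comparison of heterocluster areas between a 30-nm and a 20-nm spread
scene2 <- simulate_localizations(point_sim_config(
  field_size = c(12000, 12000), n_hetero = 40,
  molecules_per_cluster = list(lambda = 60, floor = 40),
  cluster_sd = 20, background_density = 1, seed = 43))
a1 <- cluster_areas(density_cluster(scene, 40, 10))$table
a2 <- cluster_areas(density_cluster(scene2, 40, 10))$table
ks_two_sample(a1$area_nm2[a1$composition == "hetero"],
              a2$area_nm2[a2$composition == "hetero"])
#> Two-sample Kolmogorov-Smirnov: D = 0.9, p = 2.02e-15 (n1 = 40, n2 = 40)
```

## Analysis workflow

The numbered scripts under `analysis/` regenerate a complete synthetic
WT-vs-V618G study from one seed and run every pipeline stage over it,
writing tables under `results/tables/` and figures under
`results/figures/`:

```sh
Rscript analysis/01_simulate.R   # synthetic dataset under results/data/
Rscript analysis/02_ephys.R      # charges, I-V/Q-V, coupling ratios
Rscript analysis/03_calcium.R    # dF/F0 peaks and AUCs
Rscript analysis/04_imaging.R    # PLA density, TIRF, blot ratios
Rscript analysis/05_smlm.R       # NND, clusters, areas, K-S
```

`run_demo(seed, out_dir)` performs the same rehearsal as a single call and
is byte-reproducible per seed.

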