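# vasculomorph

Multimodality analysis of abnormal tumor vasculature for preclinical
brain-tumor imaging studies, with a synthetic-data generator for every
modality so that each analysis stage is testable by parameter recovery.

## Who this is for

Preclinical imaging groups quantifying how a treatment changes tumor
vasculature in rodent brain-tumor models (e.g. 9L gliosarcoma) across
four measurement types:

* **DSC-MRI perfusion** — relative cerebral blood volume (rCBV) from
  dynamic susceptibility contrast time-series:
  ΔR2\*(t) = −ln(S(t)/S₀)/TE, CBV ∝ ∫ΔR2\* dt (trapezoidal), and
  rCBV = mean CBV(tumor ROI) / mean CBV(contralateral ROI). The
  Bonferroni voxel threshold α/n is provided for parametric maps.
* **micro-CT vessel morphometry** — from a binary vessel volume:
  topology-preserving 3D thinning, branch-graph extraction, branch
  density ρ = N(daughter segments)/V(VOI) in branches/mm³, and
  tortuosity τ = θ/L in deg/mm (branching angle over branch length).
* **IHC morphometry** — microvessel count and cross-sectional areas
  (µm²) from endothelial-stain fields via Otsu thresholding and
  connected components.
* **growth kinetics** — y = y₀·e^(kt) by nonlinear least squares;
  doubling time T_d = 0.69/k.

Cohort statistics match the conventions of the emulated study design:
one-way ANOVA with Bonferroni post tests across imaging days, unpaired
t-tests for densities and areas, exact/normal-approximation Mann-Whitney
U for tortuosity distributions.

Because such studies rarely deposit raw data, the package ships
generators (`gen_dsc`, `gen_tree`, `gen_ihc`, `gen_growth`) that plant
known ground truth — gamma-variate bolus passages at TE 34.5 ms / 1.02 s
sampling, bifurcating vascular trees rasterized at 45.19 µm, stained
0.26 mm² fields, noisy exponential growth — and the test suite verifies
that the full pipelines recover the planted parameters.

## Worked example

```r
library(vasculomorph)

# DSC-MRI: plant a tumor:contralateral blood-volume ratio of 0.65,
# run signal -> Delta-R2* -> CBV -> rCBV
sim <- gen_dsc(dsc_sim_spec(rcbv_ratio = 0.65, noise_sd = 10, seed = 1))
res <- relative_cbv(integrate_cbv(compute_delta_r2star(sim$series)), sim$rois)
sprintf("planted rCBV 0.65 -> recovered %.3f", res$rcbv)
#> "planted rCBV 0.65 -> recovered 0.649"

# micro-CT morphometry: plant 41.32 branches/mm^3, rasterize, skeletonize,
# extract the branch graph, count daughters per VOI
tr <- gen_tree(tree_spec(domain_edge_mm = 1.5, target_density = 41.32, seed = 1))
tr$truth
#> <vessel_tree_truth> 140 segments (139 daughters), 1.5 mm domain, 41.19 branches/mm^3
measure_tree(tr)
#> <morphometry_summary> 145 branches in 3.38 mm^3 = 42.96 /mm^3; median tortuosity 242.7 deg/mm

# growth kinetics: plant a 2.06-day doubling time, fit y = y0 * exp(k t)
fit_exponential(gen_growth(growth_sim_spec(doubling_days = 2.06, cv = 0.1, seed = 1)))
#> <growth_fit> y0 = 32.93 mm^3, k = 0.3287 /d, r2 = 0.992, Td = 2.1 d

# exact Mann-Whitney U (tortuosity-style comparison)
mann_whitney_u(c(1, 2, 3), c(4, 5, 6))$p_two_sided
#> 0.1
```

The recovered 0.649 is the planted blood-volume ratio passed through the
whole perfusion pipeline under noise; the measured 42.96 branches/mm³ is
the planted density recovered through rasterization, thinning and graph
extraction; the fitted 2.1 days recovers the planted doubling time from
a noisy 5-point trajectory.

## Command line

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "vasculomorph", package = "vasculomorph"))') \
    simulate tree --config tree.json --seed 1 --out out/
# subcommands: simulate tree|dsc|ihc|growth, perfusion, morphometry,
#              ihc, growth, stats, run
```

`run` executes a full two-arm cohort experiment (simulate → analyze →
compare) and writes `rcbv.csv`, `morphometry.csv`, `tortuosity_hist.csv`,
`ihc.csv`, `growth.csv`, `stats.csv`, `run.log`, reproducible
byte-for-byte from config + seed.

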