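# dmisim

Simulation and analysis of three-compartment **diffusion microstructure
imaging (DMI)** in perilesional white matter, built for the question of
whether the T2/FLAIR-hyperintense zone around a contrast-enhancing brain
tumour looks like pure vasogenic edema (as around metastases) or edema plus
infiltrating tumour (as around glioblastoma, GBM). It is aimed at
neuroimaging methodologists and biostatisticians who want a fully synthetic,
seeded, end-to-end testbed for this analysis: no patient data are required
anywhere.

## The model and the analysis

Each white-matter voxel is a mixture of three water pools
(stick–zeppelin–ball):

```
S(b, g) = s0 [ v_i exp(-b D_i (g·u)^2)
             + v_e exp(-b (D_e⊥ + (D_e∥ - D_e⊥)(g·u)^2))
             + v_f exp(-b D_f) ],     v_i + v_e + v_f = 1
```

with b in ms/µm², diffusivities in µm²/ms, `u` the axon axis and `D_f = 3.0`
(free water). The volume fractions — **V-intra** (`v_i`), **V-extra**
(`v_e`) and **V-CSF** (`v_f`) — are estimated per voxel by a
simulated-regression posterior-mean estimator: draw parameters from a prior,
render noisy multi-shell signals, and regress the fractions on per-shell
powder means normalized by the b = 0 signal (degree-3 polynomial least
squares, outputs renormalized onto the simplex). An exhaustive grid-search
oracle at fixed canonical diffusivities provides an independent check of the
estimator.

Around the voxel level the package provides:

- **Phantoms** — spherical enhancing core + perilesional rim + NAWM at 32³,
  rendered in *GBM* or *metastasis* mode (the metastasis rim carries more
  free water), with Rician noise and ground-truth maps;
- **ROI metrics** — NAWM built by exclusion (white matter minus T2 ROI minus
  core), ROI means normalized by NAWM means, ROI volume in ml;
- **Cohort simulation** — per-patient records with log-normal marginals
  matched to published medians/IQRs (19 GBM / 17 metastases) and a Gaussian
  copula with analytically compensated correlations;
- **Group statistics** — one-way ANCOVA controlling for lesion volume with
  Bonferroni correction, Pearson correlations, Mann–Whitney U (exact
  enumeration for small samples), and ROC analysis with the Youden
  ("equally weighted" sensitivity/specificity) optimal cutpoint.

## Worked example

```r
library(dmisim)

cohort <- simulate_cohort(default_cohort_config(seed = 42))
analyze_cohort(cohort)
#>         metric     F   p_raw p_bonferroni   auc cutpoint direction  sens  spec
#> 1 v_intra_norm  6.50 0.01564      0.04693 0.737    0.252        >= 0.632 0.941
#> 2 v_extra_norm  4.86 0.03458      0.10374 0.721    0.914        >= 0.579 0.882
#> 3   v_csf_norm 10.25 0.00302      0.00905 0.820    3.990        <= 0.737 0.882
```

One simulated cohort at the published group sizes: the covariate-adjusted
group effect is strongest for normalized V-CSF (F = 10.25, Bonferroni
p = 0.009), and V-CSF discriminates GBM from metastasis best (AUC 0.82);
the direction `<=` says *low* perilesional free water predicts GBM, with the
optimal cutpoint at a normalized V-CSF of about 4.0 (sensitivity 0.74,
specificity 0.88). V-extra is the weakest discriminator — the ordering the
method is expected to show.

```r
roc <- roc_analysis(cohort$v_csf_norm, cohort$group, positive_class = "GBM")
roc
#> <dmi_roc> AUC = 0.820; cutpoint 3.99 (<= predicts GBM); sens 0.737, spec 0.882
autoplot(roc)            # ROC curve with the Youden point marked
plot_cohort_metrics(cohort)  # group boxplots of the three normalized metrics
```

The imaging path end to end (phantom → estimator → ROI metrics):

```r
full_run(seed = 42)$phantoms[, c("group", "v_csf_norm", "truth_v_csf_norm")]
#>        group v_csf_norm truth_v_csf_norm
#> 1        GBM       2.11             3.49
#> 2 metastasis       3.28             5.50
```

The fitted normalized V-CSF is higher in the metastasis-mode phantom than in
the GBM-mode phantom, matching the ground-truth direction; the compression
relative to truth is posterior-mean shrinkage, discussed in the methods
vignette (`vignettes/dmisim-methods.Rmd`).

A thin command-line front end (`inst/cli/dmisim`) exposes the same steps as
`simulate-phantom`, `fit`, `roi-metrics`, `simulate-cohort`, `analyze` and
`full-run` subcommands, reading FSL-style bval/bvec gradient tables and
NIfTI-1 volumes and writing seeded JSON sidecars next to every output.

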