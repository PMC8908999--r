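---
title: "Methods: three-compartment diffusion microstructure simulation and perilesional group analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: three-compartment diffusion microstructure simulation and perilesional group analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmisim)
```

## Scope

`dmisim` implements, on synthetic data, the analysis chain used to compare
the microstructure of perilesional T2/FLAIR-hyperintense white matter
between glioblastoma (GBM) and brain metastasis: a three-compartment
diffusion signal model, voxelwise estimation of the compartment volume
fractions, reduction to per-patient ROI metrics normalized to
normal-appearing white matter (NAWM), and the group-level statistics
(covariate-adjusted ANCOVA, Pearson correlations, Mann–Whitney comparisons,
ROC analysis with an equally weighted sensitivity/specificity cutpoint).
Because no patient imaging is distributed, the package ships two synthetic
generators — a volumetric phantom and a patient-level cohort simulator — and
every statistical claim in its test suite is made against those generators.

## The signal model

Each white-matter voxel is modelled as three non-exchanging water pools
("stick–zeppelin–ball"):

* **intra-axonal** (fraction $v_i$): one-dimensional diffusion along the
  axon axis $u$, attenuation $\exp(-b D_i (g\cdot u)^2)$;
* **extra-axonal cellular** (fraction $v_e$): axially symmetric Gaussian
  diffusion, $\exp\!\big(-b\,[D_{e\perp} + (D_{e\parallel}-D_{e\perp})(g\cdot u)^2]\big)$;
* **free water / CSF** (fraction $v_f$): isotropic, $\exp(-b D_f)$.

with $v_i + v_e + v_f = 1$ and the measured signal
$S(b, g) = s_0 (v_i A_i + v_e A_e + v_f A_f)$. b-values are in ms/µm²
(1 ms/µm² = 1000 s/mm²), diffusivities in µm²/ms. $D_f$ is fixed at 3.0
µm²/ms, free water at body temperature. Orientation averages over the unit
sphere (spherical means, "powder averages") have closed forms used
throughout: the stick average is
$\sqrt{\pi/(4 b D_i)}\,\mathrm{erf}(\sqrt{b D_i})$, the zeppelin average is
the stick form in $D_{e\parallel}-D_{e\perp}$ scaled by
$\exp(-b D_{e\perp})$, with a series limit below
$b\,\Delta D < 10^{-6}$ to keep the expression continuous as the tensor
becomes isotropic. Magnitude-MR noise is Rician:
$\sqrt{(S+\varepsilon_1)^2+\varepsilon_2^2}$ with independent Gaussian
$\varepsilon_k$ of scale $\sigma = s_0/\mathrm{SNR}$, SNR quoted at $b=0$.

The default acquisition (`default_scheme()`) is one $b=0$ volume plus
shells at $b = 1$ and $2$ ms/µm² with 30 directions each. The direction set
is produced by electrostatic repulsion with antipodal symmetry from a
Fibonacci-spiral start; the optimization is run long enough (2000 steps)
that 30-point powder averages track the closed-form spherical means to
about $2\times10^{-3}$, which matters because the estimator and its oracle
compare finite powder averages against closed forms. Two shells are the
minimum that identifies three compartments; the scheme is a configurable
stand-in for a clinical multi-shell protocol, not a copy of one.

## Fraction estimation

The estimator follows the simulated-regression reading of Bayesian
posterior-mean estimation: draw microstructure parameters from a prior,
render noisy signals under the acquisition scheme, and regress the known
fractions on rotation-invariant signal features. The features are the
per-shell powder means divided by the mean $b=0$ signal — invariant to
fibre orientation (and to orientation dispersion, which is why dispersion
is not simulated), so the regression target is a smooth two-feature map.
A degree-3 polynomial basis with interactions is fitted by least squares,
one regression per fraction; predictions are clipped to $[0,1]$ and
renormalized, so outputs always lie on the simplex. Defaults: fractions
uniform on the simplex; $D_i \sim U(1.0, 2.5)$,
$D_{e\parallel} \sim U(0.5, 2.5)$,
$D_{e\perp}/D_{e\parallel} \sim U(0.1, 1.0)$ µm²/ms; training SNR
$U(20, 50)$; 4000 training draws. Training takes on the order of a second
and is deterministic given the prior seed.

Two numerical points deserve emphasis.

**The verification oracle.** `grid_oracle_fit()` is an independent check:
exhaustive search over the fraction simplex against the closed-form
per-shell features at fixed canonical diffusivities
($D_i = 2.0$, $D_{e\parallel} = 1.5$, $D_{e\perp} = 0.5$, $D_f = 3.0$).
The two-feature map is mildly ill-conditioned (stick and zeppelin averages
are similar), so a single 0.02-step grid can return a point two steps from
the continuous optimum; the implementation therefore refines the coarse
optimum with a second exhaustive pass at step 0.002 in a ±0.04 window.
Both passes are deterministic, with ties broken toward the
lexicographically first grid point.

**What "agreement with the oracle" can mean.** The regression estimator
approximates the posterior mean *under its training prior*. When that
prior spans a wide diffusivity range, the posterior mean is shrunk by
diffusivity marginalization and is a different estimand from the oracle's
fixed-diffusivity least-squares fit — the two can disagree by more than 0.1
on extreme fractions even with noise-free data and a perfect regression.
Equivalence checks between the estimator and the oracle are therefore run
with the prior concentrated at the canonical diffusivities, so both routes
estimate the same quantity; the wide prior remains the default for
realistic use, where tissue diffusivities are genuinely unknown. The same
logic applies when validating recovery on phantoms, which are rendered at
the canonical diffusivities.

## The phantom

`phantom_config()` describes a synthetic patient on a 32³ grid of 2 mm
isotropic voxels: a spherical enhancing core (default radius 8 mm), a
surrounding perilesional T2 rim (default thickness 8 mm), the remaining
brain sphere as NAWM, and background. Zone fraction means are
NAWM $(0.45, 0.45, 0.10)$, GBM rim $(0.25, 0.40, 0.35)$ and metastasis rim
$(0.15, 0.30, 0.55)$, jittered per voxel by a Dirichlet distribution with
concentration 100 around the zone mean. These absolute fractions are
declared synthetic: published results report only NAWM-normalized ratios,
so the zone means are chosen to make the normalized contrasts point in the
reported directions — more free water in the metastasis rim (vasogenic
edema), less extreme elevation in the GBM rim (edema plus cellular tumour
infiltration) — not to reproduce any measured absolute value. Diffusivities
are fixed at the canonical values; each voxel gets a random orientation.
The enhancing core is rendered with rim microstructure and excluded by mask
downstream, mirroring how segmentation keeps enhancing tumour out of the
perilesional ROI. Default SNR is 30 at $b=0$.

The phantom deliberately omits realistic anatomy, partial-volume mixing
across zone boundaries, fibre crossings, dispersion, compartmental
T2 differences and acquisition artifacts. Passing phantom tests therefore
demonstrates internal consistency of model, estimator and ROI reduction —
not performance on clinical data.

## ROI metrics

NAWM is built by exclusion: white matter minus the T2-hyperintense ROI and
the enhancing core. Per patient and per metric the pipeline reports the ROI
mean, the NAWM mean, their ratio (the normalized metric) and the ROI volume
in ml (voxel count × voxel volume / 1000). The ROI reduction is the
arithmetic mean (the common ROI convention; the choice is isolated in
`roi_mean()`), and normalization is a plain ratio — consistent with
published normalized values above 1 for free water and below 1 for the
cellular fractions in edema. Ratios are exactly invariant to any global
multiplicative scaling of the maps.

## The cohort simulator

`simulate_cohort()` generates per-patient records directly at the
statistical level, so the group analysis can be exercised at scale without
imaging. Marginals are log-normal for the normalized metrics and the T2
lesion volume — positive, right-skewed quantities summarized by medians and
IQRs — and normal for age. A log-normal is fixed by its (median, IQR) in
closed form: $\mu = \log m$ and
$\sigma = \mathrm{asinh}\!\big(\mathrm{IQR}/(2m)\big)/z_{0.75}$.
Defaults encode the published group summaries: sizes 19/17; V-intra
medians (IQRs) 0.25 (0.13) vs 0.20 (0.03); V-extra 0.88 (0.30) vs
0.81 (0.18); V-CSF 3.17 (1.26) vs 4.52 (0.86); T2 volume 20.7 (22.1) vs
19.5 (35.1) ml; ages Normal(66.4, 14.1²) and Normal(63.5, 11.8²); steroid
counts 7/19 and 6/17; sex counts 10/9 and 9/8 (no sex effect modelled).

Dependence is a Gaussian copula per group with two structural pairs:
V-CSF with T2 volume (targets 0.33 GBM, 0.51 metastasis) and age with
V-CSF (−0.67, −0.62). Imposing a Pearson target directly on the latent
scale would understate the observed correlation after the log-normal
transform (for the metastasis volume marginal, whose $\sigma \approx 1.2$,
the attenuation is large: a latent 0.51 yields roughly 0.36 observed), so
the latent correlations are compensated analytically — closed-form moment
inversion for log-normal/log-normal and normal/log-normal pairs — and the
compensated matrix is checked for positive definiteness at configuration
time. Large-sample checks in the test suite confirm the observed-scale
correlations land on the targets.

Two honest caveats, verified quantitatively in the test suite rather than
assumed: (i) sample IQRs of the heavy-tailed volume marginals have a
relative sampling error around 1–1.5% even at $n = 20\,000$ per group, so
single-draw checks at a 2% band can fail by luck for a generator whose
population quantiles are exact; (ii) at the published sample sizes the
V-extra group contrast is small relative to its configured spread
(log-scale separation under one sampling SD of the group medians), so its
direction reproduces in most but not nearly all simulated cohorts — unlike
the free-water contrast, which is essentially always visible.

## Group statistics

* **ANCOVA**: linear model `metric ~ covariate + group` with a partial
  F-test of the group term (equivalent to Type III here); for two groups
  df $= (1, n-3)$. Published F statistics quote a denominator df of 1,
  which is not reproducible for 36 subjects with one covariate and is
  treated as a typographical artifact. Bonferroni correction defaults to
  $m = 3$, the three metrics.
* **Pearson correlation** with the two-sided $t$-transform p-value.
* **Mann–Whitney U**: exact enumeration of all group assignments over
  midranks for combined $n \le 12$ (ties handled by the same midrank
  convention); otherwise the normal approximation with tie-corrected
  variance and no continuity correction.
* **ROC**: candidate cutpoints are midpoints between consecutive distinct
  scores plus infinite sentinels; the direction (≥ or ≤ predicts positive)
  is chosen as the one whose best sensitivity + specificity is higher; AUC
  by the trapezoidal rule (identical to the pair-counting statistic
  $U/(n_1 n_2)$); the reported cutpoint maximizes sensitivity +
  specificity (the Youden reading of "equally weighted"), with exact ties
  broken toward the smallest candidate for reproducibility. Confusion
  metrics (sens/spec/PPV/NPV) are reported at that cutpoint. GBM is the
  positive class in the cohort wrapper, matching a cutpoint that calls GBM
  at *low* normalized V-CSF.

## Reproducibility and problem sizes

All randomness is seeded; one top-level seed is split into per-module
substreams deterministically, and every file output carries a JSON sidecar
with the seed, a config hash and the package version. The test suite and
the acceptance script run at desk scale by design: 32³ phantoms (seconds
to render and fit), 4000-draw training sets, 200–500 voxel recovery
panels, 200 simulated cohorts for direction/power summaries, 500 null
cohorts for the type-I-error check, and 20 000 patients per group for
generator-fidelity checks. These sizes were chosen so each check isolates
one property with comfortable Monte-Carlo margin while the whole suite
stays fast.

## Limitations

The package validates an analysis pipeline against its own declared
generative models. It does not establish clinical performance: the phantom
is geometrically idealized, the cohort simulator reproduces only printed
summary statistics (medians, IQRs, two correlation structures, group
sizes) under a declared log-normal/Gaussian-copula assumption, and the
acquisition scheme is a placeholder for a clinical protocol. Estimated
fractions are posterior means and inherit shrinkage toward the prior mean,
visible as compression of normalized ROI ratios relative to ground truth;
group *directions* and discrimination orderings are preserved, which is
what the group-level claims rest on.
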