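---
title: "Multi-component T2 relaxometry: model, estimation and group inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-component T2 relaxometry: model, estimation and group inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mct2)
```

## The signal model

A multi-echo spin-echo (GRASE) acquisition samples the transverse decay of
brain water at echo times $TE_n = n\,\Delta TE$ (here 32 echoes,
$\Delta TE = 10.24$ ms). Water in a voxel is not a single pool: myelin
water relaxes fast (T2 below about 40 ms), intra- and extracellular water
dominates the 40–200 ms range, and free fluid (CSF, enlarged perivascular
space) relaxes slowly. The measured train is modeled as a non-negative
mixture over a fixed logarithmic grid of $N = 60$ T2 values spanning
10–2000 ms:

$$ y_n \;=\; \sum_{j=1}^{N} A_{nj}(\alpha)\, x_j + \varepsilon_n, \qquad x_j \ge 0, $$

where column $j$ of the dictionary $A(\alpha)$ is the echo train predicted
for T2 $= t_j$ at refocusing flip angle $\alpha$.

Real refocusing pulses are not 180°: B1 inhomogeneity reduces the local
angle and creates stimulated-echo pathways that inflate later echoes. The
dictionary therefore comes from the extended phase graph (EPG) formalism
(`epg_decay()`): configuration states $F^+(k), F^-(k), Z(k)$ evolve by
relaxation over each $\Delta TE/2$, an integer dephasing shift per crusher
(perfect spoiling), and RF mixing at each pulse. States are truncated at
order `n_echoes + 1`, which is lossless within the train: a higher order
cannot rephase before the last echo. Longitudinal regrowth during the
train is neglected — the train (328 ms) is short relative to T1, and this
is the convention of echo-train fitting; T1 enters only through the decay
of magnetization stored longitudinally between pulses. At $\alpha = 180°$ the recursion
collapses to $\exp(-TE_n/\mathrm{T2})$ exactly, which the tests verify to
$10^{-10}$; at lower angles it is checked to $10^{-3}$ against an
independent isochromat ensemble (100 000 uniformly dephased spins with
explicit rotation and relaxation per half interval).

Assumptions worth stating: T1 is not measured alongside the GRASE scan, so
a fixed `t1 = 1000` ms is assumed (configurable); the echo train is short
relative to T1, so the sensitivity of the fit to this choice is weak. The
excitation is treated as an ideal 90° pulse — B1 error enters only through
the refocusing angle, which is the quantity being estimated. Recovery over
the 2000 ms repetition time is taken as complete; TR is recorded for
provenance only. Slice-profile, diffusion and non-CPMG phase effects are
out of scope.

## Per-voxel estimation

Estimation proceeds in two stages (`fit_volume()`):

1. **Flip angle.** For each voxel the echo train is fitted by plain NNLS
   against the dictionary of every candidate angle (2° steps over
   90–180°; the grid resolution is a design choice balancing dictionary
   count against angle precision) and the angle minimizing the mean
   squared residual is kept, ties going to the larger angle. For this
   purpose only, the data are first smoothed with a 4.8 mm FWHM Gaussian
   — the flip-angle field is spatially smooth, so borrowing neighbours
   suppresses noise without biasing the spectral fit, which always uses
   the raw signal.

2. **Spectrum.** With the selected dictionary, the T2 spectrum solves the
   identity-Tikhonov regularized NNLS problem
   $\min_{x \ge 0} \lVert Ax - y\rVert^2 + \lambda^2 \lVert x \rVert^2$
   via the augmented system $[A; \lambda I]$. The weight is set by the
   chi-squared residual criterion with $k = 1.02$: among 50 log-spaced
   candidates spanning $10^{-6}$ to $10$ times $\lVert A\rVert_F$,
   $\lambda^\*$ is the largest with data misfit
   $\chi^2(\lambda) \le k\,\chi^2(0)$, then refined by bisection between
   the bracketing candidates until $\chi^2(\lambda^\*)/\chi^2(0)$ matches
   $k$ to 0.1% relative. The bisection makes the candidate range
   non-critical. A numerically perfect unregularized fit returns
   $\lambda^\* = 0$ directly. Magnitude data are fitted as-is; no Rician
   bias correction is applied.

Voxels are processed independently (no spatial regularization); results do
not depend on visiting order. When no mask is given, voxels whose
first-echo signal is below 5% of the volume's 99th-percentile signal are
skipped.

## From spectra to biomarkers

`compute_metrics()` / `metric_maps()` integrate the spectrum over three
windows: myelin water (T2 < 40 ms, strict), intra-extracellular water
(40–200 ms, both boundaries inclusive — the boundary rule is fixed for
reproducibility even though log-spaced grid points rarely land on it) and
free/quasi-free water (above 200 ms up to the 2000 ms grid maximum, beyond
which no mass can exist by construction). This yields

- **TWC** — total area under the distribution, normalized so that its mean
  over a CSF mask is 1 (`normalize_twc()`); CSF acts as an internal
  reference of stable composition.
- **MWF**, **IEWF**, **FQFWF** — window masses over TWC; they sum to 1.
- **T2IE** — the amplitude-weighted geometric mean T2 within 40–200 ms,
  undefined when that window is empty.

Undefined voxels carry `NA`, which smoothing (`smooth_metric_maps()`, 2 mm
FWHM by default, applied after normalization and before statistics)
propagates by renormalizing kernel weights over defined neighbours.
ROI summaries (`roi_means()`) average defined voxels only and flag missing
regions explicitly. ROI means are taken on the smoothed maps by default,
matching the voxelwise pipeline; pass the unsmoothed maps to disable.
For phantoms the CSF mask comes from the ground-truth labels; for real
data `csf_mask_from_maps()` offers a heuristic (free-water fraction above
0.9 and above-median TWC), since CSF delineation is not part of the
relaxometry output.

## The synthetic phantom

`generate_phantom()` builds a 24×24×8 block phantom (1.7×1.7×4 mm voxels)
with a background rim, a grey-matter shell, a white-matter interior and a
central CSF block — large enough for the smoothing kernels, small enough
to fit in minutes on one CPU. Each tissue is a three-pool delta mixture;
the defaults (WM: T2 20/80/2000 ms at fractions 0.15/0.83/0.02, density
0.70; GM: 20/95/2000 ms at 0.03/0.94/0.03, density 0.82; CSF: 2000 ms,
density 1) are conventional values for validation, not measurements, and
are configurable and recorded in the returned truth object. The
refocusing-angle field is a smooth quadratic ramp 120°→180° across x,
exercising the flip-estimation path over a realistic B1 range. Noise is
stationary single-coil Rician: $\sqrt{(s+g_1)^2 + g_2^2}$ with
$\sigma$ = (mean WM first-echo signal)/SNR.

What the phantom does **not** emulate: spatially correlated (multi-coil)
noise, partial-volume mixing at tissue borders, continuous (non-delta) T2
distributions, Gibbs ringing, motion, and the denoising step applied to
real acquisitions. Passing recovery tests on the phantom therefore
demonstrates correctness of the estimator, not its clinical accuracy on
raw scanner data. In particular, per-voxel myelin-water estimates at
SNR 100 carry an intrinsic standard deviation near 0.04 with the
chi-squared criterion at $k = 1.02$ (about half the unregularized
scatter), plus a small downward bias from the regularizer smearing the
20 ms pool across the 40 ms cutoff and from the uncorrected Rician floor —
real pipelines recover precision by denoising before fitting, which is
outside this package's scope.

```{r phantom, eval = FALSE}
ph <- generate_phantom(snr = 100, seed = 7)
fit <- fit_volume(ph$volume, mask = ph$truth$labels > 0)
maps <- metric_maps(fit)
maps$twc <- normalize_twc(maps$twc, ph$truth$labels == 3)
maps <- smooth_metric_maps(maps)   # 2 mm FWHM
```

## The synthetic cohort and group inference

`generate_cohort()` draws a three-group cohort with the 53/70/16
(CU/SCD−/SCD+) structure: per-group age and depressive-symptom (GDS)
distributions typical of a 50+ primary-care sample, log TIV-normalized
white-matter-hyperintensity load with a mild age slope, and hippocampal
Z-scores satisfying each group's defining constraint by construction.
Regional biomarker means are
`baseline + covariate slopes + group shift (in SD units) + noise`; all
group shifts default to zero, so the default cohort is a null generator
on which test calibration can be checked. Hippocampal per-side values can
additionally be coupled to the Z-score (`z_slope`) to create purely
volume-driven group differences, used to verify that adding the Z
covariate absorbs such effects.

`classify_scd()` implements the diagnostic rule: complaints plus left
and/or right hippocampal Z strictly below −1 gives SCD+; complaints with
both at or above −1 gives SCD−; no complaints with both in the normal
range gives CU (otherwise the record is flagged `excluded`).
`wmh_load()` binarizes a lesion-probability map at 0.5 (0.5 itself counts
as lesion — the boundary is unspecified in common descriptions, so the
inclusive choice is fixed and documented), normalizes the lesion volume by
TIV and log transforms, guarding zero-lesion subjects with one voxel
volume.

Group models: `ancova_f()` tests the group factor over nuisance
covariates by nested linear models; inference is by Freedman–Lane
permutation (reduced-model residuals are permuted and the full statistic
recomputed), the scheme standard permutation tools use when covariates are
present. `pairwise_t()` provides covariate-adjusted two-group follow-ups.
`signature_models()` runs one test per metric and applies Bonferroni over
the metric family (5 for the cortical signature), reporting the family
size and listwise exclusions. `tfce()` implements threshold-free cluster
enhancement ($H = 2$, $E = 0.5$, 26-connectivity, step `max/100` — the
conventional volumetric settings) with exact per-threshold
connected-component labeling in compiled code; negative lobes are
enhanced on the negated map. `tfce_permutation_test()` combines the F-map,
TFCE and max-statistic family-wise correction
$p(v) = (1 + \#\{\max^* \ge \mathrm{TFCE}(v)\})/(n_{perm}+1)$. The
study-scale permutation count is 10 000; the package default of 999 keeps
desk-scale calibration runs fast, and all counts are parameters.

`minimum_detectable_effect()` gives the two-sided two-sample
normal-approximation bound
$d = (z_{1-\alpha/2} + z_{power})\sqrt{1/n_1 + 1/n_2}$; at the cohort's
53 vs 70 split with $\alpha = 0.05$ and 80% power it evaluates to 0.51 SD.
For 53 vs 16 the same formula gives 0.80 SD (0.75 would correspond to 75%
power); both $\alpha$ and power are exposed rather than hard-coded.

## Numerical choices and problem sizes

- NNLS is Lawson–Hanson active-set in compiled code; tolerance
  $10\,\epsilon\,\lVert A\rVert_F \max(m,n)$. Tests check the KKT
  conditions and agreement with exhaustive support enumeration.
- The chi-squared bisection targets 0.1% relative accuracy on the residual
  ratio within 60 iterations; $\chi^2(0) \le 10^{-12}\lVert y\rVert^2$ is
  treated as a perfect fit.
- Gaussian smoothing is separable band-matrix convolution with
  $\sigma = \mathrm{FWHM}/(2\sqrt{2\ln 2})$ per axis in voxel units;
  kernels are truncated at $4\sigma$ and renormalized at edges and around
  `NA`s.
- Degenerate inputs are explicit: all-zero signals fit to all-zero spectra;
  all-zero spectra yield `NA` metrics; empty CSF masks, empty flip grids
  and singular designs raise errors rather than returning silent values.
- Test and validation problem sizes are chosen for minutes-scale runs on a
  single CPU: the 24×24×8 phantom (~3200 brain voxels), 500 null datasets
  × 999 permutations for ANCOVA calibration, 200 datasets × 199
  permutations for family-wise error calibration on 6×6×2 maps. These
  sizes give binomial confidence intervals comfortably inside the
  calibration bands being checked.

## Known limitations

- Delta-pool phantoms are harder for an identity-Tikhonov regularizer than
  the broad distributions of real tissue; per-voxel MWF scatter at SNR 100
  is accordingly large (see above). TWC, IEWF and the flip-angle map are
  recovered much more tightly (TWC to well under 2%).
- No spatial regularization or denoising: each voxel is fitted alone.
- The registration, denoising, lesion-segmentation and normative-modeling
  steps that surround this pipeline in a full study are consumed as inputs
  (masks, Z-scores, lesion maps), not reimplemented.
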