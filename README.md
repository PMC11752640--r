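# mct2 — multi-component T2 relaxometry and myelin water mapping

Quantitative MRI groups interested in tissue microstructure — myelin loss,
neurodegeneration, neuroinflammation, free-water accumulation — estimate a
*spectrum* of T2 relaxation times in every voxel of a multi-echo spin-echo
(GRASE) scan, rather than a single decay constant. `mct2` implements that
pipeline end to end in R, together with the group-level statistics used in
ageing-cohort studies, and a synthetic phantom/cohort generator with known
ground truth for validation.

## The model

The echo train of a voxel, sampled at $TE_n = n\,\Delta TE$ (32 echoes,
$\Delta TE = 10.24$ ms), is a non-negative mixture over $N = 60$
log-spaced T2 values in 10–2000 ms:

$$y_n = \sum_j A_{nj}(\alpha)\,x_j + \varepsilon_n,\qquad x_j \ge 0,$$

with dictionary columns predicted by the extended phase graph (EPG)
formalism at the local refocusing flip angle $\alpha$ (stimulated echoes
from imperfect pulses included). Per voxel, $\alpha$ is estimated by
dictionary search on 4.8 mm-smoothed data, then the spectrum solves the
identity-Tikhonov regularized NNLS problem

$$\min_{x\ge 0}\ \lVert A x - y\rVert^2 + \lambda^2\lVert x\rVert^2,$$

with $\lambda$ chosen so the data misfit is $k = 1.02$ times the
unregularized minimum (the chi-squared residual criterion, refined by
bisection). Spectra are integrated into five biomarkers: myelin water
fraction (MWF, T2 < 40 ms), intra-/extracellular water fraction (IEWF,
40–200 ms) and its geometric-mean T2 (T2IE), free/quasi-free water
fraction (FQFWF, > 200 ms), and CSF-normalized total water content (TWC).
Group inference covers hippocampal Z-score classification (CU / SCD− /
SCD+), ANCOVA with Freedman–Lane permutations, TFCE with max-statistic
family-wise correction, Bonferroni-corrected per-metric models, and
minimum-detectable-effect computations.

## Worked example

Fit a noisy three-pool white-matter voxel at a 150° refocusing angle and
read off the biomarkers:

```r
library(mct2)
scheme <- acquisition_scheme()            # 32 echoes, dTE 10.24 ms
grid   <- make_t2_grid()                  # 60 log-spaced T2, 10-2000 ms
dict   <- build_dictionary(grid, flip_deg = 150)

wm <- default_tissues()$WM                # T2 20/80/2000 ms, 0.15/0.83/0.02
y0 <- 0.7 * rowSums(sapply(seq_along(wm$t2s), function(c)
        wm$fractions[c] * epg_decay(wm$t2s[c], 1000, 150, scheme)))
y  <- add_rician_noise(y0, sigma = 0.002, seed = 1)   # ~SNR 250

f <- fit_spectrum_regularized(dict, y0)   # noise-free: near-exact recovery
round(unlist(compute_metrics(f$spectrum, grid)), 4)
# twc_raw     mwf    iewf   fqfwf    t2ie
#  0.7000  0.1498  0.8304  0.0199 79.9868

fn <- fit_spectrum_regularized(dict, y)   # noisy: regularized path
round(fn$chi2_reg / fn$chi2_min, 4)       # 1.0197  (the k = 1.02 target)
round(unlist(compute_metrics(fn$spectrum, grid)), 4)
# twc_raw     mwf    iewf   fqfwf    t2ie
#  0.7005  0.1062  0.8789  0.0149 77.2033
```

Noise-free, the three-pool truth (fractions 0.15/0.83/0.02, water density
0.70, intra-extracellular T2 80 ms) is recovered almost exactly; the noisy
fit shows the per-voxel scatter that single-voxel myelin estimates carry
at finite SNR (see the vignette's limitations section). Volume-level
processing follows the same path per voxel:

```r
ph   <- generate_phantom(snr = 100, seed = 7)     # 24 x 24 x 8 phantom
fit  <- fit_volume(ph$volume, mask = ph$truth$labels > 0)
maps <- metric_maps(fit)
maps$twc <- normalize_twc(maps$twc, ph$truth$labels == 3)
maps <- smooth_metric_maps(maps)                  # 2 mm FWHM
round(mean(maps$twc[ph$truth$labels == 1]), 3)    # 0.708 (truth 0.70)
```

And the cohort design:

```r
coh <- generate_cohort(cohort_spec(), seed = 7)
table(classify_scd(coh))
#   CU SCD- SCD+ excluded
#   53   70   16        0
round(minimum_detectable_effect(53, 70, 0.05, 0.80), 2)   # 0.51
signature_models(coh, n_perm = 999)       # per-metric F, Bonferroni over 5
```

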