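# melapress

Quantification for cell-culture compression experiments — the kind of
assay where a weighted insert applies intermittent compressive stress
(e.g. 2 h on / 2 h off) to melanoma cells cultured under a collagen gel,
and every readout is an image or a qPCR table. The package is aimed at
lab scientists and image-analysis engineers who need the complete
measurement chain to be scripted, tested and reproducible rather than
assembled from interactive ImageJ/MATLAB steps.

It implements four analysis stages plus seeded synthetic-data generators
with known ground truth for validating all of them:

- **Gel creep by DIC** — subset matching by zero-normalized
  cross-correlation with subpixel peak refinement, Green–Lagrange strain
  fields on a node lattice, and a representative strain
  γ = √(med(Sxx)² + med(Syy)²) per frame.
- **Kelvin–Voigt creep fitting** — the three-element model
  γ(t) = σ₀/E₁ + (σ₀/E₂)(1 − e^(−t/τ)), τ = η/E₂, fitted by
  Levenberg–Marquardt in log-parameters; delay time τ and a Pearson fit
  index per sample, with median summaries over replicate gels.
- **Cell image metrics** — colony progression distance
  l_t = √(a_t/π) − √(a₀/π) and its OLS rate; live/dead counting
  (LoG blob detection; Otsu/mean thresholding + distance-transform
  watershed); dead-cell rate and proliferation rate
  CPR = (N_L+N_D)/(N_L+N_D)_control; total F-actin length by
  bandpass → Otsu → skeletonization, and LFC = L_f/N_n.
- **Expression statistics** — 2^−ΔΔCt relative quantification and
  Dunnett many-to-one tests with a seeded Monte-Carlo multivariate-t
  adjustment.

## Worked example

Generate one synthetic creep test (a microsphere-seeded gel imaged once a
minute for 30 min while it creeps with a true delay time of 7.74 min),
measure the creep curve from the raw frames by DIC, and fit the model:

```r
library(melapress)

kv  <- kv_params(sigma0 = 770, E1 = 2.2e4, E2 = 1.55e4, eta = 1.55e4 * 7.74)
gel <- gen_creep_sequence(kv, duration = 30, dt = 1,
         spec = speckle_spec(image_shape = c(160L, 160L), n_spots = 90L,
                             noise_sd = 0.01, seed = 2024))
res <- creep_analysis(gel, sigma0 = 770)
res$fit
#> Three-element Kelvin-Voigt creep fit
#>   sigma0 (fixed): 770 Pa
#>   E1 = 1.696e+17 Pa, E2 = 1.593e+04 Pa, eta = 1.245e+05 Pa.min
#>   delay time tau = 7.818 min
#>   fit index (Pearson r) = 0.9999; converged: TRUE (11 iterations)
```

The recovered delay time (7.82 min) is within about 1% of the 7.74 min
ground truth. The huge fitted E1 is expected, not a defect: a DIC creep
curve is anchored at zero because the first frame is taken under load, so
the instantaneous elastic term is unobservable and E1 degenerates to a
nuisance offset — τ, E2/η and the fit index are the meaningful outputs
(see the methods vignette).

Expression statistics on a synthetic Ct table with true fold changes
0.5 (T4) and 2 (T8) versus control:

```r
ct <- gen_ct_table(ct_spec(c(control = 1, T4 = 0.5, T8 = 2),
                           ct_noise_sd = 0.15, seed = 7))
fc <- fold_change(ct, "Mmp14", "Gapdh", "control")
fc$summary
#>     group mean_fold sd_fold
#> 1 control     1.006  0.1261
#> 2      T4     0.493  0.0264
#> 3      T8     2.019  0.2107

folds <- split(fc$per_sample$fold, fc$per_sample$group)
dunnett_test(folds[c("T4", "T8")], folds$control, seed = 7)
#> Dunnett many-to-one test (two-sided, 100000 MC draws, df = 6)
#>   group mean_diff      t df p_unadjusted p_adjusted significance
#> 1    T4   -0.5127 -4.403  6    0.0045531    0.00819            *
#> 2    T8    1.0133  8.702  6    0.0001272    0.00018          ***
#> significance: * p < 0.05, *** p < 0.001 (family-wise adjusted)
```

Both configured effects are detected with family-wise control; the fold
estimates bracket the generating truths.

A complete synthetic study — creep, progression, viability, actin and
expression tables for three groups, written as CSV with a JSON manifest —
runs with one call (or via the CLI wrapper in `inst/cli/melapress.R`):

```r
run_demo(seed = 17, outdir = "demo_out")
```

Re-running with the same seed reproduces every table byte for byte.

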