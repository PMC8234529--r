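---
title: "Methods: strain mapping, creep fitting and image quantification in melapress"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: strain mapping, creep fitting and image quantification in melapress}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

melapress quantifies cell-culture compression experiments in which a
weighted insert compresses cells under a collagen gel layer. Four readouts
are covered: (i) the creep deformation of the gel itself, measured by
digital image correlation (DIC) of microsphere-seeded gel images and fitted
with a three-element Kelvin–Voigt model; (ii) colony expansion from
phase-contrast frames; (iii) viability, proliferation and bulk F-actin
morphology from fluorescence images; (iv) relative mRNA expression from Ct
tables, with Dunnett many-to-one statistics. Because raw microscopy of this
kind is rarely shareable, every stage is paired with a seeded synthetic
generator that produces inputs with known ground truth; the test suite
validates each stage, and the pipeline end to end, against those truths.

## Digital image correlation

Gel deformation is measured by subset matching. A regular lattice of nodes
is laid over the reference frame (`build_grid()`); nodes are kept
`(subset_size - 1)/2 + search_radius` pixels away from every border so the
interrogation window and its whole search range stay inside the frame. At
each node the window (default 31 px, odd so it is centered) is compared
against every integer offset within ±`search_radius` (default 10 px) in the
deformed frame using the zero-normalized cross-correlation (ZNCC):
mean-subtracted and variance-normalized, so uniform gain or offset changes
in illumination cancel. The integer argmax is the match; a window with zero
intensity variance has no texture to match and raises an error rather than
returning an arbitrary offset.

Integer matching alone quantizes displacement to whole pixels, which is far
too coarse for gel strains of a few percent. Each axis is therefore refined
with a three-point peak interpolation through the maximum and its two
neighbors. We fit the parabola to the *logarithm* of the three correlation
values (a Gaussian peak model) whenever all three are positive, and fall
back to a plain quadratic vertex otherwise. The choice matters: on
speckle images the plain quadratic exhibits the well-known pixel-locking
bias that pulls estimates toward integer offsets (about ±0.017 px at
quarter-pixel shifts with our default speckle texture), and that bias is
systematic, so it distorts the low-strain early part of a creep curve; the
log-domain fit roughly halves it. The refinement is clamped to ±0.5 px; a
peak on the search-window boundary is left unrefined; and a lattice peak
with correlation 1 (a perfect match, as for an exact integer shift of a
noiseless image) skips refinement entirely, because no interpolation past a
perfect correlation is meaningful — this is what makes integer rigid
translations come back exactly.

Displacement gradients are taken by central differences between
neighbouring lattice nodes (one-sided at lattice edges) and assembled into
the Green–Lagrange strain

$$S_{xx} = u_x + \tfrac12(u_x^2 + v_x^2),\quad
  S_{yy} = v_y + \tfrac12(u_y^2 + v_y^2),\quad
  S_{xy} = \tfrac12(u_y + v_x + u_x u_y + v_x v_y),$$

whose quadratic terms make the field exactly invariant to rigid rotation —
a property the tests exercise with analytically prescribed rotation fields.
Failed nodes (flat texture, or peak correlation below `min_corr`, default
0.25) are flagged invalid and propagate `NA` through any finite-difference
stencil that touches them; they are never silently zeroed.

The scalar fed to creep fitting, the *representative strain*, is the norm
of the vector of median normal strains,
$\gamma = \sqrt{\mathrm{med}(S_{xx})^2 + \mathrm{med}(S_{yy})^2}$, with
shear excluded. The phrase "squared norm of the median normal strain" in
the field's usage is ambiguous between this Euclidean norm and a literal
sum of squares; we default to the Euclidean reading because the creep model
equates the representative value to a strain, not a strain², and expose the
literal reading behind `convention = "sum_of_squares"` for comparison. The
median (not the mean) makes the scalar robust to the occasional mismatched
node, and the tests check it is unchanged by outlier nodes that do not move
the medians.

Whether the "analyzed area" should be the full frame or a sub-region is an
acquisition choice; `build_grid()` takes an optional ROI and the default is
the whole frame.

## Kelvin–Voigt creep fitting

Under constant stress $\sigma_0$ the three-element generalized
Kelvin–Voigt model (a spring $E_1$ in series with a spring–dashpot pair
$E_2$, $\eta$) creeps as

$$\gamma(t) = \frac{\sigma_0}{E_1}
  + \frac{\sigma_0}{E_2}\left(1 - e^{-t/\tau}\right),
  \qquad \tau = \frac{\eta}{E_2},$$

an instantaneous elastic step followed by a delayed exponential rise to
$\sigma_0/E_1 + \sigma_0/E_2$. The delay time $\tau$ is the quantity of
biological interest here: if it is small compared to the compression
period, the shear transient the gel transmits to the cells is negligible.

`fit_kv()` estimates $E_1, E_2, \eta$ by Levenberg–Marquardt
(`minpack.lm::nls.lm`) on $\log E_1, \log E_2, \log \eta$, which enforces
positivity without constrained optimization. $\sigma_0$ is treated as known
(770 Pa in the default configuration, matching the weighted-insert setup)
and held fixed — only three parameters are free. Initial values come from
the data: $E_1$ from the first positive strain sample, $E_2$ from the total
delayed rise, $\eta$ from a time constant of one third of the record; the
iteration cap is 500 with a gradient tolerance of $10^{-10}$, and
non-convergence is flagged on the result rather than thrown. The fit index
is the Pearson correlation between observed and fitted strain over the same
samples used for fitting (no hold-out), computed from the explicit textbook
formula and cross-checked against `stats::cor` in the tests.

One subtlety is the $t = 0$ anchor. A DIC-derived creep curve is measured
relative to the first frame, so $\gamma(t_0) = 0$ by construction, while
the model has $\gamma(0) = \sigma_0/E_1 > 0$. When the first frame is
acquired under load — the usual creep-test protocol, and what the synthetic
generator emulates — the elastic step has already happened before imaging
starts, the measured curve is exactly the delayed (exponential) part, and
the fitted $E_1$ drifts to a large nuisance value whose only role is to
zero the offset; $\tau$, $E_2$ and the fit index are unaffected. The
log-parameterization handles this benignly: the residual gradient with
respect to $\log E_1$ vanishes as $E_1$ grows and LM stops on its tolerance.
Tests on directly generated (un-anchored) curves confirm all three
parameters are recovered to better than 1% without noise.

Two exact structural properties are used as tests: the model is linear in
$\sigma_0$ (doubling $\sigma_0$ and $\gamma$ together leaves the moduli
unchanged), and rescaling time by $c$ scales $\eta$ and $\tau$ by $c$ with
the moduli unchanged.

## Colony progression, viability, and F-actin morphology

**Progression.** Phase-contrast colony frames are median-filtered
(half-size 2 px; the unspecified "filtering" of typical protocols is taken
as a median filter, the standard choice against salt-and-pepper camera
noise), Otsu-binarized, reduced to the largest connected component, and
hole-filled; the occupied area $a_t$ is that component's pixel count. The
progression distance is the equivalent-circle radius difference
$l_t = \sqrt{a_t/\pi} - \sqrt{a_0/\pi}$ and the progression *rate* is the
OLS slope of $l_t$ against time. A polarity flag (auto / bright / dark)
makes the segmentation invariant to contrast inversion; "auto" takes the
minority intensity class, since a colony occupies less than half the field.

**Viability.** Live cells (calcein-AM-like channel) are counted with
scale-normalized Laplacian-of-Gaussian blob detection at
$\sigma = d/(2\sqrt2)$ for a configured cell diameter $d$, local-maximum
selection within a $d/2$ suppression radius, and a threshold relative to
the strongest response. This replaces the interactive template-based
counter used in common practice (the ImageJ ITCN plugin) with a
functionally equivalent, scriptable detector; it is validated against
generator ground truth, not against the plugin. Dead cells and nuclei are
counted by global thresholding (Otsu, or the image mean for DAPI-like
channels), a distance-transform watershed to split touching nuclei (EBImage,
with an h-maxima-style tolerance, default 2 px, against
over-segmentation), and a minimum-area filter (default 9 px). The
dead-cell-rate formula is reported exactly as conventionally printed,
$\mathrm{DCR} = N_L/(N_L+N_D)$, under the explicit name `dcr_printed` —
that numerator is widely suspected to be a typo for $N_D$ — with the
complementary `dead_fraction` $= N_D/(N_L+N_D)$ alongside; the two always
sum to one and the package asserts it. The proliferation rate is
$\mathrm{CPR} = (N_L+N_D)/(N_L+N_D)_{\mathrm{control}}$.

**F-actin.** Phalloidin-channel frames pass a difference-of-Gaussians
bandpass (defaults $\sigma$ = 1 and 13.3 px, passing structures of roughly
3–40 px, mirroring ImageJ FFT-bandpass conventions), Otsu binarization,
and Zhang–Suen thinning to single-pixel-wide skeletons; the total filament
length $L_f$ is the skeleton pixel count and
$\mathrm{LFC} = L_f/N_n$ is the length per cell. The pixel count is a
*chain-code* length: an 8-connected digital curve uses one pixel per
$\max(|\cos\theta|,|\sin\theta|)^{-1}$ of arc length, so for isotropic
random curves the pixel count averages about 0.90 of the continuous arc
length. The synthetic generator therefore records its ground truth in the
same metric — the pixel count of the rasterized centerline — alongside the
continuous arc length, so recovery tests compare like with like; a
diagonal-aware arc-length estimate is attached to every `actin_length()`
result for users who want the geometric length. This is a bulk, multi-cell
metric by design: in dense sheets single-cell segmentation is not reliable,
and the method does not attempt it, nor does it distinguish filamentous
from globular actin.

All pixel counters normalize intensities affinely to [0, 1] first, so they
are invariant to global gain and offset; the tests assert counts are
unchanged by intensity rescaling.

## Relative expression and Dunnett statistics

Ct tables (columns `group`, `sample`, `gene`, `ct`) are processed with the
2^−ΔΔCt method: technical replicates are averaged on the Ct scale (Ct is
the log-domain quantity; averaging 2^−Ct instead would bias low-Ct wells),
ΔCt = Ct(target) − Ct(reference) per biological replicate, ΔΔCt subtracts
the calibrator group's mean ΔCt, and fold = 2^−ΔΔCt. The calibrator's mean
fold is 1 by construction. A missing reference-gene well fails loudly,
naming the replicate.

Group contrasts use Dunnett's many-to-one test: pooled-variance t
statistics of each treatment against the control, with the family-wise
adjustment taken from the equicorrelated multivariate t distribution
(correlations $\sqrt{\lambda_i\lambda_j}$, $\lambda_i = n_i/(n_i+n_0)$).
The adjusted p-values are computed by seeded Monte-Carlo integration
(default $10^5$ draws: correlated normals via a shared control variate,
divided by a common $\sqrt{\chi^2_\nu/\nu}$), which is deterministic given
the seed and avoids platform-dependent quadrature; with $10^5$ draws the
Monte-Carlo standard error of a p-value near 0.05 is about 0.0007. Tests
cross-check against `multcomp::glht` on fixed data, verify the k = 1 case
collapses to the pooled two-sample t-test, and calibrate the family-wise
error rate under the null (2,000 simulated three-group datasets; the
acceptance band is 0.03–0.07 at α = 0.05). Alternatives are two-sided
throughout, and stars follow the 0.05 (*) and 0.001 (***) conventions. One
caveat found while testing: the "adjusted p nondecreasing in k" heuristic
can be violated at extreme |t| because adding a group also raises the
pooled degrees of freedom; the property holds where the multiplicity
penalty dominates, and the test uses a moderate effect size accordingly.
Efficiency-corrected (Pfaffl) quantification and multi-reference
normalization are out of scope.

## The synthetic generators

Each generator takes an explicit integer seed (never the wall clock) and
returns rendered frames plus its ground truth; identical spec and seed give
bit-identical output, and ground truths survive the TIFF + JSON sidecar
round trip.

*Speckle pairs* mimic phase-contrast microsphere markers: dark
anti-aliased discs on a bright background, Gaussian-blurred so subset
correlation has smooth texture, 8-bit-like dynamic range. The deformed
frame is produced by *inverse* mapping — every target pixel samples the
reference at the analytically inverted prescribed map with Catmull-Rom
bicubic interpolation — which leaves no holes and preserves texture.
Prescribed maps are uniform translations or homogeneous displacement-
gradient tensors about the frame center; scenes whose motion pushes more
than 25% of spots out of frame are rejected as unmatchable.

*Creep sequences* warp the same reference with a horizontal stretch whose
amplitude at frame $k$ is $\sqrt{1+2\gamma(t_k)}-1$, so the exact
Green–Lagrange strain of frame $k$ equals the Kelvin–Voigt strain
$\gamma(t_k)$ — ground truth exact in strain units at any amplitude, not
merely to first order. Frame 0 is generated under load (see the anchoring
discussion above). Default acquisition mirrors a bench creep test: one
frame per minute for 30 minutes.

*Colony series* draw one quasi-circular region per frame with radius
$r_0 + \text{rate}\cdot t$ and a smooth low-harmonic boundary wobble; the
recorded truth is the rasterized pixel area actually drawn. *Live/dead
pairs* place non-overlapping Gaussian blobs and assign
$\mathrm{round}(n \cdot \text{dead fraction})$ of them to the red channel.
*Filament scenes* draw smooth random curves (unit steps, slowly drifting
heading, reflected at borders) stroked at a configured thickness, with
nuclei in a separate channel. *Ct tables* place the truth on the Ct scale:
Ct(target) = Ct(reference) + ΔCt(calibrator) − log₂(fold) + noise, so the
zero-noise ΔΔCt round trip is exact.

What the generators deliberately do **not** emulate: optics (no PSF, no
depth effects), photon noise statistics (Gaussian intensity noise only),
cell morphology beyond soft blobs, filament branching and crossing
*density* typical of real cytoskeletons, chromatic or registration error
between channels, and any gel mechanics beyond the prescribed displacement
law. Passing the recovery tests therefore demonstrates the *estimators*
are correct and well-calibrated on images whose truth is known — not that
segmentation would be this accurate on real micrographs, where contrast,
debris and clumping dominate the error budget.

## Default parameters and problem sizes

| parameter | default | unit | why |
|---|---|---|---|
| subset_size | 31 | px | large enough for stable ZNCC texture on ~3 px spots |
| spacing | 16 | px | ~half-subset overlap; 7–13 nodes/axis on test frames |
| search_radius | 10 | px | covers the few-px displacements of gel creep |
| min_corr | 0.25 | — | below this a peak is noise, node flagged invalid |
| sigma0 | 770 | Pa | applied compressive stress of the insert setup |
| max LM iterations | 500 | — | with gtol 1e-10; non-convergence flagged |
| median filter | 2 | px | colony pre-filter half-size |
| cell_diameter | 12 | px | LoG scale for blob counting |
| watershed h | 2 | px | h-maxima depth against over-segmentation |
| min_area | 9 | px | smallest accepted nucleus component |
| DoG sigmas | 1, 13.3 | px | bandpass ~3–40 px structures |
| Dunnett draws | 1e5 | — | MC s.e. ≈ 7e-4 near p = 0.05 |

Validation runs use deliberately desk-scale sizes, chosen as the package's
own benchmark conditions: creep batches of six 160×160 px sequences with
90 spots, 31 frames over 30 min, intensity noise 0.01, and true delay
times {5.8, 7.0, 7.60, 7.88, 9.0, 10.4} min (median 7.74 min); live/dead
scenes of ~120 cells on 360×360 px; filament scenes of ~10 filaments and
1,500–1,800 px total length; 2,000 simulated datasets for the null
calibration of the Dunnett adjustment. The end-to-end creep benchmark
recovers the median delay time to about 1% under these conditions, an
order of magnitude inside the 5% acceptance band used by
`scripts/acceptance.R`.

## Known limitations

- First-order subset matching only: no affine subset shape functions, so
  accuracy degrades for strains well beyond ~5% per frame pair or large
  rotations; gel creep at a few percent is squarely inside the envelope.
- Skeleton pixel count is a chain-code length (≈0.90 of arc length for
  isotropic curves); use the attached diagonal-aware estimate when the
  geometric length matters.
- The LoG counter assumes rounded, roughly equal-sized cells; it is not a
  dense-sheet segmenter.
- Dunnett p-values carry Monte-Carlo error (~7e-4 at default draws);
  increase `n_draws` for p-values near a decision boundary.
- The fitted E1 from under-load-anchored creep curves is a nuisance
  parameter, not a gel modulus; interpret only tau, E2/eta jointly, and the
  fit index from such curves.
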