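---
title: "Kinetic texture radiomics for DCE-MRI: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic texture radiomics for DCE-MRI: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinetex)
```

## The problem

Dynamic contrast-enhanced (DCE) MRI images a lesion before, during and after
a gadolinium bolus; malignant tissue enhances faster and more heterogeneously
than benign tissue, and within ER-positive breast cancers the *spatial and
temporal pattern* of enhancement carries information about recurrence risk.
`kinetex` computes a fixed 176-feature panel describing one representative
2-D lesion section over T contrast phases, and provides the evaluation
machinery (LDA classification, repeated cross-validation, feature selection,
stability and learning-curve analysis) needed to ask whether those features
separate a low-risk from a high-risk class.

The package operates downstream of lesion segmentation: its inputs are a
`dce_series` (an H x W x T intensity stack with acquisition times in minutes
and pixel spacing in mm) and a `roi_mask` (a binary lesion mask with at
least 16 pixels forming one 8-connected component). Timestamps are
mandatory on load; the readers refuse to assume uniform spacing unless the
caller supplies `dt` explicitly.

## Pharmacokinetics

Tissue contrast concentration follows the standard (one-compartment) Tofts
model

$$C(t) = K^{trans} \int_0^t C_p(\tau)\, e^{-k_{ep}(t-\tau)}\, d\tau, \qquad
  k_{ep} = K^{trans}/v_e,$$

with $K^{trans}$ (1/min) the plasma-to-tissue transfer constant and $v_e$
the extravascular-extracellular volume fraction. The arterial input
$C_p(t) = D\,(a_1 e^{-m_1 t} + a_2 e^{-m_2 t})$ is the classical
biexponential population form with $D = 0.1$ mmol/kg, $a_1 = 3.99$,
$a_2 = 4.78$ kg/L, $m_1 = 0.144$, $m_2 = 0.0111$ 1/min — a population AIF
matching the standard clinical dose; all five numbers are configurable via
`default_aif()`. Because the AIF is exactly biexponential, the convolution
has the closed form $(e^{-m t} - e^{-k_{ep} t})/(k_{ep} - m)$ per
exponential (series limit $t\,e^{-mt}$ as $k_{ep} \to m$, guarded at
$|k_{ep}-m| < 10^{-8}$), so the model is evaluated exactly rather than by
numerical quadrature.

Relative signal enhancement $(S(t)-S(0))/S(0)$ is treated as proportional
to concentration; no T1 mapping or SPGR signal equation is used. Bolus
arrival is fixed at the first post-baseline phase (configurable).
`fit_tofts()` runs bounded Levenberg-Marquardt
($K^{trans} \in [10^{-4}, 5]$, $v_e \in [0.01, 1]$) from four fixed starting
points and returns the best-residual fit; $k_{ep}$ is always the derived
ratio, never independently estimated. Curves with near-zero signal or
non-convergent fits come back flagged (`near.zero.signal`,
`no.convergence`) rather than as silent NaN. The scalar PK features are the
ROI means of per-pixel fits (a whole-ROI fit of the mean curve is available
via `pk_per_pixel = FALSE`); a series in which more than half of the pixel
fits fail is rejected.

**Identifiability.** At the default acquisition (7 phases, 1 min apart) the
washout is only resolved for $k_{ep} \lesssim 2$/min, and estimates are
unbiased only while the peak concentration clears the noise floor
(contrast-to-noise $\ge$ ~10). Outside that regime the likelihood ridge
produces heavy-tailed $K^{trans}$ estimates — a property of the sampling
design, not of the optimiser — which is why the noisy-recovery checks in
the test suite are restricted to the identifiable regime, while noiseless
recovery is exact (< 2% relative error) over the full parameter grid.

## Shape features

From the Moore-traced boundary (the lesion must not touch the image edge),
with radial distances $d_i$ from the pixel-mean centroid and
$\rho_i = d_i / \max d$:

* area overlap ratio $= \mathrm{area} / (\pi \max(d)^2)$;
* variance of distance ratio $= \mathrm{var}(\rho)$;
* compactness $= -P^2/(4\pi\,\mathrm{area})$ — the *negated* isoperimetric
  quotient (disk $\to -1$), so more spiculated margins score lower,
  matching the reported ordering of the risk classes;
* smoothness $= \mathrm{mean}\,|d_i - (d_{i-1}+d_{i+1})/2| / \max d$;
* normalised average radial distance ratio $= \mathrm{mean}(\rho)$;
* standard deviation of normalised distance ratio $= \mathrm{sd}(\rho)$.

These are the standard radial-distance margin descriptors; each formula is
implemented exactly as written above so alternates can be swapped in one
place. Two discretisation facts are worth knowing. First, smoothness is a
*pixel-scale* roughness measure: rasterisation jitter contributes to it for
every shape, smooth low-frequency lobes contribute little (their larger
$\max d$ normalises them down), and re-rasterising the same contour at
finer resolution lowers it. It therefore separates jagged from smooth
margins at a fixed scale rather than spiculated from round outlines —
compactness is the spiculation measure. Second, all six features are
translation invariant, stable under 90° rotation, and (except smoothness)
stable to ~3% under re-rasterisation at doubled resolution.

## Enhancement, intensity and textural kinetics

The enhancement curve is the relative enhancement of the ROI-mean signal.
EK features read the curve directly: maximal uptake, time to peak (first
maximum, minutes), uptake rate (max/time-to-peak, 0 if the peak is at
t = 0), washout rate (drop from peak to the final phase per minute, 0 if
the peak is final).

IK and TK fit a third-order polynomial $c_0 + c_1 u + c_2 u^2 + c_3 u^3$ on
time normalised to $u \in [0,1]$; normalising time keeps the coefficients
comparable across acquisitions of different total duration, while curve
values are deliberately not rescaled (their units are the feature's units).
The fit is ordinary least squares (`lm.fit`), exact when T = 4. IK applies
this to the enhancement curve (4 features); TK applies it to each of 37
per-phase texture statistics (148 features). Per phase, per-pixel texture
maps are computed over the lesion bounding box — so border lesion pixels
have neighbours — and averaged over ROI pixels:

* **first-order** (12 curves): mean, median, range, sample sd in sliding
  windows of width 3, 5, 7 (three dyadic-odd windows; 4 stats x 3 windows x
  4 coefficients = 48 features), windows clipped at the box edge;
* **Sobel** (3): mean |gx|, |gy| and gradient magnitude, 3x3 kernels with
  replicate padding;
* **Kirsch** (9): mean absolute response of the eight 3x3 compass masks
  plus the per-pixel maximum over directions;
* **Haralick** (13): grey-level co-occurrence statistics from a 5x5 window
  centred on each pixel, intensities min-max quantised over the box to
  G = 64 levels per phase, distance-1 offsets in 4 directions, symmetric
  and pooled. "Contrast" statistics (energy, inverse moment, average,
  variance, entropy) are moments of the $|i-j|$ marginal; "intensity"
  statistics moments of the $(i+j)/2$ marginal; plus entropy, energy,
  correlation (0 when either marginal is degenerate) and information
  measures of correlation 1 and 2 with the standard $0\log 0 = 0$ guards.
  A constant window yields the point-mass GLCM exactly: energy 1, entropy 0.

G, the GLCM window, and the first-order windows are configurable through
`kinetex_config()`. Per-phase min-max quantisation makes every Haralick
curve invariant to global intensity offsets and scalings — an important
property given that MR intensities are arbitrary units.

## Dynamic texture descriptors (DHoG, DLBP)

**DHoG.** Per phase, central-difference gradients are computed over the
bounding box ("y-up", so orientations follow the mathematical convention);
pixels that are in the ROI and have non-zero gradient magnitude are *valid*.
Valid-pixel orientations are counted — unweighted; magnitude weighting is
available behind `dhog_weighted` — into B even bins over [0°, 360°) within
every cell of a spatial pyramid (levels 1x1, 2x2, 4x4; depth L = 3 keeps
roughly ten pixels per cell for the smallest 5 mm lesions). All cell
histograms across cells and levels are summed into one aggregate, so each
valid pixel is counted once per level (per-phase total = valid pixels x L, a
conservation law the tests assert). Aggregates are averaged over phases and
the scalar feature is the base-2 Shannon entropy of the normalised
phase-averaged histogram, one scalar per B in {2, 4, 6, 8, 10}.

**DLBP.** Per phase, each box pixel is compared with its 8 neighbours
(bit = 1 iff neighbour >= centre; clockwise from top-left, top-left the most
significant bit), giving codes 0..255; validity requires all 8 neighbours
inside the box. Codes are binned into B equal-width bins (B in
{8, 16, 32, 64, 128, 256}; coarse-B histograms are exact block aggregations
of the 256-bin histogram), histogrammed per cell of a fixed 4x4 grid over
the bounding box, normalised to sum 1 per phase, averaged across the phases
in which the cell has valid pixels, and concatenated over cells. The scalar
is the entropy of the renormalised concatenation. LBP comparisons make the
descriptor exactly invariant to global intensity offsets; DHoG is invariant
to offsets and positive scalings.

**Scalarisation and its direction.** The descriptors natively produce
histograms; one scalar per bin configuration is needed for the feature
table, and entropy was chosen because both descriptors are interpreted as
lesion-heterogeneity measures (the raw histograms are retained in the
descriptor objects for inspection or export). Empirically, on the phantom
the two entropies respond in *opposite* directions to pharmacokinetic
heterogeneity: DLBP entropy rises (a richer micro-pattern spectrum fills
more code bins), while DHoG orientation entropy sits near its ceiling
$\log_2 B$ for any noisy, isotropic lesion and *declines* slightly as
structured gradients concentrate orientations. Both responses are monotone
and are asserted in the tests with their measured signs; users ranking
features should treat DHoG entropy as an (inverse) anisotropy measure
rather than a positively-oriented heterogeneity score.

## The phantom

The generator emulates the acquisition envelope the pipeline targets:

* grid spacing 0.5 mm (clinical range 0.2–0.8 mm), lesion radii drawn from
  5–9 mm (diameters within the 5–50 mm clinical range, centred on typical
  index-lesion sizes), 7 phases at 1 min (within the 5–10 phase envelope);
* star-convex lesions: boundary radius
  $r(\theta) = R(1 + s\,P(\theta))$ with $P$ a seeded sum of `n_lobes`
  sinusoidal harmonics (amplitudes $\propto 1/k$) normalised to unit
  variance, clipped below at $-0.7$ so the mask stays star-convex; the
  spiculation amplitude $s$ is the margin-irregularity dial;
* $K^{trans}$ fields: log-normal, built from seeded white noise smoothed
  with a Gaussian kernel (correlation length ~3 px), standardised,
  exponentiated and scaled to a target within-lesion coefficient of
  variation (the *heterogeneity* dial) and mean; $v_e$ is spatially
  constant (0.4); $k_{ep}$ is always the ratio;
* signal: $S(t) = S_0 (1 + \gamma C(t))$ with $\gamma = 1$ L/mmol and
  $S_0 = 100$, additive Gaussian noise (sd 2, i.e. 2% of baseline; a Rician
  switch exists but magnitudes are far above the noise floor at these
  SNRs), flat background at $0.3\,S_0$;
* cohorts: per-lesion parameters are drawn from class-conditional
  distributions — heterogeneity log-normal (log-sd 0.4) around the class
  median, spiculation and mean $K^{trans}$ truncated normal (sd 0.12 and
  0.04) around the class mean — and every lesion receives a scanner gain
  $e^{N(0, 0.4)}$ multiplying signal and noise alike, emulating the
  arbitrary-units, un-normalised intensities of multi-scanner MR data. The
  spreads make the two classes overlap the way clinical cohorts do; setting
  the class values of every pair equal makes the classes exchangeable, the
  null case used for calibration tests.

What the phantom does **not** emulate: breast anatomy and surrounding
tissue, motion and coil inhomogeneity, T2* effects, partial-volume margins,
multi-lesion cases, and — importantly — lesion micro-architecture beyond a
smoothed log-normal CV field. That last gap matters for interpreting the
end-to-end tests: in this phantom, per-phase texture dispersion statistics
are an essentially noiseless readout of the heterogeneity dial, so
textural-kinetic features dominate classification and the feature-selection
step has no need to add a DHoG/DLBP feature even though those features
discriminate well on their own (best single DLBP feature Az ~ 0.84 on the
strong-effect cohort). A passing pipeline test therefore demonstrates
correct mechanics and calibration, not that any one family would win on
clinical data.

## Classification and evaluation

`fit_lda()` is a two-class Gaussian classifier with pooled within-class
covariance, empirical priors, and internal z-scoring by training-fold
statistics (avoids scale pathologies across feature families). A ridge
$\lambda = 10^{-6}\,\mathrm{tr}(S)/p$ keeps the pooled covariance positive
definite when $p > n$, so the full 176-feature panel can be fit on small
cohorts. Posteriors are logistic in the linear discriminant.

`repeated_cv()` draws seeded stratified random halves (re-drawn, bounded at
20 attempts, if a fold ever lacks a class), trains on each half, scores the
other, pools the out-of-fold posteriors and records Az (rank-based
Mann-Whitney AUC, ties counted one half), PPV/NPV at posterior 0.5
(undefined ratios flagged NA, never silently 0) and error rate. Reported:
means over repeats (default 100), 95% *percentile* confidence intervals
(2.5/97.5 quantiles over repeats; the CI type is a package choice), RSD%,
and the per-repeat Az vector so RSD is recomputable. On exchangeable-class
cohorts the percentile CI covers Az = 0.5 at near-nominal rate (measured
0.93 over 200 null cohorts).

`sffs_select()` implements floating forward selection with criterion
J(S) = mean repeated-CV Az of LDA on S. The criterion uses 25 repeats (vs
100 for reporting) to bound runtime, and every evaluation shares one seed so
subsets are compared on identical splits; results are cached per subset, ties
break toward the lower feature index, conditional backward steps require a
strict improvement over the best recorded smaller subset (which also rules
out add/remove cycles), and a global iteration cap guards the floating
search. The returned subset is the best-J subset over sizes 1..max_k.

`rank_stable_features()` applies the top-half rule: keep features whose
mean Az is strictly above the grand-mean Az *and* whose RSD is strictly
below the grand-mean RSD. Note a statistical property of this rule: under
exchangeable classes about a quarter of features satisfy both conditions by
chance (the two thresholds are means over the same features), so the
selection is essentially never empty for large panels — the meaningful null
property, asserted in the tests, is that no *particular* feature is
selected systematically across replicates.

`learning_curve()` holds out a stratified 25% test set, subsamples the
training pool at each requested size (50 seeded replicates), and
`fit_power_law()` fits $err(n) = a\,n^{-\alpha} + \epsilon$ by bounded
L-BFGS-B with analytic gradients from 8 multi-starts
($a \in [10^{-8}, 100]$, $\alpha \in (0, 2]$, $\epsilon \in [0, 0.5]$);
$\epsilon$ estimates the Bayes error. A constant error sequence drives the
power term to the boundary ($a \to$ lower bound or $\alpha \to 2$) with
$\epsilon$ absorbing the level — the documented degenerate limit.

## Problem sizes used by the test suite

The unit tests run on small fixtures (12–64 px grids, single lesions); the
end-to-end tests use one strong-effect cohort of 30 + 30 lesions, one null
cohort of 20 + 20, and five null replicates of 8 + 8 with 4–6 mm lesions;
CV repeats are 100 for reporting, 25 inside SFFS, 50 in calibration loops.
These sizes were chosen so the full suite exercises every stage at
statistically meaningful scale while remaining comfortable on one CPU.

## Known limitations

* One representative 2-D section per lesion; no 3-D/volumetric features,
  no multi-lesion handling.
* No cross-site intensity harmonisation is attempted; families that are not
  offset/scale invariant (first-order TK, Sobel, Kirsch, EK maximal uptake)
  inherit the scanner's intensity scale. DHoG, DLBP, Haralick TK, PK, IK
  and shape are invariant by construction.
* The Tofts fit assumes the population AIF; per-patient AIFs and the
  extended model (vascular term) are out of scope.
* DHoG/DLBP bin-histogram scalarisation by entropy is one defensible
  reduction among several; the descriptor objects expose the full
  histograms so alternative reductions can be computed without re-running
  the image-level pipeline.
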