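---
title: "Methods: cold-stress phenotyping from leaf spatial-variability features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cold-stress phenotyping from leaf spatial-variability features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem and the model

Strawberry (*Fragaria x ananassa* 'Toyonoka') grown through winter is
routinely exposed to cold spells. Photosynthetic physiology degrades in
characteristic ways: the maximum net photosynthetic rate $P_{max}$ falls,
membranes leak electrolytes (relative electrolyte conductivity
$REC = C_1/C_2$ rises), and total chlorophyll $Chl_{a+b}$ declines under
mild, sustained cooling. `coldpheno` implements a purely phenotypic route to
monitoring that damage and predicting its risk level, from two imaging
modalities:

* **PAM chlorophyll fluorescence**: five frames (Fo, Fm, Fo', Fm', Fs) give
  eight quenching-parameter maps per leaf: Fv/Fm, NPQ, qP, qL, qN, Y(II),
  Y(NPQ), Y(NO). The lake-model forms are used, so the energy partition
  $Y(II) + Y(NPQ) + Y(NO) = 1$ holds as an algebraic identity
  ($Fs/Fm + (Fs/Fm' - Fs/Fm) + (Fm'-Fs)/Fm' = 1$).
* **Band reflectance**: four band means (blue 475-485, green 545-555, red
  645-655, NIR 780-790 nm) combined pairwise into five normalized-difference
  indices (NDVI, NDVInb, NDVIng, NDVIgb, NDVIgr).

The central idea is that the *spatial structure* of these 13 maps - not
their leaf averages alone - carries physiological information. Three
sampling supports are extracted per leaf: a transect parallel to the main
vein, a perpendicular transect at the leaf's widest point, and the largest
inscribed near-circular region. On each support, 16 spatial-variability
operators are evaluated (8 statistical: A, VAR, COV, IQR, SKE, KUR, INE,
ACOR; 8 structural: SENT, LENT, CON, ASM, TENT, HOM, INEM, SGA), giving
$13 \times 3 \times 16 = 624$ features per plant.

Three derived indices close the loop:

* **PPPI** (Photosynthetic Physiological Potential Index): a fixed linear
  combination of raw $P_{max}$, $REC$, $Chl_{a+b}$ via three component-score
  vectors and variance-contribution weights, minus 5. Applying it to the
  control physiology reconstructed from the published percentage relations
  gives 4.544, matching the published control mean 4.545 within 0.001 -
  which is how we settled that the loadings act on *raw*, unstandardized
  values.
* **RNAT** (relative negative accumulated temperature):
  $\sum_t T_{CK}(t) - T_{LT}(t)$ over hourly profiles, in degC h.
* **CDRI** $= PPPI - RNAT/650$, discretized into risk levels 0-4 at
  thresholds 3, 2, 1, 0 (left-closed bands; the divisor 650 is a fixed
  constant of the method).

Mutual information (equal-frequency discretization, plug-in estimate, base-2
logs) ranks the 624 features against each physiological target; the top two
per target - with a substitution rule under conflicts - form the six *key
features*. Tree ensembles (gradient boosting "XGB", AdaBoost.R2 "AB",
random forest "RF") invert PPPI and RNAT from those six features; CDRI and
risk levels follow, and exact Shapley values explain the fitted models.

# The synthetic world

No raw data accompany the original study, so the package ships a seeded
generator (`build_dataset()`) that emulates its stated world: a 5 temperature
(control 25/15 plus 19/9, 16/6, 13/3, 10/0 degC) x 3 duration (3, 6, 9 d)
factorial. Every published anchor is honored:

* **Temperature**: each design follows one normalized diurnal shape
  (minimum at 05:00, maximum at 14:00, piecewise-cosine between - the
  standard agro-meteorological interpolant; the published figure is not
  numerically readable, so only anchors and smoothness are honored). All
  designs share a 10 degC amplitude, so control-minus-treatment differences
  are constant hourly and RNAT is analytic (e.g. 15 degC x 72 h = 1080).
* **Physiology cell means**: REC and Chl means per treatment cell follow the
  published trends (REC rising to plateaus 0.352/0.384 under the two coldest
  gradients, 108.66 %/91.29 % above control; Chl declining under mild
  gradients with the transient 10/0 degC increase to 3.26), and $P_{max}$ is
  then *solved* per cell so that the cell's expected PPPI equals the
  published group mean. The severe-stress cell reproduces the printed
  $P_{max}$ = 8.601 to 0.002, an internal-consistency check of the published
  table itself. Control physiology (16.598, 0.184, 2.933) is reconstructed
  from printed percentage relations.
* **Replicate scatter**: sd 0.45 umol m^-2 s^-1 ($P_{max}$), 0.012 (REC),
  0.09 mg g^-1 (Chl). These reproduce PPPI spreads at the lower end of the
  published per-cell standard deviations (0.09-0.82); the published spreads
  include batch effects (two growing seasons) that the generator does not
  model. Chosen once, not revisited.
* **Raw measurements**: conductivities with fixed $C_2 = 200$ uS/cm and
  $C_1 = REC \cdot C_2$; absorbances inverted from the chlorophyll equations
  at V = 25 mL, D = 1, m = 0.2 g with A665/A649 = 1.2; light-response points
  on the 12-irradiance gradient (1600 ... 20, 0) generated from the modified
  rectangular hyperbola $P_n(I) = \alpha(1-\beta I)/(1+\gamma I)\,I - R_d$
  with $\beta = 3\times10^{-4}$, $\gamma = 1.5\times10^{-3}$, $R_d = 0.8$
  and $\alpha$ solved from the target $P_{max}$. The physiology module
  recovers REC and Chl to 1e-9 and $P_{max}$ within 1 % at zero noise.
* **Leaves**: 64 x 64 masks from rotated noisy ellipses (semi-axes ~26 x 16
  px, low-order harmonic margin perturbation). Parameter fields combine a
  fixed base-to-tip gradient along the vein with spatially correlated
  heterogeneity whose amplitude rises with stress severity; severity
  channels are tied to the sample's own physiology ($P_{max}$ -> Y(II)/qP
  fields, REC -> the Y(NO)/Y(NPQ) split, Chl -> qP shape and Fv/Fm) and to
  the accumulated dose (spectral indices). Because quantization is min-max
  per support, the texture features respond to the *ratio* of heterogeneity
  to the fixed gradient, which is exactly what the severity scales.
* **Cleaning**: a configurable fraction of mask pixels (default 1 %) is
  corrupted to zeros/saturation to exercise the abnormal-pixel removal.

**What a green test establishes - and what it does not.** The generator
validates the machinery (formulas, supports, selection, models) on a world
whose ground truth is known and whose trends match the published factorial
in expectation. It does not establish radiometric realism, instrument noise
structure (the Gaussian pixel noise is a stand-in; the study states none),
optics, or canopy geometry; and the published real-data benchmark numbers
(R^2 0.98, ACC 92 %, Kappa 0.904) are *not* reproduction targets - they
require the unpublished dataset.

# Numerical and design choices

* **Fluorescence forms**: the source cites textbook references without
  printing formulas; the lake-model forms above are adopted because the
  quantum-yield triple must satisfy the sum identity. qN uses
  $(Fm-Fm')/(Fm-Fo)$, with $1-(Fm'-Fo')/(Fm-Fo)$ available as a switch.
  Whether the instrument's Y(NO) uses the connected-units (qL-based) form is
  unknown; the choice is recorded in the map module rather than guessed at.
* **GLCM settings**: L = 16 gray levels, offset (0, 1), symmetric,
  normalized - common texture-analysis defaults; the source names none.
  1D supports are stacked into an N x N square before the GLCM, which is
  provably equivalent to adjacent-pair co-occurrence of the profile.
* **SGA**: the printed formula (a bare double sum over the "GLCM gradient
  matrix") is degenerate - any normalized distribution sums to 1. We
  implement the standard gray-level/gradient-level small-gradient dominance
  $T = \sum_{i,j} H(i,j)/(j+1)^2 / \sum H$ with gradient = absolute first
  differences quantized to L levels. This is an interpretation, flagged
  prominently here.
* **VAR**: the printed formula omits the square on $(x_i - A)$; the
  population variance is intended (the published worked example
  VAR([1,2,3,4]) = 1.25 confirms it).
* **KUR** is excess kurtosis (the printed "-3" retained). Degenerate
  (constant) supports define COV, SKE, KUR, ACOR, LENT as 0.
* **Quantile convention**: IQR uses linear-interpolation quantiles (R type
  7). 2D statistical operators run on the row-major flattened patch; the
  sequential formulas need *an* order and the source gives none.
* **Transects**: the main vein is approximated by the principal
  second-moment axis of the mask (the source does not say how the vein was
  located); sampling is unit-spaced with nearest-pixel lookup and no
  interpolation, consecutive duplicate pixels dropped; isotropic masks fall
  back to a horizontal axis with a warning.
* **MI estimator**: bins $= \max(4, \lfloor\sqrt{n/5}\rfloor)$,
  equal-frequency, deterministic tie-splitting by rank; invariant under
  strictly monotone transforms and symmetric. Note that the estimator's
  plug-in bias grows with bins^2/n; the package's independence anchor
  (< 0.05 bits at n = 2000) is checked at 8 bins, where the bias bound
  holds.
* **Selection conflicts**: when one feature is top-2 for two targets it is
  kept by the target with the larger MI and the other target substitutes its
  next-ranked unclaimed feature - this reproduces the published behavior,
  where a contested spectral contrast feature stayed with the chlorophyll
  target and the third-ranked feature backfilled the $P_{max}$ list.
* **Tree ensembles**: the deployment environment has no gradient-boosting,
  random-forest or CART package, so the trees are built in-package (exact
  greedy weighted CART in C++). "XGB" is least-squares gradient boosting
  with shrinkage 0.1; "AB" is AdaBoost.R2 with linear loss, weighted trees
  and weighted-median combination; "RF" bags bootstrap resamples with
  per-tree feature subsets (mtry = p/3). Tuning follows the stated contract:
  `n_estimators` in {50, 100, 200, 400} and `max_depth` in {2, 3, 4, 6} by
  mean 5-fold CV R^2 on a seeded, treatment-stratified 5:1 training split,
  with prefix evaluation sharing one fit per depth/fold. Ties prefer the
  smaller model. The expected ordering XGB >= AB >= RF is logged, not
  asserted - at desk scale sampling noise can invert it.
* **Explanations**: exact Shapley values by coalition enumeration (the
  models use 6 features; 2^6 coalitions) with replace-and-average
  marginalization over a background sample, rather than a TreeSHAP
  implementation; additivity (base + sum = prediction) holds exactly.
* **Planted-recovery testing**: recovering a planted 6-feature ground truth
  by marginal-MI top-2 selection requires the planted set to be
  *identifiable*: a feature with a near-monotone duplicate (e.g. TENT vs
  ASM of the same co-occurrence matrix, |rho| > 0.93) cannot be
  distinguished by any monotone-invariant dependence measure at n = 180.
  The acceptance test therefore plants six low-redundancy features (max
  cross-|rho| < 0.5) spanning both sources and all three supports. This
  redundancy is also the practical reason a substitution rule is needed in
  the original selection procedure.
* **I/O**: rasters are CSV grids with a JSON manifest and configs are JSON
  (the offline deployment image has no TIFF or YAML R library); every
  artifact is plain text.

# Known limitations

* The vein-axis surrogate fails on strongly lobed or multi-leaflet masks;
  the dominant mask component is assumed to be a single leaflet.
* The generator's noise model (log-normal pixel noise, Gaussian replicate
  scatter) is a stand-in; no claim is made about instrument error structure.
* PPPI loadings are consumed as printed constants; the published cumulative
  variance table contains an internal arithmetic inconsistency (75.583 where
  the two contributions sum to 76.583), documented but not repaired.
* The published abstract and conclusion disagree on the real-data accuracy
  (92.13 % vs 92.31 %); neither is an implementation target.

Every empirical number quoted above is computed by the test suite
(`tests/testthat/`, in particular `test-acceptance.R`) or by
`scripts/acceptance.R`; the vignette states no result they do not compute.
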