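---
title: "Quantifying nucleoplasmic lamin dynamics: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying nucleoplasmic lamin dynamics: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(laminquant)
```

## Scope

A-type lamins exist in two pools: a stable filament meshwork at the nuclear
periphery (the lamina) and a smaller, mobile pool dispersed through the
nucleoplasm whose abundance and dynamics depend on binding partners such as
LAP2α. `laminquant` implements the quantitative machinery used to
characterize that nucleoplasmic pool from live- and fixed-cell microscopy:

1. image-based nucleoplasmic-to-peripheral (N/P) intensity ratios with
   DNA-content cell-cycle staging,
2. continuous-photobleaching (CP) decomposition into immobile and mobile
   fractions,
3. fluorescence correlation spectroscopy (FCS) with a triplet-3D
   correlation model and Stokes–Einstein mass-ratio predictions,
4. quantification of extraction-resistant intranuclear lamin structures,
5. 3D telomere-trajectory analysis (rigid drift/rotation correction,
   convex-hull motion volumes, MSD curves), and
6. the statistical toolbox used across these readouts.

Because raw microscopy of this kind is rarely deposited, every analysis
stage is paired with a synthetic-data generator that stores its ground
truth; the package's regression suite is built on recovering those truths.

## N/P ratio quantification

Nuclei are segmented from the lamin channel by a global Otsu threshold on
the z-mean projection, hole filling, and a distance-transform seeded
watershed that splits touching nuclei (markers are the connected regions
where the distance transform exceeds 80% of its per-object maximum — round
objects produce one marker each, merged pairs two). The nucleus is then
partitioned: the *nucleoplasm* is the nucleus eroded by a rim width
(default 0.8 µm), realized as pixels whose Euclidean distance to the
boundary exceeds the rim in pixels; the *periphery* is the remainder. The
two regions are disjoint by construction and their union is exactly the
nucleus — both properties are enforced by tests on random masks.

Intensities are read asymmetrically on purpose:

* nucleoplasm = **median of the z-minimum projection** over nucleoplasm
  pixels — the minimum projection suppresses out-of-focus light from the
  much brighter lamina above and below the mid-plane;
* periphery = **upper quartile (75th percentile) of the z-maximum
  projection** over rim pixels — the maximum projection captures the
  brightest in-focus section of the lamina.

Single-plane images serve as both projections. The ratio is invariant
under global multiplicative intensity changes (illumination, exposure),
which is also tested. A manual variant reproduces the line-profile
protocol: a three-pixel-wide bar across the nucleus, peripheral intensity
as the mean of the two end-half peaks, nucleoplasmic intensity as the mean
of the 30 samples centred on the midpoint.

Time series are normalized to an anchor ratio. The anchor is either
explicit (first post-mitotic frame) or automatic: the last time point
before the first ratio exceeding the running-baseline mean by 2 baseline
standard deviations (the multiple is configurable; the source protocol
defines the anchor only verbally, so the 2-SD rule is this package's
concrete choice).

Cell-cycle staging integrates the DNA-stain intensity over each nucleus
and gates the resulting axis into G1 (2C) and S-G2 (up to 4C) windows
supplied by the user, mirroring a DNA-content histogram gating.

**Rim width default.** The erosion depth used for the N/P partition is not
stated by the source protocol; 0.8 µm is adopted because it is the only
rim value printed anywhere in the methods (the structure-quantification
exclusion rim), and it is overridable everywhere.

## Intranuclear structure quantification

Candidate structures are detected inside each nucleus with a Huang
fuzzy-entropy threshold (the named method for this step), labeled as
8-connected components, and filtered by the stated rules: area within
0.0001–5 µm² and centroid farther than 0.8 µm from the nuclear boundary
(so lamina signal is never counted). Inclusion is centroid-based; whether
partial rim overlap should exclude a particle is unspecified in the
source, so the centroid rule is used and documented. Counts are verified
against an exhaustive flood-fill + explicit-distance oracle in the tests.

## Continuous photobleaching

A confocal spot is parked in the nucleoplasm and intensity is sampled at
~1 kHz for ~60 s. Immobile molecules in the spot bleach quickly; mobile
molecules exchange with the unbleached nucleoplasmic reservoir and decay
slowly. The published analysis delegates to an algorithm in a cited prior
work that is not reproduced there; `laminquant` adopts the operational
definition

$$I(t)/I_0 = f\,e^{-k_\text{fast} t} + (1-f)\,e^{-k_\text{slow} t},$$

with the fast amplitude $f$ reported as the immobile fraction. The fit is
constrained ($0 \le f \le 1$, $k_\text{fast} \ge 5\,k_\text{slow}$ by
default) so the labels cannot swap, uses a deterministic multi-start grid
(slope-based guess plus coverage of the fast-rate decades), and decimates
traces to ≤ 6000 points by block averaging for speed. Recovery is
unbiased to < 0.02 across $f \in \{0.1, 0.3, 0.5, 0.7\}$ at SNR 50 in the
acceptance battery. Population summaries histogram per-cell fractions and
compare cohorts on arcsine-transformed values.

## FCS model

The correlation model is the standard triplet-3D form

$$G(t) = \Big[1 + \sum_{j} T_j\big(e^{-t/\tau_{\text{Trip},j}} - 1\big)\Big]
\sum_{i} \rho_i \big[1 + (t/\tau_{\text{Diff},i})^{a_i}\big]^{-1}
\big[1 + (t/\tau_{\text{Diff},i})^{a_i} k^{-2}\big]^{-1/2} + G_\infty,$$

with one dark state, two diffusing species and anomaly exponents fixed at
1 by default. The published rendering of this equation drops brackets and
exponents; the canonical form above is consistent with the printed
parameter list and is the one implemented. Instrument constants default
to the calibrated values $k = 7.92$ and $V_\text{eff} = 0.267$ fl. The
beam waist comes from the confocal relation
$V_\text{eff} = \pi^{3/2} k w_0^3$ (the printed formula is also garbled;
this standard inversion gives $w_0 \approx 0.18$ µm), and diffusion
coefficients from $D_i = w_0^2 / (4\tau_{\text{Diff},i})$ — an identity
the package maintains to machine precision.

Fitting is weighted least squares in $G$ (uniform weights unless per-lag
SDs are supplied), with multi-start initialization over the lag range and
species returned fast-first. The triplet lifetime is fitted per dataset
by default (the source does not say whether it was fixed). A parsimony
flag marks fits where one contribution vanishes or the two diffusion
times nearly coincide — the signature of over-specifying the species
count. The offset $G_\infty$ can be fixed at zero for curves known to
decay fully in range.

A multi-tau correlator (`autocorrelate`) turns photon traces into curves:
full-resolution lags for the first block, then the trace is binned by two
per block, with symmetric normalization to damp slow drift. It is checked
against analytic white-noise bounds and against a particle-level Brownian
simulation through a 3D Gaussian detection volume.

For interpretation, the Stokes–Einstein relation for spherical complexes
of equal density predicts $D_a/D_b = (m_b/m_a)^{1/3}$. With a 175 kDa
lamin + partner complex versus the 100 kDa lamin alone this gives 0.83 —
the desk-scale acceptance target.

## Telomere trajectories

Nuclei move and rotate during the 20.5 min acquisition (50 time points),
so trajectories are first rigidly registered: per frame, the constellation
of telomeres shared with frame 1 is aligned by the closed-form
least-squares rigid transform (SVD/Kabsch, with the reflection guard);
frames with fewer than three usable non-collinear points are left
uncorrected and flagged. Only complete tracks (all 50 points) enter
downstream analysis — incomplete tracks are dropped, never interpolated.

Motion is summarized by the volume of the 3D convex hull of all track
positions (an incremental hull; degenerate point sets return 0) and by
time-averaged MSD curves. Population curves report the per-lag mean with
the central 70% band, realized as the 15th–85th percentile per lag (the
band estimator is not defined by the source; percentiles are this
package's choice). Hull volumes are summarized with Tukey box-plot
conventions.

**A registration caveat established by simulation:** aligning on the
telomere constellation itself absorbs roughly $2/n$ of the genuine
diffusive variance per frame ($n$ = telomeres used), biasing hull volumes
down by about $(1 - 2/n)^{3/2}$. With dense labeling (tens of telomeres,
as in the package's recovery test at $n = 60$) drift-contaminated volumes
are recovered within 10% (median); with sparse constellations
(n ≈ 10) the shrinkage reaches ~25%. Image-based drift correction, as
performed by commercial software on the full nucleus, does not share this
bias — a known limitation of the point-based surrogate.

## Synthetic data: the stated world

The generators render exactly the conditions the protocols describe, and
their defaults are fixed once:

* **Nucleus images**: disks of radius 5 µm with a 0.8 µm bright rim at
  intensity 200, nucleoplasm 50 (true N/P = 0.25, the order of magnitude
  of measured G1 ratios), background 5, on a 0.2 µm/px grid; Gaussian
  read noise; non-overlapping placement with bounded retries. DNA channel:
  per-nucleus integrated density drawn lognormally (CV 5%) around 2C or
  4C means, matching a bimodal DNA-content histogram.
* **CP traces**: 60 s at 1 kHz; the two-exponential surrogate above with
  $k_\text{fast} = 1\,/\text{s}$, $k_\text{slow} = 0.01\,/\text{s}$;
  additive Gaussian noise (SNR is not stated by the source, so it is a
  configurable parameter, 50 in the acceptance battery).
* **FCS curves**: the model evaluated on a log-spaced grid spanning ≥ 4
  decades around the diffusion times, plus relative Gaussian noise per
  lag.
* **Trajectories**: 50 points over 20.5 min; free diffusion as Gaussian
  steps with per-axis variance $2D\Delta t$; confined diffusion by
  specular reflection at a sphere; anomalous subdiffusion by
  fractional-Gaussian increments with exponent $\alpha$; a shared rigid
  drift/rotation per nucleus; localization noise added last.
* **Structure images**: bright disks of stated areas on the nucleoplasmic
  background, with truth counts computed from the same area and rim
  filters the detector applies.

What the generators deliberately do **not** emulate: photon shot
statistics and detector physics, the optical PSF (nucleus edges are
hard), irregular nuclear shapes, chromatin texture, or bleaching during
z-stack acquisition. A green recovery test therefore establishes the
correctness and calibration of the estimators on well-posed inputs — not
robustness to every artifact of real microscopy.

## Statistics

Proportions are arcsine-square-root transformed (the printed formula is
corrupted; $\arcsin\sqrt{p}$ is the standard variance-stabilizing form and
is what is implemented), ratios are log-transformed. Two-group designs use
Student's t (unpaired or paired) or Mann–Whitney U with Cohen's d (pooled
SD; the source does not name its estimator, and d is computed on raw
values by default). Multi-group designs use one-way ANOVA with Tukey HSD
or Kruskal–Wallis with Dunn's z post test (Bonferroni-adjusted), and
repeated-measures two-way ANOVA covers time × genotype curves. Degenerate
inputs (all values tied) return p = 1 rather than erroring. Box plots
follow Tukey: whiskers at the most extreme points within 1.5 IQR of the
quartiles, everything outside flagged as an outlier. Every test's type-I
error is calibrated by 2,000-replicate null simulation in the acceptance
suite.

## Numerical choices

* Coordinates are pixel centers, distances in µm via the pixel size;
  boundary distances use the exact Euclidean distance transform
  (Felzenszwalb–Huttenlocher two-pass).
* Erosion depth is rounded to the nearest integer pixel count, minimum 1.
* The hull uses a volume tolerance of $10^{-12} \times \text{scale}^3$ for
  facet visibility; collinear/coplanar inputs return volume 0.
* CP and FCS fits run bounded quasi-Newton optimization (`nlminb`) in
  log/logistic-transformed parameters; species ordering is enforced after
  fitting, not during.
* TIFF I/O is a minimal uncompressed 32-bit-float codec (multi-page,
  little-endian) with the pixel size in both the resolution tags and a
  JSON description; it round-trips with standard readers.

## Known limitations

* The CP model is a phenomenological surrogate; it does not model
  reservoir-exchange kinetics, so `k_slow` should not be read as a
  physical bleaching constant.
* Point-constellation registration biases motion volumes down for sparse
  constellations (see above).
* Cell-cycle gates are user-supplied, not fitted; no automatic antimode
  detection is attempted.
* The Huang threshold is computed per nucleus on a 256-bin histogram;
  extremely low-contrast structures below quantization resolution are
  missed.
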