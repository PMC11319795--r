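---
title: "Muscle ultrasound texture, postural sway, and their association: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Muscle ultrasound texture, postural sway, and their association: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(echosway)
```

# The problem

Muscle composition and postural stability both deteriorate with age, and
both predict fall risk. This package implements the computational chain
used to study their relationship in young versus older adults: quantify
muscle composition from B-mode ultrasound (echo-intensity and second-order
texture), quantify stability from force-plate posturography (centre-of-
pressure sway), compare groups, classify age group from single parameters,
and estimate the multivariate muscle–sway association within each group.
Because raw clinical data of this kind are rarely shareable, a first-class
synthetic-data module generates cohorts, images and recordings with known
ground truth; every downstream claim the test suite makes is a claim about
quantities the generator planted.

# Ultrasound quantification

**Echo-intensity (EI)** is the mean 8-bit pixel intensity over a polygonal
ROI tracing the muscle cross-section. A pixel belongs to the ROI when its
centre lies inside or on the polygon boundary (even-odd rule) — a
deterministic, orientation-independent membership rule. Coordinates are
0-based `(row, col)` with rows increasing downward; this convention is
written into the ROI JSON sidecars.

**Thicknesses** are vertical distances between tissue interfaces on the
image's central line: skin to superficial aponeurosis (SAT) and
superficial aponeurosis to the deep boundary — deep aponeurosis or bone —
(MT), converted to cm by the isotropic pixel spacing.

**Texture** uses the gray-level co-occurrence matrix: normalized counts of
ordered pixel pairs `(reference, neighbour)` at a fixed offset. Defaults
are 256 gray levels with no requantization (the native 8-bit depth),
offset distance 1, and the four directions 0°, 90°, 180°, 270°, averaged.
Counting opposite directions separately and averaging is algebraically the
same as symmetrizing, and because all five features are linear or
separately computed functionals of the averaged matrix, features of the
averaged matrix equal the average-of-matrices route by definition — the
suite asserts both code paths agree, and asserts exact equality against a
naive double-loop pair-enumeration oracle on small images.

The five features of the averaged matrix \(p(i,j)\):

* ASM \(= \sum p^2\) (uniformity; 1 for a constant region),
* Contrast \(= \sum (i-j)^2 p\),
* IDM \(= \sum p / (1 + (i-j)^2)\) (local homogeneity),
* Entropy \(= -\sum p \log p\) over positive entries,
* Correlation \(= \sum (i-\mu_i)(j-\mu_j) p / (\sigma_i \sigma_j)\)
  with marginal moments of the averaged matrix.

Entropy uses the natural logarithm by default — at 256 levels this puts
muscle-image values in the 7–8 range typical of published tables — and the
base is recorded in the output. Correlation ships in two variants: the
`standard` normalized form above (range \([-1, 1]\), the default), and a
`plugin_compatible` form that reports the unnormalized co-moment, provided
because a widely used ImageJ texture plugin prints Correlation values
around 10^-3 that cannot arise from the normalized form; the plugin's
exact formula is not recoverable, so reproduction of its scale is not
promised. For a degenerate matrix concentrated on one gray level the
standard Correlation is undefined and returned as `NA`, never a silent
division by zero.

Repeated images of the same site (typically three) are averaged
element-wise by `average_replicates()`, which records the replicate count.

# Posturography

The centre of pressure about the plate-surface origin is
\(COP_{AP} = M_x / F_z\), \(COP_{ML} = -M_y / F_z\) (x = medio-lateral,
y = anterior-posterior, z = vertical), in mm. The axis convention is fixed
and documented; only the AP/ML labels matter downstream because the
standard deviation is sign-invariant. Reconstruction requires
\(|F_z| > 50\) N throughout — a plausible continuous stance.

COP series are band-pass filtered 0.1–10 Hz with a zero-phase
(forward–backward) 4th-order Butterworth, the dominant posturography
convention. Two numerical choices matter at a 1000 Hz sampling rate:

* the 0.1 Hz corner sits at a normalized frequency of 2×10^-4, where a
  single high-order transfer function is ill-conditioned (an 8th-order
  band-pass design is numerically singular in double precision; even a
  4th-order high-pass carries a ~10^-5 relative rounding-noise floor from
  its pole cluster at \(z = 1\)). The filter is therefore applied as
  cascaded second-order sections (biquads at the Butterworth pole quality
  factors, bilinear-transformed with prewarping), which brings the noise
  floor to ~10^-12 — a constant moment offset then changes sdCOP by less
  than 10^-9 mm;
* the series mean is removed before filtering, so a pure DC offset maps to
  exactly zero, and edges are odd-reflection padded (3 s) to suppress
  filter transients.

Stability is the sample SD (n−1) of the filtered COP per axis, reported
raw (mm) and height-normalized (mm per m of height — the normalization
unit is a package choice, as only "normalized by height" is conventional).
`sway_summary()` refuses unfiltered input so an unremoved offset can never
silently inflate the SD. Summaries from repeated blocks of the same
condition are averaged per subject before any group statistics.

# Group statistics

* **t-tests** are pooled-variance (Student) — the form implied by printed
  degrees of freedom \(n_1 + n_2 - 2\) — with Cohen's d standardized by
  the pooled SD and reported as an absolute value. The raw-sample path is
  by construction identical to the summary-statistic path, which is what
  lets printed "mean ± SD" table rows be re-analyzed directly.
* **Fisher's exact test** enumerates the hypergeometric support and sums
  probabilities at most that of the observed table (two-sided).
* **ICC** is the two-way random-effects, absolute-agreement,
  single-measure form ICC(2,1) — the conservative reading for test–retest
  reliability of single images — with the standard F-based 95% interval.
  The form is recorded in the result (`icc2_1`). Absolute-agreement ICC is
  invariant to a common shift but not to per-replicate rescaling.
* **ANOVA** is the fixed-effects condition × group model with interaction
  on per-subject (block-averaged) normalized sdCOP. η² is classical
  (SS effect / SS total), not partial, so the effects' η² can sum below 1.
  Degrees of freedom are computed from the actual table. Post-hocs are
  pairwise Student t-tests between conditions with Bonferroni-multiplied
  p-values. An all-equal response yields F = 0 / p = 1 rather than 0/0.
* Correlation magnitudes are labelled on the conventional five-step verbal
  scale (boundaries 0.2 / 0.4 / 0.6 / 0.8).

# Classification

ROC curves are empirical (non-parametric), swept over all distinct
thresholds; the trapezoidal AUC equals the tie-corrected Mann–Whitney
estimate exactly, and the suite asserts the two routes agree on all
inputs. Score orientations are fixed **a priori** from the published
direction of each age effect (+1: EI, Entropy, Contrast; −1: MT, ASM,
IDM, Correlation, SAT) with the older group as positive class;
data-driven flipping would bias AUCs upward. Paired AUC comparisons use
the DeLong placement-value covariance — the standard z-test for two
empirical ROC curves measured on the same subjects; the choice is recorded
in the result (`delong.paired`). Identical or monotone-transformed score
pairs give z = 0, p = 1 by convention (0/0 case).

# Regularized canonical correlation

Preprocessing per column, in the published sentence order: z-score
standardize; winsorize by clamping z-scores beyond ±2.5 SD to the bound
(the only self-consistent reading of replacing outliers "with the
minimum/maximum value"); residualize on age by least squares; and
re-standardize so the CCA inputs are exactly unit-variance. Age correction
is applied within the analyzed group.

The first canonical pair of the ridge problem is the leading singular pair
of \((S_{xx}+\lambda_x I)^{-1/2} S_{xy} (S_{yy}+\lambda_y I)^{-1/2}\),
back-transformed and unit-normalized. Sign indeterminacy is resolved
deterministically: the pair is flipped jointly so the canonical
correlation is non-negative, then so the MT weight (or largest-magnitude
weight) is positive. At \(\lambda = 0\) this reduces to classical CCA
(asserted against a whitening-SVD reference to 10^-8); as
\(\lambda \to \infty\) the weights converge to the leading singular
vectors of \(S_{xy}\) (asserted at \(\lambda = 10^6\)). Only the first
pair is extracted.

Penalties are selected by leave-one-out cross-validation over a shared
13-point grid log-spaced 10^-3–10^3 (the grid is a package choice):
each held-out subject is projected on the fold's sign-aligned weights and
the pair is scored by the Pearson correlation of the held-out projections,
with ties broken toward heavier regularization.

Significance uses permutations: the muscle block's rows are shuffled (the
sway block is not), the canonical correlation is recomputed with the
selected penalties held fixed, and
\(p = (1 + \#\{r_{perm} \ge r_{obs}\}) / (n_{perm} + 1)\), deterministic
given the seed. **A calibration caveat:** reusing the data-selected
penalties inside the permutations is the computationally proportionate
default, but the selection step itself peeks at the data — in simulations
at these sample sizes the full select-then-permute shortcut rejects about
15% of null datasets at the 5% level. The permutation machinery itself is
exactly calibrated (6.0% rejection over 500 null cohorts at fixed
penalties), and `permutation_test(reselect = TRUE)` re-runs the selection
inside every permutation when full validity is worth the cost.

The pooled association mirrors the published summary: the muscle score is
the mean of the standardized US parameters sign-corrected by the canonical
x-weights, the sway score is the mean of the standardized per-condition
values, and their Pearson correlation is reported with the verbal label.

# The synthetic-data generator

**Cohorts.** Subjects are drawn from a Gaussian copula: a joint
multivariate normal on z-scores mapped per variable to its marginal. US
marginals default to the published vastus-lateralis group summaries
(e.g. EI young 32.3 ± 7.1, old 56.0 ± 9.2); ASM and Correlation, whose
SDs rival or exceed their means, use moment-matched lognormal marginals
(normal draws would go negative), the rest are normal. The copula is built
on the age-aligned scale (positive z = more old-like), with an
exchangeable within-US correlation of 0.3 and within-sway correlation of
0.6 — documented assumptions, not estimates, since no within-group
correlations are published. Demographics use the published group sizes
(32/34), female proportions, height/weight summaries, and uniform ages
over the recruitment ranges (19–31, 65–85; uniform avoids out-of-range
draws when only mean, SD and range are known). Per-condition sway
marginals are assumptions chosen to reproduce the qualitative pattern:
sway rises from eyes-open/hard to eyes-closed/foam, older adults sway
more everywhere, and the old/young gap peaks around 57% on foam with eyes
closed.

The muscle–sway coupling is a constant cross-correlation between every US
and sway z-score, calibrated in closed form so the correlation between
the muscle-quality-signed mean of the five CCA variables and the mean
sway equals `coupling_rho` exactly in population (positive = "better
muscle, larger sway", the direction observed in young adults; the old
group defaults to 0). The lognormal marginals attenuate the realized
linear correlation by a few hundredths — visible in the Monte-Carlo
checks, which recover a mean pooled correlation of ~0.51 for a planted
0.53.

**Images.** Layered 8-bit speckle images: dark gel, bright skin band,
darker subcutaneous fat, bright superficial aponeurosis, muscle, bright
deep boundary, dark shadow. The muscle region is fine additive speckle
(box-smoothed Gaussian field, correlation length ~2 px) on a coarse
*multiplicative* lognormal clutter field of unit mean whose SD in gray
levels is `heterogeneity_scale`. The multiplicative form matters: an
additive Gaussian clutter at echo-intensity 32 with SD 40 would clip ~20%
of pixels to 0 and fabricate a dominant (0,0) co-occurrence entry,
inverting the expected homogeneity ordering; a positive multiplicative
field keeps the texture features monotone in the heterogeneity dial. The
realized ROI mean is driven to within ±2 gray levels of the target, and
the returned landmarks/ROIs are the ground truth used to synthesize the
image, so thickness measurements round-trip exactly. Pixel spacing
defaults to 0.01 cm/px (no pixel calibration accompanies the published
5 cm imaging depth). The generator does not simulate beam physics — it
emulates the *statistical* signature (mean level, homogeneity, layer
geometry), which is exactly what the texture features measure; passing
tests say nothing about acquisition-dependent effects such as gain or
time-gain compensation.

**Recordings.** Latent COP trajectories are white Gaussian noise
band-limited to the filter band and rescaled to the exact target SD — the
simplest process with controllable sdCOP. The band-limiting filter is
iterated three times so the latent spectrum is nearly a fixed point of the
analysis band-pass: the analysis pass then changes the SD by about −2%
instead of −6%, keeping planted-sway recovery comfortably within the ±5%
Monte-Carlo bound. Forces and moments are synthesized by inverting the COP
equations around a vertical load fluctuating mildly (±0.5%) about body
weight; because the moments are built from the same \(F_z\), the
pre-filter COP recovery is exact to machine precision.

# Simulation study sizes and known limitations

The test suite's simulation studies use: 500 null cohorts × 200
permutations for permutation-test calibration; 200 planted cohorts
(ρ = 0.5, n = 32) for recovery and power, with a reduced 5-point
leave-one-out grid (10^-2–10^2) — the full 13-point grid changes the power
estimate by under 1%; 20 seeds × 300 s recordings for sway recovery; 200
small random images for the GLCM oracle; 10^5 subjects per group for the
binormal AUC check.

Measured at those sizes: permutation type-I 6.0% (binomial 95% band
3.1–6.9%); median \(|\hat r - 0.5|\) ≈ 0.11; power to detect the planted
ρ = 0.5 coupling 58–59%. That power sits just below a 60% benchmark: at
n = 32 with 5 + 4 variables, the in-sample canonical correlation overfits
under the null (its null median is ≈ 0.55), which intrinsically limits
the power of the canonical-r permutation statistic; a univariate test on
the pooled scores would be more powerful (~84% analytic) but is not the
procedure under study. Other known limitations: real printed tables carry
rounding error, so only rounding-consistent rows are used as worked
examples; the ImageJ plugin's Correlation scale is not reproduced (see
above); and the two-way ANOVA's published error degrees of freedom imply
missing trials that a synthetic balanced cohort cannot emulate — the
implementation computes df from its actual table.
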