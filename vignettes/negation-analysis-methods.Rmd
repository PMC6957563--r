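---
title: "Models and methods behind negmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind negmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

negmap implements the statistical machinery of a three-level study of
logical negation — behavior, ROI-level fMRI, and observer-independent
cytoarchitectonic mapping — together with synthetic-data generators that
carry known ground truth. This vignette documents the models, the
parameter choices and their rationale, the numerical decisions, and what
the package's tests do and do not establish.

## The behavioral model

A trial's reaction time in the 2 (Polarity) × 2 (Probe type) ×
5 (Proportion) within-subject design is generated as

$$RT = \left(\mu_0 + \delta_{\text{cond}} +
A\,e^{-(\log p - c)^2 / 2w^2} + b_s\right)\,
e^{\varepsilon - \sigma_e^2/2},$$

with a negation cost $\delta_\text{ling}$ on negative linguistic trials
(*less*), a symbol-reversal cost $\delta_\text{symb}$ on negative symbolic
trials (`<`), a Gaussian difficulty bump on the log-proportion axis
(Weber's law: discriminability depends on the ratio, so difficulty is a
function of $\log p$), a subject intercept $b_s \sim N(0, \tau^2)$ clipped
at ±3 SD to keep means positive, and multiplicative lognormal trial noise,
mean-corrected so that the expected cell mean equals the deterministic
part exactly. RT positivity and right skew motivate the multiplicative
noise; the analyses themselves log-transform RT. Accuracy is Bernoulli
(default 16% errors) independent of RT — a deliberate simplification; real
error trials are faster or slower in structured ways.

### Default parameters and where they come from

| parameter | default | rationale |
|---|---|---|
| $\delta_\text{ling}$ | 152.5 ms | the linguistic polarity gap between the study's printed condition means |
| $\delta_\text{symb}$ | 83.4 ms | the symbolic polarity gap |
| $\mu_0$ | 880 ms | positive-condition baseline level |
| $\tau$ (between-subject SD) | 250 ms | see below |
| $\sigma_e$ (lognormal scale) | 0.12 | see below |
| $A$, $w$, $c$ | 180 ms, 0.4, −0.1 | difficulty tuning; see the identifiability analysis |
| error rate | 0.16 | 84% ± 4% correct in the modeled study |

The noise split deserves a note. Printed condition SDs near 300 ms and a
group proportion-mean curve that fits a Gaussian at $R^2 \approx 0.995$
cannot both hold unless most of the RT variance is *between subjects*:
subject intercepts cancel in the group curve's shape, so the trial-level
noise must be small. The defaults $\tau = 250$, $\sigma_e = 0.12$
reproduce both facts (condition SD $\approx \sqrt{250^2 + (0.12
\cdot 1100)^2} \approx 283$ ms; group-curve $R^2 \approx 0.99$). One
consequence of having no subject-specific effect-size variance (the
parameter set has a single intercept SD) is that simulated paired-t values
for the polarity effects are larger than the study's printed ones; the
package does not model random slopes.

### The proportion axis

The five blue/yellow ratios are free design values. The default,
$\exp(-1.2, -0.6, -0.1, 0.5, 1.1)$ (≈ 0.30–3.0), straddles equality
asymmetrically. The asymmetry is essential, not cosmetic: the
three-parameter Gaussian below is fitted with a *fixed center*, and on a
symmetric axis the five ratios collapse to three distinct distances from
the center — exactly as many constraints as parameters — so width,
amplitude and baseline ride a degenerate ridge and ~10 ms of noise in the
proportion means turns into ~150 ms of baseline error. With five distinct
distances and a bump narrow enough that the Gaussian factor spans
~0.02–1 over the axis, the decomposition recovers an injected 150 ms
baseline shift with a mean absolute error under 10 ms.

## NetNegInt and inference

`net_neg_int()` computes the interaction contrast
$(\overline{RT}_\text{less} - \overline{RT}_\text{more}) -
(\overline{RT}_< - \overline{RT}_>)$ on untransformed milliseconds, both
from grand cell means and per subject (the per-subject vector feeds the
brain–behavior correlation, whose natural units are ms). The
repeated-measures ANOVA (`rm_anova_2x2_log()`) runs on per-subject cell
means of log RT via `aov()` with the full within-subject error
stratification; for a 2×2 fully-within design every effect has 1 and
$n-1$ df and the interaction F equals the squared paired t on the
difference-of-differences — the package tests this identity against an
independent `t.test()` route at 10⁻¹⁰ relative tolerance. Strata whose
total sum of squares is numerically null relative to the data (identical
cells, exactly zero contrasts) are reported as F = 0, p = 1 rather than
the 0/0 ratio `aov()` would produce. The default trial filter keeps
correct trials only, with optional per-subject mean + k·SD trimming; no
trimming is applied by default.

## The Gaussian decomposition and its permutation test

`fit_gaussian_3param()` fits $b + A\,e^{-(u-c)^2/2w^2}$ (center fixed,
default: the log-ratio of the hardest, closest-to-equal proportion) to the
full set of a condition's RTs by least squares. Numerics:

- the mean structure is constant within a proportion, so the trial-level
  SSE is minimized exactly by weighted least squares on per-proportion
  means with trial-count weights;
- $b$ and $A$ are linear given $w$ and are profiled out in closed form;
  the fit reduces to a deterministic 1-D search over $w$ (log-spaced grid,
  downhill walk from $w_0 = \text{span}/2$, golden-section refinement);
- the search is *local* from $w_0$, and $b, A$ are box-constrained
  ($b \ge 0$, $0 \le A \le 4\times$ the range of the proportion means).
  Both choices target the same degeneracy: at large widths the Gaussian
  factor is nearly constant over the axis and an amplitude the size of the
  whole RT level can trade off against the baseline. An RT floor and a
  difficulty cost are nonnegative quantities, and an amplitude several
  times the observed modulation means the curve is flat over the sampled
  axis — not a meaningful tuning curve;
- constant data yield a flagged degenerate fit (amplitude 0, undefined
  $R^2$).

`fit_weber()` is the same model on the five group proportion means, on
either a linear or a log-compressed axis; comparing the two $R^2$ values
is the Weber's-law check. On generator data (Gaussian in log ratio) the
log axis wins in ≥ 95% of simulated studies.

`permutation_baseline_test()` compares the three fitted parameters between
conditions. The null distribution exchanges the two condition labels
*within subject* (each subject's complete trial sets are swapped or not),
respecting the paired design; trial-level shuffling is available behind
`unit = "trial"`. Two-sided p-values use the add-one correction
$(1 + \#\{|T^\pi| \ge |T|\})/(1 + n_\pi)$; when $n_\pi \ge 2^S$ the test
enumerates all flips exactly. Under a null negation cost the baseline
rejection rate at $\alpha = 0.05$ is calibrated (0.03–0.07 over 500
simulations); under a pure 150 ms shift the baseline parameter is detected
essentially always while amplitude and width stay at nominal rates.

## PSC generation and ROI statistics

`gen_psc()` draws per-subject condition-by-phase PSC values whose
subject-level NetNegInt contrast is coupled to a supplied behavioral
vector at exactly $\rho$: the BOLD effect is $\text{net}_\mu +
\sigma_\text{net}(\rho z_s + \sqrt{1-\rho^2}\,\epsilon_s)$ with $z_s$ the
standardized behavioral effect, distributed across the four cells along
the interaction contrast; cell-level noise ($\sigma_\text{psc}$) is
projected orthogonal to that contrast so it perturbs cells without
diluting the coupling. Sample correlation therefore converges to $\rho$,
and $\rho = 1$ with zero noise gives an exact affine relation.
`psc_interaction_test()` reuses the ANOVA engine on raw PSC (no log — PSC
can be negative); `behavior_bold_correlation()` defaults to a one-tailed
positive Pearson test, the directional hypothesis for a region tracking
the behavioral cost.

## Volumes

A `volume_grid` is a 3-D array plus a 4×4 affine mapping **0-based** voxel
indices to mm at voxel centers (NIfTI convention; I/O via RNifti).
Conventions: nearest-neighbor, label-preserving resampling for binary
masks (fractions of labeled volumes must not be blurred), with the
continuous index rounded half-up; `overlap_fractions()` resamples both
masks onto a common 1 mm grid covering their joint extent and reports
shared voxels as percent of each input; `peak_probability()` is a
nearest-voxel lookup with the same rounding; `center_of_mass()` is the
intensity-weighted mean of voxel-center coordinates;
`build_prob_map()` averages aligned binary masks, so
$\sum \text{map} \times v_\text{voxel}$ equals the mean individual volume
exactly. `area_volume()` is the Cavalieri estimator
$\sum a_i \cdot t \cdot k \cdot f$ with section thickness $t$, sampling
interval $k$ and shrinkage factor $f$.

## Observer-independent border detection

The histology phantom is a grayscale image whose cortical ribbon holds a
laminar grey-level-index template — `"granular"` with a conspicuous
layer-IV peak, `"dysgranular"` with that peak attenuated and denser deep
layers — switching templates at known traverse positions, plus Gaussian
pixel noise (default SD 0.05 on a [0, 1] scale). It emulates the
statistical structure the procedure assumes (laminar profiles, abrupt
template change); it does not emulate curved ribbons with varying
thickness, staining gradients, blood vessels, or tangential cutting
artifacts, so passing recovery tests demonstrate the procedure's
statistical behavior, not robustness to real histological nuisance.

The procedure: equidistant traverses from the outer (layer I/II) to the
inner (layer VI/white matter) contour, arc-length matched, each resampled
to 100 depth samples by bilinear interpolation (depth normalization
removes cortical-thickness confounds); per profile a 10-dimensional
feature vector (mean, centroid, SD, skewness, kurtosis of the profile and
of its absolute central-difference derivative — the canonical moment set
for this procedure); features standardized across the ROI. For each
position $x$ and blocksize $b$, the squared Mahalanobis distance between
the mean feature vectors of the $b$ profiles on each side, with pooled
within-block covariance (ridge-regularized with escalating $\varepsilon$
if singular, flagged); significance via Hotelling's $T^2 = (b/2)D^2$
transformed to an F statistic with $(d,\ 2b - d - 1)$ df.

Border calling (`detect_borders()`) takes the significant local maxima of
$D^2$ per blocksize (default range 8–24 in steps of 2) and accepts
positions recurring within ±2 traverses in a majority of blocksizes. Three
choices depart from the obvious defaults, each driven by a simulation
finding:

- **Bonferroni across positions** (default, rather than per-position
  $\alpha = 0.05$): distance curves of neighboring blocksizes share
  profiles, so chance exceedances persist across blocksizes and
  per-position testing yields a 37% false-border rate on homogeneous
  phantoms vs 1% with the correction;
- **per-blocksize flank suppression**: a block of width $b$ straddles any
  border within $b$ of its split position, so a weaker significant maximum
  closer than $b$ to a stronger one (they appear around border − b/2 for
  large blocks) is a flank of the same border, not a second border;
- **global minimum separation** equal to the smallest blocksize: borders
  closer than the narrowest block cannot be resolved, so closer accepted
  calls are merged keeping the best-supported one.

With defaults, 100 phantom realizations give 100% single-border recovery
within ±2 traverses and a ≤ 1% false-positive rate on homogeneous
phantoms, with two borders at separation 25 resolved exactly.

## Problem sizes

The test suite and acceptance script use the study-sized design (21
subjects, 6 tokens, 5 proportions) throughout; the heavier simulations are
500 null datasets × 199 permutations for permutation calibration, 100
simulations for shift recovery, 200 for the Weber ordering, 20 random
fixtures for the Mahalanobis cross-check against a naive double-loop
reference, and 100 + 100 phantoms for border recovery/false positives.
The full suite runs in a few minutes on one CPU.

## Known limitations

- No random slopes in the RT model (subject-specific negation costs), so
  simulated paired-t magnitudes overshoot the modeled study's.
- Accuracy is independent of RT; no speed–accuracy trade-off.
- Traverses are straight segments between arc-length-matched contour
  points; curved field-line tracing is not implemented.
- The PSC generator produces condition-level values only — no time series,
  no hemodynamic model.
- Whole-brain GLMs, cluster correction, spatial normalization and real
  histology processing are out of scope by design; volumes enter the
  package already aligned.
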