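# negmap

Analysis machinery for dissociating **logical negation** from language and
numerosity, spanning the three levels such a study needs: behavior
(reaction times), functional imaging (ROI percent signal change), and
microanatomy (observer-independent cytoarchitectonic mapping). Everything
runs on synthetic data with known ground truth, so every stage of the
pipeline is testable end to end.

## The science in brief

Polar quantifier pairs like *more*/*less* differ by an **implicit
negation**: *less* reverses truth values and inference direction without
any negative morpheme. In a speeded sentence–picture verification task
crossing Polarity (positive/negative) with Probe type (linguistic
quantifiers vs. symbolic inequalities `>`/`<`), the processing cost of that
hidden negation appears as a difference of differences,

```
NetNegInt = (RT_less − RT_more) − (RT_< − RT_>)
```

while numerical-comparison difficulty follows **Weber's law**: the RT curve
over blue/yellow proportion ratios becomes Gaussian once the ratio axis is
log-compressed. The package implements:

- `gen_trials()` / `gen_psc()` / `gen_histology_phantom()` / `gen_volume()`
  — generators for trial tables, coupled PSC data, laminar histology
  phantoms and voxel volumes, all with known ground truth;
- `net_neg_int()`, `rm_anova_2x2_log()`, `paired_t()`, `filter_trials()`,
  `condition_summary()` — the behavioral statistics;
- `fit_weber()`, `fit_gaussian_3param()`, `permutation_baseline_test()` —
  the Weber's-law axis comparison and the three-parameter Gaussian
  decomposition (baseline, amplitude, width; fixed center) of the negation
  cost, with within-subject label-flip permutation inference;
- `psc_interaction_test()`, `behavior_bold_correlation()`, `conjunction()`,
  `overlap_fractions()`, `peak_probability()`, `center_of_mass()`,
  `threshold_roi()` — ROI statistics and functional–anatomical overlap;
- `extract_profiles()`, `profile_features()`, `sliding_mahalanobis()`,
  `detect_borders()` / `find_borders()`, `area_volume()`,
  `build_prob_map()`, `asymmetry_test()` — the observer-independent border
  detection: grey-level-index profiles, 10 moment features, blockwise
  Mahalanobis distance with Hotelling significance, blocksize-stable
  border calls, Cavalieri volumetry and probabilistic maps.

## Worked example

The numbered scripts under `analysis/` run the whole study on synthetic
data (`Rscript analysis/01_simulate.R`, then `02`–`05`). The decomposition
stage, for instance:

```r
library(negmap)
design <- design_spec()                       # 21 subjects, 2x2x5 design
trials <- filter_trials(gen_trials(design, rt_model_params(), seed = 101))
more <- trials[trials$polarity == "positive" & trials$probe_type == "linguistic", ]
less <- trials[trials$polarity == "negative" & trials$probe_type == "linguistic", ]
attr(more, "proportions") <- attr(less, "proportions") <- design$proportions
permutation_baseline_test(more, less, n_perm = 999, seed = 303)
```

prints

```
Permutation decomposition (999 Monte-Carlo permutations, unit = subject)
  baseline  diff =   151.102   p = 0.00100
  amplitude diff =     1.008   p = 0.95000
  width     diff =    -0.018   p = 0.90400
```

the signature result: the injected 152.5 ms negation cost loads on the
**baseline** parameter only — negation adds a constant to RT at every
proportion — while amplitude and width (the Weber difficulty tuning) do
not differ between *more* and *less*. The Weber stage of the same run gives
R²(log) = 0.985 vs R²(linear) = 0.823, and the border-detection stage
recovers the phantom's areal border at traverse 41 exactly, with support
from all 9 blocksizes.

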