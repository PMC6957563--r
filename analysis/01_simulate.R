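#!/usr/bin/env Rscript
# Generate the synthetic study: a trial table from the 2 (Polarity) x
# 2 (Probe type) x 5 (Proportion) within-subject design at the published
# effect sizes, and ROI percent-signal-change data coupled to the
# behavioral negation effect. Downstream scripts read these files.

library(negmap)

dir.create("results", showWarnings = FALSE)

design <- design_spec()                       # 21 subjects, 6 tokens, 5 ratios
params <- rt_model_params()                   # 152.5 / 83.4 ms injected costs
trials <- gen_trials(design, params, seed = 101)
write_trials(trials, "results/trials.csv")
cat("trials:", nrow(trials), "rows ->", "results/trials.csv\n")

# behavioral NetNegInt per subject drives the BOLD coupling (rho = 0.4,
# the order of the published behavior-BOLD correlation)
nn <- net_neg_int(trials)
psc <- gen_psc(design, psc_model_params(rho = 0.4), nn$per_subject$net,
               seed = 102)
write_psc(psc, "results/psc.csv")
cat("PSC:", nrow(psc), "rows (phases I, II) ->", "results/psc.csv\n")

writeLines(jsonlite::toJSON(list(proportions = design$proportions),
                            digits = NA),
           "results/design.json")
cat("ratio axis ->", "results/design.json\n")
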