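#!/usr/bin/env Rscript
# Weber's-law check (Gaussian fit on linear vs log-compressed proportion
# axis) and the three-parameter Gaussian decomposition of the negation
# cost with permutation inference on each parameter.

library(negmap)

props <- jsonlite::fromJSON("results/design.json")$proportions
trials <- read_trials("results/trials.csv", proportions = props)
trials <- filter_trials(trials)
attr(trials, "proportions") <- props

# group mean RT per proportion, fitted on both axes
m <- as.numeric(tapply(trials$rt_ms, trials$proportion, mean))
fw_log <- fit_weber(m, props, compress = "log")
fw_lin <- fit_weber(m, props, compress = "linear")
print(fw_log); print(fw_lin)
cat(sprintf("Weber check: R2(log) = %.3f vs R2(linear) = %.3f\n",
            fw_log$r_squared, fw_lin$r_squared))

# decomposition: which Gaussian parameter carries the negation cost?
more <- trials[trials$polarity == "positive" & trials$probe_type == "linguistic", ]
less <- trials[trials$polarity == "negative" & trials$probe_type == "linguistic", ]
attr(more, "proportions") <- attr(less, "proportions") <- props
fit_more <- fit_gaussian_3param(more)
fit_less <- fit_gaussian_3param(less)
print(fit_more); print(fit_less)

perm <- permutation_baseline_test(more, less, n_perm = 999, seed = 303)
print(perm)

write_results_json(list(
  weber = list(r2_log = fw_log$r_squared, r2_linear = fw_lin$r_squared,
               proportion_means = m),
  fit_more = fit_more[c("baseline", "amplitude", "width", "r_squared")],
  fit_less = fit_less[c("baseline", "amplitude", "width", "r_squared")],
  permutation = list(observed = as.list(perm$observed),
                     p = as.list(perm$p), n_perm = perm$n_perm)
), "results/psychometrics.json")
cat("-> results/psychometrics.json\n")
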