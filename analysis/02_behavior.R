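#!/usr/bin/env Rscript
# Behavioral analysis: accuracy filtering, condition means, the NetNegInt
# interaction signature, paired t tests and the repeated-measures ANOVA on
# log RT.

library(negmap)

props <- jsonlite::fromJSON("results/design.json")$proportions
trials <- read_trials("results/trials.csv", proportions = props)

kept <- filter_trials(trials)                 # correct trials only
cs <- condition_summary(kept)
write.csv(cs, "results/behavior_condition_summary.csv", row.names = FALSE)
print(cs)

nn <- net_neg_int(kept)
print(nn)

t_ling <- paired_t(nn$per_subject$delta_ling, rep(0, nrow(nn$per_subject)))
t_symb <- paired_t(nn$per_subject$delta_symb, rep(0, nrow(nn$per_subject)))
cat(sprintf("linguistic polarity effect: t(%d) = %.2f, p = %.3g\n",
            t_ling$df, t_ling$t, t_ling$p))
cat(sprintf("symbolic polarity effect:   t(%d) = %.2f, p = %.3g\n",
            t_symb$df, t_symb$t, t_symb$p))

an <- rm_anova_2x2_log(kept)
print(an)

write_results_json(list(
  accuracy = mean(trials$correct),
  netnegint = list(delta_ling = nn$delta_ling, delta_symb = nn$delta_symb,
                   net = nn$net),
  t_linguistic = t_ling[c("t", "df", "p")],
  t_symbolic = t_symb[c("t", "df", "p")],
  anova = split(an[c("F", "df1", "df2", "p")], an$effect)
), "results/behavior_tests.json")
cat("-> results/behavior_tests.json\n")
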