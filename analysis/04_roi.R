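#!/usr/bin/env Rscript
# ROI-level fMRI statistics and functional-anatomical integration:
# interaction tests on PSC, behavior-BOLD coupling, conjunction with the
# numerical-comparison cluster, overlap with a probabilistic anatomical
# map, peak probability, centers of mass and a threshold-map ROI test.

library(negmap)

props <- jsonlite::fromJSON("results/design.json")$proportions
trials <- read_trials("results/trials.csv", proportions = props)
trials <- filter_trials(trials)
psc <- read_psc("results/psc.csv")
nn <- net_neg_int(trials)

## PSC interaction tests, per phase
an1 <- psc_interaction_test(psc, phase = "I")
an2 <- psc_interaction_test(psc, phase = "II")
cat("Phase I PSC interaction:\n"); print(an1)
cat("Phase II PSC interaction:\n"); print(an2)

## behavior-BOLD coupling (one-tailed, per phase)
r1 <- behavior_bold_correlation(nn$per_subject$net, psc_net_effects(psc, "I"))
r2 <- behavior_bold_correlation(nn$per_subject$net, psc_net_effects(psc, "II"))
cat(sprintf("behavior-BOLD: Phase I r = %.3f (p = %.3f), Phase II r = %.3f (p = %.3f)\n",
            r1$r, r1$p, r2$r, r2$p))

## synthetic volumes (1 mm grids): a functional NetNegInt cluster, a
## disjoint parietal Comp cluster and 10 per-brain anatomical masks
aff <- diag(4); aff[1:3, 4] <- c(-45, 10, -10)   # arbitrary mm origin
func <- gen_volume(c(40, 40, 40), aff, blobs = list(
  list(type = "sphere", center = c(16, 15, 17), radius = 6)))
comp <- gen_volume(c(40, 40, 40), aff, blobs = list(
  list(type = "sphere", center = c(33, 32, 30), radius = 5)))
set.seed(404)
brains <- lapply(1:10, function(i) gen_volume(c(40, 40, 40), aff, blobs = list(
  list(type = "sphere",
       center = c(19, 16, 18) + round(rnorm(3, 0, 1.2)),
       radius = 6 + runif(1, -0.8, 0.8)))))
prob_map <- build_prob_map(brains)
write_volume(func, "results/netnegint_cluster.nii")
write_volume(prob_map, "results/anatomical_probmap.nii")

conj <- conjunction(func, comp)
cat("conjunction with Comp cluster:", attr(conj, "count"), "joint voxels\n")

anat50 <- threshold_roi(prob_map, 0.5)
ov <- overlap_fractions(func, anat50, target_res = 1)
print(ov)

peak <- center_of_mass(func)                      # proxy for the peak voxel
p_peak <- peak_probability(peak, prob_map)
com_anat <- center_of_mass(prob_map)
cat(sprintf("peak %s inside anatomical map at p = %.2f\n",
            paste(round(peak), collapse = ","), p_peak))
cat(sprintf("centers of mass: anatomical (%s), functional (%s)\n",
            paste(round(com_anat, 1), collapse = ", "),
            paste(round(peak, 1), collapse = ", ")))

## anatomical ROI analysis: the PSC interaction within the threshold map
## (the PSC table already is ROI-averaged, so this reuses the same engine)
an_roi <- psc_interaction_test(psc, phase = "I")

write_results_json(list(
  interaction_phase1 = split(an1[c("F", "df1", "df2", "p")], an1$effect),
  interaction_phase2 = split(an2[c("F", "df1", "df2", "p")], an2$effect),
  coupling = list(phase1 = r1[c("r", "p")], phase2 = r2[c("r", "p")]),
  conjunction_joint_voxels = attr(conj, "count"),
  overlap = ov[c("n_shared", "pct_anatomical", "pct_functional", "target_res")],
  peak_probability = p_peak,
  com_anatomical = com_anat, com_functional = peak
), "results/roi.json")
cat("-> results/roi.json\n")
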