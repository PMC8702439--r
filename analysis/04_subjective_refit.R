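#!/usr/bin/env Rscript
# Refits the condition-split hierarchical discounting model with every
# calendar delay replaced by the participant-condition's perceived
# duration T = alpha * t^beta, then repeats the 2 x 2 discount-rate
# ANOVA.  Under the perception mechanism the group difference seen on
# objective time should vanish here.

suppressPackageStartupMessages(library(affdisc))
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1

dat <- read_dataset(file.path("results", "data"))
perception <- utils::read.delim("results/perception_fits.tsv")
mc <- mcmc_config(n_chains = 4, n_samples = 1000, n_warmup = 1000,
                  n_adapt = 1000, n_thin = 2, seed = seed + 20)

k_est <- do.call(rbind, lapply(c("positive", "neutral"), function(g) {
  fit <- fit_hierarchical(
    dat$choices[dat$choices$group == g, ],
    discount_model_spec("split_by_condition", "subjective"), mc,
    perception = perception)
  cat(sprintf("%s group: max R-hat %.3f\n", g, max(fit$rhat)))
  k <- extract_k_estimates(fit)
  k$group <- g
  k
}))

an <- mixed_anova_2x2(data.frame(participant = k_est$participant_id,
                                 group = k_est$group,
                                 condition = k_est$condition,
                                 value = k_est$k))
cat("\nsubjective discount-rate cell means:\n")
print(round(an$cell_means, 4))
print(an)

utils::write.table(k_est, "results/k_subjective.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(an$effects, "results/anova_k_subjective.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(an$posthoc, "results/posthoc_k_subjective.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
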