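#!/usr/bin/env Rscript
# Converts line-scale judgments to subjective days (cohort-mean one-week
# anchor), fits the power law T = alpha * t^beta per participant and
# condition, and tests both parameters with 2 x 2 mixed ANOVAs.

suppressPackageStartupMessages(library(affdisc))

dat <- read_dataset(file.path("results", "data"))
perception <- fit_perception(dat$judgments,
                             week_anchor_policy = "cohort_mean")
perception$group <- dat$judgments$group[
  match(perception$participant_id, dat$judgments$participant_id)]

cat("perception parameter group means (immediate-condition fit):\n")
imm <- perception[perception$condition == "immediate", ]
print(aggregate(cbind(alpha, beta) ~ group, imm, mean), row.names = FALSE)

for (par in c("alpha", "beta")) {
  an <- mixed_anova_2x2(data.frame(participant = perception$participant_id,
                                   group = perception$group,
                                   condition = perception$condition,
                                   value = perception[[par]]))
  cat(sprintf("\n%s ANOVA:\n", par))
  print(an)
  utils::write.table(an$effects,
                     sprintf("results/anova_%s.tsv", par), sep = "\t",
                     quote = FALSE, row.names = FALSE)
}
utils::write.table(perception, "results/perception_fits.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
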