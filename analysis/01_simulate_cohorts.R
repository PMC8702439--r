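#!/usr/bin/env Rscript
# Generates the two synthetic cohorts under the default scenario:
# a 31 + 31 titration cohort (staircase choices on perceived time, line
# judgments) and a 57 + 58 fixed-battery cohort (ten-pair choices,
# attribute-attention responses).  Writes all input tables plus the
# generative truth used by later recovery checks.

suppressPackageStartupMessages(library(affdisc))
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1

out <- file.path("results", "data")

cohort1 <- sample_cohort(default_group_spec("positive"),
                         default_group_spec("neutral"), seed = seed)
choices1 <- simulate_cohort_choices(cohort1, study = 1, seed = seed + 1,
                                    time_basis = "subjective")
judgments <- simulate_cohort_judgments(cohort1, seed = seed + 2)
write_dataset(out, list(choices = choices1, judgments = judgments,
                        truth = cohort1))

cohort2 <- sample_cohort(default_group_spec("positive", n_participants = 57),
                         default_group_spec("neutral", n_participants = 58),
                         seed = seed + 3)
choices2 <- simulate_cohort_choices(cohort2, study = 2, seed = seed + 4,
                                    time_basis = "subjective")
attention <- simulate_cohort_attention(cohort2, seed = seed + 5)
dir.create(file.path(out, "study2"), recursive = TRUE, showWarnings = FALSE)
write_dataset(file.path(out, "study2"),
              list(choices = choices2, attention = attention,
                   truth = cohort2))

cat(sprintf("titration cohort: %d participants, %d trials, %d judgments\n",
            nrow(cohort1), nrow(choices1), nrow(judgments)))
cat(sprintf("fixed-battery cohort: %d participants, %d trials\n",
            nrow(cohort2), nrow(choices2)))
cat("tables written under", out, "\n")
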