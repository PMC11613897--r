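#!/usr/bin/env Rscript
# Stage 3: group-wise PRS percentiles and discrimination.
#
# Ranks each woman's raw polygenic score within her genetic-similarity
# group (average-rank percentile 100*r/N), standardizes against
# undiagnosed women, and reports the rank AUC of the raw score for the two
# groups large enough to support it.

library(brcascreen)

cohort <- read_cohort("results/cohort.tsv")
rec <- survival_records(cohort)

scores <- assign_percentiles(
  data.frame(participant_id = cohort$participant_id,
             raw_score = cohort$prs_raw,
             genetic_group = cohort$genetic_group,
             stringsAsFactors = FALSE),
  exclude = rec$event == 1L)
write.table(scores, "results/prs.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat("within-group percentile ranges by genetic-similarity group:\n")
print(vapply(split(scores$percentile, scores$genetic_group), range, numeric(2)))

for (g in c("Europe", "Americas")) {
  keep <- cohort$genetic_group == g
  auc <- prs_auc(cohort$prs_raw[keep], rec$event[keep] == 1L)
  cat(sprintf("raw-score AUC for breast cancer, %s group: %.2f (n = %d)\n",
              g, auc, sum(keep)))
}
cat("wrote results/prs.tsv\n")
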