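#!/usr/bin/env Rscript
# Stage 7: correlations among family history, carrier status and PRS.
#
# Restricted to undiagnosed women in the Europe genetic-similarity group
# (normalized PRS values are only comparable within a group): Fisher's
# exact test of carrier status vs family history, and Welch t tests of the
# PRS z-score against family history and carrier status.

library(brcascreen)

cohort <- read_cohort("results/cohort.tsv")
a <- association_analyses(cohort)

cat(sprintf("undiagnosed Europe-group women: %d\n", a$n))
cat(sprintf("carrier x FHx: OR = %.2f (exact CI %.2f-%.2f), p = %.2e\n",
            a$fhx_vs_carrier$or, a$fhx_vs_carrier$conf_int[1],
            a$fhx_vs_carrier$conf_int[2], a$fhx_vs_carrier$p))
cat(sprintf("PRS z vs FHx: t = %.2f, p = %.2e\n",
            a$prs_vs_fhx$t, a$prs_vs_fhx$p))
if (!is.null(a$prs_vs_carrier)) {
  cat(sprintf("PRS z vs carrier status: t = %.2f, p = %.2f\n",
              a$prs_vs_carrier$t, a$prs_vs_carrier$p))
}

jsonlite::write_json(list(
  n = a$n, table = as.list(a$table),
  fhx_vs_carrier = list(or = a$fhx_vs_carrier$or, p = a$fhx_vs_carrier$p,
                        conf_int = a$fhx_vs_carrier$conf_int),
  prs_vs_fhx = a$prs_vs_fhx, prs_vs_carrier = a$prs_vs_carrier
), "results/associations.json", auto_unbox = TRUE, digits = NA)
cat("wrote results/associations.json\n")
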