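#!/usr/bin/env Rscript
# Hardy-Weinberg equilibrium goodness-of-fit tests, per SNP, in cases and
# controls separately, on the marginal-exact fixture cohort.

library(vdburden)

co <- read_cohort("results/cohort_marginal.tsv", study_panel())
h <- hwe_table(co)
write.table(h, "results/hwe.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
print(h, digits = 3)
message(sprintf(
  "all %d SNP-by-group tests consistent with HWE (min p = %.2f)",
  nrow(h), min(h$p_value)))
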