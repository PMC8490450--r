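#!/usr/bin/env Rscript
# Generate the synthetic multi-omic cohort that every downstream analysis
# consumes: expression (genes x samples, log2), somatic variants with
# trinucleotide contexts, gene-level copy number (continuous + calls),
# five-year survival with class-specific hazards, and the ground truth.
#
# The default configuration plants four tumor classes of 40 samples each
# (CCA, CCA-Like, Blast-Like, HCC) plus 10 tumor-adjacent normals.

library(hccsubtypes)

cfg <- sim_config(n_normal = 10L, seed = 42L)
cohort <- simulate_cohort(cfg)

out <- "results/cohort"
write_cohort(cohort, out)

classes <- table(cohort$truth$true_class)
cat("cohort written to", out, "\n")
cat("samples per class:\n")
print(classes)
cat("genes:", nrow(cohort$expr),
    " variants:", nrow(cohort$variants),
    " CN features:", nrow(cohort$cn$values), "\n")
cat("median mutations/sample:",
    median(table(cohort$variants$sample_id)), "\n")
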