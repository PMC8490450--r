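#!/usr/bin/env Rscript
# Reference-anchored subtype classification of the simulated cohort:
# filter to the most variable genes, median-center, correlate every sample
# to the cohort CCA centroid (Spearman), call CCA-Like above the
# mean - 1 SD threshold, then Blast-Like in the upper hepatoblast-
# correlation tertile. Also computes the bile-duct-vs-liver
# differentiation score per sample.

library(hccsubtypes)

expr <- read_expression("results/cohort/expression.tsv")
cent <- read_expression("results/cohort/centroids.tsv")
attr(cent, "is_centered") <- NULL
truth <- read.delim("results/cohort/truth.tsv", stringsAsFactors = FALSE)
centroids <- lapply(as.data.frame(cent), setNames, rownames(cent))

cca_ids <- truth$sample_id[truth$true_class == "CCA"]
normal_ids <- truth$sample_id[truth$true_class == "Normal"]

config <- list(min_expr = 1, min_expr_fraction = 0.7, top_n_variable = 1000L)
asg <- assign_subtypes(expr, cca_ids, centroids, config = config,
                       normal_ids = normal_ids)

# bile-duct vs liver differentiation score on the centered filtered matrix
genes <- filter_genes(expr, config$min_expr, config$min_expr_fraction,
                      config$top_n_variable)
centered <- median_center(expr[genes, ])
rho_nbd <- spearman_to_centroid(centered, centroids$NBD)
rho_liver <- spearman_to_centroid(centered, centroids$Liver)
asg$nbd_vs_liver_score <- differentiation_score(rho_nbd, rho_liver)[asg$sample_id]

write.table(asg, "results/02_subtype_assignments.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

conf <- table(truth = truth$true_class[match(asg$sample_id, truth$sample_id)],
              predicted = asg$label)
cat("classification threshold (CCA mean - 1 SD):",
    round(asg$threshold_used[1], 4), "\n")
cat("hepatoblast tertile cutoff:", round(asg$tertile_cutoff_used[1], 4), "\n")
cat("confusion matrix:\n"); print(conf)
cat("label recovery:",
    round(100 * mean(asg$label == truth$true_class[
      match(asg$sample_id, truth$sample_id)]), 2), "%\n")
cat("median NBD-vs-liver score by predicted label:\n")
print(round(tapply(asg$nbd_vs_liver_score, asg$label, median), 3))
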