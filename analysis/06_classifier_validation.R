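#!/usr/bin/env Rscript
# Nearest-centroid classifier: train a 150-gene ClaNC-style classifier on
# the HCC tumor classes of the cohort, then predict an independent
# validation cohort carrying a cohort-wide per-gene batch shift — the
# cross-cohort setting that the median-centering convention is meant to
# absorb.

library(hccsubtypes)

expr <- read_expression("results/cohort/expression.tsv")
asg <- read.delim("results/02_subtype_assignments.tsv", stringsAsFactors = FALSE)
labels <- setNames(asg$label, asg$sample_id)
train_ids <- names(labels)[labels %in% c("CCA-Like", "Blast-Like", "HCC")]

genes <- filter_genes(expr, 1, 0.7, 1000L)
centered <- median_center(expr[genes, train_ids])
clf <- train_clanc(centered, labels[train_ids], total_genes = 150L)
write.table(clf$genes, "results/06_classifier_genes.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write_expression(clf$centroids, "results/06_classifier_centroids.tsv",
                 id_column = "gene_id")
cat("classifier: ", nrow(clf$centroids), "genes,",
    paste(clf$classes, collapse = "/"), "\n")

# independent validation cohort, plus a global per-gene batch shift
val <- simulate_cohort(sim_config(seed = 4242L))
truth_val <- val$truth$true_class
val_ids <- names(truth_val)[truth_val != "CCA"]
set.seed(99)
shifted <- unclass(val$expr) + rnorm(nrow(val$expr), 0, 1)
pred <- predict(clf, median_center(shifted[genes, val_ids]))
write.table(pred, "results/06_validation_predictions.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

conf <- table(truth = truth_val[pred$sample_id], predicted = pred$label)
cat("validation confusion matrix:\n"); print(conf)
cat("validation accuracy:",
    round(100 * mean(pred$label == truth_val[pred$sample_id]), 2), "%\n")
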