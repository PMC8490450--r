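#!/usr/bin/env Rscript
# Derived expression statistics on the classified cohort: program module
# scores per sample, a high/low grouping with Fisher-exact class enrichment,
# and per-gene differential expression (Welch t + BH) for the two contrasts
# of interest: CCA-Like vs Blast-Like/HCC, and CCA-Like vs CCA.

library(hccsubtypes)

expr <- read_expression("results/cohort/expression.tsv")
cent <- read_expression("results/cohort/centroids.tsv")
asg <- read.delim("results/02_subtype_assignments.tsv", stringsAsFactors = FALSE)
labels <- setNames(asg$label, asg$sample_id)

# derive program gene sets from the reference centroids: the 50 genes most
# specific to each program (centroid minus the mean of the other two)
programs <- c("hepatocyte", "cholangiocyte", "hepatoblast")
sets <- lapply(programs, function(p) {
  contrast <- cent[, p] - rowMeans(cent[, setdiff(programs, p)])
  rownames(cent)[order(contrast, decreasing = TRUE)[1:50]]
})
names(sets) <- paste0(programs, "_signature")
write_gmt(sets, "results/03_program_signatures.gmt")

centered <- median_center(expr)
scores <- vapply(sets, function(g) module_score(centered, g),
                 numeric(ncol(expr)))
write.table(data.frame(sample_id = rownames(scores), scores),
            "results/03_module_scores.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("median module score by class (rows: class):\n")
print(round(apply(scores, 2, tapply, labels[rownames(scores)], median), 3))

# high/low grouping over the program signatures and enrichment vs HCC
grp <- immune_grouping(centered, sets)
tumors <- names(labels)[labels != "Normal"]
enrich <- class_enrichment(grp$group[tumors], labels[tumors], "HCC")
write.table(enrich, "results/03_group_enrichment.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("\nhigh/low enrichment vs HCC (Fisher exact):\n")
print(enrich, digits = 3)

# differential expression, CCA-Like against its two comparators
cl <- names(labels)[labels == "CCA-Like"]
rest <- names(labels)[labels %in% c("Blast-Like", "HCC")]
cca <- names(labels)[labels == "CCA"]
de1 <- differential_expression(expr, cl, rest)
de2 <- differential_expression(expr, cl, cca)
de1$gene <- rownames(de1); de2$gene <- rownames(de2)
write.table(de1, "results/03_de_ccalike_vs_blast_hcc.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(de2, "results/03_de_ccalike_vs_cca.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("\nCCA-Like vs Blast-Like/HCC: ",
    sum(de1$fdr < 0.05 & abs(de1$log2_fold_change) > 1),
    "genes at FDR < 0.05 and |log2 FC| > 1\n")
cat("CCA-Like vs CCA:            ",
    sum(de2$fdr < 0.05 & abs(de2$log2_fold_change) > 1),
    "genes at FDR < 0.05 and |log2 FC| > 1\n")
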