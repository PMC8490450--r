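#!/usr/bin/env Rscript
# Class-level copy-number landscape comparison: per-class mean tracks and
# pairwise differences, per-gene Welch tests, segment-wise Fisher tests
# under BH control for every comparison of interest, anchor-gene alteration
# frequencies (BAP1 / FOXC1 / MYC) and expression-copy-number correlation.

library(hccsubtypes)

cn <- read_copy_number("results/cohort/cn_values.tsv",
                       "results/cohort/cn_calls.tsv",
                       "results/cohort/cn_features.tsv")
expr <- read_expression("results/cohort/expression.tsv")
asg <- read.delim("results/02_subtype_assignments.tsv", stringsAsFactors = FALSE)
labels <- setNames(asg$label, asg$sample_id)
tumors <- names(labels)[labels != "Normal"]
cn$values <- cn$values[, tumors]
cn$calls <- cn$calls[, tumors]

tracks <- class_mean_cn(cn, labels[tumors])
write.table(tracks$means, "results/05_class_mean_cn.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(tracks$differences, "results/05_class_diff_cn.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

tt <- pairwise_cn_ttest(cn, labels[tumors], "CCA", "HCC")
write.table(tt, "results/05_ttest_cca_vs_hcc.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("CCA vs HCC: ", sum(tt$significant),
    "of", nrow(tt), "genes differ at p < 0.05 (Welch)\n")

comparisons <- list(c("CCA-Like", "CCA"), c("CCA-Like", "HCC"),
                    c("Blast-Like", "CCA"), c("Blast-Like", "HCC"))
cat("\nsegment-wise Fisher tests (loss direction, BH < 0.05):\n")
for (cmp in comparisons) {
  seg <- segment_fisher(cn, labels[tumors], cmp[1], cmp[2], "loss")
  f <- sprintf("results/05_segments_%s_vs_%s.tsv",
               gsub("-", "", tolower(cmp[1])), gsub("-", "", tolower(cmp[2])))
  write.table(seg, f, sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("  %-11s vs %-4s: %4d significant segments\n",
              cmp[1], cmp[2], attr(seg, "n_significant")))
}

cat("\nanchor-gene alteration frequency by class (%):\n")
freq <- rbind(
  BAP1_loss = 100 * gene_alteration_frequency(cn, "BAP1", labels[tumors], "loss"),
  FOXC1_gain = 100 * gene_alteration_frequency(cn, "FOXC1", labels[tumors], "gain"),
  MYC_gain = 100 * gene_alteration_frequency(cn, "MYC", labels[tumors], "gain"))
print(round(freq, 1))
write.table(data.frame(alteration = rownames(freq), freq),
            "results/05_anchor_gene_frequencies.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("\nexpression-copy-number correlation:\n")
for (g in c("BAP1", "MYC", "FOXC1")) {
  res <- suppressWarnings(
    expr_cn_correlation(expr[, tumors], cn, g, labels[tumors]))
  ov <- res[res$class == "overall", ]
  cat(sprintf("  %-5s overall r = %5.2f (p = %.2e)\n", g, ov$r, ov$p_value))
  write.table(res, sprintf("results/05_expr_cn_%s.tsv", tolower(g)),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
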