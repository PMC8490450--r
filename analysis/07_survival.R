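#!/usr/bin/env Rscript
# Five-year-censored survival comparison across the classified subtypes:
# Kaplan-Meier curves and median times, the k-group log-rank test,
# univariate Cox models for class / stage / grade, and the multivariate
# model combining class with any univariately significant clinical
# covariate (referent class: HCC).

library(hccsubtypes)

clinical <- read_clinical("results/cohort/clinical.tsv")
asg <- read.delim("results/02_subtype_assignments.tsv", stringsAsFactors = FALSE)
clinical$label <- asg$label[match(clinical$sample_id, asg$sample_id)]
cl5 <- censor_at(clinical, 1826)

curves <- lapply(split(cl5, cl5$label), function(d)
  km_estimate(d$time_days, d$event))
km_tab <- do.call(rbind, lapply(names(curves), function(cl)
  data.frame(class = cl, time = curves[[cl]]$time,
             at_risk = curves[[cl]]$at_risk, events = curves[[cl]]$events,
             surv = curves[[cl]]$surv)))
write.table(km_tab, "results/07_km_curves.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("median time-to-event (days, 5-year censored):\n")
print(vapply(curves, function(k) k$median_time, numeric(1)))

lr <- logrank_test(cl5$time_days, cl5$event, cl5$label)
cat(sprintf("\nlog-rank: chi-square = %.2f, df = %d, p = %.2e\n",
            lr$chisq, lr$df, lr$p_value))

cat("\nunivariate Cox models:\n")
uni <- list()
for (cv in c("label", "stage", "grade")) {
  fit <- cox_fit(cl5, cv, referents = list(label = "HCC", stage = "I",
                                           grade = "G1"))
  uni[[cv]] <- fit$table
  cat(" ", cv, ":\n")
  print(fit$table, digits = 3)
}
write.table(do.call(rbind, uni), "results/07_cox_univariate.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

# multivariate: class plus univariately significant clinical covariates
keep <- c("label",
          names(uni)[-1][vapply(uni[-1], function(t) any(t$p_value < 0.05),
                                logical(1))])
cat("\nmultivariate covariates:", paste(keep, collapse = " + "), "\n")
multi <- cox_fit(cl5, keep, referents = list(label = "HCC", stage = "I",
                                             grade = "G1"))
print(multi$table, digits = 3)
write.table(multi$table, "results/07_cox_multivariate.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
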