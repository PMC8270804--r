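#!/usr/bin/env Rscript
# Step 4: ROC analysis and high-sensitivity cutoffs.
#
# Training-set ROC, test-set ROC, cutoffs C1 (training sensitivity 100%)
# and C2 (>= 95%) identified on the training set and applied unchanged to
# the test set; the specificity at each cutoff is the fraction of
# avoidable benign biopsies.

suppressPackageStartupMessages(library(breastdce))
pred <- read.csv("results/predictions.csv")

tr <- pred$split == "train"
roc_tr <- roc_curve(pred$pseudo_probability[tr], pred$label[tr])
roc_te <- roc_curve(pred$pseudo_probability[!tr], pred$label[!tr])
cat("training: "); print(roc_tr)
cat("test:     "); print(roc_te)

thresholds <- c(
  C1 = as.numeric(find_sensitivity_cutoff(pred$pseudo_probability[tr],
                                          pred$label[tr], 1.00)),
  C2 = as.numeric(find_sensitivity_cutoff(pred$pseudo_probability[tr],
                                          pred$label[tr], 0.95)))
cat(sprintf("cutoffs: C1 > %.4f, C2 > %.4f\n", thresholds["C1"],
            thresholds["C2"]))

reports <- evaluate_cutoffs(pred$pseudo_probability[!tr], pred$label[!tr],
                            thresholds, pred$lesion_id[!tr])
for (nm in names(reports)) {
  cat("\n--", nm, "on the test set --\n")
  print(reports[[nm]])
  if (length(reports[[nm]]$false_negative_ids))
    cat(" missed cancers:", paste(reports[[nm]]$false_negative_ids,
                                  collapse = ", "), "\n")
}

write.csv(roc_te$points, "results/roc_test.csv", row.names = FALSE)
summary <- data.frame(
  cutoff = names(reports),
  threshold = thresholds,
  sensitivity_pct = sapply(reports, function(r) 100 * r$sensitivity),
  specificity_pct = sapply(reports, function(r) 100 * r$specificity),
  avoidable_biopsies_pct = sapply(reports, function(r)
    100 * r$avoidable_biopsy_fraction),
  n_false_negative = sapply(reports, function(r)
    length(r$false_negative_ids)))
write.csv(summary, "results/cutoff_summary.csv", row.names = FALSE)
cat("\nwrote results/roc_test.csv and results/cutoff_summary.csv\n")
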