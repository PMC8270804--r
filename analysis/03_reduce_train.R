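#!/usr/bin/env Rscript
# Step 3: dimension reduction and classifier training.
#
# 70/30 random split, correlation-matrix PCA on the training lesions
# (eigenvalue > 3 retained), architecture-searched MLP trained by scaled
# conjugate gradient, pseudo-probabilities predicted for every lesion.

suppressPackageStartupMessages(library(breastdce))
feats <- read.csv("results/features.csv", check.names = FALSE)

seed <- 470L
cfg <- study_config()
X <- as.matrix(feats[, -(1:3)])
sp <- split_cohort(feats$label, cfg$train_fraction, seed = seed + 1L)

pca <- suppressWarnings(fit_pca(X[sp$train, ], cfg$pca_cutoff))
print(pca)
scores <- pca_project(pca, X)

mlpcfg <- cfg$mlp
mlpcfg$seed <- seed + 2L
mlp <- train_mlp(scores[sp$train, ], feats$label[sp$train], mlpcfg)
print(mlp)

out <- data.frame(lesion_id = feats$lesion_id, label = feats$label,
                  split = ifelse(seq_len(nrow(feats)) %in% sp$train,
                                 "train", "test"),
                  pseudo_probability = predict_pseudo_probability(mlp, scores))
write.csv(out, "results/predictions.csv", row.names = FALSE)
write_pca_json(pca, "results/pca_model.json")
write_mlp_json(mlp, "results/mlp_model.json")
cat(sprintf("split: %d train (%d malignant) / %d test (%d malignant)\n",
            length(sp$train), sum(out$label[sp$train] == "malignant"),
            length(sp$test), sum(out$label[sp$test] == "malignant")))
cat("wrote results/predictions.csv, pca_model.json, mlp_model.json\n")
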