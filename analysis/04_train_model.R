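#!/usr/bin/env Rscript
# Split the feature table 60/20/20 (class- and volume-balanced), rank
# features by mRMR on the training rows, choose the feature count by
# stratified threefold cross-validated balanced accuracy over the pooled
# training + validation rows, and fit the class-weighted L2 logistic
# model (C = 1, max_iter = 10, 'balanced' weights, intercept).

suppressMessages(library(cribromics))
suppressMessages(library(data.table))

features <- fread("results/features.csv")
features$target <- as.integer(features$label == "GP4Crib+")
seed <- 20260930
features <- split_dataset(features, seed = seed)
fwrite(features, "results/features_split.csv")

meta <- c("case_id", "region_id", "label", "volume_cc", "split", "target")
candidates <- setdiff(names(features), meta)
train <- features[split == "train"]
ranking <- mrmr_rank(as.matrix(train[, ..candidates]), train$target,
                     max_features = 20)
cat("Top 5 mRMR-ranked features:\n")
print(data.table(rank = 1:5, feature = ranking$features[1:5],
                 score = round(ranking$scores[1:5], 4)))

sel <- suppressWarnings(
  select_feature_count_cv(features, ranking, k_max = 20, seed = seed + 1))
cat("\nChosen feature count k =", sel$k, "\n")

feats <- ranking$features[seq_len(sel$k)]
fit_rows <- features[split %in% c("train", "validation")]
model <- suppressWarnings(
  fit_logistic(as.matrix(fit_rows[, ..feats]), fit_rows$target))
cribromics:::write_model_json(model, "results/model.json")

cat("\nModel: intercept", round(model$intercept, 3), "\n")
print(round(model$coefficients, 4))
if (sel$k == 1) {
  cat("\nSingle-feature model; decision boundary at",
      round(decision_boundary_1d(model), 3), "\n")
}
cat("\nModel written to results/model.json\n")
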