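#!/usr/bin/env Rscript
# Evaluate the fitted model on the held-out test rows: balanced accuracy,
# ROC AUC, PR AUC, sensitivity and specificity with 1000-replicate
# percentile bootstrap CIs, plus the one-sided comparison against the
# all-negative baseline (balanced accuracy 0.5).

suppressMessages(library(cribromics))
suppressMessages(library(data.table))
suppressMessages(library(jsonlite))

features <- fread("results/features_split.csv")
model <- cribromics:::read_model_json("results/model.json")
feats <- names(model$coefficients)

test <- features[split == "test"]
p <- predict_probability(model, test[, ..feats])
preds <- data.table(region_id = test$region_id, label = test$label,
                    target = test$target, probability = p,
                    predicted = as.integer(p >= model$threshold))
fwrite(preds, "results/predictions.csv")

report <- bootstrap_metrics(test$target, p, n_boot = 1000,
                            seed = 20260930)
print(report)

write_json(list(point = as.list(report$point), ci = report$ci,
                baseline_delta = report$baseline_delta,
                p_value = report$p_value, n_boot = report$n_boot),
           "results/report.json", auto_unbox = TRUE, digits = NA,
           dataframe = "rows")
cat("\nReport written to results/report.json\n")
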