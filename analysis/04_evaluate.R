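#!/usr/bin/env Rscript
# Step 4 — epoch-by-epoch agreement evaluation of the LOOCV predictions:
# LV->WK merge, ordinal encoding, per-subject and pooled confusion
# matrices, the three printed metrics (balanced accuracy, pooled-Youden
# kappa, F1), per-class metrics, a label-shuffled chance control, and
# metric-vs-covariate correlations. Run after 03_train_loocv.R.

library(cardiosleep)

if (!dir.exists("scratch/loocv")) stop("run analysis/03_train_loocv.R first")
ids <- sub("_pred\\.txt$", "",
           list.files("scratch/loocv", pattern = "_pred\\.txt$"))
pairs <- lapply(ids, function(id) list(
  true = read_hypnogram(file.path("scratch/loocv", paste0(id, "_true.txt"))),
  pred = read_hypnogram(file.path("scratch/loocv", paste0(id, "_pred.txt")))))
names(pairs) <- ids

ahi <- read.csv("results/cohort_stage_mix.csv")$ahi[match(
  ids, read.csv("results/cohort_stage_mix.csv")$subject)]
cs <- cohort_summary(pairs, covariates = data.frame(ahi = ahi))

pooled <- confusion_matrix5(
  unlist(lapply(pairs, function(p) merge_and_encode(p$true))),
  unlist(lapply(pairs, function(p) merge_and_encode(p$pred))))
write.csv(as.data.frame.matrix(unclass(pooled)), "results/confusion.csv")

set.seed(72)
t_all <- unlist(lapply(pairs, function(p) merge_and_encode(p$true)))
p_all <- unlist(lapply(pairs, function(p) merge_and_encode(p$pred)))
k_shuf <- mean(replicate(200,
  overall_metrics(confusion_matrix5(sample(t_all), p_all))["kappa"]))

out <- list(
  per_subject = cs$per_subject,
  cohort_mean = as.list(cs$mean), cohort_sd = as.list(cs$sd),
  per_class = per_class_metrics(pooled),
  kappa_cohen_pooled = kappa_cohen(pooled),
  shuffled_control_kappa = k_shuf,
  covariate_correlations = cs$correlations)
jsonlite::write_json(out, "results/metrics.json", auto_unbox = TRUE,
                     digits = 6, dataframe = "rows")

message(sprintf(
  "Cohort mean +/- SD: accuracy %.3f +/- %.3f, kappa %.3f +/- %.3f, F1 %.3f +/- %.3f",
  cs$mean["accuracy"], cs$sd["accuracy"], cs$mean["kappa"], cs$sd["kappa"],
  cs$mean["f1"], cs$sd["f1"]))
message(sprintf("Shuffled-label control kappa: %.4f (chance level)", k_shuf))
message("Pooled confusion matrix in results/confusion.csv; full report in results/metrics.json")
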