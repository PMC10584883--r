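#!/usr/bin/env Rscript
# Step 3 — leave-one-subject-out training and prediction with the
# desk-scale biLSTM profile (1 layer x 32 units; the full-scale profile is
# stager_config()). Each fold trains on 11 nights with the held-out night
# as the early-stopping validation set, then predicts it. Run after
# 02_features.R. Takes a few minutes on one CPU.

library(cardiosleep)

if (!dir.exists("scratch/features")) stop("run analysis/02_features.R first")
ids <- sub("\\.csv$", "", list.files("scratch/features", pattern = "^S\\d+\\.csv$"))
feats <- list(); labs <- list()
for (id in ids) {
  feats[[id]] <- read_features(file.path("scratch/features", paste0(id, ".csv")))
  labs[[id]] <- read_hypnogram(file.path("scratch/features",
                                         paste0(id, "_labels.txt")))
}

res <- loocv(feats, labs, fast_stager_config(seed = 71))

dir.create("scratch/loocv", showWarnings = FALSE)
for (id in names(res)) {
  write_hypnogram(res[[id]]$pred,
                  file.path("scratch/loocv", paste0(id, "_pred.txt")))
  write_hypnogram(res[[id]]$true,
                  file.path("scratch/loocv", paste0(id, "_true.txt")))
}
h <- res[[1]]$model$history
write.csv(within(h, {
  train_loss <- round(train_loss, 5); val_loss <- round(val_loss, 5)
  val_acc <- round(val_acc, 4); grad_norm <- round(grad_norm, 5)
}), "results/training_history_fold1.csv", row.names = FALSE)

message("Fold 1 trained for ", nrow(h), " epochs; final val loss ",
        round(tail(h$val_loss, 1), 4), ", val accuracy ",
        round(tail(h$val_acc, 1), 4))
message("Learning-rate steps observed: ",
        paste(unique(h$lr), collapse = " -> "),
        "; max post-clip gradient norm ", round(max(h$grad_norm), 3))
message("Wrote scratch/loocv/ and results/training_history_fold1.csv")
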