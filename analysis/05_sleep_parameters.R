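#!/usr/bin/env Rscript
# Step 5 — sleep parameters (TST, SL, WASO, REM%, NREM%, SE) from the
# reference and predicted hypnograms, and their agreement: paired t,
# Pearson r, Deming regression, Bland-Altman bias and limits of agreement,
# and the proportional-bias Spearman test. Run after 03_train_loocv.R.

library(cardiosleep)

if (!dir.exists("scratch/loocv")) stop("run analysis/03_train_loocv.R first")
ids <- sub("_pred\\.txt$", "",
           list.files("scratch/loocv", pattern = "_pred\\.txt$"))
pairs <- lapply(ids, function(id) list(
  true = read_hypnogram(file.path("scratch/loocv", paste0(id, "_true.txt"))),
  pred = read_hypnogram(file.path("scratch/loocv", paste0(id, "_pred.txt")))))
names(pairs) <- ids

per <- do.call(rbind, lapply(ids, function(id) {
  ref <- sleep_parameters(pairs[[id]]$true, strip_padding = TRUE)
  prd <- sleep_parameters(pairs[[id]]$pred, strip_padding = TRUE)
  cbind(subject = id, source = c("psg", "predicted"), rbind(ref, prd))
}))
per[, 3:9] <- round(per[, 3:9], 2)
write.csv(per, "results/sleep_params.csv", row.names = FALSE)

tbl <- suppressWarnings(compare_sleep_parameters(pairs, strip_padding = TRUE))
num <- vapply(tbl, is.numeric, logical(1))
tbl[num] <- lapply(tbl[num], round, 4)
write.csv(tbl, "results/agreement.csv", row.names = FALSE)

message("Parameter agreement (bias = predicted - reference):")
print(tbl[, c("parameter", "ref_mean", "pred_mean", "bias",
              "loa_lower", "loa_upper", "deming_slope", "pearson_r")])
message("Wrote results/sleep_params.csv and results/agreement.csv")
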