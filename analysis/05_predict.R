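#!/usr/bin/env Rscript
# Stage 5: random-forest prediction of the binary PVI changes from the
# nine baseline risk factors: all 511 predictor combinations, five-fold
# cross-validation repeated `n_repeats` times, 50 trees. The full
# 100-repeat sweep over five indices is a long run; n_repeats is set
# lower here and can be raised for a final pass.

library(capmech)

n_repeats <- 10L   # raise to 100 for a final full-length pass
seed <- 1L

features <- read.csv("results/features.csv", stringsAsFactors = FALSE)
bl <- features[features$timepoint == "baseline", ]
morph <- bl[, c("slice_id", "patient_id", "timepoint",
                "LA", "PA", "PB", "MinCapT", "MeanCapT")]
mech <- bl[, c("slice_id", "MaxCapS", "MeanCapS", "MaxCapSn", "MeanCapSn")]

results <- list()
for (idx in c("C", "MaxS", "MeanS", "MaxSn", "MeanSn")) {
  oc <- read.csv(sprintf("results/outcomes_%s.csv", idx),
                 stringsAsFactors = FALSE)
  ids <- intersect(morph$slice_id, oc$slice_id)
  if (length(unique(oc$binary[oc$slice_id %in% ids])) < 2) {
    cat(sprintf("%s-PVI: single-class outcomes, skipped\n", idx))
    next
  }
  tab <- assemble_features(morph[morph$slice_id %in% ids, ],
                           mech[mech$slice_id %in% ids, ],
                           oc[oc$slice_id %in% ids, ])
  sw <- sweep_combinations(tab, seed = seed, n_repeats = n_repeats,
                           progress = TRUE)
  write.csv(sw, sprintf("results/prediction_%s.csv", idx),
            row.names = FALSE)
  results[[idx]] <- sw
  cat(sprintf("%s-PVI: best %s (acc %.3f, auc %.3f); best single %s (acc %.3f)\n",
              idx, sw$predictor_subset[1], sw$acc[1], sw$auc[1],
              sw$predictor_subset[which(sw$n_predictors == 1)[1]],
              sw$acc[which(sw$n_predictors == 1)[1]]))
}

if (length(results) > 1) {
  rep <- improvement_report(results)
  write.csv(rep$per_pvi, "results/improvement_report.csv", row.names = FALSE)
  cat(sprintf("mean accuracy improvement of best combination over best single: %.1f points\n",
              rep$summary$mean_improvement_pts))
  cat(sprintf("mean best-combination AUC: %.3f\n", rep$summary$mean_auc))
}
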