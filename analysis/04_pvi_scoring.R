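#!/usr/bin/env Rscript
# Stage 4: score the five plaque vulnerability indices. C-PVI uses the
# published cap-thickness cuts; the stress/strain cuts are calibrated so
# that each index best matches baseline C-PVI (the same construction the
# published cuts came from), then baseline -> follow-up changes are
# reduced to binary outcomes.

library(capmech)

features <- read.csv("results/features.csv", stringsAsFactors = FALSE)
bl <- features[features$timepoint == "baseline", ]
thr <- list(C = pvi_thresholds("C"))
c_lab <- score_pvi(bl$MinCapT, thr$C)
for (idx in c("MaxS", "MeanS", "MaxSn", "MeanSn")) {
  meas <- capmech:::PVI_MEASURES[[idx]]
  ok <- is.finite(bl[[meas]])
  thr[[idx]] <- calibrate_thresholds(bl[[meas]][ok], c_lab[ok], idx)
  cat(sprintf("%s-PVI cuts: %s (match rate with C-PVI %.2f)\n", idx,
              paste(signif(thr[[idx]]$cuts, 4), collapse = ", "),
              attr(thr[[idx]], "match_rate")))
}
yaml::write_yaml(
  lapply(thr, function(t) list(index = t$index_name, cuts = t$cuts,
                               orientation = t$orientation,
                               match_rate = attr(t, "match_rate"))),
  "results/thresholds.yaml")

for (idx in names(thr)) {
  oc <- pvi_outcomes(features, idx, thr[[idx]])
  write.csv(oc, sprintf("results/outcomes_%s.csv", idx), row.names = FALSE)
  cat(sprintf("%s-PVI: %d positive / %d negative changes\n", idx,
              sum(oc$binary > 0), sum(oc$binary < 0)))
}
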