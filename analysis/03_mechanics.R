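#!/usr/bin/env Rscript
# Stage 3: per slice, recover the zero-load geometry (5% axial shrink,
# circumferential shrink matched to the in-vivo lumen area at systolic
# pressure), solve the thin-slice anisotropic Mooney-Rivlin model, and
# extract the cap stress/strain predictors at the 100 even-spaced lumen
# points. This is the expensive stage (a few seconds per slice;
# both timepoints of the full cohort take a couple of hours).

library(capmech)

files <- list.files("results/cohort", pattern = "\\.json$", full.names = TRUE)
stopifnot(length(files) > 0)
rows <- list()
t0 <- Sys.time()
for (i in seq_along(files)) {
  sl <- read_slice(files[[i]])
  rows[[i]] <- slice_features(sl)
  if (i %% 20 == 0) {
    cat(sprintf("  %d/%d slices (%.1f min elapsed)\n", i, length(files),
                as.numeric(Sys.time() - t0, units = "mins")))
  }
}
features <- do.call(rbind, rows)
write.csv(features, "results/features.csv", row.names = FALSE)

bl <- features[features$timepoint == "baseline", ]
cat(sprintf("mechanics for %d slices\n", nrow(features)))
cat(sprintf("baseline: MaxCapS median %.0f kPa, MaxCapSn median %.3f, circ shrink %.3f +/- %.3f\n",
            median(bl$MaxCapS), median(bl$MaxCapSn),
            mean(bl$circ_shrink), sd(bl$circ_shrink)))
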