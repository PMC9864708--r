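#!/usr/bin/env Rscript
# Stage 2: read the cohort contour files back and compute the
# morphological risk factors (LA, PA, PB, MinCapT, MeanCapT) per slice.

library(capmech)

files <- list.files("results/cohort", pattern = "\\.json$", full.names = TRUE)
stopifnot(length(files) > 0)
morph <- do.call(rbind, lapply(files, function(f) morphology(read_slice(f))))
dir.create("results", showWarnings = FALSE)
write.csv(morph, "results/morphology.csv", row.names = FALSE)

bl <- morph[morph$timepoint == "baseline", ]
cat(sprintf("morphology for %d slices (%d baseline)\n", nrow(morph), nrow(bl)))
cat(sprintf("baseline: LA %.2f +/- %.2f mm^2, PB %.2f +/- %.2f, MinCapT median %.2f mm\n",
            mean(bl$LA), sd(bl$LA), mean(bl$PB), sd(bl$PB),
            median(bl$MinCapT, na.rm = TRUE)))
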