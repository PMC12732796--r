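#!/usr/bin/env Rscript
# TM6 opening: the TM2-TM6 C-alpha distance (positions 2.39 / 6.33).
#
# Generates a two-basin scenario in which TM6 itself is the mobile group
# (closed state at the build geometry, open state displaced 4.2 A outward)
# and summarizes the bimodal distance distribution across the ensemble.

suppressMessages(library(gik))
out <- "results/analysis/05_tm_opening"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 1L

# open-state displacement along the outward radial direction of TM6
a6 <- 2 * pi * 5 / 7
open_disp <- 4.2 * c(cos(a6), sin(a6), 0)
spec <- scenario_spec(
  seed = seed, n_replicates = 6L, frames_per_replicate = 300L,
  basins = list(
    list(fraction = 0.45, displacement = c(0, 0, 0), rotation = 0),
    list(fraction = 0.45, displacement = open_disp, rotation = 0)),
  noise_sigma = 0.3, mobile = "TM6")
ens <- make_ensemble(spec)
cx <- attr(ens, "complex")

tm <- tm_distance_series(ens, cx$receptor_map, "6.33", "2.39")
write.table(tm, file.path(out, "tm2_tm6_distance.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

truth <- attr(ens, "truth")$basin_of_frame
qs <- quantile(tm$distance, c(0.05, 0.25, 0.5, 0.75, 0.95))
cat("TM2-TM6 distance (6.33 <-> 2.39), all analyzed frames:\n")
print(round(qs, 2))
for (b in 1:2)
  cat(sprintf("  basin %d mean: %.2f A (n = %d)\n",
              b, mean(tm$distance[truth == b]), sum(truth == b)))
cat(sprintf("Finding: the open basin sits %.1f A wider than the closed one.\n",
            mean(tm$distance[truth == 2]) - mean(tm$distance[truth == 1])))
cat("Distance series written under", out, "\n")
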