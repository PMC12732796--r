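#!/usr/bin/env Rscript
# Block-averaged RMSD statistics.
#
# Two parts: (a) the across-replicate estimator applied to the twelve
# published per-replicate mean RMSDs (degenerate one-block series), which
# must give 2.28 +/- 0.07 A; (b) the full path on a simulated ensemble:
# per-frame superposed C-alpha RMSD of the alpha5 helix against the build
# topology, 50-frame blocks, per-replicate and across-replicate summaries.

suppressMessages(library(gik))
out <- "results/analysis/06_block_rmsd"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 1L

replicate_means <- c(2.69, 2.21, 2.08, 2.11, 2.10, 2.55,
                     2.02, 2.19, 2.65, 2.43, 2.21, 2.08)
bs0 <- block_stats(as.list(replicate_means), block_size = 1)
cat(sprintf("Published replicate means recombined: %.2f +/- %.2f A\n",
            bs0$ensemble_mean, bs0$ensemble_sem))

ens <- make_ensemble(scenario_spec(seed = seed))
cx <- attr(ens, "complex")
sel <- intersect(select_atoms(ens$topology, segment = "H5",
                              map = cx$galpha_map),
                 select_atoms(ens$topology, atom = "CA"))
series <- rmsd_series(ens, sel, superpose = TRUE)
bs <- block_stats(series, block_size = 50L)
print(bs)
write.table(bs$per_replicate, file.path(out, "block_rmsd_per_replicate.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
summary_df <- data.frame(block_size_frames = bs$block_size_frames,
                         ensemble_mean_A = round(bs$ensemble_mean, 2),
                         ensemble_sem_A = round(bs$ensemble_sem, 2))
write.table(summary_df, file.path(out, "block_rmsd_summary.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("Simulated ensemble: %.2f +/- %.3f A over %d replicates (50-frame blocks)\n",
            bs$ensemble_mean, bs$ensemble_sem, nrow(bs$per_replicate)))
cat("The narrow replicate spread reflects the stationary generator:\n",
    "every replicate samples the same basin mixture.\n")
cat("Tables written under", out, "\n")
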