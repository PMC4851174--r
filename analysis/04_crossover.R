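#!/usr/bin/env Rscript
# Desk-scale analogue of the coalescent-vs-concatenation comparison: Yule
# species trees over a grid of expected root heights R and population sizes
# Ne give a broad range of mean branch lengths in coalescent units. Two
# surrogate estimators stand in for the inference methods: the
# coalescent-style arm has branch-length-independent noise, the
# concatenation-style arm degrades as coalescent branch lengths shrink
# (severe incomplete lineage sorting). The smoothed error ratio crosses 1 at
# a finite branch length: the crossover point.

suppressPackageStartupMessages(library(mscbench))

seed <- 20160128
grid <- expand.grid(R = c(0.5, 1, 2, 4, 8, 16), Ne = c(0.25, 0.5, 1),
                    rep = 1:6)
set.seed(seed %% 100000)

pts <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
  cfg <- experiment_config("exp2", n = 5, nl = 2, replicates = 1,
                           seed = seed + i, R = grid$R[i], Ne = grid$Ne[i])
  b <- generate(cfg, sim_alignments = FALSE)[[1]]
  bmean <- mean_branch_length_coalescent(b$species_tree)
  e_coal <- relative_error(b$species_tree,
                           surrogate_estimate(b, noise = 0.4, k = 50))
  e_concat <- relative_error(b$species_tree,
                             surrogate_estimate(b, noise = 0.4 / bmean,
                                                k = 50))
  data.frame(R = grid$R[i], Ne = grid$Ne[i],
             branch_length = bmean,
             ratio = error_ratio(e_coal, e_concat))
}))
pts <- pts[is.finite(pts$ratio) & pts$ratio > 0, ]

dir.create("results", showWarnings = FALSE)
write.table(pts, "results/error_ratio_points.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

cross <- find_crossover(pts$branch_length, pts$ratio, span = 0.75)
cat(sprintf("error ratio points: %d; branch lengths span %.3f-%.3f coalescent units\n",
            nrow(pts), min(pts$branch_length), max(pts$branch_length)))
if (is.na(cross)) {
  cat("the smoothed error ratio never crosses 1: no crossover in this range\n")
} else {
  cat(sprintf("crossover point: %.3f coalescent units -- the coalescent-style\n", cross))
  cat("estimator wins below it, the concatenation-style one above it\n")
}
write.table(data.frame(crossover_coalescent_units = cross),
            "results/crossover.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
cat("wrote results/error_ratio_points.tsv, results/crossover.tsv\n")
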