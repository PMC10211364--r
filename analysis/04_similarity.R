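#!/usr/bin/env Rscript
# Beta diversity among sites: Bray-Curtis similarity on pooled per-site
# densities, UPGMA dendrogram with cophenetic correlation and species-
# bootstrap branch support. Run twice: on the shipped reference density
# table (the worked field data set) and on the simulated inventory.

suppressPackageStartupMessages(library(chronoveg))
dir.create("results", showWarnings = FALSE)
seed <- 2026

analyse <- function(abund, tag, n_reps = 999) {
  sim <- similarity_matrix(abund)
  d <- similarity_to_dist(sim)
  tree <- upgma(d)
  support <- branch_support(abund, n_reps = n_reps, seed = seed)
  write.csv(as.data.frame(unclass(sim)),
            sprintf("results/similarity_%s.csv", tag))
  write_newick(support, sprintf("results/dendrogram_%s.nwk", tag))
  cat("==", tag, "==\n")
  print(round(unclass(sim), 3))
  cat(sprintf("cophenetic correlation: %.3f\n",
              cophenetic_correlation(tree, d)))
  cat("newick:", write_newick(support), "\n\n")
}

analyse(thornscrub_abundance(), "reference")

if (!file.exists("results/synthetic_inventory.csv")) {
  source("analysis/01_simulate.R")
}
chrono <- read_inventory("results/synthetic_inventory.csv")
analyse(pooled_abundance(chrono), "synthetic")
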