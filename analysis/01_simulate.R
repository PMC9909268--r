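#!/usr/bin/env Rscript
# Stage 1: simulate the survey.
#
# Builds the factorial design (4 replicates x 4 treatments {control,
# glyphosate, nitrogen, both} x 3 vegetation communities x 2 seasons = 96
# soil samples), a 100-tip phylogeny, three kingdom ASV tables with
# moderate environmental filtering, and the 20-variable ecosystem-function
# matrix with a planted autumn deficit. Everything is written under
# results/simulated/ for the later stages.

suppressPackageStartupMessages(library(floodmicro))

seed <- 1
out_dir <- "results/simulated"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

design <- generate_design(4, c("CK", "G", "N", "GN"),
                          c("V1", "V2", "V3"), c("summer", "autumn"))
cat("design:", nrow(design), "samples,",
    length(unique(design$treatment)), "treatments,",
    length(unique(design$vegetation)), "vegetation communities,",
    length(unique(design$season)), "seasons\n")

sim <- simulation_config(n_taxa = 100, depth = 10000,
                         assembly_mode = "selection",
                         filtering_strength = 2,
                         season_effect = 1.5, noise_sd = 1, seed = seed)
tree <- generate_phylogeny(sim$n_taxa, seed = seed)

for (k in c("bacteria", "fungi", "protist")) {
  cfg <- sim
  cfg$seed <- seed + match(k, c("bacteria", "fungi", "protist"))
  tab <- generate_community_counts(tree, design, cfg)
  write_count_table(tab, file.path(out_dir, paste0("counts_", k, ".tsv")))
  cat(k, ": ", nrow(tab), " samples x ", ncol(tab), " taxa, occupancy ",
      round(mean(tab > 0), 2), "\n", sep = "")
}

ape::write.tree(tree, file.path(out_dir, "phylogeny.nwk"))
fm <- generate_function_matrix(design, sim)
floodmicro:::write_tsv_matrix(fm, file.path(out_dir, "function_matrix.tsv"),
                              "sample_id")
write.table(design, file.path(out_dir, "design.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("wrote", out_dir, "\n")
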