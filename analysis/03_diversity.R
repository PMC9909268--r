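#!/usr/bin/env Rscript
# Stage 3: alpha/beta diversity and community-environment tests.
#
# Observed richness, Shannon and Faith's PD per sample and kingdom;
# Bray-Curtis dissimilarity; one-factor PERMANOVA (season, treatment; 999
# permutations each); Mantel test between community dissimilarity and the
# standardized function-matrix distances.

suppressPackageStartupMessages(library(floodmicro))

in_dir <- "results/simulated"
out_dir <- "results/diversity"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
seed <- 1

design <- read.table(file.path(in_dir, "design.tsv"), header = TRUE,
                     sep = "\t")
tree <- ape::read.tree(file.path(in_dir, "phylogeny.nwk"))
std <- read_numeric_matrix("results/multifunctionality/standardized.tsv")

for (k in c("bacteria", "fungi", "protist")) {
  tab <- read_count_table(file.path(in_dir, paste0("counts_", k, ".tsv")),
                          orientation = "samples_in_rows")
  alpha <- alpha_diversity(tab, tree)
  write.table(alpha, file.path(out_dir, paste0("alpha_", k, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  bc <- bray_curtis(tab)
  floodmicro:::write_tsv_matrix(bc,
      file.path(out_dir, paste0("bray_curtis_", k, ".tsv")), "sample_id")

  season <- design$season[match(rownames(tab), design$sample_id)]
  treatment <- design$treatment[match(rownames(tab), design$sample_id)]
  pm_season <- permanova(bc, season, n_perm = 999, seed = seed)
  pm_trt <- permanova(bc, treatment, n_perm = 999, seed = seed + 1)
  mt <- mantel_test(bc, as.matrix(dist(std)), n_perm = 999,
                    seed = seed + 2)
  cat(sprintf(
    "%s: PERMANOVA season F = %.2f p = %.3f | treatment F = %.2f p = %.3f | Mantel r = %.3f p = %.3f\n",
    k, pm_season$f, pm_season$p, pm_trt$f, pm_trt$p, mt$r, mt$p))
  write.table(data.frame(test = c("permanova_season",
                                  "permanova_treatment", "mantel_function"),
                         statistic = c(pm_season$f, pm_trt$f, mt$r),
                         p = c(pm_season$p, pm_trt$p, mt$p)),
              file.path(out_dir, paste0("tests_", k, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
cat("wrote", out_dir, "\n")
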