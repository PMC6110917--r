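#!/usr/bin/env Rscript
# Step 6 — phylum-level gradient responses.
#
# Computes Spearman correlations of each phylum's relative abundance (and
# the alpha-diversity indices) against distance from trough, pH and EC,
# regionally and per basin, with Benjamini-Hochberg correction within each
# gradient column, and pairwise phylum-vs-phylum regressions along the
# EC-dominant (Fryxell-like) basin's transects.
#
# Needs: results/data from step 01.
# Writes: results/spearman_grid.tsv, results/phylum_regressions.tsv

library(soilscape)

seed <- 42L
community <- read_community("results/data/community.tsv")
meta <- read_metadata("results/data/metadata.tsv")
rar <- rarefy(community, depth = 500, seed = substream_seed(seed, "rarefy"))
ids <- rownames(rar$counts)

pa <- phylum_abundance(rar)
phyla <- setdiff(colnames(pa), "Other")
d <- cbind(meta[ids, ], pa[ids, phyla],
           observed_species = observed_species(rar)[ids],
           inverse_simpson = inverse_simpson(rar)[ids])

grid <- rbind(
  spearman_grid(d, rows = c(phyla, "observed_species", "inverse_simpson"),
                scope = "regional"),
  spearman_grid(d, rows = c(phyla, "observed_species", "inverse_simpson"),
                scope = "per_basin")
)
write.table(grid, "results/spearman_grid.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
sig <- grid[grid$p_adjusted <= 0.05, ]
cat(sprintf("Spearman grid: %d/%d correlations significant after BH\n",
            nrow(sig), nrow(grid)))
fry <- sig[sig$scope_cell == "Fryxell" & sig$col == "ec" &
             sig$row %in% phyla, ]
if (nrow(fry)) {
  cat("Fryxell phylum-EC responses (BH-corrected):\n")
  for (i in seq_len(nrow(fry))) {
    cat(sprintf("  %-20s rho = %+.2f\n", fry$row[i], fry$rho[i]))
  }
}

# phylum trade-offs along Fryxell transects
fids <- intersect(ids, meta$sample_id[meta$basin == "Fryxell"])
pairs <- rbind(c("Acidobacteria", "Actinobacteria"),
               c("Bacteroidetes", "Gemmatimonadetes"),
               c("Bacteroidetes", "Proteobacteria"),
               c("Bacteroidetes", "Deinococcus-Thermus"),
               c("Gemmatimonadetes", "Deinococcus-Thermus"))
reg <- phylum_regressions(as.data.frame(pa[fids, ]), pairs)
write.table(reg, "results/phylum_regressions.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("phylum-vs-phylum regressions along Fryxell transects:\n")
print(reg, row.names = FALSE, digits = 3)
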