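#!/usr/bin/env Rscript
# Step 4 — constrained ordination (CCA) at regional and basin scales.
#
# Fits CCA of the rarefied OTU table on {basin, EC, pH, distance from
# trough} regionally and on {EC, pH, distance} per basin, tests model
# significance by permutation, and writes a Table-1-shaped summary plus
# site/species/biplot score TSVs for the regional model.
#
# Needs: results/data from step 01.
# Writes: results/cca_summary.tsv, results/cca_scores_*.tsv

library(soilscape)

seed <- 42L
community <- read_community("results/data/community.tsv")
meta <- read_metadata("results/data/metadata.tsv")
rar <- rarefy(community, depth = 500, seed = substream_seed(seed, "rarefy"))
ids <- rownames(rar$counts)
m <- meta[ids, ]

fit_one <- function(counts, cons, label) {
  rr <- rar; rr$counts <- counts
  fit <- suppressMessages(cca_fit(rr, cons))
  fit <- suppressMessages(cca_permutation_test(
    fit, rr, cons, n_perm = 999,
    seed = substream_seed(seed, paste0("cca:", label))))
  cat(sprintf(paste0("%-9s total inertia %.2f, constrained %.2f (%.0f%%), ",
                     "chi2 %.2f, F %.2f, p %.3f\n"),
              label, fit$total_inertia, fit$constrained_inertia,
              100 * fit$constrained_proportion, fit$model_chi2, fit$model_f,
              fit$model_p))
  data.frame(scope = label, total_inertia = fit$total_inertia,
             constrained_proportion = fit$constrained_proportion,
             unconstrained_proportion = 1 - fit$constrained_proportion,
             model_chi2 = fit$model_chi2, model_f = fit$model_f,
             model_p = fit$model_p)
}

tab <- fit_one(rar$counts, m[, c("basin", "ec", "ph", "dist_from_trough")],
               "regional")
for (b in unique(m$basin)) {
  bids <- m$sample_id[m$basin == b]
  tab <- rbind(tab, fit_one(rar$counts[bids, , drop = FALSE],
                            m[bids, c("ec", "ph", "dist_from_trough")], b))
}
write.table(tab, "results/cca_summary.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

reg <- suppressMessages(cca_fit(rar, m[, c("basin", "ec", "ph",
                                           "dist_from_trough")]))
for (what in c("site_scores", "species_scores", "biplot_scores")) {
  sc <- as.data.frame(reg[[what]])
  sc <- cbind(id = rownames(sc), sc)
  write.table(sc, sprintf("results/cca_scores_%s.tsv",
                          sub("_scores", "", what)),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
cat("wrote results/cca_summary.tsv and score tables\n")
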